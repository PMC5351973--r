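# Genotype/phenotype containers, on-disk round trips, the VCF dialect and
# quality control.

test_that("marker matrix validates shapes, ids and coding ranges", {
  v <- matrix(0:3 %% 3, 2, 2)
  expect_error(marker_matrix(v, plant_ids = "onlyone"), "plant_ids")
  expect_error(marker_matrix(v, marker_ids = c("a", "a")), "duplicate")
  expect_error(marker_matrix(matrix(3, 1, 1)), "0, 2")
  expect_error(marker_matrix(matrix(2, 1, 1), marker_type = "dominant"),
               "0, 1")
  g <- tiny_geno()
  expect_s3_class(g, "marker_matrix")
  expect_equal(dim(g), c(4, 3))
  # imputed fractional codes remain valid
  v2 <- g$values; v2[1, 1] <- 1.25
  expect_s3_class(marker_matrix(v2, g$plant_ids, g$marker_ids,
                                g$marker_type), "marker_matrix")
})

test_that("subsetting works by index and id and preserves marker types", {
  g <- tiny_geno()
  s <- subset_markers(g, plants = c("P2", "P4"), markers = c("M3", "M1"))
  expect_equal(s$plant_ids, c("P2", "P4"))
  expect_equal(s$marker_ids, c("M3", "M1"))
  expect_equal(s$marker_type, c("dominant", "codominant"))
  expect_equal(s$values["P4", "M1"], 1)
  expect_error(subset_markers(g, plants = "nope"), "unknown plant")
})

test_that("dominant markers are doubled onto the dose scale", {
  g <- tiny_geno()
  d <- dose_matrix(g)
  expect_equal(unname(d[, 3]), c(0, 2, 2, 0))   # dominant column 0/1 -> 0/2
  expect_equal(unname(d[, 1]), c(0, 2, 1, 1))   # codominant untouched
  g$values[1, 1] <- NA
  expect_error(dose_matrix(g), "impute")
})

test_that("genotypes survive a write/read round trip", {
  g <- tiny_geno()
  path <- tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, marker_type = g$marker_type)
  expect_equal(g2$values, g$values)
  expect_equal(g2$plant_ids, g$plant_ids)
  expect_equal(g2$marker_ids, g$marker_ids)
  unlink(path)
})

test_that("the VCF dialect maps genotype calls to ALT doses", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT:DP\t1|1:9\t./.:1\t0|1:4",
    "1\t300\trs3\tG\tA,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"), path)
  expect_warning(g <- read_genotypes(path, format = "vcf"), "multiallelic")
  expect_equal(g$plant_ids, c("S1", "S2", "S3"))
  expect_equal(g$marker_ids, c("rs1", "1_200"))  # missing ID -> CHROM_POS
  expect_equal(unname(g$values[, "rs1"]), c(0, 1, 2))
  expect_equal(unname(g$values[, "1_200"]), c(2, NA, 1))
  unlink(path)
})

test_that("malformed VCFs are rejected with clear errors", {
  p1 <- tempfile(); writeLines("##fileformat=VCFv4.2", p1)
  expect_error(read_genotypes(p1, format = "vcf"), "CHROM")
  p2 <- tempfile()
  writeLines(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t1\t.\tA\tG\t.\t.\t."), p2)
  expect_error(read_genotypes(p2, format = "vcf"), "malformed")
  unlink(c(p1, p2))
})

test_that("phenotype tables validate columns and reject duplicates", {
  df <- data.frame(plant_id = "a", experiment = "germplasm", family = "f",
                   block = "B1", trait = "t", value = 1)
  expect_s3_class(phenotype_table(df), "phenotype_table")
  expect_error(phenotype_table(df[, -6]), "missing column")
  expect_error(phenotype_table(transform(df, experiment = "field")),
               "experiment")
  expect_error(phenotype_table(rbind(df, df)), "duplicate")
  expect_error(phenotype_table(transform(df, value = NA)), "non-finite")
  # same plant/trait/block in the *other* experiment is legal
  ok <- rbind(df, transform(df, experiment = "diallel"))
  expect_s3_class(phenotype_table(ok), "phenotype_table")
})

test_that("phenotypes survive a write/read round trip", {
  ph <- two_block_pheno(c(1, 2), c(3, 4))
  path <- tempfile(fileext = ".csv")
  write_phenotypes(ph, path)
  ph2 <- read_phenotypes(path)
  expect_equal(as.data.frame(ph2), as.data.frame(ph))
  unlink(path)
})

test_that("QC filters by dose-scale MAF and mean-imputes the rest", {
  v <- rbind(c(0, 0, 1, NA), c(0, 1, 1, 1), c(0, 2, 0, 1), c(0, 1, 0, 0))
  g <- marker_matrix(v, marker_type = c("codominant", "codominant",
                                        "dominant", "dominant"))
  # M1 monomorphic (maf 0); M3 dominant with dose-scale p = 0.5
  f <- impute_and_filter(g, maf_min = 0.2)
  expect_false("M1" %in% f$marker_ids)
  expect_true(all(c("M2", "M3") %in% f$marker_ids))
  expect_false(anyNA(f$values))
  expect_equal(f$values[1, "M4"], mean(c(1, 1, 0)))  # column mean imputation
  # idempotent
  f2 <- impute_and_filter(f, maf_min = 0.2)
  expect_equal(f2$values, f$values)
})

test_that("QC removes markers with too much missing data", {
  v <- rbind(c(NA, 1), c(NA, 1), c(NA, 2), c(0, 0))
  g <- marker_matrix(v)
  f <- impute_and_filter(g, max_missing = 0.5)
  expect_equal(f$marker_ids, "M2")
  expect_error(impute_and_filter(g, maf_min = 0.6), "maf_min")
  expect_error(impute_and_filter(subset_markers(g, markers = 1),
                                 max_missing = 0.1), "all markers removed")
})

test_that("run configurations load from YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 7", "traits:", "  - GY"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$seed, 7)
  expect_equal(unlist(cfg$traits), "GY")
  expect_error(read_run_config(tempfile()), "not found")
  unlink(path)
})
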