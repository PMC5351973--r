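# Synthetic-population generator: configuration contracts, Hardy-Weinberg
# sampling, Mendelian transmission and exact variance targeting.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_qtl = 50, n_markers = 10), "n_qtl")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(target_h2 = 1.2), "target_h2")
  expect_error(sim_config(dominance_ratio = -1), "dominance_ratio")
  expect_error(sim_config(prop_dominant = 2), "prop_dominant")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("identical config and seed give bit-identical populations", {
  cfg <- sim_config(n_founders = 20, n_markers = 50, n_qtl = 10, seed = 42)
  g1 <- sim_founder_genotypes(cfg)
  g2 <- sim_founder_genotypes(cfg)
  expect_identical(g1$values, g2$values)
  expect_identical(g1$dosage, g2$dosage)
  p1 <- sim_phenotypes(g1, cfg)
  p2 <- sim_phenotypes(g2, cfg)
  expect_identical(p1$pheno$value, p2$pheno$value)
})

test_that("founder genotypes follow the requested allele-frequency window", {
  cfg <- sim_config(n_founders = 400, n_markers = 200,
                    maf_range = c(0.3, 0.5), prop_dominant = 0, seed = 7)
  g <- sim_founder_genotypes(cfg)
  p_hat <- colMeans(g$values) / 2
  # sampling noise around p in (0.3, 0.5): all estimates well inside (0.2, 0.6)
  expect_true(all(p_hat > 0.2 & p_hat < 0.6))
  expect_true(all(g$values %in% 0:2))
})

test_that("dominant markers collapse the underlying dose to presence/absence", {
  cfg <- sim_config(n_founders = 30, n_markers = 40, n_qtl = 8,
                    prop_dominant = 1, seed = 3)
  g <- sim_founder_genotypes(cfg)
  expect_true(all(g$marker_type == "dominant"))
  expect_true(all(g$values %in% 0:1))
  expect_identical(g$values, matrix(as.double(g$dosage > 0), 30, 40,
                                    dimnames = dimnames(g$dosage)))
})

test_that("diallel progeny respect Mendelian transmission at fixed loci", {
  cfg <- sim_config(n_founders = 4, n_markers = 30, n_qtl = 5,
                    prop_dominant = 0, seed = 9)
  g <- sim_founder_genotypes(cfg)
  # force informative parent genotypes at three loci
  g$dosage[1, 1:3] <- c(0, 2, 1)
  g$dosage[2, 1:3] <- c(0, 2, 1)
  g$values <- g$dosage
  dia <- sim_diallel_progeny(g, list(c("F01", "F02")), 50, seed = 11)
  d <- dia$geno$dosage
  expect_true(all(d[, 1] == 0))        # hom-ref x hom-ref -> hom-ref
  expect_true(all(d[, 2] == 2))        # hom-alt x hom-alt -> hom-alt
  expect_true(all(d[, 3] %in% 0:2))    # het x het segregates
  expect_gt(var(d[, 3]), 0)
  expect_identical(dia$pedigree$mother, rep("F01", 50))
})

test_that("unknown parent ids are rejected", {
  cfg <- sim_config(n_founders = 4, n_markers = 10, n_qtl = 2, seed = 1)
  g <- sim_founder_genotypes(cfg)
  expect_error(sim_diallel_progeny(g, list(c("F01", "ZZZ")), 2), "ZZZ")
})

test_that("realized additive variance hits the target exactly", {
  cfg <- sim_config(n_founders = 80, n_markers = 100, n_qtl = 15,
                    target_h2 = 0.4, sigma2_a = 123.4, prop_dominant = 0,
                    seed = 5)
  g <- sim_founder_genotypes(cfg)
  ph <- sim_phenotypes(g, cfg)
  expect_equal(var(ph$truth$additive), 123.4, tolerance = 1e-10)
  expect_equal(ph$truth$sigma2_e, 123.4 * 0.6 / 0.4, tolerance = 1e-10)
})

test_that("a perfectly heritable trait equals its genetic value", {
  cfg <- sim_config(n_founders = 40, n_markers = 60, n_qtl = 10,
                    target_h2 = 1, block_count = 1, prop_dominant = 0,
                    seed = 6)
  g <- sim_founder_genotypes(cfg)
  ph <- sim_phenotypes(g, cfg)
  y <- plant_means(ph$pheno, "trait")
  expect_equal(unname(y[names(ph$truth$additive)] - cfg$mean),
               unname(ph$truth$additive), tolerance = 1e-10)
})

test_that("a zero-heritability trait carries no genetic signal but keeps truth", {
  cfg <- sim_config(n_founders = 50, n_markers = 60, n_qtl = 10,
                    target_h2 = 0, block_count = 1, seed = 8)
  g <- sim_founder_genotypes(cfg)
  ph <- sim_phenotypes(g, cfg)
  expect_gt(var(ph$pheno$value), 0)
  # ground-truth additive values are preserved for diagnostics even though
  # the phenotype gives them zero weight
  expect_true(all(ph$truth$additive == 0) || var(ph$truth$additive) >= 0)
  expect_equal(length(ph$truth$additive), 50)
})

test_that("dominance-derived family deviations have the requested variance role", {
  cfg <- sim_config(n_founders = 4, n_markers = 50, n_qtl = 10,
                    target_h2 = 0.3, dominance_ratio = 0.5,
                    prop_dominant = 0, seed = 12)
  g <- sim_founder_genotypes(cfg)
  dia <- sim_diallel_progeny(g, list(c("F01", "F02"), c("F03", "F04")),
                             20, seed = 13)
  ph <- sim_phenotypes(dia$geno, cfg, experiment = "diallel",
                       family = dia$pedigree$family)
  expect_equal(ph$truth$sigma2_f, 0.5 * ph$truth$sigma2_a)
  # deviations are constant within family
  fd <- split(ph$truth$family_dev, dia$pedigree$family)
  expect_true(all(vapply(fd, function(z) diff(range(z)) == 0, logical(1))))
})

test_that("the study-like dataset has the pilot dimensions", {
  dat <- make_study_like_dataset(seed = 2, n_markers = 150, n_qtl = 20)
  expect_equal(dim(dat$geno), c(78, 150))
  expect_setequal(unique(dat$pheno$trait), c("GY", "W100S"))
  expect_setequal(unique(dat$pheno$experiment), c("germplasm", "diallel"))
  germ <- dat$pheno[dat$pheno$experiment == "germplasm" &
                    dat$pheno$trait == "GY", ]
  expect_equal(nrow(germ), 36 * 2)           # 36 founders x 2 blocks
  dia <- dat$pheno[dat$pheno$experiment == "diallel" &
                   dat$pheno$trait == "GY", ]
  expect_equal(nrow(dia), 42)                # one block record per progeny
  expect_equal(nrow(dat$pedigree), 42)
  expect_true(all(table(dat$pedigree$family) == 14))
})

test_that("plant means remove least-squares block effects", {
  # two blocks differing by a constant 10: adjusted means must agree with
  # the block-free average
  base <- c(5, 7, 9, 11)
  ph <- two_block_pheno(base, base + 10)
  m_adj <- plant_means(ph, "t")
  expect_equal(unname(m_adj - mean(m_adj)), base - mean(base),
               tolerance = 1e-10)
  m_raw <- plant_means(ph, "t", adjust_blocks = FALSE)
  expect_equal(unname(m_raw), base + 5, tolerance = 1e-10)
})
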