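# Input/output and container types for genotype and phenotype data.

#' Construct a marker matrix
#'
#' The central genotype container: an n-plants by m-markers matrix of
#' small-integer codes.  Codominant markers (SNPs) are coded as allele dose
#' 0/1/2; dominant markers (presence/absence scores such as DArTs) as 0/1.
#' Missing genotypes are `NA`.
#'
#' @param values numeric matrix (plants in rows, markers in columns).
#' @param plant_ids character vector of unique plant identifiers.
#' @param marker_ids character vector of unique marker identifiers.
#' @param marker_type character vector, `"codominant"` or `"dominant"` per
#'   marker.
#' @return an object of class `marker_matrix` with fields `values`,
#'   `plant_ids`, `marker_ids`, `marker_type`.
#' @export
marker_matrix <- function(values, plant_ids = rownames(values),
                          marker_ids = colnames(values),
                          marker_type = rep("codominant", ncol(values))) {
  values <- as.matrix(values)
  if (is.null(plant_ids)) plant_ids <- paste0("P", seq_len(nrow(values)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(values)))
  plant_ids <- as.character(plant_ids)
  marker_ids <- as.character(marker_ids)
  if (length(plant_ids) != nrow(values))
    stopf("plant_ids length (%d) != rows (%d)", length(plant_ids), nrow(values))
  if (length(marker_ids) != ncol(values))
    stopf("marker_ids length (%d) != columns (%d)", length(marker_ids), ncol(values))
  if (anyDuplicated(plant_ids)) stopf("duplicate plant ids")
  if (anyDuplicated(marker_ids)) stopf("duplicate marker ids")
  marker_type <- match.arg(marker_type, c("codominant", "dominant"),
                           several.ok = TRUE)
  marker_type <- rep_len(marker_type, ncol(values))
  cod <- values[, marker_type == "codominant", drop = FALSE]
  dom <- values[, marker_type == "dominant", drop = FALSE]
  # raw codes are integers; imputed matrices may carry fractional means,
  # so the container enforces the coding range only
  if (length(cod) && !all(is.na(cod) | (cod >= 0 & cod <= 2)))
    stopf("codominant entries must lie in [0, 2] or be NA")
  if (length(dom) && !all(is.na(dom) | (dom >= 0 & dom <= 1)))
    stopf("dominant entries must lie in [0, 1] or be NA")
  dimnames(values) <- list(plant_ids, marker_ids)
  structure(list(values = values, plant_ids = plant_ids,
                 marker_ids = marker_ids, marker_type = marker_type),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d plants x %d markers (%d codominant, %d dominant), %d missing\n",
              nrow(x$values), ncol(x$values),
              sum(x$marker_type == "codominant"),
              sum(x$marker_type == "dominant"),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$values)

#' Subset a marker matrix by plants and/or markers
#'
#' @param x a [marker_matrix()].
#' @param plants,markers index vectors (integer, logical or id character).
#' @return a `marker_matrix`.
#' @export
subset_markers <- function(x, plants = NULL, markers = NULL) {
  stopifnot(inherits(x, "marker_matrix"))
  pi <- if (is.null(plants)) seq_along(x$plant_ids) else plants
  mi <- if (is.null(markers)) seq_along(x$marker_ids) else markers
  if (is.character(pi)) pi <- match(pi, x$plant_ids)
  if (is.character(mi)) mi <- match(mi, x$marker_ids)
  if (anyNA(pi)) stopf("unknown plant id(s)")
  if (anyNA(mi)) stopf("unknown marker id(s)")
  marker_matrix(x$values[pi, mi, drop = FALSE],
                x$plant_ids[pi], x$marker_ids[mi], x$marker_type[mi])
}

#' Allele-dose matrix of a marker matrix
#'
#' Converts stored codes to a common dose scale: codominant markers stay
#' 0/1/2; dominant presence/absence markers are mapped 0/1 -> 0/2 so that a
#' single centered-matrix code path serves the relationship-matrix and
#' regression machinery.
#'
#' @param geno a [marker_matrix()]; must not contain missing values (run
#'   [impute_and_filter()] first).
#' @return numeric matrix of doses.
#' @export
dose_matrix <- function(geno) {
  stopifnot(inherits(geno, "marker_matrix"))
  v <- geno$values
  if (anyNA(v)) stopf("missing genotypes present; impute first")
  dom <- geno$marker_type == "dominant"
  if (any(dom)) v[, dom] <- 2 * v[, dom]
  v
}

#' Read a genotype matrix from disk
#'
#' Two dialects are supported.  The canonical interchange format is a
#' tab-delimited table with one row per plant, a `plant_id` first column and
#' one column per marker.  VCF (v4.2, read-only) is an optional convenience:
#' biallelic records are mapped to ALT-allele dose (GT `0/0`->0, `0/1`->1,
#' `1/1`->2, `./.`->NA); multiallelic records are skipped with a warning.
#'
#' @param path file path.
#' @param format `"delimited"` or `"vcf"`.
#' @param marker_type per-marker types for the delimited dialect (recycled);
#'   VCF markers are always codominant.
#' @return a [marker_matrix()].
#' @export
read_genotypes <- function(path, format = c("delimited", "vcf"),
                           marker_type = "codominant") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "delimited") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1))
    if (ncol(dt) < 2) stopf("no marker columns in %s", path)
    ids <- dt[[1]]
    vals <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    marker_matrix(vals, ids, colnames(dt)[-1], marker_type)
  } else {
    read_genotypes_vcf(path)
  }
}

#' @keywords internal
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1) stopf("malformed VCF: missing #CHROM header")
  cols <- strsplit(sub("^#", "", hdr), "\t")[[1]]
  if (length(cols) < 10) stopf("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  vals <- matrix(NA_real_, nrow = length(samples), ncol = 0)
  ids <- character(0)
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1]]
    if (length(f) != length(cols))
      stopf("malformed VCF record at data line %d", i)
    if (grepl(",", f[5], fixed = TRUE)) {
      warnf("skipping multiallelic VCF record at data line %d (%s)", i, f[3])
      next
    }
    gt_idx <- match("GT", strsplit(f[9], ":")[[1]])
    if (is.na(gt_idx)) stopf("no GT field at data line %d", i)
    gts <- vapply(f[-(1:9)], function(s) strsplit(s, ":")[[1]][gt_idx], "")
    dose <- vapply(gts, function(g) {
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_real_)
      sum(al == "1")
    }, 0.0, USE.NAMES = FALSE)
    vals <- cbind(vals, dose)
    ids <- c(ids, if (f[3] == ".") paste0(f[1], "_", f[2]) else f[3])
  }
  marker_matrix(vals, samples, ids, "codominant")
}

#' Write a genotype matrix as tab-delimited text
#'
#' @param geno a [marker_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "marker_matrix"))
  dt <- data.table::data.table(plant_id = geno$plant_ids)
  dt <- cbind(dt, data.table::as.data.table(geno$values))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Phenotype table constructor/validator
#'
#' Long-format plant-level records.  Columns: `plant_id`, `experiment`
#' (`"germplasm"` or `"diallel"`), `family`, `block`, `replicate`
#' (within-plot repetition label; defaults to `1` when absent), `trait`,
#' `value`.  Several replicates of the same plant in the same block are
#' what identify the block-by-genotype plot variance component.
#'
#' @param df a data.frame with those columns (`replicate` optional).
#' @return the validated data.frame with class `phenotype_table` prepended.
#' @export
phenotype_table <- function(df) {
  if (!("replicate" %in% names(df))) df$replicate <- 1L
  need <- c("plant_id", "experiment", "family", "block", "replicate",
            "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("phenotype table missing column(s): %s",
                          paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$plant_id <- as.character(df$plant_id)
  df$experiment <- as.character(df$experiment)
  if (!all(df$experiment %in% c("germplasm", "diallel")))
    stopf("experiment must be 'germplasm' or 'diallel'")
  df$family <- as.character(df$family)
  df$block <- as.character(df$block)
  df$replicate <- as.character(df$replicate)
  df$trait <- as.character(df$trait)
  if (!all(is.finite(df$value))) stopf("non-finite phenotype values")
  key <- paste(df$experiment, df$plant_id, df$trait, df$block, df$replicate)
  if (anyDuplicated(key))
    stopf("duplicate (plant, trait, block, replicate) record(s) within an experiment")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read/write phenotype tables (CSV)
#'
#' @param path file path.
#' @return [read_phenotypes()] returns a [phenotype_table()];
#'   [write_phenotypes()] returns `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  phenotype_table(data.table::fread(path, header = TRUE))
}

#' @rdname read_phenotypes
#' @param pheno a [phenotype_table()].
#' @export
write_phenotypes <- function(pheno, path) {
  data.table::fwrite(as.data.frame(pheno), path)
  invisible(path)
}

#' Marker quality control: filter and mean-impute
#'
#' Removes markers whose minor-allele frequency falls below `maf_min` or
#' whose missing-data proportion exceeds `max_missing`, then replaces any
#' remaining missing entries by the marker's mean observed code.  With the
#' defaults (`maf_min = 0`, `max_missing = 1`) no marker is removed and the
#' panel mirrors an all-markers analysis.  Idempotent.
#'
#' @param geno a [marker_matrix()].
#' @param maf_min minimum minor-allele frequency in `[0, 0.5]`.
#' @param max_missing maximum missing proportion in `[0, 1]`.
#' @param verbose log a summary of removed markers.
#' @return a filtered, fully imputed `marker_matrix`.  Imputed entries are
#'   fractional means on the stored coding scale.
#' @export
impute_and_filter <- function(geno, maf_min = 0, max_missing = 1,
                              verbose = FALSE) {
  stopifnot(inherits(geno, "marker_matrix"))
  if (maf_min < 0 || maf_min > 0.5) stopf("maf_min must be in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1) stopf("max_missing must be in [0, 1]")
  v <- geno$values
  miss_prop <- colMeans(is.na(v))
  # allele frequency on the dose scale (dominant 0/1 -> 0/2)
  mult <- ifelse(geno$marker_type == "dominant", 2, 1)
  p <- colMeans(sweep(v, 2, mult, `*`), na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- maf >= maf_min & miss_prop <= max_missing
  # strictly-below-threshold removal for MAF: monomorphic (maf 0) removed
  # whenever maf_min > 0
  if (maf_min > 0) keep <- maf > 0 & keep
  if (!any(keep)) stopf("all markers removed by QC filters")
  if (verbose && any(!keep))
    gwsel_log(sprintf("QC removed %d/%d markers (maf < %g or missing > %g)",
                      sum(!keep), length(keep), maf_min, max_missing))
  v <- v[, keep, drop = FALSE]
  if (anyNA(v)) {
    mu <- colMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mu[idx[, 2]]
  }
  out <- geno
  out$values <- v
  out$marker_ids <- geno$marker_ids[keep]
  out$marker_type <- geno$marker_type[keep]
  dimnames(out$values) <- list(out$plant_ids, out$marker_ids)
  out
}

#' Read a flat key/value run configuration (YAML)
#'
#' @param path YAML file with scalar keys (chain lengths, fold counts, seeds,
#'   thresholds, paths).
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stopf("config must be a key/value mapping")
  cfg
}
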