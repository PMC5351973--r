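# Synthetic half-sib / diallel populations with known genetic architecture.
#
# Every downstream stage (REML, whole-genome regression, cross-validation,
# marker-density curves) is exercised against data from this generator, so
# its defaults mirror the study dimensions: 36 germplasm half-sib founders,
# 3 full-sib diallel families of 14 progeny, 1,248 markers, and target
# narrow-sense heritabilities of 0.27 (grain yield) and 0.35 (weight of
# 100 seeds).

#' Simulation configuration
#'
#' @param n_founders number of germplasm (half-sib) founder plants.
#' @param n_halfsib_plants phenotyped plants per founder family in the
#'   germplasm design (per block).
#' @param diallel_families number of full-sib families in the diallel.
#' @param progeny_per_family progeny per full-sib family.
#' @param n_markers marker panel size.
#' @param n_qtl number of causal loci (subset of the markers).
#' @param maf_range allele-frequency range `(lo, hi]` within `(0, 0.5]` from
#'   which founder frequencies are drawn uniformly.
#' @param target_h2 narrow-sense heritability
#'   `h2 = sigma_a^2 / (sigma_a^2 + sigma_f^2 + sigma_e^2)` the phenotype
#'   simulator realizes (block effects are design nuisance on top).
#' @param dominance_ratio `sigma_f^2 / sigma_a^2`, the family (dominance)
#'   variance of the diallel relative to the additive variance.
#' @param prop_dominant proportion of markers scored as dominant
#'   presence/absence (DArT-like); the remainder are codominant SNPs.
#' @param block_count number of blocks.
#' @param block_sd standard deviation of block effects, in trait units.
#' @param missing_rate proportion of genotype calls set missing (exercises
#'   imputation; default 0).
#' @param mean trait mean, in trait units.
#' @param sigma2_a additive genetic variance, in squared trait units.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders = 36, n_halfsib_plants = 1,
                       diallel_families = 3, progeny_per_family = 14,
                       n_markers = 1248, n_qtl = 100,
                       maf_range = c(0.05, 0.5), target_h2 = 0.3,
                       dominance_ratio = 0, prop_dominant = 0.5,
                       block_count = 2, block_sd = 0, missing_rate = 0,
                       mean = 100, sigma2_a = 100, seed = 1L) {
  cfg <- list(n_founders = n_founders, n_halfsib_plants = n_halfsib_plants,
              diallel_families = diallel_families,
              progeny_per_family = progeny_per_family,
              n_markers = n_markers, n_qtl = n_qtl, maf_range = maf_range,
              target_h2 = target_h2, dominance_ratio = dominance_ratio,
              prop_dominant = prop_dominant, block_count = block_count,
              block_sd = block_sd, missing_rate = missing_rate,
              mean = mean, sigma2_a = sigma2_a, seed = as.integer(seed))
  for (f in c("n_founders", "n_markers", "block_count"))
    if (!is_count(cfg[[f]])) stopf("%s must be a positive integer", f)
  if (!is.numeric(cfg$n_qtl) || cfg$n_qtl < 0 || cfg$n_qtl > cfg$n_markers)
    stopf("n_qtl must be in [0, n_markers]")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stopf("maf_range must be within (0, 0.5] with lo <= hi")
  if (target_h2 < 0 || target_h2 > 1) stopf("target_h2 must be in [0, 1]")
  if (dominance_ratio < 0) stopf("dominance_ratio must be >= 0")
  if (prop_dominant < 0 || prop_dominant > 1)
    stopf("prop_dominant must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate founder genotypes under Hardy-Weinberg equilibrium
#'
#' Each marker gets an allele frequency drawn uniformly within
#' `cfg$maf_range`; founder genotypes are then drawn per marker from the
#' Hardy-Weinberg genotype distribution.  Markers are independent (no
#' linkage map is simulated; the downstream analysis never uses positions).
#' A `prop_dominant` fraction of markers is scored dominant: the underlying
#' diploid dose is kept in the `dosage` field (the simulator's ground truth)
#' while the observed code collapses to presence/absence of the minor allele.
#'
#' @param cfg a [sim_config()].
#' @return a [marker_matrix()] with extra fields `dosage` (underlying 0/1/2
#'   doses) and `freq` (simulated allele frequencies).
#' @export
sim_founder_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  m <- cfg$n_markers; n <- cfg$n_founders
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  dose <- vapply(seq_len(m), function(j)
    rbinom(n, 2L, p[j]), integer(n))
  dose <- matrix(as.double(dose), nrow = n)
  n_dom <- round(cfg$prop_dominant * m)
  type <- rep("codominant", m)
  if (n_dom > 0) type[sample.int(m, n_dom)] <- "dominant"
  obs <- dose
  dom <- type == "dominant"
  if (any(dom)) obs[, dom] <- as.double(dose[, dom] > 0)
  if (cfg$missing_rate > 0) {
    drop <- runif(length(obs)) < cfg$missing_rate
    obs[drop] <- NA_real_
  }
  ids <- sprintf("F%02d", seq_len(n))
  mk <- sprintf("M%04d", seq_len(m))
  out <- marker_matrix(obs, ids, mk, type)
  out$dosage <- matrix(dose, n, m, dimnames = list(ids, mk))
  out$freq <- p
  out
}

#' Simulate diallel progeny by Mendelian gamete sampling
#'
#' Each progeny receives, at every marker independently (no linkage), one
#' allele sampled from each parent's underlying diploid genotype.  Dominant
#' markers are re-scored from the progeny dose.
#'
#' @param founders a [marker_matrix()] carrying a `dosage` field (as produced
#'   by [sim_founder_genotypes()]).
#' @param parent_pairs list of length-2 character vectors of parent plant
#'   ids, one per family.
#' @param progeny_per_family progeny per cross.
#' @param seed integer seed.
#' @return a list with `geno` (a `marker_matrix` of all progeny, with
#'   `dosage`) and `pedigree` (data.frame plant_id, family, mother, father).
#' @export
sim_diallel_progeny <- function(founders, parent_pairs, progeny_per_family,
                                seed = 1L) {
  stopifnot(inherits(founders, "marker_matrix"))
  if (is.null(founders$dosage))
    stopf("founders must carry underlying doses (field 'dosage')")
  set.seed(as.integer(seed))
  m <- ncol(founders$values)
  ped <- NULL
  prog <- NULL
  for (k in seq_along(parent_pairs)) {
    pr <- as.character(parent_pairs[[k]])
    idx <- match(pr, founders$plant_ids)
    if (anyNA(idx)) stopf("unknown parent id(s): %s",
                          paste(pr[is.na(idx)], collapse = ", "))
    d1 <- founders$dosage[idx[1], ]
    d2 <- founders$dosage[idx[2], ]
    for (i in seq_len(progeny_per_family)) {
      # gamete allele count: hom 0 -> 0, het -> Bernoulli(1/2), hom 2 -> 1
      g1 <- ifelse(d1 == 1, rbinom(m, 1L, 0.5), d1 / 2)
      g2 <- ifelse(d2 == 1, rbinom(m, 1L, 0.5), d2 / 2)
      prog <- rbind(prog, g1 + g2)
      ped <- rbind(ped, data.frame(
        plant_id = sprintf("D%d_%02d", k, i),
        family = sprintf("FS%d", k), mother = pr[1], father = pr[2],
        stringsAsFactors = FALSE))
    }
  }
  obs <- prog
  dom <- founders$marker_type == "dominant"
  if (any(dom)) obs[, dom] <- as.double(prog[, dom] > 0)
  geno <- marker_matrix(obs, ped$plant_id, founders$marker_ids,
                        founders$marker_type)
  geno$dosage <- matrix(prog, nrow(prog), m,
                        dimnames = list(ped$plant_id, founders$marker_ids))
  list(geno = geno, pedigree = ped)
}

#' Simulate phenotypes from a known genetic architecture
#'
#' A set of `cfg$n_qtl` markers is sampled as causal loci; additive allele
#' effects are drawn standard normal and rescaled so the realized additive
#' variance equals `cfg$sigma2_a` exactly.  Family (dominance-derived)
#' deviations, when `cfg$dominance_ratio > 0` and a `family` column is
#' supplied, are drawn at family level with variance
#' `dominance_ratio * sigma2_a`.  The residual variance is solved from
#' `target_h2 = sigma_a^2 / (sigma_a^2 + sigma_f^2 + sigma_e^2)`; block
#' effects (`block_sd`) are added on top as design nuisance.  Each plant gets
#' one record per block.
#'
#' @param geno a [marker_matrix()]; underlying doses (`dosage` field) are
#'   used for the causal loci when present, observed codes otherwise.
#' @param cfg a [sim_config()]; fields used: `n_qtl`, `target_h2`,
#'   `dominance_ratio`, `block_count`, `block_sd`, `mean`, `sigma2_a`, `seed`.
#' @param experiment `"germplasm"` or `"diallel"` label for the records.
#' @param family optional per-plant family ids (defaults: each plant its own
#'   half-sib family).
#' @param trait trait name for the records.
#' @param qtl optional causal architecture to reuse (the `truth$qtl`
#'   data.frame from a previous call): the same markers and effects are
#'   applied to this genotype set instead of sampling a new set, so that
#'   one trait keeps one architecture across experiments; the realized
#'   additive variance is then a property of the genotypes, not a target.
#' @return list with `pheno` (a [phenotype_table()]) and `truth` (list:
#'   `additive` per-plant additive values, `family_dev` per-plant family
#'   deviations, `qtl` data.frame of causal markers and effects,
#'   `sigma2_a`, `sigma2_f`, `sigma2_e`).
#' @export
sim_phenotypes <- function(geno, cfg, experiment = "germplasm",
                           family = NULL, trait = "trait", qtl = NULL) {
  stopifnot(inherits(geno, "marker_matrix"), inherits(cfg, "sim_config"))
  if (cfg$n_qtl > ncol(geno$values)) stopf("n_qtl exceeds marker count")
  set.seed(derive_seed(cfg$seed, 2L, nchar(trait)))
  n <- nrow(geno$values)
  dose <- if (!is.null(geno$dosage)) geno$dosage else {
    if (anyNA(geno$values)) stopf("missing genotypes and no dosage field")
    dose_matrix(geno)
  }
  if (is.null(family)) family <- paste0("HS_", geno$plant_ids)
  h2 <- cfg$target_h2

  a <- rep(0, n)
  sigma2_a <- 0
  if (!is.null(qtl)) {
    qidx <- match(qtl$marker_id, geno$marker_ids)
    if (anyNA(qidx)) stopf("qtl marker(s) not in the genotype panel")
    eff <- qtl$effect
    a <- as.numeric(scale(dose[, qidx, drop = FALSE] %*% eff,
                          scale = FALSE))
    sigma2_a <- var(a)
    if (sigma2_a <= 0) stopf("degenerate causal set: zero additive variance")
  } else if (cfg$n_qtl > 0 && h2 > 0) {
    qidx <- sort(sample.int(ncol(dose), cfg$n_qtl))
    eff <- rnorm(cfg$n_qtl)
    a_raw <- drop(dose[, qidx, drop = FALSE] %*% eff)
    va <- var(a_raw)
    if (va <= 0) stopf("degenerate causal set: zero additive variance")
    sc <- sqrt(cfg$sigma2_a / va)
    eff <- eff * sc
    a <- as.numeric(scale(dose[, qidx, drop = FALSE] %*% eff, scale = FALSE))
    sigma2_a <- cfg$sigma2_a
    qtl <- data.frame(marker_id = geno$marker_ids[qidx], effect = eff,
                      stringsAsFactors = FALSE)
  }
  sigma2_f <- cfg$dominance_ratio * sigma2_a
  fam_levels <- unique(family)
  f_dev <- rep(0, n)
  if (sigma2_f > 0) {
    fe <- rnorm(length(fam_levels), 0, sqrt(sigma2_f))
    f_dev <- fe[match(family, fam_levels)]
  }
  a_in_pheno <- a
  if (h2 >= 1) {
    sigma2_e <- 0
  } else if (h2 <= 0) {
    # pure-noise trait: the additive values remain as ground truth but get
    # zero weight in the phenotype (h2 = 0 is the limit sigma_e -> Inf)
    a_in_pheno <- rep(0, n); f_dev <- rep(0, n); sigma2_f <- 0
    sigma2_e <- max(cfg$sigma2_a, 1)  # noise on the trait scale
  } else {
    sigma2_e <- sigma2_a * (1 - h2) / h2 - sigma2_f
    if (sigma2_e < 0)
      stopf("target_h2 = %g unreachable with dominance_ratio = %g",
            h2, cfg$dominance_ratio)
  }
  blocks <- sprintf("B%d", seq_len(cfg$block_count))
  b_eff <- if (cfg$block_sd > 0) rnorm(cfg$block_count, 0, cfg$block_sd)
           else rep(0, cfg$block_count)
  recs <- NULL
  for (b in seq_along(blocks)) {
    e <- if (sigma2_e > 0) rnorm(n, 0, sqrt(sigma2_e)) else rep(0, n)
    recs <- rbind(recs, data.frame(
      plant_id = geno$plant_ids, experiment = experiment, family = family,
      block = blocks[b], trait = trait,
      value = cfg$mean + b_eff[b] + a_in_pheno + f_dev + e,
      stringsAsFactors = FALSE))
  }
  list(pheno = phenotype_table(recs),
       truth = list(additive = setNames(a, geno$plant_ids),
                    family_dev = setNames(f_dev, geno$plant_ids),
                    qtl = qtl, sigma2_a = sigma2_a, sigma2_f = sigma2_f,
                    sigma2_e = sigma2_e))
}

#' Build a study-like dataset
#'
#' Emulates the dimensions of the pilot assessment this package is designed
#' around: 36 germplasm half-sib founders plus 42 diallel progeny (3 full-sib
#' families x 14) genotyped at 1,248 markers (half DArT-like dominant), with
#' two traits -- grain yield `GY` (target h2 0.27) and weight of 100 seeds
#' `W100S` (target h2 0.35) -- under 2 germplasm blocks and 5 diallel blocks.
#'
#' @param seed integer master seed.
#' @param n_markers marker panel size (default 1248; smaller panels are
#'   useful for quick runs).
#' @param n_qtl causal loci per trait.
#' @return list with `geno` (78-plant [marker_matrix()]), `pheno` (a
#'   [phenotype_table()] with both traits and experiments), `pedigree`, and
#'   `truth` (per trait).
#' @export
make_study_like_dataset <- function(seed = 1L, n_markers = 1248,
                                    n_qtl = 100) {
  traits <- list(GY = list(h2 = 0.27, mean = 750, sigma2_a = 9600),
                 W100S = list(h2 = 0.35, mean = 55, sigma2_a = 19))
  base <- sim_config(n_founders = 36, n_markers = n_markers, n_qtl = n_qtl,
                     seed = derive_seed(seed, 10L))
  founders <- sim_founder_genotypes(base)
  set.seed(derive_seed(seed, 11L))
  # three contrasting founders crossed pairwise (complete diallel of 3)
  parents <- sample(founders$plant_ids, 3)
  pairs <- list(parents[c(1, 2)], parents[c(1, 3)], parents[c(2, 3)])
  dia <- sim_diallel_progeny(founders, pairs, 14,
                             seed = derive_seed(seed, 12L))
  geno <- marker_matrix(rbind(founders$values, dia$geno$values),
                        c(founders$plant_ids, dia$geno$plant_ids),
                        founders$marker_ids, founders$marker_type)
  geno$dosage <- rbind(founders$dosage, dia$geno$dosage)
  pheno <- NULL; truth <- list()
  for (tn in names(traits)) {
    tt <- traits[[tn]]
    cfg_g <- sim_config(n_founders = 36, n_markers = n_markers,
                        n_qtl = n_qtl, target_h2 = tt$h2,
                        block_count = 2, block_sd = sqrt(tt$sigma2_a) / 2,
                        mean = tt$mean, sigma2_a = tt$sigma2_a,
                        seed = derive_seed(seed, 13L, match(tn, names(traits))))
    ph_g <- sim_phenotypes(subset_geno_with_dosage(geno, founders$plant_ids),
                           cfg_g, "germplasm", trait = tn)
    cfg_d <- sim_config(n_founders = 36, n_markers = n_markers,
                        n_qtl = n_qtl, target_h2 = tt$h2,
                        dominance_ratio = 0.5, block_count = 5,
                        block_sd = sqrt(tt$sigma2_a) / 2, mean = tt$mean,
                        sigma2_a = tt$sigma2_a,
                        seed = derive_seed(seed, 14L, match(tn, names(traits))))
    # the diallel measures the same trait: reuse the causal architecture
    ph_d <- sim_phenotypes(subset_geno_with_dosage(geno, dia$geno$plant_ids),
                           cfg_d, "diallel", family = dia$pedigree$family,
                           trait = tn, qtl = ph_g$truth$qtl)
    # diallel plants are physically present in a single block each
    pd <- ph_d$pheno
    blk_of <- sprintf("B%d", (seq_len(42) - 1) %% 5 + 1)
    pd <- pd[pd$block == blk_of[match(pd$plant_id, dia$geno$plant_ids)], ]
    pheno <- rbind(pheno, as.data.frame(ph_g$pheno), as.data.frame(pd))
    truth[[tn]] <- list(germplasm = ph_g$truth, diallel = ph_d$truth)
  }
  list(geno = geno, pheno = phenotype_table(pheno), pedigree = dia$pedigree,
       truth = truth)
}

#' @keywords internal
subset_geno_with_dosage <- function(geno, plants) {
  out <- subset_markers(geno, plants = plants)
  if (!is.null(geno$dosage))
    out$dosage <- geno$dosage[match(plants, geno$plant_ids), , drop = FALSE]
  out
}

#' Plant-level trait values for whole-genome regression
#'
#' Collapses a phenotype table to one value per plant for a trait: the mean
#' over a plant's records, optionally adjusted for block fixed effects
#' (block effects estimated by least squares across all records of the
#' trait, then removed before averaging).  This is the `y` that the
#' regression models and cross-validation consume.
#'
#' @param pheno a [phenotype_table()].
#' @param trait trait name.
#' @param adjust_blocks remove least-squares block effects first (default
#'   TRUE).
#' @param experiment optional filter to one experiment.
#' @return named numeric vector (names = plant ids).
#' @export
plant_means <- function(pheno, trait, adjust_blocks = TRUE,
                        experiment = NULL) {
  df <- as.data.frame(pheno)
  df <- df[df$trait == trait, ]
  if (!is.null(experiment)) df <- df[df$experiment %in% experiment, ]
  if (!nrow(df)) stopf("no records for trait '%s'", trait)
  if (adjust_blocks) {
    grp <- interaction(df$experiment, df$block, drop = TRUE)
    if (nlevels(grp) > 1) {
      fit <- lm(value ~ grp, data = transform(df, grp = grp))
      df$value <- mean(df$value) + residuals(fit)
    }
  }
  out <- tapply(df$value, df$plant_id, mean)
  setNames(as.numeric(out), names(out))
}
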