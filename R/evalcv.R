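# k-fold cross-validation machinery and the prediction-ability statistic.

#' Random balanced cross-validation folds
#'
#' Partitions plants into `n_folds` disjoint, exhaustive folds whose sizes
#' differ by at most one, independently for each repeat.  Deterministic
#' under `seed`.
#'
#' @param plant_ids character vector of plant ids.
#' @param n_folds folds per repeat (study default 5).
#' @param n_repeats number of repeated randomizations.
#' @param seed integer seed.
#' @param stratify_by optional per-plant grouping (e.g. family) for
#'   stratified fold assignment.
#' @return a `cv_plan`: list with `assignment` (matrix n_plants x
#'   n_repeats of fold indices), `plant_ids`, `n_folds`, `n_repeats`,
#'   `seed`.
#' @export
make_folds <- function(plant_ids, n_folds = 5, n_repeats = 1, seed = 1L,
                       stratify_by = NULL) {
  n <- length(plant_ids)
  if (n_folds < 2) stopf("n_folds must be >= 2")
  if (n_folds > n) stopf("n_folds (%d) exceeds number of plants (%d)",
                         n_folds, n)
  if (!is.null(stratify_by) && length(stratify_by) != n)
    stopf("stratify_by must have one entry per plant")
  assignment <- matrix(NA_integer_, n, n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, 101L, r))
    if (is.null(stratify_by)) {
      assignment[, r] <- sample(rep_len(seq_len(n_folds), n))
    } else {
      for (g in split(seq_len(n), stratify_by)) {
        k <- length(g)
        assignment[g, r] <- sample(rep_len(sample(n_folds), k))
      }
    }
  }
  rownames(assignment) <- plant_ids
  structure(list(assignment = assignment, plant_ids = plant_ids,
                 n_folds = n_folds, n_repeats = n_repeats,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Prediction ability
#'
#' The Pearson correlation between predicted genetic values (GEBVs) and
#' observed phenotypic values in a validation set.
#'
#' @param gebv predicted genetic values.
#' @param y_observed observed phenotypes (same length, >= 3).
#' @return the sample Pearson correlation; `NA` (with a warning) when
#'   either input has zero variance.
#' @export
prediction_ability <- function(gebv, y_observed) {
  if (length(gebv) != length(y_observed)) stopf("length mismatch")
  if (length(gebv) < 3) stopf("need at least 3 pairs")
  if (sd(gebv) < 1e-12 || sd(y_observed) < 1e-12) {
    warnf("zero variance in GEBV or phenotype: prediction ability undefined")
    return(NA_real_)
  }
  cor(gebv, y_observed)
}

#' Cross-validated comparison of whole-genome regression methods
#'
#' For every method, repeat and fold: fit on the training plants only
#' (validation phenotypes masked; allele-frequency centering computed on
#' the training fold, so no information leaks), predict validation GEBVs,
#' and score prediction ability.  Folds whose fit fails are recorded as
#' failed and excluded from aggregates; folds with undefined correlations
#' are excluded (not zero-imputed).
#'
#' @param geno an imputed [marker_matrix()].
#' @param y named phenotype vector (plant-level values, e.g. from
#'   [plant_means()]).
#' @param methods a list of [wgr_spec()] objects (or a single one).
#' @param plan a [make_folds()] plan over the phenotyped plants.
#' @return a `cv_result`: `folds` (long data.frame: method, repeat, fold,
#'   n_valid, ability), `summary` (per method: mean ability, SE over
#'   fold-level values, mean training-fit `h2_hat`, failure count).
#' @export
cross_validate <- function(geno, y, methods, plan) {
  stopifnot(inherits(geno, "marker_matrix"), inherits(plan, "cv_plan"))
  if (inherits(methods, "wgr_spec")) methods <- list(methods)
  y <- align_y(y, plan$plant_ids)
  if (anyNA(y)) stopf("cv plan includes plants without phenotypes")
  idx <- match(plan$plant_ids, geno$plant_ids)
  if (anyNA(idx)) stopf("cv plan includes plants not in the genotype matrix")
  geno <- subset_markers(geno, plants = idx)
  rows <- list(); h2s <- list()
  for (mi in seq_along(methods)) {
    spec <- methods[[mi]]
    mname <- spec$method
    for (r in seq_len(plan$n_repeats)) {
      fold_of <- plan$assignment[, r]
      for (f in seq_len(plan$n_folds)) {
        val <- which(fold_of == f)
        ymask <- y
        ymask[val] <- NA
        sp <- spec
        sp$seed <- derive_seed(spec$seed, 7L, mi, r, f)
        fit <- tryCatch(fit_wgr(ymask, geno, sp), error = function(e) e)
        if (inherits(fit, "error")) {
          rows[[length(rows) + 1]] <- data.frame(
            method = mname, rep = r, fold = f, n_valid = length(val),
            ability = NA_real_, failed = TRUE)
          next
        }
        r_ab <- suppressWarnings(
          prediction_ability(fit$gebv[plan$plant_ids[val]], y[val]))
        rows[[length(rows) + 1]] <- data.frame(
          method = mname, rep = r, fold = f, n_valid = length(val),
          ability = r_ab, failed = FALSE)
        h2s[[length(h2s) + 1]] <- data.frame(method = mname,
                                             h2 = fit$h2_hat %||% NA_real_)
      }
    }
  }
  folds <- do.call(rbind, rows)
  h2df <- if (length(h2s)) do.call(rbind, h2s) else
    data.frame(method = character(), h2 = numeric())
  summ <- do.call(rbind, lapply(split(folds, folds$method), function(d) {
    ok <- d[!d$failed & !is.na(d$ability), ]
    data.frame(method = d$method[1],
               ability_mean = mean(ok$ability),
               ability_se = sd(ok$ability) / sqrt(nrow(ok)),
               n_folds_used = nrow(ok),
               n_failed = sum(d$failed),
               h2_hat_mean = mean(h2df$h2[h2df$method == d$method[1]],
                                  na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  structure(list(folds = folds, summary = summ, plan = plan),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:\n")
  print(x$summary, digits = 3)
  invisible(x)
}
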