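# Marker-density study: backward elimination of smallest-effect markers
# with repeated cross-validation, producing prediction-ability and
# heritability curves as a function of the marker count.

#' Rank markers by absolute effect size
#'
#' Ascending order of `|beta|` (smallest effect first); ties broken by
#' marker id (lexicographic) for determinism, and the ordering is invariant
#' to sign flips of the effects.
#'
#' @param beta named numeric vector of marker effects.
#' @return character vector of marker ids, smallest absolute effect first.
#' @export
rank_markers <- function(beta) {
  if (!all(is.finite(beta))) stopf("non-finite marker effects")
  if (is.null(names(beta))) names(beta) <- paste0("M", seq_along(beta))
  names(beta)[order(abs(beta), names(beta))]
}

#' Backward elimination over marker density
#'
#' Two linked computations produce the density curve.
#'
#' \strong{Elimination path (full data).} Starting from the full panel, a
#' model is fitted to all phenotyped plants at the current marker count;
#' its genomic heritability and variance components are recorded, marker
#' effects are backsolved, and the smallest-`|effect|` marker (or a
#' schedule-defined batch) is dropped, down to `min_markers`.  This is the
#' classic stepwise procedure and yields the retained-marker sets
#' (checkpoints) and the per-count variance components.
#'
#' \strong{Prediction ability (nested cross-validation).} Ability at each
#' recorded count is measured so that no phenotype information flows from
#' validation plants into marker selection: within every fold of every
#' repeat, markers are ranked by a model fitted to the training plants
#' only (`rank_spec`), the top-count subset is refitted on the training
#' plants, and validation plants are predicted from that fit.  Ranking on
#' the full data instead would let the selected subsets encode the
#' validation phenotypes and inflate the curve -- a pure-noise trait would
#' show spuriously high ability at intermediate counts (see the vignette);
#' with nested selection it stays flat at zero.
#'
#' When `spec` is `gblup` or `rrblup` the per-count training fits use the
#' equivalent ridge solution with the shrinkage implied by the training
#' fold's full-panel heritability estimate (one variance-component
#' estimation per fold rather than one per count); other methods are
#' refitted in full at every count.
#'
#' @param geno an imputed [marker_matrix()].
#' @param y named phenotype vector.
#' @param spec a [wgr_spec()] for the per-count fits (study setting:
#'   `gblup`, the fastest of the models).
#' @param reps CV repeats per marker count (study setting: 50); `reps = 0`
#'   skips the ability measurement (path and variance components only).
#' @param n_folds folds (study setting: 5).
#' @param schedule `"every"` drops one marker per step (the study's exact
#'   procedure); a numeric fraction in (0, 1) drops that proportion
#'   (at least one marker) per step, a documented fast mode for large
#'   panels.
#' @param seed master seed; all fold and fit seeds derive from it.
#' @param rank_spec a [wgr_spec()] for the within-fold ranking fits
#'   (default: `spec`).  A spike-slab model such as `bayesCpi` separates
#'   many small equal effects from noise markers better than ridge
#'   backsolving.
#' @param min_markers smallest marker count the elimination descends to
#'   (default 2).
#' @param checkpoint_counts marker counts at which the retained-marker list
#'   is stored.
#' @param verbose log progress.
#' @return a `density_curve`: `records` data.frame (marker_count,
#'   ability_mean, ability_se, h2_hat, sigma2_g, sigma2_e, failed),
#'   `checkpoints` (named list of retained marker ids), `final_markers`,
#'   `seed`, `schedule`.
#' @export
backward_elimination <- function(geno, y, spec = wgr_spec("gblup"),
                                 reps = 50, n_folds = 5, schedule = "every",
                                 seed = 1L, rank_spec = NULL,
                                 min_markers = 2L,
                                 checkpoint_counts = integer(0),
                                 verbose = FALSE) {
  stopifnot(inherits(geno, "marker_matrix"))
  if (ncol(geno$values) < 2) stopf("need at least 2 markers")
  if (min_markers < 2) stopf("min_markers must be >= 2")
  if (is.null(rank_spec)) rank_spec <- spec
  y <- align_y(y, geno$plant_ids)
  keep <- which(!is.na(y))
  geno <- subset_markers(geno, plants = keep)
  y <- y[keep]
  drop_frac <- if (identical(schedule, "every")) 0 else {
    if (!is.numeric(schedule) || schedule <= 0 || schedule >= 1)
      stopf("schedule must be \"every\" or a fraction in (0, 1)")
    schedule
  }

  # --- phase 1: full-data elimination path -------------------------------
  current <- geno$marker_ids
  counts <- integer(0)
  h2s <- s2gs <- s2es <- numeric(0)
  failed <- logical(0)
  checkpoints <- list()
  last_beta <- NULL
  step <- 0L
  repeat {
    step <- step + 1L
    m <- length(current)
    gsub <- subset_markers(geno, markers = current)
    full <- tryCatch(
      fit_wgr(y, gsub, spec_with_seed(spec, derive_seed(seed, 33L, step))),
      error = function(e) e)
    fail <- inherits(full, "error")
    if (!fail) {
      beta <- if (!is.null(full$beta)) full$beta else
        tryCatch(backsolve_marker_effects(full, gsub),
                 error = function(e) NULL)
      if (!is.null(beta)) last_beta <- beta
      h2s <- c(h2s, full$h2_hat %||% NA_real_)
      s2gs <- c(s2gs, full$varcomp$sigma2_g %||% NA_real_)
      s2es <- c(s2es, full$varcomp$sigma2_e %||% NA_real_)
    } else {
      h2s <- c(h2s, NA_real_); s2gs <- c(s2gs, NA_real_)
      s2es <- c(s2es, NA_real_)
    }
    counts <- c(counts, m)
    failed <- c(failed, fail || is.null(last_beta))
    if (m %in% checkpoint_counts) checkpoints[[as.character(m)]] <- current
    if (verbose) gwsel_log(sprintf("density path step %d: m = %d", step, m))
    if (m <= min_markers) break
    if (is.null(last_beta))
      stopf("no usable marker effects at %d markers", m)
    ord <- rank_markers(last_beta[current])
    n_drop <- if (drop_frac > 0) max(1L, floor(drop_frac * m)) else 1L
    n_drop <- min(n_drop, m - min_markers)
    current <- setdiff(current, ord[seq_len(n_drop)])
  }

  # --- phase 2: fold-nested prediction ability ---------------------------
  ab <- matrix(NA_real_, length(counts), 0)
  if (reps >= 1) {
    for (r in seq_len(reps)) {
      plan <- make_folds(geno$plant_ids, n_folds, 1,
                         seed = derive_seed(seed, 31L, r))
      for (f in seq_len(n_folds)) {
        val <- which(plan$assignment[, 1] == f)
        ytr <- y
        ytr[val] <- NA
        rk <- tryCatch(
          fit_wgr(ytr, geno,
                  spec_with_seed(rank_spec, derive_seed(seed, 32L, r, f))),
          error = function(e) NULL)
        if (is.null(rk)) next
        eff <- if (!is.null(rk$beta)) rk$beta else
          tryCatch(backsolve_marker_effects(rk, geno),
                   error = function(e) NULL)
        if (is.null(eff)) next
        ord <- rev(rank_markers(eff))  # largest |effect| first
        h2f <- rk$h2_hat
        if (is.null(h2f) || !is.finite(h2f)) h2f <- 0.5
        h2f <- min(max(h2f, 1e-3), 1 - 1e-3)
        col <- vapply(seq_along(counts), function(ci) {
          gm <- subset_markers(geno, markers = ord[seq_len(counts[ci])])
          ft <- tryCatch({
            if (spec$method %in% c("gblup", "rrblup")) {
              ptr <- colMeans(dose_matrix(
                subset_markers(gm, plants = setdiff(seq_along(y), val)))) / 2
              cm <- 2 * sum(ptr * (1 - ptr))
              fit_rrblup(ytr, gm, lambda = max(cm, 1e-8) * (1 - h2f) / h2f)
            } else {
              fit_wgr(ytr, gm, spec_with_seed(
                spec, derive_seed(seed, 34L, r, f, ci)))
            }
          }, error = function(e) NULL)
          if (is.null(ft)) return(NA_real_)
          suppressWarnings(
            prediction_ability(ft$gebv[geno$plant_ids[val]], y[val]))
        }, 0.0)
        ab <- cbind(ab, col)
      }
      if (verbose) gwsel_log(sprintf("density ability repeat %d done", r))
    }
  }
  ability_mean <- if (ncol(ab)) apply(ab, 1, mean, na.rm = TRUE) else
    rep(NA_real_, length(counts))
  ability_se <- if (ncol(ab)) apply(ab, 1, function(z) {
    z <- z[!is.na(z)]
    if (length(z) < 2) NA_real_ else sd(z) / sqrt(length(z))
  }) else rep(NA_real_, length(counts))

  rec <- data.frame(marker_count = counts, ability_mean = ability_mean,
                    ability_se = ability_se, h2_hat = h2s, sigma2_g = s2gs,
                    sigma2_e = s2es, failed = failed)
  structure(list(records = rec, checkpoints = checkpoints,
                 seed = as.integer(seed), schedule = schedule,
                 final_markers = current),
            class = "density_curve")
}

#' @keywords internal
spec_with_seed <- function(spec, seed) {
  spec$seed <- as.integer(seed)
  spec
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("density_curve: %d records, marker counts %d -> %d\n",
              nrow(x$records), max(x$records$marker_count),
              min(x$records$marker_count)))
  invisible(x)
}

#' Sufficient marker density from a density curve
#'
#' Reports the smallest marker count whose mean prediction ability lies
#' within one standard error of the curve's maximum -- the point past which
#' adding markers buys nothing (a plateau criterion; the visual analogue is
#' reading the flat region off the curve).
#'
#' @param curve a `density_curve`.
#' @return list with `sufficient_density` (marker count), `max_ability`,
#'   `at_count` (where the maximum sits), `table` (the plotting records).
#' @export
curve_summary <- function(curve) {
  stopifnot(inherits(curve, "density_curve"))
  rec <- curve$records[!is.na(curve$records$ability_mean), ]
  if (!nrow(rec)) stopf("empty density curve")
  imax <- which.max(rec$ability_mean)
  se_max <- rec$ability_se[imax]
  if (is.na(se_max)) se_max <- 0
  thr <- rec$ability_mean[imax] - se_max
  ok <- rec$marker_count[rec$ability_mean >= thr]
  list(sufficient_density = min(ok),
       max_ability = rec$ability_mean[imax],
       at_count = rec$marker_count[imax],
       table = rec)
}
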