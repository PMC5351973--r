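# The eight whole-genome regression models.
#
# Closed-form mixed-model solutions for RR-BLUP / G-BLUP / RKHS (spectral
# REML on the relationship or kernel matrix) and compiled Gibbs samplers for
# the Bayesian alphabet (BRR, Bayes A, Bayes B, Bayes C-pi, Bayesian LASSO).
#
# pi convention: pi is the probability that a marker has ZERO effect (the
# spike mass).  Software conventions differ; this one matches the usual
# "proportion of markers associated with zero phenotypic variance" reading.

#' Whole-genome regression specification
#'
#' @param method one of `"rrblup"`, `"gblup"`, `"brr"`, `"bayesA"`,
#'   `"bayesB"`, `"bayesCpi"`, `"blasso"`, `"rkhs"`.
#' @param burnin,niter,thin MCMC chain settings for the Bayesian methods.
#'   The study-scale default is 20,000 burn-in with 40,000 saved iterations;
#'   tests and quick runs use much shorter chains (see the vignette).
#' @param seed integer seed (chains are bit-reproducible under it).
#' @param hyper named list of hyperprior overrides; see [wgr_hyper()].
#' @param h Gaussian-kernel bandwidth for `rkhs` (on median-scaled squared
#'   distances).
#' @param kernel `"gaussian"` or `"linear"` for `rkhs`.
#' @return a `wgr_spec` list.
#' @export
wgr_spec <- function(method = c("rrblup", "gblup", "brr", "bayesA", "bayesB",
                                "bayesCpi", "blasso", "rkhs"),
                     burnin = 20000, niter = 40000, thin = 10, seed = 1L,
                     hyper = list(), h = 1, kernel = "gaussian") {
  method <- match.arg(method)
  if (burnin < 0 || niter < 1 || thin < 1)
    stopf("chain lengths must be positive and thin >= 1")
  structure(list(method = method, burnin = as.integer(burnin),
                 niter = as.integer(niter), thin = as.integer(thin),
                 seed = as.integer(seed), hyper = hyper, h = h,
                 kernel = kernel),
            class = "wgr_spec")
}

#' Default hyperpriors for the Bayesian samplers
#'
#' Scaled-inverse-chi-square priors with `nu = 4` degrees of freedom; scale
#' parameters solved from a prior-R2-of-0.5 heuristic (the prior mode of the
#' total marker variance explains half the phenotypic variance).  The
#' Bayesian LASSO uses scale 1 / d.f. 4 priors on both variances and a
#' Gamma(shape 1.1) prior on `lambda^2` with rate matched to the same
#' heuristic.  `pi` (spike mass) gets a flat Beta(1, 1) prior and is
#' estimated for both Bayes B and Bayes C-pi.  All entries overridable via
#' `wgr_spec(hyper = ...)`; set `fix_sigma_beta` / `fix_sigma_e` /
#' `fix_lambda2` / `fix_pi` to positive values to hold a parameter fixed
#' (degenerate prior).
#'
#' @param y phenotype vector.
#' @param Z centered marker matrix.
#' @param method sampler method name.
#' @param R2 prior proportion of variance attributed to markers.
#' @return named list of hyperparameters.
#' @export
wgr_hyper <- function(y, Z, method, R2 = 0.5) {
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1e-8
  msx <- sum(apply(Z, 2, var))
  if (!is.finite(msx) || msx <= 0) msx <- 1
  nu <- 4
  sb <- R2 * vy / msx * (nu + 2) / nu
  if (method %in% c("bayesB", "bayesCpi")) sb <- sb * 2  # / (1 - E[pi])
  lam2_0 <- 2 * (1 - R2) / R2 * msx
  list(nu_beta = nu,
       S_beta = if (method == "blasso") 1 else sb,
       nu_e = 4,
       S_e = if (method == "blasso") 1 else (1 - R2) * vy * (4 + 2) / 4,
       pi_a = 1, pi_b = 1,
       lambda_shape = 1.1, lambda_rate = 0.1 / lam2_0,
       fix_sigma_beta = -1, fix_sigma_e = -1, fix_lambda2 = -1, fix_pi = -1)
}

#' @keywords internal
centered_doses <- function(geno, freq = NULL) {
  M <- dose_matrix(geno)
  if (is.null(freq)) freq <- colMeans(M) / 2
  list(Z = sweep(M, 2, 2 * freq), freq = freq,
       scale_c = 2 * sum(freq * (1 - freq)))
}

#' @keywords internal
null_fit <- function(method, y, plant_ids, marker_ids = NULL) {
  warnf("constant phenotype: returning null %s fit", method)
  structure(list(method = method, mu = mean(y),
                 beta = if (!is.null(marker_ids))
                   setNames(rep(0, length(marker_ids)), marker_ids),
                 gebv = setNames(rep(0, length(plant_ids)), plant_ids),
                 plant_ids = plant_ids,
                 varcomp = list(sigma2_g = 0, sigma2_e = 0),
                 h2_hat = 0, null = TRUE),
            class = "wgr_fit")
}

#' Spectral REML for a single-kernel mixed model
#'
#' Fits `y = 1 mu + g + e` with `g ~ N(0, K sigma2_g)` by profiling the
#' restricted likelihood over the variance ratio `delta = sigma2_e /
#' sigma2_g` on the eigenbasis of `K` (one eigendecomposition, then a 1-D
#' optimization).
#'
#' @param y numeric vector (no NAs).
#' @param K PSD covariance/kernel matrix.
#' @return list `mu`, `sigma2_g`, `sigma2_e`, `eig` (the decomposition,
#'   reusable), `delta`.
#' @keywords internal
spectral_reml <- function(y, K) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, n)))
  neg2ll <- function(logdelta) {
    dd <- d + exp(logdelta)
    xx <- sum(xt^2 / dd)
    muh <- sum(xt * yt / dd) / xx
    r <- yt - xt * muh
    q <- sum(r^2 / dd)
    s2 <- q / (n - 1)
    (n - 1) * log(s2) + sum(log(dd)) + log(xx)
  }
  op <- optimize(neg2ll, c(-12, 12))
  delta <- exp(op$minimum)
  dd <- d + delta
  xx <- sum(xt^2 / dd)
  muh <- sum(xt * yt / dd) / xx
  q <- sum((yt - xt * muh)^2 / dd)
  s2g <- q / (n - 1)
  list(mu = muh, sigma2_g = s2g, sigma2_e = s2g * delta, eig = eg,
       delta = delta)
}

#' RR-BLUP: ridge-regression BLUP of marker effects
#'
#' Every marker is assumed to carry an equal share of the genetic variance
#' (`sigma2_beta = V_G / M` on the centered-dose scale).  Variance
#' components are estimated by REML on the equivalent kernel model (the
#' cross-product of the centered doses), then marker effects solve the
#' penalized mixed-model equations with shrinkage `lambda = sigma2_e /
#' sigma2_beta`.
#'
#' @param y named phenotype vector (one value per plant; `NA` for plants to
#'   predict only).
#' @param geno a [marker_matrix()] (imputed).
#' @param spec a [wgr_spec()] (optional for this closed-form method).
#' @param lambda optional fixed shrinkage, bypassing REML.
#' @return a `wgr_fit`: `mu`, `beta` (per-marker effects), `gebv` (all
#'   plants), `varcomp`, `h2_hat`, training frequencies for prediction.
#' @export
fit_rrblup <- function(y, geno, spec = NULL, lambda = NULL) {
  stopifnot(inherits(geno, "marker_matrix"))
  y <- align_y(y, geno$plant_ids)
  tr <- which(!is.na(y))
  if (length(tr) < 2) stopf("need at least 2 phenotyped plants")
  cd <- centered_doses(subset_markers(geno, plants = tr))
  Ztr <- cd$Z
  ytr <- y[tr]
  if (var(ytr) < 1e-12 || all(abs(Ztr) < 1e-12))
    return(null_fit("rrblup", ytr, geno$plant_ids, geno$marker_ids))
  # all-plants centered doses under training frequencies
  Zall <- sweep(dose_matrix(geno), 2, 2 * cd$freq)
  if (!is.null(lambda)) {
    mu <- mean(ytr)
    beta <- solve(crossprod(Ztr) + diag(lambda, ncol(Ztr)),
                  crossprod(Ztr, ytr - mu))
    beta <- drop(beta)
    vc <- list(sigma2_g = NA_real_, sigma2_e = NA_real_,
               sigma2_beta = NA_real_, lambda = lambda)
    h2 <- NA_real_
  } else {
    K <- tcrossprod(Ztr) / cd$scale_c
    fm <- spectral_reml(ytr, K)
    mu <- fm$mu
    sigma2_beta <- fm$sigma2_g / cd$scale_c
    # beta = sigma2_beta Z' V^{-1} (y - mu), V = sigma2_g K + sigma2_e I
    Vinv_r <- with(fm, {
      dd <- pmax(eig$values, 0) + delta
      eig$vectors %*% ((crossprod(eig$vectors, ytr - mu)) / dd) / sigma2_g
    })
    beta <- drop(sigma2_beta * crossprod(Ztr, Vinv_r))
    vc <- list(sigma2_g = fm$sigma2_g, sigma2_e = fm$sigma2_e,
               sigma2_beta = sigma2_beta,
               lambda = fm$sigma2_e / sigma2_beta)
    h2 <- fm$sigma2_g / (fm$sigma2_g + fm$sigma2_e)
  }
  gebv <- drop(Zall %*% beta)
  structure(list(method = "rrblup", mu = mu,
                 beta = setNames(beta, geno$marker_ids),
                 gebv = setNames(gebv, geno$plant_ids),
                 plant_ids = geno$plant_ids, train_ids = geno$plant_ids[tr],
                 freq = cd$freq, scale_c = cd$scale_c,
                 varcomp = vc, h2_hat = h2),
            class = "wgr_fit")
}

#' G-BLUP: genomic BLUP through a relationship matrix
#'
#' The animal-model mixed-model equations with the pedigree relationship
#' matrix replaced by a marker-derived genomic relationship matrix `G`
#' ([compute_grm()]).  Plants with missing phenotypes are predicted through
#' the off-diagonal block of `G` (one reference-plus-test analysis).
#'
#' @param y named phenotype vector over the plants of `G` (`NA` = predict
#'   only).
#' @param G a `relationship_matrix` of kind `"grm"` (or any PSD matrix with
#'   ids), e.g. from [compute_grm()].
#' @param spec optional [wgr_spec()].
#' @param sigma2_g,sigma2_e optional fixed variance components, bypassing
#'   REML (used e.g. to match scales with an RR-BLUP fit).
#' @return a `wgr_fit` with `gebv` for every plant in `G`, `alpha` (the
#'   BLUP weights such that `gebv = G[, train] %*% alpha`), variance
#'   components and genomic heritability `h2_hat = sigma2_g / (sigma2_g +
#'   sigma2_e)`.
#' @export
fit_gblup <- function(y, G, spec = NULL, sigma2_g = NULL, sigma2_e = NULL) {
  stopifnot(inherits(G, "relationship_matrix"))
  ids <- G$plant_ids
  y <- align_y(y, ids)
  tr <- which(!is.na(y))
  if (length(tr) < 2) stopf("need at least 2 phenotyped plants")
  ytr <- y[tr]
  if (var(ytr) < 1e-12) return(null_fit("gblup", ytr, ids))
  Gtt <- G$values[tr, tr, drop = FALSE]
  if (is.null(sigma2_g) || is.null(sigma2_e)) {
    fm <- spectral_reml(ytr, Gtt)
    mu <- fm$mu; sigma2_g <- fm$sigma2_g; sigma2_e <- fm$sigma2_e
    dd <- pmax(fm$eig$values, 0) + fm$delta
    Vinv_r <- fm$eig$vectors %*%
      (crossprod(fm$eig$vectors, ytr - mu) / dd) / sigma2_g
  } else {
    V <- sigma2_g * Gtt + diag(sigma2_e, length(tr))
    Vc <- tryCatch(chol(V), error = function(e) {
      chol(V + diag(1e-8 * mean(diag(V)), nrow(V)))
    })
    Vi1 <- backsolve(Vc, forwardsolve(t(Vc), rep(1, length(tr))))
    Viy <- backsolve(Vc, forwardsolve(t(Vc), ytr))
    mu <- sum(Vi1 * ytr) / sum(Vi1)
    Vinv_r <- Viy - Vi1 * mu
  }
  alpha <- sigma2_g * drop(Vinv_r)
  gebv <- drop(G$values[, tr, drop = FALSE] %*% alpha)
  structure(list(method = "gblup", mu = mu,
                 gebv = setNames(gebv, ids), plant_ids = ids,
                 train_ids = ids[tr], alpha = alpha,
                 K = G$values, K_kind = "grm",
                 freq = G$freq, scale_c = G$scale_c,
                 varcomp = list(sigma2_g = sigma2_g, sigma2_e = sigma2_e),
                 h2_hat = sigma2_g / (sigma2_g + sigma2_e)),
            class = "wgr_fit")
}

#' Bayesian whole-genome regression (BRR, Bayes A/B/C-pi, Bayesian LASSO)
#'
#' Single-site Gibbs sampler over the intercept, the marker effects, the
#' prior variances (common scaled-inverse-chi-square for BRR and Bayes C-pi;
#' per-marker for Bayes A and Bayes B; exponential/inverse-Gaussian
#' `tau_j^2` with a Gamma `lambda^2` for the Bayesian LASSO), the spike mass
#' `pi` (Beta conditional, Bayes B and Bayes C-pi; `pi` = probability of a
#' zero effect) and the residual variance.  Posterior means are reported;
#' chains are reproducible under `spec$seed`.
#'
#' @param y named phenotype vector (`NA` = predict only).
#' @param geno a [marker_matrix()] (imputed).
#' @param spec a [wgr_spec()] with `method` in `brr`, `bayesA`, `bayesB`,
#'   `bayesCpi`, `blasso`.
#' @param keep_samples keep the full matrix of saved effect samples
#'   (memory-heavy; used for Monte-Carlo-error diagnostics).
#' @return a `wgr_fit` with posterior-mean `beta`, `gebv`, `pi_hat`,
#'   variance summaries, `h2_hat` (posterior mean of genomic variance over
#'   genomic-plus-residual), a split-chain convergence flag, and optionally
#'   `samples`.
#' @export
fit_bayesian <- function(y, geno, spec, keep_samples = FALSE) {
  stopifnot(inherits(geno, "marker_matrix"), inherits(spec, "wgr_spec"))
  method <- spec$method
  if (!method %in% c("brr", "bayesA", "bayesB", "bayesCpi", "blasso"))
    stopf("fit_bayesian does not handle method '%s'", method)
  y <- align_y(y, geno$plant_ids)
  tr <- which(!is.na(y))
  if (length(tr) < 2) stopf("need at least 2 phenotyped plants")
  cd <- centered_doses(subset_markers(geno, plants = tr))
  ytr <- y[tr]
  if (var(ytr) < 1e-12)
    return(null_fit(method, ytr, geno$plant_ids, geno$marker_ids))
  hyper <- modifyList(wgr_hyper(ytr, cd$Z, method), spec$hyper)
  mcode <- match(method, c("brr", "bayesA", "bayesB", "bayesCpi", "blasso")) - 1L
  set.seed(spec$seed)
  res <- .gibbs_wgr_cpp(ytr, cd$Z, mcode, spec$burnin, spec$niter,
                        spec$thin, hyper, keep_samples)
  if (!all(is.finite(res$beta)))
    stopf("divergent chain: non-finite effect estimates")
  Zall <- sweep(dose_matrix(geno), 2, 2 * cd$freq)
  beta <- setNames(res$beta, geno$marker_ids)
  gebv <- drop(Zall %*% res$beta)
  # report-only split-chain check on the variance parameters
  conv <- split_chain_flag(res$sigma2_e_samples, res$var_g_samples)
  structure(list(method = method, mu = res$mu, beta = beta,
                 gebv = setNames(gebv, geno$plant_ids),
                 plant_ids = geno$plant_ids, train_ids = geno$plant_ids[tr],
                 freq = cd$freq, scale_c = cd$scale_c,
                 varcomp = list(sigma2_g = res$var_g, sigma2_e = res$sigma2_e,
                                sigma2_beta = res$sigma2_beta,
                                sigma2_j = res$sigma2_j,
                                lambda2 = res$lambda2),
                 pi_hat = if (method %in% c("bayesB", "bayesCpi"))
                   res$pi_hat else NULL,
                 prob_included = if (!is.null(res$prob_included))
                   setNames(res$prob_included, geno$marker_ids),
                 h2_hat = res$h2_hat,
                 mcmc = list(n_saved = res$n_saved,
                             beta_sd = setNames(res$beta_sd, geno$marker_ids),
                             sigma2_e_samples = res$sigma2_e_samples,
                             var_g_samples = res$var_g_samples,
                             convergence_flag = conv),
                 samples = if (keep_samples) res$beta_samples),
            class = "wgr_fit")
}

#' @keywords internal
split_chain_flag <- function(...) {
  # compares first- and second-half means of each monitored parameter,
  # scaled by the chain SD; report-only, never fatal
  flags <- vapply(list(...), function(s) {
    s <- s[is.finite(s)]
    if (length(s) < 20) return(FALSE)
    h <- length(s) %/% 2
    sdv <- sd(s)
    if (sdv < 1e-12) return(FALSE)
    abs(mean(s[1:h]) - mean(s[(h + 1):length(s)])) / sdv > 0.5
  }, logical(1))
  any(flags)
}

#' Reproducing kernel Hilbert space regression
#'
#' Genetic values modeled as a Gaussian process with covariance proportional
#' to a Gaussian kernel on the centered allele doses:
#' `K_ij = exp(-h * d2_ij / median(d2))` with `d2` squared Euclidean
#' distances (median taken over off-diagonal pairs).  Fitted exactly like
#' G-BLUP with `K` in place of the genomic relationship matrix.  With
#' `kernel = "linear"` the VanRaden matrix is used, recovering G-BLUP.
#'
#' @inheritParams fit_bayesian
#' @param spec a [wgr_spec()] with `method = "rkhs"`; `spec$h` is the
#'   bandwidth (> 0).
#' @return a `wgr_fit` (kernel model: no per-marker effects).
#' @export
fit_rkhs <- function(y, geno, spec = wgr_spec("rkhs")) {
  stopifnot(inherits(geno, "marker_matrix"))
  if (!is.null(spec$h) && spec$h <= 0) stopf("rkhs bandwidth h must be > 0")
  ya <- align_y(y, geno$plant_ids)
  tr <- which(!is.na(ya))
  fr <- colMeans(dose_matrix(subset_markers(geno, plants = tr))) / 2
  cd <- centered_doses(geno, freq = fr)
  if (identical(spec$kernel, "linear")) {
    K <- tcrossprod(cd$Z) / cd$scale_c
  } else {
    d2 <- as.matrix(stats::dist(cd$Z))^2
    md <- median(d2[upper.tri(d2)])
    if (!is.finite(md) || md <= 0) md <- 1
    K <- exp(-spec$h * d2 / md)
  }
  dimnames(K) <- list(geno$plant_ids, geno$plant_ids)
  Gk <- structure(list(values = K, plant_ids = geno$plant_ids, kind = "grm",
                       freq = cd$freq, scale_c = cd$scale_c),
                  class = "relationship_matrix")
  fit <- fit_gblup(y, Gk, spec)
  fit$method <- "rkhs"
  fit$K_kind <- spec$kernel
  fit
}

#' Fit any of the eight whole-genome regression models
#'
#' Dispatcher over [fit_rrblup()], [fit_gblup()] (building the VanRaden
#' matrix internally), [fit_bayesian()] and [fit_rkhs()].
#'
#' @param y named phenotype vector (`NA` = predict only).
#' @param geno a [marker_matrix()] (imputed).
#' @param spec a [wgr_spec()].
#' @param G optional precomputed `relationship_matrix` for `gblup`.
#' @return a `wgr_fit`.
#' @export
fit_wgr <- function(y, geno, spec, G = NULL) {
  switch(spec$method,
    rrblup = fit_rrblup(y, geno, spec),
    gblup = {
      if (is.null(G)) {
        # centering frequencies from phenotyped (training) plants only
        ya <- align_y(y, geno$plant_ids)
        tr <- which(!is.na(ya))
        fr <- colMeans(dose_matrix(subset_markers(geno, plants = tr))) / 2
        G <- compute_grm(geno, freq = fr)
      }
      fit_gblup(y, G, spec)
    },
    rkhs = fit_rkhs(y, geno, spec),
    fit_bayesian(y, geno, spec))
}

#' @export
print.wgr_fit <- function(x, ...) {
  cat(sprintf("wgr_fit [%s]: %d plants, mu = %.4g, h2_hat = %.3f\n",
              x$method, length(x$gebv), x$mu,
              if (is.null(x$h2_hat) || is.na(x$h2_hat)) NA else x$h2_hat))
  invisible(x)
}

#' Backsolve marker effects from a G-BLUP (or linear-kernel) fit
#'
#' The unique RR-BLUP-consistent decomposition of GEBVs into marker
#' effects: `beta = Z' G^-1 gebv / c` with `Z` the centered doses of the
#' training plants and `c` the VanRaden denominator.  Used by the
#' marker-density study, which ranks markers by effect size while fitting
#' with G-BLUP.
#'
#' @param fit a `wgr_fit` from [fit_gblup()] (or linear-kernel
#'   [fit_rkhs()]).
#' @param geno the [marker_matrix()] the relationship matrix was built from.
#' @return named numeric vector of marker effects.
#' @export
backsolve_marker_effects <- function(fit, geno) {
  stopifnot(inherits(fit, "wgr_fit"))
  if (isTRUE(fit$null))
    return(setNames(rep(0, ncol(geno$values)), geno$marker_ids))
  if (is.null(fit$K)) stopf("fit does not carry the relationship matrix")
  tr <- match(fit$train_ids, geno$plant_ids)
  if (anyNA(tr)) stopf("fit and genotype plants do not align")
  Z <- sweep(dose_matrix(geno)[tr, , drop = FALSE], 2, 2 * fit$freq)
  Gtt <- fit$K[match(fit$train_ids, fit$plant_ids),
               match(fit$train_ids, fit$plant_ids), drop = FALSE]
  g <- fit$gebv[fit$train_ids]
  sol <- tryCatch(solve(Gtt, g), error = function(e) {
    solve(Gtt + diag(1e-6 * mean(diag(Gtt)), nrow(Gtt)), g)
  })
  setNames(drop(crossprod(Z, sol)) / fit$scale_c, geno$marker_ids)
}

#' Predict genetic values for new genotypes
#'
#' Marker-effect models project new centered doses (centered at the
#' *training* allele frequencies) onto the estimated effects.  Matrix
#' models (G-BLUP, RKHS) require the new plants to be part of the supplied
#' relationship/kernel matrix and predict through its off-diagonal block.
#'
#' @param fit a `wgr_fit`.
#' @param geno_new a [marker_matrix()] for the plants to predict (marker-
#'   effect models: marker ids must match the training panel).
#' @return named numeric vector of predicted genetic values.
#' @export
predict_gebv <- function(fit, geno_new) {
  stopifnot(inherits(fit, "wgr_fit"), inherits(geno_new, "marker_matrix"))
  if (!is.null(fit$beta) && !isTRUE(fit$null)) {
    mis <- setdiff(names(fit$beta), geno_new$marker_ids)
    if (length(mis))
      stopf("marker mismatch; missing in new genotypes: %s%s",
            paste(head(mis, 5), collapse = ", "),
            if (length(mis) > 5) sprintf(" (+%d more)", length(mis) - 5) else "")
    gsub <- subset_markers(geno_new, markers = names(fit$beta))
    Z <- sweep(dose_matrix(gsub), 2, 2 * fit$freq)
    setNames(drop(Z %*% fit$beta), geno_new$plant_ids)
  } else if (!is.null(fit$K)) {
    idx <- match(geno_new$plant_ids, fit$plant_ids)
    if (anyNA(idx))
      stopf("matrix-model prediction requires plants inside the fitted kernel; unknown: %s",
            paste(head(geno_new$plant_ids[is.na(idx)], 5), collapse = ", "))
    tr <- match(fit$train_ids, fit$plant_ids)
    setNames(drop(fit$K[idx, tr, drop = FALSE] %*% fit$alpha),
             geno_new$plant_ids)
  } else {
    setNames(rep(0, length(geno_new$plant_ids)), geno_new$plant_ids)
  }
}

#' @keywords internal
align_y <- function(y, ids) {
  if (!is.null(names(y))) {
    out <- setNames(rep(NA_real_, length(ids)), ids)
    common <- intersect(names(y), ids)
    if (!length(common)) stopf("no phenotype names match plant ids")
    out[common] <- y[common]
    out
  } else {
    if (length(y) != length(ids))
      stopf("unnamed y must have one value per plant (%d != %d)",
            length(y), length(ids))
    setNames(as.numeric(y), ids)
  }
}
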