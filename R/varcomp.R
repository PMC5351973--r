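# EM-REML variance components for the two trial designs and the derived
# genetic parameters (heritability, coefficients of variation).
#
# Models, in matrix notation:
#   germplasm:  y = X r + Z a + W p + e
#   diallel:    y = X r + Z a + W p + T f + e
# with r the fixed block effects; a the additive (genotype) effects with
# covariance identity or a genomic relationship matrix; p the block-by-
# genotype (plot) interaction; f the full-sib family (dominance) effects,
# diallel only; e the residual.

#' Assemble mixed-model design matrices from a phenotype table
#'
#' Builds the fixed block incidence `X` and the random-term incidence
#' matrices (one column per level): additive/genotype `Z`, block-by-genotype
#' plot `W`, and (diallel) family `T`.  A plot term in which every
#' block-by-genotype cell holds at most one observation is confounded with
#' the residual and is dropped with a warning.
#'
#' @param pheno a [phenotype_table()].
#' @param design `"germplasm"` or `"diallel"` (the diallel adds the family
#'   term).
#' @param trait trait name to extract.
#' @param additive_covariance `NULL` for identity, or a
#'   `relationship_matrix` (GRM) covering all genotypes in the data.
#' @param experiment experiment label(s) to keep (defaults to `design`).
#' @return a `mixed_model` list: `y`, `X`, `terms` (named list, each with
#'   incidence `Z`, covariance inverse `Ainv`, `logdetA`, level count `q`),
#'   `trait_mean`.
#' @export
build_design <- function(pheno, design = c("germplasm", "diallel"), trait,
                         additive_covariance = NULL, experiment = design) {
  design <- match.arg(design)
  df <- as.data.frame(pheno)
  df <- df[df$trait == trait & df$experiment %in% experiment, ]
  if (!nrow(df)) stopf("no records for trait '%s' in experiment '%s'",
                       trait, paste(experiment, collapse = "/"))
  if (any(is.na(df$block) | df$block == ""))
    stopf("plant(s) with no block assignment")
  n <- nrow(df)
  blk <- factor(df$block)
  X <- if (nlevels(blk) > 1) model.matrix(~blk) else
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stopf("singular fixed-effects (block) design")

  inc <- function(fct) {
    f <- factor(fct)
    M <- matrix(0, n, nlevels(f), dimnames = list(NULL, levels(f)))
    M[cbind(seq_len(n), as.integer(f))] <- 1
    M
  }
  terms <- list()
  Za <- inc(df$plant_id)
  if (ncol(Za) < 2) stopf("additive term needs >= 2 genotype levels")
  if (is.null(additive_covariance)) {
    terms$additive <- list(Z = Za, Ainv = NULL, logdetA = 0, q = ncol(Za))
  } else {
    stopifnot(inherits(additive_covariance, "relationship_matrix"))
    idx <- match(colnames(Za), additive_covariance$plant_ids)
    if (anyNA(idx))
      stopf("GRM is missing genotype(s): %s",
            paste(head(colnames(Za)[is.na(idx)], 5), collapse = ", "))
    A <- additive_covariance$values[idx, idx, drop = FALSE]
    ch <- tryCatch(chol(A), error = function(e)
      chol(A + diag(1e-6 * mean(diag(A)), nrow(A))))
    terms$additive <- list(Z = Za, Ainv = chol2inv(ch),
                           logdetA = 2 * sum(log(diag(ch))), q = ncol(Za))
  }
  cell <- interaction(df$block, df$plant_id, drop = TRUE)
  if (max(table(cell)) > 1) {
    terms$plot <- list(Z = inc(cell), Ainv = NULL, logdetA = 0,
                       q = nlevels(cell))
  } else {
    warnf("block-by-genotype plot term has single observations per cell; dropped as unidentifiable")
  }
  if (design == "diallel") {
    if (length(unique(df$family)) < 2)
      stopf("diallel design needs >= 2 families")
    Tf <- inc(df$family)
    terms$family <- list(Z = Tf, Ainv = NULL, logdetA = 0, q = ncol(Tf))
  }
  structure(list(y = df$value, X = X, terms = terms,
                 design = design, trait = trait,
                 trait_mean = mean(df$value), data = df),
            class = "mixed_model")
}

#' EM-REML variance component estimation
#'
#' Fits the assembled mixed model by the expectation-maximization form of
#' restricted maximum likelihood on Henderson's mixed-model equations.  The
#' EM updates keep every component non-negative and the restricted
#' log-likelihood non-decreasing; the iteration trace (components and
#' log-likelihood per iteration) is returned.
#'
#' With `constrain = FALSE` the residual variance is additionally
#' re-derived as the *difference* between the sample phenotypic variance
#' (after removing fixed block effects) and the other components -- the
#' ANOVA-style bookkeeping that can turn the residual negative in small
#' samples with large genetic variance, and with it push heritability past
#' 1.
#'
#' @param model a `mixed_model` from [build_design()].
#' @param constrain keep all components non-negative (default TRUE).
#' @param tol relative-change convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param start optional named starting values (fractions of `var(y)` used
#'   otherwise).
#' @return a `varcomp` list: `components` (named: the random terms plus
#'   `residual`), `sigma2_p` (their sum), `loglik` trace, `iterations`,
#'   `converged`, `trait_mean`, `design`.
#' @export
reml_fit <- function(model, constrain = TRUE, tol = 1e-8, max_iter = 2000,
                     start = NULL) {
  stopifnot(inherits(model, "mixed_model"))
  y <- model$y
  n <- length(y)
  X <- model$X
  p <- ncol(X)
  terms <- model$terms
  kt <- length(terms)
  for (tm in terms) if (tm$q < 2) stopf("random term with < 2 levels")
  W <- do.call(cbind, c(list(X), lapply(terms, `[[`, "Z")))
  qs <- vapply(terms, `[[`, 0, "q")
  offs <- p + c(0, cumsum(qs))  # block offsets into W columns
  M0 <- crossprod(W)
  Wty <- drop(crossprod(W, y))
  yty <- sum(y^2)
  vy <- var(y)
  if (vy <= 0) stopf("constant response")
  s2 <- setNames(rep(vy / (kt + 1), kt + 1), c(names(terms), "residual"))
  if (!is.null(start)) s2[names(start)] <- unlist(start)
  floorv <- 1e-10 * vy
  s2 <- pmax(s2, floorv)

  ll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    se <- s2["residual"]
    C <- M0
    for (i in seq_len(kt)) {
      ix <- (offs[i] + 1):offs[i + 1]
      al <- se / s2[i]
      if (is.null(terms[[i]]$Ainv)) {
        diag(C)[ix] <- diag(C)[ix] + al
      } else {
        C[ix, ix] <- C[ix, ix] + terms[[i]]$Ainv * al
      }
    }
    ch <- tryCatch(chol(C), error = function(e)
      stopf("singular mixed-model equations at iteration %d", it))
    Cinv <- chol2inv(ch)
    s <- drop(Cinv %*% Wty)
    logdetC <- 2 * sum(log(diag(ch)))
    yPy <- (yty - sum(s * Wty)) / se
    q_all <- sum(qs)
    ll_it <- -0.5 * ((n - p - q_all) * log(se) +
                     sum(qs * log(s2[seq_len(kt)])) +
                     sum(vapply(terms, `[[`, 0, "logdetA")) +
                     logdetC + yPy)
    ll <- c(ll, ll_it)

    s2_new <- s2
    for (i in seq_len(kt)) {
      ix <- (offs[i] + 1):offs[i + 1]
      u <- s[ix]
      Cii <- Cinv[ix, ix, drop = FALSE]
      if (is.null(terms[[i]]$Ainv)) {
        s2_new[i] <- (sum(u^2) + se * sum(diag(Cii))) / qs[i]
      } else {
        Ainv <- terms[[i]]$Ainv
        s2_new[i] <- (drop(crossprod(u, Ainv %*% u)) +
                      se * sum(Ainv * Cii)) / qs[i]
      }
    }
    s2_new["residual"] <- (yty - sum(s * Wty)) / (n - p)
    s2_new <- pmax(s2_new, floorv)
    rel <- max(abs(s2_new - s2) / pmax(s2, floorv))
    s2 <- s2_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("EM-REML reached max_iter = %d (last relative change above tol)",
          max_iter)

  comps <- as.list(s2)
  if (!constrain) {
    # difference-method residual: sample phenotypic variance (block effects
    # removed) minus the other components; may be negative
    yadj <- residuals(lm(y ~ 0 + X)) + mean(y)
    s2p_sample <- var(yadj)
    comps$residual <- s2p_sample - sum(s2[seq_len(kt)])
  }
  structure(list(components = comps,
                 sigma2_p = sum(unlist(comps)),
                 loglik = ll, iterations = length(ll),
                 converged = converged, constrained = constrain,
                 trait_mean = model$trait_mean, design = model$design,
                 trait = model$trait),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("varcomp [%s, %s]: %s; sigma2_p = %.4g (%d EM iterations%s)\n",
              x$design, x$trait,
              paste(sprintf("%s = %.4g", names(x$components),
                            unlist(x$components)), collapse = ", "),
              x$sigma2_p, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Genetic parameters from variance components
#'
#' Completes a [reml_fit()] result into the usual genetic-parameter table:
#' additive variance, phenotypic variance, narrow-sense heritability and
#' coefficients of variation.
#'
#' The additive variance is the genotype-level component expanded by the
#' family-structure coefficient `falconer_k` (Falconer's covariance of
#' relatives: 4 when the genotype term is a half-sib family mean, 1 when it
#' is an individual additive effect).  The phenotypic variance stays the sum
#' of the model's components, so with `falconer_k > 1` the heritability can
#' legitimately exceed 1 in small samples -- the classic overestimation
#' pathology of family-based REML at tiny n.
#'
#' @param vc a `varcomp` from [reml_fit()].
#' @param trait_mean trait mean (defaults to the one stored in `vc`).
#' @param falconer_k additive expansion coefficient (default 1).
#' @return a `genetic_parameters` list: `sigma2_a`, `sigma2_f`, `sigma2_b`,
#'   `sigma2_e`, `sigma2_p`, `h2_a`, `cv_g`, `cv_e` (percent), `cv_r`.
#' @export
genetic_parameters <- function(vc, trait_mean = vc$trait_mean,
                               falconer_k = 1) {
  stopifnot(inherits(vc, "varcomp"))
  cp <- vc$components
  s2_geno <- cp$additive %||% 0
  s2_f <- cp$family %||% NA_real_
  s2_b <- cp$plot %||% 0
  s2_e <- cp$residual
  sigma2_a <- falconer_k * s2_geno
  sigma2_p <- s2_geno + (if (is.na(s2_f)) 0 else s2_f) + s2_b + s2_e
  if (sigma2_p <= 0) stopf("non-positive phenotypic variance")
  h2 <- sigma2_a / sigma2_p
  if (is.null(trait_mean) || trait_mean == 0)
    stopf("trait mean must be nonzero for coefficients of variation")
  cv_g <- if (sigma2_a >= 0) 100 * sqrt(sigma2_a) / abs(trait_mean) else {
    warnf("negative additive variance: CVg undefined")
    NA_real_
  }
  cv_e <- if (s2_e >= 0) 100 * sqrt(s2_e) / abs(trait_mean) else {
    warnf("negative residual variance: CVe undefined")
    NA_real_
  }
  cv_r <- if (!is.na(cv_e) && cv_e == 0) {
    if (!is.na(cv_g) && cv_g > 0) {
      warnf("zero residual variance: CVr infinite")
      Inf
    } else 0
  } else cv_g / cv_e
  structure(list(sigma2_a = sigma2_a, sigma2_f = s2_f, sigma2_b = s2_b,
                 sigma2_e = s2_e, sigma2_p = sigma2_p, h2_a = h2,
                 cv_g = cv_g, cv_e = cv_e, cv_r = cv_r,
                 falconer_k = falconer_k, trait = vc$trait,
                 design = vc$design),
            class = "genetic_parameters")
}

#' @export
print.genetic_parameters <- function(x, ...) {
  cat(sprintf("genetic_parameters [%s, %s]: h2_a = %.3f, CVg = %.2f%%, CVe = %.2f%%, CVr = %.3f\n",
              x$design, x$trait, x$h2_a, x$cv_g, x$cv_e, x$cv_r))
  invisible(x)
}

#' Maximum genomic-selection cycle length under indirect selection
#'
#' Genomic selection beats phenotypic selection whenever its cycle length
#' satisfies `L_Y < (r_A / H_X) * L_X`, with `r_A` the genomic prediction
#' accuracy, `H_X` the phenotypic selection accuracy and `L_X` the
#' phenotypic cycle length.  Returns that threshold in the units of `L_X`
#' (years).
#'
#' @param r_A genomic prediction accuracy (e.g. cross-validated prediction
#'   ability).
#' @param H_X phenotypic selection accuracy (a common proxy is `sqrt(h2)`;
#'   the choice is left to the caller).
#' @param L_X phenotypic-selection cycle length.
#' @return the threshold cycle length `(r_A / H_X) * L_X`.
#' @export
indirect_selection_threshold <- function(r_A, H_X, L_X) {
  if (H_X <= 0) stopf("H_X must be > 0")
  (r_A / H_X) * L_X
}

#' Write genetic parameters for several traits/designs as a CSV table
#'
#' @param params list of `genetic_parameters`.
#' @param path output path.
#' @return the assembled data.frame, invisibly.
#' @export
write_parameter_table <- function(params, path = NULL) {
  df <- do.call(rbind, lapply(params, function(g) {
    data.frame(design = g$design, trait = g$trait, sigma2_a = g$sigma2_a,
               sigma2_f = g$sigma2_f, sigma2_b = g$sigma2_b,
               sigma2_e = g$sigma2_e, sigma2_p = g$sigma2_p, h2_a = g$h2_a,
               cv_g = g$cv_g, cv_e = g$cv_e, cv_r = g$cv_r)
  }))
  if (!is.null(path)) data.table::fwrite(df, path)
  invisible(df)
}
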