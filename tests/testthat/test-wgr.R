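# The eight whole-genome regression models: closed-form equivalences,
# round trips, sampler behavior and prediction contracts.

short_chain <- function(method, seed = 1L, ...) {
  wgr_spec(method, burnin = 300, niter = 900, thin = 3, seed = seed, ...)
}

test_that("ridge-regression BLUP and genomic BLUP give the same GEBVs", {
  pop <- small_population(seed = 21, n = 50, m = 150, h2 = 0.5)
  fr <- fit_rrblup(pop$y, pop$geno)
  G <- compute_grm(pop$geno, ridge = 0)
  fg <- fit_gblup(pop$y, G, sigma2_g = fr$varcomp$sigma2_g,
                  sigma2_e = fr$varcomp$sigma2_e)
  expect_lt(max(abs(fr$gebv - fg$gebv[names(fr$gebv)])), 1e-8)
  expect_equal(fr$mu, fg$mu, tolerance = 1e-8)
})

test_that("backsolved marker effects reproduce the ridge solution exactly", {
  pop <- small_population(seed = 22, n = 40, m = 100, h2 = 0.5)
  fr <- fit_rrblup(pop$y, pop$geno)
  G <- compute_grm(pop$geno, ridge = 0)
  fg <- fit_gblup(pop$y, G, sigma2_g = fr$varcomp$sigma2_g,
                  sigma2_e = fr$varcomp$sigma2_e)
  beta <- backsolve_marker_effects(fg, pop$geno)
  expect_lt(max(abs(beta - fr$beta)), 1e-4)
  # round trip: recomputing GEBVs from the backsolved effects
  Z <- sweep(dose_matrix(pop$geno), 2, 2 * fg$freq)
  expect_lt(max(abs(drop(Z %*% beta) - fg$gebv)), 1e-4)
})

test_that("a linear kernel reduces kernel regression to genomic BLUP", {
  pop <- small_population(seed = 23, n = 35, m = 80)
  fk <- fit_rkhs(pop$y, pop$geno, wgr_spec("rkhs", kernel = "linear"))
  fg <- fit_wgr(pop$y, pop$geno, wgr_spec("gblup"))
  expect_lt(max(abs(fk$gebv - fg$gebv)), 1e-4)
})

test_that("the Gaussian kernel is a proper similarity on the dose space", {
  pop <- small_population(seed = 24, n = 25, m = 60)
  fit <- fit_rkhs(pop$y, pop$geno, wgr_spec("rkhs", h = 0.5))
  expect_equal(unname(diag(fit$K)), rep(1, 25))
  expect_true(all(fit$K > 0 & fit$K <= 1))
  expect_equal(fit$K, t(fit$K))
})

test_that("chains are reproducible and the samplers agree with ridge", {
  pop <- small_population(seed = 25, n = 60, m = 120, h2 = 0.6)
  base <- fit_rrblup(pop$y, pop$geno)
  for (m in c("brr", "bayesA", "bayesB", "bayesCpi", "blasso")) {
    f1 <- fit_wgr(pop$y, pop$geno, short_chain(m, seed = 99))
    f2 <- fit_wgr(pop$y, pop$geno, short_chain(m, seed = 99))
    expect_identical(f1$beta, f2$beta)
    expect_true(all(is.finite(f1$beta)))
    expect_gt(cor(f1$gebv, base$gebv), 0.8)
    expect_true(f1$h2_hat >= 0 && f1$h2_hat <= 1)
  }
})

test_that("spike-and-slab samplers report a spike mass and inclusion odds", {
  pop <- small_population(seed = 26, n = 50, m = 100, h2 = 0.6, n_qtl = 5)
  for (m in c("bayesB", "bayesCpi")) {
    f <- fit_wgr(pop$y, pop$geno, short_chain(m))
    expect_true(f$pi_hat >= 0 && f$pi_hat <= 1)
    expect_named(f$prob_included)
    expect_true(all(f$prob_included >= 0 & f$prob_included <= 1))
  }
  f0 <- fit_wgr(pop$y, pop$geno, short_chain("brr"))
  expect_null(f0$pi_hat)
})

test_that("hyperparameters can be held fixed through the prior overrides", {
  pop <- small_population(seed = 27, n = 30, m = 50)
  f <- fit_wgr(pop$y, pop$geno,
               short_chain("brr", hyper = list(fix_sigma_e = 2.5,
                                               fix_sigma_beta = 0.01)))
  expect_equal(f$varcomp$sigma2_e, 2.5, tolerance = 1e-12)
  expect_equal(f$varcomp$sigma2_beta, 0.01, tolerance = 1e-12)
})

test_that("a constant phenotype degrades to an explicit null fit", {
  pop <- small_population(seed = 28, n = 20, m = 30)
  y0 <- setNames(rep(5, 20), names(pop$y))
  expect_warning(f <- fit_rrblup(y0, pop$geno), "constant")
  expect_true(isTRUE(f$null))
  expect_true(all(f$gebv == 0))
})

test_that("prediction is self-consistent, order-invariant and strict on ids", {
  pop <- small_population(seed = 29, n = 40, m = 90)
  f <- fit_rrblup(pop$y, pop$geno)
  # predicting the training set reproduces the training GEBVs
  expect_equal(predict_gebv(f, pop$geno), f$gebv, tolerance = 1e-10)
  # invariant to marker column order
  perm <- sample(ncol(pop$geno$values))
  gp <- subset_markers(pop$geno, markers = perm)
  expect_equal(predict_gebv(f, gp), f$gebv, tolerance = 1e-10)
  # missing markers are reported by name
  gm <- subset_markers(pop$geno, markers = 1:50)
  expect_error(predict_gebv(f, gm), "marker mismatch")
  # a clone of a training plant gets that plant's prediction
  v <- pop$geno$values[c(1, 1), ]
  clone <- marker_matrix(v, c("c1", "c2"), pop$geno$marker_ids,
                         pop$geno$marker_type)
  pr <- predict_gebv(f, clone)
  expect_equal(unname(pr["c1"]), unname(f$gebv[1]), tolerance = 1e-10)
})

test_that("matrix models predict unphenotyped plants through the kernel block", {
  pop <- small_population(seed = 30, n = 50, m = 120, h2 = 0.8)
  ymask <- pop$y
  ymask[1:10] <- NA
  f <- fit_wgr(ymask, pop$geno, wgr_spec("gblup"))
  pred <- predict_gebv(f, subset_markers(pop$geno, plants = 1:10))
  expect_equal(unname(pred), unname(f$gebv[1:10]), tolerance = 1e-10)
  # plants outside the fitted kernel are refused
  out <- marker_matrix(pop$geno$values[1:2, ], c("new1", "new2"),
                       pop$geno$marker_ids, pop$geno$marker_type)
  expect_error(predict_gebv(f, out), "inside the fitted kernel")
})

test_that("training-only centering keeps validation plants out of the model scale", {
  pop <- small_population(seed = 31, n = 45, m = 100)
  ymask <- pop$y
  ymask[1:9] <- NA
  f <- fit_rrblup(ymask, pop$geno)
  tr_freq <- colMeans(dose_matrix(
    subset_markers(pop$geno, plants = 10:45))) / 2
  expect_equal(unname(f$freq), unname(tr_freq), tolerance = 1e-12)
})

test_that("phenotype names align onto plant ids", {
  pop <- small_population(seed = 32, n = 20, m = 30)
  y <- pop$y
  names(y)[1] <- "stranger"
  f <- fit_rrblup(y, pop$geno)
  expect_equal(length(f$gebv), 20)
  expect_error(fit_rrblup(unname(pop$y)[1:5], pop$geno), "one value per")
  expect_error(fit_rrblup(setNames(1:5, paste0("x", 1:5)), pop$geno),
               "no phenotype names match")
})
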