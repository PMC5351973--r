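# Mixed-model assembly, EM-REML estimation and derived genetic parameters.

make_balanced_data <- function(seed = 1, g = 8, b = 3, s2g = 4, s2e = 1) {
  set.seed(seed)
  ids <- paste0("G", seq_len(g))
  u <- rnorm(g, 0, sqrt(s2g))
  df <- expand.grid(plant_id = ids, block = paste0("B", seq_len(b)),
                    stringsAsFactors = FALSE)
  df$value <- 10 + u[match(df$plant_id, ids)] + rnorm(nrow(df), 0, sqrt(s2e))
  phenotype_table(data.frame(df, experiment = "germplasm",
                             family = df$plant_id, trait = "t"))
}

test_that("design assembly builds the expected incidence structure", {
  ph <- make_balanced_data()
  md <- suppressWarnings(build_design(ph, "germplasm", "t"))
  expect_equal(ncol(md$X), 3)                       # intercept + 2 blocks
  expect_equal(md$terms$additive$q, 8)
  expect_equal(dim(md$terms$additive$Z), c(24, 8))
  expect_true(all(rowSums(md$terms$additive$Z) == 1))
  # single observation per block-by-genotype cell: plot term unidentifiable
  expect_warning(build_design(ph, "germplasm", "t"), "plot")
  expect_null(suppressWarnings(build_design(ph, "germplasm", "t"))$terms$plot)
  expect_error(build_design(ph, "germplasm", "nope"), "no records")
})

test_that("a replicated plot term is kept and the diallel adds family", {
  ph <- make_balanced_data()
  rec <- rbind(transform(as.data.frame(ph), replicate = "1"),
               transform(as.data.frame(ph), replicate = "2",
                         value = value + 0.5))
  md <- build_design(phenotype_table(rec), "germplasm", "t")
  expect_false(is.null(md$terms$plot))
  expect_equal(md$terms$plot$q, 24)

  dia <- as.data.frame(make_balanced_data(seed = 2))
  dia$experiment <- "diallel"
  dia$family <- rep(c("FS1", "FS2"), length.out = nrow(dia))
  md2 <- suppressWarnings(build_design(phenotype_table(dia), "diallel", "t"))
  expect_equal(md2$terms$family$q, 2)
  dia$family <- "FS1"
  expect_error(suppressWarnings(
    build_design(phenotype_table(dia), "diallel", "t")), "families")
})

test_that("EM-REML matches the balanced-ANOVA estimators", {
  ph <- make_balanced_data(seed = 42, g = 30, b = 4, s2g = 6, s2e = 2)
  md <- suppressWarnings(build_design(ph, "germplasm", "t"))
  vc <- reml_fit(md, tol = 1e-12)
  df <- as.data.frame(ph)
  aov_tab <- anova(lm(value ~ block + plant_id, data = df))
  ms_g <- aov_tab["plant_id", "Mean Sq"]
  ms_e <- aov_tab["Residuals", "Mean Sq"]
  expect_equal(vc$components$additive, (ms_g - ms_e) / 4, tolerance = 1e-4)
  expect_equal(vc$components$residual, ms_e, tolerance = 1e-4)
  expect_true(vc$converged)
})

test_that("the EM iteration never decreases the restricted likelihood", {
  ph <- make_balanced_data(seed = 7, g = 12, b = 2)
  md <- suppressWarnings(build_design(ph, "germplasm", "t"))
  vc <- reml_fit(md)
  expect_gt(vc$iterations, 1)
  expect_true(all(diff(vc$loglik) >= -1e-8))
})

test_that("the MME-based restricted likelihood equals the direct V-form", {
  ph <- make_balanced_data(seed = 3, g = 6, b = 2)
  md <- suppressWarnings(build_design(ph, "germplasm", "t"))
  vc <- reml_fit(md)
  s2 <- unlist(vc$components)
  # one more EM pass started at the converged values records the restricted
  # log-likelihood exactly at those values
  ll_mme <- suppressWarnings(
    reml_fit(md, max_iter = 1, start = as.list(s2)))$loglik[1]
  # direct computation: lR = -1/2 [log|V| + log|X'V^-1 X| + y' P y]
  Z <- md$terms$additive$Z
  V <- s2["additive"] * tcrossprod(Z) + diag(s2["residual"], length(md$y))
  Vi <- solve(V)
  X <- md$X
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  ll_direct <- -0.5 * (determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       drop(crossprod(md$y, P %*% md$y)))
  expect_equal(as.numeric(ll_mme), as.numeric(ll_direct), tolerance = 1e-6)
})

test_that("a genomic covariance sharpens estimates and is accepted", {
  pop <- small_population(seed = 11, n = 40, m = 100, h2 = 0.6)
  cfg <- pop$cfg
  ph <- sim_phenotypes(sim_founder_genotypes(cfg), cfg)
  G <- compute_grm(pop$geno)
  md <- suppressWarnings(build_design(ph$pheno, "germplasm", "trait",
                                      additive_covariance = G))
  vc <- reml_fit(md)
  expect_true(all(unlist(vc$components) >= 0))
  expect_true(is.finite(vc$loglik[vc$iterations]))
  # missing genotypes in the GRM are caught
  G2 <- G; G2$plant_ids <- sub("F01", "XX", G2$plant_ids)
  expect_error(suppressWarnings(
    build_design(ph$pheno, "germplasm", "trait",
                 additive_covariance = G2)), "missing genotype")
})

test_that("the unconstrained difference-method residual is an exact identity", {
  ph <- make_balanced_data(seed = 5, g = 10, b = 2)
  md <- suppressWarnings(build_design(ph, "germplasm", "t"))
  vc <- reml_fit(md, constrain = FALSE)
  yadj <- residuals(lm(md$y ~ 0 + md$X)) + mean(md$y)
  expect_equal(vc$components$residual,
               var(yadj) - vc$components$additive, tolerance = 1e-10)
})

test_that("genetic parameters expand family variance by the Falconer coefficient", {
  vc <- structure(list(components = list(additive = 25, residual = 75),
                       sigma2_p = 100, loglik = 0, iterations = 1,
                       converged = TRUE, constrained = TRUE,
                       trait_mean = 50, design = "germplasm", trait = "t"),
                  class = "varcomp")
  gp1 <- genetic_parameters(vc, falconer_k = 1)
  gp4 <- genetic_parameters(vc, falconer_k = 4)
  expect_equal(gp1$h2_a, 0.25)
  expect_equal(gp4$sigma2_a, 100)
  expect_equal(gp4$h2_a, 1)            # sigma2_p stays the model sum
  expect_equal(gp1$cv_g, 100 * sqrt(25) / 50)
  expect_equal(gp1$cv_r, gp1$cv_g / gp1$cv_e)
})

test_that("degenerate parameter combinations warn instead of failing silently", {
  vc <- structure(list(components = list(additive = 30, residual = -5),
                       sigma2_p = 25, loglik = 0, iterations = 1,
                       converged = TRUE, constrained = FALSE,
                       trait_mean = 10, design = "germplasm", trait = "t"),
                  class = "varcomp")
  expect_warning(gp <- genetic_parameters(vc), "negative residual")
  expect_true(is.na(gp$cv_e))
  expect_gt(gp$h2_a, 1)
  vc0 <- structure(list(components = list(additive = 30, residual = 0),
                        sigma2_p = 30, loglik = 0, iterations = 1,
                        converged = TRUE, constrained = TRUE,
                        trait_mean = 10, design = "germplasm", trait = "t"),
                   class = "varcomp")
  expect_warning(gp0 <- genetic_parameters(vc0), "infinite")
  expect_equal(gp0$cv_r, Inf)
})

test_that("the indirect-selection cycle threshold scales as r_A / H_X", {
  expect_equal(indirect_selection_threshold(0.6, 0.5, 10), 12)
  expect_equal(indirect_selection_threshold(0.3, 0.6, 8), 4)
  expect_error(indirect_selection_threshold(0.5, 0, 1), "H_X")
})

test_that("parameter tables assemble one labelled row per fit", {
  vc <- structure(list(components = list(additive = 25, residual = 75),
                       sigma2_p = 100, loglik = 0, iterations = 1,
                       converged = TRUE, constrained = TRUE,
                       trait_mean = 50, design = "germplasm", trait = "GY"),
                  class = "varcomp")
  tab <- write_parameter_table(list(a = genetic_parameters(vc)))
  expect_equal(nrow(tab), 1)
  expect_true(all(c("design", "trait", "sigma2_a", "h2_a", "cv_r") %in%
                  names(tab)))
})
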