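# Shared fixtures for the test suite.

# A small simulated population with a quantitative trait: returns the
# genotypes (imputed), a plant-level phenotype vector and the generating
# truth.
small_population <- function(seed = 1L, n = 60, m = 120, n_qtl = 20,
                             h2 = 0.5, prop_dominant = 0.5) {
  cfg <- sim_config(n_founders = n, n_markers = m,
                    n_qtl = min(n_qtl, m %/% 2),
                    target_h2 = h2, prop_dominant = prop_dominant,
                    block_count = 1, seed = seed)
  geno <- sim_founder_genotypes(cfg)
  ph <- sim_phenotypes(geno, cfg)
  list(geno = impute_and_filter(geno), y = plant_means(ph$pheno, "trait"),
       truth = ph$truth, cfg = cfg)
}

# A tiny deterministic marker matrix with known codes.
tiny_geno <- function() {
  v <- rbind(c(0, 1, 0), c(2, 1, 1), c(1, 0, 1), c(1, 2, 0))
  marker_matrix(v, paste0("P", 1:4), paste0("M", 1:3),
                c("codominant", "codominant", "dominant"))
}

# Balanced two-block phenotype records with known block effects.
two_block_pheno <- function(values_b1, values_b2, ids = NULL) {
  n <- length(values_b1)
  if (is.null(ids)) ids <- paste0("P", seq_len(n))
  phenotype_table(data.frame(
    plant_id = rep(ids, 2), experiment = "germplasm",
    family = rep(paste0("F", seq_len(n)), 2),
    block = rep(c("B1", "B2"), each = n), trait = "t",
    value = c(values_b1, values_b2)))
}
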