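# End-to-end orchestration: simulate-or-load -> QC -> diversity -> REML
# parameters -> model comparison -> density curves, with hierarchical seeds,
# a manifest, and CSV outputs shaped like the standard report tables.

#' Run configuration for the full analysis
#'
#' Exactly one of `geno_path`/`pheno_path` (load) or `sim` (simulate) drives
#' the input stage.
#'
#' @param geno_path,pheno_path input files ([read_genotypes()] /
#'   [read_phenotypes()] formats).
#' @param sim list of arguments for [make_study_like_dataset()] (e.g.
#'   `n_markers`, `n_qtl`).
#' @param traits trait names to analyze.
#' @param methods character vector of model names for the comparison stage.
#' @param chain list: `burnin`, `niter`, `thin` for the Bayesian methods.
#' @param cv list: `n_folds`, `n_repeats`.
#' @param density list: `reps`, `schedule`, `max_markers` (subsample the
#'   panel before elimination; `NULL` = all).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "qc", "diversity", "reml", "compare", "density")`.
#' @param outdir output directory.
#' @param seed master seed; every stage derives its own stream from it.
#' @param verbose logging flag.
#' @return a `run_config` list.
#' @export
run_config <- function(geno_path = NULL, pheno_path = NULL, sim = list(),
                       traits = c("GY", "W100S"),
                       methods = c("bayesA", "bayesB", "bayesCpi", "brr",
                                   "blasso", "gblup", "rkhs", "rrblup"),
                       chain = list(burnin = 500, niter = 1500, thin = 5),
                       cv = list(n_folds = 5, n_repeats = 1),
                       density = list(reps = 5, schedule = 0.05,
                                      max_markers = NULL),
                       stages = c("simulate", "qc", "diversity", "reml",
                                  "compare", "density"),
                       outdir = tempfile("gwsel_run_"), seed = 1L,
                       verbose = FALSE) {
  have_files <- !is.null(geno_path) || !is.null(pheno_path)
  have_sim <- TRUE  # sim defaults always available
  if (have_files && (is.null(geno_path) || is.null(pheno_path)))
    stopf("provide both geno_path and pheno_path, or neither")
  structure(list(geno_path = geno_path, pheno_path = pheno_path, sim = sim,
                 traits = traits, methods = methods, chain = chain, cv = cv,
                 density = density, stages = stages, outdir = outdir,
                 seed = as.integer(seed), verbose = verbose,
                 from_files = have_files),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
run_config_from_file <- function(path) {
  cfg <- read_run_config(path)
  do.call(run_config, cfg)
}

#' Run the full genomic-wide-selection analysis
#'
#' Executes the requested stages in order, writing one CSV per report table
#' (variance components and genetic parameters; MDS coordinates; the
#' method-comparison table; the marker-density curve) plus a JSON manifest
#' with the inputs, seeds and per-output checksums that make re-runs
#' byte-comparable.
#'
#' @param cfg a [run_config()].
#' @return a report bundle (list): `manifest`, `geno`, `pheno`,
#'   `parameters`, `mds`, `comparison`, `density` (stages not run are
#'   `NULL`).  On stage failure the error is recorded in the manifest,
#'   partial results are kept, and the bundle carries `failed = TRUE`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list(),
                   outputs = list(), version = as.character(
                     utils::packageVersion("gwsel")))
  bundle <- list(failed = FALSE)
  t_all <- Sys.time()

  run_stage <- function(name, fun) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res),
                                       seconds = elapsed)
      bundle$failed <<- TRUE
      gwsel_log(sprintf("stage %s FAILED: %s", name, conditionMessage(res)),
                verbose = TRUE)
      NULL
    } else {
      manifest$stages[[name]] <<- list(status = "ok", seconds = elapsed)
      if (cfg$verbose)
        gwsel_log(sprintf("stage %s done (%.1fs)", name, elapsed))
      res
    }
  }
  emit <- function(df, file) {
    path <- file.path(cfg$outdir, file)
    data.table::fwrite(df, path)
    manifest$outputs[[file]] <<- unname(tools::md5sum(path))
    path
  }

  # --- input stage -------------------------------------------------------
  dat <- run_stage("simulate", function() {
    if (cfg$from_files) {
      list(geno = read_genotypes(cfg$geno_path),
           pheno = read_phenotypes(cfg$pheno_path), truth = NULL)
    } else {
      do.call(make_study_like_dataset,
              c(list(seed = derive_seed(cfg$seed, 1L)), cfg$sim))
    }
  })
  if (is.null(dat)) {
    manifest$seconds_total <- as.numeric(
      difftime(Sys.time(), t_all, units = "secs"))
    bundle$manifest <- manifest
    write_manifest(manifest, cfg$outdir)
    return(bundle)
  }
  bundle$pheno <- dat$pheno

  geno <- run_stage("qc", function()
    impute_and_filter(dat$geno, maf_min = 0, max_missing = 1)) %||%
    impute_and_filter(dat$geno)
  bundle$geno <- geno
  traits <- intersect(cfg$traits, unique(dat$pheno$trait))

  # --- diversity ---------------------------------------------------------
  bundle$mds <- run_stage("diversity", function() {
    ibs <- compute_ibs_distance(geno)
    mds <- classical_mds(ibs, k = 2)
    emit(data.frame(plant_id = mds$plant_ids, mds$coordinates),
         "mds_coordinates.csv")
    mds
  })

  # --- REML parameters ---------------------------------------------------
  bundle$parameters <- run_stage("reml", function() {
    params <- list()
    for (tn in traits) {
      for (dsg in intersect(unique(dat$pheno$experiment),
                            c("germplasm", "diallel"))) {
        md <- tryCatch(build_design(dat$pheno, dsg, tn),
                       error = function(e) NULL)
        if (is.null(md)) next
        vc <- suppressWarnings(reml_fit(md))
        k <- if (dsg == "germplasm") 4 else 1
        params[[paste(dsg, tn, sep = "_")]] <-
          suppressWarnings(genetic_parameters(vc, falconer_k = k))
      }
    }
    df <- write_parameter_table(params)
    emit(df, "genetic_parameters.csv")
    params
  })

  # --- model comparison --------------------------------------------------
  bundle$comparison <- run_stage("compare", function() {
    out <- NULL
    for (tn in traits) {
      yv <- plant_means(dat$pheno, tn)
      yv <- yv[names(yv) %in% geno$plant_ids]
      specs <- lapply(cfg$methods, function(mm) wgr_spec(
        mm, burnin = cfg$chain$burnin, niter = cfg$chain$niter,
        thin = cfg$chain$thin, seed = derive_seed(cfg$seed, 3L,
                                                  match(tn, traits))))
      plan <- make_folds(names(yv), cfg$cv$n_folds, cfg$cv$n_repeats,
                         seed = derive_seed(cfg$seed, 4L, match(tn, traits)))
      cvr <- cross_validate(geno, yv, specs, plan)
      tab <- report_comparison(cvr)
      tab$trait <- tn
      out <- rbind(out, tab)
    }
    emit(out, "method_comparison.csv")
    out
  })

  # --- marker density ----------------------------------------------------
  bundle$density <- run_stage("density", function() {
    out <- NULL
    for (tn in traits) {
      yv <- plant_means(dat$pheno, tn)
      yv <- yv[names(yv) %in% geno$plant_ids]
      gd <- geno
      mm <- cfg$density$max_markers
      if (!is.null(mm) && mm < ncol(geno$values)) {
        set.seed(derive_seed(cfg$seed, 5L, match(tn, traits)))
        gd <- subset_markers(geno, markers = sort(sample.int(
          ncol(geno$values), mm)))
      }
      curve <- backward_elimination(
        gd, yv, reps = cfg$density$reps, schedule = cfg$density$schedule,
        seed = derive_seed(cfg$seed, 6L, match(tn, traits)))
      tab <- curve$records
      tab$trait <- tn
      out <- rbind(out, tab)
    }
    emit(out, "density_curve.csv")
    out
  })

  manifest$seconds_total <- as.numeric(
    difftime(Sys.time(), t_all, units = "secs"))
  bundle$manifest <- manifest
  write_manifest(manifest, cfg$outdir)
  bundle
}

#' @keywords internal
write_manifest <- function(manifest, outdir) {
  # per-stage timings are informational only and excluded from the
  # checksum-stable portion of the manifest
  stable <- manifest
  stable$stages <- lapply(stable$stages, function(s) s["status"])
  stable$seconds_total <- NULL
  jsonlite::write_json(stable, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest_timed.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Method-comparison table from a cross-validation result
#'
#' One row per method with mean prediction ability, its standard error and
#' the mean estimated genomic heritability, ordered by the conventional
#' method codes (BA, BB, BC, BR, BL, GB, RK, RB).
#'
#' @param cv a `cv_result` from [cross_validate()].
#' @return data.frame (method, code, ability_mean, ability_se,
#'   n_folds_used, h2_hat_mean).
#' @export
report_comparison <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  codes <- c(bayesA = "BA", bayesB = "BB", bayesCpi = "BC", brr = "BR",
             blasso = "BL", gblup = "GB", rkhs = "RK", rrblup = "RB")
  s <- cv$summary
  s$code <- codes[s$method]
  s <- s[order(match(s$code, codes)), c("method", "code", "ability_mean",
                                        "ability_se", "n_folds_used",
                                        "n_failed", "h2_hat_mean")]
  rownames(s) <- NULL
  s
}
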