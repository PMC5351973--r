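# Genomic relationship matrix, identity-by-state distance and classical MDS.

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = Z Z' / (2 * sum_j p_j (1 - p_j))` where `Z` is the allele-dose
#' matrix centered by twice the observed allele frequencies `p_j`.  Dominant
#' presence/absence markers enter on the 0/2 dose scale (see
#' [dose_matrix()]).  A small ridge is added to the diagonal so the matrix
#' is invertible for the mixed-model equations and marker-effect backsolve.
#'
#' @param geno a [marker_matrix()] with no missing values.
#' @param ridge diagonal stabilizer (default 1e-6; set 0 for the raw matrix).
#' @param freq optional centering allele frequencies (e.g. computed on a
#'   training subset to avoid leakage in cross-validation); defaults to the
#'   observed frequencies of `geno`.
#' @return a `relationship_matrix`: list with `values` (n x n), `plant_ids`,
#'   `kind = "grm"`, plus `freq` (the centering frequencies) and `scale_c`
#'   (the VanRaden denominator), which whole-genome regression reuses.
#' @export
compute_grm <- function(geno, ridge = 1e-6, freq = NULL) {
  M <- dose_matrix(geno)
  p <- if (is.null(freq)) colMeans(M) / 2 else freq
  c0 <- 2 * sum(p * (1 - p))
  if (c0 <= 0) stopf("all markers monomorphic: zero VanRaden denominator")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / c0
  if (ridge > 0) diag(G) <- diag(G) + ridge
  dimnames(G) <- list(geno$plant_ids, geno$plant_ids)
  structure(list(values = G, plant_ids = geno$plant_ids, kind = "grm",
                 freq = p, scale_c = c0),
            class = "relationship_matrix")
}

#' Identity-by-state distance matrix
#'
#' `d_ij = 1 - mean_j s_ij(j)` where the per-marker shared-allele proportion
#' is `1 - |dose_i - dose_j| / 2` for codominant markers and an exact-match
#' indicator (1 if equal, else 0) for dominant markers.  Zero diagonal,
#' entries in `[0, 1]`.
#'
#' @param geno a [marker_matrix()] with no missing values.
#' @return a `relationship_matrix` with `kind = "ibs_distance"`.
#' @export
compute_ibs_distance <- function(geno) {
  stopifnot(inherits(geno, "marker_matrix"))
  v <- geno$values
  if (anyNA(v)) stopf("missing genotypes present; impute first")
  if (ncol(v) == 0) stopf("zero markers")
  n <- nrow(v)
  cod <- geno$marker_type == "codominant"
  D <- matrix(0, n, n)
  Vc <- v[, cod, drop = FALSE]
  Vd <- v[, !cod, drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      s <- 0
      if (ncol(Vc)) s <- s + sum(1 - abs(Vc[i, ] - Vc[k, ]) / 2)
      if (ncol(Vd)) s <- s + sum(Vd[i, ] == Vd[k, ])
      D[i, k] <- D[k, i] <- 1 - s / ncol(v)
    }
  }
  dimnames(D) <- list(geno$plant_ids, geno$plant_ids)
  structure(list(values = D, plant_ids = geno$plant_ids,
                 kind = "ibs_distance"),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix (%s): %d plants\n", x$kind,
              length(x$plant_ids)))
  invisible(x)
}

#' Classical (metric) multidimensional scaling of an IBS distance matrix
#'
#' Principal-coordinates analysis: eigendecomposition of the double-centered
#' squared-distance matrix `-1/2 J D^2 J`.  Coordinates are the top-`k`
#' eigenvectors scaled by the square root of their eigenvalues; axes with
#' non-positive eigenvalues are excluded (with a warning if fewer than `k`
#' positive axes exist).  The full eigenvalue spectrum is reported.
#'
#' @param dist a `relationship_matrix` of kind `"ibs_distance"` (or any
#'   symmetric distance matrix wrapped in that structure).
#' @param k number of axes requested (default 2).
#' @return list with `coordinates` (n x k', column-centered), `eigenvalues`
#'   (descending), `plant_ids`.
#' @export
classical_mds <- function(dist, k = 2) {
  stopifnot(inherits(dist, "relationship_matrix"))
  if (dist$kind != "ibs_distance")
    stopf("classical_mds expects an IBS distance matrix")
  D <- dist$values
  n <- nrow(D)
  fit <- stats::cmdscale(stats::as.dist(D), k = min(k, n - 1), eig = TRUE)
  ev <- sort(fit$eig, decreasing = TRUE)
  npos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1))
  if (npos < k)
    warnf("only %d positive-eigenvalue axes available (%d requested)",
          npos, k)
  coords <- fit$points[, seq_len(min(k, npos)), drop = FALSE]
  if (ncol(coords))
    coords <- sweep(coords, 2, colMeans(coords))  # exact centering
  rownames(coords) <- dist$plant_ids
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = ev, plant_ids = dist$plant_ids)
}

#' Write a labelled relationship matrix or MDS coordinates as CSV
#'
#' @param x a `relationship_matrix` or the result of [classical_mds()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relmat <- function(x, path) {
  if (inherits(x, "relationship_matrix")) {
    df <- data.frame(plant_id = x$plant_ids, as.data.frame(x$values),
                     check.names = FALSE)
  } else if (!is.null(x$coordinates)) {
    df <- data.frame(plant_id = x$plant_ids, x$coordinates,
                     check.names = FALSE)
  } else stopf("unsupported object")
  data.table::fwrite(df, path)
  invisible(path)
}
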