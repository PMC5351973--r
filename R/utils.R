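#' @useDynLib gwsel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var cor rnorm runif rbinom optimize median sd lm model.matrix residuals coef complete.cases setNames quantile
#' @importFrom utils head modifyList
NULL

#' Derive a reproducible sub-seed from a master seed
#'
#' Hierarchical seed derivation so that independent stages (or repeats within
#' a stage) of an analysis get distinct but reproducible random streams from a
#' single master seed.  Values stay below 2^31 - 1 so they are valid R
#' integer seeds.
#'
#' @param master integer master seed.
#' @param ... one or more non-negative integers identifying the stage, repeat
#'   and so on.
#' @return an integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    # 64-bit safe LCG-style mix kept inside double precision
    s <- (s * 48271 + as.double(k) * 2654435761 + 1) %% 2147483629
  }
  as.integer(s %% 2147483587 + 1)
}

#' @keywords internal
gwsel_log <- function(..., verbose = getOption("gwsel.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[gwsel] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)
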