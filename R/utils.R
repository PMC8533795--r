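#' @keywords internal
#' @useDynLib netgradient, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

DAYS_PER_YEAR <- 365.25

## Gauss-Legendre nodes/weights on [-1, 1], Golub-Welsch via the symmetric
## tridiagonal Jacobi matrix. Cached per node count.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  if (n < 1) stop("need at least one quadrature node")
  if (n == 1) {
    out <- list(nodes = 0, weights = 2)
  } else {
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    out <- list(nodes = e$values[ord], weights = 2 * (e$vectors[1, ord])^2)
  }
  .gl_cache[[key]] <- out
  out
}

## Decimal calendar year of a Date; used for the time-updated year during
## follow-up (piecewise-constant life-table cells).
decimal_year <- function(date) {
  lt <- as.POSIXlt(date)
  lt$year + 1900 + lt$yday / DAYS_PER_YEAR
}

`%||%` <- function(a, b) if (is.null(a)) b else a

z95 <- 1.959964

stop_coverage <- function(fmt, ...) {
  stop(structure(
    class = c("coverage_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
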