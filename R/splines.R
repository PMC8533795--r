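## Restricted cubic spline bases, tensor products and curvature penalties.
##
## Parameterization: truncated-power natural cubic splines. The raw basis
## with k knots has k columns [1, x, N_1(x), ..., N_{k-2}(x)] with
##   N_j(x) = d_j(x) - d_{k-1}(x),
##   d_j(x) = ((x - k_j)_+^3 - (x - k_k)_+^3) / (k_k - k_j),
## which is linear beyond the boundary knots. Non-constant columns are
## centred and scaled using a fixed uniform reference grid over the knot
## range (201 points), so bases are reproducible functions of the knots
## alone; the curvature penalty is transformed consistently. The curvature
## penalty integrates products of second derivatives exactly (the second
## derivatives are piecewise linear, so Simpson's rule per knot interval
## is exact).

REF_GRID_N <- 201L

#' Knot placement at percentiles of the deceased
#'
#' Knots are placed at the k equally spaced percentiles (0, 1/(k-1), ..., 1)
#' of the covariate's distribution among patients who died, the information-
#' carrying subset in an excess-hazard likelihood.
#'
#' @param values_among_deceased covariate values of records with event = 1
#' @param k number of knots (>= 3)
#' @param label dimension label, one of "time", "age", "edi"
#' @return object of class `knot_set`
#' @export
place_knots <- function(values_among_deceased, k,
                        label = c("time", "age", "edi")) {
  label <- match.arg(label)
  if (k < 3) stop("a restricted cubic spline needs at least 3 knots")
  x <- values_among_deceased[is.finite(values_among_deceased)]
  if (length(unique(x)) < k) {
    stop("degenerate knots: fewer than k distinct values among the deceased")
  }
  kn <- unname(stats::quantile(x, probs = seq(0, 1, length.out = k), type = 7))
  kn <- unique(kn)
  if (length(kn) < 3) {
    stop("degenerate knots: fewer than 3 distinct knots after collapsing")
  }
  knot_set(kn, label)
}

#' Construct a knot set from explicit values
#' @param values strictly increasing knot locations (>= 3)
#' @param label dimension label
#' @export
knot_set <- function(values, label = "time") {
  values <- as.numeric(values)
  if (length(values) < 3 || is.unsorted(values, strictly = TRUE)) {
    stop("knots must be >= 3 strictly increasing values")
  }
  structure(list(values = values, label = label), class = "knot_set")
}

## raw truncated-power natural basis, k columns (deriv 0 or 2)
.rcs_raw <- function(x, kn, deriv = 0) {
  k <- length(kn)
  n <- length(x)
  d <- function(j) {
    if (deriv == 0) {
      (pmax(x - kn[j], 0)^3 - pmax(x - kn[k], 0)^3) / (kn[k] - kn[j])
    } else {
      6 * (pmax(x - kn[j], 0) - pmax(x - kn[k], 0)) / (kn[k] - kn[j])
    }
  }
  B <- matrix(0, n, k)
  if (deriv == 0) {
    B[, 1] <- 1
    B[, 2] <- x
  }
  if (k > 2) {
    dk1 <- d(k - 1)
    for (j in seq_len(k - 2)) B[, j + 2] <- d(j) - dk1
  }
  B
}

## exact integral of products of second derivatives (k x k, rows/cols 1:2 zero)
.rcs_penalty_raw <- function(kn) {
  k <- length(kn)
  S <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    xa <- kn[i]; xb <- kn[i + 1]; xm <- (xa + xb) / 2
    Da <- .rcs_raw(xa, kn, deriv = 2)
    Dm <- .rcs_raw(xm, kn, deriv = 2)
    Db <- .rcs_raw(xb, kn, deriv = 2)
    S <- S + (xb - xa) / 6 *
      (crossprod(Da) + 4 * crossprod(Dm) + crossprod(Db))
  }
  (S + t(S)) / 2
}

## centring/scaling of the non-constant raw columns over the reference grid
.rcs_transform <- function(kn) {
  xg <- seq(kn[1], kn[length(kn)], length.out = REF_GRID_N)
  Bg <- .rcs_raw(xg, kn)
  m <- colMeans(Bg)
  s <- apply(Bg, 2, stats::sd)
  m[1] <- 0; s[1] <- 1
  s[s == 0] <- 1
  list(center = m, scale = s)
}

## full marginal basis (k columns, column 1 == 1) plus transformed penalty
.rcs_full <- function(x, kn) {
  tr <- .rcs_transform(kn)
  B <- .rcs_raw(x, kn)
  B <- sweep(B, 2, tr$center, `-`)
  B <- sweep(B, 2, tr$scale, `/`)
  S <- .rcs_penalty_raw(kn)
  S <- S / tcrossprod(tr$scale)
  list(design = B, penalty = S)
}

#' One-dimensional restricted cubic spline basis block
#'
#' Returns the k-1 non-constant basis columns (centred over the knot-range
#' reference grid, unit-scaled) and the matching exact curvature penalty.
#' The model intercept is carried once, globally, at the model level.
#'
#' @param x evaluation points
#' @param knots a [knot_set()]
#' @param deriv 0 for the basis, 2 for its second derivative
#' @return object of class `basis_block`: list(design, penalties, label)
#' @export
rcs_basis <- function(x, knots, deriv = 0) {
  kn <- knots$values
  if (deriv == 2) {
    tr <- .rcs_transform(kn)
    D <- sweep(.rcs_raw(x, kn, deriv = 2), 2, tr$scale, `/`)
    return(basis_block(D[, -1, drop = FALSE], list(), knots$label))
  }
  f <- .rcs_full(x, kn)
  basis_block(f$design[, -1, drop = FALSE],
              list(f$penalty[-1, -1, drop = FALSE]),
              knots$label)
}

#' @rdname rcs_basis
#' @param design design matrix
#' @param penalties list of symmetric PSD penalty matrices
#' @param label block label
#' @export
basis_block <- function(design, penalties, label = "") {
  p <- ncol(design)
  for (S in penalties) {
    if (!all(dim(S) == p)) stop("penalty dimension does not match design")
  }
  structure(list(design = design, penalties = penalties, label = label),
            class = "basis_block")
}

## row-wise Kronecker product, first margin fastest
row_kronecker <- function(mats) {
  out <- mats[[1]]
  for (m in mats[-1]) {
    n <- nrow(out)
    if (nrow(m) != n) stop("margins must have matching row counts")
    out <- out[, rep(seq_len(ncol(out)), times = ncol(m)), drop = FALSE] *
      m[, rep(seq_len(ncol(m)), each = ncol(out)), drop = FALSE]
  }
  out
}

## Kronecker penalty for margin j of given marginal sizes; ordering matches
## row_kronecker (first margin fastest <=> last factor in kronecker())
kron_penalty <- function(S_j, sizes, j) {
  mats <- lapply(sizes, diag)
  mats[[j]] <- S_j
  Reduce(kronecker, rev(mats))
}

#' Penalized tensor-product basis
#'
#' Row-wise Kronecker product of 2 or 3 marginal blocks (first margin
#' varying fastest), with one Kronecker-structured penalty per margin:
#' the marginal curvature penalty crossed with identities on the other
#' margins.
#'
#' @param margins list of `basis_block`s, each carrying exactly one penalty
#' @return a `basis_block` with `length(margins)` penalties
#' @export
tensor_basis <- function(margins) {
  if (!length(margins) %in% 2:3) stop("tensor_basis takes 2 or 3 margins")
  sizes <- vapply(margins, function(b) ncol(b$design), integer(1))
  if (prod(sizes) > 1e4) stop("tensor dimension overflow (> 10^4 columns)")
  design <- row_kronecker(lapply(margins, `[[`, "design"))
  pens <- lapply(seq_along(margins), function(j) {
    if (length(margins[[j]]$penalties) != 1) {
      stop("each margin must carry exactly one penalty")
    }
    kron_penalty(margins[[j]]$penalties[[1]], sizes, j)
  })
  basis_block(design, pens,
              paste(vapply(margins, `[[`, "", "label"), collapse = ":"))
}

#' Interaction-only tensor-product basis
#'
#' Tensor product of two marginal blocks whose span contains no function of
#' either variable alone: the marginal blocks must be the centred
#' non-constant restricted-cubic columns (as returned by [rcs_basis()]), so
#' every tensor column averages to zero over the marginal reference grid and
#' the block carries pure interaction only. Penalties are the two Kronecker
#' constructions. Errors if the resulting design is rank deficient on the
#' supplied evaluation points.
#'
#' @param margins list of exactly 2 `basis_block`s
#' @export
interaction_tensor_basis <- function(margins) {
  if (length(margins) != 2) stop("interaction tensor takes exactly 2 margins")
  out <- tensor_basis(margins)
  ## a rank check is only meaningful when the evaluation points themselves
  ## span each margin (e.g. at a single fixed time the rows are degenerate
  ## by construction, not by error)
  margins_full <- all(vapply(margins, function(b) {
    nrow(b$design) >= ncol(b$design) && qr(b$design)$rank == ncol(b$design)
  }, logical(1)))
  if (margins_full && nrow(out$design) >= ncol(out$design)) {
    if (qr(out$design)$rank < ncol(out$design)) {
      stop("interaction tensor design is rank deficient after constraints")
    }
  }
  out
}
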