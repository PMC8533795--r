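## Model structures for the log excess hazard:
##   constant : intercept only (testing / degenerate baseline)
##   M0  : tensor(time, age)                       - no deprivation effect
##   M1  : tensor(time, age) + s(EDI)              - proportional EDI effect
##   M1b : tensor(time, age) + s(EDI) + tint(time, EDI) - time-dependent
##   M2  : tensor(time, age, EDI)                  - time- and age-dependent
##
## The global intercept is the pure-constant Kronecker column of the leading
## tensor block (both marginal bases carry an explicit constant column), so
## no extra identifiability constraint is needed; the added s(EDI) and
## tint blocks contain no constant and no marginal main effects.
## Column ordering within tensors: time fastest, then age, then EDI.

#' Excess-hazard model specification
#'
#' @param structure one of "M0", "M1", "M1b", "M2", "constant"
#' @param knots named list of [knot_set()]s: `time`, `age` and (for M1/M1b/M2)
#'   `edi`
#' @param n_nodes Gauss-Legendre nodes per subject for cumulative-hazard
#'   quadrature (default 20)
#' @param tint_two_lambdas should the interaction-only tensor carry one
#'   smoothing parameter per direction (default TRUE)?
#' @return object of class `model_spec`
#' @export
model_spec <- function(structure = c("M0", "M1", "M1b", "M2", "constant"),
                       knots, n_nodes = 20, tint_two_lambdas = TRUE) {
  structure <- match.arg(structure)
  if (structure != "constant") {
    need <- if (structure == "M0") c("time", "age") else c("time", "age", "edi")
    if (!all(need %in% names(knots))) {
      stop("knots must contain: ", paste(need, collapse = ", "))
    }
  } else {
    knots <- list()
  }
  if (n_nodes < 10) stop("need at least 10 quadrature nodes")
  obj <- list(structure = structure, knots = knots,
              n_nodes = as.integer(n_nodes),
              tint_two_lambdas = isTRUE(tint_two_lambdas))
  class(obj) <- "model_spec"
  obj$p <- length(model_term_labels(obj)$columns)
  obj
}

#' Build a model specification with knots placed from a cohort
#'
#' Knots are placed at equally spaced percentiles of follow-up time, age at
#' diagnosis and EDI among the deceased.
#'
#' @param structure model structure
#' @param cohort an `eh_cohort`
#' @param k named knot counts (defaults: 6 for time, 5 for age, 5 for EDI)
#' @inheritParams model_spec
#' @export
model_spec_from_cohort <- function(structure, cohort,
                                   k = c(time = 6, age = 5, edi = 5),
                                   n_nodes = 20, tint_two_lambdas = TRUE) {
  dead <- cohort[cohort$event == 1, ]
  if (nrow(dead) < 3) stop("too few events to place knots")
  kn <- list(
    time = place_knots(dead$time_years, k[["time"]], "time"),
    age = place_knots(dead$age, k[["age"]], "age"),
    edi = place_knots(dead$edi, k[["edi"]], "edi")
  )
  model_spec(structure, kn, n_nodes, tint_two_lambdas)
}

## internal: marginal full bases for the needed dimensions
.margins <- function(spec, t, a, edi) {
  out <- list()
  if (spec$structure == "constant") return(out)
  out$time <- .rcs_full(t, spec$knots$time$values)
  out$age <- .rcs_full(a, spec$knots$age$values)
  if (spec$structure != "M0") out$edi <- .rcs_full(edi, spec$knots$edi$values)
  out
}

## column labels / block offsets, used for layout bookkeeping
model_term_labels <- function(spec) {
  if (spec$structure == "constant") {
    return(list(columns = "(Intercept)", blocks = list()))
  }
  kt <- length(spec$knots$time$values)
  ka <- length(spec$knots$age$values)
  ke <- if (!is.null(spec$knots$edi)) length(spec$knots$edi$values) else 0
  cols <- switch(spec$structure,
    M0 = kt * ka,
    M1 = kt * ka + (ke - 1),
    M1b = kt * ka + (ke - 1) + (kt - 1) * (ke - 1),
    M2 = kt * ka * ke
  )
  blocks <- switch(spec$structure,
    M0 = list(tensor_ta = 1:(kt * ka)),
    M1 = list(tensor_ta = 1:(kt * ka),
              s_edi = kt * ka + 1:(ke - 1)),
    M1b = list(tensor_ta = 1:(kt * ka),
               s_edi = kt * ka + 1:(ke - 1),
               tint_te = kt * ka + (ke - 1) + 1:((kt - 1) * (ke - 1))),
    M2 = list(tensor_tae = 1:(kt * ka * ke))
  )
  list(columns = paste0("b", seq_len(cols)), blocks = blocks)
}

#' Model design matrix at given covariate values
#'
#' @param spec a [model_spec()]
#' @param t time since diagnosis (years)
#' @param a age at diagnosis (years)
#' @param edi deprivation score (may be omitted for M0/constant)
#' @return numeric matrix, `length(t)` rows; column 1 is the intercept
#' @export
model_matrix <- function(spec, t, a, edi = NULL) {
  n <- length(t)
  if (spec$structure == "constant") return(matrix(1, n, 1))
  if (spec$structure != "M0" && is.null(edi)) stop("edi values required")
  a <- rep_len(a, n)
  if (!is.null(edi)) edi <- rep_len(edi, n)
  m <- .margins(spec, t, a, edi)
  Bt <- m$time$design; Ba <- m$age$design
  switch(spec$structure,
    M0 = row_kronecker(list(Bt, Ba)),
    M1 = cbind(row_kronecker(list(Bt, Ba)),
               m$edi$design[, -1, drop = FALSE]),
    M1b = cbind(row_kronecker(list(Bt, Ba)),
                m$edi$design[, -1, drop = FALSE],
                row_kronecker(list(Bt[, -1, drop = FALSE],
                                   m$edi$design[, -1, drop = FALSE]))),
    M2 = row_kronecker(list(Bt, Ba, m$edi$design))
  )
}

## embed a block penalty into the full coefficient space
.embed <- function(S, p, at) {
  out <- matrix(0, p, p)
  out[at, at] <- S
  out
}

#' Penalty blocks of a model specification
#'
#' The penalties are block-diagonal by model term. Each block carries the
#' column indices of its term and one small penalty matrix per smoothing
#' direction. Keeping the block structure explicit allows the generalized
#' determinant in the LAML criterion to be computed block-wise with a fixed
#' penalized-subspace rank, which stays numerically stable when smoothing
#' parameters differ by many orders of magnitude.
#'
#' @param spec a [model_spec()]
#' @return list of blocks: list(cols, parts = named list of matrices)
#' @export
model_penalty_blocks <- function(spec) {
  if (spec$structure == "constant") return(list())
  kt <- length(spec$knots$time$values)
  ka <- length(spec$knots$age$values)
  St <- .rcs_full(spec$knots$time$values[1], spec$knots$time$values)$penalty
  Sa <- .rcs_full(spec$knots$age$values[1], spec$knots$age$values)$penalty
  Se <- if (!is.null(spec$knots$edi)) {
    .rcs_full(spec$knots$edi$values[1], spec$knots$edi$values)$penalty
  }
  ke <- if (!is.null(Se)) length(spec$knots$edi$values) else 0
  lab <- model_term_labels(spec)$blocks
  blocks <- list()
  if (spec$structure == "M2") {
    blocks$tensor_tae <- list(
      cols = lab$tensor_tae,
      parts = list(
        tensor_time = kron_penalty(St, c(kt, ka, ke), 1),
        tensor_age = kron_penalty(Sa, c(kt, ka, ke), 2),
        tensor_edi = kron_penalty(Se, c(kt, ka, ke), 3)
      )
    )
    return(blocks)
  }
  blocks$tensor_ta <- list(
    cols = lab$tensor_ta,
    parts = list(
      tensor_time = kron_penalty(St, c(kt, ka), 1),
      tensor_age = kron_penalty(Sa, c(kt, ka), 2)
    )
  )
  if (spec$structure %in% c("M1", "M1b")) {
    blocks$s_edi <- list(
      cols = lab$s_edi,
      parts = list(s_edi = Se[-1, -1, drop = FALSE])
    )
  }
  if (spec$structure == "M1b") {
    Stt <- St[-1, -1, drop = FALSE]
    See <- Se[-1, -1, drop = FALSE]
    parts <- if (spec$tint_two_lambdas) {
      list(tint_time = kron_penalty(Stt, c(kt - 1, ke - 1), 1),
           tint_edi = kron_penalty(See, c(kt - 1, ke - 1), 2))
    } else {
      list(tint = kron_penalty(Stt, c(kt - 1, ke - 1), 1) +
             kron_penalty(See, c(kt - 1, ke - 1), 2))
    }
    blocks$tint_te <- list(cols = lab$tint_te, parts = parts)
  }
  blocks
}

#' Penalty matrices of a model specification
#'
#' One symmetric PSD matrix per smoothing direction, embedded in the full
#' coefficient space: two for tensor(time, age), one for s(EDI), one or two
#' for the interaction-only tensor, three for the 3-D tensor.
#'
#' @param spec a [model_spec()]
#' @return named list of p x p matrices
#' @export
model_penalties <- function(spec) {
  blocks <- model_penalty_blocks(spec)
  p <- spec$p
  pens <- list()
  for (b in blocks) {
    for (nm in names(b$parts)) {
      pens[[nm]] <- .embed(b$parts[[nm]], p, b$cols)
    }
  }
  pens
}

#' Linear predictor: the log excess hazard
#'
#' @param beta coefficient vector (length `spec$p`)
#' @param spec a [model_spec()]
#' @inheritParams model_matrix
#' @export
log_excess_hazard <- function(beta, spec, t, a, edi = NULL) {
  X <- model_matrix(spec, t, a, edi)
  if (length(beta) != ncol(X)) stop("coefficient/design dimension mismatch")
  drop(X %*% beta)
}

#' Cumulative excess hazard by Gauss-Legendre quadrature
#'
#' Integrates `exp(log hE)` over `[0, t]` for each subject with `n_nodes`
#' Gauss-Legendre nodes (exact for polynomial integrands of degree up to
#' `2 n_nodes - 1`).
#'
#' @inheritParams log_excess_hazard
#' @param t upper limits (followup times), one per subject
#' @param n_nodes quadrature nodes (>= 10); defaults to the model
#'   specification's
#' @export
cumulative_excess_hazard <- function(beta, spec, t, a, edi = NULL,
                                     n_nodes = NULL) {
  n_nodes <- n_nodes %||% spec$n_nodes
  if (n_nodes < 10) stop("need at least 10 quadrature nodes")
  gl <- gauss_legendre(n_nodes)
  n <- length(t)
  a <- rep_len(a, n)
  if (!is.null(edi)) edi <- rep_len(edi, n)
  u <- as.vector(outer(gl$nodes + 1, t / 2))            # node fastest
  w <- as.vector(outer(gl$weights, t / 2))
  eta <- log_excess_hazard(beta, spec,
                           u, rep(a, each = n_nodes),
                           if (!is.null(edi)) rep(edi, each = n_nodes))
  if (any(!is.finite(eta))) stop("non-finite log excess hazard in quadrature")
  colSums(matrix(w * exp(eta), n_nodes, n))
}
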