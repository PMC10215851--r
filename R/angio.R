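# ensemble helpers: a B-scan ensemble is a (Z, X, N) complex array or an
# M x N matrix of per-pixel repeat vectors; internally everything is M x N
.as_ensemble_matrix <- function(ensemble) {
  if (is.matrix(ensemble)) return(ensemble)
  d <- dim(ensemble)
  if (length(d) != 3) stop("ensemble must be a (Z, X, N) array or an M x N matrix")
  matrix(ensemble, d[1] * d[2], d[3])
}

.restore_ensemble <- function(m, ensemble) {
  if (is.matrix(ensemble)) return(m)
  array(m, dim(ensemble))
}

#' Remove global inter-repeat bulk-motion phase from an ensemble
#'
#' Estimates, for each adjacent repeat pair, the intensity-weighted circular
#' mean of the inter-repeat phase difference \eqn{\arg \sum_p x_{p,k+1}
#' \bar{x}_{p,k}} and multiplies each repeat by a unit-modulus correction that
#' zeroes it, with the first repeat as phase reference. A pure global phase
#' ramp is removed exactly; flow signals are untouched up to their (small)
#' contribution to the global estimate.
#'
#' @param ensemble `(Z, X, N)` complex array or M x N matrix, N >= 2.
#' @return The phase-aligned ensemble, same shape as the input.
#' @export
align_bulk_phase <- function(ensemble) {
  m <- .as_ensemble_matrix(ensemble)
  n_rep <- ncol(m)
  if (n_rep < 2) stop("need at least 2 repeats")
  d <- vapply(seq_len(n_rep - 1), function(k) {
    w <- sum(m[, k + 1] * Conj(m[, k]))
    if (Mod(w) == 0) {
      warning("all-zero repeat pair: bulk phase undefined, passing through")
      0
    } else Arg(w)
  }, numeric(1))
  phi <- cumsum(c(0, d))
  out <- m * matrix(exp(-1i * phi), nrow(m), n_rep, byrow = TRUE)
  .restore_ensemble(out, ensemble)
}

#' Repeat-space sample covariance of a B-scan ensemble
#'
#' \eqn{C = (1/M) \sum_p x_p x_p^H} over all M = Z*X pixel vectors
#' \eqn{x_p \in C^N}; Hermitian positive semi-definite, with
#' `trace(C) = N * mean per-pixel ensemble power`.
#'
#' @param ensemble `(Z, X, N)` complex array or M x N matrix.
#' @return N x N complex Hermitian matrix.
#' @export
ed_covariance <- function(ensemble) {
  m <- .as_ensemble_matrix(ensemble)
  if (ncol(m) < 2) stop("need at least 2 repeats")
  C <- (t(m) %*% Conj(m)) / nrow(m)
  # non-finite input surfaces here (cheap check on the N x N result)
  if (!all(is.finite(Re(C)) & is.finite(Im(C)))) stop("non-finite ensemble values")
  (C + Conj(t(C))) / 2
}

#' Choose the clutter rank from an eigenvalue spectrum
#'
#' Fixed mode returns `fixed_k` unchanged. Adaptive mode returns the smallest
#' K whose leading eigenvalues hold at least `energy_threshold` of the total
#' energy, clipped to `[1, N - 1]`. An all-zero spectrum yields K = 1.
#'
#' @param eigenvalues Nonnegative eigenvalues sorted descending.
#' @param energy_threshold Cumulative-energy fraction for adaptive selection.
#' @param fixed_k If non-`NULL`, the rank to return as-is.
#' @return Integer clutter rank K.
#' @export
select_clutter_rank <- function(eigenvalues, energy_threshold = 0.9,
                                fixed_k = NULL) {
  if (!is.null(fixed_k)) return(as.integer(fixed_k))
  ev <- eigenvalues
  if (is.unsorted(rev(ev))) stop("eigenvalues must be sorted descending")
  if (any(ev < -1e-12 * max(abs(ev), 1))) stop("eigenvalues must be >= 0")
  tot <- sum(ev)
  if (tot <= 0) return(1L)
  k <- which(cumsum(ev) / tot >= energy_threshold)[1]
  as.integer(min(max(k, 1L), length(ev) - 1L))
}

#' Eigen-decomposition clutter filter (ED-OMAG) for one ensemble
#'
#' Eigendecomposes the repeat-space covariance, projects every pixel vector
#' off the K leading (clutter) eigenvectors, and returns the mean residual
#' power per pixel as the flow value: \eqn{f_p = \|x_p - \sum_{i \le K}
#' (e_i^H x_p) e_i\|^2 / N}. Rank-1 static tissue (identical repeats up to a
#' global phase) is cancelled exactly at K = 1, while decorrelating flow
#' retains most of its power in the residual. The projector is idempotent;
#' with degenerate eigenvalues any orthonormal basis of the eigenspace yields
#' the same projector.
#'
#' @param ensemble `(Z, X, N)` complex array or M x N matrix.
#' @param k Clutter rank, `1 <= k <= N - 1`.
#' @param C Optional covariance to use (defaults to [ed_covariance()] of the
#'   ensemble itself; supplying it decouples basis estimation from filtering).
#' @param statistic `"power"` (mean residual power, default), `"amplitude"`
#'   (its square root) or `"max"` (max residual magnitude squared).
#' @return Nonnegative flow frame: Z x X matrix (or length-M vector for
#'   matrix input).
#' @export
ed_filter <- function(ensemble, k, C = NULL,
                      statistic = c("power", "amplitude", "max")) {
  statistic <- match.arg(statistic)
  m <- .as_ensemble_matrix(ensemble)
  n_rep <- ncol(m)
  if (k < 1 || k > n_rep - 1) stop("clutter rank k must be in [1, N-1]")
  if (is.null(C)) C <- ed_covariance(m)
  eg <- eigen(C, symmetric = TRUE)
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  resid <- m - (m %*% Conj(E)) %*% t(E)
  rp <- Mod(resid)^2
  flow <- switch(statistic,
                 power = rowSums(rp) / n_rep,
                 amplitude = sqrt(rowSums(rp) / n_rep),
                 max = apply(rp, 1, max))
  if (is.matrix(ensemble)) flow else matrix(flow, dim(ensemble)[1], dim(ensemble)[2])
}

#' Reconstruct the flow-magnitude volume of a full OCT cube
#'
#' Per slow-axis position: optional bulk-phase alignment, repeat-space
#' covariance, clutter-rank selection, and eigen-decomposition filtering.
#' The clutter rank used at every position is recorded in the result.
#'
#' @param cube An [oct_cube()] (or complex `(Z, X, Y, N)` array).
#' @param k Fixed clutter rank (default 1), or `"adaptive"` to select by
#'   cumulative eigen-energy.
#' @param energy_threshold Energy fraction for adaptive rank selection.
#' @param align_phase Remove global inter-repeat phase first (default `TRUE`).
#' @param statistic Flow statistic passed to [ed_filter()].
#' @param with_intensity Also accumulate the structural mean-intensity volume
#'   from the same ensembles (attached as attribute `"intensity"`), saving a
#'   separate pass over the cube.
#' @return A `flow_cube`: nonnegative numeric `(Z, X, Y)` array with
#'   attributes `clutter_rank` (integer per position) and `optics` (if the
#'   input carried them).
#' @export
flow_cube <- function(cube, k = 1, energy_threshold = 0.9,
                      align_phase = TRUE,
                      statistic = c("power", "amplitude", "max"),
                      with_intensity = FALSE) {
  statistic <- match.arg(statistic)
  d <- dim(cube)
  if (length(d) != 4) stop("cube must be (Z, X, Y, N)")
  Z <- d[1]; X <- d[2]; Y <- d[3]
  flow <- array(0, c(Z, X, Y))
  intensity <- if (with_intensity) array(0, c(Z, X, Y))
  ranks <- integer(Y)
  adaptive <- identical(k, "adaptive")
  for (y in seq_len(Y)) {
    res <- tryCatch({
      ens <- matrix(cube[, , y, ], Z * X, d[4])
      if (with_intensity)
        intensity[, , y] <- matrix(cube_power_mean(ens, d[4]), Z, X)
      if (align_phase) ens <- align_bulk_phase(ens)
      C <- ed_covariance(ens)
      ky <- if (adaptive) {
        ev <- pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0)
        select_clutter_rank(ev, energy_threshold)
      } else as.integer(k)
      list(flow = ed_filter(ens, ky, C = C, statistic = statistic), k = ky)
    }, error = function(e) {
      stop(sprintf("flow reconstruction failed at slow-axis position %d: %s",
                   y, conditionMessage(e)), call. = FALSE)
    })
    flow[, , y] <- res$flow
    ranks[y] <- res$k
  }
  structure(flow, clutter_rank = ranks, optics = attr(cube, "optics"),
            intensity = intensity, class = c("flow_cube", class(flow)))
}
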