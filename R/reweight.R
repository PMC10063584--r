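#' Canonical reweighting of a multicanonical ensemble
#'
#' Converts snapshots sampled under a multicanonical bias at `T_mc` into a
#' canonical ensemble at temperature `T` via per-snapshot weights
#' `w_j proportional to exp(E_mc(E_j)/(R*T_mc) - E_j/(R*T))`, normalized to
#' sum to one. The computation is log-sum-exp stabilized, so extreme
#' temperature gaps cannot underflow to all-zero weights. Weights are per
#' snapshot (not per energy bin): downstream landscape and cluster
#' probabilities sum them directly.
#'
#' The effective sample size `1/sum(w^2)` is always attached; a warning is
#' emitted below 100, where reweighted expectations become unreliable.
#'
#' @param ens an [ensemble()] sampled under `bias`.
#' @param bias the [bias_function()] the run was generated with.
#' @param T target temperature in K.
#' @return An object of class `weight_vector`: list with `w` (normalized
#'   weights), `T`, `ess` and `log_w` (unnormalized log weights).
#' @export
canonical_weights <- function(ens, bias, T) {
  if (T <= 0) stop("temperature must be positive")
  E <- ens$energy
  lw <- bias_value(bias, E) / (GAS_CONSTANT * bias$T_mc) - E / (GAS_CONSTANT * T)
  lw <- lw - max(lw)
  w <- exp(lw)
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  if (ess < 100) {
    warning(sprintf("effective sample size %.1f < 100 at T = %g K; reweighted estimates may be noisy",
                    ess, T))
  }
  structure(list(w = w, T = T, ess = ess, log_w = lw),
            class = "weight_vector")
}

#' Uniform weights
#'
#' The degenerate weight vector of the raw (bias-free) multicanonical
#' ensemble itself; useful for observing the flat-histogram ensemble.
#'
#' @param n number of snapshots.
#' @param T nominal temperature label.
#' @export
uniform_weights <- function(n, T = NA_real_) {
  structure(list(w = rep(1 / n, n), T = T, ess = n, log_w = rep(0, n)),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("weight_vector: %d weights at T = %g K, ESS = %.1f\n",
              length(x$w), x$T, x$ess))
  invisible(x)
}

#' Weighted histogram of an observable
#'
#' Bins one value per snapshot with the snapshot weights (right-open bins);
#' the resulting masses sum to one over the in-range values. Out-of-range
#' values are excluded from the mass and counted in the `overflow`
#' attribute (with a message).
#'
#' @param values numeric vector, one value per snapshot.
#' @param weights a `weight_vector` (or plain numeric weights).
#' @param edges strictly increasing bin edges.
#' @param label observable label carried in the result.
#' @return An object of class `distribution`: list with `edges`, `mass`,
#'   `mids`, `T`, `label`, `overflow`.
#' @export
reweighted_histogram <- function(values, weights, edges, label = "observable") {
  w <- if (inherits(weights, "weight_vector")) weights$w else weights
  if (length(values) != length(w)) stop("one value per snapshot required")
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  bin <- findInterval(values, edges, left.open = FALSE, rightmost.closed = FALSE)
  inside <- bin >= 1 & bin <= length(edges) - 1 & values < edges[length(edges)]
  overflow <- sum(w[!inside])
  if (overflow > 0) {
    message(sprintf("%d value(s) outside the bin range (mass %.3g excluded)",
                    sum(!inside), overflow))
  }
  mass <- vapply(seq_len(length(edges) - 1),
                 function(b) sum(w[inside & bin == b]), numeric(1))
  total <- sum(mass)
  if (total <= 0) stop("no weighted mass inside the bin range")
  structure(list(edges = edges, mass = mass / total,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 T = if (inherits(weights, "weight_vector")) weights$T else NA_real_,
                 label = label, overflow = overflow),
            class = "distribution")
}

#' @export
print.distribution <- function(x, ...) {
  cat(sprintf("distribution of %s: %d bins on [%.3g, %.3g], T = %g K\n",
              x$label, length(x$mass), x$edges[1],
              x$edges[length(x$edges)], x$T))
  invisible(x)
}

#' Weighted mean and variance of an observable
#'
#' @param values numeric vector, one value per snapshot.
#' @param weights a `weight_vector` or numeric weights.
#' @return Named numeric vector with `mean` and `var`.
#' @export
weighted_moments <- function(values, weights) {
  w <- if (inherits(weights, "weight_vector")) weights$w else weights
  w <- w / sum(w)
  m <- sum(w * values)
  c(mean = m, var = sum(w * (values - m)^2))
}
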