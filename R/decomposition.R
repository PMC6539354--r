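# Period, division and division-period efficiencies read off a solved
# program.  By default all four levels are evaluated from the slacks that
# are optimal for the *overall* program (one optimization per DMU), which
# guarantees the decomposition identity
#   theta = sum_t W^t sum_k W^k N_k^t / sum_t W^t sum_k W^k D_k^t,
# a weighted mediant of the period (or division) ratios.

# weights actually used, recovered from the stored Wkt (Wkt = outer(Wk, Wt))
wkt_margins <- function(sol) {
  Wk <- rowSums(sol$Wkt); Wt <- colSums(sol$Wkt)
  list(division = Wk / sum(Wk), period = Wt / sum(Wt))
}

#' Period, division and division-period efficiencies of a solution
#'
#' `period_efficiency()` returns
#' \eqn{(\sum_k W^k N_k^t) / (\sum_k W^k D_k^t)} for period `t`;
#' `division_efficiency()` returns
#' \eqn{(\sum_t W^t N_k^t) / (\sum_t W^t D_k^t)} for division `k`;
#' `division_period_efficiency()` returns \eqn{N_k^t / D_k^t}.
#' `N` and `D` are the per-(division, period) numerator and denominator
#' parts of the overall objective at the optimum.
#'
#' @param sol A `dndea_solution` from [solve_dmu()].
#' @param t Period label (or index).
#' @param k Division name (or index).
#' @return A single efficiency score in `(0, 1]`.
#' @export
period_efficiency <- function(sol, t) {
  t <- resolve_label(t, colnames(sol$N), "period")
  w <- wkt_margins(sol)$division
  sum(w * sol$N[, t]) / sum(w * sol$D[, t])
}

#' @rdname period_efficiency
#' @export
division_efficiency <- function(sol, k) {
  k <- resolve_label(k, rownames(sol$N), "division")
  w <- wkt_margins(sol)$period
  sum(w * sol$N[k, ]) / sum(w * sol$D[k, ])
}

#' @rdname period_efficiency
#' @export
division_period_efficiency <- function(sol, k, t) {
  k <- resolve_label(k, rownames(sol$N), "division")
  t <- resolve_label(t, colnames(sol$N), "period")
  sol$N[k, t] / sol$D[k, t]
}

resolve_label <- function(x, labels, what) {
  if (is.numeric(x)) {
    if (x < 1 || x > length(labels))
      stop(sprintf("%s index %s out of range", what, x), call. = FALSE)
    return(labels[x])
  }
  if (!x %in% labels)
    stop(sprintf("unknown %s: %s", what, x), call. = FALSE)
  x
}

# all decomposition levels for one solution, as a list of matrices
decompose_solution <- function(sol) {
  w <- wkt_margins(sol)
  Kn <- nrow(sol$N); Tn <- ncol(sol$N)
  period <- vapply(seq_len(Tn), function(t)
    sum(w$division * sol$N[, t]) / sum(w$division * sol$D[, t]), 0)
  names(period) <- colnames(sol$N)
  division <- vapply(seq_len(Kn), function(k)
    sum(w$period * sol$N[k, ]) / sum(w$period * sol$D[k, ]), 0)
  names(division) <- rownames(sol$N)
  list(overall = sol$theta, period = period, division = division,
       division_period = sol$N / sol$D)
}
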