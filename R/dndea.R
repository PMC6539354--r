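#' Fit a dynamic network slacks-based-measure DEA model
#'
#' Evaluates every decision-making unit of a panel against the best-practice
#' frontier defined by the whole panel, under the non-oriented
#' slacks-based measure with undesirable outputs, within-period links
#' between divisions, good carry-overs between consecutive periods, and
#' variable returns to scale. Each unit's fractional program is linearized
#' by the Charnes-Cooper transformation and solved by the simplex method; a
#' second lexicographic pass makes reported slacks (and hence factor
#' indices) deterministic among alternate optima.
#'
#' The overall efficiency of unit \eqn{o} is
#' \deqn{\theta_o^* = \min \frac{\sum_t W^t \sum_k W^k \left[1 -
#'   \frac{1}{m_k + linkin_k}\left(\sum_i \frac{s_i^{t-}}{x_{io}^t} +
#'   \sum_l \frac{s_l^{in\,t}}{z_{lo}^{in\,t}}\right)\right]}
#'   {\sum_t W^t \sum_k W^k \left[1 + \frac{1}{r_{1k} + r_{2k} + ngood_k}
#'   \left(\sum_r \frac{s_r^{good\,t+}}{y_{ro}^{good\,t}} +
#'   \sum_r \frac{s_r^{bad\,t-}}{y_{ro}^{bad\,t}} +
#'   \sum_c \frac{s_c^{good(t,t+1)}}{z_{co}^{good(t,t+1)}}\right)\right]}}
#' subject to the frontier constraints (intensity vectors \eqn{\lambda_k^t}
#' summing to one per division and period, input/output/link/carry-over
#' balances, carry-over continuity between consecutive periods).
#'
#' @param data A [dea_panel()] or a long data frame accepted by it.
#' @param spec A [dea_spec()].
#' @param link_continuity Also require each link's source and target
#'   intensity blocks to agree on the link quantity (off by default; the
#'   link otherwise only constrains the receiving division, as an input).
#' @param reoptimize If `TRUE`, period, division and division-period scores
#'   are each re-optimized with the objective restricted to that slice
#'   (separate LP per score) instead of being read from the overall-optimal
#'   slacks. The default `FALSE` keeps the decomposition identity exact.
#' @param lex Run the lexicographic maximal-slack pass (default `TRUE`).
#' @param tol Feasibility tolerance for solution verification.
#' @return An object of class `dndea`; see [efficiency()],
#'   [factor_indices()], and the `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `plot` methods.
#' @examples
#' spec <- dea_spec(list(unit = list(inputs = "x", good_outputs = "y")))
#' df <- data.frame(dmu = rep(c("A", "B"), each = 2), period = "p1",
#'                  division = "unit", variable = rep(c("x", "y"), 2),
#'                  value = c(1, 1, 2, 1))
#' fit <- dndea(df, spec)
#' coef(fit)          # overall efficiencies: A = 1, B = 0.5
#' @export
dndea <- function(data, spec, link_continuity = FALSE, reoptimize = FALSE,
                  lex = TRUE, tol = 1e-6) {
  cl <- match.call()
  spec <- validate_spec(spec)
  panel <- if (inherits(data, "dndea_panel")) data else dea_panel(data, spec)

  solutions <- solve_all(spec, panel, link_continuity = link_continuity,
                         lex = lex, tol = tol)
  ok <- !vapply(solutions, is.null, TRUE)
  if (!any(ok)) stop("no DMU could be solved", call. = FALSE)

  dmus <- panel$dmus
  periods <- panel$periods
  divisions <- names(spec$divisions)
  Tn <- length(periods); K <- length(divisions)

  overall <- stats::setNames(rep(NA_real_, length(dmus)), dmus)
  period <- matrix(NA_real_, length(dmus), Tn, dimnames = list(dmus, periods))
  division <- matrix(NA_real_, length(dmus), K,
                     dimnames = list(dmus, divisions))
  dp_names <- paste(rep(divisions, each = Tn), rep(periods, K), sep = ":")
  division_period <- matrix(NA_real_, length(dmus), K * Tn,
                            dimnames = list(dmus, dp_names))

  for (d in dmus[ok]) {
    dec <- decompose_solution(solutions[[d]])
    overall[d] <- dec$overall
    period[d, ] <- dec$period
    division[d, ] <- dec$division
    division_period[d, ] <- as.vector(t(dec$division_period))
  }

  if (reoptimize) {
    w <- resolve_weights(spec, Tn)
    mask_solve <- function(d, Wkt) {
      s <- solve_dmu(spec, panel, d, link_continuity = link_continuity,
                     lex = FALSE, Wkt = Wkt, tol = tol)
      s$theta
    }
    for (d in dmus[ok]) {
      for (t in seq_len(Tn)) {
        Wkt <- matrix(0, K, Tn); Wkt[, t] <- w$division
        period[d, t] <- mask_solve(d, Wkt)
      }
      for (k in seq_len(K)) {
        Wkt <- matrix(0, K, Tn); Wkt[k, ] <- w$period
        division[d, k] <- mask_solve(d, Wkt)
        for (t in seq_len(Tn)) {
          Wkt <- matrix(0, K, Tn); Wkt[k, t] <- 1
          division_period[d, (k - 1L) * Tn + t] <- mask_solve(d, Wkt)
        }
      }
    }
  }

  indices <- tabulate_indices(solutions[ok], spec)

  structure(list(
    call = cl, spec = spec, panel = panel, solutions = solutions,
    overall = overall, period = period, division = division,
    division_period = division_period, factor_indices = indices,
    options = list(link_continuity = link_continuity,
                   reoptimize = reoptimize, lex = lex, tol = tol),
    weights = resolve_weights(spec, Tn)
  ), class = "dndea")
}

#' Extract efficiency scores from a fitted model
#'
#' @param object A fitted [dndea()] model.
#' @param level One of `"overall"`, `"period"`, `"division"`,
#'   `"division_period"`.
#' @return A named vector (overall) or DMU-by-slice matrix of scores in
#'   `(0, 1]`.
#' @export
efficiency <- function(object, level = c("overall", "period", "division",
                                         "division_period")) {
  stopifnot(inherits(object, "dndea"))
  level <- match.arg(level)
  switch(level, overall = object$overall, period = object$period,
         division = object$division, division_period = object$division_period)
}

#' Extract the factor index table from a fitted model
#'
#' @param object A fitted [dndea()] model.
#' @return The per-(dmu, period, variable) total-factor efficiency index
#'   table (see [tabulate_indices()]).
#' @export
factor_indices <- function(object) {
  stopifnot(inherits(object, "dndea"))
  object$factor_indices
}

#' @export
print.dndea <- function(x, digits = 6, ...) {
  cat("Dynamic network SBM-DEA fit\n")
  cat(sprintf("  %d DMU(s), %d period(s), %d division(s)\n",
              length(x$panel$dmus), length(x$panel$periods),
              length(x$spec$divisions)))
  cat("  overall efficiency:\n")
  print(round(x$overall, digits))
  invisible(x)
}

#' @export
summary.dndea <- function(object, ...) {
  ov <- object$overall
  structure(list(
    call = object$call,
    n_dmu = length(object$panel$dmus),
    n_period = length(object$panel$periods),
    divisions = names(object$spec$divisions),
    overall = ov,
    efficient = names(ov)[!is.na(ov) & ov >= 1 - 1e-9],
    score_summary = summary(ov[!is.na(ov)]),
    period = object$period,
    division = object$division,
    options = object$options
  ), class = "summary.dndea")
}

#' @export
print.summary.dndea <- function(x, digits = 4, ...) {
  cat("Dynamic network SBM-DEA fit\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\n%d DMU(s) x %d period(s); divisions: %s\n",
              x$n_dmu, x$n_period, paste(x$divisions, collapse = ", ")))
  cat("\nOverall efficiency distribution:\n")
  print(signif(x$score_summary, digits))
  cat(sprintf("\nEfficient DMU(s) (score = 1): %s\n",
              if (length(x$efficient)) paste(x$efficient, collapse = ", ")
              else "none"))
  cat("\nMean division efficiency:\n")
  print(signif(colMeans(x$division, na.rm = TRUE), digits))
  invisible(x)
}

#' @export
coef.dndea <- function(object, ...) object$overall

#' Frontier targets of a fitted model
#'
#' The frontier target of each variable is the observed value adjusted by
#' its optimal slack: `actual - slack` for inputs, incoming links and bad
#' outputs; `actual + slack` for good outputs and carry-overs.
#'
#' @param object A fitted [dndea()] model.
#' @param ... Unused.
#' @return Data frame of targets per `(dmu, division, period, variable)`.
#' @export
fitted.dndea <- function(object, ...) {
  fi <- object$factor_indices
  dir <- ifelse(fi$role %in% c("good_output", "carryover"), 1, -1)
  data.frame(fi[c("dmu", "division", "period", "variable", "role",
                  "actual")],
             target = fi$actual + dir * fi$slack)
}

#' Optimal slacks of a fitted model
#'
#' @param object A fitted [dndea()] model.
#' @param ... Unused.
#' @return Long data frame of slacks per `(dmu, division, period,
#'   variable)`, with the slack/observed ratio.
#' @export
residuals.dndea <- function(object, ...) {
  out <- lapply(names(object$solutions), function(d) {
    s <- object$solutions[[d]]
    if (is.null(s)) return(NULL)
    cbind(dmu = d, s$slacks)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot efficiency scores of a fitted model
#'
#' Draws per-DMU overall efficiency (sorted) and, when the panel has more
#' than one period, the period-efficiency trajectories.
#'
#' @param x A fitted [dndea()] model.
#' @param which `"overall"` or `"period"`.
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.dndea <- function(x, which = c("overall", "period"), ...) {
  which <- match.arg(which)
  if (which == "overall" || ncol(x$period) == 1L) {
    ov <- sort(x$overall, na.last = TRUE)
    graphics::barplot(ov, las = 2, ylim = c(0, 1),
                      ylab = "overall efficiency",
                      main = "Overall SBM efficiency by DMU", ...)
    graphics::abline(h = 1, lty = 2)
  } else {
    graphics::matplot(t(x$period), type = "b", pch = 16, lty = 1,
                      ylim = c(0, 1.05), xaxt = "n",
                      xlab = "period", ylab = "period efficiency",
                      main = "Period efficiency trajectories", ...)
    graphics::axis(1, at = seq_len(ncol(x$period)),
                   labels = colnames(x$period))
  }
  invisible(x)
}
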