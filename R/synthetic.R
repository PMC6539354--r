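# Synthetic panel generators.  Two constructions:
#  * generate_planted_frontier(): units with a *provable* efficiency status,
#    used to validate the solver.  Frontier units are sampled on a common
#    supporting hyperplane (per division and period) with a strictly
#    positive normal over "cost" coordinates (inputs, incoming links, bad
#    outputs) and "benefit" coordinates (good outputs, carry-overs):
#    every convex combination of frontier units stays on the plane, and any
#    point that weakly dominates a plane point would fall strictly below
#    it — impossible inside the hull.  Hence planted units score exactly 1.
#    Dominated units are convex combinations with costs inflated and
#    benefits deflated, so a feasible benchmark with strictly positive
#    slack exists by construction and their score is strictly below 1.
#  * generate_two_stage_panel(): a yearbook-like panel for the packaged
#    two-stage configuration, with no planted status but controllable
#    cross-DMU dispersion per stage.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

cost_roles <- c("input", "link_in", "bad_output")
benefit_roles <- c("good_output", "carryover")

#' Generate a panel with a planted efficient frontier
#'
#' Draws `n_efficient` frontier units whose variable values, per division
#' and period, lie on a common hyperplane with strictly positive weights
#' (costs minus benefits constant), which makes every frontier unit — and
#' every convex combination of them — undominated, so each scores exactly 1
#' under [dndea()]. The remaining units are convex combinations of the
#' frontier units with all cost variables (inputs, incoming links, bad
#' outputs) inflated and all benefit variables (good outputs, carry-overs)
#' deflated by random multiplicative factors, so each is strictly dominated
#' and scores strictly below 1. The convex weights used are returned as
#' dominance certificates.
#'
#' Every division must declare at least one cost variable. All draws come
#' from one stream seeded by `seed`, in documented order: hyperplane
#' normals, frontier units, combination weights, then inflation/deflation
#' factors.
#'
#' @param spec A validated [dea_spec()].
#' @param n_dmu Total number of units.
#' @param n_periods Number of periods.
#' @param n_efficient Number of planted frontier units (at least 1).
#' @param seed Integer seed; same seed, same panel.
#' @param inflate_range Range of the multiplicative factors (>= 1) applied
#'   to cost variables of dominated units. `c(1, 1)` makes every unit an
#'   exact frontier combination, hence efficient.
#' @param deflate_range Range of the factors (<= 1) applied to benefit
#'   variables of dominated units.
#' @param magnitude_decades Frontier values span this many decades
#'   (log-uniform), default 2.
#' @return A list of class `dndea_synthetic`: `panel` (a [dea_panel()]),
#'   `planted_efficient_ids`, `certificates` (convex weights and factors
#'   per dominated unit), and `params`.
#' @export
generate_planted_frontier <- function(spec, n_dmu = 10, n_periods = 2,
                                      n_efficient = 3, seed = 1,
                                      inflate_range = c(1.05, 1.6),
                                      deflate_range = c(0.6, 0.95),
                                      magnitude_decades = 2) {
  spec <- validate_spec(spec)
  if (n_efficient < 1 || n_efficient > n_dmu)
    stop("need 1 <= n_efficient <= n_dmu", call. = FALSE)
  if (any(inflate_range < 1) || any(deflate_range > 1) ||
      any(deflate_range <= 0))
    stop("inflation factors must be >= 1 and deflation factors in (0, 1]",
         call. = FALSE)
  sv <- spec_variables(spec)
  for (k in names(spec$divisions)) {
    svk <- sv[sv$division == k, ]
    if (!any(svk$role %in% cost_roles))
      stop(sprintf("division '%s' has no input, link or bad output; the planted-frontier construction needs at least one cost variable per division",
                   k), call. = FALSE)
  }

  dmus <- sprintf("dmu%02d", seq_len(n_dmu))
  periods <- sprintf("p%d", seq_len(n_periods))
  eff_ids <- dmus[seq_len(n_efficient)]
  dom_ids <- setdiff(dmus, eff_ids)

  with_seed(seed, {
    # values[[division]][[variable]]: n_dmu x n_periods
    values <- list()
    for (k in names(spec$divisions)) {
      svk <- sv[sv$division == k, ]
      nc_ <- sum(svk$role %in% cost_roles)
      values[[k]] <- lapply(stats::setNames(svk$variable, svk$variable),
                            function(v) matrix(NA_real_, n_dmu, n_periods,
                                               dimnames = list(dmus, periods)))
      for (t in seq_len(n_periods)) {
        alpha <- stats::setNames(stats::runif(nrow(svk), 0.5, 2), svk$variable)
        ck <- 10^stats::runif(1, 1, magnitude_decades)
        for (f in seq_len(n_efficient)) {
          ben <- svk$variable[svk$role %in% benefit_roles]
          yb <- 10^stats::runif(length(ben), 0, magnitude_decades)
          names(yb) <- ben
          budget <- ck + sum(alpha[ben] * yb)
          cost <- svk$variable[svk$role %in% cost_roles]
          p <- stats::rexp(length(cost)) + 0.05
          p <- p / sum(p)
          xb <- p * budget / alpha[cost]
          names(xb) <- cost
          for (v in ben) values[[k]][[v]][f, t] <- yb[[v]]
          for (v in cost) values[[k]][[v]][f, t] <- xb[[v]]
        }
      }
    }

    # dominated units: convex combinations, costs up, benefits down
    certificates <- list()
    for (d in dom_ids) {
      w <- stats::rexp(n_efficient) + 0.02
      w <- w / sum(w)
      fac <- list()
      for (k in names(spec$divisions)) {
        svk <- sv[sv$division == k, ]
        for (i in seq_len(nrow(svk))) {
          v <- svk$variable[i]
          f <- if (svk$role[i] %in% cost_roles)
            stats::runif(1, inflate_range[1], inflate_range[2])
          else stats::runif(1, deflate_range[1], deflate_range[2])
          base <- colSums(values[[k]][[v]][seq_len(n_efficient), , drop = FALSE] * w)
          values[[k]][[v]][d, ] <- base * f
          fac[[paste(k, v, sep = "/")]] <- f
        }
      }
      certificates[[d]] <- list(weights = stats::setNames(w, eff_ids),
                                factors = unlist(fac))
    }
    NULL
  })

  long <- values_to_long(values, sv, dmus, periods)
  structure(list(
    panel = dea_panel(long, spec, periods = periods),
    planted_efficient_ids = eff_ids,
    certificates = certificates,
    params = list(n_dmu = n_dmu, n_periods = n_periods,
                  n_efficient = n_efficient, seed = seed,
                  inflate_range = inflate_range,
                  deflate_range = deflate_range,
                  magnitude_decades = magnitude_decades)
  ), class = "dndea_synthetic")
}

values_to_long <- function(values, sv, dmus, periods) {
  rows <- lapply(seq_len(nrow(sv)), function(i) {
    M <- values[[sv$division[i]]][[sv$variable[i]]]
    data.frame(dmu = rep(dmus, length(periods)),
               period = rep(periods, each = length(dmus)),
               division = sv$division[i], variable = sv$variable[i],
               value = as.vector(M), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a yearbook-like two-stage panel
#'
#' Emulates the shape of a city panel for the packaged two-stage
#' configuration ([two_stage_spec()]): city sizes span two decades
#' (log-uniform); labor, energy consumption and GDP are positively
#' correlated through size; CO2 and AQI increase with energy use; health
#' expenditure and media reports scale with size with independent noise;
#' respiratory disease and mortality increase with the pollution links; the
#' fixed-asset carry-over follows a smooth (AR) path over periods; a mild
#' common growth trend runs across periods. The two dispersion parameters
#' are the standard deviations of the stage-specific log-normal noise, so
#' the cross-DMU spread of stage-2 performance exceeds that of stage 1 at
#' the defaults.
#'
#' @param n_dmu Number of units (default 31).
#' @param n_periods Number of periods (default 4).
#' @param stage1_dispersion,stage2_dispersion Log-scale noise SDs for the
#'   production and health-treatment stages (defaults 0.15 and 0.45).
#' @param seed Integer seed.
#' @return A list of class `dndea_synthetic` with `panel`, empty
#'   `planted_efficient_ids` (no status is planted), and `params`.
#' @export
generate_two_stage_panel <- function(n_dmu = 31, n_periods = 4,
                                     stage1_dispersion = 0.15,
                                     stage2_dispersion = 0.45,
                                     seed = 1) {
  if (stage1_dispersion <= 0 || stage2_dispersion <= 0)
    stop("dispersion parameters must be positive", call. = FALSE)
  spec <- two_stage_spec()
  dmus <- sprintf("city%02d", seq_len(n_dmu))
  periods <- as.character(seq(2013, length.out = n_periods))
  s1 <- stage1_dispersion; s2 <- stage2_dispersion

  long <- with_seed(seed, {
    size <- 10^stats::runif(n_dmu, 0, 2)
    growth <- 1.03^(seq_len(n_periods) - 1L)
    ln <- function(sd) matrix(exp(stats::rnorm(n_dmu * n_periods, 0, sd)),
                              n_dmu, n_periods)
    base <- outer(size, growth)

    labor <- base * ln(s1)
    energy <- base * ln(s1)
    gdp <- 1.5 * base * ln(s1)
    co2 <- 2.5 * energy * ln(s1)
    aqi <- 80 * (energy / size)^0.3 * ln(s1 / 2)
    # AR(1) log-noise keeps the capital stock path smooth across periods
    e <- matrix(stats::rnorm(n_dmu * n_periods, 0, s1), n_dmu, n_periods)
    for (t in seq_len(n_periods)[-1]) e[, t] <- 0.7 * e[, t - 1] + 0.3 * e[, t]
    fixed_assets <- 0.8 * base * exp(e)
    health_expenditure <- 0.12 * base * ln(s2)
    media_reports <- 50 * sqrt(size) * ln(s2) + 1
    birth_rate <- 12 * ln(s2 / 3)
    respiratory_diseases <- 0.5 * co2^0.6 * outer(size, rep(1, n_periods))^0.4 * ln(s2)
    mortality_rate <- 7 * (aqi / 80)^0.4 * ln(s2 / 3)

    vals <- list(
      production = list(labor = labor, energy_consumption = energy,
                        gdp = gdp, fixed_assets = fixed_assets),
      health_treatment = list(health_expenditure = health_expenditure,
                              media_reports = media_reports,
                              birth_rate = birth_rate,
                              respiratory_diseases = respiratory_diseases,
                              mortality_rate = mortality_rate,
                              co2 = co2, aqi = aqi))
    sv <- spec_variables(spec)
    for (k in names(vals)) for (v in names(vals[[k]]))
      dimnames(vals[[k]][[v]]) <- list(dmus, periods)
    values_to_long(vals, sv, dmus, periods)
  })

  structure(list(
    panel = dea_panel(long, spec, periods = periods),
    planted_efficient_ids = character(0),
    certificates = list(),
    params = list(n_dmu = n_dmu, n_periods = n_periods,
                  stage1_dispersion = stage1_dispersion,
                  stage2_dispersion = stage2_dispersion, seed = seed)
  ), class = "dndea_synthetic")
}

#' @export
print.dndea_synthetic <- function(x, ...) {
  cat(sprintf("Synthetic panel: %d DMU(s) x %d period(s)%s\n",
              x$params$n_dmu, x$params$n_periods,
              if (length(x$planted_efficient_ids))
                sprintf("; planted efficient: %s",
                        paste(x$planted_efficient_ids, collapse = ", "))
              else ""))
  print(x$panel)
  invisible(x)
}
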