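#' Write report tables for a fitted model
#'
#' Emits four files into `dir`:
#' \describe{
#'   \item{overall.csv}{one row per DMU, one column per period holding the
#'     period efficiency — the per-year reading of the overall score. The
#'     whole-window overall efficiency is in `results.json`.}
#'   \item{stages.csv}{one row per DMU, one column per period-division pair
#'     (`2013-I`, `2013-II`, ...) holding division-period scores.}
#'   \item{factors.csv}{one row per DMU, one column per
#'     `<period> <variable>` pair holding total-factor efficiency indices.}
#'   \item{results.json}{machine-readable scores, slacks and intensities,
#'     consumed by [verify_run()].}
#' }
#'
#' @param fit A fitted [dndea()] model.
#' @param dir Output directory (created if missing).
#' @param precision Decimal places for the CSV tables (default 6; full
#'   precision is kept in `results.json`).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(fit, dir, precision = 6) {
  stopifnot(inherits(fit, "dndea"))
  if (precision < 1) stop("`precision` must be at least 1", call. = FALSE)
  dmus <- fit$panel$dmus
  if (!length(dmus) || all(is.na(fit$overall)))
    stop("refusing to write reports: no solved DMUs", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  periods <- fit$panel$periods
  divisions <- names(fit$spec$divisions)
  rnd <- function(x) round(x, precision)

  overall <- data.frame(NO. = seq_along(dmus), DMU = dmus,
                        rnd(fit$period), check.names = FALSE)
  names(overall)[-(1:2)] <- periods
  p_overall <- file.path(dir, "overall.csv")
  utils::write.csv(overall, p_overall, row.names = FALSE, quote = FALSE)

  # period-major stage columns: 2013-I, 2013-II, 2014-I, ...
  roman <- as.character(utils::as.roman(seq_along(divisions)))
  cols <- as.vector(vapply(periods, function(p) paste0(p, "-", roman),
                           character(length(divisions))))
  stage <- matrix(NA_real_, length(dmus), length(cols),
                  dimnames = list(NULL, cols))
  for (ki in seq_along(divisions)) for (ti in seq_along(periods)) {
    src <- paste(divisions[ki], periods[ti], sep = ":")
    stage[, (ti - 1L) * length(divisions) + ki] <-
      fit$division_period[, src]
  }
  stages <- data.frame(NO. = seq_along(dmus), DMU = dmus, rnd(stage),
                       check.names = FALSE)
  p_stages <- file.path(dir, "stages.csv")
  utils::write.csv(stages, p_stages, row.names = FALSE, quote = FALSE)

  fi <- fit$factor_indices
  sv <- spec_variables(fit$spec)
  fcols <- character(0); fmat <- NULL
  for (i in seq_len(nrow(sv))) {
    for (p in periods) {
      sel <- fi$division == sv$division[i] & fi$variable == sv$variable[i] &
        fi$period == p
      col <- fi$index[sel][match(dmus, fi$dmu[sel])]
      fmat <- cbind(fmat, col)
      fcols <- c(fcols, paste(p, sv$variable[i]))
    }
  }
  colnames(fmat) <- fcols
  factors <- data.frame(NO. = seq_along(dmus), DMU = dmus, rnd(fmat),
                        check.names = FALSE)
  p_factors <- file.path(dir, "factors.csv")
  utils::write.csv(factors, p_factors, row.names = FALSE, quote = FALSE)

  results <- list(
    dmus = dmus, periods = periods, divisions = divisions,
    weights = fit$weights, options = fit$options,
    overall = as.list(fit$overall),
    period = fit$period, division = fit$division,
    division_period = fit$division_period,
    factor_indices = fit$factor_indices,
    solutions = lapply(fit$solutions, function(s) {
      if (is.null(s)) return(NULL)
      # lambda flattened column-major over (dmu, period, division)
      list(theta = s$theta, N = s$N, D = s$D,
           lambda = as.vector(s$lambda), slacks = s$slacks)
    })
  )
  p_json <- file.path(dir, "results.json")
  jsonlite::write_json(results, p_json, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(c(overall = p_overall, stages = p_stages, factors = p_factors,
              results = p_json))
}

#' Re-verify a written results file against its inputs
#'
#' Reloads `results.json`, the panel CSV and the spec JSON, rebuilds each
#' recorded solution (intensities and slacks), recomputes all constraint
#' residuals from scratch, and recomputes the overall efficiency from the
#' recorded slack ratios via the weighted-mediant identity. Passes when
#' every residual and every efficiency discrepancy is at most `tol`.
#'
#' @param results_path Path to a `results.json` written by
#'   [write_reports()].
#' @param data_path Path to the long panel CSV.
#' @param spec_path Path to the spec JSON.
#' @param tol Tolerance (default `1e-6`).
#' @return List with `pass`, `max_residual`, `max_theta_diff`, and the
#'   per-DMU detail.
#' @export
verify_run <- function(results_path, data_path, spec_path, tol = 1e-6) {
  res <- jsonlite::read_json(results_path, simplifyVector = TRUE)
  spec <- read_spec_json(spec_path)
  panel <- read_panel_csv(data_path, spec, periods = res$periods)
  dmus <- res$dmus
  divisions <- res$divisions; periods <- res$periods
  n <- length(dmus)

  detail <- list(); max_res <- 0; max_diff <- 0
  for (d in dmus) {
    rec <- res$solutions[[d]]
    if (is.null(rec)) next
    lam <- array(as.numeric(unlist(rec$lambda)),
                 dim = c(n, length(periods), length(divisions)),
                 dimnames = list(dmus, periods, divisions))
    slacks <- as.data.frame(rec$slacks)
    sol <- structure(list(dmu = d, theta = rec$theta, lambda = lam,
                          slacks = slacks,
                          Wkt = outer(res$weights$division,
                                      res$weights$period)),
                     class = "dndea_solution")
    chk <- verify_solution(sol, spec, panel, tol = tol)

    # recompute theta from the recorded slack ratios
    w <- outer(res$weights$division, res$weights$period)
    dims <- spec$dims
    N <- matrix(1, length(divisions), length(periods),
                dimnames = list(divisions, periods))
    D <- N
    for (ki in seq_along(divisions)) for (ti in seq_along(periods)) {
      sel <- slacks$division == divisions[ki] & slacks$period == periods[ti]
      ml <- dims$m[ki] + dims$linkin[ki]
      rg <- dims$r1[ki] + dims$r2[ki] + dims$ngood[ki]
      if (ml > 0)
        N[ki, ti] <- 1 - sum(slacks$ratio[sel & slacks$role %in%
                                            c("input", "link_in")]) / ml
      if (rg > 0)
        D[ki, ti] <- 1 + sum(slacks$ratio[sel & slacks$role %in%
                                            c("good_output", "bad_output",
                                              "carryover")]) / rg
    }
    theta <- sum(w * N) / sum(w * D)
    diff <- abs(theta - rec$theta)
    max_res <- max(max_res, chk$max_residual)
    max_diff <- max(max_diff, diff)
    detail[[d]] <- list(max_residual = chk$max_residual, theta_diff = diff)
  }
  list(pass = max_res <= tol && max_diff <= tol,
       max_residual = max_res, max_theta_diff = max_diff, detail = detail)
}
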