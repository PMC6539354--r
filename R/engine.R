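# Core slacks-based-measure engine: per-DMU fractional program assembly,
# Charnes-Cooper linearization, simplex solve, and slack recovery.
#
# Decision variables of the fractional program, for evaluated DMU o:
#   lambda_k^t  intensity vector over DMUs, one block per (division, period)
#   sigma       one slack *ratio* (slack / observed value of o) per
#               input, incoming link, good output, bad output and carry-over
#               of each (division, period)
# Working with slack ratios rather than raw slacks keeps every matrix entry
# O(1) even when variables span several decades; raw slacks are recovered as
# sigma * observed at the end.

# --- program assembly -------------------------------------------------------

# Wkt: K x T matrix of weights W^k * W^t (or a mask of it for re-optimized
# decompositions).  Rows follow spec division order, columns panel periods.
assemble_program <- function(spec, panel, dmu, Wkt = NULL,
                             link_continuity = FALSE) {
  spec <- validate_spec(spec)
  dmus <- panel$dmus
  periods <- panel$periods
  n <- length(dmus); Tn <- length(periods)
  dnames <- names(spec$divisions)
  K <- length(dnames)
  o <- match(dmu, dmus)
  if (is.na(o)) stop("unknown DMU: ", dmu, call. = FALSE)

  if (is.null(Wkt)) {
    w <- resolve_weights(spec, Tn)
    Wkt <- outer(w$division, w$period)
  }
  dimnames(Wkt) <- list(dnames, periods)

  dims <- spec$dims
  m_plus_link <- dims$m + dims$linkin
  r_plus_good <- dims$r1 + dims$r2 + dims$ngood
  names(m_plus_link) <- names(r_plus_good) <- dims$division

  # lambda block column offsets: division-major, then period
  lam_off <- function(k, t) ((match(k, dnames) - 1L) * Tn + (t - 1L)) * n
  n_lambda <- n * K * Tn

  sv <- spec_variables(spec)

  # slack variable table (one row per slack ratio variable)
  slack_meta <- list()
  for (k in dnames) for (t in seq_len(Tn)) {
    sub <- sv[sv$division == k, ]
    for (i in seq_len(nrow(sub))) {
      slack_meta[[length(slack_meta) + 1L]] <- data.frame(
        division = k, period = periods[t], t = t,
        variable = sub$variable[i], role = sub$role[i],
        stringsAsFactors = FALSE)
    }
  }
  slack_meta <- do.call(rbind, slack_meta)
  n_slack <- nrow(slack_meta)
  slack_meta$col <- n_lambda + seq_len(n_slack)

  # observed value of the evaluated DMU for each slack
  slack_meta$obs <- mapply(function(d, v, t)
    panel_matrix(panel, d, v)[o, t],
    slack_meta$division, slack_meta$variable, slack_meta$t)

  numer_roles <- c("input", "link_in")
  denom_roles <- c("good_output", "bad_output", "carryover")
  slack_meta$num_coef <- ifelse(
    slack_meta$role %in% numer_roles,
    Wkt[cbind(slack_meta$division, slack_meta$period)] /
      m_plus_link[slack_meta$division], 0)
  slack_meta$den_coef <- ifelse(
    slack_meta$role %in% denom_roles,
    Wkt[cbind(slack_meta$division, slack_meta$period)] /
      r_plus_good[slack_meta$division], 0)

  nv <- n_lambda + n_slack
  rows <- list(); rhs <- numeric(0); meta <- list()
  add_row <- function(a, b, family, division, period, variable) {
    rows[[length(rows) + 1L]] <<- a
    rhs[length(rhs) + 1L] <<- b
    meta[[length(meta) + 1L]] <<- data.frame(
      family = family, division = division, period = period,
      variable = variable, stringsAsFactors = FALSE)
  }

  sgn <- c(input = 1, link_in = 1, good_output = -1, bad_output = 1,
           carryover = -1)

  # per-(division, period, variable) rows, scaled by the observed value so
  # every coefficient is O(1):  (vals / obs) %*% lambda + sgn * sigma = 1
  for (i in seq_len(nrow(slack_meta))) {
    k <- slack_meta$division[i]; t <- slack_meta$t[i]
    v <- slack_meta$variable[i]; role <- slack_meta$role[i]
    vals <- panel_matrix(panel, k, v)[, t]
    a <- numeric(nv)
    a[lam_off(k, t) + seq_len(n)] <- vals / slack_meta$obs[i]
    a[slack_meta$col[i]] <- sgn[[role]]
    add_row(a, 1, family = role, division = k,
            period = periods[t], variable = v)
  }

  # variable returns to scale: e'lambda_k^t = 1
  for (k in dnames) for (t in seq_len(Tn)) {
    a <- numeric(nv)
    a[lam_off(k, t) + seq_len(n)] <- 1
    add_row(a, 1, family = "vrs", division = k, period = periods[t],
            variable = NA_character_)
  }

  # carry-over continuity between consecutive periods:
  #   sum_j z_j^(t) lambda_jk^t = sum_j z_j^(t) lambda_jk^(t+1),  t = 1..T-1
  co <- spec$carryovers
  for (i in seq_len(nrow(co))) {
    k <- co$division[i]; v <- co$variable[i]
    Z <- panel_matrix(panel, k, v)
    if (Tn > 1) for (t in seq_len(Tn - 1L)) {
      z <- Z[, t] / mean(Z[, t])   # row scaling only
      a <- numeric(nv)
      a[lam_off(k, t) + seq_len(n)] <- z
      a[lam_off(k, t + 1L) + seq_len(n)] <- -z
      add_row(a, 0, family = "carry_continuity", division = k,
              period = periods[t], variable = v)
    }
  }

  # optional within-period link continuity between source and target blocks
  if (link_continuity && nrow(spec$links)) {
    lk <- spec$links
    for (i in seq_len(nrow(lk))) {
      Z <- panel_matrix(panel, lk$target[i], lk$variable[i])
      for (t in seq_len(Tn)) {
        z <- Z[, t] / mean(Z[, t])
        a <- numeric(nv)
        a[lam_off(lk$source[i], t) + seq_len(n)] <- z
        a[lam_off(lk$target[i], t) + seq_len(n)] <-
          a[lam_off(lk$target[i], t) + seq_len(n)] - z
        add_row(a, 0, family = "link_continuity", division = lk$target[i],
                period = periods[t], variable = lk$variable[i])
      }
    }
  }

  lambda_meta <- data.frame(
    division = rep(dnames, each = Tn * n),
    period = rep(rep(periods, each = n), K),
    dmu = rep(dmus, K * Tn),
    col = seq_len(n_lambda), stringsAsFactors = FALSE)

  structure(list(
    dmu = dmu, o = o, n = n, K = K, Tn = Tn,
    dmus = dmus, periods = periods, divisions = dnames,
    A = do.call(rbind, rows), b = rhs,
    con_meta = do.call(rbind, meta),
    lambda_meta = lambda_meta, slack_meta = slack_meta,
    n_lambda = n_lambda, nv = nv,
    Wkt = Wkt, w_total = sum(Wkt),
    m_plus_link = m_plus_link, r_plus_good = r_plus_good
  ), class = "dndea_fp")
}

# --- Charnes-Cooper linearization ------------------------------------------

# The ratio objective
#   min (w_total - sum nc * sigma) / (w_total + sum dc * sigma)
# over the polytope A (lambda, sigma) = b becomes, with tau > 0 scaling all
# variables (V = tau * v):
#   min  w_total * tau - nc' S
#   s.t. w_total * tau + dc' S = 1       (normalization)
#        A V - b tau            = 0
#        tau >= tau_min, V >= 0
linearize <- function(fp, tau_min = 1e-9) {
  nv <- fp$nv
  obj <- c(numeric(nv), fp$w_total)
  obj[fp$slack_meta$col] <- -fp$slack_meta$num_coef
  den <- c(numeric(nv), fp$w_total)
  den[fp$slack_meta$col] <- fp$slack_meta$den_coef
  A3 <- rbind(cbind(fp$A, -fp$b), den)
  b3 <- c(rep(0, length(fp$b)), 1)
  A2 <- matrix(c(numeric(nv), 1), 1L)
  structure(list(obj = obj, A3 = A3, b3 = b3, A2 = A2, b2 = tau_min,
                 fp = fp), class = "dndea_lp")
}

solve_linear_program <- function(a, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                                 A3 = NULL, b3 = NULL, maxi = FALSE) {
  A <- rbind(A1, A2, A3)
  b <- c(b1, b2, b3)
  sense <- c(rep("<=", length(b1)), rep(">=", length(b2)),
             rep("=", length(b3)))
  # retry once under Bland's rule from the start: slower but immune to the
  # degenerate stalling that aggressive pricing can hit
  res <- tryCatch(lp_solve(a, A, b, sense, maximize = maxi),
                  error = function(e) e)
  if (inherits(res, "error"))
    res <- lp_solve(a, A, b, sense, maximize = maxi, bland_start = TRUE,
                    maxit = 500000L)
  list(soln = res$x, value = res$value)
}

# --- per-DMU solve ----------------------------------------------------------

#' Solve the efficiency program for one DMU
#'
#' Assembles the non-oriented dynamic network SBM fractional program for the
#' evaluated unit, linearizes it by the Charnes-Cooper transformation,
#' minimizes, and (by default) runs a second lexicographic pass that
#' maximizes total slack at the optimal efficiency so that reported slacks
#' and factor indices are deterministic among alternate optima.
#'
#' @param spec A validated [dea_spec()].
#' @param panel A validated [dea_panel()].
#' @param dmu DMU identifier.
#' @param link_continuity Also tie each link's source and target intensity
#'   blocks through the link values (off by default).
#' @param lex Run the lexicographic maximal-slack pass (default `TRUE`).
#' @param Wkt Optional K x T weight matrix overriding `W^k * W^t` (used
#'   internally for re-optimized decompositions).
#' @param tol Feasibility tolerance for the built-in residual check.
#' @return An object of class `dndea_solution`: overall efficiency `theta`,
#'   recovered intensities and slacks, and the per-(division, period)
#'   numerator/denominator parts `N` and `D` from which period, division and
#'   division-period efficiencies are read.
#' @export
solve_dmu <- function(spec, panel, dmu, link_continuity = FALSE, lex = TRUE,
                      Wkt = NULL, tol = 1e-6) {
  fp <- assemble_program(spec, panel, dmu, Wkt = Wkt,
                         link_continuity = link_continuity)
  lp <- linearize(fp)
  res <- solve_linear_program(lp$obj, A2 = lp$A2, b2 = lp$b2,
                              A3 = lp$A3, b3 = lp$b3, maxi = FALSE)
  v <- res$soln
  tau <- v[fp$nv + 1L]
  if (!is.finite(tau) || tau <= 0)
    stop("degenerate scaling factor in linearized program", call. = FALSE)
  theta <- min(max(res$value, 0), 1)
  sigma <- v[fp$slack_meta$col] / tau
  lambda <- v[seq_len(fp$n_lambda)] / tau

  # lexicographic pass: among all solutions attaining theta, maximize the
  # total slack ratio.  The constraints are linear in (lambda, sigma) and the
  # attained-efficiency condition N(sigma) <= theta * D(sigma) is too.
  if (lex) {
    nc <- numeric(fp$nv); dc <- numeric(fp$nv)
    nc[fp$slack_meta$col] <- fp$slack_meta$num_coef
    dc[fp$slack_meta$col] <- fp$slack_meta$den_coef
    ratio_row <- nc + theta * dc
    ratio_rhs <- max(fp$w_total * (1 - theta) - 1e-9, 0)
    a <- numeric(fp$nv)
    a[fp$slack_meta$col] <- 1
    res2 <- tryCatch(
      solve_linear_program(a, A2 = matrix(ratio_row, 1L), b2 = ratio_rhs,
                           A3 = fp$A, b3 = fp$b, maxi = TRUE),
      error = function(e) NULL)
    if (!is.null(res2)) {
      sigma <- res2$soln[fp$slack_meta$col]
      lambda <- res2$soln[seq_len(fp$n_lambda)]
    }
  }

  sm <- fp$slack_meta
  sm$ratio <- pmax(sigma, 0)
  sm$slack <- sm$ratio * sm$obs

  # numerator / denominator parts per (division, period)
  N <- matrix(1, fp$K, fp$Tn, dimnames = list(fp$divisions, fp$periods))
  D <- matrix(1, fp$K, fp$Tn, dimnames = list(fp$divisions, fp$periods))
  for (k in fp$divisions) for (ti in seq_len(fp$Tn)) {
    rows <- sm$division == k & sm$t == ti
    num_rows <- rows & sm$role %in% c("input", "link_in")
    den_rows <- rows & sm$role %in% c("good_output", "bad_output", "carryover")
    if (fp$m_plus_link[[k]] > 0)
      N[k, ti] <- 1 - sum(sm$ratio[num_rows]) / fp$m_plus_link[[k]]
    if (fp$r_plus_good[[k]] > 0)
      D[k, ti] <- 1 + sum(sm$ratio[den_rows]) / fp$r_plus_good[[k]]
  }

  lam <- array(lambda, dim = c(fp$n, fp$Tn, fp$K),
               dimnames = list(fp$dmus, fp$periods, fp$divisions))

  sol <- structure(list(
    dmu = dmu, theta = theta, status = "optimal",
    lambda = lam,
    slacks = sm[c("division", "period", "variable", "role", "obs",
                  "slack", "ratio")],
    N = N, D = D, Wkt = fp$Wkt, w_total = fp$w_total,
    link_continuity = link_continuity, lex = lex
  ), class = "dndea_solution")

  chk <- verify_solution(sol, spec, panel, tol = tol)
  if (!chk$pass)
    warning(sprintf("DMU %s: max constraint residual %.2e exceeds tol %.1e",
                    dmu, chk$max_residual, tol), call. = FALSE)
  sol
}

#' @export
print.dndea_solution <- function(x, ...) {
  cat(sprintf("dndea solution for DMU '%s': overall efficiency %.6f (%s)\n",
              x$dmu, x$theta, x$status))
  nz <- x$slacks[x$slacks$ratio > 1e-9, ]
  if (nrow(nz)) {
    cat("  nonzero slacks:\n")
    print(format(nz, digits = 6), row.names = FALSE)
  } else cat("  all slacks zero (efficient)\n")
  invisible(x)
}

#' Solve the efficiency program for every DMU
#'
#' Maps [solve_dmu()] over all units of the panel (in panel order). Failures
#' of individual units are collected and reported as a warning; the batch is
#' not aborted.
#'
#' @inheritParams solve_dmu
#' @return A named list of `dndea_solution` objects (failed units are
#'   `NULL`).
#' @export
solve_all <- function(spec, panel, link_continuity = FALSE, lex = TRUE,
                      tol = 1e-6) {
  out <- vector("list", length(panel$dmus))
  names(out) <- panel$dmus
  failed <- character(0)
  for (d in panel$dmus) {
    # out[d] <- list(...) keeps NULL entries in place for failed units
    out[d] <- list(tryCatch(
      solve_dmu(spec, panel, d, link_continuity = link_continuity,
                lex = lex, tol = tol),
      error = function(e) {
        failed <<- c(failed, sprintf("%s (%s)", d, conditionMessage(e)))
        NULL
      }))
  }
  if (length(failed))
    warning("solve failed for DMU(s): ", paste(failed, collapse = "; "),
            call. = FALSE)
  out
}

#' Verify a solution's constraint residuals
#'
#' Recomputes every constraint family directly from the panel values, the
#' recovered intensities and the absolute slacks — independently of the
#' scaled matrices used inside the solver — and reports the maximum absolute
#' residual per family (relative to the observed value for value
#' constraints).
#'
#' @param sol A `dndea_solution`.
#' @inheritParams solve_dmu
#' @return List with `residuals` (named per family), `max_residual`, and
#'   `pass` (all residuals below `tol`).
#' @export
verify_solution <- function(sol, spec, panel, tol = 1e-6) {
  spec <- validate_spec(spec)
  o <- match(sol$dmu, panel$dmus)
  Tn <- length(panel$periods)
  res <- c(input = 0, link_in = 0, good_output = 0, bad_output = 0,
           carryover = 0, vrs = 0, carry_continuity = 0)

  sm <- sol$slacks
  sgn <- c(input = 1, link_in = 1, good_output = -1, bad_output = 1,
           carryover = -1)
  for (i in seq_len(nrow(sm))) {
    k <- sm$division[i]; v <- sm$variable[i]
    t <- match(sm$period[i], panel$periods)
    vals <- panel_matrix(panel, k, v)[, t]
    lhs <- sum(vals * sol$lambda[, t, k]) + sgn[[sm$role[i]]] * sm$slack[i]
    r <- abs(lhs - sm$obs[i]) / sm$obs[i]
    res[sm$role[i]] <- max(res[sm$role[i]], r)
  }
  for (k in names(spec$divisions)) for (t in seq_len(Tn))
    res["vrs"] <- max(res["vrs"], abs(sum(sol$lambda[, t, k]) - 1))
  co <- spec$carryovers
  for (i in seq_len(nrow(co))) {
    Z <- panel_matrix(panel, co$division[i], co$variable[i])
    if (Tn > 1) for (t in seq_len(Tn - 1L)) {
      lhs <- sum(Z[, t] * sol$lambda[, t, co$division[i]])
      rhs <- sum(Z[, t] * sol$lambda[, t + 1L, co$division[i]])
      res["carry_continuity"] <- max(res["carry_continuity"],
                                     abs(lhs - rhs) / mean(Z[, t]))
    }
  }
  list(residuals = res, max_residual = max(res), pass = max(res) <= tol)
}
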