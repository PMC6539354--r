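# Dense two-phase primal simplex with periodic refactorization.
#
# The Charnes-Cooper linearization of an SBM program always contains
# homogenized equality rows with zero right-hand side, which the simplex
# implementations shipped with base R's recommended packages do not handle
# reliably, so the package carries its own solver.  Phase 1 minimizes the
# sum of artificial variables, phase 2 the true objective.  Dantzig pricing
# with a permanent switch to Bland's rule after a stall guarantees
# termination on degenerate programs (DEA programs are routinely
# degenerate), and the working tableau is recomputed from the original data
# at regular intervals to keep the accumulated floating-point drift of
# tableau updates in check.  All programs solved here are small and
# row-scaled to O(1) coefficients, so dense linear algebra is appropriate.

# Minimize (or maximize) obj'x subject to A x (sense) b, x >= 0.
# sense: character vector over rows: "<=", ">=", "=".
lp_solve <- function(obj, A, b, sense, maximize = FALSE, tol = 1e-8,
                     maxit = NULL, must_solve = TRUE, bland_start = FALSE) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(sense) == m, length(obj) == n)
  cost <- if (maximize) -obj else obj

  # equilibrate: scale rows then columns towards unit magnitude so that
  # pivot selection is not dominated by raw value disparities
  rmax <- apply(abs(A), 1, max)
  rscl <- ifelse(rmax > 0, 1 / rmax, 1)
  A <- A * rscl
  b <- b * rscl
  cmax <- apply(abs(A), 2, max)
  cscl <- ifelse(cmax > 0, 1 / cmax, 1)
  A <- sweep(A, 2, cscl, `*`)
  cost <- cost * cscl

  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
    sense[flip] <- chartr("<>", "><", sense[flip])
  }

  # slack/surplus columns, then one artificial per row (for "<=" rows the
  # slack itself is the initial basic variable and the artificial is unused)
  n_slack <- sum(sense != "=")
  S <- matrix(0, m, n_slack)
  slack_of <- integer(m)
  j <- 0L
  for (i in seq_len(m)) {
    if (sense[i] == "=") next
    j <- j + 1L
    S[i, j] <- if (sense[i] == "<=") 1 else -1
    slack_of[i] <- n + j
  }
  need_art <- sense != "<="
  n_art <- sum(need_art)
  Ar <- matrix(0, m, n_art)
  art_of <- integer(m)
  j <- 0L
  for (i in which(need_art)) {
    j <- j + 1L
    Ar[i, j] <- 1
    art_of[i] <- n + n_slack + j
  }

  N <- n + n_slack + n_art
  A0 <- cbind(A, S, Ar)          # original (unpivoted) columns
  b0 <- b
  basis <- ifelse(need_art, art_of, slack_of)
  art_cols <- if (n_art) n + n_slack + seq_len(n_art) else integer(0)
  if (is.null(maxit)) maxit <- max(2000L, 100L * (m + n))

  fail <- function(status) {
    if (must_solve) stop("linear program ", status, call. = FALSE)
    list(x = rep(NA_real_, n), value = NA_real_, status = status)
  }

  if (n_art > 0L) {
    cost1 <- c(rep(0, n + n_slack), rep(1, n_art))
    ph1 <- simplex_phase(A0, b0, basis, cost1, tol, maxit,
                         banned = integer(0), bland_start = bland_start)
    if (ph1$status != "optimal") return(fail("infeasible"))
    basis <- ph1$basis
    if (ph1$value > 1e-6 * max(1, max(abs(b0)))) return(fail("infeasible"))
    # drop rows whose artificial stays basic: pivot out where possible,
    # otherwise the row is redundant and is removed outright
    keep <- rep(TRUE, length(b0))
    Tm <- factorized_tableau(A0, b0, basis)
    if (is.null(Tm)) return(fail("numerically singular basis"))
    for (r in which(basis %in% art_cols)) {
      row <- Tm[r, seq_len(n + n_slack)]
      piv <- which(abs(row) > 1e-7)[1]
      if (is.na(piv)) keep[r] <- FALSE
      else { Tm <- pivot_tableau(Tm, r, piv); basis[r] <- piv }
    }
    if (!all(keep)) {
      A0 <- A0[keep, , drop = FALSE]; b0 <- b0[keep]; basis <- basis[keep]
    }
  }

  cost2 <- c(cost, rep(0, n_slack + n_art))
  ph2 <- simplex_phase(A0, b0, basis, cost2, tol, maxit, banned = art_cols,
                       bland_start = bland_start)
  if (ph2$status != "optimal") return(fail(ph2$status))

  x <- numeric(N)
  x[ph2$basis] <- ph2$xB
  x[x < 0 & x > -1e-9] <- 0
  value <- sum(cost * x[seq_len(n)])
  # undo the column equilibration for the reported solution
  list(x = x[seq_len(n)] * cscl, value = if (maximize) -value else value,
       status = "optimal")
}

pivot_tableau <- function(Tm, r, enter) {
  piv <- Tm[r, ] / Tm[r, enter]
  col <- Tm[, enter]
  Tm <- Tm - tcrossprod(col, piv)
  Tm[r, ] <- piv
  Tm
}

# rebuild the simplex tableau [B^-1 A0 | B^-1 b] from the original data;
# NULL when the basis matrix is numerically singular
factorized_tableau <- function(A0, b0, basis) {
  B <- A0[, basis, drop = FALSE]
  tryCatch(cbind(solve(B, A0), solve(B, b0)), error = function(e) NULL)
}

simplex_phase <- function(A0, b0, basis, cost, tol, maxit,
                          banned = integer(0), refresh_every = 120L,
                          bland_start = FALSE) {
  m <- nrow(A0); N <- ncol(A0)
  allowed <- rep(TRUE, N)
  allowed[banned] <- FALSE
  Tm <- factorized_tableau(A0, b0, basis)
  if (is.null(Tm)) stop("numerically singular starting basis", call. = FALSE)
  bland <- bland_start
  last_obj <- Inf; stall <- 0L; since_refresh <- 0L
  for (iter in seq_len(maxit)) {
    if (since_refresh >= refresh_every) {
      Tm2 <- factorized_tableau(A0, b0, basis)
      if (!is.null(Tm2)) Tm <- Tm2
      since_refresh <- 0L
    }
    cb <- cost[basis]
    red <- cost - as.vector(crossprod(Tm[, seq_len(N), drop = FALSE], cb))
    red[!allowed] <- 0
    cand <- which(red < -tol)
    if (!length(cand)) {
      # confirm optimality on a freshly factorized tableau
      Tm2 <- factorized_tableau(A0, b0, basis)
      if (!is.null(Tm2)) {
        Tm <- Tm2
        red <- cost - as.vector(crossprod(Tm[, seq_len(N), drop = FALSE],
                                          cost[basis]))
        red[!allowed] <- 0
        cand <- which(red < -10 * tol)
      }
      if (!length(cand)) {
        xB <- Tm[, N + 1L]
        return(list(basis = basis, xB = xB,
                    value = sum(cost[basis] * xB), status = "optimal"))
      }
      since_refresh <- 0L
    }
    enter <- if (bland) cand[1] else cand[which.min(red[cand])]
    colv <- Tm[, enter]
    pos <- which(colv > tol)
    if (!length(pos))
      return(list(basis = basis, xB = Tm[, N + 1L], value = NA_real_,
                  status = "unbounded"))
    rhs <- pmax(Tm[pos, N + 1L], 0)
    ratio <- rhs / colv[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + tol * (1 + rmin)]
    # stable pivots first; Bland's index rule once anti-cycling is active
    r <- if (length(ties) == 1L) ties
    else if (bland) ties[which.min(basis[ties])]
    else ties[which.max(colv[ties])]
    Tm <- pivot_tableau(Tm, r, enter)
    basis[r] <- enter
    since_refresh <- since_refresh + 1L
    obj <- sum(cost[basis] * Tm[, N + 1L])
    if (obj < last_obj - 1e-12) { last_obj <- obj; stall <- 0L }
    else {
      stall <- stall + 1L
      if (stall >= 60L) bland <- TRUE  # permanent: guarantees termination
    }
  }
  stop("simplex iteration limit reached", call. = FALSE)
}
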