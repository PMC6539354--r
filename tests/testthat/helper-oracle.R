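# Independent brute-force oracle for tiny instances (one division, up to
# three DMUs, up to two periods, at most one carry-over).
#
# The SBM objective is a ratio of two affine functions of the intensity
# vector(s), hence quasilinear: its minimum over the feasible polytope is
# attained at a vertex.  oracle_theta() therefore enumerates every vertex of
# the feasible set in lambda-space (all active-set combinations of the
# inequality constraints together with the equality rows), evaluates the
# ratio exactly at each feasible vertex, and returns the minimum.  This
# shares nothing with the solver path: no program assembly, no
# Charnes-Cooper transformation, no LP iterations.
#
# oracle_theta_grid() is a secondary single-period check that minimizes the
# same ratio over a plain grid on the intensity simplex.

# constraint system over lambda = (lambda^1, ..., lambda^T) stacked, for the
# single division of `spec`; slacks are implied (inequality directions)
oracle_system <- function(spec, panel, dmu) {
  stopifnot(length(spec$divisions) == 1L)
  k <- names(spec$divisions)[1]
  o <- match(dmu, panel$dmus)
  n <- length(panel$dmus)
  Tn <- length(panel$periods)
  dk <- spec$divisions[[k]]
  co <- spec$carryovers$variable[spec$carryovers$division == k]
  stopifnot(length(co) <= 1L, Tn <= 2L)
  nv <- n * Tn
  idx <- function(t) (t - 1L) * n + seq_len(n)

  Aeq <- NULL; beq <- NULL
  for (t in seq_len(Tn)) {
    a <- numeric(nv); a[idx(t)] <- 1
    Aeq <- rbind(Aeq, a); beq <- c(beq, 1)
  }
  if (length(co) && Tn == 2L) {
    z <- panel$values[[k]][[co]][, 1]
    a <- numeric(nv); a[idx(1)] <- z; a[idx(2)] <- -z
    Aeq <- rbind(Aeq, a); beq <- c(beq, 0)
  }

  Ain <- NULL; bin <- NULL   # rows a . lambda <= b
  add_le <- function(a, b) { Ain <<- rbind(Ain, a); bin <<- c(bin, b) }
  for (i in seq_len(nv)) {   # lambda >= 0
    a <- numeric(nv); a[i] <- -1; add_le(a, 0)
  }
  for (t in seq_len(Tn)) {
    for (v in dk$inputs) {
      vals <- panel$values[[k]][[v]][, t]
      a <- numeric(nv); a[idx(t)] <- vals
      add_le(a, vals[o])
    }
    for (v in dk$good_outputs) {
      vals <- panel$values[[k]][[v]][, t]
      a <- numeric(nv); a[idx(t)] <- -vals
      add_le(a, -vals[o])
    }
    for (v in dk$bad_outputs) {
      vals <- panel$values[[k]][[v]][, t]
      a <- numeric(nv); a[idx(t)] <- vals
      add_le(a, vals[o])
    }
    for (v in co) {
      vals <- panel$values[[k]][[v]][, t]
      a <- numeric(nv); a[idx(t)] <- -vals
      add_le(a, -vals[o])
    }
  }
  list(k = k, o = o, n = n, Tn = Tn, nv = nv, dk = dk, co = co,
       Aeq = Aeq, beq = beq, Ain = Ain, bin = bin, idx = idx)
}

# ratio objective at one lambda (uniform weights cancel in the ratio)
oracle_ratio <- function(sys, panel, lambda) {
  num <- 0; den <- 0
  m <- length(sys$dk$inputs)
  rg <- length(sys$dk$good_outputs) + length(sys$dk$bad_outputs) +
    length(sys$co)
  for (t in seq_len(sys$Tn)) {
    l <- lambda[sys$idx(t)]
    sin_sum <- 0; sout_sum <- 0
    for (v in sys$dk$inputs) {
      vals <- panel$values[[sys$k]][[v]][, t]
      sin_sum <- sin_sum + max(vals[sys$o] - sum(vals * l), 0) / vals[sys$o]
    }
    for (v in sys$dk$good_outputs) {
      vals <- panel$values[[sys$k]][[v]][, t]
      sout_sum <- sout_sum + max(sum(vals * l) - vals[sys$o], 0) / vals[sys$o]
    }
    for (v in sys$dk$bad_outputs) {
      vals <- panel$values[[sys$k]][[v]][, t]
      sout_sum <- sout_sum + max(vals[sys$o] - sum(vals * l), 0) / vals[sys$o]
    }
    for (v in sys$co) {
      vals <- panel$values[[sys$k]][[v]][, t]
      sout_sum <- sout_sum + max(sum(vals * l) - vals[sys$o], 0) / vals[sys$o]
    }
    num <- num + 1 - if (m) sin_sum / m else 0
    den <- den + 1 + if (rg) sout_sum / rg else 0
  }
  unname(num / den)
}

# enumerate all vertices of {Aeq l = beq, Ain l <= bin} and minimize the ratio
oracle_theta <- function(spec, panel, dmu, tol = 1e-7) {
  sys <- oracle_system(spec, panel, dmu)
  n_eq <- nrow(sys$Aeq)
  free <- sys$nv - n_eq
  stopifnot(free >= 0)
  best <- Inf
  combos <- if (free == 0) matrix(integer(0), 1, 0)
  else t(utils::combn(nrow(sys$Ain), free))
  for (ci in seq_len(nrow(combos))) {
    act <- combos[ci, ]
    M <- rbind(sys$Aeq, sys$Ain[act, , drop = FALSE])
    rhs <- c(sys$beq, sys$bin[act])
    l <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(l)) next
    viol <- sys$Ain %*% l - sys$bin
    if (max(viol) > tol * max(1, max(abs(sys$bin)))) next
    val <- oracle_ratio(sys, panel, l)
    if (val < best) best <- val
  }
  best
}

# secondary check: plain grid search on the simplex (single period only)
oracle_theta_grid <- function(spec, panel, dmu, step = 1e-3, ftol = 1e-9) {
  sys <- oracle_system(spec, panel, dmu)
  stopifnot(sys$Tn == 1L, sys$n <= 3L)
  grid <- if (sys$n == 2) {
    l1 <- seq(0, 1, by = step)
    cbind(l1, 1 - l1)
  } else {
    g <- expand.grid(l1 = seq(0, 1, by = step), l2 = seq(0, 1, by = step))
    g <- g[g$l1 + g$l2 <= 1 + 1e-12, ]
    cbind(g$l1, g$l2, pmax(1 - g$l1 - g$l2, 0))
  }
  feas <- rep(TRUE, nrow(grid))
  for (r in seq_len(nrow(sys$Ain))) {
    feas <- feas & (grid %*% sys$Ain[r, sys$idx(1)] <=
                      sys$bin[r] + ftol * max(1, abs(sys$bin[r])))
  }
  grid <- grid[feas, , drop = FALSE]
  vals <- vapply(seq_len(nrow(grid)), function(i)
    oracle_ratio(sys, panel, grid[i, ]), 0)
  min(vals)
}
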