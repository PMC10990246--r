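# Active-set refinement of a dual QP solution.
#
# The Goldfarb-Idnani solver can stall at a feasible but suboptimal point when
# YKY is (structurally) singular: the replicated labeled rows give exactly
# opposite column pairs, so curvature along many directions is only the
# diagonal jitter.  Starting from the solver's point, this routine performs
# standard primal active-set iterations on the *original* problem
#   min 1/2 g'Hg - 1'g   s.t.  y'g = 0,  t'g >= 0,  0 <= g <= u,
# solving each equality-constrained subproblem by pseudoinverse (the KKT
# system is singular by construction).  It only ever returns a feasible point
# with objective no worse than the seed.

pinv_solve <- function(A, b, rtol = 1e-13) {
  # rtol must sit well below the kernel-jitter scale (1e-8): the structurally
  # duplicated +/- columns of YKY leave directions whose only curvature is the
  # jitter, and those are exactly the directions the linear term still drives.
  sv <- svd(A)
  pos <- sv$d > rtol * max(sv$d, .Machine$double.eps)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (dinv * crossprod(sv$u, b))
}

refine_dual <- function(g, H, y, tvec, upper, maxit = 60, tol = 1e-9) {
  N <- length(g)
  obj <- function(x) 0.5 * drop(crossprod(x, H %*% x)) - sum(x)
  tau <- pmax(1e-8 * pmax(upper, 1), 1e-12)
  g <- pmin(pmax(g, 0), upper)
  best <- g; best_obj <- obj(g)
  at_lo <- g <= tau
  at_up <- g >= upper - tau
  ineq_active <- abs(sum(tvec * g)) <= 1e-8 * max(1, sum(abs(g)))
  for (it in seq_len(maxit)) {
    free <- which(!at_lo & !at_up)
    fixed <- which(at_lo | at_up)
    gB <- ifelse(at_up, upper, 0)
    ncon <- 1L + as.integer(ineq_active)
    nf <- length(free)
    # KKT system over free variables + equality (+ order row if active)
    Cmat <- rbind(y[free], if (ineq_active) tvec[free])
    rhs_c <- -c(sum(y[fixed] * gB[fixed]),
                if (ineq_active) sum(tvec[fixed] * gB[fixed]))
    lin <- if (length(fixed)) drop(H[free, fixed, drop = FALSE] %*% gB[fixed]) - 1
           else rep(-1, nf)
    M <- rbind(cbind(H[free, free, drop = FALSE], t(Cmat)),
               cbind(Cmat, matrix(0, ncon, ncon)))
    sol <- pinv_solve(M, c(-lin, rhs_c))
    gF <- sol[seq_len(nf)]
    mults <- sol[nf + seq_len(ncon)]
    lambda <- mults[1]
    mu <- if (ineq_active) -mults[2] else 0   # stationarity: Hg - 1 + lambda*y - mu*t = 0
    # step toward the subproblem solution, clipped at the first blocking bound
    target <- gB; target[free] <- gF
    dir <- target - g
    smax <- 1
    block <- 0L
    for (i in free) {
      if (dir[i] < -tol) { s <- (0 - g[i]) / dir[i]; if (s < smax) { smax <- s; block <- i } }
      if (dir[i] > tol)  { s <- (upper[i] - g[i]) / dir[i]; if (s < smax) { smax <- s; block <- i } }
    }
    if (!ineq_active) {
      tg <- sum(tvec * g); td <- sum(tvec * dir)
      if (td < -tol && tg + td * smax < 0) {
        s <- -tg / td
        if (s < smax) { smax <- s; block <- -1L }
      }
    }
    g <- pmin(pmax(g + smax * dir, 0), upper)
    o <- obj(g)
    if (o < best_obj - 1e-14 * abs(best_obj)) { best <- g; best_obj <- o }
    if (smax < 1) {
      # hit a bound (or the order inequality): grow the working set
      if (block == -1L) ineq_active <- TRUE
      else if (dir[block] < 0) at_lo[block] <- TRUE else at_up[block] <- TRUE
      next
    }
    # full step taken: check multiplier signs to decide release or stop
    grad <- drop(H %*% g) - 1 + lambda * y - mu * tvec
    viol_lo <- which(at_lo & grad < -tol * max(1, max(abs(grad))))
    viol_up <- which(at_up & grad > tol * max(1, max(abs(grad))))
    rel_t <- ineq_active && mu < -tol
    if (!length(viol_lo) && !length(viol_up) && !rel_t) break
    scores <- c(if (length(viol_lo)) -grad[viol_lo],
                if (length(viol_up)) grad[viol_up],
                if (rel_t) -mu)
    pick <- which.max(scores)
    nlo <- length(viol_lo); nup <- length(viol_up)
    if (pick <= nlo) at_lo[viol_lo[pick]] <- FALSE
    else if (pick <= nlo + nup) at_up[viol_up[pick - nlo]] <- FALSE
    else ineq_active <- FALSE
    at_lo[g > tau] <- FALSE
    at_up[g < upper - tau] <- FALSE
  }
  if (obj(g) <= best_obj) best <- g
  pmin(pmax(best, 0), upper)
}
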