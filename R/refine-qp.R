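# Generic primal active-set refinement for   min 1/2 z'Dz + c'z  s.t.  Az >= b
# (first `meq` rows equalities).  Seeded with a feasible point from a
# numerical solver, it polishes to machine precision by exact KKT solves on
# the working set; singular KKT systems (D only curves a subspace, redundant
# rows) are handled by pseudoinverse.  Returns a feasible point with
# objective no worse than the seed.
refine_qp <- function(z, D, cvec, A, b, meq = 0, maxit = 100, tol = 1e-10) {
  obj <- function(x) 0.5 * drop(crossprod(x, D %*% x)) + sum(cvec * x)
  m <- nrow(A)
  res <- drop(A %*% z) - b
  scale_r <- pmax(sqrt(rowSums(A^2)), 1)
  W <- which(seq_len(m) <= meq | res <= tol * scale_r)
  best <- z; best_obj <- obj(z)
  for (it in seq_len(maxit)) {
    AW <- A[W, , drop = FALSE]
    nW <- length(W)
    M <- rbind(cbind(D, t(AW)), cbind(AW, matrix(0, nW, nW)))
    sol <- pinv_solve(M, c(-cvec, b[W]))
    zstar <- sol[seq_along(z)]
    lambda <- -sol[length(z) + seq_len(nW)]
    dz <- zstar - z
    if (max(abs(dz)) > 1e-14 * max(1, max(abs(z)))) {
      Ad <- drop(A %*% dz)
      smax <- 1; block <- 0L
      out <- setdiff(seq_len(m), W)
      for (r in out) {
        if (Ad[r] < -tol) {
          s <- (b[r] - sum(A[r, ] * z)) / Ad[r]
          if (s < smax) { smax <- max(s, 0); block <- r }
        }
      }
      z <- z + smax * dz
      o <- obj(z)
      if (o < best_obj + 1e-12 * max(1, abs(best_obj))) { best <- z; best_obj <- o }
      if (block > 0L) { W <- c(W, block); next }
    }
    # full step: drop the worst wrong-sign multiplier among inequalities
    ineq <- which(W > meq)
    if (length(ineq)) {
      lam_i <- lambda[ineq]
      worst <- which.min(lam_i)
      if (lam_i[worst] < -tol * max(1, max(abs(lambda)))) {
        W <- W[-ineq[worst]]
        next
      }
    }
    break
  }
  if (obj(z) <= best_obj) best <- z
  best
}
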