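#' Assemble the dual quadratic program of the ordinal classifier
#'
#' The weakly supervised ordinal SVM separates three ordered classes
#' (0 = normal brain < 1 = tumor, gene non-altered < 2 = tumor, gene altered)
#' with one weight vector \eqn{w} in a reproducing kernel Hilbert space and
#' two biases \eqn{b_0 \le b_1}.  Its Lagrangian dual is a convex QP in the
#' multiplier vector \eqn{\gamma = (\alpha^{(1)}, \alpha^{(2)}, \beta^{(0)},
#' \beta^{(12)})}:
#' \deqn{\min_\gamma \tfrac12 \gamma^\top Y K Y \gamma - \mathbf 1^\top \gamma}
#' subject to one equality row
#' \eqn{-\sum\alpha^{(1)} + \sum\alpha^{(2)} - \sum\beta^{(0)} +
#' \sum\beta^{(12)} = 0}, one order inequality
#' \eqn{-\sum\alpha^{(1)} + \sum\alpha^{(2)} \ge 0} (the dual footprint of
#' \eqn{b_0 \le b_1}), and boxes \eqn{0 \le \alpha \le C_1},
#' \eqn{0 \le \beta \le C_2}.  The class-12 block spans the labeled blocks
#' followed by the unlabeled block (`X1 || X2 || X12`, \eqn{m_{12}'} rows):
#' labeled tumoral samples are constrained on both boundaries.
#'
#' `Y` is the block sign matrix \eqn{\mathrm{diag}(-1^{n_1}, +1^{n_2},
#' -1^{m_0}, +1^{m_{12}'})} and `K` the Gram matrix of the stacked rows.
#' Because the labeled rows appear twice, `Y K Y` is structurally singular;
#' the kernel's diagonal jitter keeps the QP strictly convex.
#'
#' @param ts a [training_set()] (already on the scale the kernel expects).
#' @param C1 box bound on the labeled-block multipliers (> 0).
#' @param C2 box bound on the normal/class-12 multipliers (> 0).
#' @param kernel a [kernel_spec()] with a concrete rbf bandwidth.
#' @return an object of class `wso_dual_qp` with elements `H` (= YKY +
#'   jitter), `K`, `y` (block signs), `tvec` (order-inequality row), `upper`
#'   (per-variable box), `blocks` (index list), `X` (stacked rows), `kernel`,
#'   `C1`, `C2`.
#' @seealso [solve_dual()], [wsosvm_fit()]
#' @export
assemble_dual <- function(ts, C1, C2, kernel) {
  stopifnot(inherits(ts, "wso_training_set"), inherits(kernel, "wso_kernel"))
  if (!is.numeric(C1) || C1 <= 0 || !is.numeric(C2) || C2 <= 0)
    stop("C1 and C2 must be positive")
  bs <- block_sizes(ts)
  if (bs["n1"] == 0L) stop("empty class block: X1 (labeled class-1 samples)")
  if (bs["n2"] == 0L) stop("empty class block: X2 (labeled class-2 samples)")
  n1 <- bs[["n1"]]; n2 <- bs[["n2"]]; m0 <- bs[["m0"]]; m12p <- bs[["m12p"]]
  X <- rbind(ts$X1, ts$X2, ts$X0, ts$X1, ts$X2, ts$X12)
  y <- rep(c(-1, 1, -1, 1), c(n1, n2, m0, m12p))
  tvec <- rep(c(-1, 1, 0, 0), c(n1, n2, m0, m12p))
  upper <- rep(c(C1, C1, C2, C2), c(n1, n2, m0, m12p))
  idx <- split(seq_len(n1 + n2 + m0 + m12p),
               rep(c("alpha1", "alpha2", "beta0", "beta12"),
                   c(n1, n2, m0, m12p)))
  K <- kernel_matrix(X, spec = kernel)
  H <- (y %o% y) * K
  structure(
    list(H = H, K = K, y = y, tvec = tvec, upper = upper,
         blocks = idx[c("alpha1", "alpha2", "beta0", "beta12")],
         sizes = bs, X = X, kernel = kernel, C1 = C1, C2 = C2),
    class = "wso_dual_qp"
  )
}

#' Solve the dual quadratic program
#'
#' Solves the assembled dual with the dual active-set method of Goldfarb and
#' Idnani ([quadprog::solve.QP()]).  If the factorization fails or the
#' returned point violates its constraints beyond `tol` (both can happen when
#' the replicated labeled rows make YKY nearly singular), the diagonal
#' regularization is escalated by factors of 100 and the solve retried; the
#' reported objective is always evaluated on the originally assembled `H`.
#'
#' @param qp a `wso_dual_qp` from [assemble_dual()].
#' @param tol feasibility tolerance for accepting a solve.
#' @param refine run active-set refinement on the original (base-jitter)
#'   problem after the solver seed; defaults to on for problems up to 400
#'   variables, where the refinement cost is negligible and high-precision
#'   KKT conditions matter (oracle comparisons, margin checks).
#' @return an object of class `wso_dual_solution`: multipliers `alpha1`,
#'   `alpha2`, `beta0`, `beta12`, the concatenated `gamma`, block signs `y`,
#'   the dual `objective` (minimization form), `status`, the residual of the
#'   equality row, the slack of the order inequality, and the extra jitter
#'   (if any) the solver needed.
#' @export
solve_dual <- function(qp, tol = 1e-8, refine = length(qp$y) <= 400) {
  stopifnot(inherits(qp, "wso_dual_qp"))
  N <- length(qp$y)
  Amat <- cbind(qp$y, qp$tvec, diag(N), -diag(N))
  bvec <- c(0, 0, rep(0, N), -qp$upper)
  scale <- max(mean(abs(diag(qp$H))), .Machine$double.eps)
  g <- NULL; used_extra <- 0
  # large problems start the ladder higher: the structural +/- column pairs
  # make the factorization fail at tiny regularization almost surely there,
  # and each failed attempt costs a full dense solve
  ladder <- if (N > 400) c(1e-6, 1e-4, 1e-2) else c(0, 1e-8, 1e-6, 1e-4, 1e-2)
  for (extra in ladder * scale) {
    sol <- tryCatch(
      quadprog::solve.QP(qp$H + diag(extra, N), rep(1, N), Amat, bvec, meq = 1),
      error = function(e) e
    )
    if (inherits(sol, "error")) next
    cand <- sol$solution
    viol <- max(-min(cand), max(cand - qp$upper), abs(sum(qp$y * cand)),
                max(0, -sum(qp$tvec * cand)))
    if (viol <= max(tol, 1e-7 * max(qp$upper))) {
      g <- cand; used_extra <- extra
      break
    }
    if (is.null(g)) { g <- cand; used_extra <- extra }  # best effort so far
  }
  if (is.null(g))
    stop("dual QP solver failed to converge (all jitter escalations rejected)")
  g <- pmin(pmax(g, 0), qp$upper)
  if (refine)
    g <- refine_dual(g, qp$H, qp$y, qp$tvec, qp$upper)
  # objective reported on the jitter-free YKY: the regularized problem's
  # optimum carries a bias of jitter*||gamma||^2/2, which would otherwise
  # dominate the duality gap whenever the multipliers are large
  objective <- 0.5 * (drop(crossprod(g, qp$H %*% g)) -
                        qp$kernel$jitter * sum(g^2)) - sum(g)
  structure(
    list(alpha1 = g[qp$blocks$alpha1], alpha2 = g[qp$blocks$alpha2],
         beta0 = g[qp$blocks$beta0], beta12 = g[qp$blocks$beta12],
         gamma = g, y = qp$y, objective = objective, status = "optimal",
         eq_residual = sum(qp$y * g), order_slack = sum(qp$tvec * g),
         extra_jitter = used_extra),
    class = "wso_dual_solution"
  )
}

# decision values of the fitted expansion at the training rows
# (kernel jitter removed from the diagonal contribution)
dual_h_train <- function(sol, qp) {
  coef <- sol$y * sol$gamma
  drop(qp$K %*% coef) - qp$kernel$jitter * coef
}

#' Recover the ordered biases from a dual solution
#'
#' Interior support vectors (multipliers strictly inside their box, with
#' tolerance \eqn{\tau = 10^{-6}\max(C_1, C_2)}) sit exactly on their margin,
#' so each contributes a bias estimate: \eqn{b_1 = h(x)+1} for class-1 and
#' \eqn{h(x)-1} for class-2 interior SVs, and analogously \eqn{b_0 = h(x)+1}
#' for class-0 and \eqn{h(x)-1} for class-12 interior SVs.  Estimates are
#' averaged.  When a boundary has no interior SV, the bias is taken as the
#' midpoint of the interval that the bound-active multipliers' KKT conditions
#' leave feasible; an interval empty beyond tolerance raises a degeneracy
#' error.  Finally `b0 <- min(b0, b1)` enforces the ordinal contract against
#' residual numerical noise.
#'
#' @param sol a `wso_dual_solution`.
#' @param qp the `wso_dual_qp` it solved.
#' @return list with `b0`, `b1` and the recovery `source` per boundary
#'   (`"interior"` or `"interval"`).
#' @export
recover_biases <- function(sol, qp) {
  h <- dual_h_train(sol, qp)
  g <- sol$gamma
  tau <- 1e-6 * max(qp$C1, qp$C2)
  at0 <- g <= tau
  atC <- g >= qp$upper - tau
  interior <- !at0 & !atC
  one_boundary <- function(lo_idx, hi_idx, lo_tgt, hi_tgt) {
    # lo_idx: block whose margin reads b = h + 1 ; hi_idx: b = h - 1
    cand <- c(h[lo_idx][interior[lo_idx]] + 1,
              h[hi_idx][interior[hi_idx]] - 1)
    if (length(cand)) return(list(b = mean(cand), source = "interior"))
    # KKT interval from bound-active multipliers:
    #   lo block at 0  => b >= h+1 ; lo block at C => b <= h+1
    #   hi block at 0  => b <= h-1 ; hi block at C => b >= h-1
    lo <- suppressWarnings(max(h[lo_idx][at0[lo_idx]] + 1,
                               h[hi_idx][atC[hi_idx]] - 1))
    hi <- suppressWarnings(min(h[lo_idx][atC[lo_idx]] + 1,
                               h[hi_idx][at0[hi_idx]] - 1))
    if (lo > hi + 1e-6 * max(1, abs(lo), abs(hi)))
      stop("bias recovery degenerate: empty KKT-feasible interval [",
           signif(lo, 6), ", ", signif(hi, 6), "]")
    b <- if (is.finite(lo) && is.finite(hi)) (min(lo, hi) + max(lo, hi)) / 2
         else if (is.finite(lo)) lo
         else if (is.finite(hi)) hi
         else 0
    list(b = b, source = "interval")
  }
  up <- one_boundary(qp$blocks$alpha1, qp$blocks$alpha2)
  lo <- one_boundary(qp$blocks$beta0, qp$blocks$beta12)
  list(b0 = min(lo$b, up$b), b1 = up$b,
       source = c(b0 = lo$source, b1 = up$source))
}

#' Fit a weakly supervised ordinal SVM
#'
#' Composition of the full training path: per-feature standardization over
#' all training samples, rbf-bandwidth resolution, dual assembly
#' ([assemble_dual()]), QP solve ([solve_dual()]) and bias recovery
#' ([recover_biases()]).  Deterministic given data and hyperparameters.
#'
#' The fitted decision function is the kernel expansion
#' \deqn{h(x) = -\sum_i \alpha_i^{(1)} k(x, x_i^{(1)})
#'  + \sum_{i'} \alpha_{i'}^{(2)} k(x, x_{i'}^{(2)})
#'  - \sum_k \beta_k^{(0)} k(x, x_k^{(0)})
#'  + \sum_j \beta_j^{(12)} k(x, x_j^{(12)}),}
#' and a sample is assigned class 2 if \eqn{h(x) \ge b_1}, class 1 if
#' \eqn{b_0 \le h(x) < b_1}, class 0 otherwise (boundary points take the
#' higher class, matching the non-strict inequalities of the decision rule).
#'
#' @param ts a [training_set()].
#' @param C1 penalty/box parameter for the labeled 1-vs-2 boundary.
#' @param C2 penalty/box parameter for the tumor-vs-normal boundary.
#' @param kernel a [kernel_spec()].
#' @param scale standardize features using all training samples (recommended;
#'   disable for pre-scaled or constructed data).
#' @return an object of class `wsosvm`: support expansion (`SV`, `coef`),
#'   biases `b0 <= b1`, resolved kernel, scaler, hyperparameters, block
#'   sizes, the dual solution and QP diagnostics.
#' @examples
#' set.seed(1)
#' ts <- training_set(
#'   X1 = matrix(rnorm(40), 20), X2 = matrix(rnorm(40, 4), 20),
#'   X0 = matrix(rnorm(40, -4), 20)
#' )
#' fit <- wsosvm_fit(ts, C1 = 1, C2 = 1, kernel = kernel_spec("linear"))
#' table(predict(fit, ts$X2))
#' @export
wsosvm_fit <- function(ts, C1 = 1, C2 = 1, kernel = kernel_spec("rbf"),
                       scale = TRUE) {
  stopifnot(inherits(ts, "wso_training_set"))
  Xall <- rbind(ts$X1, ts$X2, ts$X12, ts$X0)
  scaler <- if (scale) fit_scaler(Xall) else NULL
  sts <- training_set(
    apply_scaler(ts$X1, scaler), apply_scaler(ts$X2, scaler),
    if (nrow(ts$X12)) apply_scaler(ts$X12, scaler) else NULL,
    if (nrow(ts$X0)) apply_scaler(ts$X0, scaler) else NULL
  )
  kernel <- resolve_kernel(kernel, apply_scaler(Xall, scaler))
  qp <- assemble_dual(sts, C1, C2, kernel)
  sol <- solve_dual(qp)
  b <- recover_biases(sol, qp)
  coef <- sol$y * sol$gamma
  keep <- abs(coef) > 1e-10 * max(C1, C2)
  if (!any(keep)) keep <- rep(TRUE, length(coef))  # all-margin degenerate case
  structure(
    list(SV = qp$X[keep, , drop = FALSE], coef = coef[keep],
         b0 = b$b0, b1 = b$b1, bias_source = b$source,
         kernel = kernel, scaler = scaler, C1 = C1, C2 = C2,
         sizes = qp$sizes, dual = sol,
         feature_names = colnames(ts$X1)),
    class = "wsosvm"
  )
}

#' @export
print.wsosvm <- function(x, ...) {
  cat("Weakly supervised ordinal SVM\n")
  cat("  blocks: n1 =", x$sizes[["n1"]], " n2 =", x$sizes[["n2"]],
      " m12 =", x$sizes[["m12"]], " m0 =", x$sizes[["m0"]], "\n")
  cat("  kernel:", x$kernel$kind,
      if (x$kernel$kind == "rbf") paste0("(gamma = ", signif(x$kernel$gamma, 4), ")"),
      "  C1 =", x$C1, " C2 =", x$C2, "\n")
  cat("  biases: b0 =", signif(x$b0, 6), " b1 =", signif(x$b1, 6),
      " support vectors:", nrow(x$SV), "\n")
  invisible(x)
}

#' Decision values of a fitted model
#'
#' Evaluates the kernel expansion \eqn{h(x)} (continuous ordinal evidence;
#' larger means "more altered") for each row of `X`.  Scaling stored in the
#' model is applied internally.
#'
#' @param model a fitted `wsosvm`.
#' @param X numeric matrix (rows = samples) or a single vector.
#' @return numeric vector of \eqn{h} values.
#' @export
decision_value <- function(model, X) {
  stopifnot(inherits(model, "wsosvm"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  d_model <- if (!is.null(model$w)) length(model$w) else ncol(model$SV)
  if (ncol(X) != d_model)
    stop("dimension mismatch: model expects d = ", d_model,
         ", got ", ncol(X))
  Xs <- apply_scaler(X, model$scaler)
  if (!is.null(model$w)) return(drop(Xs %*% model$w))
  drop(kernel_matrix(Xs, model$SV, model$kernel) %*% model$coef)
}

#' Classify samples into the ordinal classes 0/1/2
#'
#' @param model a fitted `wsosvm`.
#' @param X samples in rows (or one vector).
#' @return integer vector of classes: 2 if \eqn{h \ge b_1}, 1 if
#'   \eqn{b_0 \le h < b_1}, 0 if \eqn{h < b_0}.
#' @export
classify <- function(model, X) {
  h <- decision_value(model, X)
  ifelse(h >= model$b1, 2L, ifelse(h >= model$b0, 1L, 0L))
}

#' @param object a fitted `wsosvm`.
#' @param newdata samples in rows.
#' @param type `"class"` for ordinal labels, `"decision"` for \eqn{h(x)}.
#' @param ... unused.
#' @rdname classify
#' @export
predict.wsosvm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (type == "decision") decision_value(object, newdata)
  else classify(object, newdata)
}

#' Brute-force penalized-primal oracle
#'
#' Solves the penalized primal counterpart of the dual directly, with an
#' explicit weight vector (linear kernel only):
#' \deqn{\min_{w, b_0, b_1, \xi, \zeta} \tfrac12 \|w\|^2
#'   + C_1 \textstyle(\sum \xi^{(1)} + \sum \xi^{(2)})
#'   + C_2 (\sum \zeta^{(0)} + \sum \zeta^{(12)})}
#' subject to the labeled margin constraints on \eqn{b_1}, the normal /
#' class-12 margin constraints on \eqn{b_0} (labeled rows replicated into the
#' class-12 block), nonnegative slacks and \eqn{b_0 \le b_1}.  Strong duality
#' of the convex QP makes this an independent oracle for the dual path; it is
#' intended for small verification instances and refuses large ones.
#'
#' @inheritParams wsosvm_fit
#' @param max_n refuse instances with more than this many stacked samples.
#' @return a `wsosvm` model carrying the explicit `w`, `b0`, `b1` and the
#'   primal `objective`.
#' @export
primal_oracle_fit <- function(ts, C1 = 1, C2 = 1, max_n = 80) {
  stopifnot(inherits(ts, "wso_training_set"))
  bs <- block_sizes(ts)
  if (bs[["n1"]] == 0 || bs[["n2"]] == 0)
    stop("empty class block: both labeled blocks are required")
  ntot <- bs[["n1"]] + bs[["n2"]] + bs[["m0"]] + bs[["m12p"]]
  if (ntot > max_n)
    stop("primal oracle restricted to small instances (", ntot, " > ", max_n, ")")
  d <- ncol(ts$X1)
  n1 <- bs[["n1"]]; n2 <- bs[["n2"]]; m0 <- bs[["m0"]]; m12p <- bs[["m12p"]]
  X12p <- rbind(ts$X1, ts$X2, ts$X12)
  nv <- d + 2 + n1 + n2 + m0 + m12p  # w, b0, b1, slacks
  iw <- seq_len(d); ib0 <- d + 1; ib1 <- d + 2
  is1 <- d + 2 + seq_len(n1)
  is2 <- d + 2 + n1 + seq_len(n2)
  iz0 <- d + 2 + n1 + n2 + seq_len(m0)
  iz12 <- d + 2 + n1 + n2 + m0 + seq_len(m12p)
  eps <- 1e-10  # tiny diagonal so the (diagonal) factorization stays positive
  Dmat <- diag(c(rep(1, d), rep(eps, nv - d)))
  dvec <- rep(0, nv)
  dvec[c(is1, is2)] <- -C1
  dvec[c(iz0, iz12)] <- -C2
  rows <- list()
  add <- function(wpart, b0c, b1c, slack_i) {
    r <- rep(0, nv); r[iw] <- wpart; r[ib0] <- b0c; r[ib1] <- b1c
    r[slack_i] <- 1
    rows[[length(rows) + 1]] <<- r
  }
  for (i in seq_len(n1))  add(-ts$X1[i, ], 0, 1, is1[i])    # -w'x + b1 + xi >= 1
  for (i in seq_len(n2))  add(ts$X2[i, ], 0, -1, is2[i])    #  w'x - b1 + xi >= 1
  for (k in seq_len(m0))  add(-ts$X0[k, ], 1, 0, iz0[k])    # -w'x + b0 + zt >= 1
  for (j in seq_len(m12p)) add(X12p[j, ], -1, 0, iz12[j])   #  w'x - b0 + zt >= 1
  Aineq <- do.call(rbind, rows)
  slackpos <- diag(nv)[c(is1, is2, iz0, iz12), , drop = FALSE]
  order_row <- rep(0, nv); order_row[ib1] <- 1; order_row[ib0] <- -1
  Amat <- t(rbind(Aineq, slackpos, order_row))
  bvec <- c(rep(1, nrow(Aineq)), rep(0, nrow(slackpos)), 0)
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec)
  # The slack regularization biases the solver's point by ~1e-5 in flat
  # directions, far too coarse for oracle duty; polish to machine precision
  # with exact active-set KKT refinement of the unregularized problem
  # (D has curvature only on the w block).
  D0 <- diag(c(rep(1, d), rep(0, nv - d)))
  z <- refine_qp(sol$solution, D0, -dvec, t(Amat), bvec)
  # final direct descent on the slack-eliminated hinge objective mops up the
  # rare instance where the active-set refinement cycles out early
  hinge_obj <- function(p) {
    w <- p[seq_len(d)]; b1 <- p[d + 2]; b0 <- min(p[d + 1], b1)
    0.5 * sum(w^2) +
      C1 * (sum(pmax(0, drop(ts$X1 %*% w) - b1 + 1)) +
            sum(pmax(0, 1 - (drop(ts$X2 %*% w) - b1)))) +
      C2 * (sum(pmax(0, if (m0) drop(ts$X0 %*% w) - b0 + 1 else numeric(0))) +
            sum(pmax(0, 1 - (drop(X12p %*% w) - b0))))
  }
  p <- z[seq_len(d + 2)]
  if (d + 2 <= 12) {
    val <- hinge_obj(p)
    for (restart in 1:8) {
      op <- stats::optim(p, hinge_obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 20000))
      if (op$value >= val - 1e-13 * max(1, abs(val))) break
      p <- op$par; val <- op$value
    }
  }
  w <- p[seq_len(d)]
  b0 <- min(p[d + 1], p[d + 2]); b1 <- p[d + 2]
  slacks <- c(pmax(0, drop(ts$X1 %*% w) - b1 + 1),
              pmax(0, 1 - (drop(ts$X2 %*% w) - b1)),
              pmax(0, if (m0) drop(ts$X0 %*% w) - b0 + 1 else numeric(0)),
              pmax(0, 1 - (drop(X12p %*% w) - b0)))
  objective <- 0.5 * sum(w^2) +
    C1 * sum(slacks[seq_len(n1 + n2)]) +
    C2 * sum(slacks[n1 + n2 + seq_len(m0 + m12p)])
  structure(
    list(w = w, b0 = b0, b1 = b1,
         kernel = kernel_spec("linear"), scaler = NULL,
         C1 = C1, C2 = C2, sizes = bs, objective = objective,
         slacks = slacks, feature_names = colnames(ts$X1)),
    class = "wsosvm"
  )
}
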