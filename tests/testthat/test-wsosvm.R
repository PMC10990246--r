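test_that("dual assembly has the documented block structure", {
  ts <- training_set(X1 = matrix(0), X2 = matrix(1), X0 = matrix(-2))
  qp <- assemble_dual(ts, C1 = 1, C2 = 2, kernel_spec("linear"))
  # m12' = n1 + n2 + m12 bookkeeping: 1 + 1 + 1 + 2 = 5 variables
  expect_equal(length(qp$y), 5L)
  # block signs follow diag(-1^n1, 1^n2, -1^m0, 1^m12')
  expect_equal(qp$y, c(-1, 1, -1, 1, 1))
  expect_equal(qp$tvec, c(-1, 1, 0, 0, 0))
  expect_equal(qp$upper, c(1, 1, 2, 2, 2))
  # linear term of the dual is -1 per multiplier (solver maximizes +1'g)
  expect_equal(dim(qp$H), c(5L, 5L))
  expect_error(assemble_dual(training_set(matrix(numeric(0), 0, 1),
                                          matrix(1), X0 = matrix(0)),
                             1, 1, kernel_spec("linear")),
               "empty class block: X1")
})

test_that("quadratic matrix equals YKY elementwise on a hand-built instance", {
  # 3 distinct samples, no unlabeled, linear kernel: K is the outer product
  x1 <- c(1, 0); x2 <- c(0, 2); x0 <- c(-1, -1)
  ts <- training_set(X1 = matrix(x1, 1), X2 = matrix(x2, 1),
                     X0 = matrix(x0, 1))
  qp <- assemble_dual(ts, 1, 1, kernel_spec("linear", jitter = 0))
  X <- rbind(x1, x2, x0, x1, x2)
  y <- c(-1, 1, -1, 1, 1)
  H_hand <- (y %o% y) * (X %*% t(X))
  expect_equal(unname(qp$H), unname(H_hand))
})

test_that("the 1-D analytic instance recovers (w, b0, b1) = (1, -2, 0)", {
  ts <- training_set(X1 = matrix(-1), X2 = matrix(1), X0 = matrix(-3))
  fit <- wsosvm_fit(ts, C1 = 1e4, C2 = 1e4, kernel = kernel_spec("linear"),
                    scale = FALSE)
  w <- sum(fit$coef * fit$SV[, 1])
  expect_equal(w, 1, tolerance = 1e-4)
  expect_equal(fit$b1, 0, tolerance = 1e-4)
  expect_equal(fit$b0, -2, tolerance = 1e-4)
  # the oracle lands on the same point
  orc <- primal_oracle_fit(ts, 1e4, 1e4)
  expect_equal(orc$w, 1, tolerance = 1e-4)
  expect_equal(orc$b0, -2, tolerance = 1e-4)
  expect_equal(orc$b1, 0, tolerance = 1e-4)
})

test_that("dual path and penalized-primal oracle agree on random instances", {
  set.seed(42)
  for (r in 1:20) {
    inst <- random_small_instance()
    f <- wsosvm_fit(inst$ts, inst$C1, inst$C2, kernel_spec("linear"),
                    scale = FALSE)
    o <- primal_oracle_fit(inst$ts, inst$C1, inst$C2)
    gap <- o$objective + f$dual$objective
    expect_lt(abs(gap), 1e-6)
    expect_gt(gap, -1e-6)        # weak duality up to solver tolerance
    G <- matrix(rnorm(30 * inst$d), 30)
    expect_lt(max(abs(decision_value(f, G) - decision_value(o, G))), 1e-4)
  }
})

test_that("every solved instance is KKT-feasible with margin-consistent interior SVs", {
  set.seed(202)
  for (r in 1:10) {
    inst <- random_small_instance(d = 2)
    kern <- if (r %% 2) kernel_spec("linear") else kernel_spec("rbf", gamma = 0.5)
    qp <- assemble_dual(inst$ts, inst$C1, inst$C2, kern)
    sol <- solve_dual(qp)
    g <- sol$gamma
    expect_gte(min(g), 0)
    expect_lte(max(g - qp$upper), 0)
    expect_lt(abs(sol$eq_residual), 1e-6)
    expect_gt(sol$order_slack, -1e-6)
    b <- recover_biases(sol, qp)
    expect_lte(b$b0, b$b1)
    # complementary slackness: interior SVs sit on their margin
    h <- wsosvm:::dual_h_train(sol, qp)
    tau <- 1e-6 * max(inst$C1, inst$C2)
    interior <- g > tau & g < qp$upper - tau
    target <- rep(c(-1, 1, -1, 1),
                  c(qp$sizes[["n1"]], qp$sizes[["n2"]], qp$sizes[["m0"]],
                    qp$sizes[["m12p"]]))
    bias <- rep(c(b$b1, b$b1, b$b0, b$b0),
                c(qp$sizes[["n1"]], qp$sizes[["n2"]], qp$sizes[["m0"]],
                  qp$sizes[["m12p"]]))
    if (any(interior))
      expect_lt(max(abs(h[interior] - bias[interior] - target[interior])), 1e-4)
  }
})

test_that("with no normal and no unlabeled samples the b1 boundary matches a binary SVM", {
  skip_if_not_installed("e1071")
  set.seed(77)
  X1 <- matrix(rnorm(60), 30, 2)
  X2 <- matrix(rnorm(60, mean = 2.2), 30, 2)
  ts <- training_set(X1 = X1, X2 = X2)
  for (kern in list(kernel_spec("linear"), kernel_spec("rbf", gamma = 0.5))) {
    C <- 1
    f <- wsosvm_fit(ts, C1 = C, C2 = C, kernel = kern, scale = FALSE)
    sv <- e1071::svm(x = rbind(X1, X2),
                     y = factor(rep(c(1, 2), each = 30)),
                     kernel = if (kern$kind == "linear") "linear" else "radial",
                     gamma = if (kern$kind == "rbf") kern$gamma else 1,
                     cost = C, scale = FALSE)
    grid <- as.matrix(expand.grid(seq(-2, 4, length.out = 25),
                                  seq(-2, 4, length.out = 25)))
    ours <- ifelse(decision_value(f, grid) >= f$b1, 2, 1)
    theirs <- as.integer(as.character(predict(sv, grid)))
    expect_gte(mean(ours == theirs), 0.99)
  }
})

test_that("fitting is deterministic and separable cohorts are classified perfectly", {
  ts <- toy_training_set(n = 15, sep = 6, seed = 3)
  f1 <- wsosvm_fit(ts, 1, 1, kernel_spec("rbf"))
  f2 <- wsosvm_fit(ts, 1, 1, kernel_spec("rbf"))
  expect_identical(f1$coef, f2$coef)
  expect_identical(c(f1$b0, f1$b1), c(f2$b0, f2$b1))
  expect_equal(unname(classify(f1, ts$X1)), rep(1L, 15))
  expect_equal(unname(classify(f1, ts$X2)), rep(2L, 15))
  expect_equal(unname(classify(f1, ts$X0)), rep(0L, 15))
  pred12 <- classify(f1, ts$X12)
  expect_true(all(pred12 %in% c(1L, 2L)))
})

test_that("the decision rule is boundary-inclusive and ordinal-monotone", {
  model <- structure(list(w = 1, b0 = -2, b1 = 0,
                          kernel = kernel_spec("linear"), scaler = NULL),
                     class = "wsosvm")
  expect_equal(unname(classify(model, matrix(c(0.5, -1, -2.5)))), c(2L, 1L, 0L))
  expect_equal(unname(classify(model, matrix(0))), 2L)    # h == b1 -> class 2
  expect_equal(unname(classify(model, matrix(-2))), 1L)   # h == b0 -> class 1
  h_seq <- seq(-4, 2, by = 0.1)
  cls <- classify(model, matrix(h_seq))
  expect_true(all(diff(cls) >= 0))
})

test_that("zero multipliers give h identically 0 and dimension mismatches error", {
  model <- structure(list(SV = matrix(0, 1, 2), coef = 0,
                          b0 = -1, b1 = 1, kernel = kernel_spec("rbf", gamma = 1),
                          scaler = NULL), class = "wsosvm")
  expect_equal(decision_value(model, matrix(rnorm(10), 5)), rep(0, 5))
  expect_error(decision_value(model, matrix(1, 1, 3)), "dimension mismatch")
})

test_that("h from the kernel expansion equals the explicit linear w", {
  set.seed(10)
  inst <- random_small_instance(d = 3)
  f <- wsosvm_fit(inst$ts, inst$C1, inst$C2, kernel_spec("linear"),
                  scale = FALSE)
  w <- colSums(f$coef * f$SV)
  G <- matrix(rnorm(60), 20)
  expect_equal(decision_value(f, G), drop(G %*% w), tolerance = 1e-10)
})

test_that("rbf decision values obey the kernel Lipschitz bound", {
  ts <- toy_training_set(n = 8, sep = 4, seed = 5)
  f <- wsosvm_fit(ts, 1, 1, kernel_spec("rbf", gamma = 0.7), scale = FALSE)
  # |h(x)-h(x')| <= sum|coef| * sqrt(2 gamma) * ||x - x'|| for the rbf kernel
  L <- sum(abs(f$coef)) * sqrt(2 * 0.7)
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(2); dx <- rnorm(2, sd = 0.05)
    dh <- abs(decision_value(f, x + dx) - decision_value(f, x))
    expect_lte(dh, L * sqrt(sum(dx^2)) + 1e-12)
  }
})

test_that("degenerate all-identical data still yields a feasible fit", {
  ts <- training_set(X1 = matrix(1, 3, 2), X2 = matrix(1, 3, 2),
                     X0 = matrix(1, 2, 2))
  f <- wsosvm_fit(ts, 1, 1, kernel_spec("rbf", gamma = 1), scale = FALSE)
  expect_true(is.finite(f$b0) && is.finite(f$b1))
  expect_lte(f$b0, f$b1)
  expect_true(all(classify(f, matrix(1, 2, 2)) %in% 0:2))
})

test_that("unlabeled points between classes pull b0 down, never past the labeled margin", {
  # 1-D construction: class 0 far left, labeled at -1/+1; unlabeled mass in
  # between can only move the tumor-vs-normal boundary toward class 0
  base <- training_set(X1 = matrix(c(-1, -1.2), 2), X2 = matrix(c(1, 1.2), 2),
                       X0 = matrix(c(-5, -5.5), 2))
  with12 <- training_set(X1 = base$X1, X2 = base$X2, X0 = base$X0,
                         X12 = matrix(c(-2.5, -3), 2))
  f0 <- wsosvm_fit(base, 10, 10, kernel_spec("linear"), scale = FALSE)
  f1 <- wsosvm_fit(with12, 10, 10, kernel_spec("linear"), scale = FALSE)
  expect_lte(f1$b0, f0$b0 + 1e-6)
  expect_lte(f1$b0, f1$b1)
  # oracle sees the same direction
  o0 <- primal_oracle_fit(base, 10, 10)
  o1 <- primal_oracle_fit(with12, 10, 10)
  expect_lte(o1$b0, o0$b0 + 1e-6)
})

test_that("the primal oracle refuses oversized instances", {
  big <- toy_training_set(n = 40, seed = 2)
  expect_error(primal_oracle_fit(big, 1, 1, max_n = 80), "small instances")
})
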