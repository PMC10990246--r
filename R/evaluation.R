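#' Cross-validation fold assignment
#'
#' Stratified (default) partition of labeled samples into `k` folds,
#' deterministic under `seed`.  With `group` set, all samples of a group
#' (e.g. one patient's biopsies) go to the same fold, balancing fold sizes
#' greedily; stratification then applies only approximately.
#'
#' @param y class labels (any type coercible to factor).
#' @param k number of folds (>= 2).
#' @param stratified keep class proportions per fold.
#' @param group optional grouping vector (same length as `y`).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k = 10L, stratified = TRUE, group = NULL,
                       seed = 1L) {
  n <- length(y)
  if (n < k) stop("need at least k = ", k, " samples, got ", n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- integer(n)
  if (!is.null(group)) {
    sizes <- table(group)
    ord <- sample(names(sizes))                 # random tie-breaking
    ord <- ord[order(-sizes[ord])]              # largest groups first
    load <- numeric(k)
    gf <- stats::setNames(integer(length(ord)), ord)
    for (g in ord) {
      f <- which.min(load)
      gf[g] <- f
      load[f] <- load[f] + sizes[[g]]
    }
    fold <- gf[as.character(group)]
    names(fold) <- NULL
    return(fold)
  }
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k)
        warning("class ", cls, " has fewer members (", length(idx),
                ") than folds (", k, "); stratification is best-effort")
      fold[idx] <- (sample(length(idx)) %% k) + 1L
    }
  } else {
    fold <- (sample(n) %% k) + 1L
  }
  fold
}

#' Draw auxiliary unlabeled-tumoral and normal samples
#'
#' Applies the auxiliary sampling rule: the unlabeled tumoral draw and the
#' normal-brain draw are equal-sized and together match the labeled count
#' (`n12 = ceiling(n_labeled/2)`, `n0 = floor(n_labeled/2)`; the odd one
#' goes to the tumoral side).  The tumoral draw is split equally between the
#' CE and NE compartments when compartment tags are available (odd counts
#' favor CE).  Requests larger than a pool are truncated with a warning.
#'
#' @param pool12 matrix of unlabeled-tumoral candidates.
#' @param pool0 matrix of normal-brain candidates.
#' @param n_labeled labeled-sample count the joint draw must match.
#' @param compartment optional `"CE"`/`"NE"` tags for `pool12` rows.
#' @param seed integer seed.
#' @return list with matrices `X12`, `X0` and the drawn row indices
#'   `idx12`, `idx0`.
#' @export
sample_auxiliary <- function(pool12, pool0, n_labeled, compartment = NULL,
                             seed = 1L) {
  pool12 <- as.matrix(pool12); pool0 <- as.matrix(pool0)
  if (nrow(pool12) == 0 || nrow(pool0) == 0)
    stop("auxiliary pools must be non-empty")
  n12 <- ceiling(n_labeled / 2)
  n0 <- floor(n_labeled / 2)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  take <- function(pool_idx, m, what) {
    if (m > length(pool_idx)) {
      warning("requested ", m, " ", what, " samples but pool has only ",
              length(pool_idx), "; sampling the whole pool")
      m <- length(pool_idx)
    }
    pool_idx[sample.int(length(pool_idx), m)]
  }
  if (!is.null(compartment)) {
    nce <- ceiling(n12 / 2); nne <- n12 - nce
    idx12 <- c(take(which(compartment == "CE"), nce, "CE"),
               take(which(compartment == "NE"), nne, "NE"))
  } else {
    idx12 <- take(seq_len(nrow(pool12)), n12, "unlabeled tumoral")
  }
  idx0 <- take(seq_len(nrow(pool0)), n0, "normal")
  list(X12 = pool12[idx12, , drop = FALSE],
       X0 = pool0[idx0, , drop = FALSE],
       idx12 = idx12, idx0 = idx0)
}

#' Accuracy, sensitivity and specificity on labeled predictions
#'
#' Metrics are defined on the labeled tumoral classes with class 2 (altered)
#' as the positive class.  Predictions of class 0 on labeled samples are
#' errors against their true class for accuracy, and count as negative-side
#' calls for sensitivity/specificity.  Undefined metrics (empty positive or
#' negative truth set) are returned as `NA`, never as 0.
#'
#' @param truth true labels in `{1, 2}`.
#' @param pred predicted classes in `{0, 1, 2}`.
#' @return list with `accuracy`, `sensitivity`, `specificity` and the 2x3
#'   `confusion` matrix (rows: truth 1..2, columns: predicted 0..2).
#' @export
compute_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), all(truth %in% c(1, 2)))
  conf <- table(factor(truth, levels = 1:2), factor(pred, levels = 0:2))
  conf <- unclass(conf)
  dimnames(conf) <- list(truth = c("1", "2"), pred = c("0", "1", "2"))
  n1 <- sum(conf["1", ]); n2 <- sum(conf["2", ])
  acc <- (conf["1", "1"] + conf["2", "2"]) / (n1 + n2)
  sens <- if (n2 > 0) conf["2", "2"] / n2 else NA_real_
  spec <- if (n1 > 0) (conf["1", "0"] + conf["1", "1"]) / n1 else NA_real_
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       confusion = conf)
}

# internal: fit on training labeled blocks + freshly drawn auxiliaries and
# predict the held-out labeled samples (plus optional screening samples)
cv_fold_eval <- function(Xl, yl, train_idx, test_idx, pool12, pool0,
                         compartment, C1, C2, kernel, scale, seed,
                         screening = TRUE) {
  aux <- sample_auxiliary(pool12, pool0, length(train_idx),
                          compartment = compartment, seed = seed)
  ts <- training_set(X1 = Xl[train_idx[yl[train_idx] == 1], , drop = FALSE],
                     X2 = Xl[train_idx[yl[train_idx] == 2], , drop = FALSE],
                     X12 = aux$X12, X0 = aux$X0)
  fit <- wsosvm_fit(ts, C1 = C1, C2 = C2, kernel = kernel, scale = scale)
  pred <- classify(fit, Xl[test_idx, , drop = FALSE])
  out <- list(truth = yl[test_idx], pred = pred)
  if (screening) {
    # tumor-vs-normal screen on held-out labeled + a held-out auxiliary draw
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed + 499L)
    remaining12 <- setdiff(seq_len(nrow(pool12)), aux$idx12)
    remaining0 <- setdiff(seq_len(nrow(pool0)), aux$idx0)
    n_scr <- length(test_idx)
    s12 <- if (length(remaining12))
      remaining12[sample.int(length(remaining12),
                             min(ceiling(n_scr / 2), length(remaining12)))]
      else integer(0)
    s0 <- if (length(remaining0))
      remaining0[sample.int(length(remaining0),
                            min(floor(n_scr / 2) + 1, length(remaining0)))]
      else integer(0)
    scr_X <- rbind(Xl[test_idx, , drop = FALSE],
                   pool12[s12, , drop = FALSE], pool0[s0, , drop = FALSE])
    scr_tumor <- rep(c(TRUE, TRUE, FALSE),
                     c(length(test_idx), length(s12), length(s0)))
    scr_pred <- classify(fit, scr_X) > 0L
    out$screen_correct <- sum(scr_pred == scr_tumor)
    out$screen_total <- length(scr_tumor)
  }
  out
}

#' Repeated stratified cross-validation
#'
#' Repeats `n_repeats` times: split the labeled biopsy samples into
#' `n_folds` stratified folds, and per fold train on the remaining labeled
#' folds plus freshly drawn auxiliary samples (equal CE/NE unlabeled counts,
#' unlabeled + normal total matching the labeled training count) and predict
#' the held-out fold.  Reports per-repeat accuracy/sensitivity/specificity
#' and their mean and SD across repeats, plus the tumor-vs-normal screening
#' accuracy used by the first tuning stage.
#'
#' @param ts a [training_set()] whose `X12`/`X0` blocks act as the auxiliary
#'   pools.
#' @param C1,C2 hyperparameters.
#' @param kernel a [kernel_spec()].
#' @param n_folds,n_repeats cross-validation layout (defaults 10 x 30).
#' @param stratified stratify folds by class.
#' @param group_by_patient keep each patient's biopsies in one fold
#'   (requires patient ids in `ts`).
#' @param scale passed to [wsosvm_fit()].
#' @param seed integer seed; repeat `r` derives its seed as `seed + r - 1`.
#' @return an object of class `wso_cv_report`.
#' @export
repeated_cv <- function(ts, C1 = 1, C2 = 1, kernel = kernel_spec("rbf"),
                        n_folds = 10L, n_repeats = 30L, stratified = TRUE,
                        group_by_patient = FALSE, scale = TRUE, seed = 1L) {
  stopifnot(inherits(ts, "wso_training_set"), n_folds >= 2)
  lab <- labeled_block(ts)
  if (nrow(ts$X12) == 0 || nrow(ts$X0) == 0)
    stop("repeated_cv needs non-empty X12 and X0 pools for auxiliary draws")
  group <- if (group_by_patient) {
    if (is.null(lab$patient)) stop("group_by_patient needs patient ids")
    lab$patient
  } else NULL
  reps <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rs <- seed + r - 1L
    fold <- make_folds(lab$y, k = n_folds, stratified = stratified,
                       group = group, seed = rs)
    truth <- integer(0); pred <- integer(0)
    scr_c <- 0L; scr_t <- 0L
    for (f in sort(unique(fold))) {
      res <- cv_fold_eval(lab$X, lab$y,
                          train_idx = which(fold != f),
                          test_idx = which(fold == f),
                          pool12 = ts$X12, pool0 = ts$X0,
                          compartment = ts$compartment12,
                          C1 = C1, C2 = C2, kernel = kernel, scale = scale,
                          seed = (rs %% 2000000L) * 1000L + f)
      truth <- c(truth, res$truth); pred <- c(pred, res$pred)
      scr_c <- scr_c + res$screen_correct; scr_t <- scr_t + res$screen_total
    }
    m <- compute_metrics(truth, pred)
    reps[[r]] <- data.frame(repeat_id = r, accuracy = m$accuracy,
                            sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            screening_accuracy = scr_c / scr_t)
  }
  per_repeat <- do.call(rbind, reps)
  metrics <- c("accuracy", "sensitivity", "specificity", "screening_accuracy")
  structure(
    list(per_repeat = per_repeat,
         mean = vapply(per_repeat[metrics], mean, numeric(1), na.rm = TRUE),
         sd = vapply(per_repeat[metrics], stats::sd, numeric(1), na.rm = TRUE),
         C1 = C1, C2 = C2, n_folds = n_folds, n_repeats = n_repeats,
         seed = seed),
    class = "wso_cv_report"
  )
}

#' @export
print.wso_cv_report <- function(x, ...) {
  cat("Repeated cross-validation: ", x$n_folds, " folds x ", x$n_repeats,
      " repeats  (C1 = ", x$C1, ", C2 = ", x$C2, ")\n", sep = "")
  for (m in names(x$mean))
    cat(sprintf("  %-20s %.3f (%.3f)\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Two-stage hyperparameter tuning
#'
#' Stage 1 screens `C2` on a coarse grid: settings whose cross-validated
#' tumor-vs-normal (class 1/2 vs class 0) accuracy exceeds
#' `screen_threshold` are retained (all grids evaluated at `C1 =
#' C1_screen`).  Stage 2 grids `C1` finely under each retained `C2` and
#' picks the pair maximizing labeled class-1-vs-2 CV accuracy; ties break
#' toward smaller `C1`, then smaller `C2`.  If no setting passes the
#' screen, the best-screening `C2` is used with a warning.
#'
#' @param ts a [training_set()] with auxiliary pools.
#' @param C2_grid coarse grid (default `0.01, 0.1, 1, 10, 100`).
#' @param C1_grid fine grid (default 20 log-spaced points in `[0.01, 100]`).
#' @param screen_threshold screening accuracy required of a `C2` setting.
#' @param C1_screen the `C1` used during stage-1 screening.
#' @param n_folds,n_repeats CV layout used inside tuning (repeats default to
#'   1 here; the final model is re-evaluated with the full repeated CV).
#' @param kernel,scale,seed as in [repeated_cv()].
#' @return list with the chosen `C1`, `C2`, the stage-1 `screen_trace`
#'   (data frame over the coarse grid) and stage-2 `selection_trace`.
#' @export
tune_wsosvm <- function(ts, C2_grid = c(0.01, 0.1, 1, 10, 100),
                        C1_grid = 10^seq(-2, 2, length.out = 20),
                        screen_threshold = 0.8, C1_screen = 1,
                        n_folds = 10L, n_repeats = 1L,
                        kernel = kernel_spec("rbf"), scale = TRUE,
                        seed = 1L) {
  C2_grid <- sort(C2_grid); C1_grid <- sort(C1_grid)
  screen <- vapply(C2_grid, function(C2) {
    rep <- repeated_cv(ts, C1 = C1_screen, C2 = C2, kernel = kernel,
                       n_folds = n_folds, n_repeats = n_repeats,
                       scale = scale, seed = seed)
    rep$mean[["screening_accuracy"]]
  }, numeric(1))
  screen_trace <- data.frame(C2 = C2_grid, screening_accuracy = screen,
                             kept = screen > screen_threshold)
  kept <- C2_grid[screen_trace$kept]
  if (!length(kept)) {
    warning("no C2 setting passed the ", screen_threshold,
            " screening accuracy; falling back to the best-screening C2")
    kept <- C2_grid[which.max(screen)]
  }
  sel <- do.call(rbind, lapply(kept, function(C2) {
    acc <- vapply(C1_grid, function(C1) {
      rep <- repeated_cv(ts, C1 = C1, C2 = C2, kernel = kernel,
                         n_folds = n_folds, n_repeats = n_repeats,
                         scale = scale, seed = seed)
      rep$mean[["accuracy"]]
    }, numeric(1))
    data.frame(C1 = C1_grid, C2 = C2, accuracy = acc)
  }))
  best_acc <- max(sel$accuracy)
  cand <- sel[sel$accuracy >= best_acc - 1e-12, , drop = FALSE]
  cand <- cand[order(cand$C1, cand$C2), , drop = FALSE]
  list(C1 = cand$C1[1], C2 = cand$C2[1],
       accuracy = cand$accuracy[1],
       screen_trace = screen_trace, selection_trace = sel)
}

#' One-sided Wilcoxon rank-sum test (alternative: a > b)
#'
#' Exact mode (combined n <= 12, or `exact = TRUE`) enumerates all
#' \eqn{\binom{n_a+n_b}{n_a}} assignments of the pooled observations using
#' midranks for ties and returns \eqn{P(W \ge W_{obs})} for the rank sum
#' \eqn{W} of `a`.  Larger samples use the normal approximation with tie
#' correction and continuity correction (via [stats::wilcox.test()]).
#'
#' @param a,b numeric vectors (e.g. per-repeat accuracies of two methods).
#' @param exact force or forbid the enumeration path (`NULL` = auto).
#' @return list with `p.value`, the rank-sum `statistic` of `a`, and
#'   `method`.
#' @export
wilcoxon_one_sided <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("both series must be non-empty")
  n <- length(a) + length(b)
  if (is.null(exact)) exact <- n <= 12
  pooled <- c(a, b)
  rk <- rank(pooled)                        # midranks under ties
  W <- sum(rk[seq_along(a)])
  if (exact) {
    if (choose(n, length(a)) > 5e6)
      stop("exact enumeration infeasible for these sample sizes")
    combos <- utils::combn(n, length(a))
    sums <- colSums(matrix(rk[combos], nrow = length(a)))
    p <- mean(sums >= W - 1e-9)
    return(list(p.value = p, statistic = W, method = "exact enumeration"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "greater", exact = FALSE))
  list(p.value = wt$p.value, statistic = W,
       method = "normal approximation with tie correction")
}
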