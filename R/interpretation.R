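#' Shapley-value attribution of decision values
#'
#' Attributes the continuous decision value \eqn{h(x)} (not the discrete
#' class — \eqn{h} is the model's ordinal evidence) to input features.
#' Feature "absence" means replacement by background values.  Two estimation
#' paths:
#'
#' * exact enumeration (automatic for `d <= 12`): value of a coalition `S`
#'   is the mean of \eqn{h} over hybrids taking `x` on `S` and each
#'   background row elsewhere; Shapley values use the exact subset weights;
#' * permutation sampling: for each of `n_permutations` random feature
#'   orders paired with a sampled background row, features are switched from
#'   background to `x` one at a time and marginal changes accumulated.  The
#'   telescoping sum makes local accuracy exact:
#'   \eqn{\sum_f \phi_f + \mathrm{baseline} = h(x)} for every sample.
#'
#' @param model a fitted `wsosvm`.
#' @param X samples to explain (rows).
#' @param background background sample matrix (subsampled to
#'   `max_background` rows).
#' @param n_permutations permutation draws in the sampling path.
#' @param exact force/forbid the enumeration path (`NULL` = auto).
#' @param max_background cap on background rows used.
#' @param seed integer seed for permutation and background draws.
#' @return an object of class `wso_shap_report`: matrix `phi`
#'   (samples x features), `baseline` per sample, `h` per sample, and the
#'   configuration.
#' @export
shapley_values <- function(model, X, background, n_permutations = 64L,
                           exact = NULL, max_background = 100L, seed = 1L) {
  stopifnot(inherits(model, "wsosvm"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X); background <- as.matrix(background)
  if (nrow(background) == 0) stop("background set must be non-empty")
  d <- ncol(X)
  if (is.null(exact)) exact <- d <= 12
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (nrow(background) > max_background)
    background <- background[sample.int(nrow(background), max_background), ,
                             drop = FALSE]
  B <- nrow(background)
  phi <- matrix(0, nrow(X), d,
                dimnames = list(NULL, colnames(X)))
  if (exact) {
    subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
    wts <- vapply(0:(d - 1), function(s)
      factorial(s) * factorial(d - s - 1) / factorial(d), numeric(1))
    baseline <- rep(mean(decision_value(model, background)), nrow(X))
    for (i in seq_len(nrow(X))) {
      # v(S) = mean over background rows of h(x_S, b_notS)
      v <- vapply(seq_len(nrow(subsets)), function(si) {
        S <- subsets[si, ]
        hyb <- background
        hyb[, S] <- matrix(X[i, S], B, sum(S), byrow = TRUE)
        mean(decision_value(model, hyb))
      }, numeric(1))
      key <- subsets %*% 2^(seq_len(d) - 1)
      for (f in seq_len(d)) {
        no_f <- !subsets[, f]
        sz <- rowSums(subsets[no_f, , drop = FALSE])
        v_wo <- v[no_f]
        v_w <- v[match(key[no_f] + 2^(f - 1), key)]
        phi[i, f] <- sum(wts[sz + 1] * (v_w - v_wo))
      }
    }
  } else {
    P <- n_permutations
    perms <- replicate(P, sample.int(d), simplify = FALSE)
    brows <- sample.int(B, P, replace = TRUE)
    baseline_vals <- decision_value(model, background[brows, , drop = FALSE])
    for (i in seq_len(nrow(X))) {
      contrib <- matrix(0, P, d)
      for (p in seq_len(P)) {
        z <- background[brows[p], ]
        hybrids <- matrix(z, d + 1, d, byrow = TRUE)
        acc <- z
        for (k in seq_len(d)) {
          acc[perms[[p]][k]] <- X[i, perms[[p]][k]]
          hybrids[k + 1, ] <- acc
        }
        hv <- decision_value(model, hybrids)
        contrib[p, perms[[p]]] <- diff(hv)
      }
      phi[i, ] <- colMeans(contrib)
    }
    baseline <- rep(mean(baseline_vals), nrow(X))
  }
  structure(
    list(phi = phi, baseline = baseline,
         h = decision_value(model, X),
         exact = exact, n_permutations = if (exact) NA_integer_
                        else as.integer(n_permutations),
         n_background = B, seed = seed),
    class = "wso_shap_report"
  )
}

#' Aggregate Shapley values to the MRI-contrast level
#'
#' The contrast score is the mean over samples of the summed absolute
#' per-feature Shapley values within the contrast's feature group —
#' the total (unsigned) contribution of that contrast image to the decision
#' values.
#'
#' @param report a [shapley_values()] report.
#' @param contrast_index named list partitioning feature positions by
#'   contrast (as produced by [build_feature_matrix()]).
#' @return named numeric vector of per-contrast scores, in the order of
#'   `contrast_index`.
#' @export
aggregate_by_contrast <- function(report, contrast_index) {
  stopifnot(inherits(report, "wso_shap_report"))
  pos <- sort(unlist(contrast_index))
  if (!identical(as.integer(pos), seq_len(ncol(report$phi))))
    stop("contrast_index must partition all ", ncol(report$phi),
         " feature positions")
  vapply(contrast_index, function(ix)
    mean(rowSums(abs(report$phi[, ix, drop = FALSE]))), numeric(1))
}
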