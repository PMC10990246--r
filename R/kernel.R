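#' Kernel specification
#'
#' Describes the kernel function \eqn{k(\cdot,\cdot)} that implicitly maps
#' feature vectors into a reproducing kernel Hilbert space.  The default is a
#' Gaussian radial basis kernel whose bandwidth, when left `NULL`, is resolved
#' at fit time by the heuristic \eqn{\gamma = 1 / (d \cdot \mathrm{median
#' feature variance})} computed on the full training block (labeled, unlabeled
#' and normal samples together).
#'
#' @param kind one of `"rbf"`, `"linear"`, `"polynomial"`.
#' @param gamma bandwidth of the rbf kernel, \eqn{k(x,z) = \exp(-\gamma \|x-z\|^2)}.
#'   `NULL` means "resolve from the training data".
#' @param degree,coef0 polynomial kernel parameters, \eqn{(x^\top z + c_0)^p}.
#' @param jitter magnitude of the diagonal regularization added to Gram
#'   matrices for solver stability.
#' @return an object of class `wso_kernel`.
#' @examples
#' k <- kernel_spec("rbf", gamma = 0.5)
#' kernel_eval(c(0, 0), c(1, 1), k)
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial"),
                        gamma = NULL, degree = 3, coef0 = 1,
                        jitter = 1e-8) {
  kind <- match.arg(kind)
  if (!is.null(gamma) && (!is.numeric(gamma) || gamma <= 0))
    stop("rbf bandwidth 'gamma' must be a positive number")
  if (jitter < 0) stop("'jitter' must be >= 0")
  structure(
    list(kind = kind, gamma = gamma, degree = degree, coef0 = coef0,
         jitter = jitter),
    class = "wso_kernel"
  )
}

#' @export
print.wso_kernel <- function(x, ...) {
  cat("<wso_kernel>", x$kind)
  if (x$kind == "rbf")
    cat("  gamma =", if (is.null(x$gamma)) "(resolved at fit)" else x$gamma)
  if (x$kind == "polynomial")
    cat("  degree =", x$degree, " coef0 =", x$coef0)
  cat("  jitter =", x$jitter, "\n")
  invisible(x)
}

#' Resolve the rbf bandwidth from training data
#'
#' Applies the default heuristic \eqn{\gamma = 1/(d \cdot \mathrm{median}_f
#' \mathrm{Var}(x_f))}; degenerate (zero-variance) data fall back to
#' \eqn{\gamma = 1/d}.
#'
#' @param spec a [kernel_spec()].
#' @param X numeric matrix of training rows used for the heuristic.
#' @return a `wso_kernel` with a concrete `gamma`.
#' @export
resolve_kernel <- function(spec, X) {
  stopifnot(inherits(spec, "wso_kernel"))
  if (spec$kind != "rbf" || !is.null(spec$gamma)) return(spec)
  X <- as.matrix(X)
  v <- stats::median(apply(X, 2, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1
  spec$gamma <- 1 / (ncol(X) * v)
  spec
}

#' Evaluate the kernel on a pair of vectors
#'
#' @param x,z numeric vectors of equal length.
#' @param spec a [kernel_spec()]; an rbf spec must carry a concrete `gamma`.
#' @return a scalar, symmetric in `x` and `z`; rbf values lie in (0, 1].
#' @export
kernel_eval <- function(x, z, spec) {
  if (length(x) != length(z))
    stop("kernel_eval: dimension mismatch (", length(x), " vs ", length(z), ")")
  drop(kernel_matrix(matrix(x, 1), matrix(z, 1), spec))
}

#' Kernel (Gram or cross-kernel) matrix
#'
#' With `Z = NULL` returns the Gram matrix of `X` with `jitter` added to the
#' diagonal; otherwise the rectangular kernel matrix between the rows of `X`
#' and the rows of `Z` (no jitter).
#'
#' @param X,Z numeric matrices, samples in rows.
#' @param spec a [kernel_spec()].
#' @return a `nrow(X) x nrow(Z)` matrix.
#' @export
kernel_matrix <- function(X, Z = NULL, spec) {
  stopifnot(inherits(spec, "wso_kernel"))
  X <- as.matrix(X)
  gram <- is.null(Z)
  Z <- if (gram) X else as.matrix(Z)
  if (ncol(X) != ncol(Z))
    stop("kernel_matrix: dimension mismatch (", ncol(X), " vs ", ncol(Z), ")")
  lin <- X %*% t(Z)
  K <- switch(spec$kind,
    linear = lin,
    polynomial = (lin + spec$coef0)^spec$degree,
    rbf = {
      if (is.null(spec$gamma))
        stop("rbf kernel has no bandwidth; call resolve_kernel() first")
      d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * lin
      d2[d2 < 0] <- 0
      exp(-spec$gamma * d2)
    }
  )
  if (gram) {
    K <- (K + t(K)) / 2
    K <- K + diag(spec$jitter, nrow(K))
  }
  K
}

# --- per-feature standardization -------------------------------------------

# Kernel methods need comparable feature scales; the scaler is fitted on all
# training samples (labeled + unlabeled + normal) and stored in the model.
fit_scaler <- function(X) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(as.matrix(X))
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}
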