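#' Three-source training set
#'
#' The container consumed by the ordinal classifier.  It holds the four sample
#' blocks: `X1`, labeled tumoral samples with the gene non-altered (class 1);
#' `X2`, labeled samples with the gene altered (class 2); `X12`, unlabeled
#' tumoral samples known only to belong to class 1-or-2; and `X0`,
#' normal-brain samples (class 0).  During optimization the labeled blocks are
#' additionally replicated into the class-12 constraint block, so the
#' effective class-12 size is \eqn{m_{12}' = n_1 + n_2 + m_{12}}.
#'
#' @param X1,X2 numeric matrices (rows = samples) of labeled class-1 and
#'   class-2 feature vectors.  Both must be non-empty to define the upper
#'   boundary.
#' @param X12 optional matrix of unlabeled tumoral samples (may have 0 rows).
#' @param X0 optional matrix of normal-brain samples (may have 0 rows).
#' @param patient optional list with elements `X1`, `X2`, `X12`, `X0` giving
#'   per-row patient identifiers (used by patient-grouped cross-validation).
#' @param compartment12 optional character/factor of length `nrow(X12)` with
#'   values `"CE"`/`"NE"` tagging which tumor compartment each unlabeled
#'   sample came from (drives the equal CE/NE auxiliary sampling rule).
#' @param feature_names optional character vector of column names.
#' @return an object of class `wso_training_set`.
#' @examples
#' ts <- training_set(X1 = matrix(rnorm(10), 5), X2 = matrix(rnorm(10) + 3, 5))
#' ts
#' @export
training_set <- function(X1, X2, X12 = NULL, X0 = NULL,
                         patient = NULL, compartment12 = NULL,
                         feature_names = NULL) {
  as_block <- function(X, d) {
    if (is.null(X)) X <- matrix(numeric(0), 0, d)
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    X
  }
  X1 <- as_block(X1, 0); d <- ncol(X1)
  X2 <- as_block(X2, d); X12 <- as_block(X12, d); X0 <- as_block(X0, d)
  for (nm in c("X2", "X12", "X0")) {
    B <- get(nm)
    if (nrow(B) > 0 && ncol(B) != d)
      stop("block ", nm, " has dimension ", ncol(B), ", expected ", d)
  }
  if (!is.null(compartment12)) {
    compartment12 <- as.character(compartment12)
    if (length(compartment12) != nrow(X12))
      stop("compartment12 must have one entry per row of X12")
    if (!all(compartment12 %in% c("CE", "NE")))
      stop("compartment12 values must be 'CE' or 'NE'")
  }
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == d)
    colnames(X1) <- colnames(X2) <- feature_names
    if (nrow(X12)) colnames(X12) <- feature_names
    if (nrow(X0)) colnames(X0) <- feature_names
  }
  structure(
    list(X1 = X1, X2 = X2, X12 = X12, X0 = X0,
         patient = patient, compartment12 = compartment12),
    class = "wso_training_set"
  )
}

#' @export
print.wso_training_set <- function(x, ...) {
  cat("<wso_training_set>  d =", ncol(x$X1), "\n")
  cat("  labeled class 1 (non-altered):", nrow(x$X1), "\n")
  cat("  labeled class 2 (altered):    ", nrow(x$X2), "\n")
  cat("  unlabeled tumoral (class 1/2):", nrow(x$X12), "\n")
  cat("  normal brain (class 0):       ", nrow(x$X0), "\n")
  invisible(x)
}

#' Block sizes of a training set
#'
#' @param ts a [training_set()].
#' @return named integer vector with `n1`, `n2`, `m12`, `m0` and the effective
#'   class-12 block size `m12p` \eqn{= n_1+n_2+m_{12}}.
#' @export
block_sizes <- function(ts) {
  stopifnot(inherits(ts, "wso_training_set"))
  n1 <- nrow(ts$X1); n2 <- nrow(ts$X2)
  m12 <- nrow(ts$X12); m0 <- nrow(ts$X0)
  c(n1 = n1, n2 = n2, m12 = m12, m0 = m0, m12p = n1 + n2 + m12)
}

# stacked labeled block + labels (1/2), used by CV and tuning
labeled_block <- function(ts) {
  list(X = rbind(ts$X1, ts$X2),
       y = rep(c(1L, 2L), c(nrow(ts$X1), nrow(ts$X2))),
       patient = c(ts$patient$X1, ts$patient$X2))
}
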