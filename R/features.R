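#' Radiomic feature bank configuration
#'
#' Defines the per-contrast feature bank applied to each image window.  The
#' default bank emits exactly 56 features per contrast — 8 statistical,
#' 20 gray-level co-occurrence (5 Haralick statistics x 4 offset angles at
#' distance 1) and 28 Gabor (14 filters x response-magnitude mean and SD,
#' with 14 = 4 orientations x 3 frequencies + 2 extra low-frequency
#' filters) — for a total of 280 over the five MRI contrasts.  The bank is a
#' configuration, recorded in model metadata, so alternative compositions can
#' be swapped in.
#'
#' @param statistics character vector of statistical features; any of
#'   `"mean"`, `"sd"`, `"skewness"`, `"kurtosis"`, `"min"`, `"max"`,
#'   `"median"`, `"iqr"`.
#' @param glcm_levels gray levels for window quantization (min-max scaling).
#' @param glcm_offsets list of integer `(drow, dcol)` offsets; the default is
#'   the four distance-1 angles 0, 45, 90, 135 degrees.
#' @param glcm_stats Haralick statistics to compute per offset; any of
#'   `"contrast"`, `"correlation"`, `"energy"`, `"homogeneity"`, `"entropy"`.
#' @param glcm_average average the statistics over offsets (collapses the
#'   GLCM block to `length(glcm_stats)` features) instead of reporting them
#'   per offset.
#' @param gabor_frequencies,gabor_orientations cycles/pixel and degrees of
#'   the main Gabor grid.
#' @param gabor_extra list of extra `(frequency, orientation)` pairs appended
#'   to the grid.
#' @param gabor_kernel_size odd side length of the filter support in pixels.
#' @param window window side length in pixels (even; the window centered at
#'   `(r, c)` spans the half-open pixel range `[r-window/2, r+window/2)` per
#'   axis, 0-based).
#' @return an object of class `wso_feature_bank`.
#' @export
feature_bank_config <- function(statistics = c("mean", "sd", "skewness",
                                               "kurtosis", "min", "max",
                                               "median", "iqr"),
                                glcm_levels = 32,
                                glcm_offsets = list(c(0L, 1L), c(-1L, 1L),
                                                    c(-1L, 0L), c(-1L, -1L)),
                                glcm_stats = c("contrast", "correlation",
                                               "energy", "homogeneity",
                                               "entropy"),
                                glcm_average = FALSE,
                                gabor_frequencies = c(0.15, 0.25, 0.4),
                                gabor_orientations = c(0, 45, 90, 135),
                                gabor_extra = list(c(0.08, 0), c(0.08, 90)),
                                gabor_kernel_size = 7,
                                window = 8L) {
  stopifnot(glcm_levels >= 2, window >= 2, window %% 2 == 0,
            gabor_kernel_size %% 2 == 1)
  cfg <- structure(
    list(statistics = statistics, glcm_levels = as.integer(glcm_levels),
         glcm_offsets = glcm_offsets, glcm_stats = glcm_stats,
         glcm_average = glcm_average,
         gabor_frequencies = gabor_frequencies,
         gabor_orientations = gabor_orientations,
         gabor_extra = gabor_extra,
         gabor_kernel_size = as.integer(gabor_kernel_size),
         window = as.integer(window)),
    class = "wso_feature_bank"
  )
  cfg
}

#' Per-contrast dimension of a feature bank
#'
#' @param cfg a [feature_bank_config()].
#' @return integer count of features the bank emits per contrast.
#' @export
bank_dimension <- function(cfg) {
  n_glcm <- length(cfg$glcm_stats) *
    (if (cfg$glcm_average) 1L else length(cfg$glcm_offsets))
  n_gabor <- 2L * (length(cfg$gabor_frequencies) *
                     length(cfg$gabor_orientations) + length(cfg$gabor_extra))
  length(cfg$statistics) + n_glcm + n_gabor
}

#' Extract an image window
#'
#' The window of even side `size` "centered" at the 0-based pixel `(r, c)`
#' covers rows `[r - size/2, r + size/2)` and likewise for columns
#' (half-open, so an 8x8 window centered at (4,4) covers rows and columns
#' 0..7).  Windows crossing the image boundary are an error: padded texture
#' would be an artifact, so callers are expected to keep centers at least
#' `size/2` pixels inside.
#'
#' @param image numeric matrix.
#' @param center 0-based `(row, col)` integer pair.
#' @param size window side in pixels.
#' @return a `size x size` matrix.
#' @export
extract_window <- function(image, center, size = 8L) {
  r <- center[1]; cc <- center[2]; half <- size %/% 2
  r0 <- r - half; c0 <- cc - half
  if (r0 < 0 || c0 < 0 || r0 + size > nrow(image) || c0 + size > ncol(image))
    stop("window of size ", size, " centered at (", r, ",", cc,
         ") crosses the image boundary")
  image[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size), drop = FALSE]
}

#' Statistical features of a window
#'
#' First-order intensity statistics.  Moments use the population convention
#' (divide by n); skewness and excess kurtosis are defined as 0 for constant
#' windows (zero variance).
#'
#' @param patch numeric matrix (or vector).
#' @param statistics which statistics to return, in order.
#' @return named numeric vector.
#' @export
statistical_features <- function(patch,
                                 statistics = c("mean", "sd", "skewness",
                                                "kurtosis", "min", "max",
                                                "median", "iqr")) {
  x <- as.numeric(patch)
  n <- length(x)
  if (n == 0) stop("empty patch")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  s <- sqrt(m2)
  vals <- c(
    mean = mu,
    sd = s,
    skewness = if (s > 0) mean((x - mu)^3) / s^3 else 0,
    kurtosis = if (s > 0) mean((x - mu)^4) / s^4 - 3 else 0,
    min = min(x),
    max = max(x),
    median = stats::median(x),
    iqr = stats::IQR(x)
  )
  vals[statistics]
}

# min-max quantization of a window to L gray levels (0 .. L-1); a constant
# window maps entirely to level 0
quantize_patch <- function(patch, levels) {
  rng <- range(patch)
  if (rng[2] <= rng[1]) return(matrix(0L, nrow(patch), ncol(patch)))
  q <- floor((patch - rng[1]) / (rng[2] - rng[1]) * levels)
  q[q >= levels] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' Gray-level co-occurrence matrix of a quantized window
#'
#' Counts co-occurring level pairs at the given pixel offset, symmetrized
#' (both directions counted) and normalized to sum to 1.
#'
#' @param patchq integer matrix of levels in `0 .. levels-1` (see
#'   [glcm_features()] for quantization from raw intensities).
#' @param offset integer `(drow, dcol)` displacement.
#' @param levels number of gray levels.
#' @return a `levels x levels` matrix summing to 1 (all zeros if the offset
#'   admits no pixel pairs).
#' @export
glcm <- function(patchq, offset, levels) {
  nr <- nrow(patchq); nc <- ncol(patchq)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  P <- matrix(0, levels, levels)
  if (length(r1) && length(c1)) {
    a <- patchq[r1, c1, drop = FALSE]
    b <- patchq[r1 + dr, c1 + dc, drop = FALSE]
    tab <- table(factor(a, levels = 0:(levels - 1)),
                 factor(b, levels = 0:(levels - 1)))
    P <- unclass(tab) + t(unclass(tab))
    dimnames(P) <- NULL
    if (sum(P) > 0) P <- P / sum(P)
  }
  P
}

# Haralick statistics of one normalized GLCM.  Conventions for the
# degenerate single-level window: energy 1, all else 0 (correlation is 0/0
# and defined as 0).
glcm_stat_values <- function(P, stats_wanted) {
  L <- nrow(P)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  vals <- c(
    contrast = sum((i - j)^2 * P),
    correlation = if (sd_i > 0 && sd_j > 0)
      sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j) else 0,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j))),
    entropy = -sum(P[P > 0] * log(P[P > 0]))
  )
  vals[stats_wanted]
}

#' Gray-level co-occurrence features of a window
#'
#' Quantizes the window (min-max to `cfg$glcm_levels` levels), builds one
#' symmetric normalized GLCM per configured offset and returns the Haralick
#' statistics — per offset by default, or averaged over offsets when the bank
#' says so.
#'
#' @param patch numeric matrix of raw intensities.
#' @param cfg a [feature_bank_config()].
#' @return named numeric vector (`<stat>.o<k>` per offset, or `<stat>` if
#'   averaged).
#' @export
glcm_features <- function(patch, cfg = feature_bank_config()) {
  q <- quantize_patch(patch, cfg$glcm_levels)
  per_off <- lapply(cfg$glcm_offsets, function(off)
    glcm_stat_values(glcm(q, off, cfg$glcm_levels), cfg$glcm_stats))
  if (cfg$glcm_average) {
    out <- Reduce(`+`, per_off) / length(per_off)
    names(out) <- cfg$glcm_stats
    return(out)
  }
  out <- unlist(lapply(seq_along(per_off), function(k) {
    v <- per_off[[k]]
    names(v) <- paste0(cfg$glcm_stats, ".o", k)
    v
  }))
  out
}

# --- Gabor filter bank ------------------------------------------------------

# Complex Gabor kernel: Gaussian envelope times a plane-wave carrier whose
# wave vector points along `theta` degrees from the row axis (theta = 0
# responds maximally to horizontal stripes, i.e. intensity varying with row).
# Both parts are made DC-free so constant windows give zero response.
gabor_kernel <- function(frequency, theta_deg, size) {
  half <- (size - 1) / 2
  u <- matrix(-half:half, size, size)        # row offsets
  v <- t(u)                                   # col offsets
  th <- theta_deg * pi / 180
  xprime <- u * cos(th) + v * sin(th)
  sigma <- 0.56 / frequency                   # ~1 octave bandwidth
  env <- exp(-(u^2 + v^2) / (2 * sigma^2))
  re <- env * cos(2 * pi * frequency * xprime)
  im <- env * sin(2 * pi * frequency * xprime)
  re <- re - mean(re)
  im <- im - mean(im)
  complex(real = re, imaginary = im) |> matrix(size, size)
}

gabor_bank <- function(cfg) {
  grid <- expand.grid(f = cfg$gabor_frequencies, o = cfg$gabor_orientations,
                      KEEP.OUT.ATTRS = FALSE)
  pars <- rbind(as.matrix(grid),
                do.call(rbind, cfg$gabor_extra))
  kernels <- lapply(seq_len(nrow(pars)), function(k)
    gabor_kernel(pars[k, 1], pars[k, 2], cfg$gabor_kernel_size))
  names(kernels) <- sprintf("f%s.o%s", format(pars[, 1], trim = TRUE),
                            format(pars[, 2], trim = TRUE))
  kernels
}

# Circular cross-correlation operator of a kernel on a size x size patch,
# expressed as a dense (complex) matrix acting on vec(patch).  Cached per
# (bank configuration, window size) because building it costs more than
# applying it.
.gabor_cache <- new.env(parent = emptyenv())

gabor_operator <- function(cfg) {
  key <- paste0(digest_config(cfg[c("gabor_frequencies", "gabor_orientations",
                                    "gabor_extra", "gabor_kernel_size")]),
                "_w", cfg$window)
  hit <- get0(key, envir = .gabor_cache)
  if (!is.null(hit)) return(hit)
  n <- cfg$window
  kernels <- gabor_bank(cfg)
  half <- (cfg$gabor_kernel_size - 1) / 2
  idx <- function(r, cc) (cc - 1) * n + r    # column-major vec index, 1-based
  ops <- lapply(kernels, function(g) {
    M <- matrix(0 + 0i, n * n, n * n)
    for (du in -half:half) for (dv in -half:half) {
      wgt <- g[du + half + 1, dv + half + 1]
      if (wgt == 0) next
      for (r in 1:n) for (cc in 1:n) {
        rr <- ((r - 1 + du) %% n) + 1
        cc2 <- ((cc - 1 + dv) %% n) + 1
        M[idx(r, cc), idx(rr, cc2)] <- M[idx(r, cc), idx(rr, cc2)] + wgt
      }
    }
    M
  })
  # stack: (14*n^2) x n^2, response for filter k in rows ((k-1)n^2+1):(k n^2)
  op <- list(M = do.call(rbind, ops), n_filters = length(kernels),
             filter_names = names(kernels), npix = n * n)
  assign(key, op, envir = .gabor_cache)
  op
}

#' Gabor texture features of a window
#'
#' Cross-correlates the window with a bank of complex Gabor filters
#' (circular boundary) and summarizes each filter's response magnitude by its
#' mean and population SD over the window.  Filters are DC-free, so adding a
#' constant to the window leaves every feature unchanged.
#'
#' @param patch numeric matrix whose side equals the bank's `window`.
#' @param cfg a [feature_bank_config()].
#' @return named numeric vector, `<filter>.mean` and `<filter>.sd` per filter.
#' @export
gabor_features <- function(patch, cfg = feature_bank_config()) {
  if (nrow(patch) != cfg$window || ncol(patch) != cfg$window)
    stop("patch must match the bank window size (", cfg$window, ")")
  op <- gabor_operator(cfg)
  resp <- Mod(op$M %*% as.vector(patch))
  out <- numeric(2 * op$n_filters)
  nm <- character(2 * op$n_filters)
  for (k in seq_len(op$n_filters)) {
    rk <- resp[((k - 1) * op$npix + 1):(k * op$npix)]
    mu <- mean(rk)
    out[2 * k - 1] <- mu
    out[2 * k] <- sqrt(mean((rk - mu)^2))
    nm[2 * k - 1] <- paste0(op$filter_names[k], ".mean")
    nm[2 * k] <- paste0(op$filter_names[k], ".sd")
  }
  stats::setNames(out, nm)
}

# batched gabor features for many vectorized patches (columns of P);
# returns matrix n_windows x (2*n_filters)
gabor_features_batch <- function(P, cfg) {
  op <- gabor_operator(cfg)
  R <- Mod(op$M %*% P)                 # (14*npix) x W
  W <- ncol(P)
  out <- matrix(0, W, 2 * op$n_filters)
  nm <- character(2 * op$n_filters)
  for (k in seq_len(op$n_filters)) {
    Rk <- R[((k - 1) * op$npix + 1):(k * op$npix), , drop = FALSE]
    mu <- colMeans(Rk)
    out[, 2 * k - 1] <- mu
    out[, 2 * k] <- sqrt(colMeans(Rk^2) - mu^2)
    nm[2 * k - 1] <- paste0(op$filter_names[k], ".mean")
    nm[2 * k] <- paste0(op$filter_names[k], ".sd")
  }
  out[out < 0] <- 0    # guard tiny negative variance roundoff
  colnames(out) <- nm
  out
}

# feature names emitted by the bank for one contrast (order matches
# window_features)
bank_feature_names <- function(cfg) {
  gl <- if (cfg$glcm_average) cfg$glcm_stats
        else unlist(lapply(seq_along(cfg$glcm_offsets),
                           function(k) paste0(cfg$glcm_stats, ".o", k)))
  kn <- names(gabor_bank(cfg))
  c(paste0("stat.", cfg$statistics),
    paste0("glcm.", gl),
    paste0("gabor.", rep(kn, each = 2), c(".mean", ".sd")))
}

# all features of one window of one contrast
window_features <- function(patch, cfg) {
  c(statistical_features(patch, cfg$statistics),
    glcm_features(patch, cfg),
    gabor_features(patch, cfg))
}

#' Full multi-contrast feature vector of one window
#'
#' Concatenates the per-contrast feature blocks of the window centered at
#' `center`, in the stack's contrast order.  With the default bank and the
#' five standard contrasts the vector has 280 entries (56 per contrast).
#'
#' @param stack a [contrast_stack()].
#' @param center 0-based `(row, col)` window center.
#' @param cfg a [feature_bank_config()].
#' @return named numeric vector with attribute `contrast_index`, a named list
#'   partitioning feature positions by contrast.
#' @export
build_feature_vector <- function(stack, center, cfg = feature_bank_config()) {
  out <- build_feature_matrix(stack, matrix(center, nrow = 1), cfg)
  v <- out[1, ]
  attr(v, "contrast_index") <- attr(out, "contrast_index")
  v
}

#' Feature matrix for many windows
#'
#' Vectorized form of [build_feature_vector()]: one row per window center.
#' This is the workhorse behind biopsy feature tables, auxiliary sampling and
#' stride-1 prediction maps.
#'
#' @param stack a [contrast_stack()].
#' @param centers integer matrix of 0-based `(row, col)` centers, one per row.
#' @param cfg a [feature_bank_config()].
#' @return numeric matrix `nrow(centers) x (5 * bank_dimension(cfg))` with
#'   named columns `<contrast>.<family>.<feature>` and attribute
#'   `contrast_index`.
#' @export
build_feature_matrix <- function(stack, centers, cfg = feature_bank_config()) {
  stopifnot(inherits(stack, "wso_contrast_stack"))
  centers <- matrix(as.integer(centers), ncol = 2)
  contrasts <- names(stack$images)
  per_names <- bank_feature_names(cfg)
  dper <- length(per_names)
  W <- nrow(centers)
  res <- matrix(0, W, dper * length(contrasts))
  cn <- character(0)
  n <- cfg$window
  for (ci in seq_along(contrasts)) {
    img <- stack$images[[ci]]
    # vectorize all patches once per contrast
    P <- matrix(0, n * n, W)
    patches <- vector("list", W)
    for (wi in seq_len(W)) {
      patches[[wi]] <- extract_window(img, centers[wi, ], n)
      P[, wi] <- as.vector(patches[[wi]])
    }
    stat_block <- t(vapply(patches, statistical_features,
                           numeric(length(cfg$statistics)),
                           statistics = cfg$statistics))
    glcm_block <- t(vapply(patches, glcm_features,
                           numeric(length(cfg$glcm_stats) *
                                     (if (cfg$glcm_average) 1
                                      else length(cfg$glcm_offsets))),
                           cfg = cfg))
    gab_block <- gabor_features_batch(P, cfg)
    res[, (ci - 1) * dper + seq_len(dper)] <-
      cbind(stat_block, glcm_block, gab_block)
    cn <- c(cn, paste0(contrasts[ci], ".", per_names))
  }
  colnames(res) <- cn
  attr(res, "contrast_index") <- stats::setNames(
    lapply(seq_along(contrasts),
           function(ci) (ci - 1) * dper + seq_len(dper)),
    contrasts)
  res
}

# stable short hash of a configuration list (serialization-based, no deps)
digest_config <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  # rolling polynomial hash; exact in doubles (stays far below 2^53)
  h <- 0
  for (b in raw) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}
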