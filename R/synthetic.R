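#' Configuration for a synthetic feature-space cohort
#'
#' Describes a direct feature-space cohort with the four sample sources the
#' ordinal classifier consumes.  Class centroids are collinear and ordered
#' along a common direction (class 0 below class 1 below class 2), giving the
#' ordinal geometry the model assumes; the unlabeled block is a mixture of
#' the class-1 and class-2 generators.  Default block sizes mirror a
#' single-gene biopsy cohort with an equally sized auxiliary pool split
#' between unlabeled tumoral and normal samples.
#'
#' @param n1,n2 labeled class-1 / class-2 counts.
#' @param m12 unlabeled tumoral count.
#' @param m0 normal-brain count.
#' @param d feature dimension.
#' @param separation distance between adjacent class centroids, in units of
#'   `noise_sd` (the within-class SD), i.e. a Mahalanobis-style spacing.
#' @param noise_sd within-class standard deviation (> 0).
#' @param imbalance_ratio expected class-2 share of the unlabeled mixture;
#'   defaults to `n2 / (n1 + n2)`.
#' @param mode `"gaussian"` for isotropic Gaussian classes;
#'   `"annuli"` for a nonlinear variant where tumoral classes live on
#'   concentric shells around the normal-class center (exercises nonlinear
#'   kernels; the collinear-centroid geometry does not apply).
#' @param seed integer random seed; equal seeds give bit-identical cohorts.
#' @return an object of class `wso_feature_cohort_config`.
#' @export
feature_cohort_config <- function(n1 = 171, n2 = 130, m12 = 150, m0 = 151,
                                  d = 20, separation = 4, noise_sd = 1,
                                  imbalance_ratio = NULL,
                                  mode = c("gaussian", "annuli"),
                                  seed = 1L) {
  mode <- match.arg(mode)
  if (any(c(n1, n2, m12, m0) < 0)) stop("counts must be >= 0")
  if (d < 1) stop("feature dimension d must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(imbalance_ratio))
    imbalance_ratio <- if (n1 + n2 > 0) n2 / (n1 + n2) else 0.5
  if (imbalance_ratio < 0 || imbalance_ratio > 1)
    stop("imbalance_ratio must be in [0, 1]")
  structure(
    list(n1 = as.integer(n1), n2 = as.integer(n2), m12 = as.integer(m12),
         m0 = as.integer(m0), d = as.integer(d), separation = separation,
         noise_sd = noise_sd, imbalance_ratio = imbalance_ratio,
         mode = mode, seed = as.integer(seed)),
    class = "wso_feature_cohort_config"
  )
}

#' Generate a synthetic feature-space cohort
#'
#' Draws the four blocks around collinear centroids
#' \eqn{\mu_0 = -s u, \mu_1 = 0, \mu_2 = +s u} (with \eqn{u} the unit
#' diagonal direction and \eqn{s} = `separation * noise_sd`), with isotropic
#' Gaussian noise of SD `noise_sd`.  The unlabeled block mixes the class-1
#' and class-2 generators with class-2 probability `imbalance_ratio`.  In
#' `"annuli"` mode the tumoral classes are concentric shells around the
#' normal cluster instead.
#'
#' @param config a [feature_cohort_config()].
#' @return a [training_set()]; attributes `centroids` (3 x d matrix),
#'   `unlabeled_class` (latent 1/2 labels of the X12 rows) and `config`.
#' @export
generate_feature_cohort <- function(config) {
  stopifnot(inherits(config, "wso_feature_cohort_config"))
  cfg <- config
  u <- rep(1, cfg$d) / sqrt(cfg$d)
  s <- cfg$separation * cfg$noise_sd
  centroids <- rbind(mu0 = -s * u, mu1 = 0 * u, mu2 = s * u)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  rmat <- function(n) matrix(stats::rnorm(n * cfg$d, sd = cfg$noise_sd), n, cfg$d)
  if (cfg$mode == "gaussian") {
    draw <- function(n, cls) {
      if (n == 0) return(matrix(numeric(0), 0, cfg$d))
      sweep(rmat(n), 2, centroids[cls, ], "+")
    }
  } else {
    # tumoral classes on shells of radius s and 2s around the class-0 center
    draw <- function(n, cls) {
      if (n == 0) return(matrix(numeric(0), 0, cfg$d))
      if (cls == 1) return(sweep(rmat(n), 2, centroids[1, ], "+"))
      dirs <- matrix(stats::rnorm(n * cfg$d), n, cfg$d)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      radius <- (cls - 1) * s + stats::rnorm(n, sd = cfg$noise_sd)
      sweep(dirs * radius, 2, centroids[1, ], "+")
    }
  }
  X0 <- draw(cfg$m0, 1)
  X1 <- draw(cfg$n1, 2)
  X2 <- draw(cfg$n2, 3)
  z <- if (cfg$m12 > 0)
    2L + (stats::runif(cfg$m12) < cfg$imbalance_ratio) else integer(0)
  X12 <- if (cfg$m12 > 0) {
    M <- matrix(0, cfg$m12, cfg$d)
    if (any(z == 2L)) M[z == 2L, ] <- draw(sum(z == 2L), 2)
    if (any(z == 3L)) M[z == 3L, ] <- draw(sum(z == 3L), 3)
    M
  } else NULL
  fn <- paste0("f_", seq_len(cfg$d))
  ts <- training_set(X1, X2, X12, X0, feature_names = fn,
                     compartment12 = if (cfg$m12 > 0)
                       rep(c("CE", "NE"), length.out = cfg$m12) else NULL)
  attr(ts, "centroids") <- centroids
  attr(ts, "unlabeled_class") <- z - 1L
  attr(ts, "config") <- cfg
  ts
}

#' Configuration for a synthetic image-mode cohort
#'
#' Describes multiparametric single-slice "patients": five co-registered
#' contrast images over a shared grid, a tumoral AOI split into CE and NE
#' compartments, a contralateral normal region, a latent per-pixel
#' genetic-status field per gene, and point biopsies carrying the latent
#' label at their location.  The latent fields are Gaussian-smoothed
#' white-noise fields thresholded at their within-AOI median, giving
#' spatially coherent altered/non-altered subregions without modeling tumor
#' biology.
#'
#' Intensity structure per contrast: each region (normal / NE / CE) has its
#' own mean, gene alteration adds a contrast-specific shift inside the
#' altered subregion, and two noise layers are added — smooth correlated
#' texture (Gaussian-blurred white noise) and i.i.d. pixel noise.
#'
#' @param n_patients number of patients.
#' @param image_shape `(rows, cols)` in pixels.
#' @param contrasts contrast names (exactly five for the standard pipeline).
#' @param genes gene names; one latent field per gene.
#' @param region_means `3 x n_contrast` matrix of mean intensities (rows:
#'   normal, NE, CE).
#' @param class_effect per-contrast intensity shift added where a gene is
#'   altered (class 2), in the same arbitrary units.
#' @param gene_contrast_weights `n_gene x n_contrast` 0/1 (or fractional)
#'   matrix saying which contrasts each gene's alteration imprints on;
#'   `NULL` assigns each gene a distinct pair of contrasts (so the relative
#'   contrast contributions differ between genes, as they do for real driver
#'   genes).
#' @param noise_sd i.i.d. pixel noise SD.
#' @param texture_sd,texture_smooth SD and Gaussian smoothing length
#'   (pixels) of the correlated texture layer.
#' @param label_smooth smoothing length (pixels) of the latent label field;
#'   larger values give larger coherent subregions.
#' @param aoi_radius,ce_radius,normal_radius disk radii in pixels of the
#'   AOI, its CE core and the contralateral normal region.
#' @param n_biopsies `(min, max)` biopsies per patient, sampled uniformly.
#' @param window window size the cohort must support; biopsy and sampling
#'   eligibility keep centers at least `window/2` pixels inside their
#'   region.
#' @param seed integer random seed.
#' @return an object of class `wso_image_cohort_config`.
#' @export
image_cohort_config <- function(n_patients = 4,
                                image_shape = c(64L, 64L),
                                contrasts = c("T1C", "T2", "MD", "FA", "rCBV"),
                                genes = c("EGFR", "PDGFRA", "PTEN"),
                                region_means = rbind(
                                  normal = c(1.0, 1.0, 1.2, 0.9, 1.0),
                                  ne     = c(1.6, 2.2, 1.8, 0.5, 1.8),
                                  ce     = c(3.0, 2.6, 1.4, 0.4, 2.6)),
                                class_effect = c(1.5, 1.5, 0.8, 0.8, 1.5),
                                gene_contrast_weights = NULL,
                                noise_sd = 0.4,
                                texture_sd = 0.3,
                                texture_smooth = 2,
                                label_smooth = 6,
                                aoi_radius = 15,
                                ce_radius = 8,
                                normal_radius = 9,
                                n_biopsies = c(2L, 8L),
                                window = 8L,
                                seed = 1L) {
  if (length(image_shape) != 2) stop("image_shape must be (rows, cols)")
  if (ncol(region_means) != length(contrasts))
    stop("region_means needs one column per contrast")
  if (length(class_effect) != length(contrasts))
    stop("class_effect needs one value per contrast")
  if (is.null(gene_contrast_weights)) {
    nc <- length(contrasts)
    gene_contrast_weights <- t(vapply(seq_along(genes), function(i) {
      w <- numeric(nc)
      w[(((i - 1) * 2) %% nc) + 1] <- 1
      w[(((i - 1) * 2 + 1) %% nc) + 1] <- 1
      w
    }, numeric(length(contrasts))))
  }
  if (!all(dim(gene_contrast_weights) == c(length(genes), length(contrasts))))
    stop("gene_contrast_weights must be n_gene x n_contrast")
  half <- window %/% 2
  # AOI disk plus window margin plus normal region must fit on the grid
  need <- 2 * (aoi_radius + half + 2) + 2 * (normal_radius + half + 2)
  if (min(image_shape) < 2 * (aoi_radius + half + 2) ||
      max(image_shape) < need / 1.3)
    stop("image_shape too small for AOI radius ", aoi_radius,
         " + normal region + window margin")
  structure(
    list(n_patients = as.integer(n_patients),
         image_shape = as.integer(image_shape), contrasts = contrasts,
         genes = genes, region_means = region_means,
         class_effect = class_effect,
         gene_contrast_weights = gene_contrast_weights, noise_sd = noise_sd,
         texture_sd = texture_sd, texture_smooth = texture_smooth,
         label_smooth = label_smooth, aoi_radius = aoi_radius,
         ce_radius = ce_radius, normal_radius = normal_radius,
         n_biopsies = as.integer(n_biopsies), window = as.integer(window),
         seed = as.integer(seed)),
    class = "wso_image_cohort_config"
  )
}

disk_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cc <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1], shape[2])
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

smooth_field <- function(shape, sigma) {
  z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  # cap the Gaussian brush below the image size (gblur default is 6*sigma+1)
  radius <- min(2 * ceiling(3 * sigma) + 1, (min(shape) %/% 2) * 2 - 1)
  f <- matrix(as.numeric(EBImage::gblur(z, sigma = sigma, radius = radius)),
              shape[1], shape[2])
  f / stats::sd(as.vector(f))
}

#' Generate a synthetic image-mode cohort
#'
#' @param config an [image_cohort_config()].
#' @return list of patients; each has `patient_id`, `stack`
#'   (a [contrast_stack()]), `latent` (named list per gene of matrices with
#'   classes 1/2 on AOI pixels, NA outside) and `biopsies` (data frame
#'   `row`, `col` (0-based), `gene`, `status`).
#' @export
generate_image_cohort <- function(config) {
  stopifnot(inherits(config, "wso_image_cohort_config"))
  cfg <- config
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  shape <- cfg$image_shape
  half <- cfg$window %/% 2
  aoi_center <- c(shape[1] / 2, cfg$aoi_radius + half + 2)
  normal_center <- c(shape[1] / 2,
                     shape[2] - cfg$normal_radius - half - 3)
  lapply(seq_len(cfg$n_patients), function(p) {
    aoi <- disk_mask(shape, aoi_center, cfg$aoi_radius)
    ce <- disk_mask(shape, aoi_center, cfg$ce_radius) & aoi
    ne <- aoi & !ce
    normal <- disk_mask(shape, normal_center, cfg$normal_radius)
    latent <- stats::setNames(lapply(cfg$genes, function(g) {
      f <- smooth_field(shape, cfg$label_smooth)
      thr <- stats::median(f[aoi])
      L <- matrix(NA_integer_, shape[1], shape[2])
      L[aoi] <- ifelse(f[aoi] > thr, 2L, 1L)
      L
    }), cfg$genes)
    images <- stats::setNames(lapply(seq_along(cfg$contrasts), function(ci) {
      base <- matrix(cfg$region_means["normal", ci], shape[1], shape[2])
      base[normal] <- cfg$region_means["normal", ci]
      base[ne] <- cfg$region_means["ne", ci]
      base[ce] <- cfg$region_means["ce", ci]
      # each gene's altered subregion shifts the contrasts it is coupled to
      for (gi in seq_along(cfg$genes)) {
        wgt <- cfg$gene_contrast_weights[gi, ci]
        if (wgt == 0) next
        alt <- latent[[gi]] == 2L & aoi
        alt[is.na(alt)] <- FALSE
        base[alt] <- base[alt] + wgt * cfg$class_effect[ci]
      }
      base +
        cfg$texture_sd * smooth_field(shape, cfg$texture_smooth) +
        matrix(stats::rnorm(prod(shape), sd = cfg$noise_sd),
               shape[1], shape[2])
    }), cfg$contrasts)
    stack <- contrast_stack(images, aoi, ce, ne, normal)
    eligible <- window_fits_mask(aoi, cfg$window)
    coords <- mask_coords(eligible)
    if (nrow(coords) == 0)
      stop("AOI too small: no biopsy location admits a ", cfg$window,
           "x", cfg$window, " window")
    nb_range <- seq(cfg$n_biopsies[1], cfg$n_biopsies[2])
    nb <- nb_range[sample.int(length(nb_range), 1)]
    pick <- coords[sample(nrow(coords), min(nb, nrow(coords))), , drop = FALSE]
    biopsies <- do.call(rbind, lapply(cfg$genes, function(g) {
      data.frame(row = pick[, 1], col = pick[, 2], gene = g,
                 status = latent[[g]][cbind(pick[, 1] + 1, pick[, 2] + 1)])
    }))
    list(patient_id = sprintf("P%03d", p), stack = stack, latent = latent,
         biopsies = biopsies)
  })
}

#' Extract biopsy-window features for a whole image cohort
#'
#' Builds the labeled feature blocks for one gene from every patient's
#' biopsy windows, ready for [wsosvm_fit()] or cross-validation.
#'
#' @param cohort result of [generate_image_cohort()].
#' @param gene gene name to take labels from.
#' @param cfg a [feature_bank_config()].
#' @return a [training_set()] with labeled blocks only (patient ids
#'   attached); combine with [sample_patient_windows()] for auxiliary blocks.
#' @export
cohort_biopsy_features <- function(cohort, gene, cfg = feature_bank_config()) {
  rows <- list(); labs <- integer(0); pats <- character(0)
  for (pt in cohort) {
    b <- pt$biopsies[pt$biopsies$gene == gene, , drop = FALSE]
    if (!nrow(b)) next
    F <- build_feature_matrix(pt$stack, as.matrix(b[, c("row", "col")]), cfg)
    rows[[length(rows) + 1]] <- F
    labs <- c(labs, b$status)
    pats <- c(pats, rep(pt$patient_id, nrow(b)))
  }
  X <- do.call(rbind, rows)
  training_set(X1 = X[labs == 1L, , drop = FALSE],
               X2 = X[labs == 2L, , drop = FALSE],
               patient = list(X1 = pats[labs == 1L], X2 = pats[labs == 2L]),
               feature_names = colnames(X))
}

#' Sample feature windows from a patient's regions
#'
#' Draws window centers uniformly among centers whose window fits entirely
#' inside the requested region (`"CE"`/`"NE"` centers must also keep the
#' window inside the AOI) and returns their feature vectors.  Used for
#' auxiliary unlabeled-tumoral and normal-brain samples.
#'
#' @param stack a [contrast_stack()].
#' @param region `"CE"`, `"NE"` or `"normal"`.
#' @param n number of windows (silently truncated to the eligible count).
#' @param cfg a [feature_bank_config()].
#' @param seed integer seed.
#' @return list with `features` (matrix) and `centers` (0-based coordinates).
#' @export
sample_patient_windows <- function(stack, region = c("CE", "NE", "normal"),
                                   n, cfg = feature_bank_config(), seed = 1L) {
  region <- match.arg(region)
  inner <- switch(region, CE = stack$ce_mask, NE = stack$ne_mask,
                  normal = stack$normal_mask)
  fits <- window_fits_mask(if (region == "normal") stack$normal_mask
                           else stack$aoi_mask, cfg$window)
  eligible <- fits & inner
  coords <- mask_coords(eligible)
  if (nrow(coords) == 0)
    stop("region ", region, " admits no ", cfg$window, "x", cfg$window,
         " windows")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pick <- coords[sample(nrow(coords), min(n, nrow(coords))), , drop = FALSE]
  list(features = build_feature_matrix(stack, pick, cfg), centers = pick)
}
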