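test_that("feature cohorts honor block sizes, determinism and empty blocks", {
  cfg <- feature_cohort_config(n1 = 0, n2 = 0, m12 = 0, m0 = 5, d = 2)
  ts <- generate_feature_cohort(cfg)
  expect_equal(unname(block_sizes(ts)[c("n1", "n2", "m12", "m0")]),
               c(0L, 0L, 0L, 5L))
  expect_equal(dim(ts$X0), c(5L, 2L))
  cfg7 <- feature_cohort_config(n1 = 8, n2 = 6, m12 = 4, m0 = 5, d = 3,
                                seed = 7)
  expect_identical(generate_feature_cohort(cfg7), generate_feature_cohort(cfg7))
  expect_error(feature_cohort_config(d = 0), "d must be")
  expect_error(feature_cohort_config(noise_sd = 0), "noise_sd")
})

test_that("empirical centroid spacing matches the configured separation", {
  cfg <- feature_cohort_config(n1 = 200, n2 = 200, m12 = 0, m0 = 200,
                               d = 10, separation = 6, noise_sd = 1, seed = 4)
  ts <- generate_feature_cohort(cfg)
  d12 <- sqrt(sum((colMeans(ts$X2) - colMeans(ts$X1))^2))
  d01 <- sqrt(sum((colMeans(ts$X1) - colMeans(ts$X0))^2))
  expect_lt(abs(d12 - 6) / 6, 0.1)
  expect_lt(abs(d01 - 6) / 6, 0.1)
})

test_that("generated classes project to monotonically ordered means", {
  cfg <- feature_cohort_config(n1 = 100, n2 = 100, m12 = 80, m0 = 100,
                               d = 6, separation = 3, seed = 9)
  ts <- generate_feature_cohort(cfg)
  cen <- attr(ts, "centroids")
  axis <- cen["mu2", ] - cen["mu0", ]
  axis <- axis / sqrt(sum(axis^2))
  proj <- function(X) mean(X %*% axis)
  expect_lt(proj(ts$X0), proj(ts$X1))
  expect_lt(proj(ts$X1), proj(ts$X2))
  # unlabeled block sits between the labeled extremes
  expect_gt(proj(ts$X12), proj(ts$X0))
})

test_that("unlabeled mixture proportion follows the imbalance ratio", {
  cfg <- feature_cohort_config(n1 = 10, n2 = 10, m12 = 4000, m0 = 10,
                               d = 2, imbalance_ratio = 0.3, seed = 21)
  ts <- generate_feature_cohort(cfg)
  z <- attr(ts, "unlabeled_class")
  # binomial concentration: within 4 SE of the configured mixing probability
  expect_lt(abs(mean(z == 2L) - 0.3), 4 * sqrt(0.3 * 0.7 / length(z)))
})

test_that("annuli mode produces radially separated tumoral classes", {
  cfg <- feature_cohort_config(n1 = 150, n2 = 150, m12 = 0, m0 = 150,
                               d = 2, separation = 6, mode = "annuli",
                               seed = 2)
  ts <- generate_feature_cohort(cfg)
  c0 <- colMeans(ts$X0)
  r1 <- sqrt(rowSums(sweep(ts$X1, 2, c0)^2))
  r2 <- sqrt(rowSums(sweep(ts$X2, 2, c0)^2))
  expect_lt(mean(r1), mean(r2))
})

test_that("image cohorts satisfy the mask algebra and biopsy containment", {
  co <- image_cohort_config(n_patients = 2, n_biopsies = c(3L, 3L), seed = 5)
  coh <- generate_image_cohort(co)
  expect_length(coh, 2)
  for (pt in coh) {
    st <- pt$stack
    expect_identical(st$ce_mask | st$ne_mask, st$aoi_mask)
    expect_false(any(st$ce_mask & st$ne_mask))
    expect_false(any(st$aoi_mask & st$normal_mask))
    b <- pt$biopsies[pt$biopsies$gene == co$genes[1], ]
    expect_equal(nrow(b), 3)
    # inside the AOI with the full window margin
    fits <- window_fits_mask(st$aoi_mask, co$window)
    expect_true(all(fits[cbind(b$row + 1, b$col + 1)]))
    # biopsy labels equal the latent field at their pixels, for every gene
    for (g in co$genes) {
      bg <- pt$biopsies[pt$biopsies$gene == g, ]
      expect_equal(bg$status,
                   pt$latent[[g]][cbind(bg$row + 1, bg$col + 1)])
    }
    # latent fields are defined exactly on the AOI
    for (g in co$genes)
      expect_identical(!is.na(pt$latent[[g]]), st$aoi_mask)
  }
  expect_identical(coh, generate_image_cohort(co))
})

test_that("altered regions carry the configured intensity shift", {
  co <- image_cohort_config(n_patients = 1, genes = "EGFR",
                            gene_contrast_weights = matrix(1, 1, 5),
                            noise_sd = 0.2, texture_sd = 0.1, seed = 8)
  pt <- generate_image_cohort(co)[[1]]
  lat <- pt$latent$EGFR
  # restrict to the NE compartment so the regional base mean is constant
  ne <- pt$stack$ne_mask
  img <- pt$stack$images[[1]]
  m_alt <- mean(img[ne & !is.na(lat) & lat == 2L])
  m_non <- mean(img[ne & !is.na(lat) & lat == 1L])
  n_alt <- sum(ne & !is.na(lat) & lat == 2L)
  se <- sqrt(0.2^2 + 0.1^2) / sqrt(n_alt) * 2   # two noise layers, crude SE
  expect_lt(abs((m_alt - m_non) - co$class_effect[1]), max(6 * se, 0.15))
})

test_that("window eligibility masks match a brute-force check", {
  set.seed(13)
  mask <- matrix(runif(400) > 0.3, 20, 20)
  fits <- window_fits_mask(mask, 4)
  brute <- matrix(FALSE, 20, 20)
  for (r in 0:19) for (cc in 0:19) {
    rs <- (r - 2):(r + 1); cs <- (cc - 2):(cc + 1)
    if (min(rs) < 0 || min(cs) < 0 || max(rs) > 19 || max(cs) > 19) next
    brute[r + 1, cc + 1] <- all(mask[rs + 1, cs + 1])
  }
  expect_identical(fits, brute)
})

test_that("too-small images are rejected at configuration time", {
  expect_error(image_cohort_config(image_shape = c(24L, 24L)),
               "too small")
})
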