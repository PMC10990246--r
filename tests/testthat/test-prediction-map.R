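# a small image cohort and fitted model shared across the map tests
map_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    co <- image_cohort_config(n_patients = 3, image_shape = c(52L, 52L),
                              genes = "EGFR",
                              gene_contrast_weights = matrix(1, 1, 5),
                              class_effect = c(3, 3, 1.6, 1.6, 3),
                              aoi_radius = 13, ce_radius = 6,
                              normal_radius = 6, label_smooth = 11,
                              n_biopsies = c(6L, 9L), seed = 14)
    coh <- generate_image_cohort(co)
    cfg <- small_bank()
    lab <- cohort_biopsy_features(coh, "EGFR", cfg)
    aux12 <- list(); aux0 <- list(); compt <- character(0)
    for (i in seq_along(coh)) {
      st <- coh[[i]]$stack
      ce <- sample_patient_windows(st, "CE", 4, cfg, seed = 100 + i)
      ne <- sample_patient_windows(st, "NE", 4, cfg, seed = 200 + i)
      nb <- sample_patient_windows(st, "normal", 8, cfg, seed = 300 + i)
      aux12[[i]] <- rbind(ce$features, ne$features)
      compt <- c(compt, rep(c("CE", "NE"), each = 4))
      aux0[[i]] <- nb$features
    }
    ts <- training_set(lab$X1, lab$X2, do.call(rbind, aux12),
                       do.call(rbind, aux0), compartment12 = compt,
                       feature_names = colnames(lab$X1))
    fit <- wsosvm_fit(ts, C1 = 10, C2 = 1, kernel_spec("rbf"))
    cache <<- list(co = co, coh = coh, cfg = cfg, lab = lab, fit = fit)
    cache
  }
})

test_that("map cardinality equals AOI pixels with in-bounds windows", {
  fx <- map_fixture()
  st <- fx$coh[[1]]$stack
  map <- generate_map(fx$fit, st, fx$cfg, gene = "EGFR")
  dims <- dim(st$images[[1]])
  inb <- window_fits_mask(matrix(TRUE, dims[1], dims[2]), fx$cfg$window)
  expect_equal(map$n_mapped, sum(st$aoi_mask & inb))
  expect_equal(sum(!is.na(map$class_map)), map$n_mapped)
  expect_equal(map$n_skipped, sum(st$aoi_mask) - map$n_mapped)
  # an AOI touching the boundary margin produces skipped pixels
  st2 <- st
  aoi2 <- st2$aoi_mask; aoi2[1:3, 1:6] <- TRUE
  st2 <- contrast_stack(st$images, aoi2, st$ce_mask,
                        aoi2 & !st$ce_mask, st$normal_mask & !aoi2)
  map2 <- generate_map(fx$fit, st2, fx$cfg)
  expect_gt(map2$n_skipped, 0)
})

test_that("map classes recompute from decision values and match classify()", {
  fx <- map_fixture()
  pt <- fx$coh[[2]]
  map <- generate_map(fx$fit, pt$stack, fx$cfg, gene = "EGFR")
  ok <- !is.na(map$class_map)
  recls <- ifelse(map$decision_map[ok] >= map$b1, 2L,
                  ifelse(map$decision_map[ok] >= map$b0, 1L, 0L))
  expect_equal(map$class_map[ok], recls)
  b <- pt$biopsies[pt$biopsies$gene == "EGFR", ]
  direct <- classify(fx$fit,
                     build_feature_matrix(pt$stack,
                                          as.matrix(b[, c("row", "col")]),
                                          fx$cfg))
  expect_equal(unname(map$class_map[cbind(b$row + 1, b$col + 1)]),
               unname(direct))
})

test_that("personalization is seed-deterministic and patient-dependent", {
  fx <- map_fixture()
  p1a <- personalize(fx$fit, fx$coh[[1]]$stack, fx$lab, fx$cfg, seed = 5)
  p1b <- personalize(fx$fit, fx$coh[[1]]$stack, fx$lab, fx$cfg, seed = 5)
  expect_identical(p1a$coef, p1b$coef)
  expect_identical(c(p1a$b0, p1a$b1), c(p1b$b0, p1b$b1))
  p2 <- personalize(fx$fit, fx$coh[[2]]$stack, fx$lab, fx$cfg, seed = 5)
  expect_false(identical(p1a$coef, p2$coef))
})

test_that("sharply separated latent regions are mapped accurately", {
  fx <- map_fixture()
  ags <- vapply(1:2, function(pi) {
    per <- personalize(fx$fit, fx$coh[[pi]]$stack, fx$lab, fx$cfg, seed = 9)
    map <- generate_map(per, fx$coh[[pi]]$stack, fx$cfg, gene = "EGFR")
    map_agreement(map, fx$coh[[pi]]$latent$EGFR, border = 4)$agreement
  }, numeric(1))
  expect_gte(mean(ags), 0.9)
})

test_that("co-alteration maps cross-tabulate their inputs", {
  fx <- map_fixture()
  pt <- fx$coh[[1]]
  map_a <- generate_map(fx$fit, pt$stack, fx$cfg, gene = "EGFR")
  map_b <- map_a
  map_b$gene <- "PDGFRA"
  set.seed(8)
  ok <- !is.na(map_b$class_map)
  map_b$class_map[ok] <- sample(1:2, sum(ok), TRUE)
  joint <- co_alteration_map(map_a, map_b)
  tab <- table(map_a$class_map[ok] == 2L, map_b$class_map[ok] == 2L)
  expect_equal(unname(joint$counts[["neither"]]), unname(tab["FALSE", "FALSE"]))
  expect_equal(unname(joint$counts[["both"]]),
               if ("TRUE" %in% rownames(tab) && "TRUE" %in% colnames(tab))
                 unname(tab["TRUE", "TRUE"]) else 0L)
  expect_equal(sum(joint$counts), sum(ok))
  # degenerate inputs
  all2 <- map_a; all2$class_map[ok] <- 2L
  j2 <- co_alteration_map(all2, all2)
  expect_equal(unname(j2$counts[["both"]]), sum(ok))
  all1 <- map_a; all1$class_map[ok] <- 1L
  j3 <- co_alteration_map(all1, map_b)
  expect_equal(unname(j3$counts[[2]]), 0L)   # gene-A-only impossible
  # mismatched grids error
  bad <- map_b; bad$class_map <- bad$class_map[1:10, 1:10]
  expect_error(co_alteration_map(map_a, bad), "same grid")
})

test_that("map summaries are proper class fractions", {
  fx <- map_fixture()
  map <- generate_map(fx$fit, fx$coh[[3]]$stack, fx$cfg)
  fr <- map_summary(map)
  expect_equal(sum(fr), 1)
  all2 <- map; all2$class_map[!is.na(all2$class_map)] <- 2L
  expect_equal(unname(map_summary(all2)["altered"]), 1)
  half <- map
  ok <- which(!is.na(half$class_map))
  half$class_map[ok] <- rep(c(1L, 2L), length.out = length(ok))
  expect_equal(unname(map_summary(half)["altered"]), 0.5, tolerance = 0.01)
})
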