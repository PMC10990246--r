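#' Personalize a fitted model to one patient
#'
#' Re-trains the classifier under a template's tuned hyperparameters, keeping
#' the cohort's labeled biopsy blocks but drawing the auxiliary unlabeled
#' tumoral and normal samples from this patient's own image (same equal
#' CE/NE split and labeled-matched total as in training).
#'
#' @param model template `wsosvm` (supplies `C1`, `C2` and the kernel
#'   specification; an unresolved-rbf template re-resolves its bandwidth on
#'   the personalized training set).
#' @param stack the patient's [contrast_stack()].
#' @param labeled_ts [training_set()] holding the cohort's labeled blocks.
#' @param cfg the [feature_bank_config()] the model was trained with.
#' @param seed integer seed for the auxiliary draws.
#' @return a patient-specific fitted `wsosvm`.
#' @export
personalize <- function(model, stack, labeled_ts,
                        cfg = feature_bank_config(), seed = 1L) {
  stopifnot(inherits(model, "wsosvm"), inherits(stack, "wso_contrast_stack"),
            inherits(labeled_ts, "wso_training_set"))
  n_lab <- nrow(labeled_ts$X1) + nrow(labeled_ts$X2)
  n12 <- ceiling(n_lab / 2); n0 <- floor(n_lab / 2)
  nce <- ceiling(n12 / 2); nne <- n12 - nce
  ce <- sample_patient_windows(stack, "CE", nce, cfg, seed = seed)
  ne <- sample_patient_windows(stack, "NE", nne, cfg, seed = seed + 1L)
  nb <- sample_patient_windows(stack, "normal", n0, cfg, seed = seed + 2L)
  ts <- training_set(
    X1 = labeled_ts$X1, X2 = labeled_ts$X2,
    X12 = rbind(ce$features, ne$features), X0 = nb$features,
    compartment12 = rep(c("CE", "NE"),
                        c(nrow(ce$features), nrow(ne$features))),
    feature_names = colnames(labeled_ts$X1)
  )
  kern <- model$kernel
  wsosvm_fit(ts, C1 = model$C1, C2 = model$C2, kernel = kern,
             scale = !is.null(model$scaler))
}

#' Regional prediction map over the tumoral AOI
#'
#' Places the stride-1 sliding window at every AOI pixel, extracts the full
#' multi-contrast feature vector and classifies it, producing a per-pixel
#' ordinal class map and the underlying decision values.  AOI pixels whose
#' window crosses the image boundary are skipped (no padding) and counted in
#' `n_skipped`.  Class-0 predictions inside the AOI are retained — they are a
#' model-data-mismatch signal surfaced by [map_summary()], not forced into
#' class 1.
#'
#' @param model a fitted (typically [personalize()]d) `wsosvm`.
#' @param stack the patient's [contrast_stack()].
#' @param cfg the [feature_bank_config()] matching the model's features.
#' @param gene optional gene name carried in the map metadata.
#' @param patient_id optional patient identifier.
#' @return an object of class `wso_prediction_map`: integer `class_map` and
#'   numeric `decision_map` matrices (NA outside the mapped pixels), the
#'   mapped pixel count `n_mapped`, `n_skipped`, and metadata.
#' @export
generate_map <- function(model, stack, cfg = feature_bank_config(),
                         gene = NULL, patient_id = NULL) {
  stopifnot(inherits(model, "wsosvm"), inherits(stack, "wso_contrast_stack"))
  dims <- dim(stack$images[[1]])
  inbounds <- window_fits_mask(matrix(TRUE, dims[1], dims[2]), cfg$window)
  usable <- stack$aoi_mask & inbounds
  skipped <- sum(stack$aoi_mask) - sum(usable)
  centers <- mask_coords(usable)
  if (nrow(centers) == 0) stop("no AOI pixel admits an in-bounds window")
  F <- build_feature_matrix(stack, centers, cfg)
  h <- decision_value(model, F)
  cls <- ifelse(h >= model$b1, 2L, ifelse(h >= model$b0, 1L, 0L))
  class_map <- matrix(NA_integer_, dims[1], dims[2])
  decision_map <- matrix(NA_real_, dims[1], dims[2])
  class_map[centers + 1L] <- cls
  decision_map[centers + 1L] <- h
  structure(
    list(class_map = class_map, decision_map = decision_map,
         b0 = model$b0, b1 = model$b1,
         n_mapped = nrow(centers), n_skipped = skipped,
         gene = gene, patient_id = patient_id,
         bank_hash = digest_config(unclass(cfg))),
    class = "wso_prediction_map"
  )
}

#' @export
print.wso_prediction_map <- function(x, ...) {
  cat("<wso_prediction_map>", if (!is.null(x$gene)) paste0("gene ", x$gene),
      if (!is.null(x$patient_id)) paste0(" patient ", x$patient_id), "\n")
  cat("  mapped pixels:", x$n_mapped, " skipped (boundary):", x$n_skipped, "\n")
  fr <- map_summary(x)
  cat(sprintf("  altered %.3f | non-altered %.3f | class-0 QC %.3f\n",
              fr["altered"], fr["non_altered"], fr["class0"]))
  invisible(x)
}

#' Joint co-alteration map of two genes
#'
#' Combines two prediction maps of the same patient/AOI into a per-pixel
#' joint state, calling a pixel "altered" for a gene when its class is 2.
#'
#' @param map_a,map_b [generate_map()] results on the same grid and AOI.
#' @return an object of class `wso_coalteration_map` whose `state_map` is a
#'   factor-coded integer matrix (1 neither, 2 A-only, 3 B-only, 4 both) with
#'   `levels` attribute naming the genes, plus the joint `counts` table.
#' @export
co_alteration_map <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "wso_prediction_map"),
            inherits(map_b, "wso_prediction_map"))
  A <- map_a$class_map; B <- map_b$class_map
  if (!identical(dim(A), dim(B)) || !identical(is.na(A), is.na(B)))
    stop("maps are not on the same grid/AOI")
  ga <- if (is.null(map_a$gene)) "A" else map_a$gene
  gb <- if (is.null(map_b$gene)) "B" else map_b$gene
  state <- matrix(NA_integer_, nrow(A), ncol(A))
  ok <- !is.na(A)
  state[ok] <- 1L + (A[ok] == 2L) + 2L * (B[ok] == 2L)
  levels <- c("neither", paste0(ga, "_only"), paste0(gb, "_only"), "both")
  counts <- table(factor(state[ok], levels = 1:4, labels = levels))
  structure(list(state_map = state, levels = levels, counts = counts,
                 genes = c(ga, gb)),
            class = "wso_coalteration_map")
}

#' Per-patient alteration fractions of a prediction map
#'
#' @param map a [generate_map()] result.
#' @return named vector: fraction of mapped AOI pixels predicted altered
#'   (class 2), non-altered (class 1) and the class-0 QC fraction.  The three
#'   fractions sum to 1.
#' @export
map_summary <- function(map) {
  stopifnot(inherits(map, "wso_prediction_map"))
  v <- map$class_map[!is.na(map$class_map)]
  c(altered = mean(v == 2L), non_altered = mean(v == 1L),
    class0 = mean(v == 0L))
}

#' Agreement of a prediction map with a latent label field
#'
#' Quality-control helper for synthetic cohorts: compares the map's
#' altered/non-altered calls with the generator's latent field, excluding a
#' border band (within `border` pixels, Chebyshev distance) around any
#' discontinuity of the field — boundaries between latent regions and the
#' AOI edge alike — where the window inevitably mixes populations.  Class-0
#' predictions count as disagreements.
#'
#' @param map a [generate_map()] result.
#' @param latent integer matrix of latent classes 1/2 (NA outside the AOI).
#' @param border excluded half-width around latent boundaries, in pixels
#'   (defaults to the window radius).
#' @return list with `agreement` (fraction), `n_compared`, `n_border`.
#' @export
map_agreement <- function(map, latent, border = 4L) {
  stopifnot(inherits(map, "wso_prediction_map"))
  dims <- dim(latent)
  boundary <- matrix(FALSE, dims[1], dims[2])
  for (du in -border:border) for (dv in -border:border) {
    if (du == 0 && dv == 0) next
    rs <- seq_len(dims[1]); cs <- seq_len(dims[2])
    rs_s <- rs + du; cs_s <- cs + dv
    okr <- rs_s >= 1 & rs_s <= dims[1]; okc <- cs_s >= 1 & cs_s <= dims[2]
    sub <- latent[rs[okr], cs[okc], drop = FALSE]
    shf <- latent[rs_s[okr], cs_s[okc], drop = FALSE]
    diffm <- !is.na(sub) & (is.na(shf) | sub != shf)
    tmp <- matrix(FALSE, dims[1], dims[2])
    tmp[rs[okr], cs[okc]] <- diffm
    boundary <- boundary | tmp
  }
  use <- !is.na(map$class_map) & !is.na(latent) & !boundary
  list(agreement = mean(map$class_map[use] == latent[use]),
       n_compared = sum(use), n_border = sum(boundary & !is.na(latent)))
}
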