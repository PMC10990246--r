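#' Co-registered multi-contrast image stack
#'
#' Image-mode input: five co-registered 2-D contrast images (conventionally
#' T1+C, T2, MD, FA, rCBV) plus the region masks the method needs — the
#' tumoral area of interest (AOI), its contrast-enhancing (CE) and
#' non-enhancing (NE) compartments, and a contralateral normal-brain region.
#' Construction enforces the mask algebra: `ce | ne == aoi`, `ce & ne`
#' empty, `aoi & normal` empty, and a single shared grid.
#'
#' @param images named list of numeric matrices, one per contrast, all the
#'   same dimension.
#' @param aoi_mask,ce_mask,ne_mask,normal_mask logical matrices on the same
#'   grid.
#' @param pixel_spacing physical pixel size in mm (metadata only).
#' @return an object of class `wso_contrast_stack`.
#' @export
contrast_stack <- function(images, aoi_mask, ce_mask, ne_mask, normal_mask,
                           pixel_spacing = 1) {
  stopifnot(is.list(images), length(images) >= 1)
  if (is.null(names(images)) || any(names(images) == ""))
    stop("contrast images must be named")
  dims <- dim(images[[1]])
  for (nm in names(images)) {
    if (!identical(dim(images[[nm]]), dims))
      stop("grid mismatch: contrast '", nm, "' has different dimensions")
  }
  masks <- list(aoi = aoi_mask, ce = ce_mask, ne = ne_mask,
                normal = normal_mask)
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), dims))
      stop("grid mismatch: ", nm, " mask has different dimensions")
    storage.mode(masks[[nm]]) <- "logical"
  }
  if (any(masks$ce & masks$ne))
    stop("mask inconsistency: CE and NE overlap")
  if (!identical(masks$ce | masks$ne, masks$aoi))
    stop("mask inconsistency: CE union NE must equal the AOI")
  if (any(masks$aoi & masks$normal))
    stop("mask inconsistency: AOI and normal region overlap")
  structure(
    list(images = images, aoi_mask = masks$aoi, ce_mask = masks$ce,
         ne_mask = masks$ne, normal_mask = masks$normal,
         pixel_spacing = pixel_spacing),
    class = "wso_contrast_stack"
  )
}

#' @export
print.wso_contrast_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat("<wso_contrast_stack> ", d[1], "x", d[2], " pixels, contrasts: ",
      paste(names(x$images), collapse = ", "), "\n", sep = "")
  cat("  AOI ", sum(x$aoi_mask), " px (CE ", sum(x$ce_mask), ", NE ",
      sum(x$ne_mask), "), normal ", sum(x$normal_mask), " px\n", sep = "")
  invisible(x)
}

#' Window-eligible centers within a mask
#'
#' A center is eligible when the whole `size x size` window around it (the
#' half-open convention of [extract_window()]) lies inside `mask`.  Computed
#' with an integral image, so it is cheap even for full-image queries.
#'
#' @param mask logical matrix.
#' @param size window side in pixels.
#' @return logical matrix marking eligible 0-based centers.
#' @export
window_fits_mask <- function(mask, size = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  half <- size %/% 2
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(mask * 1, 2, cumsum), 1, cumsum) |> t()
  fits <- matrix(FALSE, nr, nc)
  # 0-based center (r,c) -> window rows r-half .. r+half-1 (1-based r-half+1 ..)
  rs <- which(seq_len(nr) - 1 >= half & seq_len(nr) - 1 + half <= nr)
  cs <- which(seq_len(nc) - 1 >= half & seq_len(nc) - 1 + half <= nc)
  for (r in rs) {
    r0 <- r - half; r1 <- r + half - 1      # 1-based inclusive
    cnt <- S[r1 + 1, cs + half] - S[r0, cs + half] -
      S[r1 + 1, cs - half] + S[r0, cs - half]
    fits[r, cs] <- cnt == size * size
  }
  fits
}

# 0-based coordinates (n x 2) of TRUE cells of a logical matrix
mask_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  cbind(row = w[, 1] - 1L, col = w[, 2] - 1L)
}
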