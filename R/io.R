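#' Write a training set as a delimited feature table
#'
#' One row per sample with columns `sample_id`, `source` (one of `labeled1`,
#' `labeled2`, `unlabeled12`, `normal0`), `patient_id`, optional
#' `compartment`, then the feature columns in order.
#'
#' @param ts a [training_set()].
#' @param path output file (CSV).
#' @export
write_feature_table <- function(ts, path) {
  stopifnot(inherits(ts, "wso_training_set"))
  blocks <- list(labeled1 = ts$X1, labeled2 = ts$X2,
                 unlabeled12 = ts$X12, normal0 = ts$X0)
  rows <- list()
  sid <- 0L
  for (src in names(blocks)) {
    B <- blocks[[src]]
    if (!nrow(B)) next
    pid <- ts$patient[[sub("labeled1", "X1",
                       sub("labeled2", "X2",
                       sub("unlabeled12", "X12", sub("normal0", "X0", src))))]]
    if (is.null(pid)) pid <- rep(NA_character_, nrow(B))
    comp <- if (src == "unlabeled12" && !is.null(ts$compartment12))
      ts$compartment12 else rep(NA_character_, nrow(B))
    df <- data.frame(sample_id = sprintf("s%05d", sid + seq_len(nrow(B))),
                     source = src, patient_id = pid, compartment = comp)
    sid <- sid + nrow(B)
    rows[[src]] <- cbind(df, as.data.frame(B))
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a delimited feature table into a training set
#'
#' Expects the layout written by [write_feature_table()]: columns
#' `sample_id`, `source`, `patient_id`, optional `compartment`, then numeric
#' feature columns.  Unknown source tags and non-numeric feature values are
#' reported with their row number.
#'
#' @param path CSV file.
#' @return a [training_set()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "source", "patient_id")
  if (!all(required %in% names(df)))
    stop("feature table must have columns ", paste(required, collapse = ", "))
  known <- c("labeled1", "labeled2", "unlabeled12", "normal0")
  bad <- which(!df$source %in% known)
  if (length(bad))
    stop("unknown source tag '", df$source[bad[1]], "' in row ", bad[1])
  meta <- c(required, "compartment")
  fcols <- setdiff(names(df), meta)
  if (!length(fcols)) stop("no feature columns found")
  for (fc in fcols) {
    if (!is.numeric(df[[fc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[fc]]))))
      stop("non-numeric value in feature column ", fc, ", row ",
           if (length(bad)) bad[1] else "?")
    }
  }
  X <- as.matrix(df[fcols])
  pick <- function(src) X[df$source == src, , drop = FALSE]
  pid <- function(src) {
    p <- df$patient_id[df$source == src]
    if (all(is.na(p))) NULL else p
  }
  comp <- if ("compartment" %in% names(df)) {
    cc <- df$compartment[df$source == "unlabeled12"]
    if (all(is.na(cc))) NULL else cc
  } else NULL
  training_set(X1 = pick("labeled1"), X2 = pick("labeled2"),
               X12 = pick("unlabeled12"), X0 = pick("normal0"),
               patient = list(X1 = pid("labeled1"), X2 = pid("labeled2"),
                              X12 = pid("unlabeled12"), X0 = pid("normal0")),
               compartment12 = comp, feature_names = fcols)
}

#' Save a fitted model as JSON
#'
#' Serializes the support expansion, biases, kernel specification, scaler,
#' hyperparameters and feature names at full precision.  Plain-text on
#' purpose: models are small and diffable.
#'
#' @param model a fitted `wsosvm`.
#' @param path output file.
#' @export
save_wsosvm <- function(model, path) {
  stopifnot(inherits(model, "wsosvm"))
  obj <- list(
    format = "wsosvm-model", version = 1L,
    SV = model$SV, coef = model$coef, w = model$w,
    b0 = model$b0, b1 = model$b1,
    kernel = unclass(model$kernel), scaler = model$scaler,
    C1 = model$C1, C2 = model$C2, sizes = as.list(model$sizes),
    feature_names = model$feature_names
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Load a model saved by [save_wsosvm()]
#'
#' @param path JSON file.
#' @return a fitted `wsosvm`.
#' @export
load_wsosvm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "wsosvm-model"))
    stop("not a wsosvm model file: ", path)
  kernel <- do.call(kernel_spec, obj$kernel[c("kind")])
  kernel$gamma <- obj$kernel$gamma
  kernel$degree <- obj$kernel$degree
  kernel$coef0 <- obj$kernel$coef0
  kernel$jitter <- obj$kernel$jitter
  scaler <- if (!is.null(obj$scaler))
    list(center = unlist(obj$scaler$center), scale = unlist(obj$scaler$scale))
  structure(
    list(SV = if (!is.null(obj$SV)) as.matrix(obj$SV) else NULL,
         coef = obj$coef, w = obj$w, b0 = obj$b0, b1 = obj$b1,
         kernel = kernel, scaler = scaler, C1 = obj$C1, C2 = obj$C2,
         sizes = unlist(obj$sizes), feature_names = obj$feature_names),
    class = "wsosvm"
  )
}

#' Read image-mode inputs
#'
#' Loads the five contrast volumes, the four masks and the biopsy table from
#' files and validates the stack invariants.  Volumes may be NIfTI
#' (`.nii`/`.nii.gz`, read via the RNifti package) or headerless CSV
#' matrices; the dialect is chosen by extension.  Biopsy coordinates are
#' 0-based `(row, col)`.
#'
#' @param contrast_paths named character vector of volume files.
#' @param mask_paths named character vector with entries `aoi`, `ce`, `ne`,
#'   `normal`.
#' @param biopsy_path CSV with columns `row`, `col`, `gene`, `status` (and
#'   optionally `patient_id`).
#' @return list with `stack` (a [contrast_stack()]) and `biopsies`.
#' @export
read_image_inputs <- function(contrast_paths, mask_paths, biopsy_path = NULL) {
  read_vol <- function(p) {
    if (grepl("\\.nii(\\.gz)?$", p)) {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("reading NIfTI volumes requires the RNifti package")
      v <- RNifti::readNifti(p)
      matrix(as.numeric(v), dim(v)[1], dim(v)[2])
    } else {
      as.matrix(utils::read.csv(p, header = FALSE))
    }
  }
  images <- lapply(contrast_paths, read_vol)
  names(images) <- names(contrast_paths)
  masks <- lapply(mask_paths, function(p) read_vol(p) > 0.5)
  stack <- contrast_stack(images, masks[["aoi"]], masks[["ce"]],
                          masks[["ne"]], masks[["normal"]])
  biopsies <- NULL
  if (!is.null(biopsy_path)) {
    biopsies <- utils::read.csv(biopsy_path, comment.char = "#",
                                stringsAsFactors = FALSE)
    need <- c("row", "col", "gene", "status")
    if (!all(need %in% names(biopsies)))
      stop("biopsy table must have columns ", paste(need, collapse = ", "))
    if (!all(biopsies$status %in% c(1L, 2L)))
      stop("biopsy status labels must be 1 (non-altered) or 2 (altered)")
    inside <- stack$aoi_mask[cbind(biopsies$row + 1L, biopsies$col + 1L)]
    if (!all(inside))
      stop("biopsy at (", biopsies$row[!inside][1], ",",
           biopsies$col[!inside][1], ") lies outside the tumoral AOI")
  }
  list(stack = stack, biopsies = biopsies)
}

#' Write a synthetic image cohort to disk
#'
#' One directory per patient holding one volume per contrast, the four
#' masks and a biopsy table; NIfTI or CSV dialect by `format`.  The biopsy
#' table starts with a pragma comment stating the 0-based row-major
#' coordinate convention.
#'
#' @param cohort result of [generate_image_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` (default, text-only) or `"nifti"`.
#' @return invisibly, the per-patient directories.
#' @export
write_image_cohort <- function(cohort, dir, format = c("csv", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vol <- function(m, p) {
    if (format == "nifti") {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("writing NIfTI volumes requires the RNifti package")
      RNifti::writeNifti(RNifti::asNifti(m * 1), paste0(p, ".nii.gz"))
    } else {
      utils::write.table(m * 1, paste0(p, ".csv"), sep = ",",
                         row.names = FALSE, col.names = FALSE)
    }
  }
  out <- character(0)
  for (pt in cohort) {
    pd <- file.path(dir, pt$patient_id)
    dir.create(pd, showWarnings = FALSE)
    for (nm in names(pt$stack$images))
      write_vol(pt$stack$images[[nm]], file.path(pd, nm))
    write_vol(pt$stack$aoi_mask, file.path(pd, "mask_aoi"))
    write_vol(pt$stack$ce_mask, file.path(pd, "mask_ce"))
    write_vol(pt$stack$ne_mask, file.path(pd, "mask_ne"))
    write_vol(pt$stack$normal_mask, file.path(pd, "mask_normal"))
    bp <- file.path(pd, "biopsies.csv")
    con <- file(bp, "w")
    writeLines("# coordinates: 0-based (row, col), row-major", con)
    utils::write.csv(pt$biopsies, con, row.names = FALSE, quote = FALSE)
    close(con)
    out <- c(out, pd)
  }
  invisible(out)
}
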