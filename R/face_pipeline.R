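#' Facial zones analysed for erythema
#'
#' The four regions of interest, in canonical order: left cheek, right cheek,
#' nose, chin.
#' @export
FACE_ZONES <- c("left_cheek", "right_cheek", "nose", "chin")

#' Whole-face aggregation weights
#'
#' Cheeks carry 0.35 each, nose and chin 0.15 each (they sum to 1): cheeks
#' dominate the clinical picture of centrofacial erythema.
#' @export
FACE_WEIGHTS <- c(left_cheek = 0.35, right_cheek = 0.35,
                  nose = 0.15, chin = 0.15)

TIMEPOINTS <- c("T0", "T1", "T2")

check_timepoint <- function(timepoint) {
  if (!all(timepoint %in% TIMEPOINTS)) {
    bad <- setdiff(unique(timepoint), TIMEPOINTS)
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "),
         " (expected T0, T1, T2)", call. = FALSE)
  }
  factor(timepoint, levels = TIMEPOINTS)
}

check_weights <- function(weights) {
  if (length(weights) != 4L || any(!is.finite(weights))) {
    stop("weights must be four finite values (left cheek, right cheek, nose, chin)",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("face weights must sum to 1 (got ", format(sum(weights)), ")",
         call. = FALSE)
  }
  stats::setNames(as.numeric(weights), FACE_ZONES)
}

#' Convert an 8-bit RGB image to greyscale luminance
#'
#' Uses the Rec. 601 luma weights 0.299 R + 0.587 G + 0.114 B, rounded
#' half-up to the nearest integer and clamped to \code{[0, 255]}. A 2-D
#' matrix input (already greyscale) is validated and passed through.
#'
#' @param rgb_image H x W x 3 array with integer values in \code{[0, 255]},
#'   or a grey matrix.
#' @return grey image matrix.
#' @export
to_grey <- function(rgb_image) {
  if (is.matrix(rgb_image)) return(as_grey_image(rgb_image))
  if (!is.array(rgb_image) || length(dim(rgb_image)) != 3L ||
      dim(rgb_image)[3] != 3L) {
    stop("expected an H x W x 3 RGB array or a grey matrix, got dims ",
         paste(dim(rgb_image), collapse = "x"), call. = FALSE)
  }
  if (any(rgb_image < 0) || any(rgb_image > 255) ||
      any(rgb_image != floor(rgb_image))) {
    stop("RGB channels must contain integers in [0, 255] (8-bit)",
         call. = FALSE)
  }
  y <- 0.299 * rgb_image[, , 1] + 0.587 * rgb_image[, , 2] +
    0.114 * rgb_image[, , 3]
  y <- matrix(y, dim(rgb_image)[1], dim(rgb_image)[2])  # keep dims for 1x1
  as_grey_image(pmin(pmax(floor(y + 0.5), 0), 255))
}

#' Read a PNG photograph as an 8-bit grey image
#'
#' Greyscale files pass through; RGB(A) files are converted by [to_grey()]
#' (any alpha channel is dropped).
#'
#' @param path PNG file path.
#' @return grey image matrix.
#' @export
read_grey_png <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  x <- png::readPNG(path)
  x255 <- round(x * 255)
  if (is.matrix(x255)) return(as_grey_image(x255))
  nc <- dim(x255)[3]
  if (nc == 2L) return(as_grey_image(x255[, , 1]))       # grey + alpha
  if (nc >= 3L) return(to_grey(x255[, , 1:3, drop = FALSE]))
  stop("unsupported PNG channel count: ", nc, call. = FALSE)
}

#' Read a PNG mask (nonzero = inside the ROI)
#'
#' @param path PNG file path; multi-channel files use the first channel.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  x <- png::readPNG(path)
  if (!is.matrix(x)) x <- x[, , 1]
  x > 0
}

#' Write a grey image or mask to PNG
#'
#' @param image grey image matrix (written as 8-bit grey) or logical mask
#'   (written as 0/255).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_grey_png <- function(image, path) {
  if (is.logical(image)) {
    m <- matrix(as.numeric(image), nrow(image), ncol(image))
  } else {
    m <- as_grey_image(image) / 255
  }
  png::writePNG(m, target = path)
  invisible(path)
}

#' Per-zone texture features of one face
#'
#' @param image grey image.
#' @param masks named list of four logical masks, names exactly
#'   \code{FACE_ZONES}.
#' @param d,angle GLCM offset (defaults 1 pixel, 0 degrees).
#' @param subject,timepoint optional identifiers used in error messages.
#' @return named list zone -> list(contrast, homogeneity, n_pairs).
#' @export
extract_zone_features <- function(image, masks, d = 1L, angle = 0,
                                  subject = NULL, timepoint = NULL) {
  missing_zones <- setdiff(FACE_ZONES, names(masks))
  if (length(missing_zones)) {
    stop("missing ROI mask(s): ", paste(missing_zones, collapse = ", "),
         context_tag(subject, timepoint), call. = FALSE)
  }
  out <- lapply(FACE_ZONES, function(z) {
    tryCatch(
      texture_features(image, masks[[z]], d = d, angle = angle, zone = z),
      error = function(e) {
        stop(conditionMessage(e), context_tag(subject, timepoint),
             call. = FALSE)
      }
    )
  })
  stats::setNames(out, FACE_ZONES)
}

context_tag <- function(subject, timepoint) {
  if (is.null(subject) && is.null(timepoint)) return("")
  paste0(" [subject ", subject %||% "?", ", timepoint ", timepoint %||% "?", "]")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted whole-face texture scores
#'
#' @param per_zone output of [extract_zone_features()].
#' @param weights four weights for (left cheek, right cheek, nose, chin);
#'   must sum to 1.
#' @return list with \code{face_contrast} and \code{face_homogeneity}.
#' @export
aggregate_face <- function(per_zone, weights = FACE_WEIGHTS) {
  weights <- check_weights(weights)
  missing_zones <- setdiff(FACE_ZONES, names(per_zone))
  if (length(missing_zones)) {
    stop("missing zone(s) in aggregation: ",
         paste(missing_zones, collapse = ", "), call. = FALSE)
  }
  contrasts <- vapply(FACE_ZONES, function(z) per_zone[[z]]$contrast, 0)
  homos <- vapply(FACE_ZONES, function(z) per_zone[[z]]$homogeneity, 0)
  list(face_contrast = sum(weights * contrasts),
       face_homogeneity = sum(weights * homos))
}

#' Batch feature extraction over a study manifest
#'
#' The manifest is one row per subject x timepoint with columns
#' \code{subject}, \code{timepoint}, \code{image_path}, \code{mask_lc},
#' \code{mask_rc}, \code{mask_nose}, \code{mask_chin}. Rows are processed in
#' deterministic order (subject, then T0 < T1 < T2); a failing row is
#' recorded and the run continues.
#'
#' @param manifest data frame (or CSV path) with the columns above.
#' @param weights face aggregation weights.
#' @param d,angle GLCM offset.
#' @return list with \code{features} — a long data frame with columns
#'   subject, timepoint, zone (the four zones plus \code{"face"}), contrast,
#'   homogeneity, n_pairs (NA for the face rows) — and \code{errors}, a data
#'   frame of failed rows (subject, timepoint, message).
#' @export
run_batch <- function(manifest, weights = FACE_WEIGHTS, d = 1L, angle = 0) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  needed <- c("subject", "timepoint", "image_path",
              "mask_lc", "mask_rc", "mask_nose", "mask_chin")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  weights <- check_weights(weights)
  if (nrow(manifest) == 0L) {
    warning("empty manifest: no rows to process")
    return(list(features = empty_features_frame(), errors = empty_errors_frame()))
  }
  manifest$timepoint <- as.character(manifest$timepoint)
  check_timepoint(manifest$timepoint)
  ord <- order(manifest$subject, match(manifest$timepoint, TIMEPOINTS))
  manifest <- manifest[ord, , drop = FALSE]

  feat_rows <- list()
  err_rows <- list()
  mask_cols <- c(left_cheek = "mask_lc", right_cheek = "mask_rc",
                 nose = "mask_nose", chin = "mask_chin")
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    res <- tryCatch({
      img <- read_grey_png(row$image_path)
      masks <- lapply(mask_cols, function(col) {
        as_roi_mask(read_mask_png(row[[col]]), img)
      })
      pz <- extract_zone_features(img, masks, d = d, angle = angle,
                                  subject = row$subject,
                                  timepoint = row$timepoint)
      face <- aggregate_face(pz, weights)
      zone_df <- data.frame(
        subject = row$subject, timepoint = row$timepoint, zone = FACE_ZONES,
        contrast = vapply(pz, `[[`, 0, "contrast"),
        homogeneity = vapply(pz, `[[`, 0, "homogeneity"),
        n_pairs = vapply(pz, `[[`, 0L, "n_pairs"),
        stringsAsFactors = FALSE, row.names = NULL
      )
      rbind(zone_df, data.frame(
        subject = row$subject, timepoint = row$timepoint, zone = "face",
        contrast = face$face_contrast, homogeneity = face$face_homogeneity,
        n_pairs = NA_integer_, stringsAsFactors = FALSE
      ))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      err_rows[[length(err_rows) + 1L]] <- data.frame(
        subject = row$subject, timepoint = row$timepoint,
        message = conditionMessage(res), stringsAsFactors = FALSE
      )
    } else {
      feat_rows[[length(feat_rows) + 1L]] <- res
    }
  }
  features <- if (length(feat_rows)) do.call(rbind, feat_rows)
              else empty_features_frame()
  errors <- if (length(err_rows)) do.call(rbind, err_rows)
            else empty_errors_frame()
  rownames(features) <- NULL
  list(features = features, errors = errors)
}

empty_features_frame <- function() {
  data.frame(subject = character(), timepoint = character(),
             zone = character(), contrast = numeric(),
             homogeneity = numeric(), n_pairs = integer(),
             stringsAsFactors = FALSE)
}

empty_errors_frame <- function() {
  data.frame(subject = character(), timepoint = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Write batch features and a JSON run-configuration sidecar
#'
#' @param batch result of [run_batch()].
#' @param path output CSV path; the sidecar goes to \code{<path>.json}.
#' @param config list echoed into the sidecar (weights, offsets, seed, ...).
#' @return \code{path}, invisibly.
#' @export
write_features_csv <- function(batch, path, config = list()) {
  utils::write.csv(batch$features, path, row.names = FALSE, quote = FALSE)
  sidecar <- c(list(package = "glcmface",
                    version = as.character(utils::packageVersion("glcmface")),
                    n_feature_rows = nrow(batch$features),
                    n_errors = nrow(batch$errors)),
               config)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
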