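# Number of grey levels: fixed at 256 (8-bit), never re-quantised.
GLCM_LEVELS <- 256L

#' Validate an 8-bit grey-level image
#'
#' A grey image is an integer (or integer-valued numeric) matrix with every
#' entry in \code{[0, 255]}. This is the unit of texture analysis; no
#' re-quantisation to fewer grey levels is ever performed.
#'
#' @param image numeric or integer matrix.
#' @return the image as an integer matrix, invisibly usable downstream.
#' @export
as_grey_image <- function(image) {
  if (!is.matrix(image)) {
    stop("grey image must be a matrix, got ", class(image)[1], call. = FALSE)
  }
  if (any(!is.finite(image))) {
    stop("grey image contains non-finite values", call. = FALSE)
  }
  if (any(image != floor(image))) {
    stop("grey image must contain integer grey levels", call. = FALSE)
  }
  if (any(image < 0) || any(image > 255)) {
    stop("grey levels must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(image) <- "integer"
  image
}

#' Validate a region-of-interest mask
#'
#' @param mask logical matrix (or 0/1 numeric) congruent with the image it
#'   masks; \code{TRUE} marks pixels inside the region.
#' @param image optional grey image the mask must be congruent with.
#' @param zone optional zone label used in error messages.
#' @return logical matrix.
#' @export
as_roi_mask <- function(mask, image = NULL, zone = NULL) {
  if (!is.matrix(mask)) {
    stop("ROI mask must be a matrix", call. = FALSE)
  }
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) {
      stop("ROI mask must be logical or 0/1", call. = FALSE)
    }
    mask <- mask > 0
  }
  if (anyNA(mask)) stop("ROI mask contains NA", call. = FALSE)
  if (!is.null(image) && !identical(dim(mask), dim(image))) {
    stop(
      "mask shape (", paste(dim(mask), collapse = "x"),
      ") does not match image shape (", paste(dim(image), collapse = "x"), ")",
      if (!is.null(zone)) paste0(" for zone '", zone, "'") else "",
      call. = FALSE
    )
  }
  mask
}

empty_roi_error <- function(zone) {
  stop(
    "empty ROI: no valid horizontal pixel pair",
    if (!is.null(zone)) paste0(" in zone '", zone, "'") else "",
    call. = FALSE
  )
}

#' Grey-level co-occurrence matrix over a masked region
#'
#' Tallies ordered pairs of grey levels for pixels at horizontal offset
#' \code{d} (angle 0 degrees, left pixel then its right neighbour). A pair
#' contributes only when both pixels lie inside the mask; pairs straddling
#' the region boundary are dropped. The tally is asymmetric by default —
#' each pair is counted once, left to right — matching the single-offset
#' construction used in erythema texture scoring; set \code{symmetric = TRUE}
#' to also count the transposed pair.
#'
#' @param image grey image (see [as_grey_image()]).
#' @param mask ROI mask congruent with \code{image}; \code{NULL} means the
#'   whole image.
#' @param d offset distance in pixels (default 1).
#' @param angle offset angle in degrees; only 0 (horizontal) is supported.
#' @param symmetric count each pair in both directions (default \code{FALSE}).
#' @param zone optional zone label, used only to make errors identifiable.
#' @return an object of class \code{"glcm"}: a list with \code{counts}
#'   (256 x 256 integer matrix, rows = left grey level i, columns = right
#'   grey level j, both 0-based in the row/column names), \code{d},
#'   \code{angle}, \code{symmetric} and \code{total_pairs}.
#' @examples
#' img <- matrix(c(0L, 1L, 0L, 1L), nrow = 2, byrow = TRUE)
#' g <- compute_glcm(img)
#' g$counts[1, 2]  # level pair (0,1) occurs twice
#' @export
compute_glcm <- function(image, mask = NULL, d = 1L, angle = 0,
                         symmetric = FALSE, zone = NULL) {
  image <- as_grey_image(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- as_roi_mask(mask, image, zone)
  d <- as.integer(d)
  if (d < 1L) stop("offset distance d must be >= 1", call. = FALSE)
  if (!identical(as.numeric(angle), 0)) {
    stop("only the horizontal direction (angle = 0) is supported", call. = FALSE)
  }
  w <- ncol(image)
  if (w <= d) empty_roi_error(zone)

  left_cols <- seq_len(w - d)
  right_cols <- left_cols + d
  valid <- mask[, left_cols, drop = FALSE] & mask[, right_cols, drop = FALSE]
  n_pairs <- sum(valid)
  if (n_pairs == 0L) empty_roi_error(zone)

  i <- image[, left_cols, drop = FALSE][valid]   # left grey level
  j <- image[, right_cols, drop = FALSE][valid]  # right grey level
  idx <- i * GLCM_LEVELS + j + 1L
  counts <- tabulate(idx, nbins = GLCM_LEVELS * GLCM_LEVELS)
  if (symmetric) {
    counts <- counts + tabulate(j * GLCM_LEVELS + i + 1L,
                                nbins = GLCM_LEVELS * GLCM_LEVELS)
    n_pairs <- 2L * n_pairs
  }
  # row index = i (left level), column index = j: counts filled j-fastest
  counts <- matrix(counts, nrow = GLCM_LEVELS, ncol = GLCM_LEVELS, byrow = TRUE)
  dimnames(counts) <- list(0:(GLCM_LEVELS - 1L), 0:(GLCM_LEVELS - 1L))
  structure(
    list(counts = counts, d = d, angle = angle, symmetric = symmetric,
         total_pairs = as.integer(n_pairs)),
    class = "glcm"
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat("GLCM (", GLCM_LEVELS, " levels, d = ", x$d, ", angle = ", x$angle,
      if (x$symmetric) ", symmetric" else "", "): ",
      x$total_pairs, " pairs\n", sep = "")
  invisible(x)
}

#' Normalise a GLCM to co-occurrence probabilities
#'
#' @param glcm object from [compute_glcm()].
#' @return 256 x 256 numeric matrix P with \code{sum(P) == 1} (within 1e-9).
#' @export
glcm_normalize <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  if (glcm$total_pairs < 1L) empty_roi_error(NULL)
  glcm$counts / glcm$total_pairs
}

check_prob_grid <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop("P must be a square probability matrix", call. = FALSE)
  }
  if (abs(sum(P) - 1) > 1e-9) {
    stop("probability grid does not sum to 1 (got ", format(sum(P)), ")",
         call. = FALSE)
  }
  invisible(P)
}

level_diff_matrix <- function(n) {
  idx <- seq_len(n) - 1L
  outer(idx, idx, "-")
}

#' GLCM contrast
#'
#' \eqn{\sum_{i,j} P(i,j)\,(i-j)^2}: the mean squared grey-level difference
#' between horizontally neighbouring pixels. Rises with irregular, lesional
#' skin texture; 0 exactly when all co-occurring pairs have equal levels.
#'
#' @param P normalised probability grid from [glcm_normalize()].
#' @return non-negative scalar (relative units).
#' @export
glcm_contrast <- function(P) {
  check_prob_grid(P)
  D <- level_diff_matrix(nrow(P))
  sum(P * D * D)
}

#' GLCM homogeneity
#'
#' \eqn{\sum_{i,j} P(i,j) / (1 + |i-j|)}: probability mass concentrated near
#' the diagonal. Lies in (0, 1]; equals 1 exactly when contrast is 0.
#'
#' @inheritParams glcm_contrast
#' @return scalar in (0, 1].
#' @export
glcm_homogeneity <- function(P) {
  check_prob_grid(P)
  D <- level_diff_matrix(nrow(P))
  sum(P / (1 + abs(D)))
}

#' Contrast and homogeneity of a masked region in one call
#'
#' @inheritParams compute_glcm
#' @return list with \code{contrast}, \code{homogeneity}, \code{n_pairs}.
#' @export
texture_features <- function(image, mask = NULL, d = 1L, angle = 0,
                             zone = NULL) {
  g <- compute_glcm(image, mask, d = d, angle = angle, zone = zone)
  P <- glcm_normalize(g)
  list(contrast = glcm_contrast(P), homogeneity = glcm_homogeneity(P),
       n_pairs = g$total_pairs)
}

#' Brute-force GLCM oracle
#'
#' Same contract as [compute_glcm()] implemented as a naive double loop over
#' every pixel. Exists so the vectorised construction can be checked cell by
#' cell in tests; never used in the pipeline.
#'
#' @inheritParams compute_glcm
#' @return object of class \code{"glcm"}.
#' @export
glcm_brute_force_oracle <- function(image, mask = NULL, d = 1L, angle = 0,
                                    zone = NULL) {
  image <- as_grey_image(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- as_roi_mask(mask, image, zone)
  d <- as.integer(d)
  if (!identical(as.numeric(angle), 0)) {
    stop("only the horizontal direction (angle = 0) is supported", call. = FALSE)
  }
  counts <- matrix(0L, GLCM_LEVELS, GLCM_LEVELS,
                   dimnames = list(0:255, 0:255))
  n_pairs <- 0L
  for (r in seq_len(nrow(image))) {
    for (c in seq_len(ncol(image) - d)) {
      if (mask[r, c] && mask[r, c + d]) {
        i <- image[r, c] + 1L
        j <- image[r, c + d] + 1L
        counts[i, j] <- counts[i, j] + 1L
        n_pairs <- n_pairs + 1L
      }
    }
  }
  if (n_pairs == 0L) empty_roi_error(zone)
  structure(
    list(counts = counts, d = d, angle = angle, symmetric = FALSE,
         total_pairs = n_pairs),
    class = "glcm"
  )
}
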