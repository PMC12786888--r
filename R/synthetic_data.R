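# Deterministic synthetic study: cross-polarized-style facial images with
# clustered erythema lesions and telangiectasia that respond to treatment,
# fixed per-subject ROI masks, and noisy three-rater CEA grades.

#' Simulation configuration
#'
#' Defaults mirror a 20-subject, three-timepoint phototherapy study on
#' 512 x 512 cross-polarized facial photographs. Erythema appears as
#' darkened blobs in greyscale (red lesions absorb in the green channel that
#' dominates luminance); thin dark random-walk streaks emulate
#' telangiectasia, the main fine-texture driver. Treatment multiplies all
#' lesion amplitudes by \code{effect_T1} (resp. \code{effect_T2}); 1 means no
#' effect, the default 0.4 a strong durable response.
#'
#' @param n_subjects number of subjects (default 20).
#' @param image_size side of the square image in pixels (default 512).
#' @param base_skin_level healthy-skin grey level (default 180).
#' @param lesion_count_range integer range of lesion blobs per zone
#'   (default 2..6).
#' @param lesion_amplitude grey-level depression of a lesion blob at
#'   baseline (default 40).
#' @param lesion_scale Gaussian radius of a blob in pixels; default scales
#'   with the image (\code{image_size / 64}, at least 1).
#' @param telangiectasia_count streaks per cheek (default 3).
#' @param telangiectasia_amplitude grey-level depth of a streak at baseline;
#'   default 0.75 x \code{lesion_amplitude}.
#' @param effect_T1,effect_T2 multiplicative amplitude factors in
#'   \code{[0, 1]} at the two post-treatment timepoints (defaults 0.4).
#' @param noise_sd additive Gaussian sensor noise in grey levels
#'   (default 1.5; the iid-noise floor of GLCM contrast is 2 sd^2, so 1.5
#'   keeps healthy skin well below lesional texture).
#' @param rater_bias_sd between-rater systematic offset SD in CEA units
#'   (default 0.15; calibrated so the panel agrees completely on roughly
#'   half to two-thirds of assessments).
#' @param rater_noise_sd per-assessment rater noise SD in CEA units
#'   (default 0.2).
#' @param cea_gain CEA grade expected per unit of true severity (mean
#'   within-zone grey-level depression); default 0.3 calibrates baseline
#'   severity to moderate-to-severe grades.
#' @param seed integer master seed; everything flows from it.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_subjects = 20L, image_size = 512L,
                       base_skin_level = 180, lesion_count_range = c(2L, 6L),
                       lesion_amplitude = 40, lesion_scale = NULL,
                       telangiectasia_count = 3L,
                       telangiectasia_amplitude = NULL,
                       effect_T1 = 0.4, effect_T2 = 0.4, noise_sd = 1.5,
                       rater_bias_sd = 0.15, rater_noise_sd = 0.2,
                       cea_gain = 0.3, seed = 1L) {
  if (image_size < 48L) {
    stop("image_size ", image_size, " too small: facial zones do not fit ",
         "(need >= 48)", call. = FALSE)
  }
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (any(c(effect_T1, effect_T2) < 0) || any(c(effect_T1, effect_T2) > 1)) {
    stop("effect factors must lie in [0, 1]", call. = FALSE)
  }
  if (length(lesion_count_range) != 2L || any(lesion_count_range < 0) ||
      lesion_count_range[1] > lesion_count_range[2]) {
    stop("lesion_count_range must be a non-negative increasing pair",
         call. = FALSE)
  }
  if (lesion_amplitude < 0 || noise_sd < 0 || telangiectasia_count < 0) {
    stop("amplitudes, noise and counts must be non-negative", call. = FALSE)
  }
  if (is.null(lesion_scale)) lesion_scale <- max(1, image_size / 64)
  if (is.null(telangiectasia_amplitude)) {
    telangiectasia_amplitude <- 0.75 * lesion_amplitude
  }
  structure(list(
    n_subjects = as.integer(n_subjects), image_size = as.integer(image_size),
    base_skin_level = base_skin_level,
    lesion_count_range = as.integer(lesion_count_range),
    lesion_amplitude = lesion_amplitude, lesion_scale = lesion_scale,
    telangiectasia_count = as.integer(telangiectasia_count),
    telangiectasia_amplitude = telangiectasia_amplitude,
    effect_T1 = effect_T1, effect_T2 = effect_T2, noise_sd = noise_sd,
    rater_bias_sd = rater_bias_sd, rater_noise_sd = rater_noise_sd,
    cea_gain = cea_gain, seed = as.integer(seed)
  ), class = "sim_config")
}

effect_factor <- function(config, timepoint) {
  switch(timepoint, T0 = 1, T1 = config$effect_T1, T2 = config$effect_T2,
         stop("unknown timepoint: ", timepoint, call. = FALSE))
}

# Stable substream seed from the master seed and string tags; stays < 2^31.
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (part in c(...)) {
    for (code in utf8ToInt(as.character(part))) {
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h)
}

# Zone geometry in relative coordinates (cy, cx, ry, rx).
ZONE_GEOMETRY <- list(
  left_cheek  = c(0.55, 0.27, 0.14, 0.11),
  right_cheek = c(0.55, 0.73, 0.14, 0.11),
  nose        = c(0.48, 0.50, 0.11, 0.07),
  chin        = c(0.84, 0.50, 0.07, 0.11)
)

subject_id <- function(i) sprintf("S%02d", i)

# Subject-level latent state: mask jitter, severity multiplier, shading,
# lesion and streak geometry. Fixed across timepoints by construction.
subject_state <- function(config, subject) {
  set.seed(derive_seed(config$seed, "subject", subject))
  size <- config$image_size
  jitter <- stats::runif(8, -0.02, 0.02)
  geom <- ZONE_GEOMETRY
  for (k in seq_along(geom)) {
    geom[[k]][1:2] <- geom[[k]][1:2] + jitter[(2 * k - 1):(2 * k)]
  }
  severity_mult <- stats::runif(1, 0.5, 1.5)
  shading <- list(amp = stats::runif(2, 0, 5), phase = stats::runif(2, 0, 2 * pi),
                  freq = stats::runif(2, 0.5, 1.5))
  lesions <- list()
  for (z in FACE_ZONES) {
    g <- geom[[z]]
    counts <- seq(config$lesion_count_range[1], config$lesion_count_range[2])
    n_les <- counts[sample.int(length(counts), 1)]  # safe when range collapses
    if (n_les > 0) {
      theta <- stats::runif(n_les, 0, 2 * pi)
      rad <- sqrt(stats::runif(n_les))
      lesions[[z]] <- data.frame(
        row = (g[1] + 0.8 * rad * sin(theta) * g[3]) * size,
        col = (g[2] + 0.8 * rad * cos(theta) * g[4]) * size,
        sigma = config$lesion_scale * stats::runif(n_les, 0.7, 1.4),
        amp = config$lesion_amplitude * severity_mult *
          stats::runif(n_les, 0.7, 1.3)
      )
    } else {
      lesions[[z]] <- data.frame(row = numeric(), col = numeric(),
                                 sigma = numeric(), amp = numeric())
    }
  }
  streaks <- list()
  for (z in c("left_cheek", "right_cheek")) {
    g <- geom[[z]]
    zs <- list()
    n_str <- config$telangiectasia_count
    if (n_str > 0) {
      for (s in seq_len(n_str)) {
        len <- round(size * stats::runif(1, 0.15, 0.3))
        ang <- stats::runif(1, 0, 2 * pi)
        turns <- stats::rnorm(len, 0, 0.25)
        r0 <- (g[1] + stats::runif(1, -0.5, 0.5) * g[3]) * size
        c0 <- (g[2] + stats::runif(1, -0.5, 0.5) * g[4]) * size
        angs <- ang + cumsum(turns)
        zs[[s]] <- list(
          rows = r0 + cumsum(sin(angs)),
          cols = c0 + cumsum(cos(angs)),
          amp = config$telangiectasia_amplitude * severity_mult *
            stats::runif(1, 0.7, 1.3)
        )
      }
    }
    streaks[[z]] <- zs
  }
  list(geometry = geom, severity_mult = severity_mult, shading = shading,
       lesions = lesions, streaks = streaks)
}

ellipse_mask <- function(size, g) {
  rows <- (seq_len(size) / size - g[1]) / g[3]
  cols <- (seq_len(size) / size - g[2]) / g[4]
  outer(rows^2, cols^2, "+") <= 1
}

#' Ground-truth ROI masks of one synthetic subject
#'
#' Elliptical zones with small per-subject placement jitter; identical
#' across timepoints.
#'
#' @param config [sim_config()].
#' @param subject subject identifier (e.g. \code{"S01"}).
#' @return named list of four logical masks.
#' @export
zone_masks <- function(config, subject) {
  st <- subject_state(config, subject)
  out <- lapply(FACE_ZONES, function(z) {
    ellipse_mask(config$image_size, st$geometry[[z]])
  })
  stats::setNames(out, FACE_ZONES)
}

stamp_blob <- function(field, row, col, sigma, amp) {
  size <- nrow(field)
  r <- max(1L, floor(row - 4 * sigma)):min(size, ceiling(row + 4 * sigma))
  c <- max(1L, floor(col - 4 * sigma)):min(size, ceiling(col + 4 * sigma))
  if (!length(r) || !length(c)) return(field)
  g <- amp * exp(-outer((r - row)^2, (c - col)^2, "+") / (2 * sigma^2))
  field[r, c] <- field[r, c] + g
  field
}

stamp_streak <- function(field, rows, cols, amp, sigma) {
  size <- nrow(field)
  half <- ceiling(3 * sigma)
  for (s in seq_along(rows)) {
    row <- rows[s]; col <- cols[s]
    if (row < 1 - half || row > size + half ||
        col < 1 - half || col > size + half) next
    r <- max(1L, floor(row - half)):min(size, ceiling(row + half))
    c <- max(1L, floor(col - half)):min(size, ceiling(col + half))
    g <- amp * exp(-outer((r - row)^2, (c - col)^2, "+") / (2 * sigma^2))
    field[r, c] <- pmax(field[r, c], g)
  }
  field
}

# Noiseless lesion field (grey-level depression) at a given timepoint.
lesion_field <- function(config, state, timepoint) {
  size <- config$image_size
  eff <- effect_factor(config, timepoint)
  field <- matrix(0, size, size)
  for (z in FACE_ZONES) {
    les <- state$lesions[[z]]
    for (l in seq_len(nrow(les))) {
      field <- stamp_blob(field, les$row[l], les$col[l], les$sigma[l],
                          eff * les$amp[l])
    }
  }
  sigma_t <- max(0.8, size / 400)
  tel <- matrix(0, size, size)
  for (z in c("left_cheek", "right_cheek")) {
    for (st in state$streaks[[z]]) {
      tel <- stamp_streak(tel, st$rows, st$cols, eff * st$amp, sigma_t)
    }
  }
  field + tel
}

base_field <- function(config, state) {
  size <- config$image_size
  sh <- state$shading
  rows <- sin(2 * pi * sh$freq[1] * seq_len(size) / size + sh$phase[1])
  cols <- sin(2 * pi * sh$freq[2] * seq_len(size) / size + sh$phase[2])
  config$base_skin_level + sh$amp[1] * matrix(rows, size, size) +
    sh$amp[2] * matrix(cols, size, size, byrow = TRUE)
}

#' Render one synthetic face
#'
#' Smooth base-skin field minus Gaussian lesion blobs and thin dark
#' curvilinear telangiectasia, scaled by the timepoint's treatment effect,
#' plus additive Gaussian noise, rounded and clamped to \code{[0, 255]}.
#' True severity is the mean grey-level depression of the noiseless lesion
#' field over each zone mask.
#'
#' @param config [sim_config()].
#' @param subject subject identifier.
#' @param timepoint \code{"T0"}, \code{"T1"} or \code{"T2"}.
#' @return list with \code{image} (grey matrix), \code{masks} (four logical
#'   matrices) and \code{truth} (one-row data frame: subject, timepoint,
#'   per-zone severities, face_severity).
#' @export
render_face <- function(config, subject, timepoint) {
  stopifnot(inherits(config, "sim_config"))
  check_timepoint(timepoint)
  state <- subject_state(config, subject)
  size <- config$image_size
  lesions <- lesion_field(config, state, timepoint)
  set.seed(derive_seed(config$seed, "noise", subject, timepoint))
  noise <- matrix(stats::rnorm(size * size, 0, config$noise_sd), size, size)
  img <- base_field(config, state) - lesions + noise
  img <- as_grey_image(pmin(pmax(floor(img + 0.5), 0), 255))
  masks <- lapply(FACE_ZONES, function(z) ellipse_mask(size, state$geometry[[z]]))
  names(masks) <- FACE_ZONES
  sev <- vapply(FACE_ZONES, function(z) mean(lesions[masks[[z]]]), 0)
  truth <- data.frame(subject = subject, timepoint = timepoint,
                      t(sev), face_severity = sum(FACE_WEIGHTS * sev),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(image = img, masks = masks, truth = truth)
}

#' Systematic rater offsets of the synthetic rater panel
#'
#' @param config [sim_config()].
#' @return named numeric vector of per-rater biases (CEA units) for S1-S3.
#' @export
rater_biases <- function(config) {
  set.seed(derive_seed(config$seed, "raters"))
  stats::setNames(stats::rnorm(3, 0, config$rater_bias_sd), RATERS)
}

#' Noisy ordinal grades for one assessment
#'
#' Linear-in-severity rater model:
#' \code{grade = clamp(round(gain * severity + bias + noise), 0, 4)} —
#' the minimal model producing realistic, imperfect inter-rater agreement.
#'
#' @param config [sim_config()].
#' @param subject,timepoint identify the assessment (fix the noise
#'   substream).
#' @param face_severity true whole-face severity from [render_face()].
#' @param biases per-rater offsets, default [rater_biases()].
#' @return named integer vector of grades for S1, S2, S3.
#' @export
rate_cea <- function(config, subject, timepoint, face_severity,
                     biases = rater_biases(config)) {
  set.seed(derive_seed(config$seed, "cea", subject, timepoint))
  noise <- stats::rnorm(length(biases), 0, config$rater_noise_sd)
  raw <- config$cea_gain * face_severity + biases + noise
  grades <- pmin(pmax(round(raw), 0), 4)
  stats::setNames(as.integer(grades), names(biases))
}

#' Run the whole synthetic study in memory
#'
#' Renders every subject x timepoint, extracts GLCM features through the
#' face pipeline and grades every assessment; nothing is written to disk.
#'
#' @param config [sim_config()].
#' @param d,angle GLCM offset passed to the pipeline.
#' @return list with \code{features} (long data frame, zones + face),
#'   \code{cea} (long data frame subject/timepoint/rater/grade) and
#'   \code{truth} (per subject x timepoint severities).
#' @export
simulate_features <- function(config, d = 1L, angle = 0) {
  biases <- rater_biases(config)
  feat <- list(); cea <- list(); truth <- list()
  for (i in seq_len(config$n_subjects)) {
    sub <- subject_id(i)
    for (tp in TIMEPOINTS) {
      rf <- render_face(config, sub, tp)
      pz <- extract_zone_features(rf$image, rf$masks, d = d, angle = angle,
                                  subject = sub, timepoint = tp)
      face <- aggregate_face(pz)
      zone_df <- data.frame(
        subject = sub, timepoint = tp, zone = FACE_ZONES,
        contrast = vapply(pz, `[[`, 0, "contrast"),
        homogeneity = vapply(pz, `[[`, 0, "homogeneity"),
        n_pairs = vapply(pz, `[[`, 0L, "n_pairs"),
        stringsAsFactors = FALSE, row.names = NULL
      )
      feat[[length(feat) + 1L]] <- rbind(zone_df, data.frame(
        subject = sub, timepoint = tp, zone = "face",
        contrast = face$face_contrast, homogeneity = face$face_homogeneity,
        n_pairs = NA_integer_, stringsAsFactors = FALSE
      ))
      grades <- rate_cea(config, sub, tp, rf$truth$face_severity, biases)
      cea[[length(cea) + 1L]] <- data.frame(
        subject = sub, timepoint = tp, rater = names(grades),
        grade = unname(grades), stringsAsFactors = FALSE
      )
      truth[[length(truth) + 1L]] <- rf$truth
    }
  }
  list(features = do.call(rbind, feat), cea = do.call(rbind, cea),
       truth = do.call(rbind, truth))
}

#' Write a complete synthetic study to disk
#'
#' Produces PNG images and masks, the batch manifest, the CEA grade table
#' and the ground truth; byte-identical across runs under one seed.
#'
#' @param config [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the manifest data frame.
#' @export
generate_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  biases <- rater_biases(config)
  manifest <- list(); cea <- list(); truth <- list()
  zone_suffix <- c(left_cheek = "lc", right_cheek = "rc",
                   nose = "nose", chin = "chin")
  for (i in seq_len(config$n_subjects)) {
    sub <- subject_id(i)
    for (tp in TIMEPOINTS) {
      rf <- render_face(config, sub, tp)
      img_path <- file.path(out_dir, sprintf("%s_%s.png", sub, tp))
      write_grey_png(rf$image, img_path)
      mask_paths <- character(0)
      for (z in FACE_ZONES) {
        mp <- file.path(out_dir, sprintf("%s_%s_%s.png", sub, tp, z))
        write_grey_png(rf$masks[[z]], mp)
        mask_paths[z] <- mp
      }
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject = sub, timepoint = tp, image_path = img_path,
        mask_lc = mask_paths[["left_cheek"]],
        mask_rc = mask_paths[["right_cheek"]],
        mask_nose = mask_paths[["nose"]],
        mask_chin = mask_paths[["chin"]],
        stringsAsFactors = FALSE
      )
      grades <- rate_cea(config, sub, tp, rf$truth$face_severity, biases)
      cea[[length(cea) + 1L]] <- data.frame(
        subject = sub, timepoint = tp, rater = names(grades),
        grade = unname(grades), stringsAsFactors = FALSE
      )
      truth[[length(truth) + 1L]] <- rf$truth
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, cea), file.path(out_dir, "cea.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, truth), file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
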