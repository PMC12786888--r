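RATERS <- c("S1", "S2", "S3")

check_grades <- function(grades) {
  if (length(grades) < 1L) stop("no CEA grades supplied", call. = FALSE)
  if (any(!is.finite(grades)) || any(grades != floor(grades)) ||
      any(grades < 0) || any(grades > 4)) {
    stop("CEA grades must be integers in [0, 4]", call. = FALSE)
  }
  invisible(grades)
}

#' Mean clinician erythema grade of one assessment
#'
#' The CEA is a five-level ordinal scale (0 = no erythema ... 4 = severe);
#' an assessment is typically graded independently by three raters and the
#' unrounded arithmetic mean is carried forward.
#'
#' @param grades integer grades in \code{[0, 4]}, one per rater.
#' @return mean grade in \code{[0, 4]}, unrounded.
#' @export
mean_cea <- function(grades) {
  check_grades(grades)
  mean(grades)
}

#' Complete inter-rater agreement
#'
#' Fraction of assessments on which all raters issued the identical grade.
#'
#' @param cea data frame with columns \code{subject}, \code{timepoint},
#'   \code{rater}, \code{grade} (long format, all raters present for every
#'   subject x timepoint).
#' @param raters expected rater identifiers (default S1, S2, S3).
#' @return list with \code{agree}, \code{total} and \code{percent}.
#' @export
complete_agreement_fraction <- function(cea, raters = RATERS) {
  cea <- check_cea_frame(cea, raters)
  key <- interaction(cea$subject, cea$timepoint, drop = TRUE)
  per <- tapply(cea$grade, key, function(g) length(unique(g)) == 1L)
  agree <- sum(per)
  total <- length(per)
  list(agree = as.integer(agree), total = as.integer(total),
       percent = 100 * agree / total)
}

check_cea_frame <- function(cea, raters = RATERS) {
  needed <- c("subject", "timepoint", "rater", "grade")
  missing_cols <- setdiff(needed, names(cea))
  if (length(missing_cols)) {
    stop("CEA table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_grades(cea$grade)
  key <- interaction(cea$subject, cea$timepoint, drop = TRUE)
  counts <- tapply(cea$rater, key, function(r) length(unique(r)))
  if (any(counts != length(raters))) {
    bad <- names(counts)[counts != length(raters)]
    stop("assessment(s) without all ", length(raters), " raters: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  cea
}

#' Per-session treatment energy summaries
#'
#' @param energies data frame with columns \code{subject}, \code{e1},
#'   \code{e2}, \code{e3}: energy density (J/cm2) delivered at each of the
#'   three sessions.
#' @return data frame with one row per session: \code{session}, \code{mean},
#'   \code{sd} (sample SD, n - 1 denominator), unrounded.
#' @export
energy_summary <- function(energies) {
  needed <- c("e1", "e2", "e3")
  if (nrow(energies) == 0L) stop("no treatment records", call. = FALSE)
  missing_cols <- setdiff(needed, names(energies))
  if (length(missing_cols)) {
    stop("treatment table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(energies[needed])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("energy densities must be positive", call. = FALSE)
  }
  data.frame(
    session = 1:3,
    mean = colMeans(vals),
    sd = apply(vals, 2, stats::sd),
    row.names = NULL
  )
}

#' Packaged per-subject treatment energies
#'
#' The 20-subject table of per-session energy densities (J/cm2) shipped
#' with the package, used by the arithmetic self-checks.
#'
#' @return data frame with columns subject, e1, e2, e3.
#' @export
treatment_energy_table <- function() {
  utils::read.csv(
    system.file("extdata", "treatment_energy.csv", package = "glcmface",
                mustWork = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Percent change between two positive values
#'
#' \code{100 * (before - after) / before} when reported as a decrease, and
#' \code{100 * (after - before) / before} when reported as an increase.
#' Rounding happens only at presentation.
#'
#' @param before,after positive values.
#' @param direction \code{"decrease"} (default) or \code{"increase"}.
#' @return signed percent change (positive when the value moved in the
#'   stated direction).
#' @export
percent_change <- function(before, after, direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  if (!is.finite(before) || before <= 0) {
    stop("'before' must be positive", call. = FALSE)
  }
  if (direction == "decrease") 100 * (before - after) / before
  else 100 * (after - before) / before
}

#' Spearman rank correlation with t-distribution inference
#'
#' Mid-ranks (average ranks on ties) are taken on each variable, rho is
#' their Pearson correlation, and inference uses
#' \eqn{t = \rho\sqrt{n-2}/\sqrt{1-\rho^2}} against t with n - 2 degrees of
#' freedom (two-sided) — the convention used in clinical correlation tables.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list with \code{n}, \code{rho}, \code{t_stat}, \code{p}.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    t_stat <- sign(rho) * Inf
    p <- 0
  } else {
    t_stat <- rho * sqrt(n - 2) / sqrt(1 - rho^2)
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(n = n, rho = rho, t_stat = t_stat, p = p)
}

#' Friedman rank test with Dunn post hoc comparisons
#'
#' Repeated-measures rank test across the three timepoints with the Conover
#' tie correction (mid-ranks within each subject). When there are k = 3
#' conditions the post hoc layer runs Dunn's pairwise z tests on mean ranks
#' with Bonferroni adjustment over the three comparisons.
#'
#' @param values numeric matrix, one row per subject, one column per
#'   timepoint (columns named, default T0/T1/T2). No missing cells.
#' @return list with \code{statistic} (chi-square), \code{df}, \code{p} and
#'   \code{posthoc}, a data frame with columns pair, z, p_unadj, p_adj.
#' @export
friedman_with_dunn <- function(values) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- TIMEPOINTS[seq_len(ncol(values))]
  }
  n <- nrow(values); k <- ncol(values)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (k < 2L) stop("need at least 2 timepoints", call. = FALSE)
  if (anyNA(values)) {
    bad <- which(apply(values, 1, anyNA))
    stop("missing cells for subject row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (no imputation performed)", call. = FALSE)
  }
  r <- t(apply(values, 1, rank))         # mid-ranks within subject
  Rj <- colSums(r)
  A <- sum(r^2)                           # Conover tie-corrected form
  C <- n * k * (k + 1)^2 / 4
  ss <- sum((Rj - n * (k + 1) / 2)^2)
  if (A - C <= 0) {                       # all rows fully tied
    statistic <- 0
    p <- 1
  } else {
    statistic <- (k - 1) * ss / (A - C)
    p <- stats::pchisq(statistic, df = k - 1, lower.tail = FALSE)
  }
  pairs <- utils::combn(colnames(values), 2)
  n_comp <- ncol(pairs)
  se <- sqrt(k * (k + 1) / (6 * n))       # SE of a mean-rank difference
  posthoc <- do.call(rbind, lapply(seq_len(n_comp), function(m) {
    a <- pairs[1, m]; b <- pairs[2, m]
    z <- (Rj[a] / n - Rj[b] / n) / se
    p_un <- 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste0(a, "v", b), z = unname(z),
               p_unadj = unname(p_un),
               p_adj = min(1, n_comp * unname(p_un)),
               stringsAsFactors = FALSE)
  }))
  list(statistic = statistic, df = k - 1L, p = p, posthoc = posthoc)
}

check_study_features <- function(features) {
  needed <- c("subject", "timepoint", "zone", "contrast", "homogeneity")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols)) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_timepoint(features$timepoint)
  tp_per_subject <- tapply(features$timepoint, features$subject,
                           function(t) length(unique(t)))
  if (any(tp_per_subject != 3L)) {
    bad <- names(tp_per_subject)[tp_per_subject != 3L]
    stop("subject(s) without all three timepoints: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (length(tp_per_subject) < 3L) {
    stop("need at least 3 subjects with all three timepoints", call. = FALSE)
  }
  features
}

#' Subjects x timepoints matrix of one feature in one zone
#'
#' Reshapes the long feature table into the wide per-subject matrix consumed
#' by [friedman_with_dunn()].
#'
#' @param features long feature data frame (subject, timepoint, zone, ...).
#' @param z zone name (one of the four zones or \code{"face"}).
#' @param what \code{"contrast"} or \code{"homogeneity"}.
#' @return numeric matrix, rows = subjects, columns = T0/T1/T2.
#' @export
zone_matrix <- function(features, z, what) {
  sub <- features[features$zone == z, c("subject", "timepoint", what)]
  wide <- stats::reshape(sub, idvar = "subject", timevar = "timepoint",
                         direction = "wide")
  m <- as.matrix(wide[, paste(what, TIMEPOINTS, sep = "."), drop = FALSE])
  dimnames(m) <- list(wide$subject, TIMEPOINTS)
  m
}

#' Full longitudinal study analysis
#'
#' Runs the complete statistical layer on a feature table (output of
#' [run_batch()], zones plus the aggregated face) and a CEA grade table:
#' per-timepoint medians, percent changes from baseline, Friedman + Dunn per
#' zone and for the face (contrast and homogeneity), complete-agreement
#' statistics, and per-timepoint Spearman correlations of the mean CEA grade
#' with the face-level features.
#'
#' @param features long feature data frame (subject, timepoint, zone,
#'   contrast, homogeneity); zone must include the four facial zones and
#'   \code{"face"}.
#' @param cea long CEA data frame (subject, timepoint, rater, grade);
#'   optional — omit to skip the clinician layer.
#' @param alpha significance threshold (default 0.05).
#' @return list of class \code{"glcmface_analysis"} with elements
#'   \code{zones} (per zone x feature: medians, percent changes, Friedman
#'   results), \code{agreement}, \code{correlations} and \code{alpha}.
#' @export
study_analysis <- function(features, cea = NULL, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  features <- check_study_features(features)
  zones <- intersect(c(FACE_ZONES, "face"), unique(features$zone))
  res_zones <- list()
  for (z in zones) {
    for (what in c("contrast", "homogeneity")) {
      m <- zone_matrix(features, z, what)
      med <- apply(m, 2, stats::median)
      dir <- if (what == "contrast") "decrease" else "increase"
      res_zones[[paste(z, what, sep = ".")]] <- list(
        zone = z, feature = what,
        medians = med,
        pct_change_T0_T1 = percent_change(med["T0"], med["T1"], dir),
        pct_change_T0_T2 = percent_change(med["T0"], med["T2"], dir),
        friedman = friedman_with_dunn(m)
      )
    }
  }
  agreement <- NULL
  correlations <- NULL
  if (!is.null(cea)) {
    cea <- check_cea_frame(cea)
    agreement <- complete_agreement_fraction(cea)
    mg <- stats::aggregate(grade ~ subject + timepoint, data = cea, FUN = mean)
    names(mg)[names(mg) == "grade"] <- "mean_cea"
    mg$timepoint <- as.character(mg$timepoint)
    face <- features[features$zone == "face", ]
    merged <- merge(mg, face, by = c("subject", "timepoint"))
    correlations <- do.call(rbind, lapply(TIMEPOINTS, function(tp) {
      sub <- merged[merged$timepoint == tp, ]
      rows <- lapply(c("contrast", "homogeneity"), function(what) {
        s <- spearman_cor(sub$mean_cea, sub[[what]])
        data.frame(timepoint = tp, feature = what, N = s$n, R = s$rho,
                   t = s$t_stat, p = s$p, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
  }
  structure(list(zones = res_zones, agreement = agreement,
                 correlations = correlations, alpha = alpha),
            class = "glcmface_analysis")
}

#' @export
print.glcmface_analysis <- function(x, ...) {
  cat("glcmface study analysis (alpha =", x$alpha, ")\n")
  for (nm in names(x$zones)) {
    z <- x$zones[[nm]]
    cat(sprintf("  %-24s medians %s | T0->T1 %+.2f%% T0->T2 %+.2f%% | Friedman p = %.3g\n",
                nm, paste(sprintf("%.3f", z$medians), collapse = "/"),
                z$pct_change_T0_T1, z$pct_change_T0_T2, z$friedman$p))
  }
  if (!is.null(x$agreement)) {
    cat(sprintf("  complete agreement: %d/%d (%.1f%%)\n",
                x$agreement$agree, x$agreement$total, x$agreement$percent))
  }
  if (!is.null(x$correlations)) {
    cat("  mean CEA vs face features (Spearman):\n")
    print(x$correlations, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper over [stats::shapiro.test()] for report lines that justify
#' the nonparametric test choice; not part of the inferential pipeline.
#'
#' @param x numeric vector.
#' @return list with \code{W} and \code{p}.
#' @export
normality_screen <- function(x) {
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}
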