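# Shared fixture builders. Everything is generated in code; no binary files.

random_grey_image <- function(nr = 16, nc = 16, levels = 0:255) {
  matrix(sample(levels, nr * nc, replace = TRUE), nr, nc)
}

random_mask <- function(nr = 16, nc = 16, p_inside = 0.7) {
  m <- matrix(stats::runif(nr * nc) < p_inside, nr, nc)
  # guarantee at least one horizontal pair
  r <- sample(nr, 1); c <- sample(nc - 1, 1)
  m[r, c] <- TRUE; m[r, c + 1] <- TRUE
  m
}

# Probability grid with mass on explicit (i, j, p) triples (0-based levels).
prob_grid <- function(triples, n = 256) {
  P <- matrix(0, n, n)
  for (t in triples) P[t[1] + 1, t[2] + 1] <- P[t[1] + 1, t[2] + 1] + t[3]
  P
}

# Long feature frame for study_analysis from per-zone value matrices:
# vals is a named list zone -> n x 3 matrix (T0, T1, T2).
feature_frame <- function(contrast_vals, homogeneity_vals = NULL) {
  if (is.null(homogeneity_vals)) {
    homogeneity_vals <- lapply(contrast_vals, function(m) 1 / (1 + m))
  }
  rows <- list()
  for (z in names(contrast_vals)) {
    m <- contrast_vals[[z]]; h <- homogeneity_vals[[z]]
    for (i in seq_len(nrow(m))) for (tp in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", i), timepoint = c("T0", "T1", "T2")[tp],
        zone = z, contrast = m[i, tp], homogeneity = h[i, tp],
        n_pairs = 100L, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Random three-rater CEA fixture in long format.
random_cea_frame <- function(n_subjects = 10) {
  rows <- list()
  for (i in seq_len(n_subjects)) for (tp in c("T0", "T1", "T2")) {
    g <- sample(0:4, 3, replace = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = sprintf("S%02d", i), timepoint = tp,
      rater = c("S1", "S2", "S3"), grade = g, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# Small image whose horizontal neighbour pairs include (1,2) exactly three
# times, echoing the worked co-occurrence construction.
figure_grid <- function() {
  matrix(c(
    1, 2, 0, 3,
    0, 1, 2, 3,
    1, 2, 3, 0,
    3, 3, 0, 0
  ), nrow = 4, byrow = TRUE)
}
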