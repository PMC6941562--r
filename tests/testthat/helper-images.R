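# Small image constructors used across test files.

solid_image <- function(h, w, rgb) {
  img <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}

# Random image drawn from the three phantom palettes plus background,
# guaranteed to contain a mix of classes.
random_stain_image <- function(h, w) {
  n <- h * w
  pick <- sample(1:4, n, replace = TRUE, prob = c(0.4, 0.2, 0.3, 0.1))
  R <- G <- B <- integer(n)
  R[pick == 1] <- 245L; G[pick == 1] <- 245L; B[pick == 1] <- 245L
  nb <- sum(pick == 2)
  t <- runif(nb)
  R[pick == 2] <- round(30 + 110 * t)
  G[pick == 2] <- round(30 + 110 * t)
  B[pick == 2] <- round(200 - 30 * t)
  nm <- sum(pick == 3)
  t <- runif(nm)
  R[pick == 3] <- round(200 + 20 * t)
  G[pick == 3] <- round(40 + 50 * t)
  B[pick == 3] <- round(40 + 50 * t)
  # ambiguous mid-range colours that land in other_tissue
  R[pick == 4] <- 120L; G[pick == 4] <- 160L; B[pick == 4] <- 110L
  img <- array(0L, dim = c(h, w, 3))
  img[, , 1] <- R; img[, , 2] <- G; img[, , 3] <- B
  img
}

# Independent reference segmenter: per-pixel loop over classify_pixel.
naive_segment <- function(image, scheme = threshold_scheme()) {
  h <- dim(image)[1]; w <- dim(image)[2]
  has_alpha <- dim(image)[3] == 4L
  labels <- matrix(NA_integer_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      cl <- classify_pixel(image[i, j, 1:3],
                           alpha = if (has_alpha) image[i, j, 4] else NULL,
                           scheme = scheme)
      labels[i, j] <- match(cl, color_classes())
    }
  }
  labels
}
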