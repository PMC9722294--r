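# Deliberately naive reference implementations, kept independent of the
# package internals: plain double loops, scalar arithmetic, no shared code
# with the vectorized production paths.

# Median with the mean-of-middle-two convention, written out longhand.
oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Square-ring (8,1) neighbors, clockwise from top-left.
oracle_ring <- function(image, i, j) {
  c(image[i - 1, j - 1], image[i - 1, j], image[i - 1, j + 1],
    image[i, j + 1], image[i + 1, j + 1], image[i + 1, j],
    image[i + 1, j - 1], image[i, j - 1])
}

# Scalar bilinear interpolation at real (row, col).
oracle_bilinear <- function(image, row, col) {
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  r1 <- min(r0 + 1, nrow(image)); c1 <- min(c0 + 1, ncol(image))
  (1 - fr) * (1 - fc) * image[r0, c0] + (1 - fr) * fc * image[r0, c1] +
    fr * (1 - fc) * image[r1, c0] + fr * fc * image[r1, c1]
}

oracle_gmad <- function(image, mode = "mad_of_lmads") {
  M <- nrow(image); N <- ncol(image)
  lmads <- c()
  for (j in 2:(N - 1)) for (i in 2:(M - 1)) {
    G <- oracle_ring(image, i, j)
    lmads <- c(lmads, oracle_median(abs(G - oracle_median(G))))
  }
  if (mode == "mean_of_lmads") mean(lmads)
  else oracle_median(abs(lmads - oracle_median(lmads)))
}

oracle_gsv <- function(image, denominator = "valid") {
  M <- nrow(image); N <- ncol(image)
  lsvs <- c()
  for (j in 2:(N - 1)) for (i in 2:(M - 1)) {
    G <- oracle_ring(image, i, j)
    lsvs <- c(lsvs, mean(abs(image[i, j] - G)))
  }
  if (denominator == "image_size") sum(lsvs) / (M * N) else mean(lsvs)
}

oracle_quinary_digit <- function(gc, gi, T1, T2) {
  if (gi >= gc + T2) return(2)
  if (gi >= gc + T1 && gi < gc + T2) return(1)
  if (gi >= gc - T1 && gi < gc + T1) return(0)
  if (gi >= gc - T2 && gi < gc - T1) return(-1)
  -2
}

# Full naive ILQP at (8,1): estimate thresholds, code every neighborhood
# digit by digit, histogram the four channels.
oracle_ilqp <- function(image) {
  M <- nrow(image); N <- ncol(image)
  T1 <- oracle_gmad(image)
  T2 <- oracle_gsv(image)
  if (T1 > T2) { tmp <- T1; T1 <- T2; T2 <- tmp }
  hists <- list(B2 = rep(0, 256), B1 = rep(0, 256),
                Bm1 = rep(0, 256), Bm2 = rep(0, 256))
  chv <- c(B2 = 2, B1 = 1, Bm1 = -1, Bm2 = -2)
  for (j in 2:(N - 1)) for (i in 2:(M - 1)) {
    G <- oracle_ring(image, i, j)
    gc <- image[i, j]
    dig <- vapply(G, function(g) oracle_quinary_digit(gc, g, T1, T2), numeric(1))
    for (ch in names(chv)) {
      code <- 0
      for (t in 1:8) if (dig[t] == chv[[ch]]) code <- code + 2^(t - 1)
      hists[[ch]][code + 1] <- hists[[ch]][code + 1] + 1
    }
  }
  unlist(hists, use.names = FALSE)
}

# Per-class metrics via an explicit loop over classes.
oracle_metrics <- function(cm) {
  K <- nrow(cm)
  precs <- recs <- f1s <- numeric(K)
  correct <- 0
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    correct <- correct + tp
    precs[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    recs[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[k] <- if (precs[k] + recs[k] > 0)
      2 * precs[k] * recs[k] / (precs[k] + recs[k]) else 0
  }
  list(accuracy = 100 * correct / sum(cm),
       macro_precision = mean(precs), macro_recall = mean(recs),
       macro_f1 = mean(f1s))
}

random_image <- function(side, lo = 0, hi = 255) {
  matrix(stats::runif(side * side, lo, hi), side, side)
}

# Chi-square distance between two histograms.
chisq_dist <- function(a, b) {
  s <- a + b
  ok <- s > 0
  0.5 * sum((a[ok] - b[ok])^2 / s[ok])
}

toy_net_config <- function(input_side = 64L)
  densenet_config(block_layers = c(2L, 2L, 2L, 2L), growth_rate = 8L,
                  initial_channels = 16L, input_side = input_side)
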