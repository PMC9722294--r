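# ---- image validation -------------------------------------------------------

#' Validate a grayscale image
#'
#' A grayscale image is a numeric matrix of finite, non-negative intensities.
#' For a descriptor of radius `R` the image must be at least `(2R+1)` pixels
#' on each side so that at least one full neighborhood exists.
#'
#' @param x numeric matrix of intensities.
#' @param R optional radius (pixels) to check the minimum-size invariant for.
#' @return `x`, invisibly, after validation.
#' @export
validate_gray_image <- function(x, R = NULL) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("a gray image must be a numeric matrix")
  if (any(!is.finite(x)))
    stop("image intensities must all be finite")
  if (any(x < 0))
    stop("image intensities must be non-negative")
  if (!is.null(R)) {
    if (nrow(x) < 2 * R + 1 || ncol(x) < 2 * R + 1)
      stop(sprintf("image %dx%d too small for radius %d (need >= %d per side)",
                   nrow(x), ncol(x), R, 2 * R + 1))
  }
  invisible(x)
}

# ---- neighborhood sampling --------------------------------------------------

# Offsets (drow, dcol) of the 8-connected square ring, clockwise from the
# top-left corner.  This is the classic LBP(8,1) reading order.
.square_ring_offsets <- function() {
  cbind(drow = c(-1, -1, -1, 0, 1, 1, 1, 0),
        dcol = c(-1, 0, 1, 1, 1, 0, -1, -1))
}

# Offsets of P points on a circle of radius R, clockwise starting at the top
# (12 o'clock).  k-th neighbor sits at angle 2*pi*k/P.
.circle_offsets <- function(P, R) {
  theta <- 2 * pi * (seq_len(P) - 1) / P
  off <- cbind(drow = -R * cos(theta), dcol = R * sin(theta))
  off[abs(off) < 1e-12] <- 0
  off
}

.resolve_geometry <- function(P, R, geometry) {
  geometry <- match.arg(geometry, c("auto", "square", "circular"))
  if (geometry == "auto") geometry <- if (P == 8 && R == 1) "square" else "circular"
  if (geometry == "square" && !(P == 8 && R == 1))
    stop("square geometry is only defined for (P = 8, R = 1)")
  geometry
}

# Scalar bilinear interpolation at (row, col) in matrix img (1-based, real).
.bilinear_at <- function(img, row, col) {
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0;   fc <- col - c0
  r1 <- if (fr > 0) r0 + 1 else r0
  c1 <- if (fc > 0) c0 + 1 else c0
  (1 - fr) * (1 - fc) * img[r0, c0] +
    (1 - fr) * fc * img[r0, c1] +
    fr * (1 - fc) * img[r1, c0] +
    fr * fc * img[r1, c1]
}

#' Sample one local neighborhood
#'
#' Returns the center intensity and the ordered vector of `P` neighbor
#' intensities at radius `R` around a center pixel.  For `(P = 8, R = 1)` the
#' neighbors are the 8-connected square ring read clockwise from the top-left
#' corner; for general `(P, R)` they lie on a circle of radius `R` at angles
#' `2*pi*k/P` (clockwise from 12 o'clock) with bilinear interpolation.
#'
#' @param image numeric matrix (grayscale image).
#' @param center integer vector `c(i, j)` of 1-based row/column indices.
#' @param P number of neighbors (>= 4).
#' @param R radius in pixels (positive integer).
#' @param geometry `"auto"` (square ring iff `P == 8 && R == 1`), `"square"`,
#'   or `"circular"`.
#' @return list with `gc` (center intensity), `G` (length-`P` neighbor vector),
#'   `P`, `R`, and `center`.
#' @export
sample_neighborhood <- function(image, center, P = 8, R = 1,
                                geometry = c("auto", "square", "circular")) {
  validate_gray_image(image, R)
  if (P < 4) stop("P must be at least 4")
  geometry <- .resolve_geometry(P, R, geometry)
  i <- center[1]; j <- center[2]
  if (i <= R || j <= R || i > nrow(image) - R || j > ncol(image) - R)
    stop(sprintf("center (%d, %d) is closer than R = %d pixels to the border",
                 i, j, R))
  if (geometry == "square") {
    off <- .square_ring_offsets()
    G <- image[cbind(i + off[, 1], j + off[, 2])]
  } else {
    off <- .circle_offsets(P, R)
    G <- vapply(seq_len(P), function(k)
      .bilinear_at(image, i + off[k, 1], j + off[k, 2]), numeric(1))
  }
  list(gc = image[i, j], G = G, P = P, R = R, center = c(i, j))
}

# All valid neighborhoods of an image at one scale, fully vectorized.
# Returns gc (length n) and nb (n x P matrix); centers are enumerated
# column-major over the (M-2R) x (N-2R) valid region.
.neighbor_planes <- function(image, P, R, geometry = "auto") {
  validate_gray_image(image, R)
  geometry <- .resolve_geometry(P, R, geometry)
  M <- nrow(image); N <- ncol(image)
  rows <- (R + 1):(M - R); cols <- (R + 1):(N - R)
  gc <- as.vector(image[rows, cols])
  n <- length(gc)
  nb <- matrix(0, n, P)
  if (geometry == "square") {
    off <- .square_ring_offsets()
    for (k in seq_len(P))
      nb[, k] <- as.vector(image[rows + off[k, 1], cols + off[k, 2]])
  } else {
    off <- .circle_offsets(P, R)
    for (k in seq_len(P)) {
      dr <- off[k, 1]; dc <- off[k, 2]
      r0 <- floor(dr); c0 <- floor(dc)
      fr <- dr - r0;   fc <- dc - c0
      p00 <- image[rows + r0, cols + c0]
      plane <- (1 - fr) * (1 - fc) * p00
      if (fc > 0) plane <- plane + (1 - fr) * fc * image[rows + r0, cols + c0 + 1]
      if (fr > 0) plane <- plane + fr * (1 - fc) * image[rows + r0 + 1, cols + c0]
      if (fr > 0 && fc > 0) plane <- plane + fr * fc * image[rows + r0 + 1, cols + c0 + 1]
      nb[, k] <- as.vector(plane)
    }
  }
  list(gc = gc, nb = nb, n = n)
}

# Row medians of a numeric matrix; even-width rows use the mean of the two
# middle order statistics.
.row_medians <- function(m) {
  n <- nrow(m); P <- ncol(m)
  if (P == 1L) return(m[, 1])
  s <- matrix(m[order(row(m), m)], nrow = n, byrow = TRUE)
  if (P %% 2 == 1) s[, (P + 1) / 2] else (s[, P / 2] + s[, P / 2 + 1]) / 2
}

# ---- basic LBP --------------------------------------------------------------

#' Local binary pattern code of one neighborhood
#'
#' The classic LBP thresholds every neighbor against the center: bit `i` is 1
#' iff `g_i - g_c > 0` (strict), and the code is `sum(bit_i * 2^i)`.
#'
#' @param neighborhood list as returned by [sample_neighborhood()], or any
#'   list with elements `gc` and `G`.
#' @return list with `bits` (0/1 vector) and `code` (integer in `[0, 2^P)`).
#' @export
lbp_code <- function(neighborhood) {
  gc <- neighborhood$gc; G <- neighborhood$G
  bits <- as.integer(G - gc > 0)
  list(bits = bits, code = sum(bits * 2^(seq_along(bits) - 1)))
}

# ---- adaptive threshold statistics ------------------------------------------

#' Local median absolute deviation of a neighbor set
#'
#' `median(|g_i - median(G)|)` over the neighbor intensities of one
#' neighborhood.  Even-length medians use the mean of the two middle values.
#'
#' @param G numeric vector of neighbor intensities.
#' @return non-negative scalar.
#' @export
local_mad <- function(G) {
  if (length(G) == 0) stop("empty neighbor set")
  stats::median(abs(G - stats::median(G)))
}

#' Local significant value of a neighborhood
#'
#' Mean absolute difference between the center intensity and its neighbors:
#' `(1/P) * sum(|g_c - g_i|)`.
#'
#' @param gc center intensity.
#' @param G numeric vector of neighbor intensities.
#' @return non-negative scalar.
#' @export
local_sv <- function(gc, G) {
  if (length(G) == 0) stop("empty neighbor set")
  mean(abs(gc - G))
}

#' Global median absolute deviation of an image
#'
#' Computes the local MAD of every valid neighborhood, then aggregates.  The
#' default (`"mad_of_lmads"`) is the median absolute deviation of the set of
#' local MADs; `"mean_of_lmads"` is their plain mean, an alternative
#' aggregation some descriptions of this statistic use.
#'
#' @inheritParams sample_neighborhood
#' @param gmad_mode aggregation over local MADs.
#' @return non-negative scalar, the adaptive first threshold `T1`.
#' @export
global_mad <- function(image, P = 8, R = 1,
                       gmad_mode = c("mad_of_lmads", "mean_of_lmads"),
                       geometry = "auto") {
  gmad_mode <- match.arg(gmad_mode)
  np <- .neighbor_planes(image, P, R, geometry)
  dev <- abs(np$nb - .row_medians(np$nb))
  lmads <- .row_medians(dev)
  if (gmad_mode == "mean_of_lmads") return(mean(lmads))
  stats::median(abs(lmads - stats::median(lmads)))
}

#' Global significant value of an image
#'
#' Image-wide average of the local significant value.  The default averages
#' over the neighborhoods that actually exist, `(M-2R)(N-2R)` of them;
#' `"image_size"` divides the same sum by `M*N` instead.
#'
#' @inheritParams global_mad
#' @param gsv_denominator `"valid"` or `"image_size"`.
#' @return non-negative scalar, the adaptive second threshold `T2`.
#' @export
global_sv <- function(image, P = 8, R = 1,
                      gsv_denominator = c("valid", "image_size"),
                      geometry = "auto") {
  gsv_denominator <- match.arg(gsv_denominator)
  np <- .neighbor_planes(image, P, R, geometry)
  lsv <- rowMeans(abs(np$nb - np$gc))
  if (gsv_denominator == "image_size")
    sum(lsv) / (nrow(image) * ncol(image))
  else
    mean(lsv)
}

# ---- quinary coding ---------------------------------------------------------

#' Quinary code of one neighborhood
#'
#' Maps each neighbor to a digit in `{-2,-1,0,1,2}` using two thresholds
#' `T1 <= T2` around the center intensity: 2 if `g_i >= g_c+T2`, 1 on
#' `[g_c+T1, g_c+T2)`, 0 on `[g_c-T1, g_c+T1)`, -1 on `[g_c-T2, g_c-T1)`,
#' -2 otherwise.  Branches are evaluated in this order with first match
#' winning, which keeps the map total for degenerate thresholds
#' (`T1 == T2` or `T1 == 0`).
#'
#' @param gc center intensity.
#' @param G numeric vector of neighbor intensities.
#' @param T1,T2 thresholds in intensity units; canonicalized so `T1 <= T2`.
#' @return integer vector of digits, one per neighbor.
#' @export
quinary_code <- function(gc, G, T1, T2) {
  if (T1 < 0 || T2 < 0) stop("thresholds must be non-negative")
  if (T1 > T2) { tmp <- T1; T1 <- T2; T2 <- tmp }
  d <- G - gc
  q <- rep.int(-2L, length(G))
  q[d >= -T2] <- -1L
  q[d >= -T1] <- 0L
  q[d >= T1] <- 1L
  q[d >= T2] <- 2L
  q
}

#' Split a quinary pattern into four binary patterns
#'
#' For each channel `c` in `{2, 1, -1, -2}`, bit `i` is 1 iff digit `i`
#' equals `c`.  Zero digits light no channel, so per position the four
#' channel bits sum to 1 for a nonzero digit and 0 otherwise.
#'
#' @param digits integer vector of quinary digits in `{-2,-1,0,1,2}`.
#' @return named list of four 0/1 integer vectors: `B2`, `B1`, `Bm1`, `Bm2`.
#' @export
split_binary <- function(digits) {
  if (!all(digits %in% c(-2L, -1L, 0L, 1L, 2L)))
    stop("digits must lie in {-2,-1,0,1,2}")
  list(B2 = as.integer(digits == 2L),
       B1 = as.integer(digits == 1L),
       Bm1 = as.integer(digits == -1L),
       Bm2 = as.integer(digits == -2L))
}

.channel_values <- c(B2 = 2L, B1 = 1L, Bm1 = -1L, Bm2 = -2L)

# ---- the full descriptor ----------------------------------------------------

#' ILQP texture features of one image
#'
#' For each scale `(P, R)` the two thresholds are estimated from the image
#' itself (`T1` = global MAD, `T2` = global significant value, swapped if
#' needed so `T1 <= T2`); every valid neighborhood is quinary-coded, split
#' into four binary patterns, each mapped to its decimal code, and the four
#' per-channel `2^P`-bin histograms are accumulated.  Histograms are
#' concatenated over channels (`B2`, `B1`, `Bm1`, `Bm2`) and then scales.
#'
#' Only centers with a complete neighborhood are coded (no padding), so each
#' channel histogram sums to `(M-2R)(N-2R)`.
#'
#' @inheritParams global_mad
#' @param image numeric matrix (grayscale image).
#' @param scales list of `c(P, R)` pairs; default a single `(8, 1)` scale.
#' @param normalize if `TRUE`, each channel histogram is converted to
#'   frequencies (sums to 1); counts otherwise.
#' @param gsv_denominator see [global_sv()].
#' @param allow_large permit `P > 12` (histograms beyond 4096 bins per
#'   channel, e.g. the 65536-bin `P = 16` case).  Refused by default to
#'   avoid silently huge feature vectors.
#' @return named numeric feature vector with attributes `scales`,
#'   `thresholds` (per-scale `c(T1, T2)`), `gmad_mode`, `gsv_denominator`
#'   and `normalized`.
#' @export
ilqp_features <- function(image, scales = list(c(8, 1)), normalize = FALSE,
                          gmad_mode = c("mad_of_lmads", "mean_of_lmads"),
                          gsv_denominator = c("valid", "image_size"),
                          geometry = "auto", allow_large = FALSE) {
  gmad_mode <- match.arg(gmad_mode)
  gsv_denominator <- match.arg(gsv_denominator)
  if (!is.list(scales)) scales <- list(scales)
  out <- list(); thresholds <- list()
  for (s in scales) {
    P <- as.integer(s[1]); R <- as.integer(s[2])
    if (P > 12 && !allow_large)
      stop(sprintf("P = %d implies %d histogram bins per channel; set allow_large = TRUE to permit this",
                   P, 2^P))
    if (nrow(image) < 2 * R + 1 || ncol(image) < 2 * R + 1)
      stop(sprintf("image admits no valid neighborhood at scale (P = %d, R = %d)", P, R))
    np <- .neighbor_planes(image, P, R, geometry)
    dev <- abs(np$nb - .row_medians(np$nb))
    lmads <- .row_medians(dev)
    T1 <- if (gmad_mode == "mean_of_lmads") mean(lmads) else
      stats::median(abs(lmads - stats::median(lmads)))
    lsv <- rowMeans(abs(np$nb - np$gc))
    T2 <- if (gsv_denominator == "image_size")
      sum(lsv) / (nrow(image) * ncol(image)) else mean(lsv)
    if (T1 > T2) { tmp <- T1; T1 <- T2; T2 <- tmp }
    d <- np$nb - np$gc
    q <- matrix(-2L, np$n, P)
    q[d >= -T2] <- -1L
    q[d >= -T1] <- 0L
    q[d >= T1] <- 1L
    q[d >= T2] <- 2L
    pow <- 2^(seq_len(P) - 1)
    nbins <- 2^P
    for (ch in names(.channel_values)) {
      codes <- as.vector((q == .channel_values[[ch]]) %*% pow)
      h <- tabulate(codes + 1L, nbins = nbins)
      if (normalize) h <- h / sum(h)
      names(h) <- sprintf("P%dR%d.%s.b%04d", P, R, ch, seq_len(nbins) - 1L)
      out[[sprintf("P%dR%d.%s", P, R, ch)]] <- h
    }
    thresholds[[sprintf("P%dR%d", P, R)]] <- c(T1 = T1, T2 = T2)
  }
  feat <- unlist(out, use.names = FALSE)
  names(feat) <- unlist(lapply(out, names), use.names = FALSE)
  attr(feat, "scales") <- scales
  attr(feat, "thresholds") <- thresholds
  attr(feat, "gmad_mode") <- gmad_mode
  attr(feat, "gsv_denominator") <- gsv_denominator
  attr(feat, "normalized") <- normalize
  feat
}

#' ILQP feature matrix of an image list
#'
#' Applies [ilqp_features()] to every image and stacks the results into a
#' matrix with one row per image.
#'
#' @param images list of numeric matrices.
#' @param ... passed to [ilqp_features()].
#' @return numeric matrix, `length(images)` rows.
#' @export
ilqp_feature_matrix <- function(images, ...) {
  rows <- lapply(images, ilqp_features, ...)
  m <- do.call(rbind, lapply(rows, as.numeric))
  colnames(m) <- names(rows[[1]])
  rownames(m) <- names(images)
  m
}
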