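# Densely connected convolutional feature extractor.
#
# The backbone follows the canonical dense-connectivity design: a 7x7/2 stem
# convolution with 3x3/2 max pooling, four dense blocks of bottleneck layers
# (BN - ReLU - 1x1 conv to 4*growth channels - BN - ReLU - 3x3 conv to
# `growth` channels, each layer consuming the concatenation of everything
# before it in the block), and compressing transition layers (BN - ReLU -
# 1x1 conv - 2x2/2 average pool) between blocks.  The classification head is
# absent; instead the network exposes taps at the end of each dense block,
# before its transition, which are globally average-pooled and concatenated
# into the multilayer deep feature.

.densenet_variants <- list(
  "121" = c(6L, 12L, 24L, 16L),
  "169" = c(6L, 12L, 32L, 32L),
  "201" = c(6L, 12L, 48L, 32L),
  "264" = c(6L, 12L, 64L, 48L)
)

#' DenseNet configuration
#'
#' Either name one of the four standard variants (121, 169, 201, 264) or give
#' explicit per-block layer counts (1-4 blocks; toy configurations with few
#' shallow blocks are useful for testing).
#'
#' @param variant one of `"121"`, `"169"`, `"201"`, `"264"`, or `NULL` when
#'   `block_layers` is given.
#' @param block_layers integer vector of dense-layer counts per block.
#' @param growth_rate channels added by each dense layer.
#' @param initial_channels channels after the stem (canonically twice the
#'   growth rate).
#' @param compression transition channel factor in (0, 1].
#' @param input_side network input side in pixels.
#' @return object of class `"densenet_config"`.
#' @export
densenet_config <- function(variant = NULL, block_layers = NULL,
                            growth_rate = 32L, initial_channels = 2L * growth_rate,
                            compression = 0.5, input_side = 224L) {
  if (!is.null(variant)) {
    block_layers <- .densenet_variants[[as.character(variant)]]
    if (is.null(block_layers))
      stop("unknown variant; use one of 121, 169, 201, 264")
  }
  if (is.null(block_layers)) stop("give either a variant or block_layers")
  block_layers <- as.integer(block_layers)
  if (length(block_layers) < 1 || length(block_layers) > 4)
    stop("block_layers must have 1 to 4 entries")
  if (any(block_layers <= 0)) stop("block layer counts must be positive")
  if (growth_rate <= 0) stop("growth_rate must be positive")
  if (compression <= 0 || compression > 1) stop("compression must be in (0, 1]")
  structure(list(variant = if (is.null(variant)) NA_character_ else as.character(variant),
                 block_layers = block_layers, growth_rate = as.integer(growth_rate),
                 initial_channels = as.integer(initial_channels),
                 compression = compression, input_side = as.integer(input_side)),
            class = "densenet_config")
}

#' Closed-form per-block output channel counts
#'
#' `c_out(b) = c_in(b) + L_b * growth`, with `c_in(1)` the stem channels and
#' `c_in(b+1) = floor(compression * c_out(b))` after the transition.
#'
#' @param config a [densenet_config()].
#' @return integer vector, one output channel count per dense block.
#' @export
channel_counts <- function(config) {
  stopifnot(inherits(config, "densenet_config"))
  cin <- config$initial_channels
  out <- integer(length(config$block_layers))
  for (b in seq_along(config$block_layers)) {
    out[b] <- cin + config$block_layers[b] * config$growth_rate
    cin <- floor(config$compression * out[b])
  }
  out
}

#' Length of the multilayer deep feature
#'
#' @param config a [densenet_config()].
#' @param taps dense blocks whose pooled outputs are concatenated.
#' @return integer feature length.
#' @export
densenet_feature_length <- function(config, taps = NULL) {
  cc <- channel_counts(config)
  taps <- .resolve_taps(config, taps)
  sum(cc[taps])
}

.resolve_taps <- function(config, taps) {
  nb <- length(config$block_layers)
  if (is.null(taps)) {
    taps <- if (nb >= 2) intersect(2:4, seq_len(nb)) else 1L
  }
  taps <- sort(unique(as.integer(taps)))
  if (length(taps) == 0 || any(taps < 1) || any(taps > nb))
    stop("taps must name existing dense blocks")
  taps
}

# ---- construction -----------------------------------------------------------

.he_conv <- function(kh, kw, cin, cout, zero) {
  W <- if (zero) matrix(0, kh * kw * cin, cout)
  else matrix(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
              kh * kw * cin, cout)
  list(W = W, b = numeric(cout))
}

#' Build a densely connected network with tap points
#'
#' Constructs the backbone described by `config`; the classification head is
#' not part of the network (a one-vs-rest head is attached only during
#' [ovr_finetune()]).  `weights = "random"` uses He-normal initialization,
#' `weights = "zero"` sets all convolution weights to zero (normalization is
#' then the identity in evaluation mode, which makes the network map any
#' input to the zero feature).
#'
#' @param config a [densenet_config()].
#' @param weights `"random"` or `"zero"`.
#' @param seed RNG seed used for random initialization.
#' @return object of class `"densenet"` holding parameters, normalization
#'   buffers and layer metadata.
#' @export
build_densenet <- function(config, weights = c("random", "zero"), seed = 1L) {
  stopifnot(inherits(config, "densenet_config"))
  weights <- match.arg(weights)
  zero <- weights == "zero"
  set.seed(seed)
  P <- list(); B <- list(); M <- list()
  add_bn <- function(id, ch) {
    P[[id]] <<- list(gamma = rep(1, ch), beta = numeric(ch))
    B[[id]] <<- list(mean = numeric(ch), var = rep(1, ch))
  }
  add_conv <- function(id, kh, kw, cin, cout, stride, pad) {
    P[[id]] <<- .he_conv(kh, kw, cin, cout, zero)
    M[[id]] <<- list(kh = kh, kw = kw, stride = stride, pad = pad,
                     cin = cin, cout = cout)
  }
  g <- config$growth_rate
  add_conv("stem.conv", 7, 7, 3, config$initial_channels, 2, 3)
  add_bn("stem.bn", config$initial_channels)
  cin <- config$initial_channels
  for (b in seq_along(config$block_layers)) {
    for (l in seq_len(config$block_layers[b])) {
      id <- sprintf("b%d.l%d", b, l)
      add_bn(paste0(id, ".bn1"), cin)
      add_conv(paste0(id, ".conv1"), 1, 1, cin, 4L * g, 1, 0)
      add_bn(paste0(id, ".bn2"), 4L * g)
      add_conv(paste0(id, ".conv2"), 3, 3, 4L * g, g, 1, 1)
      cin <- cin + g
    }
    if (b < length(config$block_layers)) {
      tid <- sprintf("t%d", b)
      cout <- floor(config$compression * cin)
      add_bn(paste0(tid, ".bn"), cin)
      add_conv(paste0(tid, ".conv"), 1, 1, cin, cout, 1, 0)
      cin <- cout
    }
  }
  structure(list(config = config, params = P, buffers = B, meta = M,
                 head = NULL, history = NULL, seed = seed, weights = weights),
            class = "densenet")
}

#' @export
print.densenet <- function(x, ...) {
  cc <- channel_counts(x$config)
  cat(sprintf("Densely connected feature extractor (%s)\n",
              if (is.na(x$config$variant)) "custom" else paste0("DenseNet-", x$config$variant)))
  cat(sprintf("  blocks: [%s], growth %d, compression %.2f, input %dpx\n",
              paste(x$config$block_layers, collapse = ", "),
              x$config$growth_rate, x$config$compression, x$config$input_side))
  cat(sprintf("  block output channels: %s\n", paste(cc, collapse = ", ")))
  cat(sprintf("  default tap feature length: %d\n",
              densenet_feature_length(x$config)))
  if (!is.null(x$head)) cat("  one-vs-rest head attached\n")
  invisible(x)
}

#' Per-block channel counts of a constructed network
#'
#' Walks the stored weight arrays layer by layer (reading channel counts off
#' the actual convolution weight shapes) and accumulates the concatenation
#' arithmetic, independently of the closed form in [channel_counts()].
#'
#' @param network a [build_densenet()] object.
#' @return integer vector of per-block output channel counts.
#' @export
network_channel_counts <- function(network) {
  stopifnot(inherits(network, "densenet"))
  nb <- length(network$config$block_layers)
  out <- integer(nb)
  for (b in seq_len(nb)) {
    cin <- length(network$params[[sprintf("b%d.l1.bn1", b)]]$gamma)
    l <- 1L
    ch <- cin
    repeat {
      id <- sprintf("b%d.l%d.conv2", b, l)
      if (is.null(network$params[[id]])) break
      ch <- ch + ncol(network$params[[id]]$W)
      l <- l + 1L
    }
    out[b] <- ch
  }
  out
}

# ---- forward / backward -----------------------------------------------------

.bnrc_fwd <- function(net, bn_id, conv_id, x, train, cache) {
  p <- net$params; m <- net$meta[[conv_id]]
  bn <- .bn_fwd(x, p[[bn_id]]$gamma, p[[bn_id]]$beta,
                net$buffers[[bn_id]]$mean, net$buffers[[bn_id]]$var, train)
  rl <- .relu_fwd(bn$out)
  cv <- .conv_fwd(rl$out, p[[conv_id]]$W, p[[conv_id]]$b,
                  m$kh, m$kw, m$stride, m$pad)
  list(out = cv$out,
       buffers = if (train) list(mean = bn$run_mean, var = bn$run_var) else NULL,
       cache = if (cache) list(bn = bn, relu = rl, conv = cv) else NULL)
}

.bnrc_bwd <- function(net, bn_id, conv_id, cache, dout) {
  p <- net$params; m <- net$meta[[conv_id]]
  cb <- .conv_bwd(cache$conv, p[[conv_id]]$W, dout, m$kh, m$kw, m$stride, m$pad)
  dr <- .relu_bwd(cache$relu, cb$dx)
  bb <- .bn_bwd(cache$bn, p[[bn_id]]$gamma, dr)
  list(dx = bb$dx,
       grads = stats::setNames(list(list(W = cb$dW, b = cb$db),
                                    list(gamma = bb$dgamma, beta = bb$dbeta)),
                               c(conv_id, bn_id)))
}

# Full forward pass.  Returns tap tensors (raw if cache, pooled otherwise),
# the final block output, the cache tree, and updated BN buffers.
.densenet_forward <- function(net, x, train = FALSE, cache = FALSE,
                              taps = integer(0), pool_taps = TRUE) {
  p <- net$params
  caches <- list()
  cv <- .conv_fwd(x, p$stem.conv$W, p$stem.conv$b, 7, 7, 2, 3)
  bn <- .bn_fwd(cv$out, p$stem.bn$gamma, p$stem.bn$beta,
                net$buffers$stem.bn$mean, net$buffers$stem.bn$var, train)
  if (train) net$buffers$stem.bn <- list(mean = bn$run_mean, var = bn$run_var)
  rl <- .relu_fwd(bn$out)
  mp <- .maxpool_fwd(rl$out, 3, 2, 1)
  cur <- mp$out
  if (cache) caches$stem <- list(conv = cv, bn = bn, relu = rl, mp = mp)
  tap_out <- list()
  nb <- length(net$config$block_layers)
  for (b in seq_len(nb)) {
    L <- net$config$block_layers[b]
    blk <- list(input_channels = dim(cur)[3], layers = vector("list", L))
    for (l in seq_len(L)) {
      id <- sprintf("b%d.l%d", b, l)
      s1 <- .bnrc_fwd(net, paste0(id, ".bn1"), paste0(id, ".conv1"), cur, train, cache)
      if (train) net$buffers[[paste0(id, ".bn1")]] <- s1$buffers
      s2 <- .bnrc_fwd(net, paste0(id, ".bn2"), paste0(id, ".conv2"), s1$out, train, cache)
      if (train) net$buffers[[paste0(id, ".bn2")]] <- s2$buffers
      if (cache) blk$layers[[l]] <- list(s1 = s1$cache, s2 = s2$cache)
      cur <- .ccat(cur, s2$out)
    }
    if (cache) caches[[sprintf("block%d", b)]] <- blk
    if (b %in% taps)
      tap_out[[sprintf("b%d", b)]] <- if (pool_taps) .gap_fwd(cur)$out else cur
    if (b < nb) {
      tid <- sprintf("t%d", b)
      tr <- .bnrc_fwd(net, paste0(tid, ".bn"), paste0(tid, ".conv"), cur, train, cache)
      if (train) net$buffers[[paste0(tid, ".bn")]] <- tr$buffers
      ap <- .avgpool_fwd(tr$out, 2, 2)
      if (cache) caches[[tid]] <- list(bnrc = tr$cache, ap = ap)
      cur <- ap$out
    }
  }
  list(out = cur, taps = tap_out, caches = caches, net = net)
}

# Backpropagate a gradient at the final block output down to the stem,
# collecting parameter gradients.
.densenet_backward <- function(net, caches, dcur) {
  grads <- list()
  nb <- length(net$config$block_layers)
  g <- net$config$growth_rate
  for (b in rev(seq_len(nb))) {
    if (b < nb) {
      tid <- sprintf("t%d", b)
      d_ap <- .avgpool_bwd(caches[[tid]]$ap, dcur)
      tb <- .bnrc_bwd(net, paste0(tid, ".bn"), paste0(tid, ".conv"),
                      caches[[tid]]$bnrc, d_ap)
      grads <- c(grads, tb$grads)
      dcur <- tb$dx
    }
    blk <- caches[[sprintf("block%d", b)]]
    L <- length(blk$layers)
    for (l in rev(seq_len(L))) {
      pre <- blk$input_channels + (l - 1L) * g
      dy <- dcur[, , pre + seq_len(g), , drop = FALSE]
      dprefix <- dcur[, , seq_len(pre), , drop = FALSE]
      id <- sprintf("b%d.l%d", b, l)
      b2 <- .bnrc_bwd(net, paste0(id, ".bn2"), paste0(id, ".conv2"),
                      blk$layers[[l]]$s2, dy)
      b1 <- .bnrc_bwd(net, paste0(id, ".bn1"), paste0(id, ".conv1"),
                      blk$layers[[l]]$s1, b2$dx)
      grads <- c(grads, b2$grads, b1$grads)
      dcur <- dprefix + b1$dx
    }
  }
  d_mp <- .maxpool_bwd(caches$stem$mp, dcur)
  d_rl <- .relu_bwd(caches$stem$relu, d_mp)
  bb <- .bn_bwd(caches$stem$bn, net$params$stem.bn$gamma, d_rl)
  cb <- .conv_bwd(caches$stem$conv, net$params$stem.conv$W, bb$dx, 7, 7, 2, 3)
  grads$stem.bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
  grads$stem.conv <- list(W = cb$dW, b = cb$db)
  grads
}

# ---- preprocessing ----------------------------------------------------------

.imagenet_mean <- c(0.485, 0.456, 0.406)
.imagenet_sd <- c(0.229, 0.224, 0.225)

# Bilinear resize of a matrix to H2 x W2, edge-replicating.
.resize_bilinear <- function(img, H2, W2) {
  H <- nrow(img); W <- ncol(img)
  ry <- (seq_len(H2) - 0.5) * H / H2 + 0.5
  rx <- (seq_len(W2) - 0.5) * W / W2 + 0.5
  y0 <- pmin(pmax(floor(ry), 1), H); fy <- pmin(pmax(ry - y0, 0), 1)
  x0 <- pmin(pmax(floor(rx), 1), W); fx <- pmin(pmax(rx - x0, 0), 1)
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  wy <- matrix(fy, H2, W2); wx <- matrix(fx, H2, W2, byrow = TRUE)
  (1 - wy) * (1 - wx) * img[y0, x0] + (1 - wy) * wx * img[y0, x1] +
    wy * (1 - wx) * img[y1, x0] + wy * wx * img[y1, x1]
}

#' Preprocess a grayscale image for the network
#'
#' Resizes to `input_side` x `input_side` with bilinear interpolation, maps
#' intensities to the `[0, 1]` scale (dividing by 255 or 65535 when the
#' input looks 8- or 16-bit; values already in `[0, 1]` are left alone),
#' replicates the single channel threefold, and standardizes each channel
#' with the fixed constants mean (0.485, 0.456, 0.406) and standard
#' deviation (0.229, 0.224, 0.225).
#'
#' @param image numeric matrix.
#' @param input_side output side in pixels.
#' @return array of dimension `c(input_side, input_side, 3)`.
#' @export
preprocess_image <- function(image, input_side = 224L) {
  validate_gray_image(image)
  if (length(image) == 0) stop("empty image")
  mx <- max(image)
  scale <- if (mx <= 1) 1 else if (mx <= 255) 255 else 65535
  r <- .resize_bilinear(image / scale, input_side, input_side)
  out <- array(0, c(input_side, input_side, 3L))
  for (ch in 1:3) out[, , ch] <- (r - .imagenet_mean[ch]) / .imagenet_sd[ch]
  out
}

.stack_batch <- function(pre_list) {
  d <- dim(pre_list[[1]])
  x <- array(0, c(d[1], d[2], d[3], length(pre_list)))
  for (i in seq_along(pre_list)) x[, , , i] <- pre_list[[i]]
  x
}

# ---- feature extraction -----------------------------------------------------

#' Multilayer deep features
#'
#' Runs images through the network in evaluation mode, globally
#' average-pools the output of each tapped dense block (block 1 is excluded
#' by default: the earliest block carries the low-level information the
#' texture descriptor already provides), flattens, and concatenates the
#' pooled vectors in block order.
#'
#' @param network a [build_densenet()] object (optionally fine-tuned).
#' @param images list of grayscale image matrices.
#' @param taps blocks to tap; default blocks 2-4 (all blocks after the first).
#' @param input_side network input side; defaults to the config value.
#' @param batch_size images per forward pass.
#' @return numeric matrix, one row per image, `sum(channel_counts[taps])`
#'   columns.
#' @export
extract_multilayer_features <- function(network, images, taps = NULL,
                                        input_side = NULL, batch_size = 8L) {
  stopifnot(inherits(network, "densenet"))
  taps <- .resolve_taps(network$config, taps)
  if (is.null(input_side)) input_side <- network$config$input_side
  n <- length(images)
  cc <- channel_counts(network$config)
  D <- sum(cc[taps])
  out <- matrix(0, n, D)
  colnames(out) <- unlist(lapply(taps, function(b)
    sprintf("b%d.c%04d", b, seq_len(cc[b]))))
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (batch in idx) {
    x <- .stack_batch(lapply(images[batch], preprocess_image, input_side = input_side))
    fw <- .densenet_forward(network, x, train = FALSE, cache = FALSE,
                            taps = taps, pool_taps = TRUE)
    pooled <- do.call(cbind, fw$taps[sprintf("b%d", taps)])
    out[batch, ] <- pooled
  }
  out
}

# ---- focal loss -------------------------------------------------------------

#' Focal loss
#'
#' `-alpha_t * (1 - p_t)^gamma * log(p_t)`, averaged over samples, where
#' `p_t` is the predicted probability of the true binary target.  With
#' `gamma = 0` and `alpha_t = 1` this is exactly binary cross-entropy; for
#' `gamma > 0` well-classified samples (large `p_t`) are down-weighted.
#' Probabilities are clamped to `[1e-7, 1]` for log stability.
#'
#' @param p_t numeric vector of true-target probabilities in `(0, 1]`.
#' @param gamma focusing exponent, >= 0.
#' @param alpha_t per-sample (or scalar) weighting factor.
#' @return scalar mean loss.
#' @export
focal_loss <- function(p_t, gamma = 2, alpha_t = 1) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (any(!is.finite(p_t)) || any(p_t <= 0) || any(p_t > 1 + 1e-12))
    stop("p_t must lie in (0, 1]")
  p <- pmin(pmax(p_t, 1e-7), 1)
  mean(-alpha_t * (1 - p)^gamma * log(p))
}

# ---- training ---------------------------------------------------------------

#' Fine-tuning schedule
#'
#' Adam with a two-phase learning rate (1e-5 for the first half of the
#' epochs, then 1e-6), focal exponent `gamma = 2` and weight decay 1e-2,
#' the package's default fine-tuning configuration.
#'
#' @param epochs total epochs.
#' @param lr_phase1,lr_phase2 learning rates for the two phases.
#' @param phase1_epochs epochs trained at `lr_phase1`.
#' @param gamma focal exponent.
#' @param alpha `"balanced"` (inverse class frequency per batch) or
#'   `"uniform"`.
#' @param weight_decay L2 penalty added to convolution/linear weights.
#' @param batch_size minibatch size.
#' @return object of class `"train_schedule"`.
#' @export
train_schedule <- function(epochs = 20L, lr_phase1 = 1e-5, lr_phase2 = 1e-6,
                           phase1_epochs = ceiling(epochs / 2),
                           gamma = 2, alpha = c("balanced", "uniform"),
                           weight_decay = 1e-2, batch_size = 10L) {
  alpha <- match.arg(alpha)
  if (epochs <= 0) stop("epochs must be positive")
  if (lr_phase2 > lr_phase1) stop("lr_phase2 must not exceed lr_phase1")
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(epochs = as.integer(epochs), lr_phase1 = lr_phase1,
                 lr_phase2 = lr_phase2, phase1_epochs = as.integer(phase1_epochs),
                 gamma = gamma, alpha = alpha, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size)),
            class = "train_schedule")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Per-batch inverse-class-frequency weights: positives of class j get
# n/(2*n_pos), negatives n/(2*n_neg), the "balanced" convention.
.alpha_matrix <- function(Y, mode) {
  if (mode == "uniform") return(array(1, dim(Y)))
  n <- nrow(Y)
  npos <- pmax(colSums(Y), 1)
  nneg <- pmax(n - colSums(Y), 1)
  wpos <- matrix(n / (2 * npos), n, ncol(Y), byrow = TRUE)
  wneg <- matrix(n / (2 * nneg), n, ncol(Y), byrow = TRUE)
  ifelse(Y == 1, wpos, wneg)
}

#' One-vs-rest fine-tuning with focal loss
#'
#' Attaches one independent sigmoid output per class on top of the globally
#' pooled final block, and trains the whole network with Adam: the total
#' loss is the sum over classes of the focal loss that treats that class's
#' samples as positive and all others as negative.  Training is
#' deterministic given `seed`.  The returned network keeps its tap points;
#' feature extraction ignores the head.
#'
#' @param network a [build_densenet()] object.
#' @param images list of grayscale image matrices.
#' @param labels factor (or coercible) of class labels, >= 2 classes.
#' @param schedule a [train_schedule()].
#' @param seed RNG seed for head initialization and shuffling.
#' @param input_side network input side; defaults to the config value.
#' @return the trained `"densenet"` object, with `$history` holding the
#'   per-epoch mean loss.
#' @export
ovr_finetune <- function(network, images, labels, schedule = train_schedule(),
                         seed = 0L, input_side = NULL) {
  stopifnot(inherits(network, "densenet"), inherits(schedule, "train_schedule"))
  labels <- droplevels(as.factor(labels))
  K <- nlevels(labels)
  if (K < 2) stop("one-vs-rest training needs at least 2 classes")
  if (length(images) != length(labels)) stop("images and labels differ in length")
  if (is.null(input_side)) input_side <- network$config$input_side
  n <- length(images)
  cc <- channel_counts(network$config)
  c4 <- cc[length(cc)]
  set.seed(seed)
  network$params$head.fc <- list(
    W = matrix(stats::rnorm(c4 * K, sd = sqrt(2 / c4)), c4, K),
    b = numeric(K))
  Yfull <- matrix(0, n, K)
  Yfull[cbind(seq_len(n), as.integer(labels))] <- 1
  pre <- lapply(images, preprocess_image, input_side = input_side)
  state <- .adam_init(network$params)
  decay_ids <- names(network$params)[grepl("conv|head", names(network$params))]
  t_step <- 0L
  history <- numeric(schedule$epochs)
  for (epoch in seq_len(schedule$epochs)) {
    lr <- if (epoch <= schedule$phase1_epochs) schedule$lr_phase1 else schedule$lr_phase2
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / schedule$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      nbatch <- length(batch)
      x <- .stack_batch(pre[batch])
      Y <- Yfull[batch, , drop = FALSE]
      fw <- .densenet_forward(network, x, train = TRUE, cache = TRUE)
      network <- fw$net
      gp <- .gap_fwd(fw$out)
      fc <- .linear_fwd(gp$out, network$params$head.fc$W, network$params$head.fc$b)
      s <- .sigmoid(fc$out)
      p_t <- ifelse(Y == 1, s, 1 - s)
      p <- pmin(pmax(p_t, 1e-7), 1)
      alpha <- .alpha_matrix(Y, schedule$alpha)
      gam <- schedule$gamma
      loss <- sum(colMeans(-alpha * (1 - p)^gam * log(p)))
      ep_loss <- ep_loss + loss * nbatch
      # d(loss)/d(p_t), then through p_t = y*s + (1-y)*(1-s)
      dfl <- alpha * (gam * (1 - p)^(pmax(gam - 1, 0)) * log(p) - (1 - p)^gam / p)
      if (gam == 0) dfl <- -alpha / p
      ds <- s * (1 - s)
      dz <- dfl * ifelse(Y == 1, ds, -ds) / nbatch
      lb <- .linear_bwd(fc, network$params$head.fc$W, dz)
      dgap <- .gap_bwd(gp, lb$dx)
      grads <- .densenet_backward(network, fw$caches, dgap)
      grads$head.fc <- list(W = lb$dW, b = lb$db)
      t_step <- t_step + 1L
      st <- .adam_step(network$params, grads, state, t_step, lr,
                       schedule$weight_decay, decay_ids)
      network$params <- st$params
      state <- st$state
    }
    history[epoch] <- ep_loss / n
  }
  network$head <- network$params$head.fc
  network$history <- history
  network$schedule <- schedule
  network
}

#' Save / load network weights
#'
#' Serializes the configuration, parameters, normalization buffers and head
#' (if any) together with a manifest of the build seed.
#'
#' @param network a `"densenet"` object.
#' @param path file path.
#' @return `load_densenet_weights` returns the restored `"densenet"` object.
#' @export
save_densenet_weights <- function(network, path) {
  stopifnot(inherits(network, "densenet"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_densenet_weights
#' @export
load_densenet_weights <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "densenet")) stop("file does not hold a densenet object")
  net
}
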