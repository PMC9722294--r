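# Minimal convolutional-network engine on base R arrays.
#
# Tensors are 4D arrays (H, W, C, N), column-major.  Convolutions are
# lowered to matrix multiplication (im2col), so the heavy lifting is done
# by BLAS.  Every forward op returns the cache its backward pass needs,
# which keeps the whole engine purely functional and easy to gradient-check.

# ---- im2col / col2im --------------------------------------------------------

# Lower a (H,W,C,N) tensor to a (Ho*Wo*N) x (kh*kw*C) patch matrix.
# Rows run over (ho, wo, n) with ho fastest; columns over (i, j, c) with i
# fastest, matching a (kh, kw, Cin, Cout) weight array flattened to a matrix.
.im2col <- function(x, kh, kw, stride, pad) {
  d <- dim(x)
  if (pad > 0) {
    xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  } else xp <- x
  dp <- dim(xp)
  Ho <- (dp[1] - kh) %/% stride + 1L
  Wo <- (dp[2] - kw) %/% stride + 1L
  if (Ho < 1 || Wo < 1) stop("spatial size collapsed to zero in convolution/pooling")
  ridx <- seq.int(1L, by = stride, length.out = Ho)
  cidx <- seq.int(1L, by = stride, length.out = Wo)
  cols <- matrix(0, Ho * Wo * d[4], kh * kw * d[3])
  col <- 0L
  for (c in seq_len(d[3])) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    col <- col + 1L
    cols[, col] <- xp[ridx + (i - 1L), cidx + (j - 1L), c, ]
  }
  list(cols = cols, Ho = Ho, Wo = Wo)
}

# Adjoint of .im2col: scatter-add patch gradients back to the input tensor.
.col2im <- function(cols, xdim, kh, kw, stride, pad, Ho, Wo) {
  xp <- array(0, c(xdim[1] + 2L * pad, xdim[2] + 2L * pad, xdim[3], xdim[4]))
  ridx <- seq.int(1L, by = stride, length.out = Ho)
  cidx <- seq.int(1L, by = stride, length.out = Wo)
  col <- 0L
  for (c in seq_len(xdim[3])) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    col <- col + 1L
    xp[ridx + (i - 1L), cidx + (j - 1L), c, ] <-
      xp[ridx + (i - 1L), cidx + (j - 1L), c, ] + cols[, col]
  }
  if (pad > 0) xp[pad + seq_len(xdim[1]), pad + seq_len(xdim[2]), , , drop = FALSE]
  else xp
}

# ---- convolution ------------------------------------------------------------

.conv_fwd <- function(x, Wm, b, kh, kw, stride, pad) {
  d <- dim(x)
  ic <- .im2col(x, kh, kw, stride, pad)
  Cout <- ncol(Wm)
  y <- ic$cols %*% Wm
  y <- y + matrix(b, nrow(y), Cout, byrow = TRUE)
  y <- aperm(array(y, c(ic$Ho, ic$Wo, d[4], Cout)), c(1, 2, 4, 3))
  list(out = y, cols = ic$cols, Ho = ic$Ho, Wo = ic$Wo, xdim = d)
}

.conv_bwd <- function(cache, Wm, dout, kh, kw, stride, pad) {
  dd <- dim(dout)
  dmat <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = dd[3])
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, Wm)
  dx <- .col2im(dcols, cache$xdim, kh, kw, stride, pad, cache$Ho, cache$Wo)
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalization (per channel over H, W, N) -------------------------

.bn_fwd <- function(x, gamma, beta, run_mean, run_var, train,
                    momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), m, d[3])
  if (train) {
    mu <- colMeans(xm)
    ctr <- xm - matrix(mu, m, d[3], byrow = TRUE)
    v <- colMeans(ctr * ctr)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    ctr <- xm - matrix(mu, m, d[3], byrow = TRUE)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- ctr * matrix(invstd, m, d[3], byrow = TRUE)
  ym <- xhat * matrix(gamma, m, d[3], byrow = TRUE) +
    matrix(beta, m, d[3], byrow = TRUE)
  y <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = y, xhat = xhat, invstd = invstd, d = d,
       run_mean = run_mean, run_var = run_var, train = train)
}

.bn_bwd <- function(cache, gamma, dout) {
  d <- cache$d
  m <- d[1] * d[2] * d[4]
  dym <- matrix(aperm(dout, c(1, 2, 4, 3)), m, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  gm <- matrix(gamma * cache$invstd, m, d[3], byrow = TRUE)
  if (cache$train) {
    dxhat <- dym
    t1 <- matrix(dbeta / m, m, d[3], byrow = TRUE)
    t2 <- cache$xhat * matrix(colSums(dxhat * cache$xhat) / m, m, d[3], byrow = TRUE)
    dxm <- gm * (dxhat - t1 - t2)
  } else {
    dxm <- gm * dym
  }
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations and pooling ------------------------------------------------

.relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
.relu_bwd <- function(cache, dout) dout * cache$mask

.maxpool_fwd <- function(x, k, stride, pad) {
  d <- dim(x)
  if (pad > 0) {
    xp <- array(-Inf, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  } else xp <- x
  dp <- dim(xp)
  Ho <- (dp[1] - k) %/% stride + 1L
  Wo <- (dp[2] - k) %/% stride + 1L
  ridx <- seq.int(1L, by = stride, length.out = Ho)
  cidx <- seq.int(1L, by = stride, length.out = Wo)
  best <- array(-Inf, c(Ho, Wo, d[3], d[4]))
  arg <- array(0L, c(Ho, Wo, d[3], d[4]))
  idx <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    idx <- idx + 1L
    sl <- xp[ridx + (i - 1L), cidx + (j - 1L), , , drop = FALSE]
    upd <- sl > best
    best[upd] <- sl[upd]
    arg[upd] <- idx
  }
  list(out = best, arg = arg, xdim = d, k = k, stride = stride, pad = pad,
       Ho = Ho, Wo = Wo)
}

.maxpool_bwd <- function(cache, dout) {
  d <- cache$xdim
  dxp <- array(0, c(d[1] + 2L * cache$pad, d[2] + 2L * cache$pad, d[3], d[4]))
  ridx <- seq.int(1L, by = cache$stride, length.out = cache$Ho)
  cidx <- seq.int(1L, by = cache$stride, length.out = cache$Wo)
  idx <- 0L
  for (j in seq_len(cache$k)) for (i in seq_len(cache$k)) {
    idx <- idx + 1L
    contrib <- dout * (cache$arg == idx)
    dxp[ridx + (i - 1L), cidx + (j - 1L), , ] <-
      dxp[ridx + (i - 1L), cidx + (j - 1L), , ] + contrib
  }
  if (cache$pad > 0)
    dxp[cache$pad + seq_len(d[1]), cache$pad + seq_len(d[2]), , , drop = FALSE]
  else dxp
}

.avgpool_fwd <- function(x, k, stride) {
  d <- dim(x)
  Ho <- (d[1] - k) %/% stride + 1L
  Wo <- (d[2] - k) %/% stride + 1L
  ridx <- seq.int(1L, by = stride, length.out = Ho)
  cidx <- seq.int(1L, by = stride, length.out = Wo)
  acc <- array(0, c(Ho, Wo, d[3], d[4]))
  for (j in seq_len(k)) for (i in seq_len(k))
    acc <- acc + x[ridx + (i - 1L), cidx + (j - 1L), , , drop = FALSE]
  list(out = acc / (k * k), xdim = d, k = k, stride = stride, Ho = Ho, Wo = Wo)
}

.avgpool_bwd <- function(cache, dout) {
  d <- cache$xdim
  dx <- array(0, d)
  ridx <- seq.int(1L, by = cache$stride, length.out = cache$Ho)
  cidx <- seq.int(1L, by = cache$stride, length.out = cache$Wo)
  g <- dout / (cache$k * cache$k)
  for (j in seq_len(cache$k)) for (i in seq_len(cache$k))
    dx[ridx + (i - 1L), cidx + (j - 1L), , ] <-
      dx[ridx + (i - 1L), cidx + (j - 1L), , ] + g
  dx
}

# Global average pool: (H,W,C,N) -> (N,C) matrix.
.gap_fwd <- function(x) {
  d <- dim(x)
  if (d[1] < 1 || d[2] < 1) stop("spatial size is zero at a pooled tap")
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  list(out = t(matrix(colMeans(m), d[3], d[4])), xdim = d)
}

.gap_bwd <- function(cache, dout) {
  d <- cache$xdim
  per <- t(dout) / (d[1] * d[2])          # C x N
  array(rep(as.vector(per), each = d[1] * d[2]), d)
}

.linear_fwd <- function(x, W, b) {
  list(out = x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE), x = x)
}

.linear_bwd <- function(cache, W, dout) {
  list(dx = tcrossprod(dout, W), dW = crossprod(cache$x, dout), db = colSums(dout))
}

# Concatenate two tensors along the channel dimension.
.ccat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  lapply(params, function(p) lapply(p, function(a) {
    z <- a; z[] <- 0
    list(m = z, v = z)
  }))
}

# One Adam step over a flat params/grads structure (list of layers, each a
# named list of arrays).  Weight decay is L2 added to the gradient, applied
# only to slots named in `decay_slots` of layers flagged in `decay_ids`.
.adam_step <- function(params, grads, state, t, lr, weight_decay, decay_ids,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (id in names(grads)) {
    for (slot in names(grads[[id]])) {
      g <- grads[[id]][[slot]]
      if (is.null(g)) next
      if (weight_decay > 0 && slot == "W" && id %in% decay_ids)
        g <- g + weight_decay * params[[id]][[slot]]
      st <- state[[id]][[slot]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      params[[id]][[slot]] <- params[[id]][[slot]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[id]][[slot]] <- st
    }
  }
  list(params = params, state = state)
}
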