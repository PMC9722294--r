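test_that("configuration validation and closed-form channel arithmetic", {
  cfg <- densenet_config("169")
  expect_equal(cfg$block_layers, c(6L, 12L, 32L, 32L))
  expect_equal(channel_counts(cfg), c(256L, 512L, 1280L, 1664L))
  expect_equal(densenet_feature_length(cfg), 3456L)
  expect_equal(channel_counts(densenet_config("121")), c(256L, 512L, 1024L, 1024L))

  # no transition shrinkage at compression 1: c_out = initial + L * growth
  one <- densenet_config(block_layers = 5L, growth_rate = 3L,
                         initial_channels = 7L, compression = 1)
  expect_equal(channel_counts(one), 7L + 5L * 3L)
  expect_equal(channel_counts(densenet_config(block_layers = 2L, growth_rate = 4L,
                                              initial_channels = 8L)), 16L)

  expect_error(densenet_config("150"), "variant")
  expect_error(densenet_config(block_layers = c(2, 0)), "positive")
  expect_error(densenet_config(block_layers = 2, compression = 0), "compression")
})

test_that("constructed networks realize the closed-form channel counts", {
  set.seed(21)
  for (t in 1:6) {
    nb <- sample(1:4, 1)
    cfg <- densenet_config(block_layers = sample(1:3, nb, replace = TRUE),
                           growth_rate = sample(2:6, 1),
                           initial_channels = sample(c(4L, 6L, 8L), 1),
                           compression = sample(c(0.5, 0.75, 1), 1),
                           input_side = 64L)
    net <- build_densenet(cfg, seed = t)
    expect_equal(network_channel_counts(net), channel_counts(cfg))
  }
  # dense connectivity: layer l of a block consumes c_in + (l-1)*growth
  cfg <- toy_net_config()
  net <- build_densenet(cfg, seed = 1)
  for (b in 1:4) for (l in 1:2) {
    cin_l <- nrow(net$params[[sprintf("b%d.l%d.conv1", b, l)]]$W)
    cin_blk <- length(net$params[[sprintf("b%d.l1.bn1", b)]]$gamma)
    expect_equal(cin_l, cin_blk + (l - 1) * cfg$growth_rate)
  }
})

test_that("tap extraction: zero network, dimensions, determinism, row order", {
  cfg <- toy_net_config()
  imgs <- lapply(1:5, function(i) {
    set.seed(100 + i)
    random_image(64, 0, 1)
  })

  nz <- build_densenet(cfg, weights = "zero")
  fz <- extract_multilayer_features(nz, imgs[1:2])
  expect_true(all(fz == 0))
  expect_equal(ncol(fz), sum(channel_counts(cfg)[2:4]))

  net <- build_densenet(cfg, seed = 7)
  f1 <- extract_multilayer_features(net, imgs, batch_size = 2)
  f2 <- extract_multilayer_features(net, imgs, batch_size = 5)
  expect_equal(f1, f2, tolerance = 1e-12)  # pure function of (weights, input)

  perm <- c(3, 1, 5, 2, 4)
  fp <- extract_multilayer_features(net, imgs[perm])
  expect_equal(unname(fp), unname(f1[perm, ]), tolerance = 1e-12)

  f34 <- extract_multilayer_features(net, imgs, taps = c(3, 4))
  expect_equal(ncol(f1) - ncol(f34), channel_counts(cfg)[2])
  expect_error(extract_multilayer_features(net, imgs, taps = 9), "taps")
})

test_that("preprocessing maps to the standardized 3-channel tensor", {
  img <- matrix(runif(382 * 382, 0, 255), 382, 382)
  x <- preprocess_image(img, 224)
  expect_equal(dim(x), c(224L, 224L, 3L))

  v <- 120
  xc <- preprocess_image(matrix(v, 80, 80), 32)
  for (ch in 1:3) {
    expected <- (v / 255 - cellpheno:::.imagenet_mean[ch]) / cellpheno:::.imagenet_sd[ch]
    expect_equal(max(abs(xc[, , ch] - expected)), 0, tolerance = 1e-12)
  }

  # 2x upscale then downscale recovers the original within interpolation
  # tolerance on the [0,1] scale
  set.seed(30)
  base <- cellpheno:::.gauss_blur(matrix(runif(64 * 64), 64, 64), 3.5)
  up <- cellpheno:::.resize_bilinear(base, 128, 128)
  back <- cellpheno:::.resize_bilinear(up, 64, 64)
  expect_lt(max(abs(back - base)), 1e-2)
  expect_error(preprocess_image(matrix(numeric(0), 0, 0)), "empty|small|matrix")
})

test_that("focal loss reduces to cross-entropy and down-weights easy samples", {
  grid <- seq(0.001, 1, by = 0.001)
  bce <- -log(pmax(grid, 1e-7))
  fl0 <- vapply(grid, focal_loss, numeric(1), gamma = 0, alpha_t = 1)
  expect_lt(max(abs(fl0 - bce)), 1e-12)
  expect_equal(focal_loss(1, gamma = 2), 0)
  expect_equal(focal_loss(1, gamma = 0), 0)
  # strictly decreasing in p_t for fixed gamma
  for (g in c(0, 0.5, 2)) {
    l <- vapply(grid, focal_loss, numeric(1), gamma = g)
    expect_true(all(diff(l) < 0))
  }
  # easy sample down-weighted relative to plain cross-entropy
  expect_lt(focal_loss(0.9, gamma = 2), focal_loss(0.9, gamma = 0))
  expect_error(focal_loss(0), "p_t")
  expect_error(focal_loss(1.5), "p_t")
  expect_error(focal_loss(0.5, gamma = -1), "gamma")
})

test_that("analytic gradients match numeric differentiation end to end", {
  cfg <- densenet_config(block_layers = 2L, growth_rate = 4L,
                         initial_channels = 8L, input_side = 64L)
  net <- build_densenet(cfg, seed = 3)
  set.seed(9)
  ims <- lapply(1:4, function(i) matrix(runif(64 * 64), 64, 64))
  lab <- factor(c("a", "a", "b", "b"))
  c_out <- channel_counts(cfg)
  set.seed(5)
  net$params$head.fc <- list(W = matrix(rnorm(c_out * 2, sd = 0.4), c_out, 2),
                             b = c(0.1, -0.2))
  Y <- matrix(0, 4, 2)
  Y[cbind(1:4, as.integer(lab))] <- 1
  x <- cellpheno:::.stack_batch(lapply(ims, preprocess_image, input_side = 64))

  loss_of <- function(nn) {
    fw <- cellpheno:::.densenet_forward(nn, x, train = TRUE, cache = TRUE)
    gp <- cellpheno:::.gap_fwd(fw$out)
    fc <- cellpheno:::.linear_fwd(gp$out, nn$params$head.fc$W, nn$params$head.fc$b)
    s <- 1 / (1 + exp(-fc$out))
    p <- pmin(pmax(ifelse(Y == 1, s, 1 - s), 1e-7), 1)
    sum(colMeans(-(1 - p)^2 * log(p)))
  }
  fw <- cellpheno:::.densenet_forward(net, x, train = TRUE, cache = TRUE)
  gp <- cellpheno:::.gap_fwd(fw$out)
  fc <- cellpheno:::.linear_fwd(gp$out, net$params$head.fc$W, net$params$head.fc$b)
  s <- 1 / (1 + exp(-fc$out))
  p <- pmin(pmax(ifelse(Y == 1, s, 1 - s), 1e-7), 1)
  dfl <- 2 * (1 - p) * log(p) - (1 - p)^2 / p
  dz <- dfl * ifelse(Y == 1, s * (1 - s), -s * (1 - s)) / 4
  lb <- cellpheno:::.linear_bwd(fc, net$params$head.fc$W, dz)
  grads <- cellpheno:::.densenet_backward(net, fw$caches,
                                          cellpheno:::.gap_bwd(gp, lb$dx))
  grads$head.fc <- list(W = lb$dW, b = lb$db)

  eps <- 1e-5
  set.seed(77)
  probes <- list(c("stem.conv", "W"), c("b1.l1.conv2", "W"),
                 c("b1.l2.conv1", "W"), c("b1.l1.bn1", "gamma"),
                 c("b1.l2.bn2", "beta"), c("head.fc", "W"))
  for (pr in probes) {
    id <- pr[1]; slot <- pr[2]
    i <- sample(length(net$params[[id]][[slot]]), 1)
    np <- net; np$params[[id]][[slot]][i] <- np$params[[id]][[slot]][i] + eps
    nm <- net; nm$params[[id]][[slot]][i] <- nm$params[[id]][[slot]][i] - eps
    num <- (loss_of(np) - loss_of(nm)) / (2 * eps)
    expect_equal(grads[[id]][[slot]][i], num, tolerance = 1e-4)
  }
})

test_that("schedule validation and one-vs-rest training contracts", {
  expect_error(train_schedule(epochs = 0), "epochs")
  expect_error(train_schedule(lr_phase1 = 1e-6, lr_phase2 = 1e-5), "lr_phase2")
  sch <- train_schedule()
  expect_equal(sch$epochs, 20L)
  expect_equal(sch$lr_phase1, 1e-5)
  expect_equal(sch$lr_phase2, 1e-6)
  expect_equal(sch$phase1_epochs, 10L)
  expect_equal(sch$gamma, 2)
  expect_equal(sch$weight_decay, 1e-2)

  # balanced weighting: 90/10 binary split gives the minority a 9x weight
  Y <- matrix(0, 100, 2)
  Y[1:10, 1] <- 1
  Y[11:100, 2] <- 1
  A <- cellpheno:::.alpha_matrix(Y, "balanced")
  expect_equal(A[1, 1] / A[11, 1], 9)
  expect_true(all(cellpheno:::.alpha_matrix(Y, "uniform") == 1))

  cfg <- toy_net_config()
  net <- build_densenet(cfg, seed = 0)
  set.seed(41)
  ims <- lapply(1:10, function(i) random_image(64, 0, 1))
  expect_error(ovr_finetune(net, ims, factor(rep("a", 10))), "2 classes")

  lab <- factor(rep(c("a", "b"), each = 5))
  sch <- train_schedule(epochs = 1, batch_size = 5)
  t1 <- ovr_finetune(net, ims, lab, sch, seed = 3)
  t2 <- ovr_finetune(net, ims, lab, sch, seed = 3)
  expect_identical(t1$history, t2$history)  # reproducibility contract
  expect_identical(t1$params$head.fc$W, t2$params$head.fc$W)
  expect_false(identical(t1$params$stem.conv$W, net$params$stem.conv$W))
})

test_that("weights survive a save/load round trip", {
  net <- build_densenet(densenet_config(block_layers = c(2, 2),
                                        growth_rate = 4, initial_channels = 8,
                                        input_side = 64), seed = 2)
  path <- tempfile(fileext = ".rds")
  save_densenet_weights(net, path)
  back <- load_densenet_weights(path)
  expect_identical(back$params, net$params)
  img <- list(matrix(runif(64 * 64), 64, 64))
  expect_equal(extract_multilayer_features(net, img),
               extract_multilayer_features(back, img))
})
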