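test_that("neighborhood sampling follows the stated geometry conventions", {
  img <- matrix(1:9, 3, 3, byrow = TRUE)
  nb <- sample_neighborhood(img, c(2, 2), P = 8, R = 1)
  expect_equal(nb$gc, 5)
  expect_equal(nb$G, c(1, 2, 3, 6, 9, 8, 7, 4))

  const <- matrix(7, 5, 5)
  nb <- sample_neighborhood(const, c(3, 3))
  expect_equal(nb$gc, 7)
  expect_equal(nb$G, rep(7, 8))

  expect_error(sample_neighborhood(img, c(1, 2)), "border")
  expect_error(sample_neighborhood(img, c(2, 3)), "border")

  # P = 4, R = 1 circular sampling on a ramp: axis-aligned neighbors at
  # 12, 3, 6, 9 o'clock, checked against scalar bilinear interpolation.
  ramp <- outer(1:7, 1:7, function(i, j) 2 * i + 0.5 * j)
  nb <- sample_neighborhood(ramp, c(4, 4), P = 4, R = 1)
  expect_equal(nb$G, c(oracle_bilinear(ramp, 3, 4), oracle_bilinear(ramp, 4, 5),
                       oracle_bilinear(ramp, 5, 4), oracle_bilinear(ramp, 4, 3)))

  # general circular offsets agree with scalar interpolation
  set.seed(11)
  im <- random_image(9)
  nb <- sample_neighborhood(im, c(5, 5), P = 12, R = 2)
  th <- 2 * pi * (0:11) / 12
  expected <- vapply(seq_len(12), function(k) {
    dr <- -2 * cos(th[k]); dc <- 2 * sin(th[k])
    dr[abs(dr) < 1e-12] <- 0; dc[abs(dc) < 1e-12] <- 0
    oracle_bilinear(im, 5 + dr, 5 + dc)
  }, numeric(1))
  expect_equal(nb$G, expected, tolerance = 1e-12)
})

test_that("LBP codes agree with a bitwise enumeration oracle", {
  nb <- list(gc = 5, G = c(1, 2, 3, 6, 9, 8, 7, 4))
  out <- lbp_code(nb)
  expect_equal(out$bits, c(0, 0, 0, 1, 1, 1, 1, 0))
  expect_equal(out$code, 120)
  expect_equal(lbp_code(list(gc = 3, G = rep(3, 8)))$code, 0)
  set.seed(1)
  for (t in 1:25) {
    gc <- runif(1, 0, 10)
    G <- runif(8, 0, 10)
    code <- 0
    for (i in 1:8) if (G[i] - gc > 0) code <- code + 2^(i - 1)
    expect_equal(lbp_code(list(gc = gc, G = G))$code, code)
  }
})

test_that("local MAD and local significant value match hand computations", {
  expect_equal(local_mad(c(7, 7, 7, 7)), 0)
  expect_equal(local_mad(c(1, 2, 3, 4, 5)), 1)
  # even-length median convention: median(0,0,0,8) = 0, deviations
  # (0,0,0,8) -> median 0
  expect_equal(local_mad(c(0, 0, 0, 8)), 0)
  expect_equal(local_mad(c(0, 0, 4, 8)), 2)
  expect_error(local_mad(numeric(0)), "empty")

  expect_equal(local_sv(5, rep(5, 8)), 0)
  expect_equal(local_sv(0, c(0, 0, 0, 8)), 2)
  expect_error(local_sv(1, numeric(0)), "empty")
  set.seed(2)
  for (t in 1:20) {
    G <- runif(sample(4:12, 1), 0, 100)
    gc <- runif(1, 0, 100)
    expect_equal(local_mad(G), oracle_median(abs(G - oracle_median(G))))
    expect_equal(local_sv(gc, G), sum(abs(gc - G)) / length(G))
  }
})

test_that("global thresholds equal brute-force double-loop references", {
  expect_equal(global_mad(matrix(5, 6, 6)), 0)
  expect_equal(global_sv(matrix(5, 6, 6)), 0)

  # single bright pixel: almost all local MADs stay zero, median is robust
  spike <- matrix(1, 9, 9)
  spike[5, 5] <- 100
  expect_equal(global_mad(spike), oracle_gmad(spike))
  expect_equal(global_mad(spike), 0)

  set.seed(3)
  for (t in 1:3) {
    im <- random_image(16)
    expect_equal(global_mad(im), oracle_gmad(im))
    expect_equal(global_mad(im, gmad_mode = "mean_of_lmads"),
                 oracle_gmad(im, "mean_of_lmads"))
    expect_equal(global_sv(im), oracle_gsv(im))
    expect_equal(global_sv(im, gsv_denominator = "image_size"),
                 oracle_gsv(im, "image_size"))
  }
  # checkerboard: the 4 orthogonal neighbors differ by 1, diagonals match,
  # so every interior LSV is 4/8
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(global_sv(cb), oracle_gsv(cb))
  expect_equal(global_sv(cb), 0.5)
  expect_error(global_mad(matrix(1, 2, 2)), "small")
})

test_that("quinary coding follows the five-branch transform", {
  expect_equal(quinary_code(100, 110, 3, 7), 2L)
  expect_equal(quinary_code(100, c(110, 104, 101, 99, 96, 90, 100, 107), 3, 7),
               c(2L, 1L, 0L, 0L, -1L, -2L, 0L, 2L))
  # degenerate thresholds: only the outer branches survive
  g <- c(99, 100, 101, 150, 50)
  expect_equal(quinary_code(100, g, 0, 0), c(-2L, 2L, 2L, 2L, -2L))
  # canonicalization: swapped thresholds give the same codes
  set.seed(4)
  for (t in 1:10) {
    G <- runif(8, 0, 255); gc <- runif(1, 0, 255)
    T1 <- runif(1, 0, 20); T2 <- runif(1, 0, 20)
    expect_identical(quinary_code(gc, G, T1, T2), quinary_code(gc, G, T2, T1))
    lo <- min(T1, T2); hi <- max(T1, T2)
    expected <- vapply(G, function(gi) oracle_quinary_digit(gc, gi, lo, hi),
                       numeric(1))
    expect_equal(as.numeric(quinary_code(gc, G, T1, T2)), expected)
  }
  expect_error(quinary_code(1, 1, -1, 2), "non-negative")
})

test_that("binary split is one-hot per nonzero digit", {
  b <- split_binary(c(2, 1, 0, 0, -1, -2, 0, 2))
  expect_equal(b$B2, c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(b$B1, c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(b$Bm1, c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L))
  expect_equal(b$Bm2, c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(split_binary(rep(0, 8)), list(B2 = rep(0L, 8), B1 = rep(0L, 8),
                                             Bm1 = rep(0L, 8), Bm2 = rep(0L, 8)))
  expect_error(split_binary(c(0, 3)), "digits")
  # exhaustive over all 5^4 quinary patterns of length 4
  digits <- c(-2L, -1L, 0L, 1L, 2L)
  grid <- expand.grid(digits, digits, digits, digits)
  for (r in seq_len(nrow(grid))) {
    q <- as.integer(grid[r, ])
    b <- split_binary(q)
    tot <- b$B2 + b$B1 + b$Bm1 + b$Bm2
    expect_equal(tot, as.integer(q != 0))
  }
})

test_that("constant images produce the degenerate histogram pattern", {
  f <- ilqp_features(matrix(7, 12, 10))
  nvalid <- 10 * 8
  expect_equal(unname(f["P8R1.B2.b0255"]), nvalid)
  expect_equal(sum(f[1:256]), nvalid)
  expect_equal(unname(f["P8R1.B1.b0000"]), nvalid)
  expect_equal(unname(f["P8R1.Bm1.b0000"]), nvalid)
  expect_equal(unname(f["P8R1.Bm2.b0000"]), nvalid)
  thr <- attr(f, "thresholds")$P8R1
  expect_equal(unname(thr), c(0, 0))
})

test_that("descriptor equals the naive reference and conserves mass", {
  set.seed(5)
  for (t in 1:8) {
    im <- random_image(16)
    expect_identical(as.numeric(ilqp_features(im)), oracle_ilqp(im))
  }
  im <- random_image(21)
  f <- ilqp_features(im)
  nvalid <- (21 - 2) * (21 - 2)
  for (ch in 0:3) expect_equal(sum(f[ch * 256 + 1:256]), nvalid)
  fn <- ilqp_features(im, normalize = TRUE)
  for (ch in 0:3) expect_equal(sum(fn[ch * 256 + 1:256]), 1, tolerance = 1e-9)
})

test_that("descriptor is shift-invariant and scale-stable", {
  set.seed(6)
  im <- random_image(20, 0, 100)
  expect_identical(as.numeric(ilqp_features(im)),
                   as.numeric(ilqp_features(im + 31.7)))
  # positive scaling leaves every quinary digit unchanged
  T1 <- global_mad(im); T2 <- global_sv(im)
  np <- cellpheno:::.neighbor_planes(im, 8, 1)
  k <- 3.917
  for (row in sample(nrow(np$nb), 30)) {
    d1 <- quinary_code(np$gc[row], np$nb[row, ], T1, T2)
    d2 <- quinary_code(k * np$gc[row], k * np$nb[row, ], k * T1, k * T2)
    expect_identical(d1, d2)
  }
  expect_equal(global_mad(k * im), k * T1, tolerance = 1e-9)
  expect_equal(global_sv(k * im), k * T2, tolerance = 1e-9)
})

test_that("descriptor guards degenerate inputs and oversized scales", {
  expect_error(ilqp_features(matrix(1, 4, 4), scales = list(c(8, 2))),
               "P = 8, R = 2")
  expect_error(ilqp_features(random_image(40), scales = list(c(16, 2))),
               "allow_large")
  expect_error(ilqp_features(matrix(c(1, -1, 2, 3, 4, 5, 6, 7, 8), 3, 3)),
               "non-negative")
  # multi-scale concatenation has the advertised length
  f <- ilqp_features(random_image(24), scales = list(c(8, 1), c(10, 2)))
  expect_length(f, 4 * 256 + 4 * 1024)
})
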