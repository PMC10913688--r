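# Every building block is compared against the scalar-loop oracles of
# helper-oracles.R on seeded random instances in general position.

test_that("channel attention matches the loop oracle", {
  set.seed(101)
  for (i in 1:20) {
    C <- sample(2:8, 1); H <- sample(2:5, 1); W <- sample(2:6, 1)
    x <- rand_map(C, H, W)
    p <- noise_params(init_channel_attention(C, sample(1:4, 1)))
    got <- channel_attention(x, p)
    want <- o_channel_attention(x, p)
    expect_equal(got$weights, want$weights, tolerance = 1e-6)
    expect_equal(got$output, want$output, tolerance = 1e-6)
    expect_true(all(got$weights > 0 & got$weights < 1))
  }
})

test_that("zero-parameter channel attention halves the map", {
  x <- rand_map(3, 2, 2)
  p <- init_channel_attention(3, 2)
  p$W1[] <- 0; p$W2[] <- 0
  got <- channel_attention(x, p)
  expect_equal(got$weights, rep(0.5, 3))
  expect_equal(got$output, 0.5 * x)
  expect_equal(dim(got$output), dim(x))
})

test_that("spatial attention matches the loop oracle", {
  set.seed(103)
  for (i in 1:20) {
    C <- sample(2:6, 1); H <- sample(2:5, 1); W <- sample(3:7, 1)
    x <- rand_map(C, H, W)
    p <- noise_params(init_spatial_attention(sample(c(3, 5), 1)))
    got <- spatial_attention(x, p)
    want <- o_spatial_attention(x, p)
    expect_equal(got$weights, want$weights, tolerance = 1e-6)
    expect_equal(got$output, want$output, tolerance = 1e-6)
    expect_true(all(got$weights > 0 & got$weights < 1))
  }
})

test_that("zero-weight spatial attention halves the map; constant maps give
          constant interior weights", {
  x <- rand_map(2, 3, 4)
  p <- init_spatial_attention(3)
  p$W[] <- 0
  got <- spatial_attention(x, p)
  expect_equal(got$weights, matrix(0.5, 3, 4))
  expect_equal(got$output, 0.5 * x)
  # constant input: same-padded pooling+convolution is translation
  # symmetric away from the borders
  xc <- array(2, c(2, 5, 9))
  set.seed(5)
  p2 <- noise_params(init_spatial_attention(3))
  w <- spatial_attention(xc, p2)$weights
  interior <- w[2:4, 2:8]
  expect_equal(max(interior) - min(interior), 0, tolerance = 1e-12)
})

test_that("CBAM is channel attention then spatial attention, in that order", {
  set.seed(107)
  x <- rand_map(4, 3, 5)
  p <- noise_params(init_cbam(4, 2, 3))
  got <- cbam(x, p)
  step1 <- channel_attention(x, p$channel)$output
  expect_equal(got, spatial_attention(step1, p$spatial)$output,
               tolerance = 1e-12)
  # the reversed composition differs in general
  rev2 <- channel_attention(spatial_attention(x, p$spatial)$output,
                            p$channel)$output
  expect_gt(max(abs(got - rev2)), 1e-4)
  # zero-parameterised sub-modules give exactly a quarter of the input
  p0 <- init_cbam(4, 2, 3)
  p0$channel$W1[] <- 0; p0$channel$W2[] <- 0; p0$spatial$W[] <- 0
  expect_equal(cbam(x, p0), 0.25 * x)
  expect_equal(dim(cbam(rand_map(6, 2, 9), noise_params(init_cbam(6)))),
               c(6, 2, 9))
})

test_that("a dense layer in evaluation mode matches the staged oracle", {
  set.seed(109)
  for (i in 1:20) {
    C <- sample(2:7, 1); H <- sample(3:7, 1); W <- sample(3:9, 1)
    k <- sample(2:6, 1)
    x <- rand_map(C, H, W)
    p <- noise_params(init_dense_layer(C, k, 2, 3))
    p$bn$mean <- rnorm(C, 0, 0.3)
    p$bn$var <- runif(C, 0.5, 2)
    got <- dense_layer(x, p)
    want <- o_dense_layer_eval(x, p)
    expect_equal(got, want, tolerance = 1e-6)
    expect_equal(dim(got), c(k, H, W))   # growth_rate channels, H,W kept
  }
})

test_that("a GRU step matches the scalar oracle", {
  set.seed(113)
  for (i in 1:20) {
    d_in <- sample(2:5, 1); d_h <- sample(2:5, 1)
    p <- noise_params(init_gru(d_in, d_h), sd = 0.3)
    x <- rnorm(d_in); h <- rnorm(d_h)
    expect_equal(gru_step(x, h, p), o_gru_step(x, h, p),
                 tolerance = 1e-10)
  }
  # all-zero weights: z = 0.5, candidate 0, so the state halves
  p <- init_gru(3, 3)
  for (nm in names(p)) p[[nm]][] <- 0
  h <- c(1, -2, 4)
  expect_equal(gru_step(rnorm(3), h, p), 0.5 * h)
  # zero input and state is a fixed point under zero biases
  p2 <- noise_params(init_gru(3, 3), sd = 0.3)
  p2$b_r[] <- 0; p2$b_z[] <- 0; p2$b_h[] <- 0
  expect_equal(gru_step(rep(0, 3), rep(0, 3), p2), rep(0, 3))
  expect_error(gru_step(rnorm(2), rnorm(3), p), "parameter error")
})

test_that("self-attention matches the loop oracle", {
  set.seed(127)
  for (i in 1:20) {
    T_ <- sample(2:6, 1); d_in <- sample(3:6, 1); d_att <- sample(2:5, 1)
    X <- matrix(rnorm(T_ * d_in), T_, d_in)
    p <- noise_params(init_self_attention(d_in, d_att), sd = 0.3)
    got <- self_attention(X, p)
    want <- o_self_attention(X, p)
    expect_equal(got$context, want$context, tolerance = 1e-8)
    expect_equal(got$weights, want$weights, tolerance = 1e-8)
    expect_equal(rowSums(got$weights), rep(1, T_), tolerance = 1e-9)
    # unscaled variant
    got0 <- self_attention(X, p, scale = FALSE)
    expect_equal(got0$weights, o_self_attention(X, p, FALSE)$weights,
                 tolerance = 1e-8)
  }
  # a single position attends to itself with weight exactly 1
  X1 <- matrix(rnorm(4), 1, 4)
  p <- noise_params(init_self_attention(4, 3), sd = 0.3)
  r <- self_attention(X1, p)
  expect_equal(r$weights[1, 1], 1)
  expect_equal(as.vector(r$context), as.vector(p$Wv %*% t(X1)))
})

test_that("the classifier head is a shift-invariant softmax", {
  p <- init_classifier(5)
  p$W[] <- 0
  expect_equal(classifier_head(rnorm(5), p), c(0.5, 0.5))
  set.seed(131)
  for (i in 1:10) {
    p <- noise_params(init_classifier(5), sd = 0.5)
    f <- rnorm(5)
    pr <- classifier_head(f, p)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr > 0))
    p2 <- p; p2$b <- p2$b + 3.7    # common logit shift
    expect_equal(classifier_head(f, p2), pr, tolerance = 1e-12)
  }
})

test_that("batched convolution agrees with the naive loop convolution", {
  set.seed(137)
  for (i in 1:10) {
    C <- sample(1:5, 1); H <- sample(2:6, 1); W <- sample(2:7, 1)
    co <- sample(1:4, 1); k <- sample(c(1, 3, 5), 1)
    x <- rand_map(C, H, W, B = 2)
    p <- init_conv(C, co, k, k)
    p$b <- rnorm(co)
    ci <- deep5mC:::conv_index(C, H, W, k, k)
    got <- deep5mC:::conv2d_forward(x, p, ci)$out
    for (b in 1:2) {
      xb <- array(x[, , , b], dim(x)[1:3])
      yb <- array(got[, , , b], dim(got)[1:3])
      expect_equal(yb, o_conv2d(xb, p$W, p$b, co, k, k),
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})
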