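# Architecture bookkeeping: channels follow c + L*k per block and
# ceiling(compression * c) per transition; spatial dims follow
# ceiling-mode 2x2 stride-2 pooling.

test_that("dense blocks concatenate: channels, pass-through, first layer", {
  set.seed(211)
  x <- rand_map(7, 4, 6)
  blk <- lapply(1:4, function(l)
    noise_params(init_dense_layer(7 + (l - 1) * 12, 12, 8, 3)))
  out <- dense_block(x, blk)
  expect_equal(dim(out), c(7 + 4 * 12, 4, 6))        # 55 channels
  # the block output's first c_in channels are the input unchanged
  expect_equal(out[1:7, , ], x)
  # layer 1 consumes exactly the block input
  l1 <- dense_layer(x, blk[[1]])
  expect_equal(out[8:19, , ], l1)
})

test_that("transitions compress channels and ceiling-pool the map", {
  set.seed(223)
  x <- rand_map(56, 7, 41)
  p <- init_transition(56, 0.5)
  out <- transition_layer(x, p)
  expect_equal(dim(out), c(28, 4, 21))
  # pooling a constant map returns the same constant
  xc <- array(3.5, c(2, 5, 7, 1))
  pool <- deep5mC:::avgpool2_forward(xc)$out
  expect_equal(pool, array(3.5, c(2, 3, 4, 1)))
  expect_error(init_transition(10, 0), "compression")
})

test_that("built models match the closed-form shape recurrence", {
  set.seed(227)
  for (i in 1:10) {
    cfg <- model_config(
      num_dense_blocks = sample(1:4, 1),
      layers_per_block = sample(1:3, 1),
      growth_rate = sample(2:8, 1),
      compression = sample(c(0.3, 0.5, 0.8), 1),
      spatial_kernel = sample(c(3, 5, 7), 1),
      gru_hidden = 4, attention_dim = 4,
      window_length = sample(c(9, 21, 41), 1),
      encoding = sample(c("merged", "onehot", "ncp"), 1),
      seed = i)
    mod <- build_model(cfg, quiet = TRUE)
    # recompute the recurrence independently
    C <- 1; H <- switch(cfg$encoding, merged = 7, onehot = 4, ncp = 3)
    W <- cfg$window_length
    for (b in seq_len(cfg$num_dense_blocks)) {
      C <- C + cfg$layers_per_block * cfg$growth_rate
      if (b < cfg$num_dense_blocks) {
        C <- ceiling(cfg$compression * C)
        H <- ceiling(H / 2); W <- ceiling(W / 2)
      }
    }
    expect_equal(mod$shapes$C, C)
    expect_equal(mod$shapes$D, C * H)
    expect_equal(mod$shapes$T, W)
    # and the actual forward pass delivers one probability pair per input
    x <- array(runif(H * 0 + switch(cfg$encoding, merged = 7, onehot = 4,
                                    ncp = 3) * cfg$window_length * 3),
               c(switch(cfg$encoding, merged = 7, onehot = 4, ncp = 3),
                 cfg$window_length, 3))
    fw <- deep5mC:::model_forward(mod, x)
    expect_equal(dim(fw$probs), c(2L, 3L))
    expect_equal(colSums(fw$probs), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("the default configuration has four dense blocks", {
  cfg <- model_config()
  expect_equal(cfg$num_dense_blocks, 4)
  mod <- build_model(cfg, quiet = TRUE)
  expect_length(mod$params$blocks, 4)
  expect_length(mod$params$trans, 3)
  tab <- describe_model(mod)
  expect_true("dense_block_4" %in% tab$stage)
  expect_gt(attr(tab, "n_params"), 0)
})

test_that("BiGRU output geometry and symmetry properties hold", {
  set.seed(229)
  p <- noise_params(init_bigru(4, 5), sd = 0.3)
  X <- matrix(rnorm(6 * 4), 6, 4)
  H <- bigru(X, p)
  expect_equal(dim(H), c(6L, 10L))
  # a single position is seen identically by both directions
  p_shared <- p; p_shared$backward <- p_shared$forward
  H1 <- bigru(X[1, , drop = FALSE], p_shared)
  expect_equal(H1[1, 1:5], H1[1, 6:10])
  # palindromic input with shared directions: reversing positions swaps
  # the forward and backward halves
  Xp <- rbind(X[1:3, ], X[3:1, ])
  Hp <- bigru(Xp, p_shared)
  expect_equal(Hp[6:1, c(6:10, 1:5)], Hp, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(bigru(matrix(nrow = 0, ncol = 3), p), "input error")
})

test_that("CBAM and dense layers never change the spatial extent", {
  set.seed(233)
  for (i in 1:5) {
    C <- sample(2:6, 1); H <- sample(1:6, 1); W <- sample(2:9, 1)
    x <- rand_map(C, H, W)
    expect_equal(dim(cbam(x, noise_params(init_cbam(C, 2, 3)))),
                 c(C, H, W))
    k <- sample(2:5, 1)
    expect_equal(dim(dense_layer(x, noise_params(init_dense_layer(C, k, 2, 3)))),
                 c(k, H, W))
  }
})

test_that("builds and forward passes are bit-identical under one seed", {
  cfg <- small_config(window_length = 9, seed = 77)
  d <- generate_dataset(synthetic_spec(6, 10, window_length = 9, seed = 5,
                                       motif = consensus_pwm("TGA"),
                                       motif_offset = 2))
  x <- encode_dataset(d)
  m1 <- build_model(cfg, quiet = TRUE)
  m2 <- build_model(cfg, quiet = TRUE)
  expect_identical(m1$params, m2$params)
  f1 <- deep5mC:::model_forward(m1, x)
  f2 <- deep5mC:::model_forward(m2, x)
  expect_identical(f1$probs, f2$probs)
})
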