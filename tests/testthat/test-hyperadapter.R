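test_that("adapter reduces to the identity when the up-path is zeroed", {
  set.seed(101)
  h <- 6L; d <- 3L
  p <- random_adapter_params(h, d)
  p$W_U <- matrix(0, h, d); p$b_U <- rep(0, h); p$beta <- rep(0, h)
  x <- rnorm(h)
  expect_equal(adapter_apply(x, p), x, tolerance = 1e-12)
  X <- matrix(rnorm(4 * h), 4, h)
  expect_equal(adapter_apply(X, p), X, tolerance = 1e-12)
  expect_error(adapter_apply(c(x[-1], NA), p), "non-finite")
})

test_that("adapter layer norm matches the hand-computed two-channel case", {
  # pass-through projections built in the exactly-linear regime of GeLU:
  # D shifts far into the positive branch, U shifts back
  p <- list(W_D = diag(2), b_D = c(20, 20), W_U = diag(2), b_U = c(-20, -20),
            beta = c(0, 0), gamma = c(1, 1))
  x <- c(1, 3)
  out <- adapter_apply(x, p, eps = 0)
  # LN((1,3)) = (-1, +1) with mu = 2, sigma = 1; plus the skip connection
  expect_equal(out, c(0, 4), tolerance = 1e-9)
})

test_that("adapter_apply matches a straight-line oracle on random instances", {
  set.seed(102)
  for (i in 1:100) {
    h <- sample(2:10, 1); d <- sample(1:(h - 1), 1)
    p <- random_adapter_params(h, d)
    x <- rnorm(h, 0, 2)
    expect_equal(adapter_apply(x, p), naive_adapter(x, p, 1e-5),
                 tolerance = 1e-6)
  }
})

test_that("conditioning input concatenates metadata with site embeddings", {
  cfg <- encoder_config(h = 8, L = 3, e = 8, s = 4, d = 2, n_heads = 2)
  hp <- init_hypernet_params(cfg, meta_dim = 9, seed = 1)
  m <- rnorm(9)
  expect_length(conditioning_input(m, 0, 0, hp), 9 + 2 * 8)
  c00 <- conditioning_input(m, 0, 0, hp)
  c01 <- conditioning_input(m, 0, 1, hp)
  c10 <- conditioning_input(m, 1, 0, hp)
  # changing j touches only the position block
  expect_equal(c00[1:(9 + 8)], c01[1:(9 + 8)])
  expect_false(isTRUE(all.equal(c00[(9 + 8 + 1):(9 + 16)],
                                c01[(9 + 8 + 1):(9 + 16)])))
  # changing i touches only the layer block
  expect_equal(c00[1:9], c10[1:9])
  expect_equal(c00[(9 + 9):(9 + 16)], c10[(9 + 9):(9 + 16)])
  expect_error(conditioning_input(m, 3, 0, hp), "out of range")
  expect_error(conditioning_input(m, 0, 2, hp), "position index")
})

test_that("subject embedding matches its oracle and masks negative units", {
  set.seed(103)
  cfg <- encoder_config(h = 8, L = 2, e = 4, s = 5, d = 2, hI_hidden = 7,
                        n_heads = 2)
  hp <- init_hypernet_params(cfg, meta_dim = 6, seed = 3)
  for (i in 1:100) {
    cond <- rnorm(6 + 2 * 4)
    expect_equal(subject_embedding(cond, hp),
                 naive_subject_embedding(cond, hp), tolerance = 1e-6)
  }
  # zero second-stage weights: embedding equals the second-stage bias
  hp0 <- hp
  hp0$hI$W2 <- hp0$hI$W2 * 0
  hp0$hI$b2 <- rnorm(5)
  expect_equal(subject_embedding(rnorm(14), hp0), hp0$hI$b2)
})

test_that("generated adapter parameters match an index-level oracle and are linear", {
  set.seed(104)
  cfg <- encoder_config(h = 8, L = 2, e = 4, s = 5, d = 3, n_heads = 2)
  hp <- init_hypernet_params(cfg, meta_dim = 6, seed = 4)
  hp$gen_U$W <- matrix(rnorm(length(hp$gen_U$W), 0, 0.3), nrow(hp$gen_U$W))
  hp$gen_ln$W <- matrix(rnorm(length(hp$gen_ln$W), 0, 0.3), nrow(hp$gen_ln$W))
  for (i in 1:100) {
    I <- rnorm(5)
    p <- generate_adapter_params(I, hp, cfg)
    pn <- naive_generate_params(I, hp, cfg$h, cfg$d)
    for (f in names(p)) expect_equal(p[[f]], pn[[f]], tolerance = 1e-6)
  }
  # element (k, l) of W_D is the dot product with the matching generator row
  I <- rnorm(5)
  p <- generate_adapter_params(I, hp, cfg)
  k <- 2; l <- 5
  row <- (l - 1) * cfg$d + k # column-major layout of the d x h matrix
  expect_equal(p$W_D[k, l], sum(hp$gen_D$W[row, ] * I) + hp$gen_D$b[row])
  # linearity with zero generator biases
  hp0 <- hp
  hp0$gen_D$b <- hp0$gen_D$b * 0
  hp0$gen_U$b <- hp0$gen_U$b * 0
  hp0$gen_ln$b <- hp0$gen_ln$b * 0
  I1 <- rnorm(5); I2 <- rnorm(5)
  pa <- generate_adapter_params(2 * I1 + 3 * I2, hp0, cfg)
  p1 <- generate_adapter_params(I1, hp0, cfg)
  p2 <- generate_adapter_params(I2, hp0, cfg)
  for (f in names(pa)) {
    expect_equal(pa[[f]], 2 * p1[[f]] + 3 * p2[[f]], tolerance = 1e-10)
  }
  # all-zero embedding with zero biases gives the exact identity adapter
  pz <- generate_adapter_params(rep(0, 5), hp0, cfg)
  x <- rnorm(8)
  expect_equal(adapter_apply(x, pz), x, tolerance = 1e-12)
})

test_that("full forward pass matches an independent naive implementation", {
  set.seed(105)
  cfg <- encoder_config(input_dim = 5, h = 8, L = 2, n_heads = 2, d = 3,
                        s = 4, e = 3, hI_hidden = 6, n_frames = 4)
  bb <- init_encoder_params(cfg, seed = 7)
  bb$head$w <- rnorm(8, 0, 0.5); bb$head$b <- 0.3
  hp <- init_hypernet_params(cfg, meta_dim = 6, seed = 8)
  hp$gen_U$W <- matrix(rnorm(length(hp$gen_U$W), 0, 0.2), nrow(hp$gen_U$W))
  hp$gen_ln$W <- matrix(rnorm(length(hp$gen_ln$W), 0, 0.2), nrow(hp$gen_ln$W))
  for (i in 1:10) {
    frames <- matrix(rnorm(4 * 5), 4, 5)
    m <- rnorm(6)
    # plain encoder
    expect_equal(finetune_encoder_forward(frames, bb, cfg),
                 naive_encoder_forward(frames, bb, cfg), tolerance = 1e-5)
    # personalized encoder
    sites <- lapply(0:(cfg$L - 1), function(li) lapply(0:1, function(j) {
      generate_adapter_params(
        subject_embedding(conditioning_input(m, li, j, hp), hp), hp, cfg)
    }))
    expect_equal(hyperformer_forward(frames, m, bb, hp, cfg),
                 naive_encoder_forward(frames, bb, cfg, adapters = sites),
                 tolerance = 1e-5)
  }
})

test_that("subjects with identical metadata get identical predictions", {
  set.seed(106)
  cfg <- encoder_config(input_dim = 6, h = 8, L = 2, n_heads = 2, d = 3,
                        s = 4, e = 3, n_frames = 3)
  bb <- init_encoder_params(cfg, seed = 9)
  bb$head$w <- rnorm(8, 0, 0.5)
  hp <- init_hypernet_params(cfg, meta_dim = 5, seed = 10)
  hp$gen_U$W <- matrix(rnorm(length(hp$gen_U$W), 0, 0.3), nrow(hp$gen_U$W))
  frames <- matrix(rnorm(3 * 6), 3, 6)
  m1 <- rnorm(5)
  expect_equal(hyperformer_forward(frames, m1, bb, hp, cfg),
               hyperformer_forward(frames, m1 + 0, bb, hp, cfg))
  m2 <- m1 + rnorm(5)
  expect_false(isTRUE(all.equal(hyperformer_forward(frames, m1, bb, hp, cfg),
                                hyperformer_forward(frames, m2, bb, hp, cfg))))
  expect_error(hyperformer_forward(matrix(rnorm(12), 3, 4), m1, bb, hp, cfg),
               "frame width|input_dim")
})

test_that("without positional encodings the prediction is permutation-invariant", {
  set.seed(107)
  cfg <- encoder_config(input_dim = 5, h = 8, L = 2, n_heads = 2, d = 3,
                        s = 4, e = 3, n_frames = 6, use_positions = FALSE)
  bb <- init_encoder_params(cfg, seed = 11)
  bb$head$w <- rnorm(8, 0, 0.5)
  frames <- matrix(rnorm(6 * 5), 6, 5)
  p1 <- finetune_encoder_forward(frames, bb, cfg)
  p2 <- finetune_encoder_forward(frames[sample(6), ], bb, cfg)
  expect_equal(p1, p2, tolerance = 1e-10)
  # with positions on, order matters
  cfg_pos <- encoder_config(input_dim = 5, h = 8, L = 2, n_heads = 2, d = 3,
                            s = 4, e = 3, n_frames = 6, use_positions = TRUE)
  q1 <- finetune_encoder_forward(frames, bb, cfg_pos)
  q2 <- finetune_encoder_forward(frames[6:1, ], bb, cfg_pos)
  expect_false(isTRUE(all.equal(q1, q2)))
})

test_that("hypernetwork memory does not grow with depth beyond the embeddings", {
  cfg2 <- encoder_config(h = 16, L = 2, d = 4, s = 8, e = 4, n_heads = 2)
  cfg8 <- encoder_config(h = 16, L = 8, d = 4, s = 8, e = 4, n_heads = 2)
  n2 <- count_params(init_hypernet_params(cfg2, meta_dim = 9, seed = 1))
  n8 <- count_params(init_hypernet_params(cfg8, meta_dim = 9, seed = 1))
  expect_equal(n8 - n2, (8 - 2) * cfg2$e)
})

test_that("config invariants are enforced", {
  expect_error(encoder_config(h = 8, d = 8), "smaller than h")
  expect_error(encoder_config(h = 9, n_heads = 2), "divisible")
})
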