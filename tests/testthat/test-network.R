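test_that("channel pooling matches an explicit loop oracle", {
  x <- array(c(1, 3, 2, 4), c(2, 2, 1))  # channel [[1,2],[3,4]]
  p <- channel_pool(x)
  expect_equal(p$gap, 2.5)
  expect_equal(p$gmp, 4)

  v <- array(5.5, c(3, 4, 2))
  expect_equal(channel_pool(v)$gap, c(5.5, 5.5))
  expect_equal(channel_pool(v)$gmp, c(5.5, 5.5))
  z <- array(0, c(3, 3, 4))
  expect_equal(channel_pool(z)$gap, rep(0, 4))
  expect_equal(channel_pool(z)$gmp, rep(0, 4))

  for (seed in 1:10) {
    set.seed(seed)
    d <- c(sample(2:6, 2, TRUE), sample(1:5, 1))
    x <- array(rnorm(prod(d)), d)
    expect_equal(channel_pool(x), channel_pool_loop(x))
  }
})

test_that("zero-initialized attention branches halve X and fuse to X", {
  for (seed in 1:5) {
    set.seed(seed)
    c0 <- sample(c(2, 4, 6), 1)
    h <- 2 * sample(3:8, 1)
    w <- 2 * sample(3:8, 1)
    X <- array(rnorm(h * w * c0), c(h, w, c0))
    Y <- array(rnorm(h / 2 * w / 2 * 2 * c0), c(h / 2, w / 2, 2 * c0))
    pz <- attention_params(c0, zero_init = TRUE)
    expect_equal(spatial_attention(X, Y, pz), 0.5 * X, tolerance = 1e-10)
    expect_equal(channel_attention(X, Y, pz), 0.5 * X, tolerance = 1e-10)
    expect_equal(hybrid_attention(X, Y, pz), X, tolerance = 1e-10)
  }
})

test_that("attention gates shrink features and preserve shape", {
  set.seed(42)
  X <- array(rnorm(12 * 8 * 4), c(12, 8, 4))
  Y <- array(rnorm(6 * 4 * 8), c(6, 4, 8))
  pr <- attention_params(4)
  sa <- spatial_attention(X, Y, pr)
  ca <- channel_attention(X, Y, pr)
  ha <- hybrid_attention(X, Y, pr)
  expect_equal(dim(sa), dim(X))
  expect_equal(dim(ca), dim(X))
  expect_equal(dim(ha), dim(X))
  # multiplicative gates with sigmoid weights cannot grow any element
  expect_true(all(abs(sa) <= abs(X) + 1e-12))
  expect_true(all(abs(ca) <= abs(X) + 1e-12))
  # zero input is annihilated regardless of Y
  Z <- X * 0
  expect_equal(spatial_attention(Z, Y, pr), Z)
  expect_equal(channel_attention(Z, Y, pr), Z)
  expect_equal(hybrid_attention(Z, Y, pr), Z)
  # shape contract violations are rejected
  expect_error(spatial_attention(X, array(0, c(6, 4, 4)), pr), "channels")
  expect_error(spatial_attention(X, array(0, c(5, 4, 8)), pr), "half")
})

test_that("dense blocks preserve shape and stack receptive fields", {
  set.seed(1)
  p <- dense_block_params(3, 5, dense_layers = 2, growth = 4)
  x <- array(rnorm(10 * 12 * 3), c(10, 12, 3))
  y <- dense_block(x, p)
  expect_equal(dim(y), c(10L, 12L, 5L))
  expect_error(dense_block(array(0, c(10, 12, 4)), p), "channel mismatch")

  # zero input through zero weights (no normalization) stays zero
  pz <- dense_block_params(2, 3, dense_layers = 2, growth = 2, norm = "none")
  pz0 <- lapply(pz, function(w) w * 0)
  attributes(pz0) <- attributes(pz)
  expect_equal(dense_block(array(0, c(8, 8, 2)), pz0),
               array(0, c(8, 8, 3)))

  # impulse response of 6 stacked 3x3 convs spans 13x13
  set.seed(2)
  pp <- dense_block_params(1, 1, dense_layers = 6, growth = 2, norm = "none")
  pabs <- lapply(pp, function(w) abs(w))
  attributes(pabs) <- attributes(pp)
  n <- 21
  imp <- array(0, c(n, n, 1))
  imp[11, 11, 1] <- 1
  base <- dense_block(array(0, c(n, n, 1)), pabs)
  diffm <- abs(dense_block(imp, pabs) - base)[, , 1]
  hit <- which(diffm > 1e-12, arr.ind = TRUE)
  expect_equal(max(hit[, 1]) - min(hit[, 1]) + 1, 13)
  expect_equal(max(hit[, 2]) - min(hit[, 2]) + 1, 13)
})

test_that("the assembled model meets its shape, range and determinism contracts", {
  cfg <- model_config(in_size = 224, n_blocks = 4, base_channels = 2,
                      dense_layers = 2, growth = 2, n3d_blocks = 2)
  m <- build_model(cfg, seed = 5)
  x <- array(runif(224 * 224 * 3, 0, 255), c(224, 224, 3))
  p <- predict_slice(m, x)
  expect_equal(dim(p), c(224L, 224L))
  expect_true(all(p > 0 & p < 1))
  expect_identical(predict_slice(m, x), p)

  # boundary-replicated 2.5D input is accepted
  v <- rand_volume(c(224, 224, 4), seed = 8)
  st <- extract_slices(v, "axial")
  expect_silent(predict_slice(m, make_input25d(st, 1)))

  # ablation arm without attention builds and runs
  cfg0 <- model_config(in_size = 32, n_blocks = 3, base_channels = 4,
                       dense_layers = 2, growth = 4, n3d_blocks = 1,
                       attention = "none")
  m0 <- build_model(cfg0, seed = 5)
  p0 <- predict_slice(m0, array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3)))
  expect_equal(dim(p0), c(32L, 32L))

  expect_error(model_config(in_size = 30, n_blocks = 3), "divisible")
  expect_error(predict_slice(m0, array(0, c(16, 16, 3))), "input must be")
})

test_that("hybrid attention adds trainable parameters over plain skips", {
  for (base in c(4, 8)) {
    cfg_h <- model_config(in_size = 32, n_blocks = 3, base_channels = base,
                          dense_layers = 2, growth = base, n3d_blocks = 1,
                          attention = "hybrid")
    cfg_n <- model_config(in_size = 32, n_blocks = 3, base_channels = base,
                          dense_layers = 2, growth = base, n3d_blocks = 1,
                          attention = "none")
    expect_gt(count_parameters(build_model(cfg_h, seed = 1)),
              count_parameters(build_model(cfg_n, seed = 1)))
  }
})

test_that("backpropagated gradients match central finite differences", {
  cfg <- model_config(in_size = 16, n_blocks = 2, base_channels = 3,
                      dense_layers = 2, growth = 3, n3d_blocks = 1)
  m <- build_model(cfg, seed = 3)
  set.seed(99)
  x <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  y <- (matrix(runif(256), 16, 16) > 0.7) * 1
  tape <- pancseg:::new_tape()
  out <- pancseg:::.forward_seg(m, x, tape)
  loss <- pancseg:::op_dice_loss(tape, out, y)
  pancseg:::tape_backward(tape, loss)
  g <- pancseg:::tape_param_grads(tape)
  expect_true(all(is.finite(unlist(g))))

  loss_at <- function() {
    o <- pancseg:::.forward_seg(m, x, NULL)
    pancseg:::op_dice_loss(NULL, o, y)$value
  }
  h <- 1e-5
  set.seed(12)
  rel <- c()
  for (nm in sample(names(g), 10)) {
    p <- get(nm, envir = m$params)
    i <- sample(length(p), 1)
    p2 <- p; p2[i] <- p2[i] + h
    assign(nm, p2, envir = m$params); up <- loss_at()
    p2[i] <- p[i] - h
    assign(nm, p2, envir = m$params); dn <- loss_at()
    assign(nm, p, envir = m$params)
    num <- (up - dn) / (2 * h)
    rel <- c(rel, abs(num - g[[nm]][i]) / max(1e-8, abs(num) + abs(g[[nm]][i])))
  }
  # ReLU/max-pool kinks can spoil individual finite differences, so assert
  # on the bulk of the sample
  expect_lt(stats::median(rel), 1e-5)
  expect_gte(sum(rel < 1e-3), 9)
})

test_that("checkpoints reload to an identical model", {
  cfg <- tiny_model_cfg()
  m <- build_model(cfg, seed = 21)
  x <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  prefix <- file.path(tempdir(), "ckpt")
  save_model(m, prefix)
  expect_true(file.exists(paste0(prefix, ".json")))
  m2 <- load_model(prefix)
  expect_identical(predict_slice(m2, x), predict_slice(m, x))
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(sidecar$n_blocks, cfg$n_blocks)
})
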