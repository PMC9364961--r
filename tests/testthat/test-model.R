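test_that("shape trace reproduces the canonical dimension list", {
  tr <- shape_trace(model_config())
  expected <- c(input = "300 x 2", lstm1 = "300 x 64", lstm2 = "64",
                conv1 = "296 x 64", pool1 = "98 x 64", conv2 = "94 x 32",
                pool2 = "31 x 32", flatten = "992", concatenate = "1056",
                fc1 = "64", fc2 = "32", softmax = "5")
  expect_equal(stats::setNames(tr$shape, tr$layer), expected)

  # boundary: kernel spanning the whole input leaves one position
  tr2 <- shape_trace(model_config(input_len = 5,
                                  conv_specs = list(c(4, 5)),
                                  pool_size = 1, fc_sizes = 4))
  expect_equal(tr2$shape[tr2$layer == "conv1"], "1 x 4")

  expect_error(shape_trace(model_config(input_len = 4,
                                        conv_specs = list(c(4, 5)))),
               "conv1")
})

test_that("shape trace equals a brute-force recomputation on random configs", {
  set.seed(31)
  for (r in 1:20) {
    nconv <- sample(1:3, 1)
    ker <- sample(2:6, nconv, replace = TRUE)
    fil <- sample(c(4, 8, 16), nconv, replace = TRUE)
    cfg <- try(model_config(
      input_len = sample(40:200, 1), input_channels = sample(1:3, 1),
      lstm_units = sample(c(4, 8, 16), 1), lstm_layers = sample(1:3, 1),
      conv_specs = Map(c, fil, ker), pool_size = sample(2:4, 1),
      fc_sizes = sample(c(8, 16), sample(1:2, 1), replace = TRUE),
      n_classes = 5), silent = TRUE)
    tr <- try(shape_trace(cfg), silent = TRUE)
    if (inherits(tr, "try-error")) next
    # independent step-by-step recomputation
    L <- cfg$input_len
    ok <- TRUE
    for (i in seq_len(nconv)) {
      L <- L - ker[i] + 1
      ok <- ok && identical(trace_len <- attr(tr, "dims")[[
        match(sprintf("conv%d", i), tr$layer)]][1], as.integer(L))
      L <- floor(L / cfg$pool_size)
      ok <- ok && identical(attr(tr, "dims")[[
        match(sprintf("pool%d", i), tr$layer)]][1], as.integer(L))
    }
    expect_true(ok)
    expect_equal(attr(tr, "dims")[[match("flatten", tr$layer)]],
                 as.integer(L * fil[nconv]))
    expect_equal(attr(tr, "dims")[[match("concatenate", tr$layer)]],
                 as.integer(L * fil[nconv] + cfg$lstm_units))
  }
})

test_that("conv1d_valid is exact cross-correlation", {
  # identity kernel passes the input through
  x <- matrix(rnorm(20), 10, 2)
  idk <- array(0, c(1, 2, 2)); idk[1, 1, 1] <- 1; idk[1, 2, 2] <- 1
  expect_equal(conv1d_valid(x, idk, c(0, 0)), x, ignore_attr = TRUE)

  # hand-computable sliding sum
  expect_equal(drop(conv1d_valid(matrix(1:4), array(c(1, 1), c(2, 1, 1)),
                                 0)),
               c(3, 5, 7))

  # random instances against the triple-loop oracle
  set.seed(11)
  for (r in 1:20) {
    L <- sample(6:15, 1); C <- sample(1:3, 1)
    K <- sample(2:4, 1); F <- sample(1:4, 1)
    x <- matrix(rnorm(L * C), L, C)
    k <- array(rnorm(K * C * F), c(K, C, F))
    b <- rnorm(F)
    expect_equal(conv1d_valid(x, k, b), naive_conv1d(x, k, b),
                 tolerance = 1e-10)
  }

  expect_error(conv1d_valid(matrix(1, 3, 2), array(1, c(2, 3, 1))),
               "channels")
  expect_error(conv1d_valid(matrix(1, 2, 1), array(1, c(5, 1, 1))),
               "longer")
})

test_that("lstm_cell_step follows the gate equations", {
  # all-zero parameters force the sigmoid(0) = 1/2 closed form
  U <- 3
  zp <- list(W_f = matrix(0, U, U + 1), W_i = matrix(0, U, U + 1),
             W_o = matrix(0, U, U + 1), W_c = matrix(0, U, U + 1),
             b_f = numeric(U), b_i = numeric(U), b_o = numeric(U),
             b_c = numeric(U))
  v <- c(1, -2, 0.5)
  st <- lstm_cell_step(zp, x_t = 0.3, h_prev = numeric(U), c_prev = v)
  expect_equal(st$c, 0.5 * v)
  expect_equal(st$h, 0.5 * tanh(0.5 * v))

  # saturated gates: forget ~1, input ~0 gives perfect memory
  sat <- zp
  sat$b_f <- rep(40, U); sat$b_i <- rep(-40, U)
  expect_equal(lstm_cell_step(sat, 0.3, rnorm(U), v)$c, v,
               tolerance = 1e-12)

  # random instances against the scalar oracle
  set.seed(13)
  for (r in 1:20) {
    U <- sample(2:5, 1); D <- sample(1:4, 1)
    p <- random_lstm_params(U, D)
    x <- rnorm(D); h0 <- rnorm(U); c0 <- rnorm(U)
    got <- lstm_cell_step(p, x, h0, c0)
    want <- naive_lstm_step(p, x, h0, c0)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
  }

  expect_error(lstm_cell_step(zp, c(1, 2), numeric(3), numeric(3)), "W_f")
})

test_that("attention pooling is an exp-normalized weighted sum", {
  h <- matrix(rnorm(8), 2, 4)
  expect_equal(attention_pool(h[1, , drop = FALSE], 3.7), h[1, ])
  expect_equal(attention_pool(h, c(1, 1)), (h[1, ] + h[2, ]) / 2)
  set.seed(7)
  H <- matrix(rnorm(40), 10, 4); sc <- rnorm(10)
  a <- exp(sc - max(sc)); a <- a / sum(a)
  expect_equal(attention_pool(H, sc), colSums(a * H), tolerance = 1e-12)
})

test_that("build_model realizes the static shape trace", {
  cfg <- tiny_config()
  p <- build_model(cfg, seed = 2)
  expect_identical(realized_trace(p, cfg)$shape, shape_trace(cfg)$shape)

  # canonical architecture too (single forward pass)
  cfg2 <- model_config()
  p2 <- build_model(cfg2, seed = 2)
  expect_identical(realized_trace(p2, cfg2)$shape, shape_trace(cfg2)$shape)

  # determinism of initialization
  expect_identical(unclass(build_model(cfg, seed = 5)),
                   unclass(build_model(cfg, seed = 5)))
  expect_false(identical(unclass(build_model(cfg, seed = 5)),
                         unclass(build_model(cfg, seed = 6))))
})

test_that("forward pass yields proper softmax rows and uniform start", {
  cfg <- tiny_config()
  p <- build_model(cfg, seed = 3)
  x <- array(rnorm(60 * 2 * 7, sd = 0.5), c(60, 2, 7))
  pr <- sleepstager:::forward_reference(p, cfg, x)
  expect_equal(dim(pr), c(7, 5))
  expect_true(all(pr >= 0))
  expect_equal(rowSums(pr), rep(1, 7), tolerance = 1e-6)
  # zero-initialized softmax layer: exactly uniform class probabilities
  expect_true(all(abs(pr - 0.2) < 1e-12))
})

test_that("compiled engine agrees with the reference forward pass", {
  cfg <- tiny_config()
  set.seed(21)
  p <- build_model(cfg, seed = 4)
  # randomize the head and batch-norm state so agreement is non-trivial
  p$out_W <- matrix(rnorm(8 * 5, sd = 0.5), 8, 5)
  p$out_b <- rnorm(5, sd = 0.2)
  for (i in 1:2) {
    nm <- sprintf("conv%d_", i)
    p[[paste0(nm, "rmean")]] <- rnorm(8, sd = 0.1)
    p[[paste0(nm, "rvar")]] <- runif(8, 0.5, 1.5)
    p[[paste0(nm, "beta")]] <- rnorm(8, sd = 0.1)
  }
  x <- array(rnorm(60 * 2 * 5, sd = 0.5), c(60, 2, 5))
  ref <- sleepstager:::forward_reference(p, cfg, x)
  cs <- cfg$conv_specs
  eng <- sleepstager:::cpp_predict(unclass(p), x, unclass(cfg),
                                   vapply(cs, `[`, 0L, 1),
                                   vapply(cs, `[`, 0L, 2), cfg$fc_sizes)
  expect_equal(eng, ref, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("inference has no cross-example leakage and no dropout noise", {
  cfg <- tiny_config()
  recs <- generate_dataset(1, 1, 12, fs_hz = 100, seed = 6)
  fit <- sleep_stager(recs, cfg,
                      train_schedule(epochs = 2, batch_size = 4, seed = 6))
  inp <- as_model_input(recs, model_fs_hz = 2)
  p1 <- predict(fit, inp, type = "prob")
  p2 <- predict(fit, inp, type = "prob")
  expect_identical(p1, p2)              # dropout inactive at inference

  perm <- sample(seq_len(dim(inp$x)[3]))
  pp <- predict(fit, list(x = inp$x[, , perm, drop = FALSE]), type = "prob")
  expect_equal(pp, p1[perm, ], tolerance = 1e-6, ignore_attr = TRUE)

  lab <- predict(fit, inp, type = "both")
  expect_equal(as.integer(lab$stage), max.col(lab$prob, "first"))

  # shape-nonconforming input is rejected
  bad <- array(0, c(30, 2, 1))
  expect_error(predict(fit, list(x = bad)), "conform")
})
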