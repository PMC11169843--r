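test_that("cross-entropy loss matches closed forms", {
  expect_equal(compute_loss(rep(0, 10), 3), log(10), tolerance = 1e-12)
  expect_equal(compute_loss(c(1, 0), 1), log(1 + exp(-1)),
               tolerance = 1e-12)
  # pushing the true-class membrane up drives the loss to zero
  expect_lt(compute_loss(c(50, 0, 0), 1), 1e-12)
  # batch version averages
  m <- cbind(rep(0, 4), c(10, 0, 0, 0))
  expect_equal(compute_loss(m, c(1, 1)), (log(4) + compute_loss(c(10, 0, 0, 0), 1)) / 2)
  expect_error(compute_loss(c(1, 0), 3), "range")
  expect_error(compute_loss(cbind(c(1, 0)), c(1, 2)), "one label per")
})

test_that("backward_spike sums spatial and temporal contributions", {
  z <- matrix(0, 2, 2)
  expect_equal(backward_spike(z, z, z), z)
  a <- matrix(1:4, 2)
  expect_equal(backward_spike(a), a)                 # T = 1: no future term
  expect_equal(backward_spike(a, a, NULL), 2 * a)
  expect_equal(backward_spike(a, a, a), 3 * a)
  expect_error(backward_spike(a, matrix(0, 3, 3)), "shape")
})

test_that("backward_membrane routes both pathways through the surrogate", {
  # membrane far below both windows: zero gradient
  expect_equal(backward_membrane(list(1, 1), 0, c(1, 1)), 0)
  # v=0.6, Vth0=1, Vth1=0.5: h(0.6)/1 + h(1.2)/0.5 = 1 + 2
  expect_equal(backward_membrane(list(1, 1), 0.6, c(1, 0.5)), 3)
  # upstream only on pathway 1
  expect_equal(backward_membrane(list(0, 1), 0.6, c(1, 0.5)), 2)
  # future term scaled by leak and the reset carry
  g <- backward_membrane(list(0, 0), 0.6, c(1, 0.5),
                         grad_spikes_t1 = list(1, 0), membrane_t1 = 0.9,
                         spike0_t = 0, leak = 0.5)
  expect_equal(g, 0.5 * 1 * surrogate_gradient(0.9) / 1)
  expect_error(backward_membrane(list(1), 0.5, c(1, 0.5)), "per threshold")
})

test_that("threshold_gradient evaluates the scaled membrane term", {
  # u = 1.6 lies outside the window: no contribution
  expect_equal(threshold_gradient(1, 0.8, 0.5), 0)
  # v=0.6, Vth=0.5: 1 * 1 * (-0.6/0.25)
  expect_equal(threshold_gradient(1, 0.6, 0.5), -2.4)
  # sums over neurons and timesteps
  expect_equal(threshold_gradient(list(c(1, 1)), list(c(0.6, 0.6)), 0.5),
               -4.8)
  expect_error(threshold_gradient(1, 0.5, -1), "positive")
})

test_that("STBP gradients match the literal chain-rule oracle", {
  nets <- list(list(arch = "1dtc3-2fc", shape = c(2, 2, 1)),
               list(arch = "1dtc3-1c3-2fc", shape = c(2, 2, 1)),
               list(arch = "1dtc3-p2-2fc", shape = c(2, 2, 1)),
               list(arch = "1c3-2fc-2fc", shape = c(2, 2, 1)))
  set.seed(23)
  for (net in nets) {
    arch <- parse_arch(net$arch, net$shape)
    params <- init_params(arch, gain = 2)
    # desynchronise the thresholds so both pathways carry signal
    for (i in seq_along(params$layers)) {
      if (length(params$layers[[i]]$vth) == 2L) {
        params$layers[[i]]$vth <- c(0.5, 0.35)
      }
    }
    imgs <- array(runif(prod(net$shape) * 2), c(net$shape, 2L))
    labels <- c(1L, 2L)
    for (tt in 1:3) {
      for (full in c(FALSE, TRUE)) {
        fwd <- network_forward(arch, params, imgs, tt, trace = TRUE)
        bk <- network_backward(arch, params, fwd, labels,
                               temporal_membrane_path = full)
        orc <- oracle_batch_gradients(arch, params, imgs, labels, tt,
                                      full_temporal = full)
        for (i in seq_along(arch$layers)) {
          if (is.null(orc[[i]])) next
          expect_equal(bk$grads[[i]]$dW, orc[[i]]$dW, tolerance = 1e-8,
                       label = sprintf("%s T=%d full=%s dW layer %d",
                                       net$arch, tt, full, i))
          if (!is.null(orc[[i]]$dvth)) {
            expect_equal(bk$grads[[i]]$dvth, orc[[i]]$dvth,
                         tolerance = 1e-8,
                         label = sprintf("%s T=%d full=%s dvth layer %d",
                                         net$arch, tt, full, i))
          }
        }
      }
    }
  }
})

test_that("at T = 1 the temporal-path switch is irrelevant", {
  arch <- parse_arch("2dtc3-p2-4fc-2fc", c(6, 6, 1))
  params <- init_params(arch, seed = 4)
  imgs <- array(runif(36 * 3), c(6, 6, 1, 3))
  labels <- c(1L, 2L, 1L)
  fwd <- network_forward(arch, params, imgs, 1L, trace = TRUE)
  a <- network_backward(arch, params, fwd, labels, FALSE)
  b <- network_backward(arch, params, fwd, labels, TRUE)
  expect_identical(a$grads, b$grads)
})

test_that("collapsed dual pathways reproduce plain-SCNN weight gradients", {
  # with Vth1 = Vth0 and the baseline built by kernel duplication, the
  # dual route receives the upstream signal split over two identical
  # pathways; its weight gradients equal the plain network's summed pair
  dt_arch <- parse_arch("2dtc3-p2-3fc-2fc", c(4, 4, 1))
  sc_arch <- parse_arch("4c3-p2-3fc-2fc", c(4, 4, 1))
  dt <- init_params(dt_arch, seed = 31)
  sc <- init_params(sc_arch, seed = 31)
  dt$layers[[1]]$vth <- c(0.5, 0.5)
  sc$layers[[1]]$W <- cbind(dt$layers[[1]]$W, dt$layers[[1]]$W)
  sc$layers[[1]]$vth <- 0.5
  sc$layers[[3]]$W <- dt$layers[[3]]$W
  sc$layers[[3]]$vth <- dt$layers[[3]]$vth
  sc$layers[[4]]$W <- dt$layers[[4]]$W
  imgs <- array(runif(16 * 2), c(4, 4, 1, 2))
  labels <- c(1L, 2L)
  fd <- network_forward(dt_arch, dt, imgs, 1L, trace = TRUE)
  fs <- network_forward(sc_arch, sc, imgs, 1L, trace = TRUE)
  bd <- network_backward(dt_arch, dt, fd, labels)
  bs <- network_backward(sc_arch, sc, fs, labels)
  expect_equal(bd$grads[[1]]$dW,
               bs$grads[[1]]$dW[, 1:2] + bs$grads[[1]]$dW[, 3:4],
               tolerance = 1e-12)
  expect_equal(bd$grads[[3]]$dW, bs$grads[[3]]$dW, tolerance = 1e-12)
})

test_that("learning-rate schedule multiplies by the decay every interval", {
  cfg <- train_config(lr = 0.1, lr_decay = 0.9, decay_interval = 25L,
                      epochs = 100L)
  expect_equal(effective_lr(cfg, 1), 0.1)
  expect_equal(effective_lr(cfg, 25), 0.1)
  expect_equal(effective_lr(cfg, 26), 0.09)
  expect_equal(effective_lr(cfg, 60), 0.1 * 0.9^2)
  expect_equal(effective_lr(cfg, 100), 0.1 * 0.9^3)
})

test_that("zero epochs is a no-op and empty data errors", {
  arch <- parse_arch("2dtc3-p2-4fc-2fc", c(8, 8, 1))
  params <- init_params(arch, seed = 1)
  d <- generate_synthetic_dataset(synthetic_spec(2, 5, c(8, 8), "blobs",
                                                 0.05, 1))
  res <- train_stage(arch, params, d,
                     train_config(epochs = 0L, batch_size = 4L))
  expect_identical(res$params, params)
  expect_identical(nrow(res$history), 0L)
  expect_error(train_stage(arch, params, list(images = NULL, labels = NULL),
                           train_config(epochs = 1L)), "non-empty")
})

test_that("training is seed-deterministic and thresholds stay positive", {
  arch <- parse_arch("2dtc3-p2-8fc-2fc", c(12, 12, 1))
  d <- generate_synthetic_dataset(synthetic_spec(2, 10, c(12, 12), "bars",
                                                 0.05, 3))
  cfg <- train_config(timesteps = 2L, epochs = 3L, batch_size = 5L,
                      seed = 7L, lr = 0.1)
  p0 <- init_params(arch, seed = 7)
  r1 <- train_stage(arch, p0, d, cfg)
  r2 <- train_stage(arch, p0, d, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$params, r2$params)
  # different seed, different trajectory
  cfg2 <- cfg; cfg2$seed <- 8L
  r3 <- train_stage(arch, p0, d, cfg2)
  expect_false(identical(r1$params, r3$params))
  for (l in r1$params$layers) {
    if (!is.null(l$vth)) expect_true(all(l$vth > 0))
  }
})

test_that("loss decreases over the first epochs on separable data", {
  arch <- parse_arch("2dtc3-p2-8fc-2fc", c(12, 12, 1))
  d <- generate_synthetic_dataset(synthetic_spec(2, 20, c(12, 12), "bars",
                                                 0, 5))
  p0 <- init_params(arch, seed = 5)
  res <- train_stage(arch, p0, d,
                     train_config(timesteps = 1L, epochs = 6L,
                                  batch_size = 10L, seed = 5L))
  expect_lt(tail(res$history$loss, 1), res$history$loss[1])
})

test_that("a retrain stage of zero epochs returns the pretrain result", {
  arch <- parse_arch("2dtc3-p2-4fc-2fc", c(8, 8, 1))
  d <- generate_synthetic_dataset(synthetic_spec(2, 8, c(8, 8), "blobs",
                                                 0.05, 2))
  res <- two_stage_train(
    arch, NULL, d,
    train_config(timesteps = 2L, epochs = 2L, batch_size = 4L, seed = 2L),
    train_config(timesteps = 1L, epochs = 0L, batch_size = 4L, seed = 2L))
  expect_identical(nrow(res$retrain), 0L)
  p0 <- init_params(arch, seed = 2L)
  ref <- train_stage(arch, p0, d,
                     train_config(timesteps = 2L, epochs = 2L,
                                  batch_size = 4L, seed = 2L,
                                  stage = "pretrain"))
  expect_identical(res$params, ref$params)
})
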