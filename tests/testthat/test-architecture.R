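test_that("parse_arch reads the published network strings", {
  a <- parse_arch("16c5-p2-40c5-p2-256fc-10fc", c(28, 28, 1))
  kinds <- vapply(a$layers, `[[`, character(1), "kind")
  expect_identical(kinds, c("conv", "pool", "conv", "pool", "fc", "fc_out"))
  expect_identical(a$layers[[1]]$n, 16L)
  expect_identical(a$layers[[1]]$k, 5L)
  expect_identical(a$layers[[3]]$in_shape, c(14L, 14L, 16L))
  expect_identical(a$layers[[5]]$in_shape, c(7L, 7L, 40L))
  expect_false(a$layers[[6]]$spiking)

  d <- parse_arch("8dtc5-p2-20dtc5-p2-256fc-10fc", c(28, 28, 1))
  expect_identical(d$layers[[1]]$vm_shape, c(28L, 28L, 8L))
  expect_identical(d$layers[[1]]$out_shape, c(28L, 28L, 16L))
  expect_identical(d$layers[[3]]$vm_shape, c(14L, 14L, 20L))
  expect_identical(d$layers[[3]]$out_shape, c(14L, 14L, 40L))
})

test_that("a DT network and its baseline emit identical spike-map shapes", {
  base <- parse_arch("16c5-p2-40c5-p2-256fc-10fc", c(28, 28, 1))
  dt <- parse_arch("8dtc5-p2-20dtc5-p2-256fc-10fc", c(28, 28, 1))
  for (i in seq_along(base$layers)) {
    expect_identical(dt$layers[[i]]$out_shape, base$layers[[i]]$out_shape)
  }
})

test_that("parse_arch rejects malformed input with the token position", {
  expect_error(parse_arch("", c(28, 28, 1)), "non-empty")
  expect_error(parse_arch("16q5-10fc", c(28, 28, 1)), "token 1")
  expect_error(parse_arch("16c5-xx-10fc", c(28, 28, 1)), "token 2")
  expect_error(parse_arch("16c5-p2", c(28, 28, 1)), "fully connected output")
  expect_error(parse_arch("256fc-10fc", c(28, 28, 1)), "coding layer")
  expect_error(parse_arch("16c5-10fc-p2-10fc", c(28, 28, 1)),
               "after a fully connected")
  # pooling an image below 1x1
  expect_error(parse_arch("4c3-p2-p2-p2-10fc", c(4, 4, 1)), "below 1x1")
})

test_that("synaptic_current matches brute-force convolution", {
  a <- parse_arch("1c3-2fc", c(4, 4, 1))
  ly <- a$layers[[1]]

  # all-zero input gives all-zero current
  w <- matrix(runif(9, -1, 1), 9, 1)
  expect_equal(synaptic_current(array(0, c(4, 4, 1)), w, ly),
               array(0, c(4, 4, 1)))

  # one spike, all-ones kernel: current is 1 on its 3x3 neighbourhood
  x <- array(0, c(4, 4, 1))
  x[2, 3, 1] <- 1
  cur <- synaptic_current(x, matrix(1, 9, 1), ly)
  expected <- array(0, c(4, 4, 1))
  expected[1:3, 2:4, 1] <- 1
  expect_equal(cur, expected)

  # coding layer 1x1 kernel: plain product
  a1 <- parse_arch("1c1-2fc", c(1, 1, 1))
  cur <- synaptic_current(array(0.5, c(1, 1, 1)), matrix(0.3), a1$layers[[1]])
  expect_equal(as.vector(cur), 0.15)

  # random case against the scalar loop oracle
  set.seed(42)
  a2 <- parse_arch("3c3-2fc", c(5, 4, 2))
  ly2 <- a2$layers[[1]]
  x2 <- array(runif(5 * 4 * 2), c(5, 4, 2))
  w2 <- matrix(runif(9 * 2 * 3, -1, 1), 18, 3)
  expect_equal(synaptic_current(x2, w2, ly2), oracle_conv(x2, w2, 3, 3),
               tolerance = 1e-12)
})

test_that("dtc_forward concatenates pathway-0 then pathway-1 maps", {
  a <- parse_arch("1dtc1-2fc", c(1, 1, 1))
  ly <- a$layers[[1]]
  cfg <- neuron_config(0.5, c(1.0, 0.5))
  res <- dtc_forward(array(0.7, c(1, 1, 1)), matrix(1), cfg, ly)
  expect_equal(as.vector(res$output), c(0, 1))   # below Vth0, above Vth1
  expect_equal(as.vector(res$state$membrane), 0.7)

  # 8 membrane maps emit 16 spike maps
  a8 <- parse_arch("8dtc5-p2-20dtc5-p2-256fc-10fc", c(28, 28, 1))
  w8 <- matrix(runif(25 * 8, -0.2, 0.2), 25, 8)
  r8 <- dtc_forward(array(runif(28 * 28), c(28, 28, 1)), w8,
                    neuron_config(0.5, c(0.5, 0.5)), a8$layers[[1]])
  expect_identical(dim(r8$output), c(28L, 28L, 16L))
  # degenerate equal thresholds: both halves identical
  expect_identical(r8$output[, , 1:8], r8$output[, , 9:16])
})

test_that("network_forward on a tiny net matches the hand-chained oracle", {
  for (spec in list(list(arch = "1dtc3-2fc", shape = c(2, 2, 1)),
                    list(arch = "1dtc3-1c3-2fc", shape = c(2, 2, 1)),
                    list(arch = "1dtc3-p2-2fc", shape = c(2, 2, 1)),
                    list(arch = "1c3-2fc-2fc", shape = c(2, 2, 1)))) {
    arch <- parse_arch(spec$arch, spec$shape)
    set.seed(17)
    params <- init_params(arch, seed = 17, gain = 2)
    img <- array(runif(prod(spec$shape)), c(spec$shape, 1L))
    for (tt in 1:3) {
      fwd <- network_forward(arch, params, img, tt)
      orc <- oracle_forward(arch, params, array(img, spec$shape), tt)
      expect_equal(as.vector(fwd$output), as.vector(orc$output),
                   tolerance = 1e-9)
    }
  }
})

test_that("forward pass is linear in trivial cases", {
  arch <- parse_arch("2dtc3-p2-4fc-2fc", c(8, 8, 1))
  params <- init_params(arch, seed = 1)
  # all-zero weights give all-zero output membranes
  zero <- params
  for (i in seq_along(zero$layers)) {
    if (!is.null(zero$layers[[i]]$W)) zero$layers[[i]]$W[] <- 0
  }
  img <- array(runif(64), c(8, 8, 1, 1))
  expect_equal(as.vector(network_forward(arch, zero, img, 3)$output),
               c(0, 0))
  expect_error(network_forward(arch, params, img, 0), "positive")
})

test_that("spikes stay binary at every non-coding layer input", {
  arch <- parse_arch("2dtc3-2c3-4fc-2fc", c(6, 6, 1))
  params <- init_params(arch, seed = 3)
  img <- array(runif(36 * 2), c(6, 6, 1, 2))
  fwd <- network_forward(arch, params, img, 3, trace = TRUE)
  for (t in 1:3) {
    expect_true(all(fwd$trace[[1]][[t]]$output %in% c(0, 1)))
    expect_true(all(fwd$trace[[2]][[t]]$input %in% c(0, 1)))
    expect_true(all(fwd$trace[[3]][[t]]$input %in% c(0, 1)))
  }
})

test_that("degenerate thresholds reduce a DT-SCNN to its baseline SCNN", {
  # replace each dtc layer by a conv layer with doubled channels and
  # duplicated kernels: with Vth1 = Vth0 the forward outputs must agree
  dt_arch <- parse_arch("2dtc3-p2-3dtc3-p2-8fc-3fc", c(8, 8, 1))
  sc_arch <- parse_arch("4c3-p2-6c3-p2-8fc-3fc", c(8, 8, 1))
  dt <- init_params(dt_arch, seed = 9)
  sc <- init_params(sc_arch, seed = 9)
  for (i in seq_along(dt$layers)) {
    if (dt_arch$layers[[i]]$kind == "dtc") {
      dt$layers[[i]]$vth <- c(0.5, 0.5)
      sc$layers[[i]]$W <- cbind(dt$layers[[i]]$W, dt$layers[[i]]$W)
      sc$layers[[i]]$vth <- 0.5
    } else if (!is.null(dt$layers[[i]]$W)) {
      sc$layers[[i]]$W <- dt$layers[[i]]$W
      sc$layers[[i]]$vth <- dt$layers[[i]]$vth
    }
  }
  img <- array(runif(64 * 3), c(8, 8, 1, 3))
  for (tt in c(1, 4)) {
    fd <- network_forward(dt_arch, dt, img, tt)
    fs <- network_forward(sc_arch, sc, img, tt)
    expect_equal(fd$output, fs$output, tolerance = 1e-12)
  }
})

test_that("predict_class takes the argmax with ties to the lowest index", {
  expect_identical(predict_class(c(0.1, 0.9, 0.3)), 2L)
  expect_identical(predict_class(c(0.5, 0.5)), 1L)
  expect_identical(predict_class(rep(1, 10)), 1L)
  m <- cbind(c(0, 1), c(2, -1))
  expect_identical(predict_class(m), c(2L, 1L))
  expect_error(predict_class(numeric(0)), "non-empty")
})

test_that("trace export uses layer/timestep keys", {
  arch <- parse_arch("1dtc3-2fc", c(2, 2, 1))
  params <- init_params(arch, seed = 2)
  fwd <- network_forward(arch, params, array(runif(4), c(2, 2, 1, 1)), 2,
                         trace = TRUE)
  ar <- trace_archive(fwd)
  expect_true(all(c("layer1/t1/membrane", "layer1/t2/spikes1",
                    "layer2/t2/current") %in% names(ar)))
})
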