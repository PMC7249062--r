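test_that("flm_config validates its arguments", {
  expect_s3_class(flm_config("cnn", 100, s = 2, k = 5), "flm_config")
  expect_error(flm_config("cnn", 100, k = 4), "odd")
  expect_error(flm_config("lstm", 101), "even")
  expect_error(flm_config("cnn", 0), "w_out")
})

test_that("flm_output_length is the ceiling rule", {
  expect_identical(flm_output_length(512, 2), 256L)
  expect_identical(flm_output_length(513, 2), 257L)
  expect_identical(flm_output_length(7, 4), 2L)
  expect_identical(flm_output_length(8, 1), 8L)
  expect_error(flm_output_length(0, 2))
})

test_that("flm_param_count matches the closed-form accounting", {
  # conv weights + bn scale/shift
  expect_identical(flm_param_count(flm_config("cnn", 100, k = 5), 113),
                   113L * 100L * 5L + 200L)
  # bias instead of bn
  cfg <- flm_config("cnn", 18, k = 1, bn = FALSE, bias = TRUE)
  expect_identical(flm_param_count(cfg, 100), 100L * 18L + 18L)
  # bidirectional lstm: 2 * (4h(w_in + h) + 4h) + bn
  h <- 50L
  expect_identical(flm_param_count(flm_config("lstm", 100), 195),
                   2L * (4L * h * 195L + 4L * h * h + 4L * h) + 200L)
})

test_that("parameter-count formula equals enumerated trainables", {
  for (cfg in list(flm_config("cnn", 10, s = 2, k = 5),
                   flm_config("cnn", 7, k = 1, bn = FALSE, bias = TRUE),
                   flm_config("lstm", 8))) {
    for (w_in in c(3L, 9L)) {
      par <- filternet:::.flm_init(cfg, w_in)
      expect_identical(filternet:::.n_trainable(par),
                       flm_param_count(cfg, w_in))
    }
  }
})

test_that("roi_after_stack follows the stride-product recurrence", {
  expect_identical(roi_after_stack(list(c(1, 5))), 5)
  expect_identical(roi_after_stack(list(c(1, 5), c(2, 5))), 13)
  expect_identical(roi_after_stack(list(c(1, 5), c(2, 5), c(2, 5),
                                        c(2, 5))), 61)
  # lstm anywhere => unbounded
  expect_identical(roi_after_stack(list(flm_config("cnn", 4),
                                        flm_config("lstm", 4))), Inf)
  expect_error(roi_after_stack(list()))
})

test_that("analytic ROI equals the empirically probed receptive field (stride 1)", {
  set.seed(20)
  stacks <- list(
    list(flm_config("cnn", 3, s = 1, k = 5)),
    list(flm_config("cnn", 3, s = 1, k = 5),
         flm_config("cnn", 3, s = 1, k = 3)),
    list(flm_config("cnn", 2, s = 1, k = 7),
         flm_config("cnn", 3, s = 1, k = 5),
         flm_config("cnn", 2, s = 1, k = 5)),
    list(flm_config("cnn", 2, s = 1, k = 5),
         flm_config("cnn", 2, s = 1, k = 5),
         flm_config("cnn", 2, s = 1, k = 3),
         flm_config("cnn", 2, s = 1, k = 5)))
  for (cfgs in stacks)
    expect_equal(empirical_roi(cfgs), roi_after_stack(cfgs))
})

test_that("analytic ROI bounds the realized receptive field of strided stacks", {
  # the recurrence counts kernel taps at the layer output rate; the
  # conv-then-average-pool module realizes a smaller field, so for k >= 2
  # strided layers the analytic value is a safe upper bound
  set.seed(21)
  stacks <- list(
    list(flm_config("cnn", 3, s = 2, k = 5),
         flm_config("cnn", 3, s = 2, k = 3)),
    list(flm_config("cnn", 2, s = 1, k = 5),
         flm_config("cnn", 2, s = 2, k = 5),
         flm_config("cnn", 2, s = 2, k = 5),
         flm_config("cnn", 2, s = 2, k = 5)))
  for (cfgs in stacks) {
    emp <- empirical_roi(cfgs)
    expect_lte(emp, roi_after_stack(cfgs))
    # and the bound is not vacuous: the field still grows with depth
    expect_gt(emp, empirical_roi(cfgs[-length(cfgs)]))
  }
})

test_that("FLM forward has the contracted shape and length", {
  cfg <- flm_config("cnn", 6, s = 2, k = 5, p_drop = 0)
  par <- filternet:::.flm_init(cfg, 3)
  x <- array(rnorm(3 * 21 * 2), c(3, 21, 2))
  y <- filternet:::.flm_forward(par, cfg, x)$y
  expect_identical(dim(y), c(6L, flm_output_length(21, 2), 2L))

  cfgL <- flm_config("lstm", 8, p_drop = 0)
  parL <- filternet:::.flm_init(cfgL, 3)
  yL <- filternet:::.flm_forward(parL, cfgL, x)$y
  expect_identical(dim(yL), c(8L, 21L, 2L))
})

test_that("conv uses symmetric zero padding: identity kernel reproduces input", {
  # k = 3 kernel with a centred 1 acts as the identity away from edges
  x <- array(rnorm(1 * 10 * 1), c(1, 10, 1))
  W <- array(c(0, 1, 0), c(1, 1, 3))
  y <- filternet:::.conv1d_forward(x, W, NULL)
  expect_equal(y, x)
  # shifted kernel moves the series by one sample and zero-fills the edge
  Ws <- array(c(1, 0, 0), c(1, 1, 3))
  ys <- filternet:::.conv1d_forward(x, Ws, NULL)
  expect_equal(ys[1, 2:10, 1], x[1, 1:9, 1])
  expect_equal(ys[1, 1, 1], 0)
})

test_that("average pooling divides by s and right-pads with zeros", {
  x <- array(c(1, 3, 5, 7, 9), c(1, 5, 1))
  y <- filternet:::.avgpool_forward(x, 2L)
  expect_equal(as.numeric(y), c(2, 6, 4.5))  # last bin: (9 + 0) / 2
})

test_that("batch norm standardizes with batch statistics in train mode", {
  set.seed(4)
  x <- array(rnorm(3 * 40 * 2, mean = 5, sd = 3), c(3, 40, 2))
  r <- filternet:::.bn_forward(x, gamma = rep(2, 3), beta = c(1, 2, 3),
                               run_mean = numeric(3), run_var = rep(1, 3),
                               mode = "train")
  m <- matrix(r$y, 3)
  expect_equal(rowMeans(m), c(1, 2, 3), tolerance = 1e-10)
  expect_equal(apply(m, 1, function(v) sqrt(mean((v - mean(v))^2))),
               rep(2, 3), tolerance = 1e-4)
  # eval mode uses the provided running statistics
  re <- filternet:::.bn_forward(x, rep(1, 3), numeric(3),
                                run_mean = rep(5, 3), run_var = rep(9, 3),
                                mode = "eval")
  expect_equal(re$y, (x - 5) / sqrt(9 + 1e-5), tolerance = 1e-10)
})

test_that("channel dropout zeroes whole channels and preserves expectation", {
  set.seed(9)
  mask <- filternet:::.dropout_mask(200L, 50L, 0.3)
  expect_true(all(mask %in% c(0, 1 / 0.7)))
  expect_equal(mean(mask), 1, tolerance = 0.05)
  x <- array(1, c(4, 6, 2))
  m <- filternet:::.dropout_mask(4L, 2L, 0.5)
  xd <- filternet:::.dropout_apply(x, m)
  # constant within each (channel, batch) slice
  for (b in 1:2) for (ch in 1:4)
    expect_true(all(xd[ch, , b] == xd[ch, 1, b]))
})

test_that("FLM gradients match finite differences", {
  set.seed(11)
  for (type in c("cnn", "lstm")) {
    cfg <- flm_config(type, 4, s = 2, k = 5, p_drop = 0)
    par <- filternet:::.flm_init(cfg, 3)
    x <- array(rnorm(3 * 12 * 2), c(3, 12, 2))
    tgt <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
    loss <- function(p, xx) {
      y <- filternet:::.flm_forward(p, cfg, xx, mode = "train")$y
      0.5 * sum((y - tgt)^2)
    }
    fw <- filternet:::.flm_forward(par, cfg, x, mode = "train", keep = TRUE)
    bw <- filternet:::.flm_backward(par, cfg, fw$cache, fw$y - tgt)
    h <- 1e-5
    # input gradient, every element
    gnum <- array(0, dim(x))
    for (i in seq_along(x)) {
      xa <- x; xa[i] <- xa[i] + h
      xb <- x; xb[i] <- xb[i] - h
      gnum[i] <- (loss(par, xa) - loss(par, xb)) / (2 * h)
    }
    expect_equal(bw$gx, gnum, tolerance = 1e-5)
    # a sample of parameter gradients
    flat <- filternet:::.flatten_params(par)
    gflat <- filternet:::.flatten_params(bw$grads)
    for (key in setdiff(names(flat), c("run_mean", "run_var"))) {
      vals <- flat[[key]]$values
      ii <- sample(length(vals), 1L)
      p1 <- flat; p1[[key]]$values[ii] <- vals[ii] + h
      p2 <- flat; p2[[key]]$values[ii] <- vals[ii] - h
      fn <- (loss(filternet:::.unflatten_params(p1), x) -
             loss(filternet:::.unflatten_params(p2), x)) / (2 * h)
      expect_equal(gflat[[key]]$values[ii], fn, tolerance = 1e-4)
    }
  }
})

test_that("apply_flm runs on plain matrices", {
  set.seed(2)
  x <- matrix(rnorm(3 * 64), 3)
  y <- apply_flm(x, flm_config("cnn", 4, s = 2, p_drop = 0))
  expect_identical(dim(y), c(4L, 32L))
})
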