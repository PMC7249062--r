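test_that("variants contain exactly their advertised components", {
  has <- function(spec, nm) !is.null(spec$components[[nm]])
  comp_set <- function(spec)
    names(Filter(Negate(is.null), spec$components))
  expect_setequal(comp_set(build_reference("b_lstm", 5, 3)), c("F", "G"))
  expect_setequal(comp_set(build_reference("p_cnn", 5, 3)),
                  c("A", "B", "G"))
  expect_setequal(comp_set(build_reference("p_cl", 5, 3)),
                  c("A", "B", "F", "G"))
  expect_setequal(comp_set(build_reference("ms_cnn", 5, 3)),
                  c("A", "B", "C", "E", "G"))
  expect_setequal(comp_set(build_reference("ms_cl", 5, 3)),
                  c("A", "B", "C", "E", "F", "G"))
})

test_that("reference ms_cl reproduces the published layer table", {
  spec <- build_reference("ms_cl", input_channels = 113, n_classes = 18)
  layers <- filternet:::.spec_layers(spec)
  nm <- vapply(layers, `[[`, "", "name")
  w_in <- vapply(layers, `[[`, 1L, "w_in")
  w_out <- vapply(layers, function(l) l$cfg$w_out, 1L)
  s <- vapply(layers, function(l) l$cfg$s, 1L)
  expect_identical(nm, c("A", "B1", "B2", "B3", "C1", "C2", "C3", "C4",
                         "E", "F1", "G"))
  expect_identical(w_in, c(113L, 100L, 100L, 100L, 100L, 50L, 25L, 13L,
                           195L, 100L, 100L))
  expect_identical(w_out, c(100L, 100L, 100L, 100L, 50L, 25L, 13L, 7L,
                            100L, 100L, 18L))
  expect_identical(s, c(1L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L))
  counts <- vapply(layers, function(l) flm_param_count(l$cfg, l$w_in), 1L)
  expect_identical(counts[nm == "A"], 56700L)
  expect_identical(counts[nm == "B1"], 50200L)
  expect_identical(counts[nm == "C1"], 25100L)
  expect_identical(counts[nm == "C2"], 6300L)
  expect_identical(counts[nm == "C3"], 1651L)
  expect_identical(counts[nm == "C4"], 469L)
  expect_identical(counts[nm == "E"], 19700L)
  expect_identical(counts[nm == "G"], 1818L)
})

test_that("reference ROI values match the published per-layer sequence", {
  spec <- build_reference("ms_cl", 113, 18)
  cnn <- c(spec$components$A, spec$components$B, spec$components$C)
  rois <- vapply(seq_along(cnn), function(i)
    roi_after_stack(cnn[seq_len(i)]), 1)
  expect_equal(rois, c(5, 13, 29, 61, 125, 253, 509, 765))
  expect_equal(network_roi(build_reference("p_cnn", 113, 18)), 61)
  expect_identical(network_roi(spec), Inf)  # lstm-bearing
})

test_that("variant totals match the published sums", {
  expect_identical(total_param_count(build_reference("p_cnn", 113, 18)),
                   209118L)
  expect_identical(total_param_count(build_reference("ms_cnn", 113, 18)),
                   262338L)
})

test_that("resample-concat yields 195 channels at reference widths", {
  spec <- build_reference("ms_cl", 113, 18)
  cw <- vapply(spec$components$C, function(cf) cf$w_out, 1L)
  expect_identical(cw, c(50L, 25L, 13L, 7L))
  ps1 <- matrix(rnorm(100 * 64), 100)
  taps <- lapply(seq_along(cw), function(i)
    matrix(rnorm(cw[i] * (64 %/% 2^i)), cw[i]))
  cat195 <- resample_concat(ps1, taps)
  expect_identical(nrow(cat195), 195L)
  expect_identical(ncol(cat195), 64L)
})

test_that("resampling preserves constants and aligns ends", {
  m <- matrix(3.5, 2, 5)
  up <- resample_concat(matrix(0, 1, 16), list(m))
  expect_true(all(abs(up[2:3, ] - 3.5) < 1e-12))
  # align-ends: first/last output sample equal first/last input sample
  v <- matrix(c(1, 2, 4, 8), 1)
  y <- filternet:::.resample_forward(array(v, c(1, 4, 1)), 7L)
  expect_equal(y[1, 1, 1], 1)
  expect_equal(y[1, 7, 1], 8)
  expect_equal(y[1, 4, 1], 3)  # midpoint between samples 2 and 3
})

test_that("width_scale rescales hidden widths but not input/output", {
  spec <- build_reference("ms_cnn", 113, 18, width_scale = 0.5)
  layers <- filternet:::.spec_layers(spec)
  wA <- layers[[1L]]$cfg$w_out
  expect_identical(wA, 50L)
  expect_identical(layers[[1L]]$w_in, 113L)
  expect_identical(layers[[length(layers)]]$cfg$w_out, 18L)
  expect_lt(total_param_count(spec), 262338L)
})

test_that("output stride is s^n_p1 and 1 for the base lstm", {
  expect_identical(output_stride(build_reference("ms_cl", 5, 3)), 8L)
  expect_identical(output_stride(build_reference("b_lstm", 5, 3)), 1L)
})

test_that("forward pass has the contracted output shape", {
  set.seed(6)
  spec <- filternet_spec("ms_cl", input_channels = 6, n_classes = 5,
                         base_width = 8, n_p1 = 2, n_p2 = 2, p_drop = 0)
  net <- filternet_init(spec, seed = 2)
  x <- matrix(rnorm(6 * 64), 6)
  out <- filternet_forward(net, x)
  expect_identical(dim(out$logits), c(5L, 16L))
  expect_equal(colSums(out$prob), rep(1, 16), tolerance = 1e-12)

  specb <- filternet_spec("b_lstm", input_channels = 6, n_classes = 5,
                          base_width = 8, p_drop = 0)
  netb <- filternet_init(specb, seed = 2)
  outb <- filternet_forward(netb, x)
  expect_identical(dim(outb$logits), c(5L, 64L))
})

test_that("eval-mode forward is translation covariant in the interior", {
  # shifting the input by one output stride shifts the output by one sample
  # away from the zero-padded edges
  set.seed(8)
  spec <- filternet_spec("p_cnn", input_channels = 3, n_classes = 4,
                         base_width = 8, n_p1 = 2, p_drop = 0)
  net <- filternet_init(spec, seed = 3)
  str <- output_stride(spec)
  L <- 40 * str
  x <- matrix(rnorm(3 * L), 3)
  xs <- cbind(matrix(0, 3, str), x[, seq_len(L - str)])
  y <- filternet_forward(net, x)$logits
  ys <- filternet_forward(net, xs)$logits
  roi_out <- ceiling(network_roi(spec) / str)
  keep <- (roi_out + 2):(ncol(y) - roi_out - 1)
  expect_equal(ys[, keep + 1L], y[, keep], tolerance = 1e-8)
})

test_that("initialization is reproducible and forward is deterministic", {
  spec <- tiny_ms_cnn_spec()
  n1 <- filternet_init(spec, seed = 42)
  n2 <- filternet_init(spec, seed = 42)
  expect_identical(n1$params, n2$params)
  x <- matrix(rnorm(4 * 64), 4)
  expect_identical(filternet_forward(n1, x)$logits,
                   filternet_forward(n2, x)$logits)
})

test_that("forward validates input channel count", {
  net <- filternet_init(tiny_ms_cnn_spec(), seed = 1)
  expect_error(filternet_forward(net, matrix(0, 3, 64)), "channel")
})

test_that("whole-network gradients match finite differences", {
  set.seed(7)
  spec <- filternet_spec("ms_cl", input_channels = 3, n_classes = 3,
                         base_width = 4, n_p1 = 2, n_p2 = 2, n_l = 1,
                         p_drop = 0.2)
  net <- filternet_init(spec, seed = 11)
  L <- 16; B <- 2
  x <- array(rnorm(3 * L * B), c(3, L, B))
  Lo <- L / output_stride(spec)
  lab <- matrix(sample(1:3, Lo * B, TRUE), Lo, B)
  lossfun <- function(par) {
    n2 <- net; n2$params <- par
    set.seed(999)  # same dropout draws for every evaluation
    fw <- filternet:::.net_forward(n2, x, mode = "train")
    filternet:::.xent_loss_grad(fw$logits, lab)$loss
  }
  set.seed(999)
  fw <- filternet:::.net_forward(net, x, mode = "train", keep = TRUE)
  lg <- filternet:::.xent_loss_grad(fw$logits, lab)
  bw <- filternet:::.net_backward(net, fw$caches, lg$grad)
  flat <- filternet:::.flatten_params(net$params)
  gflat <- filternet:::.flatten_params(bw$grads)
  h <- 1e-5
  for (key in names(flat)) {
    if (grepl("run_", key)) next
    vals <- flat[[key]]$values
    ga <- gflat[[key]]$values
    idx <- if (length(vals) > 3) sort(sample(length(vals), 3))
           else seq_along(vals)
    for (ii in idx) {
      p1 <- flat; p1[[key]]$values[ii] <- vals[ii] + h
      p2 <- flat; p2[[key]]$values[ii] <- vals[ii] - h
      fn <- (lossfun(filternet:::.unflatten_params(p1)) -
             lossfun(filternet:::.unflatten_params(p2))) / (2 * h)
      expect_equal(ga[ii], fn, tolerance = 1e-3,
                   label = sprintf("analytic grad %s[%d]", key, ii))
    }
  }
})

test_that("spec printing shows the layer table", {
  out <- capture.output(print(build_reference("ms_cl", 113, 18)))
  expect_true(any(grepl("ms_cl", out)))
  expect_true(any(grepl("56700|56,700", out)))
})
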