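test_that("plan_windows reproduces the documented start patterns", {
  expect_equal(plan_windows(1024, 512, 0.5)$segments[, "start"],
               c(0L, 256L, 512L), ignore_attr = TRUE)
  p1 <- plan_windows(512, 512, 0.5)
  expect_identical(nrow(p1$segments), 1L)
  expect_equal(unname(p1$segments[1, ]), c(0L, 512L))
  # L = 513, stride 1: last window right-aligned at start 1
  p2 <- plan_windows(513, 512, 0.5, stride_ratio = 1L)
  expect_equal(p2$segments[, "start"], c(0L, 1L), ignore_attr = TRUE)
  # right-alignment stays on the output grid when stride > 1
  p3 <- plan_windows(600, 512, 0.5, stride_ratio = 8L)
  expect_identical(p3$L_padded %% 8L, 0L)
  expect_true(all(p3$segments[, "start"] %% 8L == 0L))
})

test_that("plan_windows validates arguments", {
  expect_error(plan_windows(100, 512, 1.0), "overlap")
  expect_error(plan_windows(100, 512, 0.5, stride_ratio = 7L), "divisible")
})

test_that("window plans cover the input without gaps", {
  for (L in c(512, 700, 1024, 1500, 4097)) {
    plan <- plan_windows(L, 512, 0.5, stride_ratio = 8L)
    covered <- logical(plan$L_padded)
    for (i in seq_len(nrow(plan$segments)))
      covered[(plan$segments[i, "start"] + 1L):plan$segments[i, "end"]] <- TRUE
    expect_true(all(covered[seq_len(L)]), label = paste("coverage, L =", L))
  }
})

test_that("reconstruction of identical constant windows is constant", {
  plan <- plan_windows(1024, 512, 0.5, stride_ratio = 8L)
  outs <- replicate(nrow(plan$segments), matrix(2.5, 3, 64),
                    simplify = FALSE)
  rec <- reconstruct(outs, plan)
  expect_identical(dim(rec), c(3L, 128L))
  expect_true(all(abs(rec - 2.5) < 1e-12))
})

test_that("single window reconstruction is the identity", {
  plan <- plan_windows(512, 512, 0.5, stride_ratio = 8L)
  out <- matrix(rnorm(3 * 64), 3)
  expect_equal(reconstruct(list(out), plan), out, tolerance = 1e-12)
})

test_that("two half-overlapping windows match per-sample arithmetic", {
  plan <- plan_windows(768, 512, 0.5, stride_ratio = 8L)
  expect_identical(nrow(plan$segments), 2L)
  a <- matrix(rnorm(2 * 64), 2)
  b <- matrix(rnorm(2 * 64), 2)
  rec <- reconstruct(list(a, b), plan)
  # brute-force oracle
  w <- pmax(0.5 * (1 - cos(2 * pi * (0:63) / 63)), 1e-8)
  acc <- matrix(0, 2, 96); den <- numeric(96)
  acc[, 1:64] <- acc[, 1:64] + sweep(a, 2, w, "*"); den[1:64] <- den[1:64] + w
  acc[, 33:96] <- acc[, 33:96] + sweep(b, 2, w, "*")
  den[33:96] <- den[33:96] + w
  expect_equal(rec, sweep(acc, 2, den, "/"), tolerance = 1e-12)
})

test_that("reconstructed length is ceiling(L / stride) for ragged L", {
  for (L in c(512, 513, 515, 700, 1023, 1025)) {
    plan <- plan_windows(L, 512, 0.5, stride_ratio = 4L)
    outs <- replicate(nrow(plan$segments), matrix(1, 2, 128),
                      simplify = FALSE)
    expect_identical(ncol(reconstruct(outs, plan)),
                     as.integer(ceiling(L / 4)),
                     label = paste("L =", L))
  }
})

test_that("reconstruct rejects wrong window counts and shapes", {
  plan <- plan_windows(1024, 512, 0.5, stride_ratio = 8L)
  outs <- replicate(nrow(plan$segments), matrix(0, 3, 64),
                    simplify = FALSE)
  expect_error(reconstruct(outs[-1], plan), "one window output")
  outs[[2]] <- matrix(0, 3, 63)
  expect_error(reconstruct(outs, plan), "wrong shape")
})

test_that("roi_trim equals the whole-series pass away from global edges", {
  set.seed(31)
  spec <- filternet_spec("p_cnn", input_channels = 4, n_classes = 3,
                         base_width = 10, n_p1 = 2, p_drop = 0)
  net <- filternet_init(spec, seed = 13)
  roi <- network_roi(spec)
  str <- output_stride(spec)
  L <- 2048
  x <- matrix(rnorm(4 * L), 4)
  whole <- filternet_forward(net, x)$logits
  # overlap equal to the ROI (rounded up to the stride grid)
  ov <- ceiling(roi / str) * str
  wl <- 256L
  pr <- filternet_predict(net, x, window_len = wl,
                          overlap_fraction = ov / wl, method = "roi_trim")
  edge <- ceiling(roi / 2 / str)
  keep <- (edge + 1):(ncol(whole) - edge)
  expect_lt(max(abs(pr$logits[, keep] - whole[, keep])), 1e-10)
})

test_that("roi_trim errors when overlap is below the ROI", {
  plan <- plan_windows(1024, 512, 0.05, stride_ratio = 8L)
  outs <- replicate(nrow(plan$segments), matrix(0, 2, 64),
                    simplify = FALSE)
  expect_error(roi_trim_reconstruct(outs, plan, roi = 200),
               "smaller than the region of influence")
})

test_that("roi_trim refuses unbounded-ROI networks", {
  net <- filternet_init(filternet_spec("b_lstm", input_channels = 2,
                                       n_classes = 2, base_width = 4,
                                       p_drop = 0), seed = 1)
  x <- matrix(rnorm(2 * 600), 2)
  expect_error(filternet_predict(net, x, window_len = 128,
                                 method = "roi_trim"), "finite ROI")
})

test_that("single-window roi_trim is the identity", {
  plan <- plan_windows(512, 512, 0.5, stride_ratio = 8L)
  out <- matrix(rnorm(2 * 64), 2)
  expect_equal(roi_trim_reconstruct(list(out), plan, roi = 61), out,
               tolerance = 1e-12)
})

test_that("hanning windowed inference approaches the unsegmented pass", {
  set.seed(32)
  spec <- filternet_spec("p_cnn", input_channels = 3, n_classes = 3,
                         base_width = 8, n_p1 = 2, p_drop = 0)
  net <- filternet_init(spec, seed = 14)
  roi <- network_roi(spec); str <- output_stride(spec)
  L <- 6000
  x <- matrix(rnorm(3 * L), 3)
  whole <- filternet_forward(net, x)$logits
  edge <- ceiling(roi / 2 / str)
  keep <- (edge + 1):(ncol(whole) - edge)
  err <- function(wl) {
    pr <- filternet_predict(net, x, window_len = wl)
    max(abs(pr$logits[, keep] - whole[, keep]))
  }
  # error is edge contamination under the hanning taper: it shrinks as the
  # window grows and the tapered edge region becomes relatively narrower
  e <- c(err(256L), err(1024L), err(4096L))
  expect_true(all(diff(e) < 0))
  expect_lt(e[3], 1e-5)
})

test_that("windowed inference works for lstm-bearing networks", {
  set.seed(33)
  spec <- filternet_spec("p_cl", input_channels = 3, n_classes = 3,
                         base_width = 8, n_p1 = 2, n_l = 1, p_drop = 0)
  net <- filternet_init(spec, seed = 15)
  x <- matrix(rnorm(3 * 1000), 3)
  pr <- filternet_predict(net, x, window_len = 256)
  expect_identical(dim(pr$logits), c(3L, 250L))
  expect_equal(colSums(pr$prob), rep(1, 250), tolerance = 1e-12)
  expect_true(all(pr$class %in% 1:3))
})

test_that("batching windows does not change the result", {
  set.seed(34)
  net <- filternet_init(tiny_ms_cnn_spec(3L, 3L), seed = 16)
  x <- matrix(rnorm(3 * 3000), 3)
  p1 <- filternet_predict(net, x, window_len = 256, batch_windows = 1L)
  p2 <- filternet_predict(net, x, window_len = 256, batch_windows = 64L)
  expect_equal(p1$logits, p2$logits, tolerance = 1e-12)
})
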