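#' Plan sliding windows over a long input
#'
#' Splits the input axis `[0, L)` into fixed-length windows whose starts lie
#' at multiples of `step = round(window_len * (1 - overlap_fraction))`, with
#' a final window right-aligned so the whole (possibly zero-padded) input is
#' covered. Window starts are kept on the output-sample grid, so the
#' planning length is `L` rounded up to a multiple of `stride_ratio`; the
#' padded region is discarded from the reconstructed output.
#'
#' @param L Input length in samples.
#' @param window_len Window length in input samples (default 512).
#' @param overlap_fraction Fractional overlap of consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @param stride_ratio Output stride ratio of the network the windows will
#'   be fed to; `window_len` must be divisible by it.
#' @param weighting `"hanning"` (default) or `"rectangular"` overlap-add
#'   weights.
#' @return An object of class `"window_plan"`: list with `segments` (two-
#'   column matrix of half-open, 0-based `(start, end)` input intervals),
#'   `L`, `L_padded`, `window_len`, `step`, `stride_ratio`, `weighting`.
#' @examples
#' plan_windows(1024, 512, 0.5)$segments[, 1] # starts 0, 256, 512
#' @export
plan_windows <- function(L, window_len = 512L, overlap_fraction = 0.5,
                         stride_ratio = 1L, weighting = c("hanning",
                                                          "rectangular")) {
  weighting <- match.arg(weighting)
  L <- as.integer(L); window_len <- as.integer(window_len)
  stride_ratio <- as.integer(stride_ratio)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must lie in [0, 1)")
  if (window_len %% stride_ratio != 0L)
    stop("`window_len` must be divisible by the output stride ratio")
  step <- as.integer(round(window_len * (1 - overlap_fraction)))
  if (step < 1L) stop("window step must be at least 1 sample")
  Lp <- max(L, window_len)
  Lp <- as.integer(ceiling(Lp / stride_ratio) * stride_ratio)
  starts <- seq.int(0L, Lp - window_len, by = step)
  if (starts[length(starts)] + window_len < Lp) {
    # right-align a final window on the output grid
    last <- Lp - window_len
    last <- as.integer(floor(last / stride_ratio) * stride_ratio)
    starts <- c(starts, last)
  }
  segs <- cbind(start = starts, end = starts + window_len)
  structure(list(segments = segs, L = L, L_padded = Lp,
                 window_len = window_len, step = step,
                 stride_ratio = stride_ratio, weighting = weighting),
            class = "window_plan")
}

.window_weights <- function(n, weighting, floor_eps = 1e-8) {
  w <- switch(weighting,
              hanning = 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))),
              rectangular = rep(1, n))
  pmax(w, floor_eps)
}

#' Reconstruct a series from windowed network outputs
#'
#' Weighted overlap-add on the output-sample axis: each reconstructed
#' sample is the weight-normalized average of every window output covering
#' it, with Hanning (or rectangular) weights. Hanning weights are floored
#' at a small positive epsilon so samples covered by a single window reduce
#' to that window's raw output instead of dividing by zero. Averaging is
#' applied to logits; recompute probabilities afterwards.
#'
#' @param window_outputs List of numeric matrices, one per planned window,
#'   each of shape `(n_classes, window_len / stride_ratio)`.
#' @param plan A [plan_windows()] result.
#' @return Numeric matrix `(n_classes, ceiling(L / stride_ratio))`.
#' @export
reconstruct <- function(window_outputs, plan) {
  stopifnot(inherits(plan, "window_plan"))
  segs <- plan$segments
  if (length(window_outputs) != nrow(segs))
    stop("need one window output per planned segment")
  str <- plan$stride_ratio
  Lw <- plan$window_len %/% str
  Lo_p <- plan$L_padded %/% str
  Lo <- as.integer(ceiling(plan$L / str))
  nc <- nrow(window_outputs[[1L]])
  wts <- .window_weights(Lw, plan$weighting)
  acc <- matrix(0, nc, Lo_p)
  den <- numeric(Lo_p)
  for (i in seq_len(nrow(segs))) {
    out <- window_outputs[[i]]
    if (!is.matrix(out) || ncol(out) != Lw || nrow(out) != nc)
      stop("window output ", i, " has the wrong shape")
    pos <- segs[i, "start"] %/% str + seq_len(Lw)
    acc[, pos] <- acc[, pos] + sweep(out, 2L, wts, "*")
    den[pos] <- den[pos] + wts
  }
  if (any(den[seq_len(Lo)] <= 0)) stop("gap in window coverage")
  sweep(acc[, seq_len(Lo), drop = FALSE], 2L, den[seq_len(Lo)], "/")
}

#' Reconstruct by trimming half of each overlap (CNN-only networks)
#'
#' For networks with a finite region of influence, window outputs are exact
#' replicas of the unsegmented forward pass except within `roi / 2` input
#' samples of each window edge. If consecutive windows overlap by at least
#' `roi` input samples, cutting each overlap at its midpoint and
#' concatenating yields an output identical to the whole-series pass
#' everywhere except within `roi / 2` of the global ends.
#'
#' @inheritParams reconstruct
#' @param roi Region of influence of the network in input samples; must be
#'   finite (LSTM-bearing networks have unbounded ROI and cannot use this
#'   reconstruction).
#' @return Numeric matrix `(n_classes, ceiling(L / stride_ratio))`.
#' @export
roi_trim_reconstruct <- function(window_outputs, plan, roi) {
  stopifnot(inherits(plan, "window_plan"))
  if (!is.finite(roi))
    stop("ROI-trim reconstruction requires a finite ROI (CNN-only network)")
  segs <- plan$segments
  n <- nrow(segs)
  if (length(window_outputs) != n)
    stop("need one window output per planned segment")
  if (n > 1L) {
    ovl <- segs[-n, "end"] - segs[-1L, "start"]
    if (any(ovl < roi))
      stop("window overlap is smaller than the region of influence")
  }
  str <- plan$stride_ratio
  Lw <- plan$window_len %/% str
  Lo <- as.integer(ceiling(plan$L / str))
  nc <- nrow(window_outputs[[1L]])
  out <- matrix(NA_real_, nc, plan$L_padded %/% str)
  # cut each overlap at its midpoint, on the output grid
  cuts <- if (n > 1L)
    floor((segs[-n, "end"] + segs[-1L, "start"]) / 2 / str) else integer()
  lo_bound <- c(0L, cuts)                     # first kept output (0-based)
  hi_bound <- c(cuts, plan$L_padded %/% str)  # one past last kept output
  for (i in seq_len(n)) {
    w0 <- segs[i, "start"] %/% str
    keep <- seq.int(lo_bound[i] - w0 + 1L, hi_bound[i] - w0)
    out[, lo_bound[i] + seq_along(keep)] <- window_outputs[[i]][, keep]
  }
  out[, seq_len(Lo), drop = FALSE]
}

# Run a network over a window plan, batching windows; returns the list of
# per-window logit matrices.
.run_windows <- function(net, x, plan, batch_windows = NULL) {
  spec <- net$spec
  segs <- plan$segments
  n <- nrow(segs)
  wl <- plan$window_len
  if (is.null(batch_windows))
    batch_windows <- max(1L, as.integer(round(50000 / wl)))
  xp <- matrix(0, nrow(x), plan$L_padded)
  xp[, seq_len(ncol(x))] <- x
  outs <- vector("list", n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_windows - 1L)
    ids <- i:j
    xb <- array(0, c(nrow(x), wl, length(ids)))
    for (b in seq_along(ids))
      xb[, , b] <- xp[, segs[ids[b], "start"] + seq_len(wl)]
    fw <- .net_forward(net, xb, mode = "eval")
    lg <- fw$logits
    for (b in seq_along(ids))
      outs[[ids[b]]] <- matrix(lg[, , b], dim(lg)[1L], dim(lg)[2L])
    i <- j + 1L
  }
  outs
}

#' Windowed prediction over an arbitrarily long series
#'
#' Splits the input with [plan_windows()], runs the network per window in
#' batches, and reconstructs a single logit series by Hanning-weighted
#' overlap-add (default) or, for CNN-only networks, by ROI trimming.
#'
#' @param net A `"filternet_net"` or fitted `"filternet_fit"`.
#' @param x Numeric matrix `(input_channels, L)`.
#' @param window_len,overlap_fraction,weighting Passed to [plan_windows()].
#' @param method `"overlap_add"` (default) or `"roi_trim"`.
#' @param batch_windows Windows per forward batch; defaults to about
#'   50,000 input samples per batch.
#' @return List with `logits`, `prob` (matrices `(n_classes, L_out)`), and
#'   `class` (1-based max-probability class ids).
#' @export
filternet_predict <- function(net, x, window_len = 512L,
                              overlap_fraction = 0.5,
                              weighting = c("hanning", "rectangular"),
                              method = c("overlap_add", "roi_trim"),
                              batch_windows = NULL) {
  weighting <- match.arg(weighting)
  method <- match.arg(method)
  if (inherits(net, "filternet_fit")) net <- net$net
  stopifnot(inherits(net, "filternet_net"), is.matrix(x))
  spec <- net$spec
  str <- output_stride(spec)
  plan <- plan_windows(ncol(x), window_len, overlap_fraction, str, weighting)
  outs <- .run_windows(net, x, plan, batch_windows)
  lg <- if (method == "roi_trim")
    roi_trim_reconstruct(outs, plan, network_roi(spec))
  else reconstruct(outs, plan)
  pr <- matrix(.softmax(array(lg, c(dim(lg), 1L))), nrow(lg), ncol(lg))
  list(logits = lg, prob = pr, class = apply(pr, 2L, which.max))
}
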