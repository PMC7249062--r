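#' FilterNet layer module configuration
#'
#' An FLM is the unit of composition of a FilterNet: a dropout layer that
#' drops whole input channels, followed by either a 1-D CNN with ReLU
#' activation or a bidirectional LSTM, an average-pooling layer of kernel and
#' stride `s`, and (optionally) 1-D batch normalization. An FLM maps a series
#' of shape `(w_in, L)` to one of shape `(w_out, ceiling(L / s))` while
#' preserving the time span covered by the samples.
#'
#' @param type `"cnn"` or `"lstm"`. For `"lstm"` the layer is bidirectional
#'   and `w_out` is the total width of the two concatenated directions, so it
#'   must be even; `k` is ignored.
#' @param w_out Positive integer; output channels (CNN filters, or total
#'   bidirectional hidden width for an LSTM).
#' @param s Positive integer stride ratio (default 1). When `s > 1` the
#'   output is average-pooled with kernel and stride `s`.
#' @param k Positive odd integer CNN kernel length (default 5).
#' @param p_drop Channel dropout probability in `[0, 1)` (default 0.1).
#' @param bn Apply batch normalization after pooling (default `TRUE`).
#' @param bias Additive convolution bias. Defaults to `!bn`: a convolution
#'   followed by batch norm carries no bias of its own (the batch-norm shift
#'   absorbs it), while a bare output convolution does.
#' @return An object of class `"flm_config"`.
#' @examples
#' flm_config("cnn", w_out = 100, s = 2)
#' flm_config("lstm", w_out = 100)
#' @export
flm_config <- function(type = c("cnn", "lstm"), w_out, s = 1L, k = 5L,
                       p_drop = 0.1, bn = TRUE, bias = !bn) {
  type <- match.arg(type)
  w_out <- as.integer(w_out); s <- as.integer(s); k <- as.integer(k)
  if (w_out < 1L) stop("`w_out` must be a positive integer")
  if (s < 1L) stop("`s` must be a positive integer")
  if (p_drop < 0 || p_drop >= 1) stop("`p_drop` must lie in [0, 1)")
  if (type == "cnn") {
    if (k < 1L || k %% 2L == 0L) stop("`k` must be a positive odd integer")
  } else {
    if (w_out %% 2L != 0L)
      stop("lstm `w_out` must be even (split across two directions)")
    k <- NA_integer_
    bias <- FALSE  # lstm gate biases are always present; no extra conv bias
  }
  structure(list(type = type, w_out = w_out, s = s, k = k,
                 p_drop = p_drop, bn = isTRUE(bn), bias = isTRUE(bias)),
            class = "flm_config")
}

#' @export
print.flm_config <- function(x, ...) {
  cat(sprintf("FLM_%s(w_out=%d, s=%d%s, p_drop=%g, bn=%s%s)\n",
              x$type, x$w_out, x$s,
              if (x$type == "cnn") sprintf(", k=%d", x$k) else "",
              x$p_drop, x$bn,
              if (x$bias) ", bias" else ""))
  invisible(x)
}

#' Output length of an FLM
#'
#' A stride-`s` layer emits `ceiling(L_in / s)` samples; inputs whose length
#' is not a multiple of `s` are right zero-padded before pooling (training
#' windows are always chosen divisible, so the ceiling only matters for
#' free-length evaluation).
#'
#' @param L_in Positive input length in samples.
#' @param s Positive integer stride ratio.
#' @return Integer output length.
#' @examples
#' flm_output_length(512, 2) # 256
#' @export
flm_output_length <- function(L_in, s) {
  if (L_in < 1 || s < 1) stop("`L_in` and `s` must be positive")
  as.integer(ceiling(L_in / s))
}

#' Trainable-parameter count of an FLM
#'
#' CNN layers contribute `w_in * w_out * k` convolution weights, plus
#' `w_out` bias terms when `bias` is set, plus `2 * w_out` batch-norm scale
#' and shift terms when `bn` is set. Bidirectional LSTM layers contribute,
#' per direction with hidden size `h = w_out / 2`: `4h * w_in` input weights,
#' `4h * h` recurrent weights and `4h` gate biases, plus the batch-norm terms.
#'
#' @param cfg An [flm_config()].
#' @param w_in Positive integer count of input channels.
#' @return Integer number of trainable parameters.
#' @examples
#' flm_param_count(flm_config("cnn", 100, k = 5), w_in = 113) # 56700
#' @export
flm_param_count <- function(cfg, w_in) {
  stopifnot(inherits(cfg, "flm_config"))
  w_in <- as.integer(w_in)
  if (w_in < 1L) stop("`w_in` must be a positive integer")
  n <- if (cfg$type == "cnn") {
    w_in * cfg$w_out * cfg$k + if (cfg$bias) cfg$w_out else 0L
  } else {
    h <- cfg$w_out %/% 2L
    2L * (4L * h * w_in + 4L * h * h + 4L * h)
  }
  n + if (cfg$bn) 2L * cfg$w_out else 0L
}

#' Region of influence of a CNN stack
#'
#' The region of influence (ROI) is the maximum number of input samples that
#' can affect a single output sample of a stack of CNN-type FLMs. With
#' `ROI_0 = 1`, each layer `i` with kernel `k_i` and stride `s_i` adds
#' `(k_i - 1)` kernel steps at the layer's input rate, i.e.
#' `ROI_i = ROI_{i-1} + (k_i - 1) * prod(s_1, ..., s_i)`. A bidirectional
#' LSTM anywhere in the stack makes the ROI unbounded, reported as `Inf`.
#'
#' For stride-1 stacks the recurrence equals the realized receptive field
#' exactly. For strided stacks it counts each kernel tap at the layer's
#' output rate (as if the stride subsampled before the convolution); the
#' conv-then-average-pool layer module realizes a somewhat smaller
#' receptive field, so for the usual `k >= 2` strided layers the value is
#' a safe upper bound, which is the quantity windowed inference needs
#' (see [roi_trim_reconstruct()]).
#'
#' @param layers A list whose elements are either [flm_config()] objects or
#'   length-2 numeric vectors `c(s, k)`, in stack order.
#' @return Integer ROI in input samples, or `Inf` if the stack contains an
#'   LSTM layer.
#' @examples
#' roi_after_stack(list(c(1, 5), c(2, 5), c(2, 5), c(2, 5))) # 61
#' @export
roi_after_stack <- function(layers) {
  if (length(layers) == 0L) stop("`layers` must be nonempty")
  roi <- 1
  sprod <- 1
  for (ly in layers) {
    if (inherits(ly, "flm_config")) {
      if (ly$type != "cnn") return(Inf)
      s <- ly$s; k <- ly$k
    } else {
      s <- ly[[1L]]; k <- ly[[2L]]
    }
    if (s < 1 || k < 1) stop("strides and kernels must be positive")
    sprod <- sprod * s
    roi <- roi + (k - 1) * sprod
  }
  roi
}

# ---- parameter initialization --------------------------------------------

.flm_init <- function(cfg, w_in) {
  par <- list()
  if (cfg$type == "cnn") {
    sd <- sqrt(2 / (w_in * cfg$k))  # He initialization for ReLU
    par$W <- array(stats::rnorm(cfg$w_out * w_in * cfg$k, sd = sd),
                   c(cfg$w_out, w_in, cfg$k))
    if (cfg$bias) par$b <- numeric(cfg$w_out)
  } else {
    h <- cfg$w_out %/% 2L
    r <- 1 / sqrt(h)
    mk <- function(nr, nc) matrix(stats::runif(nr * nc, -r, r), nr, nc)
    par$fwd <- list(Wx = mk(4L * h, w_in), Wh = mk(4L * h, h),
                    b = stats::runif(4L * h, -r, r))
    par$bwd <- list(Wx = mk(4L * h, w_in), Wh = mk(4L * h, h),
                    b = stats::runif(4L * h, -r, r))
  }
  if (cfg$bn) {
    par$gamma <- rep(1, cfg$w_out)
    par$beta <- numeric(cfg$w_out)
    par$run_mean <- numeric(cfg$w_out)
    par$run_var <- rep(1, cfg$w_out)
  }
  par
}

# Enumerate the trainable values actually held by an instantiated layer
# (running batch-norm statistics are state, not parameters).
.n_trainable <- function(par) {
  n <- 0L
  walk <- function(x, name) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], nm)
    } else if (is.numeric(x) && !startsWith(name, "run_")) {
      n <<- n + length(x)
    }
  }
  walk(par, "")
  n
}

# ---- forward / backward through one FLM ----------------------------------
# x: (w_in, L, B). Returns y: (w_out, ceiling(L/s), B) and, when keep = TRUE,
# the caches needed for the backward pass. Sub-layer order: dropout ->
# (cnn | lstm) -> average pool -> batch norm.

.flm_forward <- function(par, cfg, x, mode = "eval", keep = FALSE) {
  if (!all(is.finite(x))) stop("non-finite values in FLM input")
  d <- dim(x)
  cache <- list(L_in = d[2L])
  if (mode == "train" && cfg$p_drop > 0) {
    mask <- .dropout_mask(d[1L], d[3L], cfg$p_drop)
    x <- .dropout_apply(x, mask)
    if (keep) cache$mask <- mask
  }
  if (cfg$type == "cnn") {
    pre <- .conv1d_forward(x, par$W, par[["b"]])  # [[ avoids partial match of $b to $beta
    act <- pmax(pre, 0)
    if (keep) { cache$x_conv <- x; cache$pre <- pre }
  } else {
    lf <- .lstm_bidir_forward(x, par)
    act <- lf$y
    if (keep) cache$lstm <- lf$cache
  }
  if (flm_output_length(d[2L], cfg$s) < 1L) stop("series too short to pool")
  y <- .avgpool_forward(act, cfg$s)
  if (keep) cache$L_act <- dim(act)[2L]
  if (cfg$bn) {
    bnr <- .bn_forward(y, par$gamma, par$beta, par$run_mean, par$run_var, mode)
    y <- bnr$y
    if (keep) {
      cache$bn <- bnr$cache
      cache$run_mean <- bnr$run_mean
      cache$run_var <- bnr$run_var
    }
  }
  if (keep) list(y = y, cache = cache) else list(y = y, cache = NULL)
}

.flm_backward <- function(par, cfg, cache, gy) {
  grads <- list()
  if (cfg$bn) {
    bb <- .bn_backward(gy, par$gamma, cache$bn)
    gy <- bb$gx
    grads$gamma <- bb$ggamma
    grads$beta <- bb$gbeta
  }
  g <- .avgpool_backward(gy, cfg$s, cache$L_act)
  if (cfg$type == "cnn") {
    g <- g * (cache$pre > 0)
    cb <- .conv1d_backward(cache$x_conv, par$W, g, has_bias = cfg$bias)
    grads$W <- cb$gW
    if (cfg$bias) grads$b <- cb$gb
    gx <- cb$gx
  } else {
    lb <- .lstm_bidir_backward(g, par, cache$lstm)
    grads$fwd <- list(Wx = lb$fwd$gWx, Wh = lb$fwd$gWh, b = lb$fwd$gb)
    grads$bwd <- list(Wx = lb$bwd$gWx, Wh = lb$bwd$gWh, b = lb$bwd$gb)
    gx <- lb$gx
  }
  if (!is.null(cache$mask)) gx <- .dropout_apply(gx, cache$mask)
  list(gx = gx, grads = grads)
}

#' Apply a single FilterNet layer module to a series
#'
#' Runs one FLM forward pass: channel dropout (train mode only), the CNN or
#' bidirectional LSTM sub-layer, average pooling with kernel and stride `s`,
#' and batch normalization. Mostly useful for inspecting layer behaviour;
#' whole networks are run through [predict.filternet_fit()] or
#' [filternet_forward()].
#'
#' @param x Numeric matrix of shape `(channels, samples)`.
#' @param cfg An [flm_config()]; its input width is taken from `nrow(x)`.
#' @param mode `"eval"` (deterministic; default) or `"train"`.
#' @param params Optional layer parameters as produced by the internal
#'   initializer; when `NULL`, parameters are drawn from the current RNG
#'   state.
#' @return Numeric matrix of shape `(w_out, ceiling(ncol(x) / s))`.
#' @examples
#' x <- matrix(abs(rnorm(3 * 64)), 3)
#' y <- apply_flm(x, flm_config("cnn", w_out = 4, s = 2, p_drop = 0))
#' dim(y) # 4 x 32
#' @export
apply_flm <- function(x, cfg, mode = c("eval", "train"), params = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), inherits(cfg, "flm_config"))
  if (is.null(params)) params <- .flm_init(cfg, nrow(x))
  out <- .flm_forward(params, cfg, array(x, c(dim(x), 1L)), mode = mode)
  matrix(out$y, dim(out$y)[1L], dim(out$y)[2L])
}
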