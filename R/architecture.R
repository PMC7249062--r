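#' Construct a FilterNet architecture specification
#'
#' A FilterNet is assembled from up to seven components: (A) a
#' full-resolution CNN layer, (B) a first pooling stack of `n_p1` stride-`s`
#' CNN layers that sets the network's output stride ratio `s^n_p1`, (C) a
#' second pooling stack of `n_p2` CNN layers that downsamples beyond the
#' output rate while halving widths layer to layer, (D) a resampling step
#' that linearly interpolates every stack-2 output back to the output length
#' and concatenates them with the stack-1 output, (E) a kernel-1 bottleneck
#' CNN, (F) a recurrent stack of `n_l` bidirectional LSTM layers, and (G) a
#' kernel-1 output CNN without batch norm that feeds a per-sample softmax.
#'
#' The five named variants use the component subsets: `b_lstm` = F+G (output
#' stride 1), `p_cnn` = A+B+G, `p_cl` = A+B+F+G, `ms_cnn` = A+B+C+D+E+G and
#' `ms_cl` = all of A-G.
#'
#' @param variant One of `"b_lstm"`, `"p_cnn"`, `"p_cl"`, `"ms_cnn"`,
#'   `"ms_cl"`.
#' @param input_channels Number of input sensor channels.
#' @param n_classes Number of output classes, including the null class.
#' @param width_scale Multiplies all hidden widths (rounded to the nearest
#'   integer, floor 1); 0.5 and 2 give the half- and double-width variants.
#' @param base_width Hidden width before scaling (reference value 100).
#' @param s Stride ratio of each pooling layer (reference value 2).
#' @param n_p1 Layers in pooling stack 1 (reference value 3).
#' @param n_p2 Layers in pooling stack 2 (reference value 4); the last
#'   stack-2 layer halves the width but keeps stride 1.
#' @param n_l Layers in the recurrent stack (reference value 1).
#' @param k CNN kernel length (reference value 5).
#' @param p_drop Channel dropout probability for all FLMs except the output
#'   module, which never uses dropout.
#' @return An object of class `"filternet_spec"`.
#' @examples
#' spec <- filternet_spec("ms_cnn", input_channels = 12, n_classes = 6)
#' total_param_count(spec)
#' @seealso [build_reference()] for the reference configurations.
#' @export
filternet_spec <- function(variant = c("ms_cl", "b_lstm", "p_cnn", "p_cl",
                                       "ms_cnn"),
                           input_channels, n_classes, width_scale = 1,
                           base_width = 100L, s = 2L, n_p1 = 3L, n_p2 = 4L,
                           n_l = 1L, k = 5L, p_drop = 0.1) {
  variant <- match.arg(variant)
  input_channels <- as.integer(input_channels)
  n_classes <- as.integer(n_classes)
  stopifnot(input_channels >= 1L, n_classes >= 2L, width_scale > 0)
  sw <- function(w) max(1L, as.integer(floor(w * width_scale + 0.5)))
  w_main <- sw(base_width)
  w_lstm <- 2L * max(1L, as.integer(floor(base_width * width_scale / 2 + 0.5)))

  has <- switch(variant,
    b_lstm = c(A = FALSE, B = FALSE, C = FALSE, D = FALSE, E = FALSE,
               F = TRUE, G = TRUE),
    p_cnn  = c(A = TRUE, B = TRUE, C = FALSE, D = FALSE, E = FALSE,
               F = FALSE, G = TRUE),
    p_cl   = c(A = TRUE, B = TRUE, C = FALSE, D = FALSE, E = FALSE,
               F = TRUE, G = TRUE),
    ms_cnn = c(A = TRUE, B = TRUE, C = TRUE, D = TRUE, E = TRUE,
               F = FALSE, G = TRUE),
    ms_cl  = c(A = TRUE, B = TRUE, C = TRUE, D = TRUE, E = TRUE,
               F = TRUE, G = TRUE))

  comp <- list()
  if (has["A"])
    comp$A <- list(flm_config("cnn", w_main, s = 1L, k = k, p_drop = p_drop))
  if (has["B"])
    comp$B <- replicate(n_p1,
      flm_config("cnn", w_main, s = s, k = k, p_drop = p_drop),
      simplify = FALSE)
  if (has["C"]) {
    widths <- integer(n_p2)
    prev <- w_main
    for (i in seq_len(n_p2)) {
      widths[i] <- max(1L, as.integer(ceiling(prev / s)))
      prev <- widths[i]
    }
    comp$C <- lapply(seq_len(n_p2), function(i)
      flm_config("cnn", widths[i], s = if (i < n_p2) s else 1L, k = k,
                 p_drop = p_drop))
  }
  if (has["E"])
    comp$E <- list(flm_config("cnn", w_main, s = 1L, k = 1L,
                              p_drop = p_drop))
  if (has["F"])
    comp$F <- replicate(n_l,
      flm_config("lstm", w_lstm, s = 1L, p_drop = p_drop),
      simplify = FALSE)
  comp$G <- list(flm_config("cnn", n_classes, s = 1L, k = 1L, p_drop = 0,
                            bn = FALSE, bias = TRUE))

  structure(list(variant = variant, components = comp,
                 input_channels = input_channels, n_classes = n_classes,
                 width_scale = width_scale, base_width = as.integer(base_width),
                 s = as.integer(s),
                 n_p1 = if (has["B"]) as.integer(n_p1) else 0L,
                 n_p2 = if (has["C"]) as.integer(n_p2) else 0L,
                 n_l = if (has["F"]) as.integer(n_l) else 0L,
                 k = as.integer(k), p_drop = p_drop),
            class = "filternet_spec")
}

#' Build one of the five reference architectures
#'
#' Returns the reference configuration of the requested variant: hidden
#' width 100, kernel 5, three stride-2 layers in pooling stack 1 (output
#' stride ratio 8), four layers in pooling stack 2 with widths halving
#' 50-25-13-7, a width-100 bottleneck and a single width-100 bidirectional
#' LSTM where the variant includes those components. `width_scale` rescales
#' every hidden width.
#'
#' @inheritParams filternet_spec
#' @return A [filternet_spec()].
#' @examples
#' spec <- build_reference("ms_cl", input_channels = 113, n_classes = 18)
#' output_stride(spec) # 8
#' @export
build_reference <- function(variant, input_channels, n_classes,
                            width_scale = 1) {
  filternet_spec(variant, input_channels = input_channels,
                 n_classes = n_classes, width_scale = width_scale)
}

#' Output stride ratio of an architecture
#'
#' @param spec A [filternet_spec()].
#' @return Integer ratio of input to output sampling frequency, `s^n_p1`
#'   (1 for the base LSTM).
#' @export
output_stride <- function(spec) {
  stopifnot(inherits(spec, "filternet_spec"))
  as.integer(spec$s^spec$n_p1)
}

# Ordered layer table: one row per FLM with its name, config and input
# width, resolving the resample/concat wiring for the bottleneck input.
.spec_layers <- function(spec) {
  out <- list()
  w <- spec$input_channels
  add <- function(name, cfg, w_in) {
    out[[length(out) + 1L]] <<- list(name = name, cfg = cfg, w_in = w_in)
  }
  comp <- spec$components
  for (i in seq_along(comp$A)) { add("A", comp$A[[i]], w); w <- comp$A[[i]]$w_out }
  for (i in seq_along(comp$B)) {
    add(paste0("B", i), comp$B[[i]], w); w <- comp$B[[i]]$w_out
  }
  w_ps1 <- w
  for (i in seq_along(comp$C)) {
    add(paste0("C", i), comp$C[[i]], w); w <- comp$C[[i]]$w_out
  }
  if (!is.null(comp$C))
    w <- w_ps1 + sum(vapply(comp$C, function(cf) cf$w_out, 1L))  # concat (D)
  for (i in seq_along(comp$E)) { add("E", comp$E[[i]], w); w <- comp$E[[i]]$w_out }
  for (i in seq_along(comp$F)) {
    add(paste0("F", i), comp$F[[i]], w); w <- comp$F[[i]]$w_out
  }
  add("G", comp$G[[1L]], w)
  out
}

#' Total trainable-parameter count of an architecture
#'
#' @param spec A [filternet_spec()].
#' @return Integer sum of [flm_param_count()] over all layers.
#' @examples
#' total_param_count(build_reference("p_cnn", 113, 18)) # 209118
#' @export
total_param_count <- function(spec) {
  layers <- .spec_layers(spec)
  sum(vapply(layers, function(l) flm_param_count(l$cfg, l$w_in), 1L))
}

#' Region of influence of an architecture
#'
#' ROI of the CNN path through components A, B and C (kernel-1 layers add
#' nothing). Architectures containing an LSTM have unbounded ROI, reported
#' as `Inf`.
#'
#' @param spec A [filternet_spec()].
#' @return ROI in input samples, or `Inf`.
#' @export
network_roi <- function(spec) {
  stopifnot(inherits(spec, "filternet_spec"))
  if (spec$n_l > 0L) return(Inf)
  comp <- spec$components
  roi_after_stack(c(comp$A, comp$B, comp$C))
}

#' @export
print.filternet_spec <- function(x, ...) {
  cat(sprintf("FilterNet spec: %s (%d input channels, %d classes, width x%g)\n",
              x$variant, x$input_channels, x$n_classes, x$width_scale))
  layers <- .spec_layers(x)
  roi <- 1; sprod <- 1; srat <- 1
  rows <- lapply(layers, function(l) {
    cfg <- l$cfg
    srat <<- srat * cfg$s
    if (cfg$type == "cnn" && is.finite(roi)) {
      sprod <<- sprod * cfg$s
      roi <<- roi + (cfg$k - 1) * sprod
    } else if (cfg$type == "lstm") roi <<- Inf
    data.frame(layer = l$name, type = cfg$type, w_in = l$w_in,
               w_out = cfg$w_out, s = cfg$s,
               k = ifelse(is.na(cfg$k), "", cfg$k),
               params = flm_param_count(cfg, l$w_in),
               stride_ratio = srat,
               roi = ifelse(is.finite(roi), roi, NA))
  })
  tab <- do.call(rbind, rows)
  print(tab, row.names = FALSE)
  cat(sprintf("total trainable parameters: %d; output stride ratio: %d\n",
              total_param_count(x), output_stride(x)))
  invisible(x)
}

#' Resample and concatenate multi-scale outputs
#'
#' Linearly interpolates (align-ends convention: first and last samples map
#' onto each other) every pooling-stack-2 output to the temporal length of
#' the final pooling-stack-1 output, then concatenates all series along the
#' channel dimension, stack-1 output first.
#'
#' @param final_ps1_output Numeric matrix `(channels, L_out)`.
#' @param c_stack_outputs List of numeric matrices covering the same time
#'   span at coarser sampling; may be empty.
#' @return Numeric matrix with `nrow(final_ps1_output) + sum(widths)` rows
#'   and `ncol(final_ps1_output)` columns.
#' @examples
#' a <- matrix(rnorm(4 * 16), 4)
#' b <- matrix(rnorm(2 * 8), 2)
#' dim(resample_concat(a, list(b))) # 6 x 16
#' @export
resample_concat <- function(final_ps1_output, c_stack_outputs) {
  stopifnot(is.matrix(final_ps1_output))
  if (length(c_stack_outputs) == 0L) return(final_ps1_output)
  L_out <- ncol(final_ps1_output)
  res <- lapply(c_stack_outputs, function(m) {
    stopifnot(is.matrix(m))
    y <- .resample_forward(array(m, c(dim(m), 1L)), L_out)
    matrix(y, nrow(m), L_out)
  })
  do.call(rbind, c(list(final_ps1_output), res))
}

# ---- instantiated networks ------------------------------------------------

#' Instantiate a FilterNet with freshly initialized weights
#'
#' @param spec A [filternet_spec()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class `"filternet_net"` holding the spec and a named
#'   list of per-layer parameters.
#' @export
filternet_init <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "filternet_spec"))
  if (!is.null(seed)) set.seed(seed)
  layers <- .spec_layers(spec)
  params <- list()
  for (l in layers) params[[l$name]] <- .flm_init(l$cfg, l$w_in)
  structure(list(spec = spec, params = params), class = "filternet_net")
}

.cat_channels <- function(lst) {
  ws <- vapply(lst, function(a) dim(a)[1L], 1L)
  d <- dim(lst[[1L]])
  out <- array(0, c(sum(ws), d[2L], d[3L]))
  off <- 0L
  for (a in lst) {
    w <- dim(a)[1L]
    out[off + seq_len(w), , ] <- a
    off <- off + w
  }
  out
}

# Forward pass over (channels, L, B) arrays. keep = TRUE retains per-layer
# caches (and updated batch-norm running stats) for backprop.
.net_forward <- function(net, x, mode = "eval", keep = FALSE) {
  spec <- net$spec
  layers <- .spec_layers(spec)
  byname <- stats::setNames(layers, vapply(layers, `[[`, "", "name"))
  caches <- list()
  run <- function(name, h) {
    out <- .flm_forward(net$params[[name]], byname[[name]]$cfg, h,
                        mode = mode, keep = keep)
    if (keep) caches[[name]] <<- out$cache
    out$y
  }
  h <- x
  if (!is.null(spec$components$A)) h <- run("A", h)
  for (i in seq_len(spec$n_p1)) h <- run(paste0("B", i), h)
  if (spec$n_p2 > 0L) {
    i1 <- h
    taps <- vector("list", spec$n_p2)
    for (i in seq_len(spec$n_p2)) {
      h <- run(paste0("C", i), h)
      taps[[i]] <- h
    }
    L_out <- dim(i1)[2L]
    res <- lapply(taps, .resample_forward, L_out = L_out)
    if (keep) caches$D <- list(tap_len = vapply(taps, function(a) dim(a)[2L], 1L),
                               tap_w = vapply(taps, function(a) dim(a)[1L], 1L),
                               w_i1 = dim(i1)[1L])
    h <- .cat_channels(c(list(i1), res))
    h <- run("E", h)
  }
  for (i in seq_len(spec$n_l)) h <- run(paste0("F", i), h)
  logits <- run("G", h)
  list(logits = logits, caches = caches)
}

# Backward pass; returns gradients in the same nested structure as params.
.net_backward <- function(net, caches, glogits) {
  spec <- net$spec
  layers <- .spec_layers(spec)
  byname <- stats::setNames(layers, vapply(layers, `[[`, "", "name"))
  grads <- list()
  back <- function(name, g) {
    bb <- .flm_backward(net$params[[name]], byname[[name]]$cfg,
                        caches[[name]], g)
    grads[[name]] <<- bb$grads
    bb$gx
  }
  g <- back("G", glogits)
  for (i in rev(seq_len(spec$n_l))) g <- back(paste0("F", i), g)
  if (spec$n_p2 > 0L) {
    g <- back("E", g)
    D <- caches$D
    gi1 <- g[seq_len(D$w_i1), , , drop = FALSE]
    off <- D$w_i1
    gtap <- vector("list", spec$n_p2)
    for (i in seq_len(spec$n_p2)) {
      gres <- g[off + seq_len(D$tap_w[i]), , , drop = FALSE]
      gtap[[i]] <- .resample_backward(gres, D$tap_len[i])
      off <- off + D$tap_w[i]
    }
    gnext <- NULL
    for (i in rev(seq_len(spec$n_p2))) {
      gout <- gtap[[i]]
      if (!is.null(gnext)) gout <- gout + gnext
      gnext <- back(paste0("C", i), gout)
    }
    g <- gi1 + gnext
  }
  for (i in rev(seq_len(spec$n_p1))) g <- back(paste0("B", i), g)
  if (!is.null(spec$components$A)) g <- back("A", g)
  list(grads = grads, gx = g)
}

#' Run a FilterNet forward over a whole series
#'
#' Evaluates the network on an unsegmented series. For long inputs prefer
#' the windowed [predict.filternet_fit()], which bounds memory use.
#'
#' @param net A `"filternet_net"` from [filternet_init()], or a fitted model.
#' @param x Numeric matrix `(input_channels, L)`. In train mode `L` must be
#'   a multiple of the output stride ratio; in eval mode any `L` at least
#'   one stride long is accepted and the output has `ceiling(L / stride)`
#'   samples.
#' @param mode `"eval"` (default) or `"train"` (enables dropout and
#'   batch-statistics normalization; used internally by the fitter).
#' @return A list with `logits` and `prob` matrices of shape
#'   `(n_classes, L_out)`; probabilities are the per-sample softmax.
#' @export
filternet_forward <- function(net, x, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (inherits(net, "filternet_fit")) net <- net$net
  stopifnot(inherits(net, "filternet_net"), is.matrix(x))
  if (nrow(x) != net$spec$input_channels)
    stop(sprintf("input has %d channels but the network expects %d",
                 nrow(x), net$spec$input_channels))
  str <- output_stride(net$spec)
  if (mode == "train" && ncol(x) %% str != 0L)
    stop("in train mode the input length must be a multiple of the output stride ratio")
  out <- .net_forward(net, array(x, c(dim(x), 1L)), mode = mode)
  lg <- matrix(out$logits, dim(out$logits)[1L], dim(out$logits)[2L])
  rownames(lg) <- NULL
  list(logits = lg, prob = matrix(.softmax(array(lg, c(dim(lg), 1L))),
                                  nrow(lg), ncol(lg)))
}
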