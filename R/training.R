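#' Training control parameters
#'
#' Defaults follow the study schedule: Adam with initial learning rate
#' 0.001 decayed by 0.95 per epoch, weight decay 0.0001, batches holding
#' about 5000 input samples, training windows of 512 input samples drawn
#' with a step of 16 output samples, at most 100 epochs, and early stopping
#' after 10 epochs without a checkpoint.
#'
#' @param max_epochs Maximum training epochs.
#' @param initial_lr Initial learning rate.
#' @param samples_per_batch Target input samples per batch; the number of
#'   windows per batch is `round(samples_per_batch / window_len)`, at
#'   least 1.
#' @param train_window_step Step between training-window starts, in output
#'   samples.
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param weight_decay L2 penalty added to every gradient.
#' @param patience Epochs without a new checkpoint before stopping.
#' @param lr_decay Multiplicative learning-rate decay per epoch.
#' @param window_len Training window length in input samples; must be
#'   divisible by the model's output stride ratio.
#' @return An object of class `"filternet_control"`.
#' @export
filternet_control <- function(max_epochs = 100L, initial_lr = 0.001,
                              samples_per_batch = 5000L,
                              train_window_step = 16L,
                              optimizer = c("adam", "rmsprop"),
                              weight_decay = 1e-4, patience = 10L,
                              lr_decay = 0.95, window_len = 512L) {
  optimizer <- match.arg(optimizer)
  stopifnot(max_epochs >= 1L, initial_lr > 0, samples_per_batch >= 1L,
            train_window_step >= 1L, weight_decay >= 0, patience >= 0L,
            lr_decay > 0, lr_decay <= 1, window_len >= 1L)
  structure(list(max_epochs = as.integer(max_epochs),
                 initial_lr = initial_lr,
                 samples_per_batch = as.integer(samples_per_batch),
                 train_window_step = as.integer(train_window_step),
                 optimizer = optimizer, weight_decay = weight_decay,
                 patience = as.integer(patience), lr_decay = lr_decay,
                 window_len = as.integer(window_len)),
            class = "filternet_control")
}

#' Smoothed, instability-penalized checkpoint metric
#'
#' The per-epoch raw value is validation loss divided by validation
#' weighted F1. The smoothed component is its exponentially weighted moving
#' average with a half-life of 3 epochs (`alpha = 1 - 0.5^(1/3)`,
#' initialized at the first raw value); the instability component is the
#' population standard deviation of the most recent `min(5, e)` raw values
#' (0 at the first epoch). The checkpoint metric is their sum, and a model
#' is checkpointed whenever it reaches a new minimum.
#'
#' @param raw_history Numeric vector of positive per-epoch raw values, in
#'   epoch order.
#' @return A list with vectors `smoothed`, `instability` and `metric`, each
#'   of length `length(raw_history)`.
#' @examples
#' checkpoint_metric(c(2, 1))$metric # about 2.2937
#' @export
checkpoint_metric <- function(raw_history) {
  if (length(raw_history) == 0L) stop("`raw_history` must be nonempty")
  if (any(!is.finite(raw_history)) || any(raw_history <= 0))
    stop("raw checkpoint values must be positive (loss / F1)")
  alpha <- 1 - 0.5^(1 / 3)
  n <- length(raw_history)
  smoothed <- numeric(n)
  smoothed[1L] <- raw_history[1L]
  for (e in seq_len(n)[-1L])
    smoothed[e] <- (1 - alpha) * smoothed[e - 1L] + alpha * raw_history[e]
  instability <- vapply(seq_len(n), function(e) {
    w <- raw_history[max(1L, e - 4L):e]
    if (length(w) < 2L) 0 else sqrt(mean((w - mean(w))^2))
  }, 1)
  list(smoothed = smoothed, instability = instability,
       metric = smoothed + instability)
}

#' Early-stopping decision
#'
#' Training stops once at least `patience` epochs have elapsed since the
#' last checkpoint (a new minimum of the checkpoint metric); on stop, the
#' weights saved at the last checkpoint are restored.
#'
#' @param history A data frame or list with a `metric` vector (per-epoch
#'   checkpoint metric), or the result of [checkpoint_metric()].
#' @param patience Non-negative integer.
#' @return `TRUE` if training should stop after the last recorded epoch.
#' @export
should_stop <- function(history, patience) {
  metric <- if (is.list(history) && !is.null(history$metric))
    history$metric else as.numeric(history)
  if (length(metric) < 1L) stop("need at least one epoch")
  last_ckpt <- max(which(metric == cummin(metric)))
  (length(metric) - last_ckpt) >= patience
}

# ---- optimizer -----------------------------------------------------------
# Parameters, gradients and optimizer state share one nested-list shape;
# leaves named run_* are batch-norm state and are not optimized.

.walk_leaves <- function(par, fn, path = character()) {
  for (nm in names(par)) {
    if (startsWith(nm, "run_")) next
    x <- par[[nm]]
    if (is.list(x)) .walk_leaves(x, fn, c(path, nm))
    else fn(c(path, nm))
  }
}

.pluck <- function(lst, path) {
  for (p in path) lst <- lst[[p]]
  lst
}

.poke <- function(lst, path, value) {
  if (length(path) == 1L) lst[[path]] <- value
  else lst[[path[1L]]] <- .poke(lst[[path[1L]]], path[-1L], value)
  lst
}

.opt_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.opt_step <- function(params, grads, state, lr, control) {
  state$t <- state$t + 1L
  t <- state$t
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  paths <- list()
  .walk_leaves(params, function(p) paths[[length(paths) + 1L]] <<- p)
  for (p in paths) {
    w <- .pluck(params, p)
    g <- .pluck(grads, p)
    if (is.null(g)) next
    g <- g + control$weight_decay * w
    if (control$optimizer == "adam") {
      m <- b1 * .pluck(state$m, p) + (1 - b1) * g
      v <- b2 * .pluck(state$v, p) + (1 - b2) * g * g
      state$m <- .poke(state$m, p, m)
      state$v <- .poke(state$v, p, v)
      mh <- m / (1 - b1^t)
      vh <- v / (1 - b2^t)
      w <- w - lr * mh / (sqrt(vh) + eps)
    } else {  # rmsprop
      v <- 0.99 * .pluck(state$v, p) + 0.01 * g * g
      state$v <- .poke(state$v, p, v)
      w <- w - lr * g / (sqrt(v) + eps)
    }
    params <- .poke(params, p, w)
  }
  list(params = params, state = state)
}

# ---- label handling ------------------------------------------------------

# Per-output-sample labels: the mode of the input labels in each
# stride-wide bin (ties go to the smaller class id); preserves short events
# better than plain subsampling.
.bin_labels <- function(y, stride) {
  if (stride == 1L) return(as.integer(y))
  Lo <- length(y) %/% stride
  y <- y[seq_len(Lo * stride)]
  m <- matrix(as.integer(y), nrow = stride)
  apply(m, 2L, function(col) {
    tb <- tabulate(col + 1L)
    which.max(tb) - 1L
  })
}

# ---- validation pass -----------------------------------------------------

# Validation loss and weighted F1 from non-overlapping windows (final
# window right-aligned), eval mode.
.validate <- function(net, x, y_out, control) {
  str <- output_stride(net$spec)
  wl <- control$window_len
  plan <- plan_windows(ncol(x), wl, overlap_fraction = 0, stride_ratio = str)
  outs <- .run_windows(net, x, plan)
  Lo <- length(y_out)
  Lw <- wl %/% str
  tot_loss <- 0; tot_n <- 0L
  pred <- integer(Lo)
  for (i in seq_len(nrow(plan$segments))) {
    pos <- plan$segments[i, "start"] %/% str + seq_len(Lw)
    keep <- pos <= Lo
    if (!any(keep)) next
    lg <- outs[[i]][, keep, drop = FALSE]
    lab <- y_out[pos[keep]] + 1L
    lr <- .xent_loss_grad(array(lg, c(dim(lg), 1L)), lab)
    tot_loss <- tot_loss + lr$loss * sum(keep)
    tot_n <- tot_n + sum(keep)
    pred[pos[keep]] <- apply(lg, 2L, which.max) - 1L
  }
  f1 <- sample_f1_scores(y_out, pred, null_class = 0L,
                         classes = 0:(net$spec$n_classes - 1L))
  list(loss = tot_loss / tot_n, f1w = f1$f1w, f1m = f1$f1m, pred = pred)
}

# ---- the fitter ----------------------------------------------------------

#' Fit a FilterNet to labeled series
#'
#' Trains the network with windowed cross-entropy over all output samples:
#' training windows of `window_len` input samples are drawn with a step of
#' `train_window_step` output samples and shuffled each epoch; every class
#' (including null) enters the loss. After each epoch the validation loss
#' and weighted F1 are computed, the checkpoint metric
#' ([checkpoint_metric()]) is updated, weights are checkpointed at each new
#' metric minimum, the learning rate is decayed, and training stops after
#' `patience` epochs without a checkpoint ([should_stop()]). The returned
#' model carries the restored checkpoint weights.
#'
#' @param spec A [filternet_spec()].
#' @param train,val [labeled_series()] objects with labels
#'   `0 ... n_classes - 1` (0 = null). Inputs are used as-is; apply
#'   [preprocess_series()] first, passing the training statistics to the
#'   validation series.
#' @param control A [filternet_control()].
#' @param seed Integer seed governing initialization, dropout and window
#'   shuffling; fits are reproducible given the seed.
#' @param verbose Print per-epoch tab-separated progress lines.
#' @return An object of class `"filternet_fit"` with elements `net`
#'   (the restored `"filternet_net"`), `history` (per-epoch data frame with
#'   `loss_val`, `f1w_val`, `raw`, `smoothed`, `instability`, `metric`,
#'   `checkpoint`, `lr`), `best_epoch`, `control`, `seed`.
#' @export
filternet_fit <- function(spec, train, val, control = filternet_control(),
                          seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "filternet_spec"),
            inherits(train, "labeled_series"),
            inherits(val, "labeled_series"))
  str <- output_stride(spec)
  if (control$window_len %% str != 0L)
    stop("`window_len` must be divisible by the output stride ratio")
  if (max(train$y, val$y) >= spec$n_classes || min(train$y, val$y) < 0L)
    stop("labels must lie in 0 .. n_classes - 1")
  set.seed(seed)
  net <- filternet_init(spec)
  wl <- control$window_len
  Lw <- wl %/% str
  wpb <- max(1L, as.integer(round(control$samples_per_batch / wl)))
  step_in <- control$train_window_step * str
  starts <- seq.int(0L, ncol(train$x) - wl, by = step_in)
  if (length(starts) == 0L) stop("training series shorter than one window")
  y_out_train <- .bin_labels(train$y, str)
  y_out_val <- .bin_labels(val$y, str)
  opt <- .opt_init(net$params)
  lr <- control$initial_lr
  hist_rows <- list()
  raws <- numeric()
  best <- list(metric = Inf, params = net$params, epoch = 0L)
  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample(starts)
    for (i in seq.int(1L, length(ord), by = wpb)) {
      ids <- ord[i:min(length(ord), i + wpb - 1L)]
      B <- length(ids)
      xb <- array(0, c(nrow(train$x), wl, B))
      lab <- matrix(0L, Lw, B)
      for (b in seq_len(B)) {
        xb[, , b] <- train$x[, ids[b] + seq_len(wl)]
        lab[, b] <- y_out_train[ids[b] %/% str + seq_len(Lw)]
      }
      fw <- .net_forward(net, xb, mode = "train", keep = TRUE)
      # adopt updated batch-norm running statistics
      for (nm in names(fw$caches)) {
        if (!is.null(fw$caches[[nm]]$run_mean)) {
          net$params[[nm]]$run_mean <- fw$caches[[nm]]$run_mean
          net$params[[nm]]$run_var <- fw$caches[[nm]]$run_var
        }
      }
      lg <- .xent_loss_grad(fw$logits, lab + 1L)
      bw <- .net_backward(net, fw$caches, lg$grad)
      st <- .opt_step(net$params, bw$grads, opt, lr, control)
      net$params <- st$params
      opt <- st$state
    }
    vres <- .validate(net, val$x, y_out_val, control)
    raws <- c(raws, vres$loss / max(vres$f1w, 1e-8))
    cm <- checkpoint_metric(raws)
    e <- length(raws)
    is_ckpt <- cm$metric[e] < best$metric
    if (is_ckpt) best <- list(metric = cm$metric[e], params = net$params,
                              epoch = epoch)
    hist_rows[[e]] <- data.frame(epoch = epoch, loss_val = vres$loss,
                                 f1w_val = vres$f1w, f1m_val = vres$f1m,
                                 raw = raws[e], smoothed = cm$smoothed[e],
                                 instability = cm$instability[e],
                                 metric = cm$metric[e],
                                 checkpoint = is_ckpt, lr = lr)
    if (verbose)
      cat(sprintf("%d\t%.4f\t%.4f\t%.4f\t%s\n", epoch, vres$loss,
                  vres$f1w, cm$metric[e], if (is_ckpt) "ckpt" else ""))
    lr <- lr * control$lr_decay
    if (should_stop(cm, control$patience)) break
  }
  net$params <- best$params
  structure(list(net = net, spec = spec,
                 history = do.call(rbind, hist_rows),
                 best_epoch = best$epoch, control = control, seed = seed),
            class = "filternet_fit")
}

#' @export
print.filternet_fit <- function(x, ...) {
  cat(sprintf("FilterNet fit: %s, %d trainable parameters\n",
              x$spec$variant, total_param_count(x$spec)))
  n <- nrow(x$history)
  cat(sprintf("trained %d epochs; checkpoint restored from epoch %d\n",
              n, x$best_epoch))
  b <- x$history[x$history$epoch == x$best_epoch, ]
  if (nrow(b))
    cat(sprintf("validation at checkpoint: loss %.4f, F1w %.4f, F1m %.4f\n",
                b$loss_val, b$f1w_val, b$f1m_val))
  invisible(x)
}

#' @export
summary.filternet_fit <- function(object, ...) {
  print(object)
  cat("\narchitecture:\n")
  print(object$spec)
  invisible(object)
}

#' @export
coef.filternet_fit <- function(object, ...) object$net$params

#' @export
plot.filternet_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$raw, h$metric), type = "l", lty = 1,
                    col = c("grey60", "black"), xlab = "epoch",
                    ylab = "validation loss / F1w", ...)
  graphics::points(h$epoch[h$checkpoint], h$metric[h$checkpoint], pch = 19)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("raw", "checkpoint metric"), lty = 1,
                   col = c("grey60", "black"), bty = "n")
  invisible(x)
}

#' Predict method for fitted FilterNets
#'
#' Windowed inference via [filternet_predict()].
#'
#' @param object A `"filternet_fit"`.
#' @param newdata Numeric matrix `(input_channels, L)` or a
#'   [labeled_series()].
#' @param type `"class"` (default), `"prob"` or `"logit"`.
#' @param ... Passed to [filternet_predict()] (window length, overlap,
#'   weighting, method).
#' @return Class-id vector (0-based, 0 = null) or a
#'   `(n_classes, L_out)` matrix, per `type`.
#' @export
predict.filternet_fit <- function(object, newdata,
                                  type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_series")) newdata <- newdata$x
  res <- filternet_predict(object$net, newdata, ...)
  switch(type, class = res$class - 1L, prob = res$prob, logit = res$logits)
}
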