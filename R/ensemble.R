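#' Contiguous fold plan
#'
#' Divides `[0, L)` into `n` disjoint contiguous intervals whose lengths
#' differ by at most one sample, ordered left to right; remainder samples
#' go to the leftmost folds. Fold `i` serves as the validation set of
#' sub-model `i`, the remaining folds as its training set.
#'
#' @param L Combined train+validation length in samples.
#' @param n Number of folds, at least 2.
#' @return An object of class `"fold_plan"`: list with `n_folds` and
#'   `folds`, a two-column matrix of half-open 0-based `(start, end)`
#'   intervals.
#' @examples
#' make_folds(10, 3)$folds # lengths 4, 3, 3
#' @export
make_folds <- function(L, n) {
  L <- as.integer(L); n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2")
  if (n > L) stop("more folds than samples")
  base <- L %/% n
  rem <- L %% n
  len <- rep(base, n) + c(rep(1L, rem), rep(0L, n - rem))
  ends <- cumsum(len)
  starts <- ends - len
  structure(list(n_folds = n, folds = cbind(start = starts, end = ends)),
            class = "fold_plan")
}

#' Average sub-model logits and apply softmax once
#'
#' @param logit_series_list Nonempty list of equally shaped
#'   `(n_classes, L_out)` logit matrices.
#' @return List with `logits` (the elementwise mean), `prob` (softmax of
#'   the mean) and `class` (1-based argmax ids).
#' @examples
#' ensemble_logits(list(rbind(2, 0), rbind(0, 2)))$prob # 0.5, 0.5
#' @export
ensemble_logits <- function(logit_series_list) {
  if (length(logit_series_list) == 0L) stop("empty logit list")
  d <- dim(logit_series_list[[1L]])
  for (m in logit_series_list)
    if (!identical(dim(m), d)) stop("logit shapes differ across sub-models")
  lg <- Reduce(`+`, logit_series_list) / length(logit_series_list)
  pr <- matrix(.softmax(array(lg, c(dim(lg), 1L))), nrow(lg), ncol(lg))
  list(logits = lg, prob = pr, class = apply(pr, 2L, which.max))
}

#' Fit an n-fold FilterNet ensemble
#'
#' Combines the training and validation series into one contiguous series,
#' splits it into `n_folds` contiguous folds, and trains one sub-model per
#' fold (fold `i` held out for validation, seed offset by the fold index).
#' At prediction time sub-model logits are averaged before a single
#' softmax.
#'
#' @param spec A [filternet_spec()].
#' @param series A [labeled_series()] holding the combined train+validation
#'   data (already preprocessed).
#' @param n_folds Number of folds (2 or more).
#' @param control A [filternet_control()].
#' @param seed Base seed; sub-model `i` uses `seed + i`.
#' @param verbose Print per-epoch progress of each sub-model.
#' @return An object of class `"filternet_ensemble"`: list with `fits`
#'   (the sub-model `"filternet_fit"` objects), `fold_plan`, `spec`,
#'   `seed`.
#' @export
filternet_fit_ensemble <- function(spec, series, n_folds = 3L,
                                   control = filternet_control(),
                                   seed = 1L, verbose = FALSE) {
  stopifnot(inherits(series, "labeled_series"))
  plan <- make_folds(ncol(series$x), n_folds)
  fits <- vector("list", n_folds)
  for (i in seq_len(n_folds)) {
    v <- plan$folds[i, ]
    vidx <- (v["start"] + 1L):v["end"]
    val <- labeled_series(series$x[, vidx, drop = FALSE], series$y[vidx],
                          fs = series$fs)
    tr <- labeled_series(series$x[, -vidx, drop = FALSE], series$y[-vidx],
                         fs = series$fs)
    fits[[i]] <- filternet_fit(spec, tr, val, control = control,
                               seed = seed + i, verbose = verbose)
  }
  structure(list(fits = fits, fold_plan = plan, spec = spec, seed = seed),
            class = "filternet_ensemble")
}

#' @export
print.filternet_ensemble <- function(x, ...) {
  cat(sprintf("FilterNet %d-fold ensemble of %s sub-models\n",
              x$fold_plan$n_folds, x$spec$variant))
  for (i in seq_along(x$fits))
    cat(sprintf("  sub-model %d: best epoch %d, F1w %.4f\n", i,
                x$fits[[i]]$best_epoch,
                x$fits[[i]]$history$f1w_val[x$fits[[i]]$best_epoch]))
  invisible(x)
}

#' Predict method for FilterNet ensembles
#'
#' Runs windowed inference with every sub-model and averages the logits
#' before a single softmax.
#'
#' @param object A `"filternet_ensemble"`.
#' @param newdata Numeric matrix `(input_channels, L)` or a
#'   [labeled_series()].
#' @param type `"class"` (default), `"prob"` or `"logit"`.
#' @param ... Passed to [filternet_predict()].
#' @return As [predict.filternet_fit()].
#' @export
predict.filternet_ensemble <- function(object, newdata,
                                       type = c("class", "prob", "logit"),
                                       ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_series")) newdata <- newdata$x
  lgs <- lapply(object$fits, function(f)
    filternet_predict(f$net, newdata, ...)$logits)
  res <- ensemble_logits(lgs)
  switch(type, class = res$class - 1L, prob = res$prob, logit = res$logits)
}
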