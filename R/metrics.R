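#' Sample-based F1 summaries
#'
#' Computes per-class precision, recall and F1 from the per-sample confusion
#' counts, then summarizes them three ways: `f1m`, the unweighted mean F1
#' over the non-null classes; `f1w`, the F1 weighted by each class's sample
#' proportion in the ground truth, over all classes including null; and
#' `f1w_nn`, the support-weighted F1 over the non-null classes only.
#'
#' A class with no true or predicted samples has per-class F1 defined as 0
#' and is excluded from `f1m`; if no non-null class is present at all,
#' `f1m` and `f1w_nn` are 0 by convention.
#'
#' @param y_true,y_pred Integer class-id vectors of equal length.
#' @param null_class Class id of the null (background) class.
#' @param classes Optional full class vocabulary; defaults to the union of
#'   ids seen in `y_true` and `y_pred`.
#' @return A list with `f1m`, `f1w`, `f1w_nn` and a `per_class` data frame
#'   (class, support, precision, recall, f1).
#' @examples
#' sample_f1_scores(c(0, 0, 1, 1), c(0, 0, 1, 0), null_class = 0)
#' @export
sample_f1_scores <- function(y_true, y_pred, null_class = 0L,
                             classes = NULL) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  per <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, support = tp + fn, precision = prec,
               recall = rec, f1 = f1, present = (tp + fp + fn) > 0)
  })
  per <- do.call(rbind, per)
  nn <- per$class != null_class
  f1m <- if (any(nn & per$present)) mean(per$f1[nn & per$present]) else 0
  f1w <- if (sum(per$support) > 0)
    sum(per$f1 * per$support) / sum(per$support) else 0
  f1w_nn <- if (sum(per$support[nn]) > 0)
    sum(per$f1[nn] * per$support[nn]) / sum(per$support[nn]) else 0
  list(f1m = f1m, f1w = f1w, f1w_nn = f1w_nn,
       per_class = per[, c("class", "support", "precision", "recall", "f1")])
}

#' Extract discrete events from a probability series
#'
#' For every non-null class, maximal runs of output samples whose class
#' probability strictly exceeds `threshold` become events on the half-open
#' interval `[start, end)` of the output-sample axis.
#'
#' @param prob Numeric matrix `(n_classes, L_out)` of per-sample class
#'   probabilities (or any score), or, for label series, the result of
#'   [events_from_labels()] is usually more direct.
#' @param threshold Detection threshold (default 0.5); comparison is strict,
#'   an exactly-threshold value does not open an event.
#' @param null_class Row index (1-based) of the null class, excluded from
#'   event extraction; use `NA` to extract events for every row.
#' @return A data frame with columns `class` (row index), `start`, `end`
#'   (half-open, 1-based start, so an event spanning samples 1..3 has
#'   `start = 1, end = 4`).
#' @examples
#' p <- rbind(c(0.8, 0.2, 0.1, 0.7), c(0.2, 0.8, 0.9, 0.3))
#' extract_events(p, null_class = 1)
#' @export
extract_events <- function(prob, threshold = 0.5, null_class = 1L) {
  stopifnot(is.matrix(prob))
  out <- list()
  for (cl in seq_len(nrow(prob))) {
    if (!is.na(null_class) && cl == null_class) next
    r <- rle(prob[cl, ] > threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (length(on))
      out[[length(out) + 1L]] <- data.frame(class = cl, start = starts[on],
                                            end = ends[on] + 1L)
  }
  if (length(out) == 0L)
    return(data.frame(class = integer(), start = integer(), end = integer()))
  do.call(rbind, out)
}

#' Events implied by a ground-truth label series
#'
#' @param y Integer label vector.
#' @param null_class Label value of the null class.
#' @return Event data frame as in [extract_events()], with `class` holding
#'   label values.
#' @export
events_from_labels <- function(y, null_class = 0L) {
  r <- rle(as.integer(y))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values != null_class)
  data.frame(class = r$values[on], start = starts[on], end = ends[on] + 1L)
}

.check_events <- function(ev, what) {
  if (nrow(ev) == 0L) return(invisible())
  if (any(ev$end <= ev$start)) stop(what, ": events must have end > start")
  for (cl in unique(ev$class)) {
    e <- ev[ev$class == cl, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop(what, ": overlapping events within class ", cl)
  }
  invisible()
}

#' Categorize events in the Ward taxonomy
#'
#' Matches actual (ground-truth) and detected events per class by interval
#' overlap (half-open intervals; touching events do not overlap) and labels
#' each actual event Correct (C), Deleted (D; no overlapping detection),
#' Fragmented (F; overlaps more than one detection), Merged (M; its single
#' detection also covers other actual events) or Fragmented-and-Merged (FM),
#' and each detected event C', Insertion (I'), Fragmenting (F'), Merging
#' (M') or FM'. True positives are the C events; FN = D + F + FM + M;
#' FP = I' + F' + M' + FM'.
#'
#' @param actual,detected Event data frames (`class`, `start`, `end`) as
#'   returned by [extract_events()] or [events_from_labels()]. Events of one
#'   class must be non-overlapping on each side.
#' @return An object of class `"event_scorecard"`: list with `overall`
#'   (named counts C, D, F, M, FM, Cp, Ip, Fp, Mp, FMp, TP, FP, FN,
#'   precision_e, recall_e, f1_e) and `per_class` (one row of the same
#'   counts per class).
#' @examples
#' act <- data.frame(class = 1, start = 1, end = 11)
#' det <- data.frame(class = 1, start = 1, end = 5)
#' ward_categorize(act, det)$overall[["f1_e"]]
#' @export
ward_categorize <- function(actual, detected) {
  .check_events(actual, "actual")
  .check_events(detected, "detected")
  cls <- sort(unique(c(actual$class, detected$class)))
  rows <- lapply(cls, function(cl) {
    a <- actual[actual$class == cl, , drop = FALSE]
    d <- detected[detected$class == cl, , drop = FALSE]
    na <- nrow(a); nd <- nrow(d)
    # overlap matrix on half-open intervals
    ov <- if (na && nd)
      outer(seq_len(na), seq_len(nd),
            function(i, j) pmin(a$end[i], d$end[j]) >
              pmax(a$start[i], d$start[j]))
    else matrix(FALSE, na, nd)
    a_deg <- rowSums(ov)  # detections touching each actual
    d_deg <- colSums(ov)  # actuals touching each detection
    a_cat <- character(na); d_cat <- character(nd)
    for (i in seq_len(na)) {
      if (a_deg[i] == 0L) a_cat[i] <- "D"
      else if (a_deg[i] > 1L) {
        merged_too <- any(d_deg[ov[i, ]] > 1L)
        a_cat[i] <- if (merged_too) "FM" else "F"
      } else {
        j <- which(ov[i, ])
        a_cat[i] <- if (d_deg[j] > 1L) "M" else "C"
      }
    }
    for (j in seq_len(nd)) {
      if (d_deg[j] == 0L) d_cat[j] <- "Ip"
      else if (d_deg[j] > 1L) {
        frag_too <- any(a_deg[ov[, j]] > 1L)
        d_cat[j] <- if (frag_too) "FMp" else "Mp"
      } else {
        i <- which(ov[, j])
        d_cat[j] <- if (a_deg[i] > 1L) "Fp" else "Cp"
      }
    }
    counts <- c(C = sum(a_cat == "C"), D = sum(a_cat == "D"),
                F = sum(a_cat == "F"), M = sum(a_cat == "M"),
                FM = sum(a_cat == "FM"),
                Cp = sum(d_cat == "Cp"), Ip = sum(d_cat == "Ip"),
                Fp = sum(d_cat == "Fp"), Mp = sum(d_cat == "Mp"),
                FMp = sum(d_cat == "FMp"))
    data.frame(class = cl, t(counts))
  })
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = integer(), C = integer(), D = integer(),
               F = integer(), M = integer(), FM = integer(),
               Cp = integer(), Ip = integer(), Fp = integer(),
               Mp = integer(), FMp = integer())
  tot <- colSums(per[, -1L, drop = FALSE])
  tp <- tot[["C"]]
  fn <- tot[["D"]] + tot[["F"]] + tot[["FM"]] + tot[["M"]]
  fp <- tot[["Ip"]] + tot[["Fp"]] + tot[["Mp"]] + tot[["FMp"]]
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  overall <- c(tot, TP = tp, FP = fp, FN = fn,
               precision_e = prec, recall_e = rec, f1_e = f1e(tp, fp, fn))
  structure(list(overall = overall, per_class = per),
            class = "event_scorecard")
}

#' @export
print.event_scorecard <- function(x, ...) {
  o <- x$overall
  cat(sprintf("events: %d actual, %d detected\n",
              sum(o[c("C", "D", "F", "M", "FM")]),
              sum(o[c("Cp", "Ip", "Fp", "Mp", "FMp")])))
  cat(sprintf("actual:   C=%d D=%d F=%d M=%d FM=%d\n",
              o[["C"]], o[["D"]], o[["F"]], o[["M"]], o[["FM"]]))
  cat(sprintf("detected: C'=%d I'=%d F'=%d M'=%d FM'=%d\n",
              o[["Cp"]], o[["Ip"]], o[["Fp"]], o[["Mp"]], o[["FMp"]]))
  cat(sprintf("TP=%d FP=%d FN=%d  Pe=%.4f Re=%.4f F1e=%.4f\n",
              o[["TP"]], o[["FP"]], o[["FN"]],
              o[["precision_e"]], o[["recall_e"]], o[["f1_e"]]))
  invisible(x)
}

#' Event F1 score
#'
#' `f1e = 2 TP / (2 TP + FP + FN)`, the harmonic mean of event precision and
#' recall. Defined as 0 when `TP = 0`, including the degenerate all-zero
#' case.
#'
#' @param TP,FP,FN Non-negative event counts.
#' @return A value in `[0, 1]`.
#' @examples
#' f1e(117, 448, 87) # about 0.304
#' @export
f1e <- function(TP, FP, FN) {
  if (TP < 0 || FP < 0 || FN < 0) stop("counts must be non-negative")
  den <- 2 * TP + FP + FN
  if (den == 0) return(0)
  2 * TP / den
}
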