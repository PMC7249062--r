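# Independent brute-force oracles used by the property tests. These are
# deliberately naive re-derivations, kept separate from the package
# internals they check.

# Empirical region of influence: feed a strictly positive baseline through
# a stack of random-weight non-negative CNN layers and measure how many
# input samples can change a central output sample via single-sample
# perturbation. Positive weights and inputs guarantee that every path
# through conv/relu/pool propagates a perturbation.
empirical_roi <- function(cfgs, L = 257L, w_in = 2L) {
  pars <- list()
  w <- w_in
  for (i in seq_along(cfgs)) {
    cfg <- cfgs[[i]]
    pars[[i]] <- list(W = array(runif(cfg$w_out * w * cfg$k, 0.5, 1),
                                c(cfg$w_out, w, cfg$k)))
    w <- cfg$w_out
  }
  run <- function(x) {
    h <- array(x, c(dim(x), 1L))
    for (i in seq_along(cfgs)) {
      cfg <- cfgs[[i]]
      h <- filternet:::.conv1d_forward(h, pars[[i]]$W, NULL)
      h <- pmax(h, 0)
      h <- filternet:::.avgpool_forward(h, cfg$s)
    }
    h
  }
  base <- matrix(1, w_in, L)
  y0 <- run(base)
  mid <- ceiling(dim(y0)[2L] / 2)
  hits <- logical(L)
  for (t in seq_len(L)) {
    xp <- base
    xp[1L, t] <- 2
    yp <- run(xp)
    hits[t] <- abs(yp[1L, mid, 1L] - y0[1L, mid, 1L]) > 1e-12
  }
  sum(hits)
}

# Brute-force Ward event matcher: per actual/detected event, count overlap
# partners by direct interval comparison and classify with independent
# logic (no shared code with ward_categorize).
brute_force_ward <- function(actual, detected) {
  overlaps <- function(a1, a2, b1, b2) max(a1, b1) < min(a2, b2)
  cls <- sort(unique(c(actual$class, detected$class)))
  tot <- c(C = 0, D = 0, F = 0, M = 0, FM = 0,
           Cp = 0, Ip = 0, Fp = 0, Mp = 0, FMp = 0)
  for (cl in cls) {
    a <- actual[actual$class == cl, , drop = FALSE]
    d <- detected[detected$class == cl, , drop = FALSE]
    apart <- lapply(seq_len(nrow(a)), function(i)
      which(vapply(seq_len(nrow(d)), function(j)
        overlaps(a$start[i], a$end[i], d$start[j], d$end[j]), TRUE)))
    dpart <- lapply(seq_len(nrow(d)), function(j)
      which(vapply(seq_len(nrow(a)), function(i)
        overlaps(a$start[i], a$end[i], d$start[j], d$end[j]), TRUE)))
    for (i in seq_len(nrow(a))) {
      p <- apart[[i]]
      lab <- if (length(p) == 0L) "D"
      else if (length(p) >= 2L) {
        if (any(vapply(p, function(j) length(dpart[[j]]) > 1L, TRUE)))
          "FM" else "F"
      } else if (length(dpart[[p]]) > 1L) "M" else "C"
      tot[lab] <- tot[lab] + 1
    }
    for (j in seq_len(nrow(d))) {
      p <- dpart[[j]]
      lab <- if (length(p) == 0L) "Ip"
      else if (length(p) >= 2L) {
        if (any(vapply(p, function(i) length(apart[[i]]) > 1L, TRUE)))
          "FMp" else "Mp"
      } else if (length(apart[[p]]) > 1L) "Fp" else "Cp"
      tot[lab] <- tot[lab] + 1
    }
  }
  tot
}

# Random non-overlapping per-class event sets for property tests.
random_event_set <- function(L, n_classes, n_events, seed) {
  set.seed(seed)
  out <- list()
  for (cl in seq_len(n_classes)) {
    taken <- logical(L)
    made <- 0L
    while (made < n_events) {
      len <- sample(2:20, 1L)
      st <- sample.int(L - len, 1L)
      if (any(taken[st:(st + len - 1L)])) next
      taken[st:(st + len - 1L)] <- TRUE
      out[[length(out) + 1L]] <- data.frame(class = cl, start = st,
                                            end = st + len)
      made <- made + 1L
    }
  }
  do.call(rbind, out)
}

# Synthetic training fixture shared by the training/ensembling tests.
make_synth_split <- function(train_n = 24000L, val_n = 8000L,
                             seed_train = 101L, seed_val = 102L) {
  cfg <- synth_config(n_channels = 4, n_classes = 3, event_rate = 3,
                      duration_range = c(30, 90), amplitude_range = c(1, 2),
                      missing_fraction = 0)
  tr <- generate_sensor_series(train_n, cfg, seed = seed_train)
  va <- generate_sensor_series(val_n, cfg, seed = seed_val)
  trp <- preprocess_series(tr)
  vap <- preprocess_series(va, stats = attr(trp, "stats"))
  list(train = trp, val = vap, cfg = cfg)
}

tiny_ms_cnn_spec <- function(input_channels = 4L, n_classes = 3L)
  filternet_spec("ms_cnn", input_channels = input_channels,
                 n_classes = n_classes, base_width = 12, n_p1 = 2,
                 n_p2 = 2, k = 5, p_drop = 0.1)
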