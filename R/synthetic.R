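#' Labeled multichannel series container
#'
#' A thin container for channel-major sensor data with aligned per-sample
#' integer labels: `x` is a `(channels, L)` numeric matrix, `y` an integer
#' vector of length `L` whose values are 0 (null class) to
#' `n_classes - 1`, `fs` the sampling rate in Hz and `mask` an optional
#' logical vector marking missing samples (whole time points).
#'
#' @param x Numeric matrix `(channels, L)`.
#' @param y Integer labels of length `ncol(x)`.
#' @param fs Sampling rate (samples per second).
#' @param mask Optional logical vector of length `ncol(x)`; `TRUE` marks a
#'   missing sample.
#' @return An object of class `"labeled_series"`.
#' @export
labeled_series <- function(x, y, fs = 30, mask = NULL) {
  stopifnot(is.matrix(x), length(y) == ncol(x))
  if (!is.null(mask)) stopifnot(is.logical(mask), length(mask) == ncol(x))
  structure(list(x = x, y = as.integer(y), fs = fs, mask = mask),
            class = "labeled_series")
}

#' @export
print.labeled_series <- function(x, ...) {
  cat(sprintf("labeled series: %d channels x %d samples @ %g Hz\n",
              nrow(x$x), ncol(x$x), x$fs))
  tab <- table(x$y)
  cat("label counts:", paste(sprintf("%s:%d", names(tab), tab),
                             collapse = " "), "\n")
  if (!is.null(x$mask))
    cat(sprintf("missing samples: %d (%.1f%%)\n", sum(x$mask),
                100 * mean(x$mask)))
  invisible(x)
}

#' Synthetic-series generator configuration
#'
#' Describes the statistical regime the generator emulates: a dominant null
#' class over unit-variance background noise, with sporadic labeled events
#' of heterogeneous durations during which a fixed per-class channel subset
#' carries a class-specific sinusoid plus DC offset, and occasional
#' contiguous bursts of missing samples.
#'
#' @param n_channels Sensor channels (default 12).
#' @param n_classes Classes including null (default 6).
#' @param fs Sampling rate in Hz (default 30, a typical wearable rate).
#' @param event_rate Expected events per 1000 samples per non-null class
#'   (default 1.5).
#' @param duration_range Min/max event duration in samples (default
#'   `c(40, 160)`, i.e. about 1.3-5.3 s at 30 Hz).
#' @param amplitude_range Min/max event signature amplitude in background
#'   standard-deviation units (default `c(0.8, 2)`).
#' @param noise_sd Background noise standard deviation (default 1).
#' @param missing_fraction Expected fraction of samples masked missing, in
#'   geometric-length bursts (default 0.03).
#' @param channels_per_class Channels carrying each class signature
#'   (default 3).
#' @param signature_seed Seed for drawing the per-class signatures. The
#'   signatures belong to the configuration, not to a realization: series
#'   generated from the same config with different seeds share class
#'   definitions, so train/validation/test splits describe the same world.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_channels = 12L, n_classes = 6L, fs = 30,
                         event_rate = 1.5, duration_range = c(40L, 160L),
                         amplitude_range = c(0.8, 2), noise_sd = 1,
                         missing_fraction = 0.03, channels_per_class = 3L,
                         signature_seed = 1L) {
  stopifnot(n_channels >= 1L, n_classes >= 2L, event_rate >= 0,
            duration_range[1L] >= 2L,
            duration_range[2L] >= duration_range[1L],
            noise_sd > 0, missing_fraction >= 0, missing_fraction < 1,
            channels_per_class >= 1L, channels_per_class <= n_channels)
  structure(list(n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes), fs = fs,
                 event_rate = event_rate,
                 duration_range = as.integer(duration_range),
                 amplitude_range = amplitude_range, noise_sd = noise_sd,
                 missing_fraction = missing_fraction,
                 channels_per_class = as.integer(channels_per_class),
                 signature_seed = as.integer(signature_seed)),
            class = "synth_config")
}

#' Generate a synthetic labeled sensor series
#'
#' Draws unit-variance Gaussian background on every channel, assigns each
#' non-null class a fixed channel subset, sinusoid frequency and DC offset
#' (drawn from the config's `signature_seed`, so realizations of the same
#' config share class definitions), places events of random duration
#' without overlap and separated
#' by at least one null sample, so label runs and events correspond one to
#' one (labels are
#' single-valued per sample), injects the class signature during each
#' event, and finally draws a missing-sample mask in contiguous bursts.
#' Deterministic given `seed`.
#'
#' @param n_samples Series length in samples.
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @return A [labeled_series()] with a missing-value `mask`. The per-class
#'   signature table is attached as attribute `"signatures"`.
#' @examples
#' ser <- generate_sensor_series(2000, synth_config(), seed = 1)
#' table(ser$y)
#' @export
generate_sensor_series <- function(n_samples, cfg = synth_config(),
                                   seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"), n_samples >= cfg$duration_range[2L])
  L <- as.integer(n_samples)
  k_nn <- cfg$n_classes - 1L
  # class signatures are drawn from the config's own seed so that every
  # realization of the same config shares class definitions
  set.seed(cfg$signature_seed)
  sig <- lapply(seq_len(k_nn), function(k) {
    list(channels = sample.int(cfg$n_channels, cfg$channels_per_class),
         freq = cfg$fs / 30 * (1 + k),         # k+1 cycles/s at fs = 30
         phase = stats::runif(1, 0, 2 * pi),
         amp = stats::runif(1, cfg$amplitude_range[1L],
                            cfg$amplitude_range[2L]),
         offset = stats::runif(1, 0.5, 1.5) * sample(c(-1, 1), 1))
  })
  set.seed(seed)
  x <- matrix(stats::rnorm(cfg$n_channels * L, sd = cfg$noise_sd),
              cfg$n_channels, L)
  y <- integer(L)
  n_events <- stats::rpois(k_nn, cfg$event_rate * L / 1000)
  occupied <- logical(L)
  for (k in seq_len(k_nn)) {
    placed <- 0L
    tries <- 0L
    while (placed < n_events[k]) {
      if ((tries <- tries + 1L) > 200L * max(1L, n_events[k]))
        stop("infeasible event packing: lower event_rate or durations")
      dur <- sample(cfg$duration_range[1L]:cfg$duration_range[2L], 1L)
      start <- sample.int(L - dur + 1L, 1L)
      idx <- start:(start + dur - 1L)
      # guard band: adjacent events would merge into one label run
      guard <- max(1L, start - 1L):min(L, start + dur)
      if (any(occupied[guard])) next
      occupied[idx] <- TRUE
      y[idx] <- k
      s <- sig[[k]]
      tt <- idx / cfg$fs
      wave <- s$amp * sin(2 * pi * s$freq * tt + s$phase) + s$offset
      x[s$channels, idx] <- x[s$channels, idx] +
        matrix(wave, length(s$channels), dur, byrow = TRUE)
      placed <- placed + 1L
    }
  }
  mask <- logical(L)
  if (cfg$missing_fraction > 0) {
    mean_burst <- 10
    p_start <- cfg$missing_fraction / mean_burst
    starts <- which(stats::runif(L) < p_start)
    for (st in starts) {
      len <- 1L + stats::rgeom(1L, 1 / mean_burst)
      mask[st:min(L, st + len - 1L)] <- TRUE
    }
  }
  out <- labeled_series(x, y, fs = cfg$fs, mask = mask)
  attr(out, "signatures") <- sig
  out
}

#' Interpolate missing samples and standardize channels
#'
#' Missing samples (per the series `mask`) are filled by per-channel linear
#' interpolation, holding the edge values constant beyond the first/last
#' observed sample. Each channel is then rescaled to zero mean and unit
#' standard deviation using `stats` when supplied (training-set statistics,
#' the usual case for validation/test data) or statistics computed from the
#' series itself otherwise. A zero-variance channel has its scale floored
#' at a small epsilon, with a warning.
#'
#' @param series A [labeled_series()].
#' @param stats Optional list with numeric vectors `mean` and `sd` (one
#'   entry per channel), as returned by a previous call.
#' @return A [labeled_series()] with no missing samples and an attribute
#'   `"stats"` holding the list(mean, sd) actually used.
#' @examples
#' ser <- generate_sensor_series(2000, synth_config(), seed = 1)
#' tr <- preprocess_series(ser)
#' st <- attr(tr, "stats")
#' @export
preprocess_series <- function(series, stats = NULL) {
  stopifnot(inherits(series, "labeled_series"))
  x <- series$x
  L <- ncol(x)
  if (!is.null(series$mask) && any(series$mask)) {
    obs <- which(!series$mask)
    if (length(obs) == 0L) stop("at least one observed sample is required")
    for (ch in seq_len(nrow(x)))
      x[ch, ] <- stats::approx(obs, x[ch, obs], xout = seq_len(L),
                               rule = 2)$y
  }
  if (is.null(stats)) {
    mu <- rowMeans(x)
    sd <- sqrt(rowMeans((x - mu)^2))
  } else {
    mu <- stats$mean
    sd <- stats$sd
    stopifnot(length(mu) == nrow(x), length(sd) == nrow(x))
  }
  if (any(sd < 1e-8)) {
    warning("zero-variance channel(s): scale floored at 1e-8")
    sd <- pmax(sd, 1e-8)
  }
  out <- labeled_series((x - mu) / sd, series$y, fs = series$fs, mask = NULL)
  attr(out, "stats") <- list(mean = mu, sd = sd)
  out
}

#' Read Opportunity-style session files (optional adapter)
#'
#' Reads whitespace-delimited `.dat` session files of the Opportunity
#' activity-recognition benchmark, selects the 113 challenge sensor columns
#' (or the smaller IMU subsets), takes the mid-level gesture track as the
#' label, and maps the raw label codes to consecutive class ids with 0 as
#' the null class. Interpolation and scaling are left to
#' [preprocess_series()] so that training-set statistics can be reused for
#' validation/test sessions. This adapter requires the externally
#' downloaded dataset and is not exercised by the package tests.
#'
#' @param files Character vector of session file paths, concatenated in
#'   order.
#' @param sensor_subset One of `"All"` (113 channels), `"Accels"` (the 5
#'   IMU accelerometers, 15 channels), `"Gyros"` (15), `"Accels+Gyros"`
#'   (30) or `"Accels+Gyros+Magnetic"` (45).
#' @param label_column 1-based column index of the label track (default
#'   250, the mid-level gesture labels).
#' @param label_codes Optional integer vector fixing the class-id order;
#'   defaults to the sorted nonzero codes found in the data.
#' @return A [labeled_series()] with a missing-value mask.
#' @export
load_opportunity <- function(files,
                             sensor_subset = c("All", "Accels", "Gyros",
                                               "Accels+Gyros",
                                               "Accels+Gyros+Magnetic"),
                             label_column = 250L, label_codes = NULL) {
  sensor_subset <- match.arg(sensor_subset)
  missing_files <- files[!file.exists(files)]
  if (length(missing_files))
    stop("missing session files: ", paste(missing_files, collapse = ", "))
  # the 113 challenge columns: 12 accelerometers (2:37), 5 body IMUs
  # keeping acc/gyro/mag (38:46, 51:59, 64:72, 77:85, 90:98), both shoes
  # (103:134)
  imu <- c(38:46, 51:59, 64:72, 77:85, 90:98)
  cols113 <- c(2:37, imu, 103:134)
  imu_local <- function(offset) as.vector(outer(offset, seq(0, 36, by = 9), "+"))
  sel <- switch(sensor_subset,
    "All" = seq_along(cols113),
    "Accels" = 36L + imu_local(1:3),
    "Gyros" = 36L + imu_local(4:6),
    "Accels+Gyros" = sort(36L + imu_local(1:6)),
    "Accels+Gyros+Magnetic" = 36L + seq_len(45L))
  dat <- do.call(rbind, lapply(files, function(f)
    as.matrix(utils::read.table(f, header = FALSE))))
  x <- t(dat[, cols113[sel], drop = FALSE])
  raw <- as.integer(dat[, label_column])
  if (is.null(label_codes)) label_codes <- sort(unique(raw[raw != 0L]))
  y <- match(raw, label_codes, nomatch = 0L)
  mask <- apply(is.na(x), 2L, any)
  x[is.na(x)] <- 0
  labeled_series(x, y, fs = 30, mask = mask)
}
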