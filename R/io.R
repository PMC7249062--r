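#' Serialize an FLM configuration to a plain-text mapping
#'
#' @param cfg An [flm_config()].
#' @return Named list with keys `type`, `w_out`, `s`, `k`, `p_drop`, `bn`,
#'   `bias` suitable for YAML serialization.
#' @seealso [flm_config_from_list()]
#' @export
flm_config_to_list <- function(cfg) {
  stopifnot(inherits(cfg, "flm_config"))
  list(type = cfg$type, w_out = cfg$w_out, s = cfg$s,
       k = if (is.na(cfg$k)) NULL else cfg$k,
       p_drop = cfg$p_drop, bn = cfg$bn, bias = cfg$bias)
}

#' Rebuild an FLM configuration from a plain-text mapping
#'
#' @param x Named list as produced by [flm_config_to_list()].
#' @return An [flm_config()].
#' @export
flm_config_from_list <- function(x) {
  flm_config(type = x$type, w_out = x$w_out,
             s = if (is.null(x$s)) 1L else x$s,
             k = if (is.null(x$k)) 5L else x$k,
             p_drop = if (is.null(x$p_drop)) 0.1 else x$p_drop,
             bn = if (is.null(x$bn)) TRUE else x$bn,
             bias = if (is.null(x$bias)) !isTRUE(x$bn %||% TRUE) else x$bias)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an architecture configuration file
#'
#' Round-trips the construction arguments of a [filternet_spec()] through a
#' YAML mapping (variant, width_scale, input_channels, n_classes, stride,
#' layer counts, kernel, dropout).
#'
#' @param spec A [filternet_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filternet_config <- function(spec, path) {
  stopifnot(inherits(spec, "filternet_spec"))
  cfg <- list(variant = spec$variant, input_channels = spec$input_channels,
              n_classes = spec$n_classes, width_scale = spec$width_scale,
              base_width = spec$base_width, stride = spec$s,
              n_p1 = spec$n_p1, n_p2 = spec$n_p2, n_l = spec$n_l,
              k = spec$k, p_drop = spec$p_drop)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read an architecture configuration file
#'
#' @param path Path written by [write_filternet_config()].
#' @return A [filternet_spec()].
#' @export
read_filternet_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  filternet_spec(variant = cfg$variant,
                 input_channels = cfg$input_channels,
                 n_classes = cfg$n_classes,
                 width_scale = cfg$width_scale %||% 1,
                 base_width = cfg$base_width %||% 100L,
                 s = cfg$stride %||% 2L,
                 n_p1 = max(1L, cfg$n_p1), n_p2 = max(1L, cfg$n_p2),
                 n_l = max(1L, cfg$n_l), k = cfg$k %||% 5L,
                 p_drop = cfg$p_drop %||% 0.1)
}

.flatten_params <- function(par) {
  out <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], c(path, nm))
    } else {
      key <- paste(path, collapse = "/")
      out[[key]] <<- list(dim = dim(x) %||% length(x), values = as.numeric(x))
    }
  }
  walk(par, character())
  out
}

.unflatten_params <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    path <- strsplit(key, "/", fixed = TRUE)[[1L]]
    e <- flat[[key]]
    v <- e$values
    if (length(e$dim) > 1L) v <- array(v, unlist(e$dim))
    out <- .poke_create(out, path, v)
  }
  out
}

.poke_create <- function(lst, path, value) {
  if (length(path) == 1L) {
    lst[[path]] <- value
  } else {
    if (is.null(lst[[path[1L]]])) lst[[path[1L]]] <- list()
    lst[[path[1L]]] <- .poke_create(lst[[path[1L]]], path[-1L], value)
  }
  lst
}

#' Save a network or fit to a single checkpoint file
#'
#' Writes a JSON checkpoint embedding the architecture configuration and
#' all weights (including batch-norm running statistics) at full double
#' precision.
#'
#' @param object A `"filternet_net"`, `"filternet_fit"` or
#'   `"filternet_ensemble"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_filternet <- function(object, path) {
  enc_net <- function(net)
    list(config = list(variant = net$spec$variant,
                       input_channels = net$spec$input_channels,
                       n_classes = net$spec$n_classes,
                       width_scale = net$spec$width_scale,
                       base_width = net$spec$base_width,
                       stride = net$spec$s, n_p1 = net$spec$n_p1,
                       n_p2 = net$spec$n_p2, n_l = net$spec$n_l,
                       k = net$spec$k, p_drop = net$spec$p_drop),
         params = .flatten_params(net$params))
  payload <- if (inherits(object, "filternet_ensemble")) {
    list(kind = "ensemble",
         folds = object$fold_plan$folds,
         nets = lapply(object$fits, function(f) enc_net(f$net)))
  } else {
    net <- if (inherits(object, "filternet_fit")) object$net else object
    stopifnot(inherits(net, "filternet_net"))
    c(list(kind = "single"), enc_net(net))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint written by [save_filternet()]
#'
#' @param path Checkpoint file path.
#' @return A `"filternet_net"`, or for ensemble checkpoints a list of them
#'   with attribute `"folds"`.
#' @export
load_filternet <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  dec_net <- function(p) {
    cfg <- p$config
    spec <- filternet_spec(variant = cfg$variant,
                           input_channels = cfg$input_channels,
                           n_classes = cfg$n_classes,
                           width_scale = cfg$width_scale,
                           base_width = cfg$base_width, s = cfg$stride,
                           n_p1 = max(1L, cfg$n_p1),
                           n_p2 = max(1L, cfg$n_p2),
                           n_l = max(1L, cfg$n_l),
                           k = cfg$k, p_drop = cfg$p_drop)
    structure(list(spec = spec, params = .unflatten_params(p$params)),
              class = "filternet_net")
  }
  if (identical(payload$kind, "ensemble")) {
    nets <- lapply(payload$nets, dec_net)
    attr(nets, "folds") <- payload$folds
    nets
  } else dec_net(payload)
}

#' Write a labeled series to a columnar text file
#'
#' One row per sample: the channel values followed by the integer label.
#' Missing samples (per the mask) are written as `NA`.
#'
#' @param series A [labeled_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_series <- function(series, path) {
  stopifnot(inherits(series, "labeled_series"))
  x <- series$x
  if (!is.null(series$mask) && any(series$mask)) x[, series$mask] <- NA
  df <- cbind(as.data.frame(t(x)), label = series$y)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a labeled series written by [write_labeled_series()]
#'
#' @param path Input file path.
#' @param fs Sampling rate to record on the series.
#' @return A [labeled_series()]; samples containing `NA` are masked.
#' @export
read_labeled_series <- function(path, fs = 30) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  y <- df$label
  x <- t(as.matrix(df[, setdiff(names(df), "label"), drop = FALSE]))
  mask <- apply(is.na(x), 2L, any)
  x[is.na(x)] <- 0
  labeled_series(unname(x), y, fs = fs, mask = mask)
}
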