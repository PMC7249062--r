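# Low-level numerical kernels. All series tensors are arrays of dim
# (channels, length, batch); gradients mirror the shapes of their primals.

.sigm <- function(x) 1 / (1 + exp(-x))

# ---- 1-D convolution (cross-correlation), zero-padded so L_out == L_in ----
# W: (w_out, w_in, k), k odd. b: length w_out or NULL.

.conv1d_forward <- function(x, W, b = NULL) {
  d <- dim(x); w_in <- d[1L]; L <- d[2L]; B <- d[3L]
  w_out <- dim(W)[1L]; k <- dim(W)[3L]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(w_in, L + 2L * pad, B))
  xp[, pad + seq_len(L), ] <- x
  acc <- matrix(0, w_out, L * B)
  for (j in seq_len(k)) {
    xs <- matrix(xp[, j:(j + L - 1L), , drop = FALSE], nrow = w_in)
    acc <- acc + matrix(W[, , j], w_out, w_in) %*% xs
  }
  if (!is.null(b)) acc <- acc + b
  array(acc, c(w_out, L, B))
}

.conv1d_backward <- function(x, W, gy, has_bias = TRUE) {
  d <- dim(x); w_in <- d[1L]; L <- d[2L]; B <- d[3L]
  w_out <- dim(W)[1L]; k <- dim(W)[3L]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(w_in, L + 2L * pad, B))
  xp[, pad + seq_len(L), ] <- x
  g <- matrix(gy, nrow = w_out)
  gW <- array(0, dim(W))
  gxp <- array(0, dim(xp))
  for (j in seq_len(k)) {
    xs <- matrix(xp[, j:(j + L - 1L), , drop = FALSE], nrow = w_in)
    gW[, , j] <- g %*% t(xs)
    gs <- crossprod(matrix(W[, , j], w_out, w_in), g)
    gxp[, j:(j + L - 1L), ] <- gxp[, j:(j + L - 1L), ] +
      array(gs, c(w_in, L, B))
  }
  gx <- array(gxp[, pad + seq_len(L), , drop = FALSE], c(w_in, L, B))
  list(gx = gx, gW = gW, gb = if (has_bias) rowSums(g) else NULL)
}

# ---- average pooling, kernel = stride = s, right zero-pad to multiple of s --

.avgpool_forward <- function(x, s) {
  if (s == 1L) return(x)
  d <- dim(x); w <- d[1L]; L <- d[2L]; B <- d[3L]
  Lo <- as.integer(ceiling(L / s)); Lp <- Lo * s
  if (Lp > L) {
    xp <- array(0, c(w, Lp, B)); xp[, seq_len(L), ] <- x
  } else xp <- x
  acc <- array(0, c(w, Lo, B))
  for (j in seq_len(s))
    acc <- acc + xp[, seq.int(j, Lp, by = s), , drop = FALSE]
  acc / s
}

.avgpool_backward <- function(gy, s, L_in) {
  if (s == 1L) return(gy)
  d <- dim(gy); w <- d[1L]; Lo <- d[2L]; B <- d[3L]
  Lp <- Lo * s
  gxp <- array(0, c(w, Lp, B))
  for (j in seq_len(s)) gxp[, seq.int(j, Lp, by = s), ] <- gy / s
  array(gxp[, seq_len(L_in), , drop = FALSE], c(w, L_in, B))
}

# ---- batch normalization over (time x batch), per channel ----

.bn_forward <- function(x, gamma, beta, run_mean, run_var, mode,
                        momentum = 0.1, eps = 1e-5) {
  d <- dim(x); w <- d[1L]
  xm <- matrix(x, nrow = w)
  if (mode == "train") {
    n <- ncol(xm)
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    vu <- if (n > 1L) v * n / (n - 1L) else v  # unbiased var for running stats
    list(y = array(gamma * xhat + beta, d),
         cache = list(xhat = xhat, inv = inv),
         run_mean = (1 - momentum) * run_mean + momentum * mu,
         run_var  = (1 - momentum) * run_var + momentum * vu)
  } else {
    inv <- 1 / sqrt(run_var + eps)
    y <- gamma * ((xm - run_mean) * inv) + beta
    list(y = array(y, d), cache = NULL, run_mean = run_mean, run_var = run_var)
  }
}

.bn_backward <- function(gy, gamma, cache) {
  d <- dim(gy); w <- d[1L]
  g <- matrix(gy, nrow = w)
  xhat <- cache$xhat; inv <- cache$inv
  n <- ncol(g)
  ggamma <- rowSums(g * xhat)
  gbeta <- rowSums(g)
  gxhat <- g * gamma
  gx <- (inv / n) * (n * gxhat - rowSums(gxhat) - xhat * rowSums(gxhat * xhat))
  list(gx = array(gx, d), ggamma = ggamma, gbeta = gbeta)
}

# ---- channel dropout: drops whole input channels, train mode only ----
# mask is (channels x batch); inverted scaling keeps expectations unchanged.

.dropout_mask <- function(w, B, p) {
  matrix((stats::runif(w * B) >= p) / (1 - p), w, B)
}

.dropout_apply <- function(x, mask) {
  d <- dim(x)
  y <- x
  for (b in seq_len(d[3L]))
    y[, , b] <- matrix(x[, , b], d[1L], d[2L]) * mask[, b]
  y
}

# ---- bidirectional LSTM ----
# Per direction: gates z = Wx x_t + Wh h_{t-1} + b, order (i, f, g, o);
# c_t = f*c_{t-1} + i*g; h_t = o * tanh(c_t). Hidden size h = w_out/2.

.lstm_dir_forward <- function(x, Wx, Wh, b, reverse = FALSE) {
  d <- dim(x); w_in <- d[1L]; L <- d[2L]; B <- d[3L]
  h4 <- nrow(Wx); h <- h4 %/% 4L
  Zx <- array(Wx %*% matrix(x, nrow = w_in) + b, c(h4, L, B))
  idx <- if (reverse) rev(seq_len(L)) else seq_len(L)
  hs <- array(0, c(h, L, B))
  gi <- array(0, c(h, L, B)); gf <- gi; gg <- gi; go <- gi
  cs <- gi; tc <- gi
  hprev <- matrix(0, h, B); cprev <- matrix(0, h, B)
  i1 <- seq_len(h); i2 <- h + i1; i3 <- 2L * h + i1; i4 <- 3L * h + i1
  for (t in idx) {
    z <- matrix(Zx[, t, ], h4, B) + Wh %*% hprev
    iv <- .sigm(z[i1, , drop = FALSE])
    fv <- .sigm(z[i2, , drop = FALSE])
    gv <- tanh(z[i3, , drop = FALSE])
    ov <- .sigm(z[i4, , drop = FALSE])
    cc <- fv * cprev + iv * gv
    tcv <- tanh(cc)
    hh <- ov * tcv
    gi[, t, ] <- iv; gf[, t, ] <- fv; gg[, t, ] <- gv; go[, t, ] <- ov
    cs[, t, ] <- cc; tc[, t, ] <- tcv
    hs[, t, ] <- hh
    hprev <- hh; cprev <- cc
  }
  list(h = hs,
       cache = list(i = gi, f = gf, g = gg, o = go, c = cs, tc = tc,
                    idx = idx, x = x))
}

.lstm_dir_backward <- function(gy, Wx, Wh, cache) {
  x <- cache$x
  d <- dim(x); w_in <- d[1L]; L <- d[2L]; B <- d[3L]
  h <- dim(cache$i)[1L]
  idx <- cache$idx
  gWx <- matrix(0, 4L * h, w_in); gWh <- matrix(0, 4L * h, h)
  gb <- numeric(4L * h)
  gx <- array(0, dim(x))
  ghn <- matrix(0, h, B); gcn <- matrix(0, h, B)
  zeros <- matrix(0, h, B)
  for (s in rev(seq_along(idx))) {
    t <- idx[s]
    iv <- matrix(cache$i[, t, ], h, B); fv <- matrix(cache$f[, t, ], h, B)
    gv <- matrix(cache$g[, t, ], h, B); ov <- matrix(cache$o[, t, ], h, B)
    tcv <- matrix(cache$tc[, t, ], h, B)
    cprev <- if (s > 1L) matrix(cache$c[, idx[s - 1L], ], h, B) else zeros
    hprev <- if (s > 1L) matrix(cache$h_store[, idx[s - 1L], ], h, B) else NULL
    gh <- matrix(gy[, t, ], h, B) + ghn
    gc <- gh * ov * (1 - tcv * tcv) + gcn
    gzi <- (gc * gv) * iv * (1 - iv)
    gzf <- (gc * cprev) * fv * (1 - fv)
    gzg <- (gc * iv) * (1 - gv * gv)
    gzo <- (gh * tcv) * ov * (1 - ov)
    gz <- rbind(gzi, gzf, gzg, gzo)
    xt <- matrix(x[, t, ], w_in, B)
    gWx <- gWx + gz %*% t(xt)
    if (s > 1L) gWh <- gWh + gz %*% t(hprev)
    gb <- gb + rowSums(gz)
    gx[, t, ] <- gx[, t, ] + crossprod(Wx, gz)
    ghn <- crossprod(Wh, gz)
    gcn <- gc * fv
  }
  list(gx = gx, gWx = gWx, gWh = gWh, gb = gb)
}

# Backprop through the hidden recurrence needs h_{t-1}; stash the output
# series into the cache after the forward pass.
.lstm_bidir_forward <- function(x, par) {
  fw <- .lstm_dir_forward(x, par$fwd$Wx, par$fwd$Wh, par$fwd$b, reverse = FALSE)
  bw <- .lstm_dir_forward(x, par$bwd$Wx, par$bwd$Wh, par$bwd$b, reverse = TRUE)
  fw$cache$h_store <- fw$h
  bw$cache$h_store <- bw$h
  d <- dim(x); h <- dim(fw$h)[1L]
  y <- array(0, c(2L * h, d[2L], d[3L]))
  y[seq_len(h), , ] <- fw$h
  y[h + seq_len(h), , ] <- bw$h
  list(y = y, cache = list(fw = fw$cache, bw = bw$cache, h = h))
}

.lstm_bidir_backward <- function(gy, par, cache) {
  h <- cache$h
  gfw <- .lstm_dir_backward(gy[seq_len(h), , , drop = FALSE],
                            par$fwd$Wx, par$fwd$Wh, cache$fw)
  gbw <- .lstm_dir_backward(gy[h + seq_len(h), , , drop = FALSE],
                            par$bwd$Wx, par$bwd$Wh, cache$bw)
  list(gx = gfw$gx + gbw$gx,
       fwd = list(gWx = gfw$gWx, gWh = gfw$gWh, gb = gfw$gb),
       bwd = list(gWx = gbw$gWx, gWh = gbw$gWh, gb = gbw$gb))
}

# ---- temporal linear resampling, align-ends convention ----

.resample_pos <- function(L_in, L_out) {
  if (L_out == 1L) return(list(lo = 1L, hi = 1L, fr = 0))
  pos <- seq(1, L_in, length.out = L_out)
  lo <- pmin(floor(pos), L_in - 1L)
  if (L_in == 1L) lo <- rep(1L, L_out)
  hi <- pmin(lo + 1L, L_in)
  list(lo = as.integer(lo), hi = as.integer(hi), fr = pos - lo)
}

.resample_forward <- function(x, L_out) {
  d <- dim(x); L_in <- d[2L]
  p <- .resample_pos(L_in, L_out)
  xl <- x[, p$lo, , drop = FALSE]
  xh <- x[, p$hi, , drop = FALSE]
  y <- sweep(xl, 2L, 1 - p$fr, "*") + sweep(xh, 2L, p$fr, "*")
  array(y, c(d[1L], L_out, d[3L]))
}

.resample_backward <- function(gy, L_in) {
  d <- dim(gy); L_out <- d[2L]
  p <- .resample_pos(L_in, L_out)
  gx <- array(0, c(d[1L], L_in, d[3L]))
  for (t in seq_len(L_out)) {
    gx[, p$lo[t], ] <- gx[, p$lo[t], ] + gy[, t, ] * (1 - p$fr[t])
    gx[, p$hi[t], ] <- gx[, p$hi[t], ] + gy[, t, ] * p$fr[t]
  }
  gx
}

# ---- softmax / cross-entropy over the class dimension ----

.softmax <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, nrow = d[1L])
  m <- exp(sweep(m, 2L, apply(m, 2L, max)))
  array(sweep(m, 2L, colSums(m), "/"), d)
}

# labels: integer matrix/vector of 1-based class ids aligned with the
# flattened (time x batch) columns of the logits.
.xent_loss_grad <- function(logits, labels) {
  d <- dim(logits); nc <- d[1L]
  p <- matrix(.softmax(logits), nrow = nc)
  lab <- as.integer(labels)
  n <- length(lab)
  idx <- cbind(lab, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = array(g / n, d))
}
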