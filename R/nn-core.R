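# Compact CPU neural-network engine behind the architecture/scrambling modules.
# Layers are environments (mutable by reference) holding weights, batch-norm
# state, gradients and SGD momentum buffers. Activation tensors are plain R
# arrays [H, W, C, N]; convolutions run through the Rcpp/Armadillo kernels.

BN_EPS <- 1e-5

# Per-channel broadcast helper: v has length C, x has dim (H, W, C, N);
# rep(v, each = H*W) recycles cleanly across the N slabs.
bcast_c <- function(v, hw) rep(v, each = hw)

chan_mean <- function(x) {
  d <- dim(x)
  rowMeans(matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3]))
}

chan_sum <- function(x) {
  d <- dim(x)
  rowSums(matrix(colSums(matrix(x, nrow = d[1] * d[2])), d[3]))
}

new_conv_bn <- function(k, cin, cout, stride = 1L) {
  e <- new.env(parent = emptyenv())
  k <- as.integer(k)
  lim <- sqrt(6 / (k * k * cin))            # He-uniform fan-in
  e$W <- array(stats::runif(k * k * cin * cout, -lim, lim),
               dim = c(k, k, cin, cout))
  e$gamma <- rep(1, cout)
  e$beta <- rep(0, cout)
  e$rmean <- rep(0, cout)
  e$rvar <- rep(1, cout)
  e$vW <- array(0, dim(e$W))
  e$vgamma <- numeric(cout)
  e$vbeta <- numeric(cout)
  e$k <- k
  e$stride <- as.integer(stride)
  e$pad <- as.integer((k - 1L) %/% 2L)
  e$cin <- as.integer(cin)
  e$cout <- as.integer(cout)
  e
}

cbn_forward <- function(L, x, train = FALSE, bn_momentum = 0.9,
                        update = train) {
  y <- conv2d_forward_cpp(x, L$W, L$stride, L$pad)
  d <- dim(y)
  hw <- d[1] * d[2]
  if (train) {
    mu <- chan_mean(y)
    yc <- y - bcast_c(mu, hw)
    v <- chan_mean(yc * yc)
    if (update) {
      L$rmean <- bn_momentum * L$rmean + (1 - bn_momentum) * mu
      L$rvar <- bn_momentum * L$rvar + (1 - bn_momentum) * v
    }
  } else {
    yc <- y - bcast_c(L$rmean, hw)
    v <- L$rvar
  }
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- yc * bcast_c(istd, hw)
  out <- xhat * bcast_c(L$gamma, hw) + bcast_c(L$beta, hw)
  list(out = out, cache = list(x = x, xhat = xhat, istd = istd))
}

cbn_backward <- function(L, cache, dout, train = TRUE) {
  d <- dim(dout)
  hw <- d[1] * d[2]
  m <- hw * d[4]
  L$ggamma <- chan_sum(dout * cache$xhat)
  L$gbeta <- chan_sum(dout)
  g_istd <- L$gamma * cache$istd
  if (train) {
    dy <- (dout - bcast_c(L$gbeta / m, hw) -
             cache$xhat * bcast_c(L$ggamma / m, hw)) * bcast_c(g_istd, hw)
  } else {
    # frozen statistics: normalization is an affine map per channel
    dy <- dout * bcast_c(g_istd, hw)
  }
  bwd <- conv2d_backward_cpp(cache$x, L$W, dy, L$stride, L$pad)
  L$gW <- bwd$dw
  bwd$dx
}

relu_fwd <- function(x) x * (x > 0)

# ---- bottleneck residual unit: 1x1 (stride) -> kxk -> 1x1, + shortcut ----

new_unit <- function(cin, width, cout, k, stride) {
  list(
    c1 = new_conv_bn(1L, cin, width, stride),
    c2 = new_conv_bn(k, width, width, 1L),
    c3 = new_conv_bn(1L, width, cout, 1L),
    sc = if (stride != 1L || cin != cout) new_conv_bn(1L, cin, cout, stride) else NULL,
    k = as.integer(k), stride = as.integer(stride),
    cin = as.integer(cin), cout = as.integer(cout)
  )
}

unit_forward <- function(u, x, train = FALSE, bnm = 0.9, update = train) {
  f1 <- cbn_forward(u$c1, x, train, bnm, update)
  r1 <- relu_fwd(f1$out)
  f2 <- cbn_forward(u$c2, r1, train, bnm, update)
  r2 <- relu_fwd(f2$out)
  f3 <- cbn_forward(u$c3, r2, train, bnm, update)
  if (is.null(u$sc)) {
    s <- x
    sc_cache <- NULL
  } else {
    fs <- cbn_forward(u$sc, x, train, bnm, update)
    s <- fs$out
    sc_cache <- fs$cache
  }
  out <- relu_fwd(f3$out + s)
  list(out = out,
       cache = list(c1 = f1$cache, r1 = r1, c2 = f2$cache, r2 = r2,
                    c3 = f3$cache, sc = sc_cache, out = out))
}

unit_backward <- function(u, cache, dout, train = TRUE) {
  dpre <- dout * (cache$out > 0)
  d2 <- cbn_backward(u$c3, cache$c3, dpre, train)
  d2 <- d2 * (cache$r2 > 0)
  d1 <- cbn_backward(u$c2, cache$c2, d2, train)
  d1 <- d1 * (cache$r1 > 0)
  dx <- cbn_backward(u$c1, cache$c1, d1, train)
  if (is.null(u$sc)) dx + dpre else dx + cbn_backward(u$sc, cache$sc, dpre, train)
}

# ---- classifier head: GAP -> fully connected -> softmax ----

new_head <- function(cin, n_classes) {
  e <- new.env(parent = emptyenv())
  lim <- sqrt(6 / cin)
  e$W <- matrix(stats::runif(cin * n_classes, -lim, lim), cin, n_classes)
  e$b <- numeric(n_classes)
  e$vW <- matrix(0, cin, n_classes)
  e$vb <- numeric(n_classes)
  e
}

gap_fwd <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4])  # C x N
}

head_forward <- function(h, feat) {
  g <- gap_fwd(feat)
  list(logits = crossprod(h$W, g) + h$b, g = g)
}

head_backward <- function(h, g, dlogits, feat_dim) {
  h$gW <- g %*% t(dlogits)
  h$gb <- rowSums(dlogits)
  dg <- h$W %*% dlogits
  hw <- feat_dim[1] * feat_dim[2]
  array(rep(as.numeric(dg) / hw, each = hw), dim = feat_dim)
}

softmax_cols <- function(z) {
  k <- nrow(z)
  z <- z - rep(apply(z, 2, max), each = k)
  e <- exp(z)
  e / rep(colSums(e), each = k)
}

# mean cross-entropy over the batch and its logit gradient
xent_loss <- function(logits, y) {
  n <- ncol(logits)
  p <- softmax_cols(logits)
  idx <- cbind(y, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

# ---- SGD with momentum over layer environments ----

sgd_step_cbn <- function(L, lr, mom) {
  L$vW <- mom * L$vW - lr * L$gW
  L$W <- L$W + L$vW
  L$vgamma <- mom * L$vgamma - lr * L$ggamma
  L$gamma <- L$gamma + L$vgamma
  L$vbeta <- mom * L$vbeta - lr * L$gbeta
  L$beta <- L$beta + L$vbeta
  invisible(L)
}

sgd_step_head <- function(h, lr, mom) {
  h$vW <- mom * h$vW - lr * h$gW
  h$W <- h$W + h$vW
  h$vb <- mom * h$vb - lr * h$gb
  h$b <- h$b + h$vb
  invisible(h)
}

unit_cbns <- function(u) {
  out <- list(u$c1, u$c2, u$c3)
  if (!is.null(u$sc)) out <- c(out, list(u$sc))
  out
}

# conv-bn environments of a trainable stack (stem optional)
stack_cbns <- function(stem, units) {
  out <- if (is.null(stem)) list() else list(stem)
  for (u in units) out <- c(out, unit_cbns(u))
  out
}

snapshot_cbn <- function(L) {
  list(W = L$W, gamma = L$gamma, beta = L$beta, rmean = L$rmean, rvar = L$rvar)
}

restore_cbn <- function(L, s) {
  L$W <- s$W; L$gamma <- s$gamma; L$beta <- s$beta
  L$rmean <- s$rmean; L$rvar <- s$rvar
  invisible(L)
}
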