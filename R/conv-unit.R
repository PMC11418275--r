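# Convolution unit (conv [+ batch norm] [+ activation]) and the dense /
# layer-norm primitives used inside transformer stages.  Every unit knows its
# trainable-parameter count and its FLOP cost in closed form; FLOPs follow
# the profiler convention used for detector budgets: one multiply-accumulate
# counts as two operations, and only convolutions / matrix products (plus
# bias adds) are counted.

autopad <- function(k, dil = 1L) ((k - 1L) * dil) %/% 2L

cu_spec <- function(cin, cout, k = 1L, s = 1L, p = NULL, dil = 1L, g = 1L,
                    bias = FALSE, bn = TRUE, act = "silu") {
  if (is.null(p)) p <- autopad(k, dil)
  stopifnot(cin %% g == 0L, cout %% g == 0L)
  list(type = "convunit", cin = as.integer(cin), cout = as.integer(cout),
       k = as.integer(k), s = as.integer(s), p = as.integer(p),
       dil = as.integer(dil), g = as.integer(g), bias = bias, bn = bn,
       act = act)
}

cu_nparams <- function(u) {
  n <- u$k^2 * (u$cin %/% u$g) * u$cout
  if (u$bias) n <- n + u$cout
  if (u$bn) n <- n + 2L * u$cout
  as.numeric(n)
}

cu_out_hw <- function(u, H, W) {
  c(conv_out_dim(H, u$k, u$s, u$p, u$dil), conv_out_dim(W, u$k, u$s, u$p, u$dil))
}

cu_flops <- function(u, H, W) {
  hw <- cu_out_hw(u, H, W)
  n <- prod(hw)
  f <- 2 * u$k^2 * (u$cin / u$g) * u$cout * n
  if (u$bias) f <- f + u$cout * n
  f
}

cu_init <- function(u) {
  fan_in <- u$k^2 * (u$cin %/% u$g)
  w <- array(stats::rnorm(u$k^2 * (u$cin %/% u$g) * u$cout,
                          sd = sqrt(2 / fan_in)),
             dim = c(u$k, u$k, u$cin %/% u$g, u$cout))
  p <- list(w = w)
  if (u$bias) p$b <- numeric(u$cout)
  if (u$bn) {
    p$gamma <- rep(1, u$cout); p$beta <- numeric(u$cout)
    p$rmean <- numeric(u$cout); p$rvar <- rep(1, u$cout)
  }
  p
}

cu_forward <- function(u, p, x, training = FALSE, keep_cache = FALSE) {
  y <- conv2d_forward(x, p$w, if (u$bias) p$b else NULL, u$s, u$p, u$dil, u$g,
                      keep_cache = keep_cache)
  cache <- attr(y, "cache"); attr(y, "cache") <- NULL
  bnc <- NULL
  if (u$bn) {
    r <- bn_forward(y, p$gamma, p$beta, p$rmean, p$rvar, training)
    bnc <- r[c("xhat", "inv")]
    if (training) bnc$new_stats <- r[c("rmean", "rvar")]
    y <- r$y
  }
  pre <- NULL
  if (u$act == "silu") { pre <- y; y <- silu(y) }
  else if (u$act == "sigmoid") { pre <- y; y <- sigmoid(y) }
  if (keep_cache)
    attr(y, "cache") <- list(conv = cache, bn = bnc, pre = pre, x = x)
  y
}

cu_backward <- function(u, p, cache, dy) {
  if (u$act == "silu") dy <- dy * silu_grad(cache$pre)
  else if (u$act == "sigmoid") {
    s <- sigmoid(cache$pre); dy <- dy * s * (1 - s)
  }
  g <- list()
  if (u$bn) {
    r <- bn_backward(dy, cache$bn, p$gamma)
    dy <- r$dx; g$gamma <- r$dgamma; g$beta <- r$dbeta
  }
  cb <- conv2d_backward(dy, cache$x, p$w, cache$conv)
  g$w <- cb$dw
  if (u$bias) g$b <- cb$db
  list(dx = cb$dx, grads = g)
}

# dense layer on token matrices (N x din) -> (N x dout)
lin_spec <- function(din, dout) list(type = "linear", din = as.integer(din),
                                     dout = as.integer(dout))
lin_nparams <- function(l) as.numeric(l$din * l$dout + l$dout)
lin_flops <- function(l, ntok) 2 * l$din * l$dout * ntok + l$dout * ntok
lin_init <- function(l)
  list(w = matrix(stats::rnorm(l$din * l$dout, sd = sqrt(1 / l$din)),
                  l$din, l$dout),
       b = numeric(l$dout))
lin_forward <- function(p, x) sweep(x %*% p$w, 2L, p$b, "+")

# layer norm over feature dimension of an (N x d) matrix
ln_spec <- function(d) list(type = "layernorm", d = as.integer(d))
ln_nparams <- function(l) as.numeric(2L * l$d)
ln_init <- function(l) list(gamma = rep(1, l$d), beta = numeric(l$d))
ln_forward <- function(p, x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  xh <- xc / sqrt(v + eps)
  sweep(sweep(xh, 2L, p$gamma, "*"), 2L, p$beta, "+")
}
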