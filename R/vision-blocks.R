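# Public building-block API: MobileViT patch unfold/fold and block, LSK
# spatial attention, GSConv and channel shuffle.  These are the same
# operators the full detector assembles; exposed standalone so their
# algebraic contracts (inverse pairs, bijections, shape preservation) can be
# exercised directly.

#' MobileViT block configuration
#'
#' @param d Expanded token dimension (must exceed the input channel count of
#'   the block it is applied to).
#' @param n Local convolution kernel size in pixels.
#' @param h,w Patch height and width in pixels; both must be `<= n`.
#' @param depth Number of transformer layers applied across patches.
#' @param heads Attention heads (`d` must be divisible by `heads`).
#' @param mlp_dim Hidden width of the transformer feed-forward network.
#' @return A list of class `mobilevit_config`.
#' @export
mobilevit_config <- function(d, n = 3L, h = 2L, w = 2L, depth = 2L,
                             heads = 4L, mlp_dim = 2L * d) {
  if (h > n || w > n)
    stop("patch dims h and w must be less than or equal to the kernel size n")
  if (d %% heads != 0L) stop("d must be divisible by heads")
  structure(list(d = as.integer(d), n = as.integer(n), h = as.integer(h),
                 w = as.integer(w), depth = as.integer(depth),
                 heads = as.integer(heads), mlp_dim = as.integer(mlp_dim)),
            class = "mobilevit_config")
}

#' Unfold a feature map into flattened patches
#'
#' Splits an `H x W x d` map into non-overlapping `h x w` patches and
#' rearranges it as a `P x N x d` array with `P = w*h` pixel positions per
#' patch and `N = H*W/P` patches.  Ordering is deterministic: within a patch,
#' position index runs down rows first then across columns; patches are
#' numbered down the patch grid rows first then across columns.
#'
#' @param x `H x W x d` numeric array.
#' @param cfg A [mobilevit_config()] (its `h`, `w` fields are used).
#' @return `P x N x d` array.
#' @export
mobilevit_unfold <- function(x, cfg) {
  d3 <- fm_dims(x)
  H <- d3[1]; W <- d3[2]; dd <- d3[3]
  h <- cfg$h; w <- cfg$w
  if (H %% h != 0L || W %% w != 0L)
    stop(sprintf("spatial dims (%d x %d) not divisible by patch (%d x %d)",
                 H, W, h, w))
  a <- array(x, c(h, H %/% h, w, W %/% w, dd))
  a <- aperm(a, c(1L, 3L, 2L, 4L, 5L))
  array(a, c(h * w, (H * W) %/% (h * w), dd))
}

#' Fold flattened patches back into a feature map
#'
#' Exact inverse of [mobilevit_unfold()]: restores patch order and the
#' spatial arrangement of pixels within each patch.
#'
#' @param xg `P x N x d` array.
#' @param cfg A [mobilevit_config()].
#' @param H,W Output spatial dims; `P*N` must equal `H*W`.
#' @return `H x W x d` array.
#' @export
mobilevit_fold <- function(xg, cfg, H, W) {
  dg <- dim(xg)
  if (is.null(dg) || length(dg) != 3L) stop("expected a P x N x d array")
  h <- cfg$h; w <- cfg$w
  if (dg[1] != h * w || dg[1] * dg[2] != H * W)
    stop("patch tensor shape inconsistent with target H x W")
  a <- array(xg, c(h, w, H %/% h, W %/% w, dg[3]))
  a <- aperm(a, c(1L, 3L, 2L, 4L, 5L))
  array(a, c(H, W, dg[3]))
}

softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1L, max))
  m / rowSums(m)
}

# one transformer encoder layer (pre-norm) on an N x d token matrix
transformer_layer <- function(tokens, lp, spec, heads) {
  d <- ncol(tokens)
  dh <- d %/% heads
  tn <- ln_forward(lp$ln1, tokens)
  qkv <- lin_forward(lp$qkv, tn)
  out <- matrix(0, nrow(tokens), d)
  for (hd in seq_len(heads)) {
    ix <- ((hd - 1L) * dh + 1L):(hd * dh)
    q <- qkv[, ix, drop = FALSE]
    k <- qkv[, d + ix, drop = FALSE]
    v <- qkv[, 2L * d + ix, drop = FALSE]
    att <- softmax_rows(tcrossprod(q, k) / sqrt(dh))
    out[, ix] <- att %*% v
  }
  tokens <- tokens + lin_forward(lp$proj, out)
  tn <- ln_forward(lp$ln2, tokens)
  tokens + lin_forward(lp$fc2, silu(lin_forward(lp$fc1, tn)))
}

mobilevit_forward <- function(mod, p, x, training = FALSE) {
  u <- mod$units
  d3 <- fm_dims(x)
  xl <- cu_forward(u$local, p$local, x, training)
  xl <- cu_forward(u$expand, p$expand, xl, training)
  cfg <- list(h = mod$patch, w = mod$patch)
  xu <- mobilevit_unfold(xl, cfg)
  P <- dim(xu)[1]
  for (pp in seq_len(P)) {
    tok <- xu[pp, , , drop = TRUE]
    if (is.null(dim(tok))) tok <- matrix(tok, nrow = dim(xu)[2])
    for (l in seq_len(mod$L))
      tok <- transformer_layer(tok, p$tf[[l]], u$tf[[l]], mod$heads)
    tok <- ln_forward(p$ln_out, tok)
    xu[pp, , ] <- tok
  }
  xf <- mobilevit_fold(xu, cfg, d3[1], d3[2])
  xf <- cu_forward(u$proj, p$proj, xf, training)
  y <- cu_forward(u$fuse, p$fuse, cat_channels(list(x, xf)), training)
  y
}

#' Apply a MobileViT block
#'
#' Hybrid convolution-transformer operator: an `n x n` convolution encodes
#' local structure, a pointwise convolution expands to `d > C` channels, the
#' map is unfolded into patches and a transformer models interactions across
#' patches at each intra-patch position, the result is folded back, projected
#' to `C` channels, concatenated with the input and fused by a final `n x n`
#' convolution.  Spatial size and channel count are preserved.
#'
#' @param x `H x W x C` numeric array.
#' @param cfg A [mobilevit_config()] with `cfg$d > C`.
#' @param params Optional parameter list from a previous call (attribute
#'   `"params"` of a result); freshly initialised when `NULL`.
#' @param seed Integer seed for weight initialisation.
#' @return `H x W x C` array with attribute `"params"`.
#' @export
mobilevit_block <- function(x, cfg, params = NULL, seed = 0L) {
  d3 <- fm_dims(x)
  if (cfg$d <= d3[3])
    stop("mobilevit_config: expanded dim d must exceed input channels C")
  mod <- mod_mobilevit(d3[3], cfg$d, cfg$depth, cfg$heads, cfg$mlp_dim,
                       patch = cfg$h, n_local = cfg$n)
  if (is.null(params)) params <- with_rng(seed, mod_init(mod))
  y <- mobilevit_forward(mod, params, x)
  attr(y, "params") <- params
  y
}

#' Number of trainable parameters of one MobileViT block
#'
#' @param C Input channel count.
#' @param cfg A [mobilevit_config()].
#' @return Parameter count (numeric scalar).
#' @export
mobilevit_block_nparams <- function(C, cfg)
  mod_nparams(mod_mobilevit(C, cfg$d, cfg$depth, cfg$heads, cfg$mlp_dim,
                            patch = cfg$h, n_local = cfg$n))

#' LSK module configuration
#'
#' @param C Channel count the module operates on.
#' @param decomposition Ordered list of `(kernel, dilation)` pairs for the
#'   depthwise large-kernel sequence; receptive field must strictly grow.
#' @param reduction Width of the 1x1 context projections.
#' @return A list of class `lsk_config`.
#' @export
lsk_config <- function(C, decomposition = list(c(5L, 1L), c(7L, 3L)),
                       reduction = C %/% 2L) {
  rf <- vapply(decomposition, function(kd) (kd[1] - 1L) * kd[2] + 1L,
               numeric(1))
  if (any(diff(rf) <= 0))
    stop("receptive field must strictly increase along the decomposition")
  structure(list(C = as.integer(C), decomposition = decomposition,
                 reduction = as.integer(reduction)), class = "lsk_config")
}

#' Apply a large-selective-kernel (LSK) spatial attention module
#'
#' A sequence of depthwise convolutions with growing kernel and dilation
#' produces multi-scale context features, each projected by a 1x1
#' convolution.  Channelwise average- and max-pooling of the stacked contexts
#' feed a small convolution whose sigmoid output provides one spatial mask
#' per decomposition stage; the masked sum of contexts is fused by a final
#' 1x1 convolution into an attention feature that multiplies the input
#' elementwise.
#'
#' @param x `H x W x C` numeric array.
#' @param cfg An [lsk_config()] with matching `C`.
#' @param params Optional parameter list; freshly initialised when `NULL`.
#' @param seed Integer seed for weight initialisation.
#' @return `H x W x C` array with attributes `"params"` and `"masks"` (the
#'   sigmoid spatial selection masks, one per stage, each in `[0, 1]`).
#' @export
lsk_module <- function(x, cfg, params = NULL, seed = 0L) {
  d3 <- fm_dims(x)
  if (d3[3] != cfg$C) stop("input channel count does not match lsk_config")
  mod <- mod_lsk(cfg$C)
  if (is.null(params)) params <- with_rng(seed, mod_init(mod))
  y <- lsk_forward(mod, params, x, training = FALSE, kc = TRUE)
  cache <- attr(y, "cache")
  attr(y, "cache") <- NULL
  attr(y, "params") <- params
  attr(y, "masks") <- cache$sel
  y
}

#' Number of trainable parameters of one LSK module
#'
#' @param cfg An [lsk_config()].
#' @return Parameter count (numeric scalar).
#' @export
lsk_nparams <- function(cfg) mod_nparams(mod_lsk(cfg$C))

#' GSConv configuration
#'
#' @param c1 Input channels.
#' @param c2 Output channels (must be even).
#' @param k Kernel size of the dense half.
#' @param s Stride.
#' @return A list of class `gsconv_config`.
#' @export
gsconv_config <- function(c1, c2, k = 3L, s = 1L) {
  if (c2 %% 2L != 0L) stop("gsconv: c2 must be even")
  structure(list(c1 = as.integer(c1), c2 = as.integer(c2), k = as.integer(k),
                 s = as.integer(s)), class = "gsconv_config")
}

#' Apply a GSConv unit
#'
#' Dense convolution from `c1` to `c2/2` channels, a 5x5 depthwise
#' convolution producing a second `c2/2` half, concatenation to `c2`
#' channels, and a uniform channel shuffle interleaving the two halves.
#'
#' @param x `H x W x c1` numeric array.
#' @param cfg A [gsconv_config()].
#' @param params Optional parameter list; freshly initialised when `NULL`.
#' @param seed Integer seed for weight initialisation.
#' @return Feature map with `c2` channels and attribute `"params"`.
#' @export
gsconv <- function(x, cfg, params = NULL, seed = 0L) {
  mod <- mod_gsconv(cfg$c1, cfg$c2, cfg$k, cfg$s)
  if (is.null(params)) params <- with_rng(seed, mod_init(mod))
  y <- mod_forward(mod, params, list(x))
  attr(y, "params") <- params
  y
}

#' Number of trainable parameters of one GSConv unit
#'
#' @param cfg A [gsconv_config()].
#' @return Parameter count (numeric scalar).
#' @export
gsconv_nparams <- function(cfg) mod_nparams(mod_gsconv(cfg$c1, cfg$c2, cfg$k,
                                                       cfg$s))

#' Channel shuffle
#'
#' Fixed group-interleave permutation of channels: with `g` groups the output
#' takes one channel from each group in turn, evenly exchanging local feature
#' information across groups.  A bijection on channels; per-pixel value
#' multisets are preserved.
#'
#' @param x `H x W x C` numeric array with `C` divisible by `groups`.
#' @param groups Number of channel groups.
#' @return Shuffled `H x W x C` array.
#' @export
channel_shuffle <- function(x, groups) {
  d3 <- fm_dims(x)
  perm <- shuffle_perm(d3[3], as.integer(groups))
  x[, , perm, drop = FALSE]
}
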