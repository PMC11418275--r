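# Low-level array primitives for H x W x C feature maps.
#
# Feature maps are plain numeric arrays with dim = c(H, W, C): dim 1 indexes
# rows (y, top to bottom), dim 2 columns (x, left to right), dim 3 channels.
# Convolutions are evaluated as im2col patch extraction followed by a BLAS
# matrix product, which is fast enough for the desk-scale inputs this package
# targets.  Patch-index matrices are memoised per geometry.

.jd_cache <- new.env(parent = emptyenv())

#' Construct a feature map
#'
#' Thin constructor/validator for the H x W x C numeric arrays used as feature
#' maps throughout the package.
#'
#' @param values Numeric vector or array of length `H * W * C`.
#' @param H,W,C Spatial height, width and channel count (all >= 1).
#' @return A numeric array with `dim = c(H, W, C)`.
#' @export
feature_map <- function(values, H, W, C) {
  stopifnot(H >= 1, W >= 1, C >= 1)
  if (length(values) != H * W * C)
    stop("feature_map: length(values) != H*W*C")
  if (!all(is.finite(values))) stop("feature_map: values must be finite")
  array(as.numeric(values), dim = c(H, W, C))
}

fm_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("expected an H x W x C array")
  d
}

# zero-pad spatial dims
pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  out
}

unpad_hw <- function(x, p, H, W) {
  if (p == 0L) return(x)
  x[(p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE]
}

conv_out_dim <- function(n, k, s, p, d = 1L) {
  eff <- (k - 1L) * d + 1L
  (n + 2L * p - eff) %/% s + 1L
}

# Linear indices (into one padded H x W plane, column-major) of every kernel
# tap for every output position.  Rows: output positions, column-major over
# (Ho, Wo); columns: kernel taps, row offset fastest then column offset --
# matching the flattening order of a (k, k, cin, cout) weight array.
im2col_index <- function(Hp, Wp, k, s, dil) {
  key <- paste("i2c", Hp, Wp, k, s, dil, sep = "_")
  hit <- .jd_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (Hp - ((k - 1L) * dil + 1L)) %/% s + 1L
  Wo <- (Wp - ((k - 1L) * dil + 1L)) %/% s + 1L
  r0 <- seq.int(1L, by = s, length.out = Ho)
  c0 <- seq.int(1L, by = s, length.out = Wo)
  rows <- rep(r0, times = Wo)           # output positions, Ho fastest
  cols <- rep(c0, each = Ho)
  idx <- matrix(0L, nrow = Ho * Wo, ncol = k * k)
  t <- 1L
  for (kj in seq_len(k)) {              # column offset slow
    for (ki in seq_len(k)) {            # row offset fast
      rr <- rows + (ki - 1L) * dil
      cc <- cols + (kj - 1L) * dil
      idx[, t] <- rr + (cc - 1L) * Hp
      t <- t + 1L
    }
  }
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  .jd_cache[[key]] <- out
  out
}

# Patch matrix for channels `chs` of padded input xp: (Ho*Wo) x (k*k*length(chs))
im2col <- function(xp, ii, chs) {
  Hp <- dim(xp)[1]; Wp <- dim(xp)[2]
  plane <- Hp * Wp
  nt <- ncol(ii$idx)
  out <- matrix(0, nrow = nrow(ii$idx), ncol = nt * length(chs))
  xf <- as.vector(xp)
  for (j in seq_along(chs)) {
    off <- (chs[j] - 1L) * plane
    out[, ((j - 1L) * nt + 1L):(j * nt)] <- xf[ii$idx + off]
  }
  out
}

#' @keywords internal
#' @noRd
conv2d_forward <- function(x, w, b = NULL, stride = 1L, pad = 0L,
                           dilation = 1L, groups = 1L, keep_cache = FALSE) {
  d <- fm_dims(x)
  kw <- dim(w)  # (k, k, cin/groups, cout)
  k <- kw[1]; cpg <- kw[3]; cout <- kw[4]
  cin <- d[3]
  stopifnot(cin %% groups == 0L, cout %% groups == 0L, cin %/% groups == cpg)
  xp <- pad_hw(x, pad)
  ii <- im2col_index(dim(xp)[1], dim(xp)[2], k, stride, dilation)
  Ho <- ii$Ho; Wo <- ii$Wo
  y <- array(0, c(Ho, Wo, cout))
  opg <- cout %/% groups
  wm <- matrix(w, nrow = k * k * cpg, ncol = cout)
  cache_P <- if (keep_cache) vector("list", groups) else NULL
  for (g in seq_len(groups)) {
    chs <- ((g - 1L) * cpg + 1L):(g * cpg)
    ocs <- ((g - 1L) * opg + 1L):(g * opg)
    P <- im2col(xp, ii, chs)
    yg <- P %*% wm[, ocs, drop = FALSE]
    if (keep_cache) cache_P[[g]] <- P
    y[, , ocs] <- array(yg, c(Ho, Wo, opg))
  }
  if (!is.null(b)) y <- sweep(y, 3L, b, "+")
  if (keep_cache)
    attr(y, "cache") <- list(P = cache_P, ii = ii, in_dim = d, pad = pad,
                             groups = groups, k = k, cpg = cpg)
  y
}

#' @keywords internal
#' @noRd
conv2d_backward <- function(dy, x, w, cache) {
  d <- cache$in_dim
  kw <- dim(w); k <- kw[1]; cpg <- kw[3]; cout <- kw[4]
  groups <- cache$groups
  opg <- cout %/% groups
  ii <- cache$ii
  Hp <- d[1] + 2L * cache$pad; Wp <- d[2] + 2L * cache$pad
  plane <- Hp * Wp
  wm <- matrix(w, nrow = k * k * cpg, ncol = cout)
  dym <- matrix(dy, nrow = ii$Ho * ii$Wo, ncol = cout)
  dw <- array(0, dim = kw)
  dwm <- matrix(dw, nrow = k * k * cpg, ncol = cout)
  dxp <- numeric(plane * d[3])
  for (g in seq_len(groups)) {
    chs <- ((g - 1L) * cpg + 1L):(g * cpg)
    ocs <- ((g - 1L) * opg + 1L):(g * opg)
    P <- cache$P[[g]]
    dyg <- dym[, ocs, drop = FALSE]
    dwm[, ocs] <- crossprod(P, dyg)
    dP <- dyg %*% t(wm[, ocs, drop = FALSE])
    nt <- k * k
    for (j in seq_len(cpg)) {
      off <- (chs[j] - 1L) * plane
      for (t in seq_len(nt)) {
        tgt <- ii$idx[, t] + off
        dxp[tgt] <- dxp[tgt] + dP[, (j - 1L) * nt + t]
      }
    }
  }
  dxp <- array(dxp, c(Hp, Wp, d[3]))
  list(dx = unpad_hw(dxp, cache$pad, d[1], d[2]),
       dw = array(dwm, dim = kw),
       db = colSums(dym))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

# channelwise batch norm over one H x W x C map (single-image statistics)
bn_forward <- function(x, gamma, beta, rmean, rvar, training, eps = 1e-5,
                       momentum = 0.03) {
  d <- fm_dims(x)
  n <- d[1] * d[2]
  xm <- matrix(x, nrow = n, ncol = d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2L, mu, "-")^2)
  } else {
    mu <- rmean; v <- rvar
  }
  inv <- 1 / sqrt(v + eps)
  xh <- sweep(sweep(xm, 2L, mu, "-"), 2L, inv, "*")
  y <- sweep(sweep(xh, 2L, gamma, "*"), 2L, beta, "+")
  out <- array(y, d)
  list(y = out, xhat = xh, inv = inv, mu = mu, var = v,
       rmean = if (training) (1 - momentum) * rmean + momentum * mu else rmean,
       rvar = if (training) (1 - momentum) * rvar + momentum * v else rvar)
}

bn_backward <- function(dy, cache, gamma) {
  d <- dim(dy)
  n <- d[1] * d[2]
  dym <- matrix(dy, nrow = n, ncol = d[3])
  xh <- cache$xhat
  dgamma <- colSums(dym * xh)
  dbeta <- colSums(dym)
  dxh <- sweep(dym, 2L, gamma, "*")
  # standard batch-norm input gradient
  t1 <- sweep(dxh, 2L, colMeans(dxh), "-")
  t2 <- sweep(xh, 2L, colMeans(dxh * xh), "*")
  dx <- sweep(t1 - t2, 2L, cache$inv, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# nearest-neighbour upsample by integer factor
upsample_nearest <- function(x, factor = 2L) {
  d <- fm_dims(x)
  x[rep(seq_len(d[1]), each = factor), rep(seq_len(d[2]), each = factor), ,
    drop = FALSE]
}

upsample_backward <- function(dy, factor = 2L) {
  d <- dim(dy)
  H <- d[1] %/% factor; W <- d[2] %/% factor
  dx <- array(0, c(H, W, d[3]))
  for (i in seq_len(factor)) for (j in seq_len(factor)) {
    dx <- dx + dy[seq.int(i, by = factor, length.out = H),
                  seq.int(j, by = factor, length.out = W), , drop = FALSE]
  }
  dx
}

# k x k max pool, stride 1, same padding (SPPF building block)
maxpool_same <- function(x, k = 5L, keep_cache = FALSE) {
  d <- fm_dims(x)
  p <- (k - 1L) %/% 2L
  # -Inf padding so border maxima are correct for negative activations
  xp2 <- array(-Inf, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  xp2[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  ii <- im2col_index(dim(xp2)[1], dim(xp2)[2], k, 1L, 1L)
  plane <- dim(xp2)[1] * dim(xp2)[2]
  xf <- as.vector(xp2)
  y <- array(0, d)
  amax <- if (keep_cache) array(0L, d) else NULL
  for (c in seq_len(d[3])) {
    M <- matrix(xf[ii$idx + (c - 1L) * plane], nrow = nrow(ii$idx))
    w <- max.col(M, ties.method = "first")
    y[, , c] <- M[cbind(seq_len(nrow(M)), w)]
    if (keep_cache)
      amax[, , c] <- ii$idx[cbind(seq_len(nrow(M)), w)] + (c - 1L) * plane
  }
  if (keep_cache)
    attr(y, "cache") <- list(amax = amax, Hp = dim(xp2)[1], Wp = dim(xp2)[2],
                             p = p, d = d)
  y
}

maxpool_backward <- function(dy, cache) {
  dxp <- numeric(cache$Hp * cache$Wp * cache$d[3])
  idx <- as.vector(cache$amax)
  v <- as.vector(dy)
  # several output cells can share one argmax; accumulate
  acc <- rowsum(v, idx)
  dxp[as.integer(rownames(acc))] <- acc[, 1]
  dxp <- array(dxp, c(cache$Hp, cache$Wp, cache$d[3]))
  unpad_hw(dxp, cache$p, cache$d[1], cache$d[2])
}

# concatenate along channels
cat_channels <- function(xs) {
  ds <- lapply(xs, fm_dims)
  H <- ds[[1]][1]; W <- ds[[1]][2]
  for (d in ds) if (d[1] != H || d[2] != W)
    stop("cat_channels: spatial dims disagree")
  ctot <- sum(vapply(ds, `[`, integer(1), 3L))
  out <- array(0, c(H, W, ctot))
  at <- 0L
  for (i in seq_along(xs)) {
    ci <- ds[[i]][3]
    out[, , (at + 1L):(at + ci)] <- xs[[i]]
    at <- at + ci
  }
  out
}
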