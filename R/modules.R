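# Network modules.  Each module is a plain list spec created by a mod_*()
# constructor; generic helpers compute trainable-parameter counts and FLOPs
# in closed form, initialise weights, and run forward (and, for the
# convolutional modules used by the trainer, backward) passes.
#
# FLOP accounting counts convolutions and matrix products only, two
# operations per multiply-accumulate plus bias additions, matching the
# profiler convention under which detector compute budgets are quoted.

mod_conv <- function(cin, cout, k = 1L, s = 1L) {
  list(type = "conv", out_ch = as.integer(cout), s = as.integer(s),
       units = list(cv = cu_spec(cin, cout, k, s)))
}

mod_c2f <- function(c1, c2, n = 1L, shortcut = FALSE) {
  ch <- c2 %/% 2L
  bt <- lapply(seq_len(n), function(i)
    list(cv1 = cu_spec(ch, ch, 3L), cv2 = cu_spec(ch, ch, 3L)))
  list(type = "c2f", out_ch = as.integer(c2), s = 1L, n = as.integer(n),
       shortcut = shortcut, ch = as.integer(ch),
       units = list(cv1 = cu_spec(c1, c2, 1L),
                    cv2 = cu_spec((2L + n) * ch, c2, 1L), m = bt))
}

mod_sppf <- function(c1, c2, k = 5L, ch = c1 %/% 2L) {
  ch <- as.integer(ch)
  list(type = "sppf", out_ch = as.integer(c2), s = 1L, k = as.integer(k),
       ch = as.integer(ch),
       units = list(cv1 = cu_spec(c1, ch, 1L), cv2 = cu_spec(4L * ch, c2, 1L)))
}

mod_upsample <- function(out_ch, factor = 2L)
  list(type = "upsample", out_ch = as.integer(out_ch), s = 1L,
       factor = as.integer(factor), units = list())

mod_concat <- function(out_ch)
  list(type = "concat", out_ch = as.integer(out_ch), s = 1L, units = list())

mod_mv2 <- function(c1, c2, s = 1L, e = 4L) {
  h <- as.integer(e * c1)
  list(type = "mv2", out_ch = as.integer(c2), s = as.integer(s),
       residual = (s == 1L && c1 == c2),
       units = list(expand = cu_spec(c1, h, 1L),
                    dw = cu_spec(h, h, 3L, s, g = h),
                    project = cu_spec(h, c2, 1L, act = "none")))
}

mod_mobilevit <- function(C, d, L = 2L, heads = 4L, hmlp = 2L * d,
                          patch = 2L, n_local = 3L) {
  stopifnot(d > C, d %% heads == 0L)
  layer <- function()
    list(ln1 = ln_spec(d), qkv = lin_spec(d, 3L * d), proj = lin_spec(d, d),
         ln2 = ln_spec(d), fc1 = lin_spec(d, hmlp), fc2 = lin_spec(hmlp, d))
  list(type = "mobilevit", out_ch = as.integer(C), s = 1L, d = as.integer(d),
       L = as.integer(L), heads = as.integer(heads), hmlp = as.integer(hmlp),
       patch = as.integer(patch),
       units = list(local = cu_spec(C, C, n_local),
                    expand = cu_spec(C, d, 1L, bias = TRUE, bn = FALSE,
                                     act = "none"),
                    tf = lapply(seq_len(L), function(i) layer()),
                    ln_out = ln_spec(d),
                    proj = cu_spec(d, C, 1L),
                    fuse = cu_spec(2L * C, C, n_local)))
}

mod_lsk <- function(C) {
  r <- C %/% 2L
  list(type = "lsk", out_ch = as.integer(C), s = 1L, r = r,
       units = list(
         dw5 = cu_spec(C, C, 5L, g = C, bias = TRUE, bn = FALSE, act = "none"),
         dw7 = cu_spec(C, C, 7L, dil = 3L, g = C, bias = TRUE, bn = FALSE,
                       act = "none"),
         f1 = cu_spec(C, r, 1L, bias = TRUE, bn = FALSE, act = "none"),
         f2 = cu_spec(C, r, 1L, bias = TRUE, bn = FALSE, act = "none"),
         squeeze = cu_spec(2L, 2L, 7L, bias = TRUE, bn = FALSE,
                           act = "sigmoid"),
         fuse = cu_spec(r, C, 1L, bias = TRUE, bn = FALSE, act = "none")))
}

mod_gsconv <- function(c1, c2, k = 3L, s = 1L, dwk = 5L) {
  if (c2 %% 2L != 0L) stop("gsconv: output channel count must be even")
  h <- c2 %/% 2L
  list(type = "gsconv", out_ch = as.integer(c2), s = as.integer(s), h = h,
       units = list(dense = cu_spec(c1, h, k, s),
                    dw = cu_spec(h, h, dwk, g = h)))
}

mod_detect <- function(nc, ch, reg_max = 16L) {
  c2 <- max(16L, ch[1] %/% 4L, 4L * reg_max)
  c3 <- max(ch[1], min(nc, 100L))
  br <- function(ci)
    list(box1 = cu_spec(ci, c2, 3L), box2 = cu_spec(c2, c2, 3L),
         box3 = cu_spec(c2, 4L * reg_max, 1L, bias = TRUE, bn = FALSE,
                        act = "none"),
         cls1 = cu_spec(ci, c3, 3L), cls2 = cu_spec(c3, c3, 3L),
         cls3 = cu_spec(c3, nc, 1L, bias = TRUE, bn = FALSE, act = "none"))
  list(type = "detect", out_ch = 4L * reg_max + nc, s = 1L, nc = as.integer(nc),
       reg_max = as.integer(reg_max), nscale = length(ch),
       units = list(scales = lapply(ch, br)))
}

# ---- generic walkers over the nested unit lists -----------------------------

walk_units <- function(u, f) {
  if (is.list(u) && !is.null(u$type)) return(f(u))
  if (is.list(u)) return(sum(vapply(u, walk_units, numeric(1), f = f)))
  0
}

unit_nparams <- function(u)
  switch(u$type, convunit = cu_nparams(u), linear = lin_nparams(u),
         layernorm = ln_nparams(u))

#' @keywords internal
#' @noRd
mod_nparams <- function(mod) {
  n <- walk_units(mod$units, unit_nparams)
  # the head carries the fixed expectation weights of the distribution-focal
  # projection; published parameter totals include them
  if (mod$type == "detect") n <- n + mod$reg_max
  n
}

init_units <- function(u) {
  if (is.list(u) && !is.null(u$type))
    return(switch(u$type, convunit = cu_init(u), linear = lin_init(u),
                  layernorm = ln_init(u)))
  lapply(u, init_units)
}

#' @keywords internal
#' @noRd
mod_init <- function(mod) {
  p <- init_units(mod$units)
  if (mod$type == "detect") p$dfl <- seq(0, mod$reg_max - 1L)
  p
}

# count trainable elements in an initialised parameter tree (BN running
# statistics are buffers, not trainable parameters)
count_param_tree <- function(p) {
  if (is.list(p)) {
    nm <- names(p)
    keep <- if (is.null(nm)) seq_along(p) else which(!nm %in% c("rmean", "rvar"))
    return(sum(vapply(p[keep], count_param_tree, numeric(1))))
  }
  length(p)
}

# ---- FLOPs ------------------------------------------------------------------

# dims: list of c(H, W) per input; returns list(flops, out = c(H, W))
mod_flops <- function(mod, dims) {
  H <- dims[[1]][1]; W <- dims[[1]][2]
  u <- mod$units
  switch(mod$type,
    conv = {
      hw <- cu_out_hw(u$cv, H, W)
      list(flops = cu_flops(u$cv, H, W), out = hw)
    },
    c2f = {
      f <- cu_flops(u$cv1, H, W) + cu_flops(u$cv2, H, W)
      for (b in u$m) f <- f + cu_flops(b$cv1, H, W) + cu_flops(b$cv2, H, W)
      list(flops = f, out = c(H, W))
    },
    sppf = list(flops = cu_flops(u$cv1, H, W) + cu_flops(u$cv2, H, W),
                out = c(H, W)),
    upsample = list(flops = 0, out = c(H, W) * mod$factor),
    concat = list(flops = 0, out = c(H, W)),
    mv2 = {
      f <- cu_flops(u$expand, H, W)
      hw <- cu_out_hw(u$dw, H, W)
      f <- f + cu_flops(u$dw, H, W) + cu_flops(u$project, hw[1], hw[2])
      list(flops = f, out = hw)
    },
    mobilevit = {
      d <- mod$d; P <- mod$patch^2; N <- (H * W) / P; ntok <- H * W
      f <- cu_flops(u$local, H, W) + cu_flops(u$expand, H, W)
      per_layer <- lin_flops(u$tf[[1]]$qkv, ntok) +
        lin_flops(u$tf[[1]]$proj, ntok) +
        lin_flops(u$tf[[1]]$fc1, ntok) + lin_flops(u$tf[[1]]$fc2, ntok) +
        4 * P * N^2 * d              # QK^T and AV, 2 ops per MAC
      f <- f + mod$L * per_layer
      f <- f + cu_flops(u$proj, H, W) + cu_flops(u$fuse, H, W)
      list(flops = f, out = c(H, W))
    },
    lsk = {
      f <- sum(vapply(u, cu_flops, numeric(1), H = H, W = W))
      list(flops = f, out = c(H, W))
    },
    gsconv = {
      hw <- cu_out_hw(u$dense, H, W)
      list(flops = cu_flops(u$dense, H, W) + cu_flops(u$dw, hw[1], hw[2]),
           out = hw)
    },
    detect = {
      f <- 0
      for (i in seq_len(mod$nscale)) {
        b <- u$scales[[i]]; hi <- dims[[i]][1]; wi <- dims[[i]][2]
        f <- f + cu_flops(b$box1, hi, wi) + cu_flops(b$box2, hi, wi) +
          cu_flops(b$box3, hi, wi) + cu_flops(b$cls1, hi, wi) +
          cu_flops(b$cls2, hi, wi) + cu_flops(b$cls3, hi, wi)
      }
      list(flops = f, out = dims[[1]])
    },
    stop("unknown module type: ", mod$type))
}
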