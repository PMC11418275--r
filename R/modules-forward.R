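# Forward and backward passes for the module zoo.  Backward is implemented
# for every convolutional module type (all of YOLOv8n plus GSConv, MV2 and
# LSK); the transformer stage of the MobileViT block is forward-only, which
# restricts the desk-scale trainer to variants without MobileViT stages.

shuffle_perm <- function(C, groups) {
  if (C %% groups != 0L) stop("channel count not divisible by groups")
  as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
}

mod_forward <- function(mod, p, xs, training = FALSE, keep_cache = FALSE) {
  u <- mod$units
  kc <- keep_cache
  switch(mod$type,
    conv = {
      y <- cu_forward(u$cv, p$cv, xs[[1]], training, kc)
      cache <- attr(y, "cache"); attr(y, "cache") <- NULL
      if (kc) attr(y, "cache") <- list(cv = cache)
      y
    },
    c2f = {
      y1 <- cu_forward(u$cv1, p$cv1, xs[[1]], training, kc)
      c1c <- attr(y1, "cache"); attr(y1, "cache") <- NULL
      ch <- mod$ch
      ys <- list(y1[, , 1:ch, drop = FALSE],
                 y1[, , (ch + 1L):(2L * ch), drop = FALSE])
      cur <- ys[[2]]
      bc <- vector("list", mod$n)
      for (i in seq_len(mod$n)) {
        t1 <- cu_forward(u$m[[i]]$cv1, p$m[[i]]$cv1, cur, training, kc)
        t1c <- attr(t1, "cache"); attr(t1, "cache") <- NULL
        t2 <- cu_forward(u$m[[i]]$cv2, p$m[[i]]$cv2, t1, training, kc)
        t2c <- attr(t2, "cache"); attr(t2, "cache") <- NULL
        cur <- if (mod$shortcut) cur + t2 else t2
        ys[[2L + i]] <- cur
        bc[[i]] <- list(cv1 = t1c, cv2 = t2c)
      }
      xcat <- cat_channels(ys)
      y <- cu_forward(u$cv2, p$cv2, xcat, training, kc)
      c2c <- attr(y, "cache"); attr(y, "cache") <- NULL
      if (kc) attr(y, "cache") <- list(cv1 = c1c, cv2 = c2c, m = bc)
      y
    },
    sppf = {
      y0 <- cu_forward(u$cv1, p$cv1, xs[[1]], training, kc)
      c1c <- attr(y0, "cache"); attr(y0, "cache") <- NULL
      p1 <- maxpool_same(y0, mod$k, kc); m1c <- attr(p1, "cache")
      attr(p1, "cache") <- NULL
      p2 <- maxpool_same(p1, mod$k, kc); m2c <- attr(p2, "cache")
      attr(p2, "cache") <- NULL
      p3 <- maxpool_same(p2, mod$k, kc); m3c <- attr(p3, "cache")
      attr(p3, "cache") <- NULL
      y <- cu_forward(u$cv2, p$cv2, cat_channels(list(y0, p1, p2, p3)),
                      training, kc)
      c2c <- attr(y, "cache"); attr(y, "cache") <- NULL
      if (kc) attr(y, "cache") <- list(cv1 = c1c, cv2 = c2c,
                                       mp = list(m1c, m2c, m3c))
      y
    },
    upsample = upsample_nearest(xs[[1]], mod$factor),
    concat = cat_channels(xs),
    mv2 = {
      y1 <- cu_forward(u$expand, p$expand, xs[[1]], training, kc)
      e1 <- attr(y1, "cache"); attr(y1, "cache") <- NULL
      y2 <- cu_forward(u$dw, p$dw, y1, training, kc)
      e2 <- attr(y2, "cache"); attr(y2, "cache") <- NULL
      y <- cu_forward(u$project, p$project, y2, training, kc)
      e3 <- attr(y, "cache"); attr(y, "cache") <- NULL
      if (mod$residual) y <- y + xs[[1]]
      if (kc) attr(y, "cache") <- list(expand = e1, dw = e2, project = e3)
      y
    },
    gsconv = {
      y1 <- cu_forward(u$dense, p$dense, xs[[1]], training, kc)
      d1 <- attr(y1, "cache"); attr(y1, "cache") <- NULL
      y2 <- cu_forward(u$dw, p$dw, y1, training, kc)
      d2 <- attr(y2, "cache"); attr(y2, "cache") <- NULL
      ycat <- cat_channels(list(y1, y2))
      perm <- shuffle_perm(2L * mod$h, 2L)
      y <- ycat[, , perm, drop = FALSE]
      if (kc) attr(y, "cache") <- list(dense = d1, dw = d2, perm = perm)
      y
    },
    lsk = lsk_forward(mod, p, xs[[1]], training, kc),
    mobilevit = mobilevit_forward(mod, p, xs[[1]], training),
    detect = {
      outs <- vector("list", mod$nscale)
      caches <- vector("list", mod$nscale)
      for (i in seq_len(mod$nscale)) {
        b <- u$scales[[i]]; pb <- p$scales[[i]]; xi <- xs[[i]]
        b1 <- cu_forward(b$box1, pb$box1, xi, training, kc)
        b1c <- attr(b1, "cache"); attr(b1, "cache") <- NULL
        b2 <- cu_forward(b$box2, pb$box2, b1, training, kc)
        b2c <- attr(b2, "cache"); attr(b2, "cache") <- NULL
        b3 <- cu_forward(b$box3, pb$box3, b2, training, kc)
        b3c <- attr(b3, "cache"); attr(b3, "cache") <- NULL
        k1 <- cu_forward(b$cls1, pb$cls1, xi, training, kc)
        k1c <- attr(k1, "cache"); attr(k1, "cache") <- NULL
        k2 <- cu_forward(b$cls2, pb$cls2, k1, training, kc)
        k2c <- attr(k2, "cache"); attr(k2, "cache") <- NULL
        k3 <- cu_forward(b$cls3, pb$cls3, k2, training, kc)
        k3c <- attr(k3, "cache"); attr(k3, "cache") <- NULL
        outs[[i]] <- cat_channels(list(b3, k3))
        caches[[i]] <- list(box1 = b1c, box2 = b2c, box3 = b3c,
                            cls1 = k1c, cls2 = k2c, cls3 = k3c)
      }
      if (kc) attr(outs, "cache") <- caches
      outs
    },
    stop("unknown module type: ", mod$type))
}

lsk_forward <- function(mod, p, x, training, kc) {
  u <- mod$units
  a0 <- cu_forward(u$dw5, p$dw5, x, training, kc)
  c0 <- attr(a0, "cache"); attr(a0, "cache") <- NULL
  a1 <- cu_forward(u$dw7, p$dw7, a0, training, kc)
  c1 <- attr(a1, "cache"); attr(a1, "cache") <- NULL
  t1 <- cu_forward(u$f1, p$f1, a0, training, kc)
  cf1 <- attr(t1, "cache"); attr(t1, "cache") <- NULL
  t2 <- cu_forward(u$f2, p$f2, a1, training, kc)
  cf2 <- attr(t2, "cache"); attr(t2, "cache") <- NULL
  stk <- cat_channels(list(t1, t2))
  d <- dim(stk)
  m <- matrix(stk, nrow = d[1] * d[2], ncol = d[3])
  avg <- rowMeans(m)
  wmx <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(nrow(m)), wmx)]
  agg <- array(c(avg, mx), c(d[1], d[2], 2L))
  sel <- cu_forward(u$squeeze, p$squeeze, agg, training, kc)  # sigmoid masks
  cs <- attr(sel, "cache"); attr(sel, "cache") <- NULL
  attn <- t1 * rep(sel[, , 1], times = mod$r) +
    t2 * rep(sel[, , 2], times = mod$r)
  dim(attn) <- dim(t1)
  s <- cu_forward(u$fuse, p$fuse, attn, training, kc)
  cf <- attr(s, "cache"); attr(s, "cache") <- NULL
  y <- x * s
  if (kc)
    attr(y, "cache") <- list(dw5 = c0, dw7 = c1, f1 = cf1, f2 = cf2,
                             squeeze = cs, fuse = cf, x = x, s = s, t1 = t1,
                             t2 = t2, sel = sel, wmx = wmx, nch = d[3])
  y
}

mod_backward <- function(mod, p, cache, dy) {
  u <- mod$units
  switch(mod$type,
    conv = {
      r <- cu_backward(u$cv, p$cv, cache$cv, dy)
      list(dxs = list(r$dx), grads = list(cv = r$grads))
    },
    c2f = {
      r2 <- cu_backward(u$cv2, p$cv2, cache$cv2, dy)
      ch <- mod$ch
      dcat <- r2$dx
      nys <- 2L + mod$n
      dys <- lapply(seq_len(nys), function(i)
        dcat[, , ((i - 1L) * ch + 1L):(i * ch), drop = FALSE])
      gm <- vector("list", mod$n)
      dcur <- array(0, dim(dys[[1]]))
      for (i in rev(seq_len(mod$n))) {
        dcur <- dcur + dys[[2L + i]]
        rb2 <- cu_backward(u$m[[i]]$cv2, p$m[[i]]$cv2, cache$m[[i]]$cv2, dcur)
        rb1 <- cu_backward(u$m[[i]]$cv1, p$m[[i]]$cv1, cache$m[[i]]$cv1, rb2$dx)
        gm[[i]] <- list(cv1 = rb1$grads, cv2 = rb2$grads)
        dcur <- if (mod$shortcut) dcur + rb1$dx else rb1$dx
      }
      dy1 <- array(0, c(dim(dcur)[1], dim(dcur)[2], 2L * ch))
      dy1[, , 1:ch] <- dys[[1]]
      dy1[, , (ch + 1L):(2L * ch)] <- dcur + dys[[2]]
      r1 <- cu_backward(u$cv1, p$cv1, cache$cv1, dy1)
      list(dxs = list(r1$dx),
           grads = list(cv1 = r1$grads, cv2 = r2$grads, m = gm))
    },
    sppf = {
      r2 <- cu_backward(u$cv2, p$cv2, cache$cv2, dy)
      ch <- mod$ch
      d0 <- r2$dx[, , 1:ch, drop = FALSE]
      d1 <- r2$dx[, , (ch + 1L):(2L * ch), drop = FALSE]
      d2 <- r2$dx[, , (2L * ch + 1L):(3L * ch), drop = FALSE]
      d3 <- r2$dx[, , (3L * ch + 1L):(4L * ch), drop = FALSE]
      d2 <- d2 + maxpool_backward(d3, cache$mp[[3]])
      d1 <- d1 + maxpool_backward(d2, cache$mp[[2]])
      d0 <- d0 + maxpool_backward(d1, cache$mp[[1]])
      r1 <- cu_backward(u$cv1, p$cv1, cache$cv1, d0)
      list(dxs = list(r1$dx), grads = list(cv1 = r1$grads, cv2 = r2$grads))
    },
    upsample = list(dxs = list(upsample_backward(dy, mod$factor)),
                    grads = list()),
    concat = {
      chs <- attr(cache, "in_ch")
      dxs <- list(); at <- 0L
      for (ci in chs) {
        dxs[[length(dxs) + 1L]] <- dy[, , (at + 1L):(at + ci), drop = FALSE]
        at <- at + ci
      }
      list(dxs = dxs, grads = list())
    },
    mv2 = {
      dres <- if (mod$residual) dy else NULL
      r3 <- cu_backward(u$project, p$project, cache$project, dy)
      r2 <- cu_backward(u$dw, p$dw, cache$dw, r3$dx)
      r1 <- cu_backward(u$expand, p$expand, cache$expand, r2$dx)
      dx <- r1$dx
      if (!is.null(dres)) dx <- dx + dres
      list(dxs = list(dx),
           grads = list(expand = r1$grads, dw = r2$grads, project = r3$grads))
    },
    gsconv = {
      inv <- order(cache$perm)
      dcat <- dy[, , inv, drop = FALSE]
      h <- mod$h
      dd <- dcat[, , 1:h, drop = FALSE]
      dw_ <- dcat[, , (h + 1L):(2L * h), drop = FALSE]
      r2 <- cu_backward(u$dw, p$dw, cache$dw, dw_)
      r1 <- cu_backward(u$dense, p$dense, cache$dense, dd + r2$dx)
      list(dxs = list(r1$dx),
           grads = list(dense = r1$grads, dw = r2$grads))
    },
    lsk = lsk_backward(mod, p, cache, dy),
    detect = {
      dxs <- NULL
      grads <- list(scales = vector("list", mod$nscale))
      for (i in seq_len(mod$nscale)) {
        b <- u$scales[[i]]; pb <- p$scales[[i]]; cc <- cache[[i]]
        nb <- 4L * mod$reg_max
        dyb <- dy[[i]][, , 1:nb, drop = FALSE]
        dyc <- dy[[i]][, , (nb + 1L):(nb + mod$nc), drop = FALSE]
        r3 <- cu_backward(b$box3, pb$box3, cc$box3, dyb)
        r2 <- cu_backward(b$box2, pb$box2, cc$box2, r3$dx)
        r1 <- cu_backward(b$box1, pb$box1, cc$box1, r2$dx)
        s3 <- cu_backward(b$cls3, pb$cls3, cc$cls3, dyc)
        s2 <- cu_backward(b$cls2, pb$cls2, cc$cls2, s3$dx)
        s1 <- cu_backward(b$cls1, pb$cls1, cc$cls1, s2$dx)
        dxs[[i]] <- r1$dx + s1$dx
        grads$scales[[i]] <- list(box1 = r1$grads, box2 = r2$grads,
                                  box3 = r3$grads, cls1 = s1$grads,
                                  cls2 = s2$grads, cls3 = s3$grads)
      }
      list(dxs = dxs, grads = grads)
    },
    stop("backward not implemented for module type: ", mod$type))
}

lsk_backward <- function(mod, p, cache, dy) {
  u <- mod$units
  ds <- dy * cache$x
  dx_direct <- dy * cache$s
  rf <- cu_backward(u$fuse, p$fuse, cache$fuse, ds)
  dattn <- rf$dx
  sel1 <- rep(cache$sel[, , 1], times = mod$r)
  sel2 <- rep(cache$sel[, , 2], times = mod$r)
  dt1 <- dattn * array(sel1, dim(dattn))
  dt2 <- dattn * array(sel2, dim(dattn))
  hw <- dim(dattn)[1] * dim(dattn)[2]
  dsel1 <- rowSums(matrix(dattn * cache$t1, nrow = hw))
  dsel2 <- rowSums(matrix(dattn * cache$t2, nrow = hw))
  dsel <- array(c(dsel1, dsel2), c(dim(dattn)[1], dim(dattn)[2], 2L))
  rs <- cu_backward(u$squeeze, p$squeeze, cache$squeeze, dsel)
  dagg <- rs$dx
  # agg channel 1: channel mean of [t1, t2]; channel 2: channel max
  nch <- cache$nch
  davg <- as.vector(dagg[, , 1]) / nch
  dstk <- matrix(rep(davg, nch), nrow = hw)
  dmx <- as.vector(dagg[, , 2])
  dstk[cbind(seq_len(hw), cache$wmx)] <-
    dstk[cbind(seq_len(hw), cache$wmx)] + dmx
  dstk <- array(dstk, c(dim(dattn)[1], dim(dattn)[2], nch))
  dt1 <- dt1 + dstk[, , 1:mod$r, drop = FALSE]
  dt2 <- dt2 + dstk[, , (mod$r + 1L):nch, drop = FALSE]
  r1 <- cu_backward(u$f1, p$f1, cache$f1, dt1)
  r2 <- cu_backward(u$f2, p$f2, cache$f2, dt2)
  r7 <- cu_backward(u$dw7, p$dw7, cache$dw7, r2$dx)
  r5 <- cu_backward(u$dw5, p$dw5, cache$dw5, r1$dx + r7$dx)
  list(dxs = list(dx_direct + r5$dx),
       grads = list(dw5 = r5$grads, dw7 = r7$grads, f1 = r1$grads,
                    f2 = r2$grads, squeeze = rs$grads, fuse = rf$grads))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
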