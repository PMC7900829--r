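# Independent plain-R double-precision reference implementation of the
# encoder-decoder forward and backward passes (depth-2 topology), written
# against the layer definitions rather than the package code. Used as the
# oracle for the compiled single-precision primitives.

ref_conv3 <- function(xc, w, b) {
  H <- dim(xc)[1]
  W <- dim(xc)[2]
  C <- dim(xc)[3]
  F <- ncol(w)
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- xc
  cols <- matrix(0, H * W, 9 * C)
  col <- 0
  for (dr in -1:1) {
    for (dc in -1:1) {
      for (ch in 1:C) {
        col <- col + 1
        cols[, col] <- as.vector(xp[(2:(H + 1)) + dr, (2:(W + 1)) + dc, ch])
      }
    }
  }
  y <- cols %*% w
  out <- array(0, c(H, W, F))
  for (f in 1:F) out[, , f] <- matrix(y[, f] + b[f], H, W)
  list(out = out, cols = cols)
}

ref_conv3_bwd <- function(cols, w, gy, C) {
  H <- dim(gy)[1]
  W <- dim(gy)[2]
  F <- dim(gy)[3]
  gymat <- matrix(0, H * W, F)
  for (f in 1:F) gymat[, f] <- as.vector(gy[, , f])
  gcols <- gymat %*% t(w)
  gxp <- array(0, c(H + 2, W + 2, C))
  col <- 0
  for (dr in -1:1) {
    for (dc in -1:1) {
      for (ch in 1:C) {
        col <- col + 1
        gxp[(2:(H + 1)) + dr, (2:(W + 1)) + dc, ch] <-
          gxp[(2:(H + 1)) + dr, (2:(W + 1)) + dc, ch] + matrix(gcols[, col], H, W)
      }
    }
  }
  list(
    gw = t(cols) %*% gymat, gb = colSums(gymat),
    gx = gxp[2:(H + 1), 2:(W + 1), , drop = FALSE]
  )
}

ref_pool2 <- function(a) {
  H <- dim(a)[1]
  W <- dim(a)[2]
  C <- dim(a)[3]
  out <- array(0, c(H / 2, W / 2, C))
  for (ch in 1:C) {
    for (i in 1:(H / 2)) {
      for (j in 1:(W / 2)) {
        out[i, j, ch] <- max(a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch])
      }
    }
  }
  out
}

ref_pool2_bwd <- function(a, gy) {
  H <- dim(a)[1]
  W <- dim(a)[2]
  C <- dim(a)[3]
  gx <- array(0, c(H, W, C))
  for (ch in 1:C) {
    for (i in 1:(H / 2)) {
      for (j in 1:(W / 2)) {
        blk <- a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch]
        k <- which.max(blk)
        ii <- (2 * i - 1) + (k - 1) %% 2
        jj <- (2 * j - 1) + (k - 1) %/% 2
        gx[ii, jj, ch] <- gx[ii, jj, ch] + gy[i, j, ch]
      }
    }
  }
  gx
}

ref_up2 <- function(a) {
  H <- dim(a)[1]
  W <- dim(a)[2]
  C <- dim(a)[3]
  out <- array(0, c(2 * H, 2 * W, C))
  for (ch in 1:C) out[, , ch] <- a[rep(1:H, each = 2), rep(1:W, each = 2), ch]
  out
}

ref_up2_bwd <- function(gy) {
  H <- dim(gy)[1] / 2
  W <- dim(gy)[2] / 2
  C <- dim(gy)[3]
  gx <- array(0, c(H, W, C))
  for (ch in 1:C) {
    for (i in 1:H) {
      for (j in 1:W) {
        gx[i, j, ch] <- sum(gy[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch])
      }
    }
  }
  gx
}

# Forward + full gradient of the mean BCE for a depth-2, skip-connected
# network on one image. Returns list(prob, grads).
ref_segnet_grads <- function(p, x, y) {
  n <- length(x)
  cur <- array(x, c(dim(x), 1))
  c1 <- ref_conv3(cur, p$w_enc1, p$b_enc1)
  e1 <- pmax(c1$out, 0)
  pl1 <- ref_pool2(e1)
  c2 <- ref_conv3(pl1, p$w_enc2, p$b_enc2)
  e2 <- pmax(c2$out, 0)
  pl2 <- ref_pool2(e2)
  cb <- ref_conv3(pl2, p$w_bott, p$b_bott)
  bt <- pmax(cb$out, 0)
  up2 <- ref_up2(bt)
  cat2 <- array(c(up2, e2), c(dim(up2)[1:2], dim(up2)[3] + dim(e2)[3]))
  cd2 <- ref_conv3(cat2, p$w_dec2, p$b_dec2)
  d2 <- pmax(cd2$out, 0)
  up1 <- ref_up2(d2)
  cat1 <- array(c(up1, e1), c(dim(up1)[1:2], dim(up1)[3] + dim(e1)[3]))
  cd1 <- ref_conv3(cat1, p$w_dec1, p$b_dec1)
  d1 <- pmax(cd1$out, 0)
  logits <- matrix(p$b_out, nrow(x), ncol(x))
  for (ch in seq_len(dim(d1)[3])) logits <- logits + d1[, , ch] * p$w_out[ch, 1]
  prob <- 1 / (1 + exp(-logits))
  dlog <- (prob - y) / n

  g <- list()
  nch <- dim(d1)[3]
  g$w_out <- matrix(sapply(1:nch, function(ch) sum(dlog * d1[, , ch])), nch, 1)
  g$b_out <- sum(dlog)
  gd1 <- array(0, dim(d1))
  for (ch in 1:nch) gd1[, , ch] <- dlog * p$w_out[ch, 1]
  bw <- ref_conv3_bwd(cd1$cols, p$w_dec1, gd1 * (cd1$out > 0), dim(cat1)[3])
  g$w_dec1 <- bw$gw
  g$b_dec1 <- bw$gb
  k <- dim(up1)[3]
  gskip1 <- bw$gx[, , -(1:k), drop = FALSE]
  gd2 <- ref_up2_bwd(bw$gx[, , 1:k, drop = FALSE])
  bw <- ref_conv3_bwd(cd2$cols, p$w_dec2, gd2 * (cd2$out > 0), dim(cat2)[3])
  g$w_dec2 <- bw$gw
  g$b_dec2 <- bw$gb
  k <- dim(up2)[3]
  gskip2 <- bw$gx[, , -(1:k), drop = FALSE]
  gbt <- ref_up2_bwd(bw$gx[, , 1:k, drop = FALSE])
  bw <- ref_conv3_bwd(cb$cols, p$w_bott, gbt * (cb$out > 0), dim(pl2)[3])
  g$w_bott <- bw$gw
  g$b_bott <- bw$gb
  ge2 <- ref_pool2_bwd(e2, bw$gx) + gskip2
  bw <- ref_conv3_bwd(c2$cols, p$w_enc2, ge2 * (c2$out > 0), dim(pl1)[3])
  g$w_enc2 <- bw$gw
  g$b_enc2 <- bw$gb
  ge1 <- ref_pool2_bwd(e1, bw$gx) + gskip1
  bw <- ref_conv3_bwd(c1$cols, p$w_enc1, ge1 * (c1$out > 0), dim(cur)[3])
  g$w_enc1 <- bw$gw
  g$b_enc1 <- bw$gb
  list(prob = prob, grads = g)
}
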