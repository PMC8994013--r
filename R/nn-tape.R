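## Minimal reverse-mode automatic differentiation engine for the network
## module.  Activations are 4-D arrays (height, width, channel, sample);
## convolution is im2col + BLAS matrix multiply.  A "tape" records nodes
## in creation order; backward() replays it in reverse, accumulating
## gradients.  With tape = NULL every op runs in inference mode (values
## only, no caches kept).
##
## Correctness of every analytic gradient here is pinned by the
## finite-difference checks in the test suite.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

new_node <- function(tape, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  if (!is.null(tape)) {
    nd$parents <- parents
    nd$backfn <- backfn
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

accum_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd)
  }
  invisible(NULL)
}

## ---- parameter plumbing -------------------------------------------------

## Parameters live as a nested named list of numeric arrays; per training
## step the tree is wrapped into leaf nodes so gradients can be collected
## back in the same shape.
wrap_params <- function(tape, params) {
  if (is.list(params)) return(lapply(params, wrap_params, tape = tape))
  new_node(tape, params)
}

collect_grads <- function(pnodes) {
  if (is.list(pnodes)) return(lapply(pnodes, collect_grads))
  if (is.null(pnodes$grad)) {
    g <- pnodes$val
    g[] <- 0
    g
  } else pnodes$grad
}

sgd_step <- function(params, grads, lr) {
  if (is.list(params))
    return(mapply(sgd_step, params, grads, MoreArgs = list(lr = lr),
                  SIMPLIFY = FALSE))
  params - lr * grads
}

## ---- im2col cache -------------------------------------------------------

.conv_cache <- new.env(parent = emptyenv())

conv_plan <- function(Hp, Wp, C, kh, kw, stride) {
  key <- paste(Hp, Wp, C, kh, kw, stride, sep = "_")
  pl <- .conv_cache[[key]]
  if (!is.null(pl)) return(pl)
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  r0 <- rep(seq(1L, by = stride, length.out = Ho), times = Wo)
  c0 <- rep(seq(0L, by = stride, length.out = Wo), each = Ho)
  kr <- rep(seq_len(kh) - 1L, times = kw)
  kc <- rep(seq_len(kw) - 1L, each = kh)
  ## idx[loc, k]: linear index into one (Hp, Wp) plane; loc = r + Ho*(c-1)
  idx <- outer(r0, kr, "+") + Hp * outer(c0, kc, "+")
  idxC <- matrix(0L, Ho * Wo, kh * kw * C)
  for (ch in seq_len(C))
    idxC[, (ch - 1L) * kh * kw + seq_len(kh * kw)] <-
      idx + (ch - 1L) * Hp * Wp
  pl <- new.env(parent = emptyenv())
  pl$Ho <- Ho; pl$Wo <- Wo; pl$idx <- idx; pl$idxC <- idxC
  pl$plane <- Hp * Wp * C
  pl$batch <- list()
  .conv_cache[[key]] <- pl
  pl
}

## batched gather index: rows of idxC replicated per sample with the
## per-sample plane offset added, so im2col is a single vector gather
conv_batch_idx <- function(plan, N) {
  key <- as.character(N)
  bi <- plan$batch[[key]]
  if (!is.null(bi)) return(bi)
  HoWo <- plan$Ho * plan$Wo
  rows <- rep(seq_len(HoWo), times = N)
  off <- rep((seq_len(N) - 1) * plan$plane, each = HoWo)
  bi <- plan$idxC[rows, , drop = FALSE] + off
  plan$batch[[key]] <- bi
  bi
}

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  out[p + seq_len(d[1L]), p + seq_len(d[2L]), , ] <- x
  out
}

conv_im2col <- function(xp, C, N, plan, khkw) {
  bi <- conv_batch_idx(plan, N)
  cols <- as.vector(xp)[bi]
  dim(cols) <- dim(bi)
  cols
}

## ---- ops ----------------------------------------------------------------

op_input <- function(tape, x) new_node(tape, x)

op_conv2d <- function(tape, x, w_node, b_node, stride = 1L, pad = 0L) {
  w <- w_node$val
  kh <- dim(w)[1L]; kw <- dim(w)[2L]; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  xv <- x$val
  stopifnot(dim(xv)[3L] == cin)
  N <- dim(xv)[4L]
  xp <- pad_hw(xv, pad)
  plan <- conv_plan(dim(xp)[1L], dim(xp)[2L], cin, kh, kw, stride)
  cols <- conv_im2col(xp, cin, N, plan, kh * kw)
  wmat <- matrix(w, kh * kw * cin, cout)
  omat <- cols %*% wmat
  omat <- omat + rep(b_node$val, each = nrow(omat))
  out <- aperm(array(omat, c(plan$Ho, plan$Wo, N, cout)), c(1L, 2L, 4L, 3L))
  if (is.null(tape)) return(new_node(tape, out))
  Hp <- dim(xp)[1L]; Wp <- dim(xp)[2L]
  H <- dim(xv)[1L]; W <- dim(xv)[2L]
  node <- new_node(tape, out, parents = list(x, w_node, b_node),
    backfn = function(nd) {
      dout <- nd$grad
      HoWo <- plan$Ho * plan$Wo
      dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), HoWo * N, cout)
      accum_grad(b_node, colSums(dmat))
      accum_grad(w_node, array(crossprod(cols, dmat), dim(w)))
      dcols <- dmat %*% t(wmat)
      dxp <- numeric(Hp * Wp * cin * N)
      khkw <- kh * kw
      bi <- conv_batch_idx(plan, N)
      ## scatter-add per kernel offset: indices within one offset's
      ## column block are unique (overlaps only occur across offsets)
      for (k in seq_len(khkw)) {
        sel <- k + khkw * (seq_len(cin) - 1L)
        tgt <- bi[, sel]
        dxp[tgt] <- dxp[tgt] + dcols[, sel]
      }
      dxp <- array(dxp, c(Hp, Wp, cin, N))
      if (pad > 0L)
        dxp <- dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
      accum_grad(x, dxp)
    })
  node
}

op_relu <- function(tape, x) {
  out <- pmax(x$val, 0)
  if (is.null(tape)) return(new_node(tape, out))
  new_node(tape, out, parents = list(x), backfn = function(nd) {
    accum_grad(x, nd$grad * (x$val > 0))
  })
}

op_sigmoid <- function(tape, x) {
  out <- 1 / (1 + exp(-x$val))
  if (is.null(tape)) return(new_node(tape, out))
  new_node(tape, out, parents = list(x), backfn = function(nd) {
    accum_grad(x, nd$grad * out * (1 - out))
  })
}

op_add <- function(tape, a, b) {
  out <- a$val + b$val
  if (is.null(tape)) return(new_node(tape, out))
  new_node(tape, out, parents = list(a, b), backfn = function(nd) {
    accum_grad(a, nd$grad)
    accum_grad(b, nd$grad)
  })
}

## nearest-neighbour 2x spatial upsampling
op_upsample2 <- function(tape, x) {
  d <- dim(x$val)
  out <- x$val[rep(seq_len(d[1L]), each = 2L),
               rep(seq_len(d[2L]), each = 2L), , , drop = FALSE]
  if (is.null(tape)) return(new_node(tape, out))
  new_node(tape, out, parents = list(x), backfn = function(nd) {
    g <- nd$grad
    i1 <- seq(1L, 2L * d[1L], by = 2L); j1 <- seq(1L, 2L * d[2L], by = 2L)
    dx <- g[i1, j1, , , drop = FALSE] + g[i1 + 1L, j1, , , drop = FALSE] +
      g[i1, j1 + 1L, , , drop = FALSE] + g[i1 + 1L, j1 + 1L, , , drop = FALSE]
    accum_grad(x, dx)
  })
}

## crop to the top-left (Ho, Wo) window (aligns ceil-division FPN sizes)
op_crop_hw <- function(tape, x, Ho, Wo) {
  d <- dim(x$val)
  if (d[1L] == Ho && d[2L] == Wo) return(x)
  out <- x$val[seq_len(Ho), seq_len(Wo), , , drop = FALSE]
  if (is.null(tape)) return(new_node(tape, out))
  new_node(tape, out, parents = list(x), backfn = function(nd) {
    dx <- array(0, d)
    dx[seq_len(Ho), seq_len(Wo), , ] <- nd$grad
    accum_grad(x, dx)
  })
}

op_concat_c <- function(tape, a, b) {
  da <- dim(a$val); db <- dim(b$val)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a$val
  out[, , da[3L] + seq_len(db[3L]), ] <- b$val
  if (is.null(tape)) return(new_node(tape, out))
  new_node(tape, out, parents = list(a, b), backfn = function(nd) {
    accum_grad(a, nd$grad[, , seq_len(da[3L]), , drop = FALSE])
    accum_grad(b, nd$grad[, , da[3L] + seq_len(db[3L]), , drop = FALSE])
  })
}

## replicate a single-sample activation across N samples
op_broadcast_n <- function(tape, x, N) {
  out <- x$val[, , , rep(1L, N), drop = FALSE]
  if (is.null(tape)) return(new_node(tape, out))
  new_node(tape, out, parents = list(x), backfn = function(nd) {
    d <- dim(x$val)
    g <- matrix(nd$grad, d[1L] * d[2L] * d[3L], N)
    accum_grad(x, array(rowSums(g), d))
  })
}

## take a subset of the samples along the batch dimension
op_select_n <- function(tape, x, ns) {
  out <- x$val[, , , ns, drop = FALSE]
  if (is.null(tape)) return(new_node(tape, out))
  new_node(tape, out, parents = list(x), backfn = function(nd) {
    dx <- array(0, dim(x$val))
    dx[, , , ns] <- nd$grad
    accum_grad(x, dx)
  })
}

## ---- RoIAlign -----------------------------------------------------------

## Bilinear crop of per-sample boxes (one box per sample, input-image
## coordinates) into a fixed out_size x out_size grid, sampling one point
## per bin centre at sub-pixel positions; border values are replicated
## outside the map.  spatial_scale converts image to feature coordinates.
op_roi_align <- function(tape, x, boxes, out_size, spatial_scale) {
  d <- dim(x$val)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  boxes <- matrix(boxes, ncol = 4L)
  stopifnot(nrow(boxes) == N)
  if (any(boxes[, 3L] <= boxes[, 1L]) || any(boxes[, 4L] <= boxes[, 2L]))
    stop("degenerate RoI box")
  out <- array(0, c(out_size, out_size, C, N))
  plans <- vector("list", N)
  for (n in seq_len(N)) {
    fx1 <- boxes[n, 1L] * spatial_scale; fy1 <- boxes[n, 2L] * spatial_scale
    fx2 <- boxes[n, 3L] * spatial_scale; fy2 <- boxes[n, 4L] * spatial_scale
    bw <- (fx2 - fx1) / out_size; bh <- (fy2 - fy1) / out_size
    ## sample point centres (0-based continuous coords); rows vary fastest
    py <- fy1 + (rep(seq_len(out_size), times = out_size) - 0.5) * bh
    px <- fx1 + (rep(seq_len(out_size), each = out_size) - 0.5) * bw
    ly <- pmin(pmax(py - 0.5, 0), H - 1)
    lx <- pmin(pmax(px - 0.5, 0), W - 1)
    y0 <- pmin(floor(ly), H - 2); x0 <- pmin(floor(lx), W - 2)
    wy <- ly - y0; wx <- lx - x0
    i00 <- (y0 + 1L) + H * x0
    i10 <- i00 + 1L
    i01 <- i00 + H
    i11 <- i01 + 1L
    wmat <- cbind((1 - wy) * (1 - wx), wy * (1 - wx),
                  (1 - wy) * wx, wy * wx)
    imat <- cbind(i00, i10, i01, i11)
    xn <- matrix(x$val[, , , n], H * W, C)
    v <- wmat[, 1L] * xn[imat[, 1L], , drop = FALSE] +
      wmat[, 2L] * xn[imat[, 2L], , drop = FALSE] +
      wmat[, 3L] * xn[imat[, 3L], , drop = FALSE] +
      wmat[, 4L] * xn[imat[, 4L], , drop = FALSE]
    out[, , , n] <- array(v, c(out_size, out_size, C))
    plans[[n]] <- list(imat = imat, wmat = wmat)
  }
  if (is.null(tape)) return(new_node(tape, out))
  new_node(tape, out, parents = list(x), backfn = function(nd) {
    dx <- array(0, d)
    for (n in seq_len(N)) {
      dv <- matrix(nd$grad[, , , n], out_size * out_size, C)
      dplane <- matrix(0, H * W, C)
      pl <- plans[[n]]
      for (k in 1:4) {
        g <- rowsum(dv * pl$wmat[, k], group = pl$imat[, k])
        rows <- as.integer(rownames(g))
        dplane[rows, ] <- dplane[rows, ] + g
      }
      dx[, , , n] <- array(dplane, c(H, W, C))
    }
    accum_grad(x, dx)
  })
}

## ---- loss ops -----------------------------------------------------------

op_flatten <- function(tape, x) {
  d <- dim(x$val)
  out <- as.vector(x$val)
  if (is.null(tape)) return(new_node(tape, out))
  new_node(tape, out, parents = list(x), backfn = function(nd) {
    accum_grad(x, array(nd$grad, d))
  })
}

op_concat_vec <- function(tape, nodes) {
  lens <- vapply(nodes, function(n) length(n$val), integer(1L))
  out <- unlist(lapply(nodes, function(n) n$val), use.names = FALSE)
  if (is.null(tape)) return(new_node(tape, out))
  ends <- cumsum(lens)
  starts <- c(1L, ends[-length(ends)] + 1L)
  new_node(tape, out, parents = nodes, backfn = function(nd) {
    for (i in seq_along(nodes))
      accum_grad(nodes[[i]], nd$grad[starts[i]:ends[i]])
  })
}

## gather with unique indices (positive-anchor selection)
op_gather <- function(tape, x, idx) {
  out <- x$val[idx]
  if (is.null(tape)) return(new_node(tape, out))
  new_node(tape, out, parents = list(x), backfn = function(nd) {
    dx <- numeric(length(x$val))
    dx[idx] <- nd$grad
    accum_grad(x, dx)
  })
}

## focal classification loss over a probability vector; labels 1/0/NA
op_focal <- function(tape, p_node, labels, params) {
  npos <- max(sum(labels == 1, na.rm = TRUE), 1)
  val <- sum(focal_terms(labels, p_node$val, params)) / npos
  if (is.null(tape)) return(new_node(tape, val))
  new_node(tape, val, parents = list(p_node), backfn = function(nd) {
    p <- pmin(pmax(p_node$val, EPS_PROB), 1 - EPS_PROB)
    a <- params$alpha_t; g <- params$gamma
    dp <- numeric(length(p))
    pos <- which(!is.na(labels) & labels == 1)
    bg <- which(!is.na(labels) & labels == 0)
    if (length(pos)) {
      pp <- p[pos]
      dp[pos] <- a * g * (1 - pp)^(g - 1) * log(pp) - a * (1 - pp)^g / pp
    }
    if (length(bg)) {
      pb <- p[bg]
      dp[bg] <- -(1 - a) * g * pb^(g - 1) * log(1 - pb) +
        (1 - a) * pb^g / (1 - pb)
    }
    accum_grad(p_node, nd$grad * dp / npos)
  })
}

## smooth-L1 over residuals pred - target, mean over components
op_smooth_l1 <- function(tape, pred_node, target, sigma) {
  x <- pred_node$val - target
  val <- if (length(x) == 0L) 0 else mean(smooth_l1_terms(x, sigma))
  if (is.null(tape)) return(new_node(tape, val))
  new_node(tape, val, parents = list(pred_node), backfn = function(nd) {
    if (length(x) == 0L) return(invisible(NULL))
    dx <- ifelse(abs(x) < sigma, x / sigma, sign(x))
    accum_grad(pred_node, nd$grad * dx / length(x))
  })
}

## mean binary cross-entropy of a probability node against binary targets
op_bce <- function(tape, p_node, y) {
  p <- pmin(pmax(p_node$val, EPS_PROB), 1 - EPS_PROB)
  y <- as.numeric(y)
  val <- -mean(y * log(p) + (1 - y) * log(1 - p))
  if (is.null(tape)) return(new_node(tape, val))
  new_node(tape, val, parents = list(p_node), backfn = function(nd) {
    dp <- nd$grad * (-y / p + (1 - y) / (1 - p)) / length(p)
    if (!is.null(dim(p_node$val))) dp <- array(dp, dim(p_node$val))
    accum_grad(p_node, dp)
  })
}

op_weighted_sum <- function(tape, nodes, weights) {
  val <- sum(weights * vapply(nodes, function(n) n$val, numeric(1L)))
  if (is.null(tape)) return(new_node(tape, val))
  new_node(tape, val, parents = nodes, backfn = function(nd) {
    for (i in seq_along(nodes))
      accum_grad(nodes[[i]], nd$grad * weights[i])
  })
}
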