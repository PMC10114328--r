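# Minimal CNN engine: enough primitives for a bottleneck residual network
# with batch normalization, trained by SGD with momentum. Tensors are
# numeric arrays of dim c(H, W, C, N) (height, width, channels, batch).
# Convolution is im2col + BLAS GEMM; the gather index for each
# (shape, kernel, stride, pad, batch) combination is built once and cached.

.plan_cache <- new.env(parent = emptyenv())

conv_out_len <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

# Gather/scatter plan for an im2col convolution.
conv_plan <- function(H, W, C, N, k, s, p) {
  key <- paste(H, W, C, N, k, s, p, sep = "_")
  hit <- .plan_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- conv_out_len(H, k, s, p); Wo <- conv_out_len(W, k, s, p)
  # patch offsets ordered (dr, dc, ch); output bases ordered (i, j)
  poff <- as.vector(outer(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"),
                          (0:(C - 1L)) * (Hp * Wp), "+"))
  base <- as.vector(outer((0:(Ho - 1L)) * s, (0:(Wo - 1L)) * s * Hp, "+"))
  idx1 <- outer(as.integer(poff), as.integer(base), "+") + 1L
  per <- Hp * Wp * C
  fullidx <- rep(as.vector(idx1), N) +
    rep((0:(N - 1L)) * per, each = length(idx1))
  plan <- list(H = H, W = W, C = C, N = N, k = k, s = s, p = p,
               Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, fullidx = fullidx,
               ri = lapply(1:k, function(dr) dr + (0:(Ho - 1L)) * s),
               ci = lapply(1:k, function(dc) dc + (0:(Wo - 1L)) * s))
  .plan_cache[[key]] <- plan
  plan
}

pad_input <- function(x, p, fill = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, dim = c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  xp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , ] <- x
  xp
}

# Forward convolution. Wm is (C_out, k*k*C_in) with columns ordered like the
# im2col patch (dr, dc, ch). Returns the output tensor and the patch matrix
# needed by the backward pass.
conv_fwd <- function(x, Wm, k, s, p) {
  d <- dim(x)
  Cout <- nrow(Wm)
  if (k == 1L && s == 1L && p == 0L) {
    Xc <- matrix(aperm(x, c(3L, 1L, 2L, 4L)), nrow = d[3L])
    Ho <- d[1L]; Wo <- d[2L]
  } else {
    plan <- conv_plan(d[1L], d[2L], d[3L], d[4L], k, s, p)
    xp <- pad_input(x, p)
    Xc <- xp[plan$fullidx]
    dim(Xc) <- c(k * k * d[3L], plan$Ho * plan$Wo * d[4L])
    Ho <- plan$Ho; Wo <- plan$Wo
  }
  Y <- Wm %*% Xc
  out <- aperm(array(Y, dim = c(Cout, Ho, Wo, d[4L])), c(2L, 3L, 1L, 4L))
  list(out = out, Xc = Xc, in_dim = d)
}

# Backward convolution: gradients w.r.t. weights and input.
conv_bwd <- function(dout, Wm, Xc, in_dim, k, s, p) {
  dd <- dim(dout)
  Cout <- dd[3L]
  dYm <- matrix(aperm(dout, c(3L, 1L, 2L, 4L)), nrow = Cout)
  dW <- tcrossprod(dYm, Xc)
  dXc <- crossprod(Wm, dYm)
  if (k == 1L && s == 1L && p == 0L) {
    dX <- aperm(array(dXc, dim = c(in_dim[3L], in_dim[1L], in_dim[2L],
                                   in_dim[4L])), c(2L, 3L, 1L, 4L))
    return(list(dX = dX, dW = dW))
  }
  plan <- conv_plan(in_dim[1L], in_dim[2L], in_dim[3L], in_dim[4L], k, s, p)
  dXp <- array(0, dim = c(plan$Hp, plan$Wp, in_dim[3L], in_dim[4L]))
  dim(dXc) <- c(k, k, in_dim[3L], plan$Ho, plan$Wo, in_dim[4L])
  for (dr in 1:k) for (dc in 1:k) {
    sl <- dXc[dr, dc, , , , , drop = FALSE]
    dim(sl) <- c(in_dim[3L], plan$Ho, plan$Wo, in_dim[4L])
    ri <- plan$ri[[dr]]; ci <- plan$ci[[dc]]
    dXp[ri, ci, , ] <- dXp[ri, ci, , , drop = FALSE] +
      aperm(sl, c(2L, 3L, 1L, 4L))
  }
  dX <- if (p > 0L)
    dXp[(p + 1L):(p + in_dim[1L]), (p + 1L):(p + in_dim[2L]), , , drop = FALSE]
  else dXp
  list(dX = dX, dW = dW)
}

# --- batch normalization ----------------------------------------------------

bn_fwd <- function(x, ly, training, momentum = 0.9, eps = 1e-5,
                   refresh = FALSE) {
  d <- dim(x); HW <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
  if (training || refresh) {
    cm <- rowMeans(matrix(.colMeans(x, HW, C * N), C, N))
    e2 <- rowMeans(matrix(.colMeans(x * x, HW, C * N), C, N))
    cv <- pmax(e2 - cm^2, 0)
    if (refresh) {
      # statistics recalibration pass: accumulate batch stats, no momentum
      ly$acc_mean <- ly$acc_mean + cm
      ly$acc_var <- ly$acc_var + cv
      ly$acc_n <- ly$acc_n + 1L
    } else {
      ly$rmean <- momentum * ly$rmean + (1 - momentum) * cm
      ly$rvar <- momentum * ly$rvar + (1 - momentum) * cv
    }
  } else {
    cm <- ly$rmean; cv <- ly$rvar
  }
  inv <- 1 / sqrt(cv + eps)
  xhat <- x * rep(inv, each = HW) - rep(cm * inv, each = HW)
  out <- xhat * rep(ly$gamma, each = HW) + rep(ly$beta, each = HW)
  list(out = out, xhat = if (training && !refresh) xhat, inv = inv)
}

bn_bwd <- function(dy, ly, cache) {
  d <- dim(dy); HW <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
  M <- HW * N
  xhat <- cache$xhat
  dbeta <- rowSums(matrix(.colSums(dy, HW, C * N), C, N))
  dgamma <- rowSums(matrix(.colSums(dy * xhat, HW, C * N), C, N))
  ly$gbeta <- dbeta
  ly$ggamma <- dgamma
  gi <- ly$gamma * cache$inv
  dy * rep(gi, each = HW) -
    rep(gi * dbeta / M, each = HW) -
    xhat * rep(gi * dgamma / M, each = HW)
}

# --- max pooling (3x3 stride 2 in the stem) ---------------------------------

pool_fwd <- function(x, k = 3L, s = 2L, p = 1L) {
  d <- dim(x)
  plan <- conv_plan(d[1L], d[2L], d[3L], d[4L], k, s, p)
  xp <- pad_input(x, p, fill = -Inf)
  Xc <- xp[plan$fullidx]
  kk <- k * k
  ncol <- length(Xc) %/% kk
  dim(Xc) <- c(kk, ncol)                 # columns ordered (ch, opos, n)
  cur <- Xc[1L, ]
  amax <- rep(1L, ncol)
  for (r in 2:kk) {
    v <- Xc[r, ]
    upd <- v > cur
    amax[upd] <- r
    cur[upd] <- v[upd]
  }
  out <- aperm(array(cur, dim = c(d[3L], plan$Ho, plan$Wo, d[4L])),
               c(2L, 3L, 1L, 4L))
  fidx <- plan$fullidx
  dim(fidx) <- c(kk, ncol)
  tpos <- fidx[cbind(amax, seq_len(ncol))]
  list(out = out, tpos = tpos, plan = plan)
}

pool_bwd <- function(dy, cache) {
  plan <- cache$plan
  dyv <- as.vector(aperm(dy, c(3L, 1L, 2L, 4L)))
  acc <- rowsum(dyv, cache$tpos)         # groups sorted numerically
  dXp <- numeric(plan$Hp * plan$Wp * plan$C * plan$N)
  dXp[sort(unique(cache$tpos))] <- acc
  dim(dXp) <- c(plan$Hp, plan$Wp, plan$C, plan$N)
  p <- plan$p
  dXp[(p + 1L):(p + plan$H), (p + 1L):(p + plan$W), , , drop = FALSE]
}

# --- global average pooling and the sigmoid head ----------------------------

gap_fwd <- function(x) {
  d <- dim(x)
  matrix(.colMeans(x, d[1L] * d[2L], d[3L] * d[4L]), d[3L], d[4L])
}

gap_bwd <- function(dy, in_dim) {
  HW <- in_dim[1L] * in_dim[2L]
  array(rep(as.vector(dy) / HW, each = HW), dim = in_dim)
}

relu <- function(x) x * (x > 0)

sigmoid <- function(z) 1 / (1 + exp(-z))
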