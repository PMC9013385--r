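# Native network primitives: 3D/2D convolutions via im2col + BLAS, pooling,
# strided transposed convolution, batch normalisation, attention gating and a
# convolutional LSTM, each with a hand-written backward pass. Gradients are
# validated against central finite differences in the test suite.

.nn_idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (is.null(.nn_idx_cache[[key]])) .nn_idx_cache[[key]] <- make()
  .nn_idx_cache[[key]]
}

# gather indices for 3x3x3 same-padding im2col on a (D,H,W) grid
conv3_idx <- function(D, H, W) {
  cache_get(sprintf("c3_%d_%d_%d", D, H, W), function() {
    Dp <- D + 2L; Hp <- H + 2L
    od <- rep(seq_len(D), times = H * W)
    oh <- rep(rep(seq_len(H), each = D), times = W)
    ow <- rep(seq_len(W), each = D * H)
    idx <- matrix(0L, D * H * W, 27L)
    for (k3 in 1:3) for (k2 in 1:3) for (k1 in 1:3) {
      o <- k1 + 3L * (k2 - 1L) + 9L * (k3 - 1L)
      idx[, o] <- (od + k1 - 1L) + Dp * (oh + k2 - 2L) + Dp * Hp * (ow + k3 - 2L)
    }
    idx
  })
}

im2col3 <- function(x) {
  d <- dim(x); D <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  xp <- array(0, c(D + 2L, H + 2L, W + 2L, C))
  xp[2:(D + 1L), 2:(H + 1L), 2:(W + 1L), ] <- x
  xpm <- matrix(xp, ncol = C)
  idx <- conv3_idx(D, H, W)
  N <- D * H * W
  P <- matrix(0, N, 27L * C)
  iv <- as.vector(idx)
  for (cc in seq_len(C)) {
    P[, (cc - 1L) * 27L + (1:27)] <- xpm[iv, cc]
  }
  P
}

conv3d_forward <- function(x, W5, b) {
  d <- dim(x); N <- prod(d[1:3]); Cout <- dim(W5)[5]
  P <- im2col3(x)
  y <- P %*% matrix(W5, ncol = Cout)
  y <- y + rep(b, each = N)
  list(y = array(y, c(d[1:3], Cout)), P = P, in_dim = d)
}

conv3d_backward <- function(dy, W5, cache) {
  d <- cache$in_dim; N <- prod(d[1:3]); Cout <- dim(W5)[5]
  dYm <- matrix(dy, N, Cout)
  dW <- array(crossprod(cache$P, dYm), dim(W5))
  db <- colSums(dYm)
  Wf <- aperm(W5[3:1, 3:1, 3:1, , , drop = FALSE], c(1, 2, 3, 5, 4))
  dx <- conv3d_forward(array(dy, c(d[1:3], Cout)), Wf, numeric(d[4]))$y
  list(dx = dx, dW = dW, db = db)
}

# 2D analogue (used inside the convolutional LSTM), 3x3 same padding
conv2_idx <- function(H, W) {
  cache_get(sprintf("c2_%d_%d", H, W), function() {
    Hp <- H + 2L
    oh <- rep(seq_len(H), times = W)
    ow <- rep(seq_len(W), each = H)
    idx <- matrix(0L, H * W, 9L)
    for (k2 in 1:3) for (k1 in 1:3) {
      o <- k1 + 3L * (k2 - 1L)
      idx[, o] <- (oh + k1 - 1L) + Hp * (ow + k2 - 2L)
    }
    idx
  })
}

im2col2 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  xpm <- matrix(xp, ncol = C)
  idx <- conv2_idx(H, W)
  N <- H * W
  P <- matrix(0, N, 9L * C)
  iv <- as.vector(idx)
  for (cc in seq_len(C)) P[, (cc - 1L) * 9L + (1:9)] <- xpm[iv, cc]
  P
}

conv2d_forward <- function(x, W4, b = NULL) {
  d <- dim(x); N <- prod(d[1:2]); Cout <- dim(W4)[4]
  P <- im2col2(x)
  y <- P %*% matrix(W4, ncol = Cout)
  if (!is.null(b)) y <- y + rep(b, each = N)
  list(y = array(y, c(d[1:2], Cout)), P = P, in_dim = d)
}

conv2d_backward_data <- function(dy, W4, in_dim) {
  Cout <- dim(W4)[4]
  Wf <- aperm(W4[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))
  conv2d_forward(array(dy, c(in_dim[1:2], Cout)), Wf)$y
}

# pointwise (1x1x1) convolution: a channel-mixing matrix product
conv1x1_forward <- function(x, Wm, b) {
  d <- dim(x); N <- prod(d[-length(d)])
  Xm <- matrix(x, N)
  y <- Xm %*% Wm + rep(b, each = N)
  list(y = array(y, c(d[-length(d)], ncol(Wm))), Xm = Xm, in_dim = d)
}

conv1x1_backward <- function(dy, Wm, cache) {
  N <- nrow(cache$Xm)
  dYm <- matrix(dy, N)
  list(dx = array(dYm %*% t(Wm), cache$in_dim),
       dW = crossprod(cache$Xm, dYm), db = colSums(dYm))
}

relu_forward <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_backward <- function(dy, cache) dy * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# batch normalisation over all spatial positions, per channel (batch of one
# 3D block, so this is instance normalisation in batch-norm clothing)
bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[length(d)]; N <- prod(d[-length(d)])
  Xm <- matrix(x, N, C)
  if (training) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2L, mu)
    v <- colMeans(xc^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- sweep(Xm, 2L, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = array(y, d), xhat = xhat, istd = istd, in_dim = d,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$in_dim; C <- d[length(d)]; N <- prod(d[-length(d)])
  dYm <- matrix(dy, N, C)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2L, s1 / N) - sweep(cache$xhat, 2L, s2 / N, `*`)
  dx <- sweep(dx, 2L, cache$istd, `*`)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

pool_idx <- function(D, H, W) {
  # linear indices into the input (per channel) for each of the 8 corners of
  # every 2x2x2 pooling cell
  cache_get(sprintf("p_%d_%d_%d", D, H, W), function() {
    D2 <- D %/% 2L; H2 <- H %/% 2L; W2 <- W %/% 2L
    od <- rep(seq_len(D2), times = H2 * W2)
    oh <- rep(rep(seq_len(H2), each = D2), times = W2)
    ow <- rep(seq_len(W2), each = D2 * H2)
    idx <- matrix(0L, D2 * H2 * W2, 8L)
    o <- 0L
    for (k3 in 1:2) for (k2 in 1:2) for (k1 in 1:2) {
      o <- o + 1L
      idx[, o] <- (2L * od - 2L + k1) + D * (2L * oh - 3L + k2) +
        D * H * (2L * ow - 3L + k3)
    }
    idx
  })
}

maxpool_forward <- function(x) {
  d <- dim(x)
  if (any(d[1:3] %% 2L != 0L)) abort("pooling needs even spatial dims.")
  C <- d[4]; D2 <- d[1] %/% 2L; H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
  idx <- pool_idx(d[1], d[2], d[3])
  N2 <- nrow(idx); Nin <- prod(d[1:3])
  y <- array(0, c(D2, H2, W2, C))
  arg <- matrix(0L, N2, C)
  xm <- matrix(x, ncol = C)
  for (cc in seq_len(C)) {
    M <- matrix(xm[as.vector(idx), cc], N2, 8L)
    a <- max.col(M, ties.method = "first")
    arg[, cc] <- idx[cbind(seq_len(N2), a)] + (cc - 1L) * Nin
    y[, , , cc] <- M[cbind(seq_len(N2), a)]
  }
  list(y = y, arg = arg, in_dim = d)
}

maxpool_backward <- function(dy, cache) {
  dx <- array(0, cache$in_dim)
  C <- cache$in_dim[4]
  dym <- matrix(dy, ncol = C)
  for (cc in seq_len(C)) dx[cache$arg[, cc]] <- dym[, cc]
  dx
}

upconv_idx <- function(D, H, W) {
  # output spatial linear indices written by each of the 8 kernel offsets of a
  # 2x2x2 stride-2 transposed convolution (cells are disjoint)
  cache_get(sprintf("u_%d_%d_%d", D, H, W), function() {
    D2 <- 2L * D; H2 <- 2L * H
    od <- rep(seq_len(D), times = H * W)
    oh <- rep(rep(seq_len(H), each = D), times = W)
    ow <- rep(seq_len(W), each = D * H)
    idx <- matrix(0L, D * H * W, 8L)
    o <- 0L
    for (k3 in 1:2) for (k2 in 1:2) for (k1 in 1:2) {
      o <- o + 1L
      idx[, o] <- (2L * od - 2L + k1) + D2 * (2L * oh - 3L + k2) +
        D2 * H2 * (2L * ow - 3L + k3)
    }
    idx
  })
}

upconv_forward <- function(x, W5, b) {
  # W5: (2,2,2,Cin,Cout)
  d <- dim(x); Cin <- d[4]; Cout <- dim(W5)[5]
  N <- prod(d[1:3])
  Xm <- matrix(x, N, Cin)
  idx <- upconv_idx(d[1], d[2], d[3])
  Nout <- 8L * N
  Ym <- matrix(0, Nout, Cout)
  Wm <- matrix(W5, ncol = Cout)  # rows: offset-major then channel
  for (o in 1:8) {
    Wo <- Wm[o + 8L * (seq_len(Cin) - 1L), , drop = FALSE]
    Ym[idx[, o], ] <- Xm %*% Wo
  }
  Ym <- sweep(Ym, 2L, b, `+`)
  list(y = array(Ym, c(2L * d[1], 2L * d[2], 2L * d[3], Cout)),
       Xm = Xm, in_dim = d)
}

upconv_backward <- function(dy, W5, cache) {
  d <- cache$in_dim; Cin <- d[4]; Cout <- dim(W5)[5]
  N <- prod(d[1:3])
  idx <- upconv_idx(d[1], d[2], d[3])
  dYm <- matrix(dy, ncol = Cout)
  Wm <- matrix(W5, ncol = Cout)
  dX <- matrix(0, N, Cin)
  dW <- array(0, dim(W5))
  dWm <- matrix(dW, ncol = Cout)
  for (o in 1:8) {
    rows <- o + 8L * (seq_len(Cin) - 1L)
    dYo <- dYm[idx[, o], , drop = FALSE]
    dX <- dX + dYo %*% t(Wm[rows, , drop = FALSE])
    dWm[rows, ] <- crossprod(cache$Xm, dYo)
  }
  list(dx = array(dX, d), dW = array(dWm, dim(W5)), db = colSums(dYm))
}

# additive attention gate: alpha = sigmoid(psi(relu(Ws s + Wg g + b)))
attention_forward <- function(s, g, par) {
  d <- dim(s); N <- prod(d[1:3])
  Sm <- matrix(s, N); Gm <- matrix(g, N)
  pre <- Sm %*% par$Ws + Gm %*% par$Wg + rep(par$b, each = N)
  act <- pmax(pre, 0)
  alpha <- sigmoid(act %*% par$psi_W + par$psi_b[1])
  Ym <- Sm * as.vector(alpha)
  list(y = array(Ym, d), alpha = array(alpha, d[1:3]),
       Sm = Sm, Gm = Gm, act = act, mask = pre > 0, a = as.vector(alpha),
       in_dim = d, g_dim = dim(g))
}

attention_backward <- function(dy, par, cache) {
  d <- cache$in_dim; N <- prod(d[1:3])
  dYm <- matrix(dy, N)
  dS <- dYm * cache$a
  dalpha <- rowSums(dYm * cache$Sm)
  dpre_psi <- dalpha * cache$a * (1 - cache$a)
  dpsi_W <- crossprod(cache$act, dpre_psi)
  dpsi_b <- sum(dpre_psi)
  dact <- (dpre_psi %*% t(par$psi_W)) * cache$mask
  list(
    ds = array(dS + dact %*% t(par$Ws), d),
    dg = array(dact %*% t(par$Wg), cache$g_dim),
    dWs = crossprod(cache$Sm, dact),
    dWg = crossprod(cache$Gm, dact),
    db = colSums(dact),
    dpsi_W = dpsi_W, dpsi_b = dpsi_b
  )
}

# convolutional LSTM along the slice axis; hidden channels = input channels
clstm_forward <- function(x, par) {
  d <- dim(x)  # (D, H, W, C)
  if (d[1] < 1L) abort("CLSTM needs a non-empty slice sequence.")
  C <- d[4]
  h <- array(0, c(d[2], d[3], C))
  cst <- h
  steps <- vector("list", d[1])
  y <- array(0, d)
  for (t in seq_len(d[1])) {
    xt <- array(x[t, , , ], c(d[2], d[3], C))
    cx <- conv2d_forward(xt, par$Wx)
    ch <- conv2d_forward(h, par$Wh)
    Nhw <- prod(d[2:3])
    z <- cx$y + ch$y + rep(par$b, each = Nhw)
    zi <- sigmoid(z[, , 1:C, drop = FALSE])
    zf <- sigmoid(z[, , C + (1:C), drop = FALSE])
    zo <- sigmoid(z[, , 2L * C + (1:C), drop = FALSE])
    zg <- tanh(z[, , 3L * C + (1:C), drop = FALSE])
    c_prev <- cst
    cst <- zf * c_prev + zi * zg
    tc <- tanh(cst)
    h <- zo * tc
    y[t, , , ] <- h
    steps[[t]] <- list(Px = cx$P, Ph = ch$P, i = zi, f = zf, o = zo, g = zg,
                       c_prev = c_prev, tc = tc)
  }
  list(y = y, steps = steps, in_dim = d)
}

clstm_backward <- function(dy, par, cache) {
  d <- cache$in_dim; C <- d[4]
  dWx <- array(0, dim(par$Wx)); dWh <- array(0, dim(par$Wh))
  db <- numeric(4L * C)
  dx <- array(0, d)
  dh_next <- array(0, c(d[2], d[3], C))
  dc_next <- dh_next
  hw_dim <- c(d[2], d[3], C)
  for (t in rev(seq_len(d[1]))) {
    st <- cache$steps[[t]]
    dh <- array(dy[t, , , ], hw_dim) + dh_next
    do_ <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_next <- dc * st$f
    dz <- array(0, c(d[2], d[3], 4L * C))
    dz[, , 1:C] <- di * st$i * (1 - st$i)
    dz[, , C + (1:C)] <- df * st$f * (1 - st$f)
    dz[, , 2L * C + (1:C)] <- do_ * st$o * (1 - st$o)
    dz[, , 3L * C + (1:C)] <- dg * (1 - st$g^2)
    dZm <- matrix(dz, ncol = 4L * C)
    dWx <- dWx + array(crossprod(st$Px, dZm), dim(par$Wx))
    dWh <- dWh + array(crossprod(st$Ph, dZm), dim(par$Wh))
    db <- db + colSums(dZm)
    dx[t, , , ] <- conv2d_backward_data(dz, par$Wx, c(d[2], d[3], C))
    dh_next <- conv2d_backward_data(dz, par$Wh, c(d[2], d[3], C))
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

# nearest-neighbour downsampling of a binary target by 2^k per axis, for the
# deep-supervision heads
downsample_mask <- function(m, k) {
  if (k == 0L) return(m)
  step <- 2L^k
  d <- dim(m)
  m[seq(1L, d[1], by = step), seq(1L, d[2], by = step),
    seq(1L, d[3], by = step), drop = FALSE]
}
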