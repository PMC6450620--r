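# Minimal dense/convolutional regression engine for 8x9 grids.
#
# Activations for a batch of N samples with C channels are stored as an
# (N*72) x C matrix: rows are sample-major, positions within a sample are
# the column-major cells of the 8x9 grid. 3x3 "same" convolution is
# implemented by im2col gathering (zero padding) followed by a single
# matrix multiply, which keeps both the forward and the backward pass in
# BLAS. All parameters are plain R matrices; Adam state lives beside them.

NROW_GRID <- 8L
NCOL_GRID <- 9L
NPOS <- 72L

# 72 x 9 neighbour table for 3x3 same convolution (0 = zero padding).
conv3_index <- local({
  idx <- NULL
  function() {
    if (!is.null(idx)) return(idx)
    pos <- expand.grid(r = 1:NROW_GRID, c = 1:NCOL_GRID)
    off <- expand.grid(dr = -1:1, dc = -1:1)
    m <- matrix(0L, NPOS, 9L)
    for (q in 1:9) {
      r <- pos$r + off$dr[q]
      c <- pos$c + off$dc[q]
      ok <- r >= 1 & r <= NROW_GRID & c >= 1 & c <= NCOL_GRID
      m[ok, q] <- (c[ok] - 1L) * NROW_GRID + r[ok]
    }
    idx <<- m
    idx
  }
})

# Batch-expanded neighbour index, (N*72) x 9.
batch_index <- function(n) {
  base <- conv3_index()
  offset <- rep((seq_len(n) - 1L) * NPOS, each = NPOS)
  idx <- base[rep(seq_len(NPOS), n), , drop = FALSE]
  nz <- idx > 0L
  idx[nz] <- idx[nz] + offset[row(idx)[nz]]
  idx
}

im2col <- function(A, idx) {
  cin <- ncol(A)
  out <- matrix(0, nrow(A), 9L * cin)
  for (q in 1:9) {
    nz <- idx[, q] > 0L
    out[nz, ((q - 1L) * cin + 1L):(q * cin)] <- A[idx[nz, q], , drop = FALSE]
  }
  out
}

col2im <- function(dX, idx, cin) {
  dA <- matrix(0, nrow(dX), cin)
  for (q in 1:9) {
    nz <- idx[, q] > 0L
    cols <- ((q - 1L) * cin + 1L):(q * cin)
    tgt <- idx[nz, q]
    dA[tgt, ] <- dA[tgt, ] + dX[nz, cols, drop = FALSE]
  }
  dA
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dim = dims)
}

# ---- parameterised pieces ---------------------------------------------------

new_conv3 <- function(cin, cout) {
  list(W = glorot_uniform(9 * cin, 9 * cout, c(9L * cin, cout)),
       b = numeric(cout))
}

new_conv1 <- function(cin, cout) {
  list(W = glorot_uniform(cin, cout, c(cin, cout)), b = numeric(cout))
}

new_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

conv3_fwd <- function(p, A, idx) {
  X <- im2col(A, idx)
  list(out = X %*% p$W + matrix(p$b, nrow(X), length(p$b), byrow = TRUE),
       X = X, cin = ncol(A))
}

conv3_bwd <- function(p, cache, dY, idx) {
  list(dA = col2im(dY %*% t(p$W), idx, cache$cin),
       dW = crossprod(cache$X, dY), db = colSums(dY))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_fwd <- function(p, X, training) {
  if (training) {
    mu <- colMeans(X)
    xc <- X - matrix(mu, nrow(X), ncol(X), byrow = TRUE)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * matrix(inv, nrow(X), ncol(X), byrow = TRUE)
    p$run_mean <- BN_MOMENTUM * p$run_mean + (1 - BN_MOMENTUM) * mu
    p$run_var <- BN_MOMENTUM * p$run_var + (1 - BN_MOMENTUM) * v
    out <- xhat * matrix(p$gamma, nrow(X), ncol(X), byrow = TRUE) +
      matrix(p$beta, nrow(X), ncol(X), byrow = TRUE)
    list(out = out, xhat = xhat, inv = inv, p = p)
  } else {
    inv <- 1 / sqrt(p$run_var + BN_EPS)
    xhat <- (X - matrix(p$run_mean, nrow(X), ncol(X), byrow = TRUE)) *
      matrix(inv, nrow(X), ncol(X), byrow = TRUE)
    out <- xhat * matrix(p$gamma, nrow(X), ncol(X), byrow = TRUE) +
      matrix(p$beta, nrow(X), ncol(X), byrow = TRUE)
    list(out = out, xhat = xhat, inv = inv, p = p)
  }
}

bn_bwd <- function(p, cache, dY) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * matrix(p$gamma, n, ncol(dY), byrow = TRUE)
  mean1 <- colMeans(dxhat)
  mean2 <- colMeans(dxhat * cache$xhat)
  dX <- (dxhat -
           matrix(mean1, n, ncol(dY), byrow = TRUE) -
           cache$xhat * matrix(mean2, n, ncol(dY), byrow = TRUE)) *
    matrix(cache$inv, n, ncol(dY), byrow = TRUE)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# conv3 (+ BN) + ReLU unit
new_unit <- function(cin, cout, use_bn = TRUE) {
  u <- list(conv = new_conv3(cin, cout), use_bn = use_bn)
  if (use_bn) u$bn <- new_bn(cout)
  u
}

unit_fwd <- function(u, A, idx, training) {
  cv <- conv3_fwd(u$conv, A, idx)
  z <- cv$out
  bn_cache <- NULL
  if (u$use_bn) {
    bn_cache <- bn_fwd(u$bn, z, training)
    u$bn <- bn_cache$p
    z <- bn_cache$out
  }
  relu_mask <- z > 0
  list(out = z * relu_mask, unit = u,
       cache = list(conv = cv, bn = bn_cache, relu = relu_mask))
}

unit_bwd <- function(u, cache, dY, idx) {
  dz <- dY * cache$relu
  g <- list()
  if (u$use_bn) {
    bb <- bn_bwd(u$bn, cache$bn, dz)
    dz <- bb$dX
    g$gamma <- bb$dgamma
    g$beta <- bb$dbeta
  }
  cb <- conv3_bwd(u$conv, cache$conv, dz, idx)
  g$W <- cb$dW
  g$b <- cb$db
  list(dA = cb$dA, grads = g)
}

# ---- whole-network forward/backward ----------------------------------------
# A model is list(spec, in_channels, blocks, head, fc). Conv families hold
# `blocks` (list of blocks, each a list of units, plus optional residual
# projection conv) and `head` (1x1 linear conv). The fully connected family
# holds `fc` (W1, b1, W2, b2).

net_forward <- function(model, A, n, training = FALSE) {
  spec <- model$spec
  if (spec$family == "fully_connected") {
    Xf <- flatten_batch(A, n)
    H <- Xf %*% model$fc$W1 +
      matrix(model$fc$b1, n, length(model$fc$b1), byrow = TRUE)
    relu_mask <- H > 0
    Hr <- H * relu_mask
    pred <- Hr %*% model$fc$W2 +
      matrix(model$fc$b2, n, length(model$fc$b2), byrow = TRUE)
    return(list(pred = pred, model = model,
                cache = list(Xf = Xf, relu = relu_mask, Hr = Hr)))
  }
  idx <- batch_index(n)
  feats <- list(A)  # concatenation pool (cascade) / running activation
  caches <- vector("list", length(model$blocks))
  cur <- A
  for (bi in seq_along(model$blocks)) {
    blk <- model$blocks[[bi]]
    blk_in <- if (spec$family == "cascade") do.call(cbind, feats) else cur
    ucaches <- vector("list", length(blk$units))
    h <- blk_in
    for (ui in seq_along(blk$units)) {
      r <- unit_fwd(blk$units[[ui]], h, idx, training)
      blk$units[[ui]] <- r$unit
      ucaches[[ui]] <- r$cache
      h <- r$out
    }
    proj_cache <- NULL
    if (spec$family == "residual") {
      if (!is.null(blk$proj)) {
        skip <- blk_in %*% blk$proj$W +
          matrix(blk$proj$b, nrow(blk_in), length(blk$proj$b), byrow = TRUE)
      } else {
        skip <- blk_in
      }
      proj_cache <- blk_in
      h <- h + skip
    }
    caches[[bi]] <- list(units = ucaches, blk_in = blk_in, proj = proj_cache)
    model$blocks[[bi]] <- blk
    if (spec$family == "cascade") feats <- c(feats, list(h)) else cur <- h
  }
  head_in <- if (spec$family == "cascade") do.call(cbind, feats) else cur
  pred72 <- head_in %*% model$head$W +
    matrix(model$head$b, nrow(head_in), 1L, byrow = TRUE)
  pred <- matrix(pred72, n, NPOS, byrow = TRUE)
  list(pred = pred, model = model,
       cache = list(caches = caches, head_in = head_in, idx = idx))
}

net_backward <- function(model, fwd, dPred) {
  spec <- model$spec
  n <- nrow(dPred)
  grads <- list()
  if (spec$family == "fully_connected") {
    ca <- fwd$cache
    grads$fc_W2 <- crossprod(ca$Hr, dPred)
    grads$fc_b2 <- colSums(dPred)
    dH <- (dPred %*% t(model$fc$W2)) * ca$relu
    grads$fc_W1 <- crossprod(ca$Xf, dH)
    grads$fc_b1 <- colSums(dH)
    return(grads)
  }
  idx <- fwd$cache$idx
  dHead72 <- matrix(t(dPred), ncol = 1L)  # back to (N*72) x 1
  grads$head_W <- crossprod(fwd$cache$head_in, dHead72)
  grads$head_b <- sum(dHead72)
  dHeadIn <- dHead72 %*% t(model$head$W)

  nb <- length(model$blocks)
  widths <- vapply(model$blocks, function(b) b$out_channels, integer(1))
  if (spec$family == "cascade") {
    # split head gradient over [input, out_1, ..., out_k]
    cuts <- cumsum(c(model$in_channels, widths))
    dpool <- vector("list", nb + 1L)
    dpool[[1L]] <- dHeadIn[, seq_len(model$in_channels), drop = FALSE]
    for (bi in seq_len(nb)) {
      dpool[[bi + 1L]] <- dHeadIn[, (cuts[bi] + 1L):cuts[bi + 1L],
                                  drop = FALSE]
    }
  } else {
    dcur <- dHeadIn
  }

  for (bi in rev(seq_len(nb))) {
    blk <- model$blocks[[bi]]
    ca <- fwd$cache$caches[[bi]]
    dOut <- if (spec$family == "cascade") dpool[[bi + 1L]] else dcur
    dSkip <- NULL
    if (spec$family == "residual") {
      if (!is.null(blk$proj)) {
        grads[[paste0("b", bi, "_proj_W")]] <- crossprod(ca$proj, dOut)
        grads[[paste0("b", bi, "_proj_b")]] <- colSums(dOut)
        dSkip <- dOut %*% t(blk$proj$W)
      } else {
        dSkip <- dOut
      }
    }
    dh <- dOut
    for (ui in rev(seq_along(blk$units))) {
      ub <- unit_bwd(blk$units[[ui]], ca$units[[ui]], dh, idx)
      dh <- ub$dA
      pref <- paste0("b", bi, "_u", ui, "_")
      for (nm in names(ub$grads)) grads[[paste0(pref, nm)]] <- ub$grads[[nm]]
    }
    dIn <- dh
    if (!is.null(dSkip)) dIn <- dIn + dSkip
    if (spec$family == "cascade") {
      # block input was cbind(input, out_1, ..., out_{bi-1})
      cuts <- cumsum(c(model$in_channels, widths[seq_len(bi - 1L)]))
      dpool[[1L]] <- dpool[[1L]] +
        dIn[, seq_len(model$in_channels), drop = FALSE]
      for (j in seq_len(bi - 1L)) {
        dpool[[j + 1L]] <- dpool[[j + 1L]] +
          dIn[, (cuts[j] + 1L):cuts[j + 1L], drop = FALSE]
      }
    } else {
      dcur <- dIn
    }
  }
  grads
}

flatten_batch <- function(A, n) {
  # (N*72) x C -> N x (72*C), cell-major within channel
  cin <- ncol(A)
  out <- matrix(0, n, NPOS * cin)
  for (c in seq_len(cin)) {
    out[, ((c - 1L) * NPOS + 1L):(c * NPOS)] <-
      matrix(A[, c], n, NPOS, byrow = TRUE)
  }
  out
}

# ---- parameter bookkeeping --------------------------------------------------

# Flatten model parameters to a named list (BN running stats excluded).
collect_params <- function(model) {
  out <- list()
  if (model$spec$family == "fully_connected") {
    out$fc_W1 <- model$fc$W1; out$fc_b1 <- model$fc$b1
    out$fc_W2 <- model$fc$W2; out$fc_b2 <- model$fc$b2
    return(out)
  }
  for (bi in seq_along(model$blocks)) {
    blk <- model$blocks[[bi]]
    for (ui in seq_along(blk$units)) {
      u <- blk$units[[ui]]
      pref <- paste0("b", bi, "_u", ui, "_")
      out[[paste0(pref, "W")]] <- u$conv$W
      out[[paste0(pref, "b")]] <- u$conv$b
      if (u$use_bn) {
        out[[paste0(pref, "gamma")]] <- u$bn$gamma
        out[[paste0(pref, "beta")]] <- u$bn$beta
      }
    }
    if (!is.null(blk$proj)) {
      out[[paste0("b", bi, "_proj_W")]] <- blk$proj$W
      out[[paste0("b", bi, "_proj_b")]] <- blk$proj$b
    }
  }
  out$head_W <- model$head$W
  out$head_b <- model$head$b
  out
}

# Write a named parameter list back into the model structure.
assign_params <- function(model, params) {
  if (model$spec$family == "fully_connected") {
    model$fc$W1 <- params$fc_W1; model$fc$b1 <- params$fc_b1
    model$fc$W2 <- params$fc_W2; model$fc$b2 <- params$fc_b2
    return(model)
  }
  for (bi in seq_along(model$blocks)) {
    for (ui in seq_along(model$blocks[[bi]]$units)) {
      pref <- paste0("b", bi, "_u", ui, "_")
      model$blocks[[bi]]$units[[ui]]$conv$W <- params[[paste0(pref, "W")]]
      model$blocks[[bi]]$units[[ui]]$conv$b <- params[[paste0(pref, "b")]]
      if (model$blocks[[bi]]$units[[ui]]$use_bn) {
        model$blocks[[bi]]$units[[ui]]$bn$gamma <-
          params[[paste0(pref, "gamma")]]
        model$blocks[[bi]]$units[[ui]]$bn$beta <-
          params[[paste0(pref, "beta")]]
      }
    }
    if (!is.null(model$blocks[[bi]]$proj)) {
      model$blocks[[bi]]$proj$W <- params[[paste0("b", bi, "_proj_W")]]
      model$blocks[[bi]]$proj$b <- params[[paste0("b", bi, "_proj_b")]]
    }
  }
  model$head$W <- params$head_W
  model$head$b <- params$head_b
  model
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- beta1 * state$m[[nm]] + (1 - beta1) * g
    v <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = params, state = state)
}
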