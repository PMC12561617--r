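# Internal network engine: layers are plain lists tagged by `type`, a
# network is an ordered list of layers. Forward passes return caches that
# the matching backward passes consume; parameter updates go through
# slot accessors so Adam, LoRA freezing and prune masks all see the same
# parameter tree.

new_layer <- function(type, name, stage = 0L, ...) {
  c(list(type = type, name = name, stage = as.integer(stage)), list(...))
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

layer_conv <- function(name, in_ch, out_ch, kh, kw = kh, pad = same_pad(kh, kw),
                       groups = 1L, bias = TRUE, stage = 0L, W = NULL, b = NULL) {
  cg <- in_ch %/% groups
  if (is.null(W)) W <- he_init(c(kh, kw, cg, out_ch), kh * kw * cg)
  if (bias && is.null(b)) b <- numeric(out_ch)
  new_layer("conv", name, stage, W = W, b = b, pad = as.integer(pad),
            groups = as.integer(groups), frozen = FALSE,
            lora = NULL, mask = NULL)
}

layer_dense <- function(name, n_in, n_out, stage = 0L, W = NULL, b = NULL) {
  if (is.null(W)) W <- matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)),
                              n_out, n_in)
  if (is.null(b)) b <- numeric(n_out)
  new_layer("dense", name, stage, W = W, b = b, frozen = FALSE,
            lora = NULL, mask = NULL)
}

layer_relu    <- function(name, stage = 0L) new_layer("relu", name, stage)
layer_maxpool <- function(name, stage = 0L) new_layer("maxpool", name, stage)
layer_flatten <- function(name, stage = 0L) new_layer("flatten", name, stage)

layer_l2sab <- function(name, kernel_size, stage = 0L, eps = 1e-6) {
  p <- l2sab_params(kernel_size)
  new_layer("l2sab", name, stage, k = p$kernel_size, W = p$weights,
            b = p$bias, eps = eps, frozen = FALSE, lora = NULL, mask = NULL)
}

layer_gct <- function(name, c, stage = 0L, eps = 1e-6) {
  new_layer("gct", name, stage, c = as.numeric(c), eps = eps)
}

# effective weight = (base + LoRA delta) * mask, as an array shaped like W
eff_weight <- function(layer) {
  W <- layer$W
  if (!is.null(layer$lora)) {
    delta <- t(layer$lora$A %*% layer$lora$B) # d_in x d_out
    if (layer$type == "dense") W <- W + t(delta) else W <- W + array(delta, dim(W))
  }
  if (!is.null(layer$mask)) W <- W * layer$mask
  W
}

# ---- forward ---------------------------------------------------------------

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      weff <- eff_weight(layer)
      b <- if (is.null(layer$b)) numeric(0) else layer$b
      y <- .conv2d_forward_cpp(x, weff, b, layer$pad, layer$groups)
      list(out = y, cache = list(x = x, weff = weff))
    },
    dense = {
      weff <- eff_weight(layer)
      y <- weff %*% x
      if (!is.null(layer$b)) y <- y + layer$b
      list(out = y, cache = list(x = x, weff = weff))
    },
    relu = {
      pos <- x > 0
      list(out = x * pos, cache = list(pos = pos))
    },
    maxpool = {
      r <- .maxpool2_forward_cpp(x)
      list(out = r$y, cache = list(idx = r$idx, in_dim = dim(x)))
    },
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(prod(d[1:3]), d[4])
      list(out = y, cache = list(in_dim = d))
    },
    l2sab = l2sab_forward(layer, x),
    gct = gct_forward(layer, x),
    stop("unknown layer type: ", layer$type)
  )
}

l2sab_forward <- function(layer, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  m <- matrix(x, HW, C * N)
  dmap <- matrix(0, HW, N)
  imax <- imin <- matrix(0L, HW, N)
  nrm <- matrix(0, 2, N) # row 1: max-map norm, row 2: min-map norm
  vmax <- vmin <- matrix(0, HW, N)
  for (n in seq_len(N)) {
    mi <- m[, (n - 1L) * C + seq_len(C), drop = FALSE]
    ia <- max.col(mi, "first"); ib <- max.col(-mi, "first")
    va <- mi[cbind(seq_len(HW), ia)]; vb <- mi[cbind(seq_len(HW), ib)]
    na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
    dmap[, n] <- va / max(na, layer$eps) - vb / max(nb, layer$eps)
    imax[, n] <- ia; imin[, n] <- ib
    nrm[, n] <- c(na, nb); vmax[, n] <- va; vmin[, n] <- vb
  }
  weff <- eff_weight_l2sab(layer)
  darr <- array(dmap, c(H, W, 1L, N))
  pre <- .conv2d_forward_cpp(darr, weff, layer$b, same_pad(layer$k), 1L)
  ms <- stats::plogis(pre)
  y <- x
  for (n in seq_len(N)) y[, , , n] <- x[, , , n] * as.vector(ms[, , 1L, n])
  list(out = y, cache = list(x = x, darr = darr, ms = ms, weff = weff,
                             imax = imax, imin = imin, nrm = nrm,
                             vmax = vmax, vmin = vmin))
}

eff_weight_l2sab <- function(layer) {
  W <- layer$W
  if (!is.null(layer$lora))
    W <- W + matrix(layer$lora$A %*% layer$lora$B, layer$k, layer$k)
  if (!is.null(layer$mask)) W <- W * layer$mask
  array(W, c(layer$k, layer$k, 1L, 1L))
}

gct_forward <- function(layer, x) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- matrix(x, HW, C * N)
  z <- matrix(colMeans(m), C, N)
  mu <- colMeans(z)
  sdz <- sqrt(colMeans(sweep(z, 2, mu)^2))
  zhat <- sweep(sweep(z, 2, mu), 2, sdz + layer$eps, "/")
  a <- exp(-zhat^2 / (2 * layer$c^2))
  y <- x * rep(a, each = HW)
  list(out = y, cache = list(x = x, z = z, mu = mu, sdz = sdz,
                             zhat = zhat, a = a))
}

# ---- backward --------------------------------------------------------------

# returns list(dx = ..., grads = list(...)) with grads congruent to the
# layer's trainable slots
layer_backward <- function(layer, cache, dy, need_dx = TRUE) {
  switch(layer$type,
    conv = {
      r <- .conv2d_backward_cpp(cache$x, cache$weff, dy, layer$pad,
                                layer$groups, !is.null(layer$b), need_dx)
      grads <- weight_grads(layer, r$dw, if (is.null(layer$b)) NULL else r$db)
      list(dx = r$dx, grads = grads)
    },
    dense = {
      dW <- dy %*% t(cache$x)
      dx <- t(cache$weff) %*% dy
      grads <- weight_grads(layer, dW, rowSums(dy))
      list(dx = dx, grads = grads)
    },
    relu = list(dx = dy * cache$pos, grads = NULL),
    maxpool = list(dx = .maxpool2_backward_cpp(dy, cache$idx, cache$in_dim),
                   grads = NULL),
    flatten = { dim(dy) <- cache$in_dim; list(dx = dy, grads = NULL) },
    l2sab = l2sab_backward(layer, cache, dy),
    gct = gct_backward(layer, cache, dy),
    stop("unknown layer type: ", layer$type)
  )
}

# maps a gradient on the effective weight back to base/LoRA/mask slots
weight_grads <- function(layer, dWeff, db) {
  if (!is.null(layer$mask)) dWeff <- dWeff * layer$mask
  g <- list()
  if (!isTRUE(layer$frozen)) {
    g$W <- dWeff
    if (!is.null(db)) g$b <- db
  }
  if (!is.null(layer$lora)) {
    # orient as d_out x d_in to match A (d_out x r), B (r x d_in)
    dWm <- if (layer$type == "dense") dWeff
           else t(matrix(dWeff, nrow = prod(utils::head(dim(dWeff), -1))))
    g$lora <- list(A = dWm %*% t(layer$lora$B),
                   B = t(layer$lora$A) %*% dWm)
  }
  g
}

l2sab_backward <- function(layer, cache, dy) {
  x <- cache$x
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  ms <- cache$ms
  dx <- dy
  dms <- array(0, c(H, W, 1L, N))
  for (n in seq_len(N)) {
    msn <- as.vector(ms[, , 1L, n])
    dx[, , , n] <- dy[, , , n] * msn
    dms[, , 1L, n] <- rowSums(matrix(dy[, , , n] * x[, , , n], HW, C))
  }
  dpre <- dms * ms * (1 - ms)
  r <- .conv2d_backward_cpp(cache$darr, cache$weff, dpre,
                            same_pad(layer$k), 1L, TRUE)
  for (n in seq_len(N)) {
    dd <- as.vector(r$dx[, , 1L, n])
    dva <- l2norm_backward(cache$vmax[, n], cache$nrm[1, n],  dd, layer$eps)
    dvb <- l2norm_backward(cache$vmin[, n], cache$nrm[2, n], -dd, layer$eps)
    dmi <- matrix(0, HW, C)
    ia <- cbind(seq_len(HW), cache$imax[, n])
    ib <- cbind(seq_len(HW), cache$imin[, n])
    dmi[ia] <- dmi[ia] + dva
    dmi[ib] <- dmi[ib] + dvb
    dx[, , , n] <- dx[, , , n] + array(dmi, c(H, W, C))
  }
  gW <- matrix(r$dw, layer$k, layer$k)
  grads <- list()
  if (!isTRUE(layer$frozen)) grads <- list(W = gW, b = r$db)
  if (!is.null(layer$lora)) {
    dWm <- matrix(gW, nrow = 1L) # d_out = 1
    grads$lora <- list(A = dWm %*% t(layer$lora$B),
                       B = t(layer$lora$A) %*% dWm)
  }
  list(dx = dx, grads = grads)
}

# backward through v -> v / max(||v||, eps)
l2norm_backward <- function(v, n, du, eps) {
  if (n > eps) du / n - v * sum(v * du) / n^3 else du / eps
}

gct_backward <- function(layer, cache, dy) {
  x <- cache$x
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  a <- cache$a
  dx <- dy * rep(a, each = HW)
  for (n in seq_len(N)) {
    s <- colSums(matrix(dy[, , , n] * x[, , , n], HW, C)) # dL/da
    g <- s * a[, n] * (-cache$zhat[, n] / layer$c^2)       # dL/dzhat
    denom <- cache$sdz[n] + layer$eps
    dz <- (g - mean(g)) / denom
    if (cache$sdz[n] > 0) {
      dz <- dz - (cache$z[, n] - cache$mu[n]) *
        sum(g * cache$zhat[, n]) / (C * cache$sdz[n] * denom)
    }
    dx[, , , n] <- dx[, , , n] + rep(dz / HW, each = HW)
  }
  list(dx = dx, grads = NULL)
}

# ---- network-level passes --------------------------------------------------

net_forward <- function(net, x, record = FALSE) {
  caches <- vector("list", length(net$layers))
  outs <- if (record) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], x)
    x <- r$out
    caches[[i]] <- r$cache
    if (record) outs[[i]] <- x
  }
  list(out = x, caches = caches, outs = outs)
}

net_backward <- function(net, caches, dout, record_dx = FALSE) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dxs <- if (record_dx) vector("list", L + 1L) else NULL
  if (record_dx) dxs[[L + 1L]] <- dout
  for (i in rev(seq_len(L))) {
    # the input gradient of the first layer is only needed when recording
    r <- layer_backward(net$layers[[i]], caches[[i]], dout,
                        need_dx = i > 1L || record_dx)
    grads[i] <- list(r$grads) # [[<-]] with NULL would drop the element
    dout <- r$dx
    if (record_dx) dxs[[i]] <- dout
  }
  list(grads = grads, dxs = dxs)
}

# ---- parameter slots -------------------------------------------------------

# enumerate trainable parameter slots as (layer index, path into the layer)
trainable_slots <- function(net) {
  slots <- list()
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type %in% c("conv", "dense", "l2sab")) {
      if (!isTRUE(l$frozen)) {
        slots[[length(slots) + 1L]] <- list(i = i, path = "W")
        if (!is.null(l$b)) slots[[length(slots) + 1L]] <- list(i = i, path = "b")
      }
      if (!is.null(l$lora)) {
        slots[[length(slots) + 1L]] <- list(i = i, path = c("lora", "A"))
        slots[[length(slots) + 1L]] <- list(i = i, path = c("lora", "B"))
      }
    }
  }
  slots
}

get_slot <- function(net, s) net$layers[[s$i]][[s$path]]
set_slot <- function(net, s, value) {
  net$layers[[s$i]][[s$path]] <- value
  net
}
grad_slot <- function(grads, s) {
  g <- grads[[s$i]]
  for (p in s$path) g <- g[[p]]
  g
}

# ---- optimizer -------------------------------------------------------------

adam_state <- function(net, slots) {
  lapply(slots, function(s) {
    p <- get_slot(net, s) * 0 # zero moments with the slot's exact shape
    list(m = p, v = p)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(net, grads, slots, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in seq_along(slots)) {
    s <- slots[[k]]
    g <- grad_slot(grads, s)
    if (is.null(g)) next
    st <- state[[k]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p <- get_slot(net, s) - lr * mhat / (sqrt(vhat) + eps)
    # keep pruned positions exactly zero
    if (identical(s$path, "W") && !is.null(net$layers[[s$i]]$mask))
      p <- p * net$layers[[s$i]]$mask
    net <- set_slot(net, s, p)
    state[[k]] <- st
  }
  list(net = net, state = state)
}

# ---- loss ------------------------------------------------------------------

# logits: K x N, y: integer class labels in 1..K
softmax_xent <- function(logits, y) {
  K <- nrow(logits); N <- ncol(logits)
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  loss <- -mean(log(pmax(p[cbind(y, seq_len(N))], 1e-12)))
  dlogits <- p
  dlogits[cbind(y, seq_len(N))] <- dlogits[cbind(y, seq_len(N))] - 1
  list(loss = loss, dlogits = dlogits / N, prob = p)
}
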