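# Minimal CPU neural-network layers with explicit backprop.
# Feature maps are arrays with dim (nz, ny, nx, C); see src/nnops.cpp for
# the convolution kernels (im2col + GEMM). Parameters are nested lists of
# numeric arrays; initialisation draws from the caller's RNG so that every
# training function is reproducible from its seed.

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

conv_par <- function(cin, cout, k = 3, s = 1, p = NULL) {
  if (is.null(p)) p <- (k - 1) %/% 2
  list(W = he_init(cout, cin * k^3, cin * k^3), b = numeric(cout),
       k = k, s = s, p = p)
}

conv_fwd <- function(x, par) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  cpp_conv3d_fwd(x, dim(x), par$W, par$b, par$k, par$s, par$p)$y
}

conv_bwd <- function(x, par, gy) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  cpp_conv3d_bwd(x, dim(x), par$W, gy, par$k, par$s, par$p)
}

convt_par <- function(cin, cout) {
  # transposed conv, kernel 2 stride 2 (exact 2x upsampling)
  list(W = he_init(cout * 8, cin, cin * 8), b = numeric(cout))
}

convt_fwd <- function(x, par) cpp_convt3d_fwd(x, dim(x), par$W, par$b)$y

convt_bwd <- function(x, par, gy) cpp_convt3d_bwd(x, dim(x), par$W, gy)

pool_fwd <- function(x, kz = 2, ky = 2, kx = 2)
  cpp_maxpool3d_fwd(x, dim(x), kz, ky, kx)

pool_bwd <- function(gy, arg, dims) cpp_maxpool3d_bwd(gy, arg, dims)

relu <- function(x) {
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  y
}

relu_bwd <- function(gy, y) {
  g <- gy * (y > 0)
  dim(g) <- dim(gy)
  g
}

linear_par <- function(nin, nout)
  list(W = he_init(nout, nin, nin), b = numeric(nout))

linear_fwd <- function(x, par) drop(par$W %*% x) + par$b  # x: vector

linear_bwd <- function(x, par, gy)
  list(gx = drop(crossprod(par$W, gy)), gW = outer(gy, x), gb = gy)

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# cross-entropy for a single sample; returns loss and dlogits
softmax_ce <- function(logits, label) {
  p <- softmax(logits)
  g <- p
  g[label] <- g[label] - 1
  list(loss = -log(max(p[label], 1e-12)), grad = g, probs = p)
}

# Batch normalisation over a list of samples (per-channel statistics across
# batch and spatial positions). par carries learnable gamma/beta and running
# moments used at inference.
bn_par <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

bn_fwd <- function(xs, par, train = TRUE, momentum = 0.9, eps = 1e-5) {
  C <- dim(xs[[1]])[4]
  V <- prod(dim(xs[[1]])[1:3])
  n <- length(xs) * V
  if (train) {
    sums <- Reduce(`+`, lapply(xs, function(x) colSums(matrix(x, V, C))))
    mu <- sums / n
    sq <- Reduce(`+`, lapply(xs, function(x)
      colSums(matrix(x, V, C)^2)))
    va <- pmax(sq / n - mu^2, 0)
    par$run_mean <- momentum * par$run_mean + (1 - momentum) * mu
    par$run_var <- momentum * par$run_var + (1 - momentum) * va
  } else {
    mu <- par$run_mean
    va <- par$run_var
  }
  inv <- 1 / sqrt(va + eps)
  xh <- lapply(xs, function(x) {
    m <- sweep(matrix(x, V, C), 2, mu, "-")
    m <- sweep(m, 2, inv, "*")
    array(m, dim = dim(x))
  })
  ys <- lapply(xh, function(h) {
    m <- sweep(matrix(h, V, C), 2, par$gamma, "*")
    m <- sweep(m, 2, par$beta, "+")
    array(m, dim = dim(h))
  })
  list(ys = ys, xh = xh, inv = inv, par = par, n = n)
}

bn_bwd <- function(cache, par, gys) {
  C <- length(par$gamma)
  xh <- cache$xh
  V <- prod(dim(xh[[1]])[1:3])
  n <- cache$n
  ggam <- Reduce(`+`, Map(function(g, h)
    colSums(matrix(g, V, C) * matrix(h, V, C)), gys, xh))
  gbet <- Reduce(`+`, lapply(gys, function(g) colSums(matrix(g, V, C))))
  sum_g <- gbet
  sum_gh <- ggam
  gxs <- Map(function(g, h) {
    gm <- matrix(g, V, C)
    hm <- matrix(h, V, C)
    t1 <- sweep(gm, 2, sum_g / n, "-")
    t2 <- sweep(hm, 2, sum_gh / n, "*")
    gx <- sweep(t1 - t2, 2, par$gamma * cache$inv, "*")
    array(gx, dim = dim(g))
  }, gys, xh)
  list(gxs = gxs, ggamma = ggam, gbeta = gbet)
}

# ---- per-sample instance normalisation (channel-wise over space) -------
# The residual backbone normalises each conv output per channel over its
# spatial extent (batch-independent, so window-at-a-time training and
# inference behave identically).

inorm_par <- function(C) list(gamma = rep(1, C), beta = numeric(C))

inorm_fwd <- function(x, par, eps = 1e-5) {
  d <- dim(x)
  V <- prod(d[1:3])
  m <- matrix(x, V, d[4])
  mu <- colMeans(m)
  va <- colMeans(m^2) - mu^2
  inv <- 1 / sqrt(pmax(va, 0) + eps)
  xh <- sweep(sweep(m, 2, mu, "-"), 2, inv, "*")
  y <- sweep(sweep(xh, 2, par$gamma, "*"), 2, par$beta, "+")
  dim(y) <- d
  list(y = y, xh = xh, inv = inv, dims = d)
}

inorm_bwd <- function(cache, par, gy) {
  d <- cache$dims
  V <- prod(d[1:3])
  g <- matrix(gy, V, d[4])
  ggamma <- colSums(g * cache$xh)
  gbeta <- colSums(g)
  t1 <- sweep(g, 2, gbeta / V, "-")
  t2 <- sweep(cache$xh, 2, ggamma / V, "*")
  gx <- sweep(t1 - t2, 2, par$gamma * cache$inv, "*")
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# conv -> instance norm (-> relu done by caller)
cin_fwd <- function(x, cpar, npar) {
  a <- conv_fwd(x, cpar)
  nf <- inorm_fwd(a, npar)
  list(y = nf$y, x = x, norm = nf)
}

cin_bwd <- function(cache, cpar, npar, gy) {
  nb <- inorm_bwd(cache$norm, npar, gy)
  cb <- conv_bwd(cache$x, cpar, nb$gx)
  list(gx = cb$gx,
       conv = list(W = cb$gW, b = cb$gb),
       norm = list(gamma = nb$ggamma, beta = nb$gbeta))
}

# ---- SGD with momentum over nested parameter lists ---------------------

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  if (is.numeric(p)) {
    z <- p * 0
    return(z)
  }
  p
}

sgd_update <- function(params, grads, vel, lr, momentum = 0.9, wd = 0) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p
      out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        out_p[[nm]] <- r$p
        out_v[[nm]] <- r$v
      }
      return(list(p = out_p, v = out_v))
    }
    if (!is.numeric(p) || is.null(g)) return(list(p = p, v = v))
    v <- momentum * v + g + wd * p
    list(p = p - lr * v, v = v)
  }
  walk(params, grads, vel)
}

# accumulate grads (same nested structure); a is modified copy
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(b)) {
    for (nm in names(b)) a[[nm]] <- acc_grads(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

scale_grads <- function(g, s) {
  if (is.list(g)) return(lapply(g, scale_grads, s = s))
  if (is.numeric(g)) return(g * s)
  g
}

# ---- Adam over nested parameter lists ----------------------------------

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, wd = 0) {
  state$t <- (state$t %||% 0) + 1
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p
      out_m <- if (is.null(m)) p else m
      out_v <- if (is.null(v)) p else v
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p
        out_m[[nm]] <- r$m
        out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    if (!is.numeric(p) || is.null(g)) return(list(p = p, m = m, v = v))
    g <- g + wd * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(p = r$p, state = list(t = t, m = r$m, v = r$v))
}

adam_init <- function(params) list(t = 0, m = zero_like(params),
                                   v = zero_like(params))

# ---- shared detector/pretext backbone ----------------------------------
# Five stages C1..C5; C1 keeps the input grid, each later stage halves it.
# Each downsampling is a stride-2 conv followed by one residual block
# (two 3x3x3 convs with an identity skip); every conv is followed by a
# per-sample instance normalisation, in the style of compact normalised
# 3D residual feature extractors.

backbone_par <- function(channels, cin = 1) {
  ch <- channels
  par <- list(stem = conv_par(cin, ch[1], 3, 1),
              stem_n = inorm_par(ch[1]))
  for (l in 2:5) {
    par[[paste0("down", l)]] <- conv_par(ch[l - 1], ch[l], 3, 2)
    par[[paste0("down", l, "_n")]] <- inorm_par(ch[l])
    par[[paste0("res", l, "a")]] <- conv_par(ch[l], ch[l], 3, 1)
    par[[paste0("res", l, "a_n")]] <- inorm_par(ch[l])
    par[[paste0("res", l, "b")]] <- conv_par(ch[l], ch[l], 3, 1)
    par[[paste0("res", l, "b_n")]] <- inorm_par(ch[l])
  }
  par
}

backbone_fwd <- function(x, par) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  cache <- list(x = x)
  cs <- cin_fwd(x, par$stem, par$stem_n)
  cache$stem <- cs
  c_prev <- relu(cs$y)
  cache$c1 <- c_prev
  for (l in 2:5) {
    cd <- cin_fwd(c_prev, par[[paste0("down", l)]],
                  par[[paste0("down", l, "_n")]])
    h <- relu(cd$y)
    ca <- cin_fwd(h, par[[paste0("res", l, "a")]],
                  par[[paste0("res", l, "a_n")]])
    r1 <- relu(ca$y)
    cb <- cin_fwd(r1, par[[paste0("res", l, "b")]],
                  par[[paste0("res", l, "b_n")]])
    cl <- relu(h + cb$y)
    cache[[paste0("d", l)]] <- cd
    cache[[paste0("a", l)]] <- ca
    cache[[paste0("b", l)]] <- cb
    cache[[paste0("h", l)]] <- h
    cache[[paste0("r1_", l)]] <- r1
    cache[[paste0("c", l)]] <- cl
    c_prev <- cl
  }
  cache
}

# gc: list with entries c1..c5 (any may be NULL); returns parameter grads
backbone_bwd <- function(par, cache, gc) {
  grads <- list()
  gnext <- NULL  # gradient flowing into c_l from stage l+1
  for (l in 5:2) {
    gcl <- gc[[paste0("c", l)]]
    g <- if (is.null(gcl)) gnext else if (is.null(gnext)) gcl else gcl + gnext
    if (is.null(g)) next
    cl <- cache[[paste0("c", l)]]
    g <- relu_bwd(g, cl)
    bb <- cin_bwd(cache[[paste0("b", l)]], par[[paste0("res", l, "b")]],
                  par[[paste0("res", l, "b_n")]], g)
    grads[[paste0("res", l, "b")]] <- bb$conv
    grads[[paste0("res", l, "b_n")]] <- bb$norm
    gr1 <- relu_bwd(bb$gx, cache[[paste0("r1_", l)]])
    ba <- cin_bwd(cache[[paste0("a", l)]], par[[paste0("res", l, "a")]],
                  par[[paste0("res", l, "a_n")]], gr1)
    grads[[paste0("res", l, "a")]] <- ba$conv
    grads[[paste0("res", l, "a_n")]] <- ba$norm
    gh <- relu_bwd(g + ba$gx, cache[[paste0("h", l)]])
    bd <- cin_bwd(cache[[paste0("d", l)]], par[[paste0("down", l)]],
                  par[[paste0("down", l, "_n")]], gh)
    grads[[paste0("down", l)]] <- bd$conv
    grads[[paste0("down", l, "_n")]] <- bd$norm
    gnext <- bd$gx
  }
  g1 <- gc$c1
  g <- if (is.null(g1)) gnext else if (is.null(gnext)) g1 else g1 + gnext
  if (!is.null(g)) {
    g <- relu_bwd(g, cache$c1)
    bs <- cin_bwd(cache$stem, par$stem, par$stem_n, g)
    grads$stem <- bs$conv
    grads$stem_n <- bs$norm
  }
  grads
}
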