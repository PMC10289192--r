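# Dense feed-forward core: ReLU hidden stack + linear 1-node head, manual
# backprop, inverted dropout between hidden layers, L2 on all weight
# matrices. Small nets (~12k parameters), so plain BLAS-backed base R matrix
# code is fast enough; no compiled code needed.

nn_init <- function(input_dim, n_layers, width, seed = NULL) {
  init <- function() {
    dims <- c(input_dim, rep(width, n_layers))
    W <- lapply(seq_len(n_layers), function(l) {
      # He initialization for ReLU layers
      matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
             dims[l], dims[l + 1])
    })
    b <- lapply(seq_len(n_layers), function(l) numeric(width))
    V <- matrix(stats::rnorm(width, sd = sqrt(1 / width)), width, 1)
    list(W = W, b = b, V = V, c = 0)
  }
  if (is.null(seed)) init() else withr::with_seed(as.integer(seed), init())
}

nn_param_count <- function(par) {
  as.integer(sum(vapply(par$W, length, integer(1))) +
               sum(vapply(par$b, length, integer(1))) + length(par$V) + 1L)
}

# Forward pass. dropout > 0 draws fresh inverted-dropout masks between hidden
# layers (never after the last hidden layer, whose output is the embedding).
# Returns embedding, prediction and the cache needed for backprop.
nn_forward <- function(par, x, dropout = 0, training = FALSE) {
  L <- length(par$W)
  h <- x
  zs <- vector("list", L)
  as <- vector("list", L)
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    z <- h %*% par$W[[l]]
    z <- z + rep(par$b[[l]], each = nrow(z))   # column-major bias add
    a <- (z > 0) * z
    if (training && dropout > 0 && l < L) {
      mask <- (stats::runif(length(a)) >= dropout) / (1 - dropout)
      dim(mask) <- dim(a)
      a <- a * mask
      masks[[l]] <- mask
    }
    zs[[l]] <- z
    as[[l]] <- a
    h <- a
  }
  pred <- as.numeric(h %*% par$V + par$c)
  list(emb = h, pred = pred,
       cache = list(x = x, zs = zs, as = as, masks = masks))
}

# Backprop for one branch. d_emb: gradient wrt the embedding (n x width, or
# NULL for zero); d_pred: gradient wrt the head output (length n). Returns
# gradients with the same shape as the parameters (no L2 term; added at the
# update).
nn_backward <- function(par, fwd, d_emb, d_pred) {
  L <- length(par$W)
  cache <- fwd$cache
  d_pred <- matrix(d_pred, ncol = 1)
  if (is.null(d_emb)) d_emb <- 0
  gW <- vector("list", L)
  gb <- vector("list", L)
  gV <- crossprod(cache$as[[L]], d_pred)
  gc <- sum(d_pred)
  dh <- d_emb + d_pred %*% t(par$V)
  for (l in rev(seq_len(L))) {
    if (!is.null(cache$masks[[l]])) dh <- dh * cache$masks[[l]]
    dz <- dh * (cache$zs[[l]] > 0)
    h_prev <- if (l == 1) cache$x else cache$as[[l - 1]]
    gW[[l]] <- crossprod(h_prev, dz)
    gb[[l]] <- colSums(dz)
    if (l > 1) dh <- dz %*% t(par$W[[l]])
  }
  list(W = gW, b = gb, V = gV, c = gc)
}

nn_add_grads <- function(g1, g2) {
  list(W = Map(`+`, g1$W, g2$W), b = Map(`+`, g1$b, g2$b),
       V = g1$V + g2$V, c = g1$c + g2$c)
}

# One SGD step; L2 decay applied to all weight matrices (not biases).
nn_sgd_step <- function(par, grads, lr, l2) {
  for (l in seq_along(par$W)) {
    par$W[[l]] <- par$W[[l]] - lr * (grads$W[[l]] + 2 * l2 * par$W[[l]])
    par$b[[l]] <- par$b[[l]] - lr * grads$b[[l]]
  }
  par$V <- par$V - lr * (grads$V + 2 * l2 * par$V)
  par$c <- par$c - lr * grads$c
  par
}
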