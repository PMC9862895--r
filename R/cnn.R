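#' Network configuration for the ligandability CNN
#'
#' Four 3x3x3 convolution layers (stride 1, zero padding 1) with batch
#' normalization and ReLU, 2x2x2 max pooling after conv blocks 2 and 4,
#' dropout before the first dense layer, one hidden dense layer with batch
#' norm + ReLU, and a 2-unit softmax output (the two components sum to 1;
#' the second is the ligandable-class probability).
#'
#' @param conv_widths Integer vector of 4 channel widths
#'   (default `c(32, 64, 64, 128)`).
#' @param dense_width Hidden dense layer width (default 256).
#' @param dropout Dropout rate before the first dense layer (default 0.3).
#' @param in_channels Input channels (default 8).
#' @param size Input voxels per axis (default 19).
#' @return A `net_config` list.
#' @export
net_config <- function(conv_widths = c(32, 64, 64, 128), dense_width = 256,
                       dropout = 0.3, in_channels = 8, size = 19) {
  stopifnot(length(conv_widths) == 4, dropout >= 0, dropout < 1)
  structure(
    list(conv_widths = as.integer(conv_widths),
         dense_width = as.integer(dense_width), dropout = dropout,
         in_channels = as.integer(in_channels), size = as.integer(size)),
    class = "net_config"
  )
}

#' Training configuration
#'
#' @param epochs Number of epochs (default 40).
#' @param clusters_per_epoch Clusters drawn per epoch (default 1024); the
#'   number of batches per epoch is `clusters_per_epoch / nc`.
#' @param nc Clusters per batch (default 64).
#' @param np Surface points per selected chain (default 8); the batch size
#'   is `nc * np`.
#' @param max_lr Peak learning rate of the one-cycle schedule (default 1e-3).
#' @param optimizer `"adam"` (default; robust at small step budgets) or
#'   `"sgd"` (plain momentum SGD).
#' @param momentum SGD momentum (default 0.9; ignored by Adam).
#' @param oversample Balance ligandable/non-ligandable samples per chain
#'   (default TRUE).
#' @param val_sample Number of validation points used for the per-epoch
#'   validation loss (0 disables; default 256).
#' @param seed Optional integer seed for reproducible training.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 40, clusters_per_epoch = 1024, nc = 64,
                         np = 8, max_lr = 1e-3, optimizer = c("adam", "sgd"),
                         momentum = 0.9, oversample = TRUE, val_sample = 256,
                         seed = NULL) {
  structure(
    list(epochs = epochs, clusters_per_epoch = clusters_per_epoch, nc = nc,
         np = np, max_lr = max_lr, optimizer = match.arg(optimizer),
         momentum = momentum, oversample = oversample,
         val_sample = val_sample, seed = seed),
    class = "train_config"
  )
}

new_bn <- function(nc) {
  list(gamma = rep(1, nc), beta = rep(0, nc),
       mean = rep(0, nc), var = rep(1, nc))
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' Build an untrained ligandability classifier
#'
#' Parameters are He-initialized from the current RNG state.
#'
#' @param cfg A [net_config()].
#' @return A `ligandability_cnn` object.
#' @export
build_network <- function(cfg = net_config()) {
  cw <- cfg$conv_widths
  cin <- c(cfg$in_channels, cw[1], cw[2], cw[3])
  params <- list()
  for (l in 1:4) {
    params[[paste0("W", l)]] <- he_init(c(3, 3, 3, cin[l], cw[l]), 27 * cin[l])
    params[[paste0("b", l)]] <- rep(0, cw[l])
    params[[paste0("bn", l)]] <- new_bn(cw[l])
  }
  s2 <- (cfg$size %/% 2) %/% 2
  nfeat <- cw[4] * s2^3
  params$W5 <- matrix(rnorm(cfg$dense_width * nfeat, sd = sqrt(2 / nfeat)),
                      cfg$dense_width, nfeat)
  params$b5 <- rep(0, cfg$dense_width)
  params$bn5 <- new_bn(cfg$dense_width)
  params$W6 <- matrix(rnorm(2 * cfg$dense_width, sd = sqrt(2 / cfg$dense_width)),
                      2, cfg$dense_width)
  params$b6 <- rep(0, 2)
  structure(
    list(cfg = cfg, params = params, losses = NULL),
    class = "ligandability_cnn"
  )
}

#' @export
print.ligandability_cnn <- function(x, ...) {
  cat(sprintf(
    "<ligandability_cnn> conv %s, dense %d, %d parameters%s\n",
    paste(x$cfg$conv_widths, collapse = "-"), x$cfg$dense_width,
    n_parameters(x), if (is.null(x$losses)) " (untrained)" else " (trained)"
  ))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param model A `ligandability_cnn`.
#' @return Integer count (weights, biases, batch-norm scales/shifts).
#' @export
n_parameters <- function(model) {
  p <- model$params
  tot <- 0L
  for (nm in names(p)) {
    tot <- tot + if (startsWith(nm, "bn")) {
      2L * length(p[[nm]]$gamma)
    } else {
      length(p[[nm]])
    }
  }
  tot
}

# ---- batch norm -------------------------------------------------------

# x arranged as an (m observations x C channels) matrix
bn_fw_mat <- function(xm, bn, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
    upd <- list(mean = (1 - momentum) * bn$mean + momentum * mu,
                var = (1 - momentum) * bn$var + momentum * v)
  } else {
    mu <- bn$mean; v <- bn$var; upd <- NULL
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(y = y, xhat = xhat, invstd = invstd, upd = upd)
}

bn_bw_mat <- function(gy, cache, gamma) {
  m <- nrow(gy)
  dgamma <- colSums(gy * cache$xhat)
  dbeta <- colSums(gy)
  dxhat <- sweep(gy, 2, gamma, "*")
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(
    m * dxhat - matrix(t1, m, length(t1), byrow = TRUE) -
      cache$xhat * matrix(t2, m, length(t2), byrow = TRUE),
    2, cache$invstd / m, "*"
  )
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Batch norm over a conv activation without permuting: the (D,H,W,C,N)
# array is viewed as a (D*H*W x C*N) matrix whose columns cycle through
# channels fastest; per-channel statistics fold the per-column sums.
conv_bn_fw <- function(x, bn, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  m <- prod(d[1:3])
  C <- d[4]; N <- d[5]
  dim(x) <- c(m, C * N)
  mtot <- m * N
  if (training) {
    mu <- rowSums(matrix(colSums(x), C, N)) / mtot
    ex2 <- rowSums(matrix(colSums(x^2), C, N)) / mtot
    v <- pmax(ex2 - mu^2, 0)
    upd <- list(mean = (1 - momentum) * bn$mean + momentum * mu,
                var = (1 - momentum) * bn$var + momentum * v)
  } else {
    mu <- bn$mean; v <- bn$var; upd <- NULL
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (x - rep(rep(mu, N), each = m)) * rep(rep(invstd, N), each = m)
  y <- xhat * rep(rep(bn$gamma, N), each = m) + rep(rep(bn$beta, N), each = m)
  dim(xhat) <- dim(y) <- dim(x)
  list(y = y, xhat = xhat, invstd = invstd, upd = upd, dim5 = d)
}

conv_bn_bw <- function(gy, cache, gamma) {
  d <- cache$dim5
  C <- d[4]; N <- d[5]
  mtot <- prod(d[1:3]) * N
  fold <- function(mat) rowSums(matrix(colSums(mat), C, N))
  dgamma <- fold(gy * cache$xhat)
  dbeta <- fold(gy)
  m <- prod(d[1:3])
  ex <- function(v) rep(rep(v, N), each = m)
  dxhat <- gy * ex(gamma)
  t1 <- fold(dxhat)
  t2 <- fold(dxhat * cache$xhat)
  dx <- (dxhat - ex(t1 / mtot) - cache$xhat * ex(t2 / mtot)) * ex(cache$invstd)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- forward / backward ----------------------------------------------

cnn_forward <- function(model, x, training = FALSE, dropout_mask = NULL) {
  p <- model$params
  cfg <- model$cfg
  cache <- list(x = x)
  a <- x
  upd <- list()
  for (l in 1:4) {
    W <- p[[paste0("W", l)]]
    d_in <- dim(a)
    z <- conv3d_fw_cpp(a, as.integer(d_in), W, p[[paste0("b", l)]], dim(W)[5])
    dz <- c(d_in[1:3], dim(W)[5], d_in[5])
    dim(z) <- dz
    bnr <- conv_bn_fw(z, p[[paste0("bn", l)]], training)
    if (training) upd[[paste0("bn", l)]] <- bnr$upd
    ym <- bnr$y
    mask <- ym > 0
    a <- ym * mask
    dim(a) <- dz
    cache[[paste0("conv", l)]] <- list(
      input = if (l == 1) x else cache[[paste0("post", l - 1)]],
      zdim = dz, bn = bnr[c("xhat", "invstd", "dim5")], mask = mask
    )
    cache[[paste0("post", l)]] <- a
    if (l %in% c(2, 4)) {
      mp <- maxpool_fw_cpp(a, as.integer(dim(a)))
      y <- mp$y
      dim(y) <- mp$ydim
      cache[[paste0("pool", l)]] <- list(argmax = mp$argmax, xdim = dim(a),
                                         ydim = mp$ydim)
      a <- y
      cache[[paste0("post", l)]] <- a
    }
  }
  d <- dim(a)
  nfeat <- prod(d[1:4])
  flat <- matrix(a, nfeat, d[5])
  if (training && cfg$dropout > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(
        (runif(length(flat)) >= cfg$dropout) / (1 - cfg$dropout),
        nfeat, d[5]
      )
    }
    flat <- flat * dropout_mask
  }
  cache$flat <- flat
  cache$dropout_mask <- dropout_mask
  cache$flat_dim <- d
  z5 <- p$W5 %*% flat + p$b5
  bn5 <- bn_fw_mat(t(z5), p$bn5, training)
  if (training) upd$bn5 <- bn5$upd
  a5m <- bn5$y * (bn5$y > 0)
  cache$d5 <- list(bn = bn5[c("xhat", "invstd")], mask = bn5$y > 0)
  a5 <- t(a5m)
  cache$a5 <- a5
  z6 <- p$W6 %*% a5 + p$b6
  zmax <- apply(z6, 2, max)
  ez <- exp(sweep(z6, 2, zmax))
  probs <- sweep(ez, 2, colSums(ez), "/")
  cache$probs <- probs
  list(probs = probs, cache = cache, bn_updates = upd)
}

# cross-entropy loss and full parameter gradients; y in {0,1}
cnn_backward <- function(model, cache, y) {
  p <- model$params
  probs <- cache$probs
  n <- ncol(probs)
  onehot <- rbind(1 - y, y)
  loss <- -mean(log(pmax(probs[cbind(y + 1, seq_len(n))], 1e-12)))
  gz6 <- (probs - onehot) / n
  g <- list()
  g$W6 <- gz6 %*% t(cache$a5)
  g$b6 <- rowSums(gz6)
  ga5 <- t(p$W6) %*% gz6
  bb <- bn_bw_mat(t(ga5) * cache$d5$mask, cache$d5$bn, p$bn5$gamma)
  g$bn5 <- list(gamma = bb$dgamma, beta = bb$dbeta)
  gz5 <- t(bb$dx)
  g$W5 <- gz5 %*% t(cache$flat)
  g$b5 <- rowSums(gz5)
  gflat <- t(p$W5) %*% gz5
  if (!is.null(cache$dropout_mask)) gflat <- gflat * cache$dropout_mask
  ga <- array(gflat, dim = cache$flat_dim)
  for (l in 4:1) {
    if (l %in% c(2, 4)) {
      pool <- cache[[paste0("pool", l)]]
      ga <- maxpool_bw_cpp(ga, pool$argmax, as.integer(pool$xdim))
      dim(ga) <- pool$xdim
    }
    cv <- cache[[paste0("conv", l)]]
    dim(ga) <- dim(cv$mask)
    gym <- ga * cv$mask
    bb <- conv_bn_bw(gym, cv$bn, p[[paste0("bn", l)]]$gamma)
    g[[paste0("bn", l)]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    gz <- bb$dx
    dim(gz) <- cv$zdim
    W <- p[[paste0("W", l)]]
    res <- conv3d_bw_cpp(cv$input, as.integer(dim(cv$input)), W, dim(W)[5], gz)
    g[[paste0("W", l)]] <- array(res$gw, dim = dim(W))
    g[[paste0("b", l)]] <- res$gb
    ga <- array(res$gx, dim = dim(cv$input))
  }
  list(loss = loss, grads = g)
}

# inference-only forward pass: batch norm folded into the convolution /
# dense weights (an affine per channel in evaluation mode), no caches
cnn_infer <- function(model, x) {
  p <- model$params
  a <- x
  for (l in 1:4) {
    W <- p[[paste0("W", l)]]
    bn <- p[[paste0("bn", l)]]
    scale <- bn$gamma / sqrt(bn$var + 1e-5)
    Wf <- sweep(W, 5, scale, "*")
    bf <- (p[[paste0("b", l)]] - bn$mean) * scale + bn$beta
    d_in <- dim(a)
    z <- conv3d_fw_cpp(a, as.integer(d_in), Wf, bf, dim(W)[5])
    dim(z) <- c(d_in[1:3], dim(W)[5], d_in[5])
    a <- z * (z > 0)
    dim(a) <- dim(z)
    if (l %in% c(2, 4)) {
      mp <- maxpool_fw_cpp(a, as.integer(dim(a)))
      a <- mp$y
      dim(a) <- mp$ydim
    }
  }
  d <- dim(a)
  flat <- matrix(a, prod(d[1:4]), d[5])
  bn5 <- p$bn5
  s5 <- bn5$gamma / sqrt(bn5$var + 1e-5)
  W5f <- p$W5 * s5
  b5f <- (p$b5 - bn5$mean) * s5 + bn5$beta
  a5 <- W5f %*% flat + b5f
  a5 <- a5 * (a5 > 0)
  z6 <- p$W6 %*% a5 + p$b6
  ez <- exp(sweep(z6, 2, apply(z6, 2, max)))
  sweep(ez, 2, colSums(ez), "/")
}

#' Forward-pass class probabilities for a batch of grids
#'
#' @param model A `ligandability_cnn`.
#' @param x Array `size x size x size x channels x n` of property grids.
#' @return A 2 x n matrix of class probabilities (columns sum to 1); row 2
#'   is the ligandable class.
#' @export
predict_grids <- function(model, x) {
  if (length(dim(x)) == 4) dim(x) <- c(dim(x), 1)
  if (!all(dim(x)[1:4] == c(rep(model$cfg$size, 3), model$cfg$in_channels))) {
    abort("input grid shape does not match the network configuration")
  }
  cnn_infer(model, x)
}

#' One-cycle learning-rate schedule
#'
#' Piecewise linear: rises from `max_lr / 25` to `max_lr` over the first
#' 30% of steps, then descends to `max_lr / 1000` over the remainder.
#' Continuous in the step.
#'
#' @param step Current step, `0..total_steps`.
#' @param total_steps Total steps in the run.
#' @param max_lr Peak learning rate.
#' @param warmup Fraction of steps in the rising phase (default 0.3).
#' @return Learning rate(s).
#' @export
one_cycle_lr <- function(step, total_steps, max_lr, warmup = 0.3) {
  peak <- warmup * total_steps
  lo <- max_lr / 25
  fin <- max_lr / 1000
  ifelse(
    step <= peak,
    lo + (max_lr - lo) * step / peak,
    max_lr + (fin - max_lr) * (step - peak) / (total_steps - peak)
  )
}

#' Cluster-granular nested cross-validation splits
#'
#' The clusters are shuffled and partitioned into `n_folds` equal parts;
#' split i uses part i as test set, the next part (cyclically) as
#' validation, and the rest for training — so the test sets are pairwise
#' disjoint, their union covers all clusters, and proportions are
#' 80/10/10 up to rounding. Splitting is at cluster granularity only:
#' chains of one cluster never straddle sets.
#'
#' @param clusters Vector of cluster ids.
#' @param n_folds Number of splits (default 10).
#' @return A tibble with columns `fold_id`, `train`, `validation`, `test`
#'   (list-columns of cluster ids).
#' @export
make_cv_splits <- function(clusters, n_folds = 10) {
  cl <- unique(clusters)
  if (length(cl) < n_folds) abort("need at least n_folds clusters")
  cl <- sample(cl)
  fold <- rep(seq_len(n_folds), length.out = length(cl))[order(seq_along(cl))]
  fold <- cut(seq_along(cl), breaks = n_folds, labels = FALSE)
  parts <- split(cl, fold)
  tibble(
    fold_id = seq_len(n_folds),
    test = unname(parts),
    validation = unname(parts[c(2:n_folds, 1)]),
    train = map(seq_len(n_folds), function(i) {
      unlist(parts[-c(i, if (i == n_folds) 1 else i + 1)], use.names = FALSE)
    })
  )
}
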