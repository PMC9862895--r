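tiny_net <- function() {
  net_config(conv_widths = c(2, 3, 3, 4), dense_width = 6, dropout = 0,
             in_channels = 2, size = 7)
}

test_that("the forward pass emits a 2-class distribution and survives zeros", {
  set.seed(1)
  m <- build_network(tiny_net())
  x <- array(rnorm(7^3 * 2 * 3), dim = c(7, 7, 7, 2, 3))
  p <- predict_grids(m, x)
  expect_equal(dim(p), c(2, 3))
  expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
  pz <- predict_grids(m, array(0, dim = c(7, 7, 7, 2, 1)))
  expect_true(all(is.finite(pz)))
  expect_gt(n_parameters(m), 0)
  expect_error(predict_grids(m, array(0, dim = c(5, 5, 5, 2, 1))), "shape")
})

test_that("analytic gradients match central differences through every layer", {
  set.seed(3)
  m <- build_network(tiny_net())
  x <- array(rnorm(7^3 * 2 * 4), dim = c(7, 7, 7, 2, 4))
  y <- c(0, 1, 1, 0)
  fw <- pocketscout:::cnn_forward(m, x, training = TRUE)
  bw <- pocketscout:::cnn_backward(m, fw$cache, y)
  eps <- 1e-5
  loss_at <- function(m2) {
    f <- pocketscout:::cnn_forward(m2, x, training = TRUE)
    pocketscout:::cnn_backward(m2, f$cache, y)$loss
  }
  set.seed(7)
  for (nm in c("W1", "W2", "W3", "W4", "W5", "W6", "b6")) {
    i <- sample(length(m$params[[nm]]), 1)
    m2 <- m
    m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    lp <- loss_at(m2)
    m2$params[[nm]][i] <- m2$params[[nm]][i] - 2 * eps
    lm <- loss_at(m2)
    num <- (lp - lm) / (2 * eps)
    ana <- bw$grads[[nm]][i]
    expect_lt(abs(num - ana), 1e-4 * max(1, abs(ana)))
  }
  for (nm in c("bn1", "bn3", "bn5")) {
    m2 <- m
    m2$params[[nm]]$gamma[1] <- m2$params[[nm]]$gamma[1] + eps
    lp <- loss_at(m2)
    m2$params[[nm]]$gamma[1] <- m2$params[[nm]]$gamma[1] - 2 * eps
    lm <- loss_at(m2)
    expect_lt(abs((lp - lm) / (2 * eps) - bw$grads[[nm]]$gamma[1]),
              1e-4 * max(1, abs(bw$grads[[nm]]$gamma[1])))
  }
})

test_that("the batch sampler honors counts, balance, and determinism", {
  ds <- local({
    set.seed(20)
    mk_pts <- function(n, frac_pos) {
      tibble::tibble(
        x = runif(n, 0, 20), y = runif(n, 0, 20), z = runif(n, 0, 20),
        atom = 1L, ligandable = seq_len(n) <= round(n * frac_pos),
        prediction = NA_real_
      )
    }
    typed <- tibble::tibble(
      name = "CA", element = "C", x = 0, y = 0, z = 0, vdw_radius = 1.7,
      type_code = "C", hydrophobicity = TRUE, aromaticity = FALSE,
      h_acceptor = FALSE, h_donor = FALSE, positive = FALSE,
      negative = FALSE, metal = FALSE, excluded = TRUE
    )
    d <- tibble::tibble(
      chain_ref = paste0("c", 1:6), cluster_id = 1:6,
      typed = rep(list(typed), 6),
      points = lapply(c(0.04, 0.05, 0.06, 0.04, 0, 0.08),
                      function(f) mk_pts(200, f))
    )
    class(d) <- c("point_dataset", class(d))
    d
  })
  set.seed(31)
  b <- sample_batch(ds, nc = 4, np = 8)
  expect_equal(nrow(b), 32)
  expect_equal(length(unique(b$chain)), 4)
  expect_error(sample_batch(ds, nc = 7, np = 8), "fewer clusters")

  # oversampling balances labels in expectation (binomial check):
  # each chain with positives contributes np/2 of them
  set.seed(32)
  fracs <- replicate(300, mean(sample_batch(ds, nc = 4, np = 8)$label))
  # chain 5 has no positives and drags the mean below 0.5 when drawn
  expected <- mean(replicate(2000, {
    picked <- sample(1:6, 4)
    mean(ifelse(picked == 5, 0, 0.5))
  }))
  expect_equal(mean(fracs), expected, tolerance = 0.02)

  # and without oversampling the positive fraction collapses to the base rate
  set.seed(33)
  raw <- replicate(100, mean(sample_batch(ds, nc = 4, np = 8, oversample = FALSE)$label))
  expect_lt(mean(raw), 0.15)

  # same seed, same batches
  set.seed(77)
  b1 <- sample_batch(ds, nc = 4, np = 8)
  set.seed(77)
  b2 <- sample_batch(ds, nc = 4, np = 8)
  expect_identical(b1, b2)
})

test_that("the one-cycle schedule is piecewise linear with the stated endpoints", {
  total <- 200
  mx <- 1e-3
  expect_equal(one_cycle_lr(0, total, mx), mx / 25)
  expect_equal(one_cycle_lr(0.3 * total, total, mx), mx)
  expect_equal(one_cycle_lr(total, total, mx), mx / 1000)
  lr <- one_cycle_lr(0:total, total, mx)
  expect_true(all(diff(lr[1:(0.3 * total)]) > 0))
  expect_true(all(diff(lr[(0.3 * total + 1):total]) < 0))
  # continuity at the peak
  expect_lt(abs(one_cycle_lr(0.3 * total + 1e-6, total, mx) - mx), 1e-8)
})

test_that("cross-validation splits partition clusters with disjoint test sets", {
  set.seed(41)
  splits <- make_cv_splits(1:100, n_folds = 10)
  expect_equal(nrow(splits), 10)
  all_tests <- unlist(splits$test)
  expect_equal(sort(all_tests), 1:100)        # disjoint and covering
  for (i in 1:10) {
    tr <- splits$train[[i]]
    va <- splits$validation[[i]]
    te <- splits$test[[i]]
    expect_equal(sort(c(tr, va, te)), 1:100)  # partition per split
    expect_length(te, 10)
    expect_length(va, 10)
    expect_length(tr, 80)
  }
  expect_error(make_cv_splits(1:5, n_folds = 10), "at least")
  # a different shuffle preserves the invariants
  set.seed(42)
  s2 <- make_cv_splits(1:37, n_folds = 10)
  expect_equal(sort(unlist(s2$test)), 1:37)
})

test_that("training reduces loss and predictions are deterministic in eval mode", {
  e <- toy_entry(42)
  f <- toy_featurized(42)
  ds <- local({
    d <- tibble::tibble(
      chain_ref = "t", cluster_id = 1L,
      typed = list(f$typed), points = list(f$points)
    )
    class(d) <- c("point_dataset", class(d))
    d
  })
  ncfg <- net_config(conv_widths = c(2, 3, 3, 4), dense_width = 8, dropout = 0)
  tcfg <- train_config(epochs = 4, clusters_per_epoch = 4, nc = 1, np = 16,
                       max_lr = 3e-3, val_sample = 0, seed = 5)
  m <- train_cnn(ds, ncfg, tcfg)
  tr <- tidy(m)
  expect_equal(nrow(tr), 4)
  expect_lt(mean(tail(tr$train_loss, 2)), mean(head(tr$train_loss, 2)))
  g <- glance(m)
  expect_equal(g$epochs, 4L)

  pts <- predict_points(m, f$typed, f$points[1:8, ])
  expect_true(all(pts$prediction >= 0 & pts$prediction <= 1))
  # duplicated point gets the identical prediction
  dup <- f$points[c(3, 3), ]
  pd <- predict_points(m, f$typed, dup)
  expect_equal(pd$prediction[1], pd$prediction[2])

  # training is reproducible bit-for-bit under the same seed
  m2 <- train_cnn(ds, ncfg, tcfg)
  expect_identical(m$params, m2$params)
})

test_that("the network memorizes a small fixed sample set", {
  set.seed(55)
  f <- toy_featurized(42)
  pos <- which(f$points$ligandable)
  neg <- which(!f$points$ligandable)
  idx <- c(sample(pos, 16, replace = TRUE), sample(neg, 16))
  lab <- as.integer(f$points$ligandable[idx])
  x <- array(0, dim = c(19, 19, 19, 8, length(idx)))
  for (k in seq_along(idx)) {
    pt <- f$points[idx[k], ]
    x[, , , , k] <- compute_grid(f$typed, c(pt$x, pt$y, pt$z))$values
  }
  m <- build_network(net_config(conv_widths = c(2, 4, 4, 8), dense_width = 16,
                                dropout = 0))
  vel <- list()
  for (step in 1:60) {
    fw <- pocketscout:::cnn_forward(m, x, training = TRUE)
    m$params <- pocketscout:::apply_bn_updates(m$params, fw$bn_updates)
    bw <- pocketscout:::cnn_backward(m, fw$cache, lab)
    upd <- pocketscout:::sgd_step(m$params, bw$grads, vel,
                                  one_cycle_lr(step, 60, 5e-3), 0.9)
    m$params <- upd$params
    vel <- upd$vel
  }
  p <- predict_grids(m, x)
  acc <- mean((p[2, ] > 0.5) == (lab == 1))
  expect_gt(acc, 0.95)
})

test_that("hyperparameter selection scores candidates and refits on train+validation", {
  ds <- local({
    feats <- lapply(c(21, 22, 23), function(s) toy_featurized(s))
    d <- tibble::tibble(
      chain_ref = paste0("c", 1:3), cluster_id = 1:3,
      typed = lapply(feats, `[[`, "typed"),
      points = lapply(feats, `[[`, "points")
    )
    class(d) <- c("point_dataset", class(d))
    d
  })
  split <- tibble::tibble(
    fold_id = 1L, train = list(1L), validation = list(2L), test = list(3L)
  )
  cands <- list(
    list(net = net_config(conv_widths = c(2, 2, 2, 2), dense_width = 4, dropout = 0),
         train = train_config(epochs = 2, clusters_per_epoch = 2, nc = 1, np = 4,
                              max_lr = 1e-3, val_sample = 16, seed = 1)),
    list(net = net_config(conv_widths = c(2, 3, 3, 4), dense_width = 6, dropout = 0),
         train = train_config(epochs = 2, clusters_per_epoch = 2, nc = 1, np = 4,
                              max_lr = 1e-3, val_sample = 16, seed = 1))
  )
  res <- tune_and_train(ds, split, cands)
  expect_s3_class(res$model, "ligandability_cnn")
  expect_true(res$best %in% 1:2)
  expect_equal(nrow(res$scores), 2)
  expect_true(all(is.finite(res$scores$score)))
  # the chosen config shaped the final model
  expect_equal(res$model$cfg$conv_widths, cands[[res$best]]$net$conv_widths)
})
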