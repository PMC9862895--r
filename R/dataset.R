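#' Featurize one chain for training or prediction
#'
#' Types the chain's atoms, computes the solvent-accessible dot surface,
#' and labels each point from the chain's retained ligands.
#'
#' @param entry A `chain_entry`.
#' @param solvent_radius,tessellation_level Passed to [sas_points()].
#' @param threshold Ligandability labeling threshold (default 1e-4).
#' @return List with `typed` (typed-atom tibble) and `points` (labeled
#'   `surface_points`).
#' @export
featurize_chain <- function(entry, solvent_radius = 1.4,
                            tessellation_level = 4, threshold = 1e-4) {
  typed <- assign_atom_types(entry)
  pts <- sas_points(entry, solvent_radius, tessellation_level)
  pts <- label_ligandability(pts, entry$ligands, threshold)
  list(typed = typed, points = pts)
}

#' Build a per-chain point dataset for CNN training
#'
#' @param entries List of `chain_entry` objects.
#' @param cluster_ids Integer cluster id per entry (defaults to one
#'   cluster per chain).
#' @param ... Passed to [featurize_chain()].
#' @return A `point_dataset` tibble: `chain_ref`, `cluster_id`, `typed`
#'   and `points` list-columns.
#' @export
build_point_dataset <- function(entries, cluster_ids = NULL, ...) {
  if (is.null(cluster_ids)) cluster_ids <- seq_along(entries)
  stopifnot(length(cluster_ids) == length(entries))
  feats <- map(entries, featurize_chain, ...)
  ds <- tibble(
    chain_ref = map_chr(entries, ~ paste(.x$structure_id, .x$chain_id, sep = ":")),
    cluster_id = as.integer(cluster_ids),
    typed = map(feats, "typed"),
    points = map(feats, "points")
  )
  class(ds) <- c("point_dataset", class(ds))
  attr(ds, "grid_cache") <- new.env(parent = emptyenv())
  ds
}

#' Sample one training batch of surface points
#'
#' Draws `nc` clusters, one chain from each, and `np` points per chain.
#' With `oversample = TRUE`, half of each chain's points (rounded down)
#' are drawn with replacement from the ligandable points and the rest
#' from the non-ligandable points, so ligandable and non-ligandable
#' samples are fed in equal expected proportion; a chain without
#' ligandable points contributes non-ligandable points only.
#'
#' @param dataset A `point_dataset`.
#' @param nc Clusters per batch.
#' @param np Points per chain; the batch has `nc * np` samples.
#' @param oversample Balance the two classes (default TRUE).
#' @return Tibble with `chain` (row index into `dataset`), `point` (row
#'   index into that chain's points) and `label` (0/1).
#' @export
sample_batch <- function(dataset, nc, np, oversample = TRUE) {
  cl <- unique(dataset$cluster_id)
  if (length(cl) < nc) abort("fewer clusters than nc")
  picked <- sample(cl, nc)
  rows <- map(picked, function(k) {
    cand <- which(dataset$cluster_id == k)
    ci <- if (length(cand) == 1) cand else sample(cand, 1)
    pts <- dataset$points[[ci]]
    pos <- which(pts$ligandable)
    neg <- which(!pts$ligandable)
    if (oversample && length(pos) > 0 && length(neg) > 0) {
      npos <- np %/% 2
      ip <- sample(pos, npos, replace = TRUE)
      ineg <- sample(neg, np - npos, replace = length(neg) < np - npos)
      idx <- c(ip, ineg)
    } else {
      pool <- if (length(pos) == 0) neg else c(pos, neg)
      idx <- sample(pool, np, replace = length(pool) < np)
    }
    tibble(chain = ci, point = idx, label = as.integer(pts$ligandable[idx]))
  })
  bind_rows(rows)
}

# assemble the grid array for a sampled batch; repeated (chain, point)
# pairs — frequent under oversampling — are served from a bounded cache
featurize_batch <- function(dataset, batch, spacing = 1.0, size = 19,
                            cache = attr(dataset, "grid_cache")) {
  nb <- nrow(batch)
  x <- array(0, dim = c(size, size, size, length(channel_names()), nb))
  preps <- list()
  for (k in seq_len(nb)) {
    ci <- batch$chain[k]
    pi <- batch$point[k]
    key <- sprintf("%d_%d_%g_%d", ci, pi, spacing, size)
    vals <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(vals)) {
      ck <- as.character(ci)
      if (is.null(preps[[ck]])) preps[[ck]] <- grid_inputs(dataset$typed[[ci]])
      p <- dataset$points[[ci]]
      vals <- grid_values(preps[[ck]], c(p$x[pi], p$y[pi], p$z[pi]),
                          spacing, size)
      if (!is.null(cache) && length(ls(cache)) < 512) cache[[key]] <- vals
    }
    x[, , , , k] <- vals
  }
  list(x = x, y = batch$label)
}

#' Train the ligandability CNN
#'
#' Stochastic gradient descent with momentum under the one-cycle
#' learning-rate schedule, cross-entropy loss, batches drawn by
#' [sample_batch()]. Training is reproducible given `train_cfg$seed`.
#'
#' @param dataset A `point_dataset` (training clusters only).
#' @param net_cfg A [net_config()].
#' @param train_cfg A [train_config()].
#' @param val_dataset Optional `point_dataset` for per-epoch validation
#'   loss (a fixed random subset of `train_cfg$val_sample` points).
#' @param spacing,size Grid geometry passed to [compute_grid()].
#' @param quiet Suppress progress output (default TRUE).
#' @return A trained `ligandability_cnn`; `model$losses` holds the
#'   per-epoch trace (`epoch`, `train_loss`, `val_loss`).
#' @export
train_cnn <- function(dataset, net_cfg = net_config(),
                      train_cfg = train_config(), val_dataset = NULL,
                      spacing = 1.0, size = net_cfg$size, quiet = TRUE) {
  tc <- train_cfg
  if (!is.null(tc$seed)) set.seed(tc$seed)
  if (is.null(attr(dataset, "grid_cache"))) {
    attr(dataset, "grid_cache") <- new.env(parent = emptyenv())
  }
  model <- build_network(net_cfg)
  nbatch <- max(1L, tc$clusters_per_epoch %/% tc$nc)
  total_steps <- tc$epochs * nbatch
  vel <- list()
  valset <- NULL
  if (!is.null(val_dataset) && tc$val_sample > 0) {
    allv <- bind_rows(imap(val_dataset$points, function(p, i) {
      tibble(chain = i, point = seq_len(nrow(p)), label = as.integer(p$ligandable))
    }))
    take <- min(tc$val_sample, nrow(allv))
    valset <- allv[sample(nrow(allv), take), ]
    valx <- featurize_batch(val_dataset, valset, spacing, size)
  }
  losses <- tibble(epoch = integer(), train_loss = numeric(),
                   val_loss = numeric())
  step <- 0
  for (ep in seq_len(tc$epochs)) {
    ep_loss <- 0
    for (bi in seq_len(nbatch)) {
      batch <- sample_batch(dataset, tc$nc, tc$np, tc$oversample)
      fb <- featurize_batch(dataset, batch, spacing, size)
      fw <- cnn_forward(model, fb$x, training = TRUE)
      model$params <- apply_bn_updates(model$params, fw$bn_updates)
      bw <- cnn_backward(model, fw$cache, fb$y)
      if (!is.finite(bw$loss)) abort("training diverged: loss is not finite")
      lr <- one_cycle_lr(step, total_steps, tc$max_lr)
      if (identical(tc$optimizer, "sgd")) {
        upd <- sgd_step(model$params, bw$grads, vel, lr, tc$momentum)
        model$params <- upd$params
        vel <- upd$vel
      } else {
        upd <- adam_step(model$params, bw$grads, vel, lr)
        model$params <- upd$params
        vel <- upd$state
      }
      ep_loss <- ep_loss + bw$loss
      step <- step + 1
    }
    vl <- NA_real_
    if (!is.null(valset)) {
      pv <- cnn_infer(model, valx$x)
      vl <- ce_loss(pv[2, ], valx$y)
    }
    losses <- bind_rows(losses, tibble(
      epoch = ep, train_loss = ep_loss / nbatch, val_loss = vl
    ))
    if (!quiet) {
      message(sprintf("epoch %d  train %.4f  val %.4f", ep,
                      ep_loss / nbatch, vl))
    }
  }
  model$losses <- losses
  model$train_cfg <- tc
  model
}

apply_bn_updates <- function(params, upd) {
  for (nm in names(upd)) {
    params[[nm]]$mean <- upd[[nm]]$mean
    params[[nm]]$var <- upd[[nm]]$var
  }
  params
}

sgd_step <- function(params, grads, vel, lr, momentum) {
  for (nm in names(grads)) {
    if (startsWith(nm, "bn")) {
      for (f in c("gamma", "beta")) {
        key <- paste(nm, f)
        v <- if (is.null(vel[[key]])) 0 else vel[[key]]
        v <- momentum * v - lr * grads[[nm]][[f]]
        vel[[key]] <- v
        params[[nm]][[f]] <- params[[nm]][[f]] + v
      }
    } else {
      v <- if (is.null(vel[[nm]])) 0 else vel[[nm]]
      v <- momentum * v - lr * grads[[nm]]
      vel[[nm]] <- v
      params[[nm]] <- params[[nm]] + v
    }
  }
  list(params = params, vel = vel)
}

# Adam with bias correction; `state` carries first/second moments and the
# step counter
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  t <- (if (is.null(state$t)) 0 else state$t) + 1
  state$t <- t
  upd1 <- function(key, g, x) {
    m <- if (is.null(state[[paste0(key, ".m")]])) 0 else state[[paste0(key, ".m")]]
    v <- if (is.null(state[[paste0(key, ".v")]])) 0 else state[[paste0(key, ".v")]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state[[paste0(key, ".m")]] <<- m
    state[[paste0(key, ".v")]] <<- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    x - lr * mhat / (sqrt(vhat) + eps)
  }
  for (nm in names(grads)) {
    if (startsWith(nm, "bn")) {
      for (f in c("gamma", "beta")) {
        params[[nm]][[f]] <- upd1(paste(nm, f), grads[[nm]][[f]],
                                  params[[nm]][[f]])
      }
    } else {
      params[[nm]] <- upd1(nm, grads[[nm]], params[[nm]])
    }
  }
  list(params = params, state = state)
}

# binary cross-entropy from ligandable-class probabilities
ce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Predict per-point ligandability for a chain
#'
#' Computes a property grid around every surface point and runs the
#' network in evaluation mode; the prediction is the ligandable-class
#' component of the softmax output.
#'
#' @param model A trained `ligandability_cnn`.
#' @param typed Typed-atom tibble of the chain ([assign_atom_types()]).
#' @param points A `surface_points` tibble.
#' @param spacing Grid spacing (default 1).
#' @param chunk Points per forward pass (default 256).
#' @return `points` with the `prediction` column filled (values in \[0,1\]).
#' @export
predict_points <- function(model, typed, points, spacing = 1.0, chunk = 256) {
  size <- model$cfg$size
  n <- nrow(points)
  preds <- numeric(n)
  px <- points$x; py <- points$y; pz <- points$z
  prep <- grid_inputs(typed)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    x <- array(0, dim = c(size, size, size, length(channel_names()), length(idx)))
    for (k in seq_along(idx)) {
      i <- idx[k]
      x[, , , , k] <- grid_values(prep, c(px[i], py[i], pz[i]), spacing, size)
    }
    preds[idx] <- cnn_infer(model, x)[2, ]
  }
  points$prediction <- preds
  points
}

#' Hyperparameter selection and final fit on one CV split
#'
#' For each candidate configuration, trains on the training clusters and
#' scores it by the mean validation loss over the last five epochs; the
#' best configuration is then retrained on the union of training and
#' validation clusters. Candidates are pairs of a `net_config` and a
#' `train_config`.
#'
#' @param dataset A `point_dataset` covering all clusters.
#' @param split One row of [make_cv_splits()] output.
#' @param candidates List of `list(net = net_config, train = train_config)`.
#' @param ... Passed to [train_cnn()].
#' @return List with the final `model`, the chosen candidate index
#'   `best`, and the per-candidate score table `scores`.
#' @export
tune_and_train <- function(dataset, split, candidates, ...) {
  tr <- dataset[dataset$cluster_id %in% split$train[[1]], ]
  va <- dataset[dataset$cluster_id %in% split$validation[[1]], ]
  scores <- map_dbl(candidates, function(cand) {
    m <- train_cnn(tr, cand$net, cand$train, val_dataset = va, ...)
    lv <- tail(m$losses$val_loss, 5)
    mean(lv, na.rm = TRUE)
  })
  best <- which.min(scores)
  both <- dataset[dataset$cluster_id %in%
                    c(split$train[[1]], split$validation[[1]]), ]
  final <- train_cnn(both, candidates[[best]]$net, candidates[[best]]$train, ...)
  list(model = final, best = best,
       scores = tibble(candidate = seq_along(candidates), score = scores))
}

#' @rdname train_cnn
#' @param x A trained `ligandability_cnn`.
#' @param ... Unused.
#' @export
tidy.ligandability_cnn <- function(x, ...) {
  if (is.null(x$losses)) abort("model is untrained")
  x$losses
}

#' @rdname train_cnn
#' @export
glance.ligandability_cnn <- function(x, ...) {
  tibble(
    n_parameters = n_parameters(x),
    epochs = if (is.null(x$losses)) 0L else max(x$losses$epoch),
    final_train_loss = if (is.null(x$losses)) NA_real_ else tail(x$losses$train_loss, 1),
    final_val_loss = if (is.null(x$losses)) NA_real_ else tail(x$losses$val_loss, 1)
  )
}
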