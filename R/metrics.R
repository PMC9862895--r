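#' Distance between geometric centers of two sites (DCC)
#'
#' @param pred,true_site Integer index vectors into `points`.
#' @param points Matrix or tibble of 3D points.
#' @return Euclidean distance between the centroids, Angstrom.
#' @export
dcc <- function(pred, true_site, points) {
  if (length(pred) == 0 || length(true_site) == 0) abort("empty site")
  xyz <- if (is.matrix(points)) points else point_matrix(points)
  sqrt(sum((colMeans(xyz[pred, , drop = FALSE]) -
              colMeans(xyz[true_site, , drop = FALSE]))^2))
}

#' Discrete volumetric overlap of two sites (DVO)
#'
#' Jaccard ratio of the point-index sets: intersection over union.
#' Both sites must index the same chain's surface points. Two empty
#' sets give 0.
#'
#' @param pred,true_site Integer index vectors.
#' @return Fraction in \[0, 1\]; 1 iff the sets are equal.
#' @export
dvo <- function(pred, true_site) {
  u <- length(union(pred, true_site))
  if (u == 0) return(0)
  length(intersect(pred, true_site)) / u
}

#' Pair true binding sites with predicted sites
#'
#' Every true site larger than `size_bound` (strict) is paired with its
#' nearest predicted site by DCC and, separately, with its best
#' predicted site by DVO. True sites with no predicted site get
#' `dcc = Inf`, `dvo = 0`. The returned flags support the three standard
#' groupings: all pairings, the best pairing per chain (minimum DCC /
#' maximum DVO), and pairings with positive DVO.
#'
#' @param predicted,true_sites `binding_sites` tibbles (or lists of index
#'   vectors) over the same chain's points.
#' @param points The chain's point coordinates.
#' @param size_bound Strict lower bound on true-site size (default 0).
#' @param chain Optional chain identifier stored on the rows.
#' @return A tibble: `chain`, `true_id`, `true_size`, `dcc`, `pred_id_dcc`,
#'   `dvo`, `pred_id_dvo`, `best_dcc`, `best_dvo` (per-chain best flags).
#' @export
pair_sites <- function(predicted, true_sites, points, size_bound = 0,
                       chain = NA_character_) {
  as_sets <- function(x) {
    if (inherits(x, "binding_sites") || is.data.frame(x)) x$point_indices else x
  }
  ps <- as_sets(predicted)
  ts <- as_sets(true_sites)
  sizes <- map_int(ts, length)
  keep <- which(sizes > size_bound)
  rows <- map(keep, function(i) {
    if (length(ps) == 0) {
      return(tibble(chain = chain, true_id = i, true_size = sizes[i],
                    dcc = Inf, pred_id_dcc = NA_integer_, dvo = 0,
                    pred_id_dvo = NA_integer_))
    }
    dccs <- map_dbl(ps, ~ dcc(.x, ts[[i]], points))
    dvos <- map_dbl(ps, ~ dvo(.x, ts[[i]]))
    tibble(
      chain = chain, true_id = i, true_size = sizes[i],
      dcc = min(dccs), pred_id_dcc = which.min(dccs),
      dvo = max(dvos), pred_id_dvo = which.max(dvos)
    )
  })
  out <- if (length(rows) > 0) bind_rows(rows) else tibble(
    chain = character(), true_id = integer(), true_size = integer(),
    dcc = numeric(), pred_id_dcc = integer(), dvo = numeric(),
    pred_id_dvo = integer()
  )
  if (nrow(out) > 0) {
    out <- out |>
      group_by(.data$chain) |>
      mutate(best_dcc = .data$dcc == min(.data$dcc),
             best_dvo = .data$dvo == max(.data$dvo)) |>
      ungroup()
    # a single best per chain even under ties
    out$best_dcc <- out$best_dcc & !duplicated(paste(out$chain, out$best_dcc))
    out$best_dvo <- out$best_dvo & !duplicated(paste(out$chain, out$best_dvo))
  } else {
    out$best_dcc <- logical()
    out$best_dvo <- logical()
  }
  out
}

#' Fraction of pairings with DCC within a cutoff
#'
#' @param dcc_values Numeric DCC values (may include `Inf` for unpaired
#'   sites, which count as misses).
#' @param cutoff Distance cutoff, Angstrom (default 4, inclusive).
#' @return Fraction in \[0, 1\].
#' @export
dcc_hit_rate <- function(dcc_values, cutoff = 4.0) {
  if (length(dcc_values) == 0) abort("no pairings")
  mean(dcc_values <= cutoff)
}

#' Summarise site pairings for the standard groupings
#'
#' Mean and standard deviation of DCC (finite values) and DVO, plus the
#' DCC hit rate, for the groups: all pairings, best per chain, and
#' DVO > 0.
#'
#' @param pairings Output of [pair_sites()] (rows from one or more chains).
#' @param cutoff DCC hit cutoff (default 4).
#' @return A tibble with one row per group.
#' @export
site_metric_summary <- function(pairings, cutoff = 4.0) {
  one <- function(df, label) {
    fin <- df$dcc[is.finite(df$dcc)]
    tibble(
      group = label, n = nrow(df),
      dcc_mean = if (length(fin)) mean(fin) else NA_real_,
      dcc_sd = if (length(fin) > 1) sd(fin) else NA_real_,
      dvo_mean = if (nrow(df)) mean(df$dvo) else NA_real_,
      dvo_sd = if (nrow(df) > 1) sd(df$dvo) else NA_real_,
      dcc_hit_rate = if (nrow(df)) dcc_hit_rate(df$dcc, cutoff) else NA_real_
    )
  }
  bind_rows(
    one(pairings, "all"),
    one(pairings[pairings$best_dcc, ], "best"),
    one(pairings[pairings$dvo > 0, ], "dvo_pos")
  )
}

#' DCC/DVO curves over a sweep of true-site size bounds
#'
#' @param predicted,true_sites,points As in [pair_sites()].
#' @param bounds Size bounds to sweep (default `seq(0, 60, 5)`).
#' @param cutoff DCC hit cutoff.
#' @return Tibble of [site_metric_summary()] rows with a `size_bound`
#'   column.
#' @export
size_bound_sweep <- function(predicted, true_sites, points,
                             bounds = seq(0, 60, 5), cutoff = 4.0) {
  bind_rows(map(bounds, function(b) {
    pr <- pair_sites(predicted, true_sites, points, size_bound = b)
    if (nrow(pr) == 0) return(NULL)
    mutate(site_metric_summary(pr, cutoff), size_bound = b, .before = 1)
  }))
}

mcc_from_counts <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Per-chain classification metrics at several thresholds
#'
#' Confusion-matrix metrics of the pointwise predictions against the
#' ligandability labels, at each threshold t (a point is called
#' ligandable when its prediction is strictly above t): sensitivity,
#' specificity, precision, accuracy, balanced accuracy, F1 and the
#' Matthews correlation coefficient, plus the threshold-free mean binary
#' cross-entropy loss (identical across thresholds by construction).
#' Conventions: MCC is 0 when its denominator vanishes; sensitivity is
#' `NA` for a chain without positive labels (and precision `NA` when
#' nothing is called positive).
#'
#' @param points Labeled and predicted `surface_points`.
#' @param thresholds Numeric thresholds (default `c(0.3, 0.5, 0.7, 0.9)`).
#' @return A tibble with one row per threshold.
#' @export
chain_classification_metrics <- function(points,
                                         thresholds = c(0.3, 0.5, 0.7, 0.9)) {
  stopifnot(!anyNA(points$prediction), !anyNA(points$ligandable))
  y <- as.integer(points$ligandable)
  p <- points$prediction
  loss <- ce_loss(p, y)
  bind_rows(map(thresholds, function(t) {
    yhat <- as.integer(p > t)
    tp <- sum(yhat == 1 & y == 1); fp <- sum(yhat == 1 & y == 0)
    tn <- sum(yhat == 0 & y == 0); fn <- sum(yhat == 0 & y == 1)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0) {
      2 * prec * sens / (prec + sens)
    } else {
      NA_real_
    }
    tibble(
      threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = sens, specificity = spec, precision = prec,
      accuracy = (tp + tn) / length(y),
      balanced_accuracy = (sens + spec) / 2,
      f1 = f1, mcc = mcc_from_counts(tp, fp, tn, fn), loss = loss
    )
  }))
}

#' Aggregate per-chain metrics across chains
#'
#' Mean and standard deviation of each metric per threshold, in the
#' average +/- standard deviation reporting convention.
#'
#' @param metric_tables List of [chain_classification_metrics()] tibbles.
#' @return A long tibble: `threshold`, `metric`, `mean`, `sd`, `n_chains`.
#' @export
aggregate_chain_metrics <- function(metric_tables) {
  all <- bind_rows(metric_tables)
  all |>
    tidyr::pivot_longer(
      c("sensitivity", "specificity", "precision", "accuracy",
        "balanced_accuracy", "f1", "mcc", "loss"),
      names_to = "metric", values_to = "value"
    ) |>
    group_by(.data$threshold, .data$metric) |>
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n_chains = sum(!is.na(.data$value)), .groups = "drop"
    )
}
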