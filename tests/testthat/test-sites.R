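mk_stats <- function(qv = c(3, 60), qa = c(0.5, 6), qs = c(0.05, 3)) {
  structure(list(qv = qv, qa = qa, qs = qs), class = "site_stats")
}

test_that("site statistics use linear-interpolation percentiles", {
  sites <- tibble::tibble(
    size = 1:10,
    avg_dist = seq(1, 2.8, by = 0.2),
    std_dist = seq(0.1, 1, by = 0.1)
  )
  st <- site_statistics(sites)
  expect_equal(st$qv, c(1.9, 9.1))
  expect_equal(st$qa, unname(quantile(sites$avg_dist, c(0.1, 0.9))))
  expect_error(site_statistics(sites[1, ]), "at least 2")
  same <- tibble::tibble(size = rep(5, 10), avg_dist = 1, std_dist = 0.2)
  expect_error(site_statistics(same), "degenerate")
})

test_that("shape statistics separate spherical shells from elongated sites", {
  # symmetric shell: icosphere vertices all at radius 5 about their centroid
  sphere <- 5 * pocketscout:::icosphere_vertices(1)
  rod <- cbind(seq(0, 30, length.out = 80), 0, 0)
  p_sph <- pocketscout:::site_props_one(sphere)
  p_rod <- pocketscout:::site_props_one(rod)
  expect_lt(p_sph$std_dist, 0.1)       # all points at one radius
  expect_gt(p_rod$std_dist, 2)         # spread of center distances
})

test_that("point components agree with brute-force transitive closure", {
  three_one <- rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 2, 0), c(20, 0, 0))
  cl <- components(three_one)
  expect_length(cl, 2)
  expect_equal(sort(lengths(cl), decreasing = TRUE), c(3, 1))

  chainpts <- cbind(seq(0, by = 3.9, length.out = 10), 0, 0)
  expect_length(components(chainpts), 1)

  set.seed(8)
  for (trial in 1:5) {
    xyz <- matrix(runif(150, 0, 15), ncol = 3)
    expect_equal(
      canon_partition(components(xyz)),
      canon_partition(components_closure(xyz)),
      info = trial
    )
  }
})

test_that("threshold selection is strict and monotone", {
  yp <- c(0.6, 0.4)
  expect_equal(select_ligandable_points(yp, 0.5), 1L)
  expect_equal(select_ligandable_points(yp, 1), integer(0))
  expect_equal(select_ligandable_points(c(0.5, 0.5), 0.5), integer(0))
  set.seed(2)
  yp <- runif(50)
  for (cc in c(0.8, 0.6, 0.4, 0.2)) {
    expect_true(all(select_ligandable_points(yp, 0.81) %in%
                      select_ligandable_points(yp, cc)))
  }
})

test_that("the decision ladder fires in the printed order", {
  st <- mk_stats()
  props <- function(size, avg, std) {
    tibble::tibble(size = size, avg_dist = avg, std_dist = std)
  }
  expect_equal(compute_condition(props(10, 2, 1), 21, 100, st), "break")
  # 30% of remaining points clustered
  expect_equal(compute_condition(props(30, 2, 1), 5, 100, st), "increase_a")
  empty <- props(numeric(), numeric(), numeric())
  expect_equal(compute_condition(empty, 5, 100, st), "decrease_b")
  # each shape branch reachable
  expect_equal(compute_condition(props(2, 2, 1), 5, 100, st), "decrease_b")    # size < qv10
  expect_equal(compute_condition(props(70 * 0.25, 2, 1), 3, 100, st), "decrease_b")
  expect_equal(compute_condition(props(80, 2, 1), 3, 1000, st), "increase_a")  # size > qv90
  expect_equal(compute_condition(props(10, 0.1, 1), 3, 100, st), "decrease_b") # avg < qa10
  expect_equal(compute_condition(props(10, 8, 1), 3, 100, st), "increase_a")   # avg > qa90
  expect_equal(compute_condition(props(10, 2, 0.01), 3, 100, st), "decrease_b")# std < qs10
  expect_equal(compute_condition(props(10, 2, 5), 3, 100, st), "increase_a")   # std > qs90
  expect_equal(compute_condition(props(10, 2, 1), 3, 100, st), "decrease_b")   # default
  # the literal reading of the average-distance upper bound
  expect_equal(
    compute_condition(props(10, 2, 1), 3, 100, st, avg_upper_literal = TRUE),
    "increase_a"
  )
})

test_that("interval updates move the threshold as printed", {
  # planted blob accepted in iteration 1 keeps the loop alive; force an
  # increase_a by clustering >20% of the points
  set.seed(6)
  xyz <- rbind(
    matrix(runif(90, 0, 8), ncol = 3),          # dense block, all selected
    matrix(runif(210, 50, 200), ncol = 3)       # sparse background
  )
  yp <- c(rep(0.95, 30), rep(0.01, 70))
  st <- mk_stats(qv = c(200, 300), qa = c(90, 100), qs = c(40, 50))  # accept nothing
  out <- binding_sites(yp, xyz, st)
  tr <- attr(out, "trace")
  first_inc <- which(tr$condition == "increase_a")[1]
  expect_false(is.na(first_inc))
  # the row after the first increase_a applies a <- 0.2(b-a)+a from (0.3, 1)
  expect_equal(tr$a[first_inc + 1], 0.44)
  expect_equal(tr$b[first_inc + 1], 1)
  expect_equal(tr$c[first_inc + 1], 0.72)
})

test_that("grouping terminates within 21 iterations on adversarial inputs", {
  set.seed(12)
  xyz <- matrix(runif(600, 0, 40), ncol = 3)
  st <- mk_stats()
  for (yp in list(rep(0, 200), rep(1, 200), runif(200), rep(0.5, 200))) {
    out <- binding_sites(yp, xyz, st)
    tr <- attr(out, "trace")
    expect_lte(nrow(tr), 21)
    expect_equal(tail(tr$condition, 1), "break")
    # c stays inside (0, 1) and within the current interval
    expect_true(all(tr$c > 0 & tr$c < 1))
    expect_true(all(tr$c >= tr$a & tr$c <= tr$b))
  }
  # all-zero predictions select nothing
  expect_equal(nrow(binding_sites(rep(0, 200), xyz, st)), 0)
})

test_that("a planted blob is recovered exactly without noise", {
  f <- toy_featurized(42)
  e <- toy_entry(42)
  truth <- true_site_indices(f$points, e$ligands)
  expect_length(truth, 1)
  yp <- make_prediction_field(f$points, truth, noise_sigma = 0, seed = 1)
  ts <- true_sites_table(f$points, e$ligands)
  st <- mk_stats(
    qv = c(ts$size * 0.5, ts$size * 2),
    qa = c(ts$avg_dist * 0.5, ts$avg_dist * 2),
    qs = c(ts$std_dist * 0.5, ts$std_dist * 2)
  )
  out <- binding_sites(yp, f$points, st)
  expect_equal(nrow(out), 1)
  expect_setequal(out$point_indices[[1]], truth[[1]])
  ctr <- colMeans(pocketscout:::point_matrix(f$points)[truth[[1]], ])
  expect_lt(sqrt(sum((c(out$x, out$y, out$z) - ctr)^2)), 1)
})

test_that("accepted sites are disjoint and within bounds, independent of order", {
  f <- toy_featurized(42)
  e <- toy_entry(42)
  truth <- true_site_indices(f$points, e$ligands)
  yp <- make_prediction_field(f$points, truth, noise_sigma = 0.1, seed = 3)
  st <- mk_stats(qv = c(5, 80), qa = c(0.8, 6), qs = c(0.1, 3))
  out <- binding_sites(yp, f$points, st)
  idx <- unlist(out$point_indices)
  expect_equal(anyDuplicated(idx), 0)
  if (nrow(out) > 0) {
    expect_true(all(out$size >= st$qv[1] & out$size <= st$qv[2]))
    expect_true(all(out$avg_dist >= st$qa[1] & out$avg_dist <= st$qa[2]))
    expect_true(all(out$std_dist >= st$qs[1] & out$std_dist <= st$qs[2]))
  }
  # permuting the points permutes but does not change the sites
  set.seed(4)
  perm <- sample(nrow(f$points))
  out2 <- binding_sites(yp[perm], f$points[perm, ], st)
  expect_equal(nrow(out2), nrow(out))
  sets1 <- canon_partition(out$point_indices)
  sets2 <- canon_partition(lapply(out2$point_indices, function(s) sort(perm[s])))
  expect_equal(sets1, sets2)
})
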