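test_that("chains sort by ligand count then total ligand atoms, stably", {
  mk <- function(id, n_lig, atoms_each) {
    e <- line_chain(30, id = id)
    e$ligands <- lapply(seq_len(n_lig), function(k) {
      a <- tibble::tibble(
        name = paste0("C", seq_len(atoms_each)), element = "C",
        x = 100 + k * 10 + seq_len(atoms_each), y = 0, z = 0,
        is_heavy = TRUE, vdw_radius = 1.7
      )
      new_ligand("LIG", a)
    })
    e
  }
  two_small <- mk("two40", 2, 20)   # 2 ligands, 40 atoms
  one_big <- mk("one100", 1, 100)   # 1 ligand, 100 atoms
  expect_equal(sort_chains(list(one_big, two_small))[[1]]$structure_id, "two40")
  a60 <- mk("a60", 1, 60)
  b40 <- mk("b40", 1, 40)
  expect_equal(sort_chains(list(b40, a60))[[1]]$structure_id, "a60")
  # full tie: stable
  t1 <- mk("first", 1, 30)
  t2 <- mk("second", 1, 30)
  expect_equal(
    vapply(sort_chains(list(t1, t2)), function(x) x$structure_id, ""),
    c("first", "second")
  )
})

test_that("rmsd follows the closed formula", {
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(p, p), 0)
  expect_equal(rmsd(matrix(c(0, 0, 0), 1), matrix(c(5, 0, 0), 1)), 5)
  p1 <- rbind(c(0, 0, 0), c(0, 0, 0))
  p2 <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(rmsd(p1, p2), sqrt(2))
  expect_error(rmsd(p, p[1:3, ]), "equal length")
})

test_that("superposition recovers rigid motions exactly", {
  e <- toy_entry(42)
  moved <- move_entry(e, t = c(5, 0, 0))
  sp <- superpose(e, moved)
  expect_s3_class(sp, "superposition")
  expect_lt(sp$rmsd, 1e-6)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)

  rot <- move_entry(e, R = rot_z(pi / 2), t = c(3, -2, 7))
  sp2 <- superpose(e, rot)
  expect_lt(sp2$rmsd, 1e-6)
})

test_that("superposition rmsd under noise matches the closed-form expectation", {
  e <- toy_entry(42)
  set.seed(99)
  sig <- 0.1
  vals <- replicate(10, {
    noisy <- move_entry(e, R = rot_z(1), t = c(1, 2, 3))
    noisy$ca_coords <- noisy$ca_coords + matrix(rnorm(length(noisy$ca_coords), sd = sig), ncol = 3)
    superpose(e, noisy)$rmsd
  })
  # per-pair squared distance ~ 3 sigma^2, slightly reduced by the fit
  expect_equal(mean(vals), sig * sqrt(3), tolerance = 0.15)
})

test_that("dissimilar chains fail the superposition gate", {
  e <- toy_entry(42)
  other <- toy_entry(43)
  expect_true(similarity(smith_waterman(e$sequence, other$sequence)) < 0.9)
  expect_null(superpose(e, other))
})

test_that("merge keeps shared ligands once and adds unique ones", {
  # two identical chains; one shared ligand + one unique on each
  base <- toy_entry(77, n_pockets = 2)
  expect_length(base$ligands, 2)
  e1 <- base
  e1$structure_id <- "s1"
  e2 <- move_entry(base, R = rot_z(0.7), t = c(10, -4, 2))
  e2$structure_id <- "s2"
  # e1 keeps pocket-1 ligand + shared pocket-2; e2 has only pocket 2 (shared)
  e2$ligands <- e2$ligands[2]
  reps <- merge_cluster(list(e1, e2))
  expect_length(reps, 1)
  expect_length(reps[[1]]$ligands, 2)  # shared one not duplicated

  # distinct sites merge additively
  e3 <- move_entry(base, t = c(-8, 3, 1))
  e3$structure_id <- "s3"
  e3$ligands <- e3$ligands[1]
  e1b <- base
  e1b$ligands <- base$ligands[2]
  reps2 <- merge_cluster(list(e1b, e3))
  expect_length(reps2, 1)
  expect_length(reps2[[1]]$ligands, 2)
  man <- attr(reps2[[1]], "manifest")
  expect_equal(nrow(man), 2)

  # singleton cluster passes through unchanged
  solo <- merge_cluster(list(e1))
  expect_length(solo, 1)
  expect_identical(solo[[1]]$atoms, e1$atoms)
})

test_that("the rmsd merge gate is strict at 2 Angstrom", {
  e <- toy_entry(42)
  n <- nrow(e$ca_coords)
  # displace all C-alphas along +x by exactly delta: best fit removes the
  # mean, residual rmsd is 0, so perturb alternating +/- delta instead
  jitter_rmsd <- function(delta) {
    m <- e
    shift <- rep(c(delta, -delta), length.out = n)
    m$ca_coords[, 1] <- m$ca_coords[, 1] + shift
    m$atoms <- m$atoms  # atoms untouched; gate uses C-alphas
    sp <- superpose(e, m)
    sp$rmsd
  }
  r_small <- jitter_rmsd(1.0)
  r_large <- jitter_rmsd(3.0)
  expect_lt(r_small, 2)
  expect_gt(r_large, 2)
  mk <- function(delta, id) {
    m <- e
    m$structure_id <- id
    m$ca_coords[, 1] <- m$ca_coords[, 1] + rep(c(delta, -delta), length.out = n)
    xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
    ca_rows <- which(m$atoms$name == "CA")
    m$atoms$x[ca_rows] <- m$ca_coords[, 1]
    m
  }
  ref <- e
  ref$structure_id <- "ref"
  far <- mk(3.0, "far")
  reps <- merge_cluster(list(ref, far))
  expect_length(reps, 2)  # gate rejected, both stand alone
  near <- mk(0.5, "near")
  reps2 <- merge_cluster(list(ref, near))
  expect_length(reps2, 1)
})

test_that("merged output never grows the ligand multiset or moves the reference", {
  base <- toy_entry(77, n_pockets = 2)
  copies <- lapply(1:3, function(k) {
    m <- move_entry(base, R = rot_z(k / 3), t = rnorm(3, sd = 5))
    m$structure_id <- paste0("c", k)
    m
  })
  n_in <- sum(vapply(copies, function(x) length(x$ligands), 1L))
  reps <- merge_cluster(copies)
  n_out <- sum(vapply(reps, function(x) length(x$ligands), 1L))
  expect_lte(n_out, n_in)
  expect_lte(length(reps), length(copies))
  ids_in <- vapply(copies, function(x) x$structure_id, "")
  expect_true(all(vapply(reps, function(x) x$structure_id, "") %in% ids_in))
})
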