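test_that("protein atom typing follows the residue templates", {
  at <- tibble::tibble(
    name = c("CA", "CG", "O", "NZ", "OD1", "ZN"),
    element = c("C", "C", "O", "N", "O", "ZN"),
    x = c(0, 1.5, 3, 4.5, 6, 20), y = 0, z = 0,
    is_heavy = TRUE, vdw_radius = vdw_radius(c("C", "C", "O", "N", "O", "ZN")),
    resid = c("ALA", "PHE", "ALA", "LYS", "ASP", "ZN"),
    resno = 1:6, insert = ""
  )
  entry <- new_chain_entry("T", "A", "AFAKD", at[1:5, ],
                           as.matrix(at[1:5, c("x", "y", "z")]))
  entry$atoms <- at
  ty <- assign_atom_types(entry)
  # phenylalanine ring carbon: aromatic + hydrophobic + excluded
  phe <- ty[ty$name == "CG", ]
  expect_equal(phe$type_code, "A")
  expect_true(phe$hydrophobicity && phe$aromaticity && phe$excluded)
  # backbone carbonyl oxygen: acceptor only
  oxy <- ty[ty$name == "O", ]
  expect_equal(oxy$type_code, "OA")
  expect_true(oxy$h_acceptor && !oxy$hydrophobicity)
  # lysine NZ carries the positive charge
  expect_true(ty$positive[ty$name == "NZ"])
  expect_true(ty$negative[ty$name == "OD1"])
  # zinc: metal channel + positive ionizable + excluded volume
  zn <- ty[ty$name == "ZN", ]
  expect_equal(zn$type_code, "ZN")
  expect_true(zn$metal && zn$positive && zn$excluded)
  # every atom is in the excluded-volume channel
  expect_true(all(ty$excluded))
})

test_that("ligand typing perceives aromatic rings and carboxylates", {
  hexagon <- t(vapply(0:5, function(k) {
    1.39 * c(cos(k * pi / 3), sin(k * pi / 3), 0)
  }, numeric(3)))
  at <- tibble::tibble(
    name = paste0("C", 1:8), element = c(rep("C", 7), "O"),
    x = c(hexagon[, 1], 3.0, 4.2), y = c(hexagon[, 2], 0, 1.1),
    z = c(hexagon[, 3], 0, 0),
    is_heavy = TRUE, vdw_radius = vdw_radius(c(rep("C", 7), "O"))
  )
  # add the second carboxylate oxygen
  at <- rbind(at, tibble::tibble(
    name = "O2", element = "O", x = 4.2, y = -1.1, z = 0,
    is_heavy = TRUE, vdw_radius = vdw_radius("O")
  ))
  lig <- new_ligand("BEN", at)
  ty <- assign_atom_types(lig)
  expect_true(all(ty$aromaticity[1:6]))
  expect_false(any(ty$aromaticity[7:9]))
  expect_true(all(ty$negative[ty$name %in% c("C8", "O2")]))
})

test_that("occupancy has the stated closed form and monotonicity", {
  expect_equal(occupancy(1.7, 1.7), 1 - exp(-1))
  expect_equal(occupancy(1e6, 1.7), 0, tolerance = 1e-12)
  expect_equal(occupancy(0, 1.7), 1)
  d <- seq(1.4, 8, by = 0.05)  # below ~1.3 A the value saturates at 1
  expect_true(all(diff(occupancy(d, 1.7)) < 0))
  # numerically invert: occupancy crosses 1e-4 near 2.15 radii
  f <- function(d) occupancy(d, 1) - 1e-4
  root <- uniroot(f, c(1, 5))$root
  expect_equal(root, 10^(1 / 3), tolerance = 1e-4)
  expect_equal(root, 2.15, tolerance = 0.01)
})

test_that("grids peak at the atom, respect [0,1], and max-aggregate", {
  one_atom <- function(xyz) {
    tibble::tibble(
      name = "C", element = "C", x = xyz[1], y = xyz[2], z = xyz[3],
      vdw_radius = 1.7, type_code = "C",
      hydrophobicity = TRUE, aromaticity = FALSE, h_acceptor = FALSE,
      h_donor = FALSE, positive = FALSE, negative = FALSE, metal = FALSE,
      excluded = TRUE
    )
  }
  g <- compute_grid(one_atom(c(0, 0, 0)), c(0, 0, 0))
  v <- g$values
  expect_equal(unname(v[10, 10, 10, "excluded"]), 1)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(v[, , , "aromaticity"] == 0))
  # radial decay along an axis
  expect_true(all(diff(v[10:19, 10, 10, "excluded"]) <= 0))

  # translation equivariance
  shift <- c(13.2, -4.5, 8.8)
  g2 <- compute_grid(one_atom(shift), shift)
  expect_equal(g2$values, v, tolerance = 1e-12)

  # two-atom grid equals the elementwise max of the single-atom grids
  a1 <- one_atom(c(-1.2, 0.4, 0))
  a2 <- one_atom(c(2.0, -0.7, 1.1))
  g12 <- compute_grid(rbind(a1, a2), c(0, 0, 0))
  gmax <- pmax(compute_grid(a1, c(0, 0, 0))$values,
               compute_grid(a2, c(0, 0, 0))$values)
  expect_equal(g12$values, gmax)
})

test_that("excluded volume dominates every channel voxelwise on real chains", {
  f <- toy_featurized(42)
  pt <- as.numeric(f$points[5, c("x", "y", "z")])
  g <- compute_grid(f$typed, pt)
  for (ch in setdiff(dimnames(g$values)[[4]], "excluded")) {
    expect_true(all(g$values[, , , ch] <= g$values[, , , "excluded"] + 1e-12))
  }
  expect_true(all(g$values >= 0 & g$values <= 1))
})

test_that("dot surface counts follow the icosahedral tessellation", {
  one <- tibble::tibble(
    x = 0, y = 0, z = 0, vdw_radius = 1.7, is_heavy = TRUE
  )
  for (lev in 0:3) {
    pts <- sas_points(one, solvent_radius = 1.4, tessellation_level = lev)
    expect_equal(nrow(pts), 10 * 4^lev + 2)
    r <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
    expect_equal(r, rep(3.1, nrow(pts)), tolerance = 1e-9)
  }
  # roughly x4 per level
  n2 <- nrow(sas_points(one, tessellation_level = 2))
  n3 <- nrow(sas_points(one, tessellation_level = 3))
  expect_equal(n3 / n2, 4, tolerance = 0.05)
})

test_that("occlusion removes buried points and spares distant atoms", {
  two_same <- tibble::tibble(
    x = c(0, 0), y = 0, z = 0, vdw_radius = 1.7, is_heavy = TRUE
  )
  one <- two_same[1, ]
  expect_equal(
    nrow(sas_points(two_same, tessellation_level = 1)),
    nrow(sas_points(one, tessellation_level = 1))
  )
  far <- tibble::tibble(
    x = c(0, 100), y = 0, z = 0, vdw_radius = 1.7, is_heavy = TRUE
  )
  expect_equal(
    nrow(sas_points(far, tessellation_level = 1)),
    2 * nrow(sas_points(one, tessellation_level = 1))
  )
  # touching atoms lose the buried caps
  near <- tibble::tibble(
    x = c(0, 2.5), y = 0, z = 0, vdw_radius = 1.7, is_heavy = TRUE
  )
  expect_lt(
    nrow(sas_points(near, tessellation_level = 1)),
    2 * nrow(sas_points(one, tessellation_level = 1))
  )
})

test_that("ligandability labels follow the strict occupancy threshold", {
  pts <- tibble::tibble(
    x = c(1, 10), y = 0, z = 0,
    atom = 1L, ligandable = NA, prediction = NA_real_
  )
  class(pts) <- c("surface_points", class(pts))
  lig <- new_ligand("LIG", tibble::tibble(
    name = "C1", element = "C", x = 0, y = 0, z = 0,
    is_heavy = TRUE, vdw_radius = 1.7
  ))
  lab <- label_ligandability(pts, list(lig))
  expect_true(lab$ligandable[1])   # occupancy(1, 1.7) ~ 1
  # occupancy(10, 1.7) < 1e-4 by the closed form
  expect_lt(occupancy(10, 1.7), 1e-4)
  expect_false(lab$ligandable[2])
  # no ligands: nothing is ligandable
  none <- label_ligandability(pts, list())
  expect_false(any(none$ligandable))
  # lowering the threshold only grows the label set
  f <- toy_featurized(42)
  e <- toy_entry(42)
  hi <- label_ligandability(f$points, e$ligands, threshold = 1e-3)
  lo <- label_ligandability(f$points, e$ligands, threshold = 1e-5)
  expect_true(all(which(hi$ligandable) %in% which(lo$ligandable)))
})

test_that("label imbalance on realistic fixtures stays small", {
  f <- toy_featurized(42)
  expect_lt(mean(f$points$ligandable), 0.25)
  expect_gt(mean(f$points$ligandable), 0)
})

test_that("surface point tables round-trip through TSV", {
  f <- toy_featurized(42)
  pts <- f$points
  pts$prediction <- runif(nrow(pts))
  path <- tempfile(fileext = ".tsv")
  write_points_tsv(pts, path)
  back <- read_points_tsv(path)
  expect_equal(back$ligandable, pts$ligandable)
  expect_equal(back$x, pts$x, tolerance = 1e-9)
  expect_equal(back$prediction, pts$prediction, tolerance = 1e-9)
})
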