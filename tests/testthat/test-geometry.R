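# coarse oracle: best rmsd over a rotation grid (Euler angles) with local
# refinement by Nelder-Mead; independent of the SVD route
rmsd_grid_oracle <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  rmsd_of <- function(ang) {
    R <- rotation_about(c(0, 0, 1), ang[3]) %*%
      rotation_about(c(0, 1, 0), ang[2]) %*%
      rotation_about(c(1, 0, 0), ang[1])
    sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
  }
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a1 in seq(0, 350, 25)) for (a2 in seq(0, 170, 25)) for (a3 in seq(0, 350, 25)) {
    v <- rmsd_of(c(a1, a2, a3))
    if (v < best) { best <- v; best_ang <- c(a1, a2, a3) }
  }
  opt <- optim(best_ang, rmsd_of, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

test_that("superposing a set onto itself gives zero rmsd and identity rotation", {
  set.seed(1)
  A <- matrix(rnorm(24), 8, 3)
  f <- superpose(A, A)
  expect_lt(f$rmsd, 1e-9)
  expect_equal(f$rotation, diag(3), tolerance = 1e-9)
  expect_equal(f$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("an applied rigid motion is recovered exactly", {
  set.seed(2)
  A <- matrix(rnorm(30), 10, 3)
  R <- rotation_about(c(0, 0, 1), 90)
  B <- A %*% t(R) + matrix(c(3, -1, 2), 10, 3, byrow = TRUE)
  f <- superpose(A, B)
  expect_lt(f$rmsd, 1e-6)
  # recovered rotation is the inverse of the applied one
  expect_equal(f$rotation %*% R, diag(3), tolerance = 1e-9)
  # orthonormality and proper handedness
  expect_equal(t(f$rotation) %*% f$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
})

test_that("noisy superposition is optimal: matches a rotation-grid oracle", {
  set.seed(3)
  A <- matrix(rnorm(15), 5, 3) * 3
  B <- A %*% t(rotation_about(c(1, 1, 0), 40)) +
    matrix(rnorm(15, 0, 0.3), 5, 3) + matrix(c(1, 2, 3), 5, 3, byrow = TRUE)
  f <- superpose(A, B)
  pre <- sqrt(mean(rowSums((A - B)^2)))
  expect_lte(f$rmsd, pre)
  expect_equal(f$rmsd, rmsd_grid_oracle(A, B), tolerance = 1e-3)
})

test_that("superposition rmsd agrees with an established implementation", {
  set.seed(31)
  for (rep in 1:3) {
    A <- matrix(rnorm(30), 10, 3) * 4
    B <- A %*% t(rotation_about(rnorm(3), runif(1, 10, 170))) +
      matrix(rnorm(30, 0, 0.5), 10, 3) + matrix(rnorm(3, 0, 5), 10, 3, byrow = TRUE)
    mine <- superpose(A, B)$rmsd
    fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(A)),
                                              mobile = as.numeric(t(B))))
    ref <- bio3d::rmsd(as.numeric(t(A)), fitted)  # reported at 3 decimals
    expect_lt(abs(mine - ref), 5e-4)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("backbone rmsd is zero for a chain against itself or a moved copy", {
  ti <- make_toy_interface(8, 0)
  sa <- select_residues(ti$model, "A")
  mp <- map_residues(sa, sa)
  expect_equal(backbone_rmsd(sa, sa, mp), 0, tolerance = 1e-9)

  moved <- transform_model(ti$model, rotation_about(c(2, 1, 5), 77), c(9, -4, 3))
  sb <- select_residues(moved, "A")
  expect_equal(backbone_rmsd(sa, sb, map_residues(sa, sb)), 0, tolerance = 1e-6)
})

test_that("backbone rmsd is invariant to rigid motion of either chain", {
  set.seed(5)
  ti <- make_toy_interface(8, 0)
  # perturb a copy so the rmsd is nonzero, then move it rigidly
  warped <- ti$model
  n <- nrow(warped$atoms)
  warped$atoms$x <- warped$atoms$x + rnorm(n, 0, 0.4)
  warped$atoms$y <- warped$atoms$y + rnorm(n, 0, 0.4)
  warped$atoms$z <- warped$atoms$z + rnorm(n, 0, 0.4)
  sa <- select_residues(ti$model, "A")
  sw <- select_residues(warped, "A")
  mp <- map_residues(sa, sw)
  r0 <- backbone_rmsd(sa, sw, mp)
  expect_gt(r0, 0.1)
  moved <- transform_model(warped, rotation_about(c(1, 3, 2), 133), c(-20, 8, 5))
  r1 <- backbone_rmsd(sa, select_residues(moved, "A"), mp)
  expect_equal(r0, r1, tolerance = 1e-6)
})

test_that("principal axis follows the N-to-C sign convention", {
  rows <- lapply(1:6, function(i) atom_row("A", i, "GLY", "CA", "C", i * 3.8, 0, 0))
  m <- structure(list(accession = NULL, atoms = do.call(rbind, rows)),
                 class = "structure_model")
  ax <- principal_axis(select_residues(m))
  expect_equal(ax$direction, c(1, 0, 0), tolerance = 1e-9)

  # same points listed C-to-N: the convention flips the axis
  m_rev <- m
  m_rev$atoms <- m_rev$atoms[6:1, ]
  m_rev$atoms$resno <- 1:6
  ax_rev <- principal_axis(select_residues(m_rev))
  expect_equal(ax_rev$direction, c(-1, 0, 0), tolerance = 1e-9)
})

test_that("helical coil axis is recovered within 5 degrees", {
  for (dir in list(c(0, 0, 1), c(1, 1, 0), c(2, -1, 3))) {
    hx <- make_helix_model(30, direction = dir)
    ax <- principal_axis(select_residues(hx$model))
    ang <- acos(min(1, abs(sum(ax$direction * hx$direction)))) * 180 / pi
    expect_lt(ang, 5)
  }
})

test_that("axis angles cover the full 0-180 range and are symmetric", {
  mk_axis <- function(d) structure(list(centroid = c(0, 0, 0),
                                        direction = d / sqrt(sum(d^2))),
                                   class = "domain_axis")
  a1 <- mk_axis(c(1, 0, 0))
  expect_equal(axis_angle(a1, a1), 0)
  expect_equal(axis_angle(a1, mk_axis(c(0, 1, 0))), 90)
  expect_equal(axis_angle(a1, mk_axis(c(-1, 0, 0))), 180)
  a2 <- mk_axis(c(1, 2, -1))
  expect_equal(axis_angle(a1, a2), axis_angle(a2, a1))
})

test_that("crossing angles are invariant to rigid motion of the whole complex", {
  h1 <- make_helix_model(25, direction = c(0, 0, 1), chain = "A")
  h2 <- make_helix_model(25, direction = c(sin(150 * pi / 180), 0,
                                           cos(150 * pi / 180)),
                         origin = c(15, 0, 0), chain = "B")
  m <- structure(list(accession = NULL,
                      atoms = rbind(h1$model$atoms, h2$model$atoms)),
                 class = "structure_model")
  ang0 <- axis_angle(principal_axis(select_residues(m, "A")),
                     principal_axis(select_residues(m, "B")))
  expect_equal(ang0, 150, tolerance = 1)
  moved <- transform_model(m, rotation_about(c(3, 1, 1), 67), c(12, -40, 7))
  ang1 <- axis_angle(principal_axis(select_residues(moved, "A")),
                     principal_axis(select_residues(moved, "B")))
  expect_equal(ang0, ang1, tolerance = 1e-6)
})

test_that("inter-domain elbow angles report conformational differences", {
  # two-domain molecule in two 'crystal forms' whose elbow differs by 14 deg
  two_domain <- function(elbow_deg) {
    d1 <- make_helix_model(20, direction = c(0, 0, 1), chain = "A")
    u <- c(sin(elbow_deg * pi / 180), 0, cos(elbow_deg * pi / 180))
    d2 <- make_helix_model(20, direction = u, origin = c(0, 0, 35),
                           chain = "A")
    d2$model$atoms$resno <- d2$model$atoms$resno + 100
    structure(list(accession = NULL,
                   atoms = rbind(d1$model$atoms, d2$model$atoms)),
              class = "structure_model")
  }
  elbow <- function(m) axis_angle(
    principal_axis(select_residues(m, resno = 1:20)),
    principal_axis(select_residues(m, resno = 101:120)))
  form1 <- two_domain(140); form2 <- two_domain(154)
  expect_equal(abs(elbow(form1) - elbow(form2)), 14, tolerance = 1)
})
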