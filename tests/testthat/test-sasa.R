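test_that("an isolated atom's SASA matches the closed form within 0.5%", {
  for (r in c(1.4, 1.8, 2.2)) {
    ts <- make_two_sphere_model(r, r, 100)  # far apart: both isolated
    s <- compute_sasa(ts$model, ts$params)
    expected <- 4 * pi * (r + 1.4)^2
    expect_lt(abs(s$atom_area[1] - expected) / expected, 0.005)
    expect_lt(abs(s$atom_area[2] - expected) / expected, 0.005)
  }
})

test_that("atoms beyond contact range do not occlude each other", {
  r <- 1.8
  ts <- make_two_sphere_model(r, r, 2 * (r + 1.4) + 0.01)
  s <- compute_sasa(ts$model, ts$params)
  expected <- 4 * pi * (r + 1.4)^2
  expect_equal(s$atom_area, rep(expected, 2), tolerance = 0.005)
})

test_that("two-sphere SASA matches the analytic spherical-cap oracle", {
  r1 <- 1.6; r2 <- 2.0
  iso1 <- 4 * pi * (r1 + 1.4)^2
  iso2 <- 4 * pi * (r2 + 1.4)^2
  for (d in seq(0.6, 6.4, by = 0.4)) {
    ts <- make_two_sphere_model(r1, r2, d)
    s <- compute_sasa(ts$model, ts$params)
    an <- two_sphere_sasa_analytic(r1, r2, d)
    expect_lt(abs(s$atom_area[1] - an$area1) / iso1, 0.01,
              label = sprintf("sphere 1 area error at d=%.1f", d))
    expect_lt(abs(s$atom_area[2] - an$area2) / iso2, 0.01,
              label = sprintf("sphere 2 area error at d=%.1f", d))
  }
})

test_that("a sphere engulfed by a larger one has zero SASA", {
  ts <- make_two_sphere_model(1.0, 2.5, 0.3)  # |R1-R2| = 1.5 > d
  s <- compute_sasa(ts$model, ts$params)
  expect_equal(s$atom_area[1], 0)
  an <- two_sphere_sasa_analytic(1.0, 2.5, 0.3)
  expect_equal(an$area1, 0)
  expect_equal(s$atom_area[2], an$area2, tolerance = 1)
})

test_that("adding an atom never increases any other atom's SASA", {
  set.seed(7)
  n <- 25
  rows <- lapply(seq_len(n), function(i)
    atom_row("A", i, "ALA", "C1", "C",
             runif(1, 0, 12), runif(1, 0, 12), runif(1, 0, 12)))
  base <- structure(list(accession = NULL, atoms = do.call(rbind, rows)),
                    class = "structure_model")
  s0 <- compute_sasa(base)$atom_area
  for (k in 1:4) {
    extra <- atom_row("A", n + k, "ALA", "C1", "C",
                      runif(1, 0, 12), runif(1, 0, 12), runif(1, 0, 12))
    grown <- structure(list(accession = NULL,
                            atoms = rbind(base$atoms, extra)),
                       class = "structure_model")
    s1 <- compute_sasa(grown)$atom_area
    expect_true(all(s1[seq_len(n)] <= s0 + 1e-9))
  }
})

test_that("SASA converges: doubling the point count moves the total < 0.5%", {
  set.seed(11)
  n <- 100
  el <- sample(c("C", "N", "O", "S"), n, replace = TRUE,
               prob = c(.6, .2, .15, .05))
  rows <- lapply(seq_len(n), function(i)
    atom_row("A", (i - 1) %/% 5 + 1, "ALA", paste0(el[i], i), el[i],
             rnorm(1, 0, 6), rnorm(1, 0, 6), rnorm(1, 0, 6)))
  m <- structure(list(accession = NULL, atoms = do.call(rbind, rows)),
                 class = "structure_model")
  t1 <- compute_sasa(m, sasa_params(n_points = 960))$total
  t2 <- compute_sasa(m, sasa_params(n_points = 1920))$total
  expect_lt(abs(t2 - t1) / t1, 0.005)
})

test_that("cell-list engine equals the all-pairs brute force (different points)", {
  set.seed(21)
  n <- 60
  el <- sample(c("C", "N", "O"), n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i)
    atom_row("A", i, "ALA", paste0(el[i], i), el[i],
             rnorm(1, 0, 5), rnorm(1, 0, 5), rnorm(1, 0, 5)))
  m <- structure(list(accession = NULL, atoms = do.call(rbind, rows)),
                 class = "structure_model")
  p <- sasa_params()
  mine <- compute_sasa(m, p)
  ref <- sasa_brute_force(m, p)
  expect_lt(abs(mine$total - sum(ref)) / mine$total, 0.02)
})

test_that("independent reference implementation agrees within 2% on a toy protein", {
  ti <- make_toy_interface(8, 3)
  p <- sasa_params()
  mine <- compute_sasa(ti$model, p)

  a <- ti$model$atoms
  tsv <- tempfile(fileext = ".tsv")
  out <- tempfile(fileext = ".txt")
  write.table(data.frame(a$x, a$y, a$z, unname(p$radii[a$element])),
              tsv, row.names = FALSE, col.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "import biotite.structure as struc",
    "d = np.loadtxt(sys.argv[1])",
    "arr = struc.AtomArray(len(d))",
    "arr.coord = d[:, :3]",
    "arr.chain_id[:] = 'A'; arr.res_id[:] = np.arange(len(d)) + 1",
    "arr.res_name[:] = 'ALA'; arr.atom_name[:] = 'CA'; arr.element[:] = 'C'",
    "s = struc.sasa(arr, probe_radius=1.4, vdw_radii=d[:, 3], point_number=960)",
    "open(sys.argv[2], 'w').write(repr(float(s.sum())) + '\\n')"), script)
  status <- system2("python", c(script, tsv, out))
  expect_equal(status, 0L)
  ref_total <- as.numeric(readLines(out))
  expect_lt(abs(mine$total - ref_total) / ref_total, 0.02)
})

test_that("per-residue sums reconstruct the total and errors are informative", {
  ti <- make_toy_interface(5, 2)
  s <- compute_sasa(ti$model)
  expect_equal(sum(s$residue_area$area), s$total, tolerance = 1e-9)
  expect_true(all(s$atom_area >= 0))

  bad <- ti$model
  bad$atoms$element[3] <- "ZZ"
  expect_error(compute_sasa(bad), "ZZ")
  expect_error(sasa_params(probe_radius = -1))
  expect_error(sasa_params(n_points = 10))
})
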