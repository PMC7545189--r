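test_that("a backbone N...O pair forms a bond iff geometry permits", {
  m <- mk_model(atom_row("A", 1, "GLY", "N", "N", 0, 0, 0),
                atom_row("A", 1, "GLY", "CA", "C", -1.2, 0.9, 0),
                atom_row("B", 1, "GLY", "O", "O", 2.9, 0, 0),
                atom_row("B", 1, "GLY", "C", "C", 3.9, 0.8, 0))
  hb <- find_hbonds(select_residues(m, "A"), select_residues(m, "B"))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_gt(hb$angle, 90)

  far <- m
  far$atoms$x[3:4] <- far$atoms$x[3:4] + 1.3  # N...O now 4.2 A
  expect_equal(nrow(find_hbonds(select_residues(far, "A"),
                                select_residues(far, "B"))), 0)

  # angle criterion: acceptor on the antecedent side of the donor
  bent <- mk_model(atom_row("A", 1, "GLY", "N", "N", 0, 0, 0),
                   atom_row("A", 1, "GLY", "CA", "C", 1.45, 0, 0),
                   atom_row("B", 1, "GLY", "O", "O", 2.9, 0.4, 0),
                   atom_row("B", 1, "GLY", "C", "C", 3.9, 1.2, 0))
  expect_equal(nrow(find_hbonds(select_residues(bent, "A"),
                                select_residues(bent, "B"))), 0)
})

test_that("salt bridges require charged groups within range", {
  m <- mk_model(atom_row("A", 1, "LYS", "NZ", "N", 0, 0, 0),
                atom_row("A", 1, "LYS", "CE", "C", -1.5, 0, 0),
                atom_row("B", 9, "GLU", "OE1", "O", 3.2, 0, 0),
                atom_row("B", 9, "GLU", "OE2", "O", 3.8, 1.1, 0),
                atom_row("B", 9, "GLU", "CD", "C", 4.1, 0.4, 0))
  sb <- find_salt_bridges(select_residues(m, "A"), select_residues(m, "B"))
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance, 3.2, tolerance = 1e-9)
  expect_equal(sb$basic_resname, "LYS")

  far <- m
  far$atoms$x[3:5] <- far$atoms$x[3:5] + 2.8  # min N-O now 6 A
  expect_equal(nrow(find_salt_bridges(select_residues(far, "A"),
                                      select_residues(far, "B"))), 0)
})

test_that("independent ion pairs are counted once per residue pair", {
  m <- mk_model(
    atom_row("A", 1, "ARG", "NH1", "N", 0, 0, 0),
    atom_row("A", 1, "ARG", "NH2", "N", 0, 2.3, 0),
    atom_row("A", 1, "ARG", "CZ", "C", -0.8, 1.15, 0),
    atom_row("B", 1, "ASP", "OD1", "O", 3.0, 0, 0),
    atom_row("B", 1, "ASP", "OD2", "O", 3.0, 2.3, 0),  # both NH-OD pairs in range
    atom_row("A", 50, "ARG", "NH1", "N", 20, 0, 0),
    atom_row("A", 50, "ARG", "CZ", "C", 19.2, 1.0, 0),
    atom_row("B", 50, "ASP", "OD1", "O", 23.5, 0, 0))
  sb <- find_salt_bridges(select_residues(m, "A"), select_residues(m, "B"))
  expect_equal(nrow(sb), 2)  # one per residue pair despite 4 close atom pairs
})

test_that("glycan hydroxyls donate and accept hydrogen bonds", {
  m <- mk_model(atom_row("A", 201, "NAG", "O3", "O", 0, 0, 0, het = TRUE),
                atom_row("A", 201, "NAG", "C3", "C", -1.4, 0, 0, het = TRUE),
                atom_row("B", 122, "PHE", "O", "O", 2.8, 0.5, 0),
                atom_row("B", 122, "PHE", "C", "C", 3.8, 1.2, 0),
                atom_row("B", 124, "GLU", "OE1", "O", 0.2, 3.1, 0),
                atom_row("B", 124, "GLU", "CD", "C", 0.4, 4.4, 0))
  hb <- find_hbonds(select_residues(m, "A"), select_residues(m, "B"))
  expect_gte(nrow(hb), 2)
  expect_true("NAG" %in% hb$donor_resname)
})

test_that("counts are symmetric in the two sides and monotone in d_max", {
  m <- make_random_contact_model(60, seed = 4)
  sa <- select_residues(m, "A"); sb <- select_residues(m, "B")
  hb_ab <- find_hbonds(sa, sb)
  hb_ba <- find_hbonds(sb, sa)
  expect_equal(nrow(hb_ab), nrow(hb_ba))
  expect_setequal(hbond_keys(m, hb_ab), hbond_keys(m, hb_ba))
  expect_equal(nrow(find_salt_bridges(sa, sb)), nrow(find_salt_bridges(sb, sa)))

  n_by_cut <- vapply(c(2.8, 3.2, 3.5, 4.0), function(d)
    nrow(find_hbonds(sa, sb, contact_criteria(d_max = d))), numeric(1))
  expect_true(all(diff(n_by_cut) >= 0))
})

test_that("finders agree exactly with all-pairs brute-force scans", {
  for (seed in c(1, 2, 3, 8)) {
    m <- make_random_contact_model(60, seed = seed)  # ~170 atoms
    sa <- select_residues(m, "A"); sb <- select_residues(m, "B")
    hb <- find_hbonds(sa, sb)
    expect_identical(hbond_keys(m, hb), hbond_brute_force(m, "A", "B"),
                     label = paste("hbond scan, seed", seed))

    sb_found <- find_salt_bridges(sa, sb)
    # brute force: every basic/acidic residue pair with min N-O <= 4
    a <- m$atoms
    basic <- which(paste(a$resname, a$atom) %in%
                     c("LYS NZ", "ARG NE", "ARG NH1", "ARG NH2"))
    acidic <- which(paste(a$resname, a$atom) %in%
                      c("ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2"))
    expected <- character(0)
    for (bi in basic) for (ai in acidic) {
      if ((a$chain[bi] == "A") == (a$chain[ai] == "A")) next
      d <- sqrt((a$x[bi] - a$x[ai])^2 + (a$y[bi] - a$y[ai])^2 +
                  (a$z[bi] - a$z[ai])^2)
      if (d <= 4.0)
        expected <- c(expected, paste(a$chain[bi], a$resno[bi],
                                      a$chain[ai], a$resno[ai]))
    }
    got <- if (nrow(sb_found) == 0) character(0) else
      paste(sb_found$basic_chain, sb_found$basic_resno,
            sb_found$acidic_chain, sb_found$acidic_resno)
    expect_setequal(got, unique(expected))
  }
})

test_that("overlapping selections are rejected", {
  m <- make_random_contact_model(10, seed = 1)
  sa <- select_residues(m, "A")
  expect_error(find_hbonds(sa, sa), "overlap")
})
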