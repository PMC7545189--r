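# shared fixture builders and independent oracles

atom_row <- function(chain, resno, resname, atom, element, x, y, z,
                     het = FALSE, icode = "", occ = 1) {
  data.frame(chain = chain, resno = as.integer(resno), icode = icode,
             resname = resname, atom = atom, altloc = "", element = element,
             x = x, y = y, z = z, occ = occ, bfactor = 0, hetero = het,
             stringsAsFactors = FALSE)
}

mk_model <- function(...) {
  structure(list(accession = NULL, atoms = do.call(rbind, list(...))),
            class = "structure_model")
}

# ---- PDB text fixtures -------------------------------------------------

pdb_line <- function(rec, serial, atom, alt, resname, chain, resno, x, y, z,
                     occ = 1, b = 0, element = substr(atom, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, ifelse(nchar(atom) < 4, paste0(" ", atom), atom),
          alt, resname, chain, resno, x, y, z, occ, b, element)
}

pdb_minimal_gly <- function() c(
  pdb_line("ATOM", 1, "N",  " ", "GLY", "A", 1, 11.104, 6.134, -6.504),
  pdb_line("ATOM", 2, "CA", " ", "GLY", "A", 1, 11.639, 6.071, -5.147),
  pdb_line("ATOM", 3, "C",  " ", "GLY", "A", 1, 10.729, 6.234, -3.936),
  "END")

pdb_altloc_fixture <- function() c(
  pdb_line("ATOM", 1, "N",  " ", "ALA", "A", 1, 0, 0, 0),
  pdb_line("ATOM", 2, "CA", "A", "ALA", "A", 1, 1.0, 0, 0, occ = 0.6),
  pdb_line("ATOM", 3, "CA", "B", "ALA", "A", 1, 1.5, 0, 0, occ = 0.4),
  "END")

pdb_altloc_tie_fixture <- function() c(
  pdb_line("ATOM", 1, "CA", "B", "ALA", "A", 1, 1.5, 0, 0, occ = 0.5),
  pdb_line("ATOM", 2, "CA", "A", "ALA", "A", 1, 1.0, 0, 0, occ = 0.5),
  "END")

# 2 protein chains (2 residues each), 2 NAG glycan residues, 5 waters
pdb_glyco_fixture <- function() {
  ln <- c()
  s <- 0
  for (ch in c("A", "B")) for (r in 1:2) {
    for (a in list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"))) {
      s <- s + 1
      ln <- c(ln, pdb_line("ATOM", s, a[1], " ", "ALA", ch, r,
                           s * 2.0, ifelse(ch == "A", 0, 8), 0,
                           element = a[2]))
    }
  }
  for (r in 1:2) for (a in c("C1", "O5")) {
    s <- s + 1
    ln <- c(ln, pdb_line("HETATM", s, a, " ", "NAG", "A", 200 + r,
                         s * 2.0, 4, 0, element = substr(a, 1, 1)))
  }
  for (r in 1:5) {
    s <- s + 1
    ln <- c(ln, pdb_line("HETATM", s, "O", " ", "HOH", "W", 300 + r,
                         s * 2.0, 20, 0, element = "O"))
  }
  c(ln, "END")
}

cif_fixture <- function() c(
  "data_FIX", "#", "loop_",
  "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
  "_atom_site.label_atom_id", "_atom_site.label_alt_id",
  "_atom_site.label_comp_id", "_atom_site.label_asym_id",
  "_atom_site.label_entity_id", "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
  "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
  "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
  "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
  "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 N N . GLY A 1 1 ? 11.104 6.134 -6.504 1.00 0.00 ? 1 GLY A N 1",
  "ATOM 2 C CA . GLY A 1 1 ? 11.639 6.071 -5.147 1.00 0.00 ? 1 GLY A CA 1",
  "HETATM 3 C C1 . NAG B 2 . ? 15.0 6.0 -3.0 1.00 0.00 ? 201 NAG A C1 1",
  "HETATM 4 O O . HOH C 3 . ? 20.0 6.0 -3.0 1.00 0.00 ? 301 HOH A O 1",
  "#")

# ---- independent oracles ----------------------------------------------

# SASA by all-pairs brute force with a seeded random point set (independent
# of the engine's deterministic spiral and of its cell list)
sasa_brute_force <- function(model, params, n_points = 2000, seed = 99) {
  a <- model$atoms
  set.seed(seed)
  v <- matrix(rnorm(3 * n_points), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  R <- unname(params$radii[a$element]) + params$probe_radius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  vapply(seq_len(nrow(a)), function(i) {
    pts <- sweep(v * R[i], 2, xyz[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in seq_len(nrow(a))[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      buried <- buried | d2 < R[j]^2
    }
    mean(!buried) * 4 * pi * R[i]^2
  }, numeric(1))
}

# exhaustive global-alignment enumeration (no DP): max identity score with
# affine gap cost open + extend * length, same convention as the implementation
align_enum_score <- function(a, b, gap_open = 5, gap_extend = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  gap_cost <- function(state_new, state_old) {
    gap_extend + if (state_new != state_old) gap_open else 0
  }
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      best <- max(best, (a[i] == b[j]) + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(a)) {
      best <- max(best, rec(i + 1, j, "ga") - gap_cost("ga", state))
    }
    if (j <= length(b)) {
      best <- max(best, rec(i, j + 1, "gb") - gap_cost("gb", state))
    }
    best
  }
  rec(1, 1, "m")
}

# independent hydrogen-bond scan: own typing tables, all atom pairs
hbond_brute_force <- function(model, chainsA, chainsB, d_max = 3.5,
                              angle_min = 90) {
  a <- model$atoms
  sugars <- c("NAG", "NDG", "MAN", "BMA", "GAL", "GLC", "FUC", "FUL",
              "XYS", "SIA", "BGC")
  donor <- (!a$hetero & a$atom == "N" & a$resname != "PRO") |
    paste(a$resname, a$atom) %in% c(
      "ARG NE", "ARG NH1", "ARG NH2", "LYS NZ", "ASN ND2", "GLN NE2",
      "HIS ND1", "HIS NE2", "TRP NE1", "SER OG", "THR OG1", "TYR OH",
      "CYS SG") |
    (a$resname %in% sugars & a$element == "O" & a$atom != "O5")
  acceptor <- (!a$hetero & a$element == "O") |
    paste(a$resname, a$atom) %in% c(
      "ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2", "ASN OD1", "GLN OE1",
      "HIS ND1", "HIS NE2", "SER OG", "THR OG1", "TYR OH", "MET SD") |
    (a$resname %in% sugars & a$element == "O")

  pairs <- character(0)
  for (di in which(donor)) {
    for (ai in which(acceptor)) {
      sd_ <- a$chain[di] %in% chainsA; sa_ <- a$chain[ai] %in% chainsA
      if (sd_ == sa_) next  # need cross-side
      d <- sqrt((a$x[di] - a$x[ai])^2 + (a$y[di] - a$y[ai])^2 +
                  (a$z[di] - a$z[ai])^2)
      if (d > d_max) next
      same <- which(a$chain == a$chain[di] & a$resno == a$resno[di] &
                      a$icode == a$icode[di])
      same <- setdiff(same, di)
      if (length(same) > 0) {
        dd <- (a$x[same] - a$x[di])^2 + (a$y[same] - a$y[di])^2 +
          (a$z[same] - a$z[di])^2
        an <- same[which.min(dd)]
        v1 <- c(a$x[an] - a$x[di], a$y[an] - a$y[di], a$z[an] - a$z[di])
        v2 <- c(a$x[ai] - a$x[di], a$y[ai] - a$y[di], a$z[ai] - a$z[di])
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang < angle_min) next
      }
      pairs <- c(pairs, paste(di, ai))
    }
  }
  sort(pairs)
}

# random mixed-residue two-chain fixture for contact stress tests
make_random_contact_model <- function(n_residues = 60, seed = 1,
                                      box = 24) {
  set.seed(seed)
  templates <- list(
    list(resname = "LYS", atoms = c("CE", "NZ"), el = c("C", "N")),
    list(resname = "ARG", atoms = c("CZ", "NH1", "NH2"), el = c("C", "N", "N")),
    list(resname = "GLU", atoms = c("CD", "OE1", "OE2"), el = c("C", "O", "O")),
    list(resname = "ASP", atoms = c("CG", "OD1", "OD2"), el = c("C", "O", "O")),
    list(resname = "SER", atoms = c("CB", "OG"), el = c("C", "O")),
    list(resname = "GLY", atoms = c("N", "CA", "C", "O"),
         el = c("N", "C", "C", "O")),
    list(resname = "NAG", atoms = c("C3", "O3"), el = c("C", "O"),
         het = TRUE))
  rows <- list()
  for (i in seq_len(n_residues)) {
    tp <- templates[[sample.int(length(templates), 1)]]
    centre <- runif(3, 0, box)
    chain <- if (i %% 2 == 0) "A" else "B"
    local <- matrix(rnorm(3 * length(tp$atoms), 0, 0.8), ncol = 3)
    for (k in seq_along(tp$atoms)) {
      rows[[length(rows) + 1L]] <- atom_row(
        chain, i, tp$resname, tp$atoms[k], tp$el[k],
        centre[1] + local[k, 1], centre[2] + local[k, 2],
        centre[3] + local[k, 3], het = isTRUE(tp$het))
    }
  }
  structure(list(accession = NULL, atoms = do.call(rbind, rows)),
            class = "structure_model")
}

# key identifying an hbond row by donor/acceptor atom (for set comparison)
hbond_keys <- function(model, hb) {
  a <- model$atoms
  idx_of <- function(chain, resno, atom) {
    which(a$chain == chain & a$resno == resno & a$atom == atom)
  }
  if (nrow(hb) == 0) return(character(0))
  sort(vapply(seq_len(nrow(hb)), function(i) {
    paste(idx_of(hb$donor_chain[i], hb$donor_resno[i], hb$donor_atom[i]),
          idx_of(hb$acceptor_chain[i], hb$acceptor_resno[i], hb$acceptor_atom[i]))
  }, character(1)))
}
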