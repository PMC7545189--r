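#' Two-sphere model with analytically known SASA and BSA
#'
#' Two single-atom residues on chains A and B at centre separation \code{d}
#' along x. Elements are named \code{X1}/\code{X2} so arbitrary radii can be
#' supplied via \code{\link{two_sphere_params}}; the exact expected areas come
#' from \code{\link{two_sphere_sasa_analytic}}.
#'
#' @param r1,r2 sphere radii, angstrom (> 0); stored in the returned params.
#' @param d centre separation, angstrom (>= 0).
#' @return list: \code{model} (a \code{structure_model}), \code{params}
#'   (a \code{sasa_params} whose radii table carries r1, r2), \code{r1},
#'   \code{r2}, \code{d}.
#' @export
make_two_sphere_model <- function(r1, r2, d) {
  .stop_if(r1 <= 0 || r2 <= 0 || d < 0, "r1, r2 must be > 0 and d >= 0")
  atoms <- data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), icode = "",
    resname = "SPH", atom = c("S1", "S2"), altloc = "",
    element = c("X1", "X2"),
    x = c(0, d), y = 0, z = 0, occ = 1, bfactor = 0, hetero = FALSE,
    stringsAsFactors = FALSE)
  model <- structure(list(accession = "two-sphere", atoms = atoms),
                     class = "structure_model")
  list(model = model, params = two_sphere_params(r1, r2),
       r1 = r1, r2 = r2, d = d)
}

#' @rdname make_two_sphere_model
#' @param probe_radius,n_points see \code{\link{sasa_params}}.
#' @export
two_sphere_params <- function(r1, r2, probe_radius = 1.4, n_points = 960) {
  sasa_params(probe_radius = probe_radius, n_points = n_points,
              radii = c(X1 = r1, X2 = r2))
}

# minimal alanine-like residue template (N, CA, C, O, CB), ideal-ish geometry
.ALA_TEMPLATE <- matrix(c(
  -1.46,  0.00,  0.00,   # N
   0.00,  0.00,  0.00,   # CA
   1.10,  1.05,  0.00,   # C
   2.15,  1.06,  0.70,   # O
  -0.54, -0.77,  1.21),  # CB
  ncol = 3, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O", "CB"), c("x", "y", "z")))

.ala_residue <- function(chain, resno, offset, flip_y = FALSE) {
  m <- .ALA_TEMPLATE
  if (flip_y) m[, "y"] <- -m[, "y"]
  data.frame(chain = chain, resno = as.integer(resno), icode = "",
             resname = "ALA", atom = rownames(m), altloc = "",
             element = substr(rownames(m), 1, 1),
             x = m[, "x"] + offset[1], y = m[, "y"] + offset[2],
             z = m[, "z"] + offset[3],
             occ = 1, bfactor = 0, hetero = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Toy two-chain interface with a known number of contacting residues
#'
#' Two poly-alanine strands of \code{n_residues} each, laid out along x with
#' 12 angstrom residue spacing (far enough apart that residues never occlude
#' their own neighbours). Chain B residues sit across from their chain A
#' partners: the \code{contact} residues at a close gap (default 6 angstrom
#' between backbone planes, well inside burial range for a 1.4 angstrom
#' probe), all others at \code{far_gap} (no burial possible). By construction
#' the interface footprint at tau = 1 contains exactly the designated
#' residues on each side.
#'
#' @param n_residues residues per chain.
#' @param contact integer vector of contacting residue numbers (1-based), or a
#'   single count meaning residues \code{1:contact}.
#' @param contact_gap,far_gap inter-strand gaps, angstrom; \code{contact_gap}
#'   must allow burial (< 2 * (r_C + probe) plus atom extent) and
#'   \code{far_gap} must forbid it.
#' @return list: \code{model}, \code{contact_resno} (the designated residue
#'   numbers), \code{expected_footprint} (c(k, k)).
#' @export
make_toy_interface <- function(n_residues = 10, contact = 4,
                               contact_gap = 6, far_gap = 30) {
  .stop_if(n_residues < 1, "need at least one residue")
  # a single value is a count (residues 1..k); a vector is explicit numbers
  contact_resno <- if (length(contact) == 1L) {
    .stop_if(contact < 0 || contact > n_residues,
             "contact count outside 0..n_residues")
    if (contact == 0) integer(0) else seq_len(contact)
  } else as.integer(contact)
  .stop_if(any(contact_resno > n_residues | contact_resno < 1),
           "contact residues outside 1..n_residues")
  .stop_if(contact_gap >= far_gap, "contact_gap must be < far_gap")

  spacing <- 12
  rows <- list()
  for (i in seq_len(n_residues)) {
    rows[[length(rows) + 1L]] <- .ala_residue("A", i, c(spacing * i, 0, 0))
    gap <- if (i %in% contact_resno) contact_gap else far_gap
    rows[[length(rows) + 1L]] <- .ala_residue("B", i, c(spacing * i, gap, 0),
                                              flip_y = TRUE)
  }
  atoms <- do.call(rbind, rows)
  model <- structure(list(accession = "toy-interface", atoms = atoms),
                     class = "structure_model")
  list(model = model, contact_resno = sort(contact_resno),
       expected_footprint = rep(length(contact_resno), 2))
}

#' Paired natural/antibody toy complexes with known mimicry fraction
#'
#' Builds a shared target chain T (poly-alanine) plus a "natural ligand"
#' chain L contacting exactly \code{n_interface} designated target residues,
#' and a second copy of the target plus an "antibody" chain H contacting
#' exactly \code{n_shared} of those residues (and, when room allows, two
#' peripheral residues outside the natural footprint, mirroring the enlarged
#' antibody epitopes seen in real complexes). The antibody complex is given a
#' seeded random rigid motion, so identical coordinates can never fake the
#' overlap. The ground truth is \code{f = n_shared / n_interface}.
#'
#' @param n_interface number of natural-interface residues (>= 1).
#' @param n_shared number of them also contacted by the antibody
#'   (0 <= n_shared <= n_interface).
#' @param seed integer; orients the rigid motion of the antibody complex.
#' @return a \code{mimicry_scenario}: list with \code{natural} and
#'   \code{antibody} (\code{structure_model}s; target is chain "T", partner
#'   chains "L"/"H"), \code{truth_f}, \code{n_interface}, \code{n_shared},
#'   \code{natural_resno}, \code{shared_resno}.
#' @export
make_mimicry_pair <- function(n_interface, n_shared, seed = 1L) {
  .stop_if(n_interface < 1, "n_interface must be >= 1")
  .stop_if(n_shared < 0 || n_shared > n_interface,
           "need 0 <= n_shared <= n_interface")
  n_res <- n_interface + 4  # room for two peripheral antibody contacts + spares
  natural_resno <- seq_len(n_interface)
  shared_resno <- if (n_shared > 0) natural_resno[seq_len(n_shared)] else integer(0)
  peripheral <- (n_interface + 2):(n_interface + 3)

  build <- function(partner_chain, contact_resno) {
    spacing <- 12
    rows <- list()
    for (i in seq_len(n_res)) {
      rows[[length(rows) + 1L]] <- .ala_residue("T", i, c(spacing * i, 0, 0))
      gap <- if (i %in% contact_resno) 6 else 30
      rows[[length(rows) + 1L]] <- .ala_residue(partner_chain, i,
                                                c(spacing * i, gap, 0),
                                                flip_y = TRUE)
    }
    structure(list(accession = NULL, atoms = do.call(rbind, rows)),
              class = "structure_model")
  }

  natural <- build("L", natural_resno)
  antibody <- build("H", c(shared_resno, peripheral))

  set.seed(as.integer(seed))
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  antibody <- transform_model(antibody,
                              rotation = rotation_about(ax, stats::runif(1, 10, 170)),
                              translation = rnorm(3, 0, 20))

  structure(list(natural = natural, antibody = antibody,
                 target_chain = "T", natural_chain = "L", antibody_chain = "H",
                 truth_f = n_shared / n_interface,
                 n_interface = n_interface, n_shared = n_shared,
                 natural_resno = natural_resno, shared_resno = shared_resno),
            class = "mimicry_scenario")
}

#' Synthetic BLI dataset with bundled ground truth
#'
#' Thin wrapper over \code{\link{simulate_sensorgram}} that mirrors a standard
#' experimental design — a 1:2 serial dilution series and 180 s association
#' and dissociation phases — and bundles the generating parameters for
#' recovery tests.
#'
#' @param truth a \code{kinetic_model}.
#' @param concentrations analyte concentrations, M; default a 6-step 1:2
#'   dilution from 500 nM.
#' @param t_assoc,t_dissoc,dt,noise_sd,seed see
#'   \code{\link{simulate_sensorgram}}.
#' @return list: \code{sensorgram}, \code{truth}.
#' @export
make_bli_dataset <- function(truth = kinetic_model(kon = 2.2e5, koff = 0.16,
                                                   Rmax = 0.8),
                             concentrations = dilution_series(500e-9, 6),
                             t_assoc = 180, t_dissoc = 180, dt = 1,
                             noise_sd = 0, seed = 1L) {
  sg <- simulate_sensorgram(truth, concentrations, t_assoc, t_dissoc, dt,
                            noise_sd, seed)
  list(sensorgram = sg, truth = truth)
}

#' Helical C-alpha trace about a known axis
#'
#' Ideal-geometry helix (default: alpha-helical 1.5 angstrom rise, 100 degrees
#' per residue, 2.3 angstrom radius) of C-alpha-only glycine residues wound
#' about a given axis — the fixture for validating \code{\link{principal_axis}}
#' against a known generating direction.
#'
#' @param n residues.
#' @param direction generating axis (normalized internally); the helix runs
#'   N-to-C along it.
#' @param origin start point.
#' @param rise,radius,turn helix geometry (angstrom, angstrom, degrees).
#' @param chain chain identifier.
#' @return list: \code{model}, \code{direction} (unit truth axis).
#' @export
make_helix_model <- function(n = 30, direction = c(0, 0, 1),
                             origin = c(0, 0, 0), rise = 1.5, radius = 2.3,
                             turn = 100, chain = "A") {
  .stop_if(n < 4, "need at least 4 residues")
  u <- direction / sqrt(sum(direction^2))
  # orthonormal frame around u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u; v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  th <- (seq_len(n) - 1) * turn * pi / 180
  pts <- t(vapply(seq_len(n), function(i) {
    origin + (i - 1) * rise * u + radius * (cos(th[i]) * v + sin(th[i]) * w)
  }, numeric(3)))
  atoms <- data.frame(chain = chain, resno = seq_len(n), icode = "",
                      resname = "GLY", atom = "CA", altloc = "", element = "C",
                      x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      occ = 1, bfactor = 0, hetero = FALSE,
                      stringsAsFactors = FALSE)
  model <- structure(list(accession = "helix", atoms = atoms),
                     class = "structure_model")
  list(model = model, direction = u)
}
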