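#' Geometric criteria for interface contacts
#'
#' Heavy-atom criteria suitable for moderate-resolution structures without
#' hydrogens: a hydrogen bond is a donor/acceptor heavy-atom pair within
#' \code{d_max} whose antecedent-donor-acceptor angle is at least
#' \code{angle_min}; a salt bridge is a basic/acidic group pair whose minimum
#' nitrogen-oxygen distance is at most \code{sb_max}.
#'
#' @param d_max donor-acceptor heavy-atom distance cutoff, angstrom.
#' @param angle_min minimum antecedent-donor-acceptor angle, degrees.
#' @param sb_max salt-bridge N-O distance cutoff, angstrom.
#' @return a \code{contact_criteria} list.
#' @export
contact_criteria <- function(d_max = 3.5, angle_min = 90, sb_max = 4.0) {
  .stop_if(d_max <= 0 || angle_min <= 0 || sb_max <= 0,
           "all criteria must be positive")
  structure(list(d_max = d_max, angle_min = angle_min, sb_max = sb_max),
            class = "contact_criteria")
}

# side-chain donor atoms by residue type; backbone N is a donor for all
# residues except proline. His carries both roles at ND1/NE2 (protonation
# unknown at these resolutions). Saccharide hydroxyl oxygens donate too.
.SC_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1", SER = "OG", THR = "OG1", TYR = "OH",
  CYS = "SG")

.SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")

.SACCHARIDES <- c("NAG", "NDG", "MAN", "BMA", "GAL", "GLC", "FUC", "FUL",
                  "XYS", "SIA", "BGC")

.is_donor <- function(atoms) {
  bb <- !atoms$hetero & atoms$atom == "N" & atoms$resname != "PRO"
  sc <- mapply(function(rn, an) an %in% (.SC_DONORS[[rn]] %||% character(0)),
               atoms$resname, atoms$atom, USE.NAMES = FALSE)
  sugar <- atoms$resname %in% .SACCHARIDES & atoms$element == "O" &
    atoms$atom != "O5"  # ring oxygen has no hydroxyl proton
  bb | sc | sugar
}

.is_acceptor <- function(atoms) {
  bb <- !atoms$hetero & atoms$element == "O"  # backbone O, OXT, side-chain O
  sc <- mapply(function(rn, an) an %in% (.SC_ACCEPTORS[[rn]] %||% character(0)),
               atoms$resname, atoms$atom, USE.NAMES = FALSE)
  sugar <- atoms$resname %in% .SACCHARIDES & atoms$element == "O"
  (bb | sc | sugar) & atoms$element %in% c("O", "N", "S")
}

# antecedent of a donor: nearest heavy atom within the same residue
.antecedent_xyz <- function(model_atoms, donor_row) {
  d <- model_atoms[donor_row, ]
  same <- which(model_atoms$chain == d$chain & model_atoms$resno == d$resno &
                  model_atoms$icode == d$icode)
  same <- setdiff(same, donor_row)
  if (length(same) == 0L) return(NULL)
  dx <- model_atoms$x[same] - d$x
  dy <- model_atoms$y[same] - d$y
  dz <- model_atoms$z[same] - d$z
  dist2 <- dx^2 + dy^2 + dz^2
  as.numeric(model_atoms[same[which.min(dist2)], c("x", "y", "z")])
}

#' Hydrogen bonds across a binary interface
#'
#' Enumerates all cross-side donor/acceptor heavy-atom pairs meeting the
#' distance and angle criteria. Donors: backbone amide N (non-proline),
#' side-chain N/O donors (Arg, Lys, Asn, Gln, His, Trp, Ser, Thr, Tyr) and
#' saccharide hydroxyl O. Acceptors: carbonyl/carboxyl/hydroxyl O, His ring N,
#' saccharide O. The donor angle is measured at the donor's nearest
#' intra-residue heavy atom (its antecedent); donors with no antecedent are
#' accepted on distance alone. One entry per donor-acceptor atom pair.
#'
#' @param sideA,sideB disjoint \code{residue_selection}s on one model.
#' @param criteria a \code{contact_criteria}.
#' @return data frame with one row per hydrogen bond: donor and acceptor
#'   chain/resno/resname/atom, \code{distance} (angstrom), \code{angle}
#'   (degrees; NA when no antecedent exists), \code{donor_side} ("a" or "b").
#' @export
find_hbonds <- function(sideA, sideB, criteria = contact_criteria()) {
  .check_disjoint(sideA, sideB)
  atoms <- sideA$model$atoms
  res <- rbind(
    .hbonds_directed(atoms, sideA$atom_idx, sideB$atom_idx, criteria, "a"),
    .hbonds_directed(atoms, sideB$atom_idx, sideA$atom_idx, criteria, "b"))
  rownames(res) <- NULL
  res
}

.hbonds_directed <- function(atoms, donor_idx, acceptor_idx, criteria, side) {
  empty <- data.frame(
    donor_chain = character(0), donor_resno = integer(0),
    donor_resname = character(0), donor_atom = character(0),
    acceptor_chain = character(0), acceptor_resno = integer(0),
    acceptor_resname = character(0), acceptor_atom = character(0),
    distance = numeric(0), angle = numeric(0), donor_side = character(0),
    stringsAsFactors = FALSE)
  don <- donor_idx[.is_donor(atoms[donor_idx, , drop = FALSE])]
  acc <- acceptor_idx[.is_acceptor(atoms[acceptor_idx, , drop = FALSE])]
  if (length(don) == 0L || length(acc) == 0L) return(empty)

  rows <- list()
  for (di in don) {
    dx <- atoms$x[acc] - atoms$x[di]
    dy <- atoms$y[acc] - atoms$y[di]
    dz <- atoms$z[acc] - atoms$z[di]
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    hit <- which(dist <= criteria$d_max)
    if (length(hit) == 0L) next
    ante <- .antecedent_xyz(atoms, di)
    for (h in hit) {
      ai <- acc[h]
      ang <- NA_real_
      if (!is.null(ante)) {
        v1 <- ante - c(atoms$x[di], atoms$y[di], atoms$z[di])
        v2 <- c(atoms$x[ai], atoms$y[ai], atoms$z[ai]) -
          c(atoms$x[di], atoms$y[di], atoms$z[di])
        ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
        if (ang < criteria$angle_min) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        donor_chain = atoms$chain[di], donor_resno = atoms$resno[di],
        donor_resname = atoms$resname[di], donor_atom = atoms$atom[di],
        acceptor_chain = atoms$chain[ai], acceptor_resno = atoms$resno[ai],
        acceptor_resname = atoms$resname[ai], acceptor_atom = atoms$atom[ai],
        distance = dist[h], angle = ang, donor_side = side,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

.BASIC <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
.ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Salt bridges across a binary interface
#'
#' Lys/Arg basic nitrogens versus Asp/Glu carboxylate oxygens; a residue pair
#' forms one bridge when its minimum cross-side N-O distance is at most
#' \code{sb_max}.
#'
#' @inheritParams find_hbonds
#' @return data frame, one row per bridged residue pair: basic and acidic
#'   chain/resno/resname, \code{distance} (minimum N-O, angstrom),
#'   \code{basic_side} ("a" or "b").
#' @export
find_salt_bridges <- function(sideA, sideB, criteria = contact_criteria()) {
  .check_disjoint(sideA, sideB)
  atoms <- sideA$model$atoms
  res <- rbind(
    .bridges_directed(atoms, sideA$atom_idx, sideB$atom_idx, criteria, "a"),
    .bridges_directed(atoms, sideB$atom_idx, sideA$atom_idx, criteria, "b"))
  rownames(res) <- NULL
  res
}

.bridges_directed <- function(atoms, basic_idx, acidic_idx, criteria, side) {
  pick <- function(idx, table) {
    sub <- atoms[idx, , drop = FALSE]
    idx[mapply(function(rn, an) an %in% (table[[rn]] %||% character(0)),
               sub$resname, sub$atom, USE.NAMES = FALSE)]
  }
  bas <- pick(basic_idx, .BASIC)
  aci <- pick(acidic_idx, .ACIDIC)
  empty <- data.frame(
    basic_chain = character(0), basic_resno = integer(0),
    basic_resname = character(0), acidic_chain = character(0),
    acidic_resno = integer(0), acidic_resname = character(0),
    distance = numeric(0), basic_side = character(0), stringsAsFactors = FALSE)
  if (length(bas) == 0L || length(aci) == 0L) return(empty)

  rows <- list()
  bas_res <- unique(.res_key(atoms$chain[bas], atoms$resno[bas], atoms$icode[bas]))
  for (bk in bas_res) {
    bi <- bas[.res_key(atoms$chain[bas], atoms$resno[bas], atoms$icode[bas]) == bk]
    aci_res <- unique(.res_key(atoms$chain[aci], atoms$resno[aci], atoms$icode[aci]))
    for (ak in aci_res) {
      ai <- aci[.res_key(atoms$chain[aci], atoms$resno[aci], atoms$icode[aci]) == ak]
      dmin <- min(sqrt(outer(atoms$x[bi], atoms$x[ai], "-")^2 +
                         outer(atoms$y[bi], atoms$y[ai], "-")^2 +
                         outer(atoms$z[bi], atoms$z[ai], "-")^2))
      if (dmin <= criteria$sb_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          basic_chain = atoms$chain[bi[1]], basic_resno = atoms$resno[bi[1]],
          basic_resname = atoms$resname[bi[1]],
          acidic_chain = atoms$chain[ai[1]], acidic_resno = atoms$resno[ai[1]],
          acidic_resname = atoms$resname[ai[1]],
          distance = dmin, basic_side = side, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

.check_disjoint <- function(sideA, sideB) {
  stopifnot(inherits(sideA, "residue_selection"),
            inherits(sideB, "residue_selection"))
  .stop_if(!identical(sideA$model$atoms, sideB$model$atoms),
           "selections must come from the same model")
  .stop_if(length(intersect(sideA$atom_idx, sideB$atom_idx)) > 0,
           "selections overlap")
}
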