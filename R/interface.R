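#' Buried surface area across a binary interface
#'
#' Per-atom BSA is the SASA an atom loses on complex formation:
#' \code{SASA(side alone) - SASA(side in complex)}. Three SASA evaluations are
#' run with identical parameters (A alone, B alone, A and B together) and each
#' side's loss is reported separately, matching the per-ectodomain convention
#' (no halving, no summing of the two sides). Tiny negative per-atom values,
#' which can arise from point sampling, are clamped to zero.
#'
#' Glycans covalently attached to a side belong in that side's selection:
#' whether a ligand-side footprint includes the area buried under the
#' receptor's N-linked glycan is controlled entirely by what the selections
#' contain.
#'
#' @param sideA,sideB disjoint \code{residue_selection}s on the same model.
#' @param params a \code{sasa_params}.
#' @return an \code{interface_map}: list with per-side per-atom BSA
#'   (\code{$atom_bsa_a}, \code{$atom_bsa_b}), per-residue BSA data frames
#'   (\code{$residue_bsa_a}, \code{$residue_bsa_b}: \code{chain, resno, icode,
#'   resname, bsa}), side totals (\code{$total_a}, \code{$total_b}) and the
#'   parameters used.
#' @export
buried_surface <- function(sideA, sideB, params = sasa_params()) {
  stopifnot(inherits(sideA, "residue_selection"),
            inherits(sideB, "residue_selection"))
  .stop_if(!identical(sideA$model$atoms, sideB$model$atoms),
           "sideA and sideB must select from the same model")
  .stop_if(length(intersect(sideA$atom_idx, sideB$atom_idx)) > 0,
           "sideA and sideB selections overlap")

  model <- sideA$model
  both <- structure(list(model = model,
                         atom_idx = c(sideA$atom_idx, sideB$atom_idx)),
                    class = "residue_selection")

  sasa_a <- compute_sasa(sideA, params)
  sasa_b <- compute_sasa(sideB, params)
  sasa_ab <- compute_sasa(both, params)

  na <- length(sideA$atom_idx)
  complex_a <- sasa_ab$atom_area[seq_len(na)]
  complex_b <- sasa_ab$atom_area[-seq_len(na)]

  atom_bsa_a <- pmax(sasa_a$atom_area - complex_a, 0)
  atom_bsa_b <- pmax(sasa_b$atom_area - complex_b, 0)

  structure(list(
    atom_bsa_a = atom_bsa_a,
    atom_bsa_b = atom_bsa_b,
    residue_bsa_a = .per_residue(.sel_atoms(sideA), atom_bsa_a),
    residue_bsa_b = .per_residue(.sel_atoms(sideB), atom_bsa_b),
    total_a = sum(atom_bsa_a),
    total_b = sum(atom_bsa_b),
    sideA = sideA, sideB = sideB, params = params
  ), class = "interface_map")
}

.per_residue <- function(atoms, values) {
  key <- .res_key(atoms$chain, atoms$resno, atoms$icode)
  per <- rowsum(values, key, reorder = FALSE)
  first <- !duplicated(key)
  data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
             icode = atoms$icode[first], resname = atoms$resname[first],
             bsa = as.numeric(per[, 1]), stringsAsFactors = FALSE)
}

#' @export
print.interface_map <- function(x, ...) {
  cat(sprintf("interface_map: side A buries %.1f A^2 (%d residues > 1 A^2), side B %.1f A^2 (%d residues > 1 A^2)\n",
              x$total_a, sum(x$residue_bsa_a$bsa > 1),
              x$total_b, sum(x$residue_bsa_b$bsa > 1)))
  invisible(x)
}

#' Interface residue footprints at a BSA threshold
#'
#' A molecule's footprint is the set of its residues burying strictly more
#' than \code{tau} square angstrom at the interface. The default threshold of
#' 1 A^2 is the one used for mimicry scoring.
#'
#' @param imap an \code{interface_map} from \code{\link{buried_surface}}.
#' @param tau threshold in A^2 (strict inequality), >= 0.
#' @return list of two \code{footprint} data frames (\code{$a}, \code{$b}),
#'   each with columns \code{chain, resno, icode, resname, bsa} and attribute
#'   \code{tau}.
#' @export
interface_residues <- function(imap, tau = 1.0) {
  stopifnot(inherits(imap, "interface_map"))
  .stop_if(tau < 0, "tau must be >= 0")
  mk <- function(df) {
    fp <- df[df$bsa > tau, , drop = FALSE]
    rownames(fp) <- NULL
    structure(fp, tau = tau, class = c("footprint", "data.frame"))
  }
  list(a = mk(imap$residue_bsa_a), b = mk(imap$residue_bsa_b))
}

#' Contribution of a residue region to one side's buried area
#'
#' Sums per-residue BSA over a region (e.g. a motif such as the FG-loop
#' FDPPPF, or a glycan) and reports it as an absolute area and a fraction of
#' that side's total, reproducing motif-contribution statements of the form
#' "this region buries X A^2, Y\% of the side total".
#'
#' @param imap an \code{interface_map}.
#' @param side \code{"a"} or \code{"b"}.
#' @param region a \code{residue_selection}; must be a subset of that side.
#' @return list: \code{area} (A^2), \code{side_total} (A^2), \code{fraction}.
#' @export
region_contribution <- function(imap, side = c("a", "b"), region) {
  side <- match.arg(side)
  stopifnot(inherits(imap, "interface_map"),
            inherits(region, "residue_selection"))
  side_sel <- if (side == "a") imap$sideA else imap$sideB
  .stop_if(!all(region$atom_idx %in% side_sel$atom_idx),
           "region is not a subset of side %s", side)
  df <- if (side == "a") imap$residue_bsa_a else imap$residue_bsa_b
  keys <- .res_key(df$chain, df$resno, df$icode)
  in_region <- keys %in% .sel_residues(region)
  area <- sum(df$bsa[in_region])
  total <- sum(df$bsa)
  list(area = area, side_total = total,
       fraction = if (total > 0) area / total else 0)
}
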