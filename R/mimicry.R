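#' Receptor-mimicry fraction of an antibody footprint
#'
#' The headline mimicry statistic: the fraction of a molecule's
#' natural-complex interface residues (BSA > tau, typically 1 A^2) that are
#' also contacted (BSA > tau in the antibody complex) by the antibody.
#' Residue correspondence between the two crystal forms of the molecule is
#' supplied as a \code{residue_mapping}; natural-footprint residues with no
#' mapped counterpart stay in the denominator but can never be in the
#' numerator.
#'
#' @param natural \code{footprint} of the molecule in its receptor/ligand
#'   complex (the denominator set). Must be non-empty.
#' @param antibody \code{footprint} of the same molecule in its antibody
#'   complex.
#' @param mapping a \code{residue_mapping} from the natural-complex copy to
#'   the antibody-complex copy of the molecule, or \code{NULL} when both
#'   footprints already share chain/numbering (identity correspondence).
#' @return a \code{mimicry_score}: list with \code{f} (fraction in [0,1]),
#'   \code{n_interface}, \code{n_contacted}, \code{natural_residues},
#'   \code{contacted_residues} (character residue keys \code{chain|resno|icode}).
#' @export
mimicry_fraction <- function(natural, antibody, mapping = NULL) {
  stopifnot(inherits(natural, "footprint"), inherits(antibody, "footprint"))
  .stop_if(nrow(natural) == 0L, "empty natural footprint")
  nat_keys <- .res_key(natural$chain, natural$resno, natural$icode)
  ab_keys <- .res_key(antibody$chain, antibody$resno, antibody$icode)
  mapped <- if (is.null(mapping)) {
    setNames(nat_keys, nat_keys)
  } else {
    .mapping_lookup(mapping)[nat_keys]  # NA where unmapped
  }
  contacted <- nat_keys[!is.na(mapped) & mapped %in% ab_keys]
  structure(list(
    f = length(contacted) / length(nat_keys),
    n_interface = length(nat_keys),
    n_contacted = length(contacted),
    natural_residues = nat_keys,
    contacted_residues = contacted
  ), class = "mimicry_score")
}

#' @export
print.mimicry_score <- function(x, ...) {
  cat(sprintf("mimicry_score: f = %.3f (%d of %d interface residues contacted by the antibody)\n",
              x$f, x$n_contacted, x$n_interface))
  invisible(x)
}

#' Per-residue natural-vs-antibody footprint comparison table
#'
#' One row per residue appearing in either footprint of the shared molecule,
#' with its BSA in the natural complex, its BSA in the antibody complex, and a
#' flag for residues contacted in both — the tabular form of a side-by-side
#' per-residue BSA bar plot.
#'
#' @param natural,antibody \code{interface_map}s; the shared molecule is side
#'   \code{"a"} of each by convention.
#' @param mapping \code{residue_mapping} from the natural copy to the antibody
#'   copy, or \code{NULL} for identity.
#' @param tau footprint threshold (A^2, strict).
#' @return data frame: \code{chain, resno, icode, resname, bsa_natural,
#'   bsa_antibody, shared}.
#' @export
footprint_table <- function(natural, antibody, mapping = NULL, tau = 1.0) {
  stopifnot(inherits(natural, "interface_map"),
            inherits(antibody, "interface_map"))
  nat <- natural$residue_bsa_a
  ab <- antibody$residue_bsa_a
  nat_keys <- .res_key(nat$chain, nat$resno, nat$icode)
  ab_keys <- .res_key(ab$chain, ab$resno, ab$icode)

  to_ab <- if (is.null(mapping)) setNames(nat_keys, nat_keys) else .mapping_lookup(mapping)
  nat$key_ab <- unname(to_ab[nat_keys])

  ab_bsa <- setNames(ab$bsa, ab_keys)
  bsa_antibody <- ifelse(is.na(nat$key_ab), 0,
                         ifelse(nat$key_ab %in% ab_keys, ab_bsa[nat$key_ab], 0))
  out <- data.frame(chain = nat$chain, resno = nat$resno, icode = nat$icode,
                    resname = nat$resname,
                    bsa_natural = nat$bsa,
                    bsa_antibody = as.numeric(bsa_antibody),
                    stringsAsFactors = FALSE)

  # antibody-only residues (no natural counterpart above zero) appended
  mapped_ab <- unname(to_ab[!is.na(to_ab)])
  extra <- ab[!(ab_keys %in% mapped_ab), , drop = FALSE]
  if (nrow(extra) > 0) {
    out <- rbind(out, data.frame(
      chain = extra$chain, resno = extra$resno, icode = extra$icode,
      resname = extra$resname, bsa_natural = 0, bsa_antibody = extra$bsa,
      stringsAsFactors = FALSE))
  }
  out <- out[out$bsa_natural > tau | out$bsa_antibody > tau, , drop = FALSE]
  out$shared <- out$bsa_natural > tau & out$bsa_antibody > tau
  rownames(out) <- NULL
  out
}
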