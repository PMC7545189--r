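#' Full interface-mimicry study of the ICOS/ICOS-L complexes
#'
#' Runs the complete analysis over the deposited crystal structures of the
#' ICOS/ICOS-L co-stimulatory complex and its therapeutic-antibody complexes:
#' the natural complex (PDB 6X4G: ICOS/ICOS-L/VNAR chaperone), the ICOS-L /
#' prezalumab Fab complex (6X4T, VNAR chaperone), the ICOS / STIM003 Fab
#' complex (7JOO, anti-kappa VHH chaperone) and the CTLA-4/B7-1 comparator
#' (1I8L). Requires the coordinate files: they are fetched once over the
#' network with \code{\link{fetch_structure}} when \code{fetch = TRUE}, or
#' read from \code{cache_dir} if already present.
#'
#' Chain roles are identified from the coordinates, not assumed: ICOS is the
#' chain carrying the FDPPPF FG-loop motif, CTLA-4 the chain carrying MYPPPY,
#' ICOS-L (and the ICOS copy in 7JOO) by highest-identity alignment to the
#' reference copy in 6X4G, the single-domain chaperones (VNAR / VHH) as the
#' shortest remaining chain, and the Fab as the two remaining chains.
#' Chaperone chains are excluded from every interface. Glycan (hetero)
#' residues are assigned to the protein chain that carries them and included
#' in that side's selections.
#'
#' @param cache_dir directory holding (or receiving) \code{6X4G.pdb},
#'   \code{6X4T.pdb}, \code{7JOO.pdb}, \code{1I8L.pdb}.
#' @param fetch attempt to download missing entries (explicit opt-in network
#'   access).
#' @param params a \code{sasa_params}.
#' @param criteria a \code{contact_criteria}.
#' @param tau footprint threshold, A^2.
#' @param icosl_d1,icosl_d2 author residue ranges of the ICOS-L V-type (D1)
#'   and C1-type (D2) domains.
#' @return named list of study quantities: per-side footprint totals for the
#'   natural and antibody complexes, motif and glycan contributions, crossing
#'   and elbow angles, cross-structure backbone r.m.s.d. values, contact
#'   counts, and the mimicry fractions.
#' @export
icos_study <- function(cache_dir = file.path(Sys.getenv("HOME"), ".cache",
                                             "epimimic-pdb"),
                       fetch = TRUE,
                       params = sasa_params(),
                       criteria = contact_criteria(),
                       tau = 1.0,
                       icosl_d1 = 19:128, icosl_d2 = 129:248) {
  get <- function(acc) {
    path <- file.path(cache_dir, paste0(acc, ".pdb"))
    if (!file.exists(path)) {
      .stop_if(!fetch, "structure %s not cached at %s and fetch = FALSE",
               acc, path)
      path <- fetch_structure(acc, cache_dir)
    }
    load_structure(path, accession = acc)
  }
  m_nat <- get("6X4G"); m_prez <- get("6X4T")
  m_stim <- get("7JOO"); m_ctla <- get("1I8L")

  # ---- chain role identification ----------------------------------------
  icos_nat <- .chain_with_motif(m_nat, "FDPPPF")
  icosl_nat <- .longest_other_chain(m_nat, icos_nat)
  icosl_prez <- .chain_best_match(m_prez, m_nat, icosl_nat)
  icos_stim <- .chain_with_motif(m_stim, "FDPPPF")
  ctla4 <- .chain_with_motif(m_ctla, "MYPPPY")

  prez_rest <- setdiff(.protein_chains(m_prez), icosl_prez)
  prez_vnar <- .shortest_chain(m_prez, prez_rest)
  prez_fab <- setdiff(prez_rest, prez_vnar)
  stim_rest <- setdiff(.protein_chains(m_stim), icos_stim)
  stim_vhh <- .shortest_chain(m_stim, stim_rest)
  stim_fab <- setdiff(stim_rest, stim_vhh)

  sel <- function(model, chains, ...) select_residues(model, chains, ...)

  # ---- natural complex: footprints, motifs, glycan, contacts ------------
  im_nat <- buried_surface(sel(m_nat, icos_nat), sel(m_nat, icosl_nat), params)
  fg <- region_contribution(im_nat, "a",
                            sel(m_nat, icos_nat, resno = 114:119,
                                hetero = FALSE))
  cc <- region_contribution(im_nat, "a",
                            sel(m_nat, icos_nat, resno = 66:71,
                                hetero = FALSE))
  # area the ICOS glycan buries on ICOS-L: interface of ICOS-L vs glycan alone
  glyc_resno <- unique(m_nat$atoms$resno[m_nat$atoms$chain == icos_nat &
                                           m_nat$atoms$hetero])
  glycan_on_icosl <- if (length(glyc_resno) > 0) {
    buried_surface(sel(m_nat, icosl_nat),
                   sel(m_nat, icos_nat, resno = glyc_resno), params)$total_a
  } else NA_real_

  hb_nat <- find_hbonds(sel(m_nat, icos_nat, hetero = FALSE),
                        sel(m_nat, icosl_nat, hetero = FALSE), criteria)

  # ---- antibody complexes ------------------------------------------------
  im_stim <- buried_surface(sel(m_stim, icos_stim),
                            sel(m_stim, stim_fab), params)
  im_prez <- buried_surface(sel(m_prez, icosl_prez),
                            sel(m_prez, prez_fab), params)
  hb_stim <- find_hbonds(sel(m_stim, icos_stim, hetero = FALSE),
                         sel(m_stim, stim_fab, hetero = FALSE), criteria)
  sb_stim <- find_salt_bridges(sel(m_stim, icos_stim, hetero = FALSE),
                               sel(m_stim, stim_fab, hetero = FALSE), criteria)
  hb_prez <- find_hbonds(sel(m_prez, icosl_prez, hetero = FALSE),
                         sel(m_prez, prez_fab, hetero = FALSE), criteria)

  # ---- geometry ----------------------------------------------------------
  crossing <- axis_angle(
    principal_axis(sel(m_nat, icos_nat, hetero = FALSE)),
    principal_axis(sel(m_nat, icosl_nat, resno = icosl_d1, hetero = FALSE)))
  elbow_nat <- axis_angle(
    principal_axis(sel(m_nat, icosl_nat, resno = icosl_d1, hetero = FALSE)),
    principal_axis(sel(m_nat, icosl_nat, resno = icosl_d2, hetero = FALSE)))
  elbow_prez <- axis_angle(
    principal_axis(sel(m_prez, icosl_prez, resno = icosl_d1, hetero = FALSE)),
    principal_axis(sel(m_prez, icosl_prez, resno = icosl_d2, hetero = FALSE)))

  icos_a <- sel(m_nat, icos_nat, hetero = FALSE)
  icos_b <- sel(m_stim, icos_stim, hetero = FALSE)
  rmsd_cross <- backbone_rmsd(icos_a, icos_b, map_residues(icos_a, icos_b))

  motif_a <- sel(m_nat, icos_nat, resno = 114:119, hetero = FALSE)
  ctla_seq <- .chain_sequence(sel(m_ctla, ctla4, hetero = FALSE))
  mstart <- regexpr("MYPPPY", paste(ctla_seq$aa, collapse = ""))[1]
  motif_b <- sel(m_ctla, ctla4,
                 resno = ctla_seq$resno[mstart:(mstart + 5)], hetero = FALSE)
  rmsd_motif <- backbone_rmsd(motif_a, motif_b,
                              map_residues(motif_a, motif_b))

  # ---- mimicry -----------------------------------------------------------
  icos_map <- map_residues(icos_a, icos_b)
  f_icos <- mimicry_fraction(interface_residues(im_nat, tau)$a,
                             interface_residues(im_stim, tau)$a, icos_map)
  icosl_a <- sel(m_nat, icosl_nat, hetero = FALSE)
  icosl_b <- sel(m_prez, icosl_prez, hetero = FALSE)
  f_icosl <- mimicry_fraction(
    interface_residues(im_nat, tau)$b,
    interface_residues(im_prez, tau)$a,
    map_residues(icosl_a, icosl_b))

  list(
    chains = list(icos_6x4g = icos_nat, icosl_6x4g = icosl_nat,
                  icosl_6x4t = icosl_prez, prezalumab_fab = prez_fab,
                  icos_7joo = icos_stim, stim003_fab = stim_fab,
                  ctla4_1i8l = ctla4),
    icos_footprint_natural = im_nat$total_a,
    icosl_footprint_natural = im_nat$total_b,
    icos_footprint_stim003 = im_stim$total_a,
    icosl_footprint_prezalumab = im_prez$total_a,
    fg_motif_area = fg$area, fg_motif_fraction = fg$fraction,
    cc_strand_area = cc$area, cc_strand_fraction = cc$fraction,
    glycan_bsa_on_icosl = glycan_on_icosl,
    crossing_angle = crossing,
    elbow_angle_natural = elbow_nat,
    elbow_angle_prezalumab = elbow_prez,
    elbow_difference = abs(elbow_nat - elbow_prez),
    icos_cross_crystal_rmsd = rmsd_cross,
    motif_rmsd_vs_ctla4 = rmsd_motif,
    hbonds_natural = nrow(hb_nat),
    hbonds_stim003 = nrow(hb_stim),
    salt_bridges_stim003 = nrow(sb_stim),
    hbonds_prezalumab = nrow(hb_prez),
    mimicry_f_icos = f_icos$f,
    mimicry_f_icosl = f_icosl$f)
}

.protein_chains <- function(model) {
  a <- model$atoms[!model$atoms$hetero, ]
  unique(a$chain)
}

.chain_with_motif <- function(model, motif) {
  for (ch in .protein_chains(model)) {
    s <- .chain_sequence(select_residues(model, ch, hetero = FALSE))
    if (grepl(motif, paste(s$aa, collapse = ""), fixed = TRUE)) return(ch)
  }
  stop("no chain of ", model$accession %||% "model", " carries motif ", motif,
       call. = FALSE)
}

.chain_lengths <- function(model, chains) {
  vapply(chains, function(ch) {
    a <- model$atoms[model$atoms$chain == ch & !model$atoms$hetero, ]
    length(unique(.res_key(a$chain, a$resno, a$icode)))
  }, numeric(1))
}

.longest_other_chain <- function(model, exclude) {
  ch <- setdiff(.protein_chains(model), exclude)
  ch[which.max(.chain_lengths(model, ch))]
}

.shortest_chain <- function(model, chains) {
  chains[which.min(.chain_lengths(model, chains))]
}

# chain of `model` most similar in sequence to `ref_chain` of `ref_model`
.chain_best_match <- function(model, ref_model, ref_chain) {
  ref_sel <- select_residues(ref_model, ref_chain, hetero = FALSE)
  best <- NULL; best_id <- -1
  for (ch in .protein_chains(model)) {
    mp <- tryCatch(map_residues(select_residues(model, ch, hetero = FALSE),
                                ref_sel),
                   error = function(e) NULL)
    if (!is.null(mp) && mp$identity > best_id) {
      best <- ch; best_id <- mp$identity
    }
  }
  .stop_if(is.null(best), "no chain of %s matches %s:%s",
           model$accession %||% "model", ref_model$accession %||% "ref",
           ref_chain)
  best
}
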