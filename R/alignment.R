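#' Map equivalent residues between two chains by global alignment
#'
#' Aligns the one-letter sequences of two selections with a global
#' (Needleman-Wunsch) alignment under identity scoring (match 1, mismatch 0,
#' affine gap cost \code{gap_open + gap_extend * length}) and returns the
#' aligned, non-gap residue pairs. This is how residues are put in
#' correspondence across crystal forms whose author numbering may disagree
#' (e.g. the same receptor solved with its natural ligand and with an
#' antibody).
#'
#' Non-standard residues are translated to \code{X}; hetero residues
#' (glycans, ions) are excluded from the sequence.
#'
#' @param chainA,chainB \code{residue_selection}s, each usually one chain.
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return a \code{residue_mapping}: list with \code{$pairs} (data frame of
#'   matched residue identifiers, columns \code{chain_a, resno_a, icode_a,
#'   chain_b, resno_b, icode_b}), \code{$score} and \code{$identity}
#'   (fraction identical among aligned pairs).
#' @export
map_residues <- function(chainA, chainB, gap_open = 5, gap_extend = 0.5) {
  sa <- .chain_sequence(chainA)
  sb <- .chain_sequence(chainB)
  .stop_if(nrow(sa) == 0L, "chainA has no polymer residues")
  .stop_if(nrow(sb) == 0L, "chainB has no polymer residues")

  aln <- Biostrings::pairwiseAlignment(
    paste(sa$aa, collapse = ""), paste(sb$aa, collapse = ""),
    type = "global", substitutionMatrix = .identity_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)

  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ia <- ib <- 0L
  rows <- vector("list", length(pa))
  n_id <- 0L; n_pair <- 0L
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (pb[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && pb[k] != "-") {
      n_pair <- n_pair + 1L
      if (pa[k] == pb[k]) n_id <- n_id + 1L
      rows[[n_pair]] <- c(ia, ib)
    }
  }
  .stop_if(n_pair == 0L, "alignment produced no residue pairs")
  m <- do.call(rbind, rows[seq_len(n_pair)])
  pairs <- data.frame(
    chain_a = sa$chain[m[, 1]], resno_a = sa$resno[m[, 1]], icode_a = sa$icode[m[, 1]],
    chain_b = sb$chain[m[, 2]], resno_b = sb$resno[m[, 2]], icode_b = sb$icode[m[, 2]],
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 score = Biostrings::score(aln),
                 identity = n_id / n_pair),
            class = "residue_mapping")
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat("residue_mapping:", nrow(x$pairs), "pairs, identity",
      sprintf("%.3f", x$identity), ", score", x$score, "\n")
  invisible(x)
}

.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")

.identity_matrix <- function() {
  aa <- c(unique(unname(.AA1)), "X")
  m <- diag(1, length(aa))
  dimnames(m) <- list(aa, aa)
  m
}

# ordered polymer residues of a selection with one-letter codes (X if unknown)
.chain_sequence <- function(sel) {
  a <- .sel_atoms(sel)
  a <- a[!a$hetero, , drop = FALSE]
  key <- .res_key(a$chain, a$resno, a$icode)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first],
             aa = unname(ifelse(a$resname[first] %in% names(.AA1),
                                .AA1[a$resname[first]], "X")),
             stringsAsFactors = FALSE)
}

# lookup: map residue keys of side A to side B under a mapping (NA if unmapped)
.mapping_lookup <- function(mapping) {
  p <- mapping$pairs
  setNames(.res_key(p$chain_b, p$resno_b, p$icode_b),
           .res_key(p$chain_a, p$resno_a, p$icode_a))
}
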