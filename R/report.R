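#' Load a structure from a PDB or mmCIF file
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format \code{"pdb"}, \code{"cif"}, or \code{NULL} to infer.
#' @param accession optional identifier; defaults to the file stem.
#' @return a \code{structure_model}.
#' @export
load_structure <- function(path, format = NULL, accession = NULL) {
  .stop_if(!file.exists(path), "no such file: %s", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parse_structure(readLines(path, warn = FALSE), format,
                  accession = accession %||% tools::file_path_sans_ext(basename(path)))
}

#' Fetch a deposited structure from the Protein Data Bank
#'
#' Explicit, opt-in network access: nothing else in the package downloads
#' anything. Files are cached in \code{dir} and reused on later calls.
#'
#' @param accession 4-character PDB identifier (e.g. \code{"6X4G"}).
#' @param dir cache directory; created if needed.
#' @param format \code{"pdb"} or \code{"cif"}.
#' @return path to the cached file.
#' @export
fetch_structure <- function(accession, dir = file.path("scratch", "pdb"),
                            format = c("pdb", "cif")) {
  format <- match.arg(format)
  .stop_if(!grepl("^[A-Za-z0-9]{4}$", accession), "bad accession: %s", accession)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(dir, paste0(toupper(accession), ".", format))
  if (file.exists(dest)) return(dest)
  url <- sprintf("https://files.rcsb.org/download/%s.%s",
                 toupper(accession), format)
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("could not fetch ", accession, " from the PDB (no network, or entry ",
         "unavailable); place the file at ", dest, " manually to proceed",
         call. = FALSE)
  }
  dest
}

#' Configuration for a binary-interface report
#'
#' Bundles the structure, the two interface sides, thresholds and criteria for
#' \code{\link{run_interface_report}}. Sides and regions are selection
#' specifications: lists of arguments to \code{\link{select_residues}}
#' (\code{chains}, \code{resno}, \code{hetero}).
#'
#' @param model a \code{structure_model}.
#' @param sideA,sideB selection specs for the two sides (disjoint).
#' @param regions named list of selection specs, each a region of one side;
#'   each entry must also name its side, e.g.
#'   \code{list(fg_motif = list(side = "a", chains = "R", resno = 114:119))}.
#' @param axisA,axisB optional selection specs for the two domains whose
#'   crossing angle is reported.
#' @param tau footprint threshold, A^2.
#' @param params a \code{sasa_params}.
#' @param criteria a \code{contact_criteria}.
#' @param out_dir directory reports are written into.
#' @return an \code{analysis_config} list.
#' @export
analysis_config <- function(model, sideA, sideB, regions = list(),
                            axisA = NULL, axisB = NULL, tau = 1.0,
                            params = sasa_params(),
                            criteria = contact_criteria(),
                            out_dir = tempfile("report")) {
  stopifnot(inherits(model, "structure_model"))
  .stop_if(tau < 0, "tau must be >= 0")
  structure(list(model = model, sideA = sideA, sideB = sideB,
                 regions = regions, axisA = axisA, axisB = axisB, tau = tau,
                 params = params, criteria = criteria, out_dir = out_dir),
            class = "analysis_config")
}

.resolve_sel <- function(model, spec) {
  spec$side <- NULL
  do.call(select_residues, c(list(model = model), spec))
}

#' Run the full interface characterization and write reports
#'
#' One call per binary interface: per-side buried-surface totals, footprints
#' at the configured threshold, region (motif) contributions, hydrogen bonds,
#' salt bridges, and (when domain axes are configured) the crossing angle.
#' Writes \code{report.json} plus per-residue BSA and contact TSV tables to
#' \code{config$out_dir}. Every number in the report is the direct output of
#' one module operation; repeated runs on the same input are byte-identical
#' (deterministic SASA sampling, no unseeded randomness).
#'
#' @param config an \code{analysis_config}.
#' @return the report, invisibly (a list mirroring \code{report.json}).
#' @export
run_interface_report <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  model <- config$model
  selA <- .resolve_sel(model, config$sideA)
  selB <- .resolve_sel(model, config$sideB)

  imap <- buried_surface(selA, selB, config$params)
  fps <- interface_residues(imap, config$tau)
  hb <- find_hbonds(selA, selB, config$criteria)
  sb <- find_salt_bridges(selA, selB, config$criteria)

  regions <- lapply(config$regions, function(spec) {
    side <- spec$side %||% "a"
    rc <- region_contribution(imap, side, .resolve_sel(model, spec))
    list(side = side, area = rc$area, side_total = rc$side_total,
         fraction = rc$fraction)
  })

  crossing <- NULL
  if (!is.null(config$axisA) && !is.null(config$axisB)) {
    crossing <- axis_angle(principal_axis(.resolve_sel(model, config$axisA)),
                           principal_axis(.resolve_sel(model, config$axisB)))
  }

  report <- list(
    accession = model$accession,
    parameters = list(tau = config$tau,
                      probe_radius = config$params$probe_radius,
                      n_points = config$params$n_points,
                      d_max = config$criteria$d_max,
                      angle_min = config$criteria$angle_min,
                      sb_max = config$criteria$sb_max),
    bsa = list(side_a_total = imap$total_a, side_b_total = imap$total_b),
    footprints = list(
      side_a = list(n = nrow(fps$a), residues = .fp_records(fps$a)),
      side_b = list(n = nrow(fps$b), residues = .fp_records(fps$b))),
    regions = regions,
    contacts = list(n_hbonds = nrow(hb), n_salt_bridges = nrow(sb)),
    crossing_angle_deg = crossing)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_tsv(imap$residue_bsa_a, file.path(config$out_dir, "bsa_side_a.tsv"))
  .write_tsv(imap$residue_bsa_b, file.path(config$out_dir, "bsa_side_b.tsv"))
  .write_tsv(hb, file.path(config$out_dir, "hbonds.tsv"))
  .write_tsv(sb, file.path(config$out_dir, "salt_bridges.tsv"))
  invisible(report)
}

.fp_records <- function(fp) {
  if (nrow(fp) == 0) return(list())
  lapply(seq_len(nrow(fp)), function(i)
    list(chain = fp$chain[i], resno = fp$resno[i], resname = fp$resname[i],
         bsa = fp$bsa[i]))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Score antibody mimicry of a natural interface and write the report
#'
#' Computes the two interface maps (the shared target molecule is side A of
#' each), aligns the two copies of the target to put residues in
#' correspondence, and reports the mimicry fraction together with the
#' per-residue natural-vs-antibody BSA table.
#'
#' @param natural \code{analysis_config} for the natural receptor/ligand
#'   complex; \code{sideA} must select the shared target molecule.
#' @param antibody \code{analysis_config} for the antibody complex of the
#'   same molecule; \code{sideA} selects that molecule's copy.
#' @param align use sequence alignment to map target residues across the two
#'   structures (default); set \code{FALSE} when numbering is already shared.
#' @param out_dir output directory (default: the natural config's).
#' @return the mimicry report, invisibly: list with \code{f},
#'   \code{n_interface}, \code{n_contacted}, \code{residues} (per-residue
#'   table), plus both side totals.
#' @export
run_mimicry_report <- function(natural, antibody, align = TRUE,
                               out_dir = natural$out_dir) {
  stopifnot(inherits(natural, "analysis_config"),
            inherits(antibody, "analysis_config"))
  nat_a <- .resolve_sel(natural$model, natural$sideA)
  nat_b <- .resolve_sel(natural$model, natural$sideB)
  ab_a <- .resolve_sel(antibody$model, antibody$sideA)
  ab_b <- .resolve_sel(antibody$model, antibody$sideB)

  imap_nat <- buried_surface(nat_a, nat_b, natural$params)
  imap_ab <- buried_surface(ab_a, ab_b, antibody$params)

  mapping <- if (align) map_residues(nat_a, ab_a) else NULL

  fp_nat <- interface_residues(imap_nat, natural$tau)$a
  fp_ab <- interface_residues(imap_ab, natural$tau)$a
  score <- mimicry_fraction(fp_nat, fp_ab, mapping)
  tab <- footprint_table(imap_nat, imap_ab, mapping, natural$tau)

  report <- list(
    molecule = paste(unique(.sel_atoms(nat_a)$chain), collapse = ","),
    f = score$f, n_interface = score$n_interface,
    n_contacted = score$n_contacted,
    natural_side_total = imap_nat$total_a,
    antibody_side_total = imap_ab$total_a,
    residues = lapply(seq_len(nrow(tab)), function(i)
      list(chain = tab$chain[i], resno = tab$resno[i],
           resname = tab$resname[i], bsa_natural = tab$bsa_natural[i],
           bsa_antibody = tab$bsa_antibody[i], shared = tab$shared[i])))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "mimicry.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_tsv(tab, file.path(out_dir, "footprint_table.tsv"))
  invisible(report)
}
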