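#!/usr/bin/env Rscript
# Interface characterization on constructed complexes with known footprints:
# buried-surface totals, interface residue calling at the 1 A^2 threshold, and
# region (motif-style) contributions, written as a full interface report.

suppressMessages(library(epimimic))
dir.create("results", showWarnings = FALSE)

cat("== toy interface footprints ==\n")
ti <- make_toy_interface(n_residues = 10, contact = 4)
cfg <- analysis_config(
  ti$model,
  sideA = list(chains = "A"), sideB = list(chains = "B"),
  regions = list(contact_half = list(side = "a", chains = "A", resno = 1:2),
                 cold_half = list(side = "a", chains = "A", resno = 8:10)),
  out_dir = file.path("results", "toy_interface"))
rep <- run_interface_report(cfg)

cat(sprintf("side A buries %.1f A^2, side B %.1f A^2\n",
            rep$bsa$side_a_total, rep$bsa$side_b_total))
cat(sprintf("footprints at tau = 1: %d and %d residues (designed: 4 and 4)\n",
            rep$footprints$side_a$n, rep$footprints$side_b$n))
cat(sprintf("residues 1-2 contribute %.1f A^2 (%.0f%% of the side total)\n",
            rep$regions$contact_half$area,
            100 * rep$regions$contact_half$fraction))
cat(sprintf("non-contacting residues 8-10 contribute %.1f A^2\n",
            rep$regions$cold_half$area))
cat("report written under results/toy_interface/\n")
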