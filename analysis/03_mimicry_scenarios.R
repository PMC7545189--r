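#!/usr/bin/env Rscript
# The mimicry statistic end to end: constructed natural/antibody complex pairs
# with known shared-footprint fractions are pushed through the whole pipeline
# (BSA -> footprints -> cross-structure residue mapping -> mimicry fraction).

suppressMessages(library(epimimic))
dir.create("results", showWarnings = FALSE)

cat("== mimicry scenarios ==\n")
cases <- expand.grid(n_interface = c(4, 5, 6, 8), n_shared = 0:8)
cases <- cases[cases$n_shared <= cases$n_interface, ]

rows <- lapply(seq_len(nrow(cases)), function(i) {
  ni <- cases$n_interface[i]; ns <- cases$n_shared[i]
  sc <- make_mimicry_pair(ni, ns, seed = 100 + i)
  out <- run_mimicry_report(
    analysis_config(sc$natural, sideA = list(chains = "T"),
                    sideB = list(chains = "L")),
    analysis_config(sc$antibody, sideA = list(chains = "T"),
                    sideB = list(chains = "H")),
    out_dir = tempfile())
  data.frame(n_interface = ni, n_shared = ns, truth = sc$truth_f,
             computed_f = out$f, exact = out$f == sc$truth_f)
})
tab <- do.call(rbind, rows)
write.table(tab, "results/mimicry_scenarios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d scenarios; computed fraction equals construction truth in all: %s\n",
            nrow(tab), all(tab$exact)))
print(head(tab, 8), row.names = FALSE)
cat("wrote results/mimicry_scenarios.tsv\n")
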