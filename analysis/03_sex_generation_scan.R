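#!/usr/bin/env Rscript
# Stage 3 — sex x generation scan and enrichment over chance.
#
# Scans each SNP in the six demographic cells (men and women of the three
# generations) under both model levels, labels entries significant
# (p <= 0.05) / suggestive (0.05 < p <= 0.1), and tests whether the count
# of significant cell-level associations exceeds the 5% chance expectation
# for the 60 tests.

suppressMessages(library(demostrat))

pheno <- read_phenotypes("results/cohort/phenotypes.tsv")
geno <- read_genotypes("results/cohort/genotypes.tsv")
cells <- build_cells(pheno)

for (model in c("baseline", "cumulative")) {
  sc <- scan_cells(pheno, geno, cells = cells, model = model)
  write_scan(sc, sprintf("results/scan_sex_generation_%s.tsv", model),
             seed = 7)
  s <- summarize_scan(sc)
  cat(sprintf("%s scan: %d tests, %d significant, %d suggestive\n",
              model, s$n_tests, s$n_significant, s$n_suggestive))
  print(s$by_generation)
  enr <- enrichment_summary(sc)
  cat(sprintf(
    "enrichment: observed %d vs %.1f expected (%.1f-fold), p_exact = %.2g\n",
    enr$observed, enr$expected, enr$fold, enr$p_exact))
  if (model == "baseline")
    write.table(enr, "results/enrichment.tsv", quote = FALSE, sep = "\t",
                row.names = FALSE)
}
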