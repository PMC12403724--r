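#!/usr/bin/env Rscript
# Insertion-site checks across all simulated implants: target-site
# duplication scan on the bounding exons and the flanking-dinucleotide
# frequencies against the 1-in-16 random-integration null.
#
# Writes: results/context/{tsd.tsv,flank_bias.tsv}

suppressPackageStartupMessages(library(stwintronr))

dir.create("results/context", showWarnings = FALSE, recursive = TRUE)
tsd_rows <- list(); recs <- list()
for (name in c("xylariaceae", "hypoxylaceae")) {
  genome <- read_fasta(file.path("results/sim", name, "genome.fasta"))
  truth <- utils::read.delim(file.path("results/sim", name, "truth.tsv"))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    g <- genome[[tr$gene]]
    f5 <- substr(g, tr$start - 20L, tr$start - 1L)
    f3 <- substr(g, tr$end + 1L, tr$end + 20L)
    tsd <- check_tsd(f5, f3)
    tsd_rows[[paste(name, tr$gene)]] <- data.frame(
      cohort = name, gene = tr$gene,
      tsd = if (is.null(tsd)) "none" else tsd$seq,
      tsd_len = if (is.null(tsd)) 0L else tsd$length)
    recs[[paste(name, tr$gene)]] <- data.frame(flank5 = f5, flank3 = f3)
  }
}
tsd_tab <- do.call(rbind, tsd_rows)
write_tsv_report(tsd_tab, "results/context/tsd.tsv")

bias <- flank_dinucleotide_bias(do.call(rbind, recs))
bias_tab <- data.frame(
  n = bias$n,
  ag_count = bias$ag_count, gt_count = bias$gt_count,
  expected_count = bias$expected_count_ag,
  p_ag = bias$p_ag, p_gt = bias$p_gt)
write_tsv_report(bias_tab, "results/context/flank_bias.tsv")

cat(sprintf("TSD (>= 3 nt exact repeat) found at %d/%d insertion sites (seamless integration expected: none)\n",
            sum(tsd_tab$tsd_len > 0), nrow(tsd_tab)))
cat(sprintf("flank dinucleotides: AG %d/%d, GU %d/%d observed vs %.2f expected under the 1/16 null (p = %.2g / %.2g)\n",
            bias$ag_count, bias$n, bias$gt_count, bias$n,
            bias$expected_count_ag, bias$p_ag, bias$p_gt))
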