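#!/usr/bin/env Rscript
# Build the synthetic study genomes: two species-style cohorts of coding
# genes with implanted [D1,2] stwintrons, one per external-intron layout
# (Xylariaceae 2+10+2, Hypoxylaceae 7+10+2), each with a cluster of
# SNP-diverged sister copies and decoy splice motifs, plus junction reads
# for the first locus of the Xylariaceae cohort.
#
# Writes: results/sim/<cohort>/genome.fasta, truth.tsv, reads.fastq

suppressPackageStartupMessages(library(stwintronr))

seed <- 20240901L
out_root <- "results/sim"

cohorts <- list(
  xylariaceae = list(n_genes = 12, sisters = list(copies = 4, snps = c(0, 2, 3, 5)),
                     seed = seed),
  hypoxylaceae = list(n_genes = 10, sisters = list(copies = 3, snps = c(0, 1, 3)),
                      seed = seed + 1L)
)

for (name in names(cohorts)) {
  cfg <- cohorts[[name]]
  dir <- file.path(out_root, name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- build_genome(n_genes = cfg$n_genes, implant_rate = 1,
                      sisters = cfg$sisters, decoy_rate = 0.4,
                      template = name, seed = cfg$seed)
  write_fasta(gen$genome, file.path(dir, "genome.fasta"))
  write_tsv_report(gen$truth, file.path(dir, "truth.tsv"))
  cat(sprintf("%s: %d genes, %d implants (%d sisters), %d decoys\n",
              name, length(gen$genome), nrow(gen$truth),
              sum(gen$truth$sister), nrow(gen$decoys)))

  # junction reads for the first implanted locus, at low error rate
  tr <- gen$truth[1, ]
  g <- gen$genome[[tr$gene]]
  hit <- Filter(function(m) m$plus_start == tr$start && m$plus_end == tr$end,
                detect_stwintrons(g))[[1]]
  e5 <- substr(g, 1, hit$start - 1)
  e3 <- substr(g, hit$end + 1, nchar(g))
  pr <- splice_products(hit, e5, e3, phase = tr$phase)
  rr <- emit_reads(pr, c(mature = 12L, splinter = 5L, misspliced = 3L,
                         pre_mRNA = 2L),
                   read_len = 75, error_rate = 0.005, seed = cfg$seed + 100L)
  write_fastq(rr$reads, file.path(dir, "reads.fastq"))
  cat(sprintf("  reads for %s: %d across four junction kinds\n",
              tr$gene, length(rr$reads)))
}
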