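# Synthetic-data generation: ground-truthed [D1,2] stwintrons, genomes of
# coding genes with implants, sister-cluster copies, decoy motifs, and
# junction-spanning read sets. All randomness flows from a single seed.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# pyrimidine-only spacer: cannot start a branch-element match (RYURAY needs
# a purine first)
.random_py <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("C", "T"), n, replace = TRUE), collapse = "")
}

#' Layout presets for synthetic stwintron templates
#'
#' Two recurring branch-to-acceptor layouts of the external intron:
#' `"xylariaceae"` (2-nt spacer, 10-nt 3' NTIRE, 2-nt spacer: distance
#' 14 nt; 185-nt template) and `"hypoxylaceae"` (7-nt spacer, 10-nt NTIRE,
#' 2-nt spacer: distance 19 nt; 190-nt template). Both carry the canonical
#' fully complementary element pair 5'-GUAUAAAAAC / 5'-GUUUUUAUGU.
#'
#' @param name `"xylariaceae"` or `"hypoxylaceae"`.
#' @return list of [build_stwintron()] arguments.
#' @export
stw_preset <- function(name = c("xylariaceae", "hypoxylaceae")) {
  name <- match.arg(name)
  switch(name,
    xylariaceae = list(internal_len = 60L, external_len = 125L,
                       internal_bp_dist = 5L,
                       ntire = list(five = "GUAUAAAAAC",
                                    three = "GUUUUUAUGU",
                                    spacer5 = 2L, spacer3 = 2L)),
    hypoxylaceae = list(internal_len = 60L, external_len = 130L,
                        internal_bp_dist = 5L,
                        ntire = list(five = "GUAUAAAAAC",
                                     three = "GUUUUUAUGU",
                                     spacer5 = 7L, spacer3 = 2L))
  )
}

# verify that proximal-branch selection on the assembled sequences recovers
# the intended branch elements (random filler may not create a nearer one)
.template_branches_ok <- function(seq, truth, motifs, bp_window = c(2L, 25L)) {
  int_seq <- substr(seq, truth$internal[1], truth$internal[2])
  br <- find_motif_sites(int_seq, motifs$branch_pattern)
  picked <- .pick_branch(br, truth$internal_acceptor[1] - truth$internal[1] + 1L,
                         bp_window[1], bp_window[2], 7L)
  if (is.na(picked) ||
      picked != truth$internal_branch[1] - truth$internal[1] + 1L) return(FALSE)
  ext_seq <- paste0(substr(seq, 1L, 1L),
                    substr(seq, truth$internal[2] + 1L, nchar(seq)))
  shift <- truth$internal[2] - 1L   # genomic pos -> external-spliced pos
  bre <- find_motif_sites(ext_seq, motifs$branch_pattern)
  pe <- .pick_branch(bre, truth$external_acceptor[1] - shift,
                     bp_window[1], bp_window[2], 7L)
  !is.na(pe) && pe == truth$external_branch[1] - shift
}

#' Build one synthetic [D1,2] stwintron with ground truth
#'
#' Assembles a stwintron obeying the nested grammar: external G1, internal
#' intron (donor GUAUGU core, branch element, acceptor), the remaining 5 nt
#' of the external donor, then the external intron body ending in branch
#' element, optional 3' NTIRE layout, and acceptor. When an NTIRE pair is
#' requested, the 5' element starts at internal-donor offset 4 (0-based),
#' so its first two nucleotides are donor nt 5-6 (GU), and the 3' element
#' sits between the external branch element and acceptor with the stated
#' spacers. Fillers are random; pyrimidine-only spacers plus a re-draw
#' validation guarantee the intended branch elements are the proximal ones.
#' Deterministic under `seed`.
#'
#' @param internal_len,external_len constituent intron lengths (nt).
#' @param internal_bp_dist branch-to-acceptor distance of the internal
#'   intron (too short to host an NTIRE-10, as in real internal introns).
#' @param ntire `NULL`, or list(five, three, spacer5, spacer3): the element
#'   pair (RNA or DNA strings, equal length 9 or 10) and the spacers around
#'   the 3' element.
#' @param external_bp_dist branch-to-acceptor distance of the external
#'   intron when `ntire` is `NULL` (ignored otherwise; with an NTIRE the
#'   distance is spacer5 + element + spacer3).
#' @param motifs a [motif_set()].
#' @param gc background GC content of filler sequence.
#' @param seed integer seed or `NULL` to use the current RNG state.
#' @return object of class `stw_template`: `seq` (the stwintron), `truth`
#'   (1-based element coordinates relative to the stwintron, layout, and
#'   lengths).
#' @export
build_stwintron <- function(internal_len = 60L, external_len = 125L,
                            internal_bp_dist = 5L, ntire = NULL,
                            external_bp_dist = 14L,
                            motifs = motif_set(), gc = 0.5, seed = NULL) {
  internal_len <- as.integer(internal_len)
  external_len <- as.integer(external_len)
  donor <- "GTATGT"; branch <- "GCTAAC"
  acc_int <- "TAG"; acc_ext <- "CAG"
  if (!is.null(ntire)) {
    five <- as_dna(ntire$five); three <- as_dna(ntire$three)
    if (nchar(five) != nchar(three)) stop("NTIRE elements must be equal length")
    if (!nchar(five) %in% c(9L, 10L)) stop("NTIRE length must be 9 or 10")
    if (substr(five, 1L, 2L) != substr(donor, 5L, 6L)) {
      stop("5' NTIRE must start with donor nt 5-6 (", substr(donor, 5, 6), ")")
    }
    sp5 <- as.integer(ntire$spacer5); sp3 <- as.integer(ntire$spacer3)
    ext_bp <- sp5 + nchar(three) + sp3
  } else {
    ext_bp <- as.integer(external_bp_dist)
  }
  if (ext_bp < 0L) stop("infeasible layout: negative external branch distance")
  ntire_tail <- if (is.null(ntire)) "" else substr(five, 3L, nchar(five))
  f_int <- internal_len - 6L - nchar(ntire_tail) - 6L - internal_bp_dist - 3L
  if (f_int < 0L) {
    stop("infeasible layout: internal_len ", internal_len,
         " too short for donor + NTIRE + branch + ", internal_bp_dist,
         "-nt gap + acceptor")
  }
  f_ext <- external_len - 1L - 5L - 6L - ext_bp - 3L
  if (f_ext < 0L) {
    stop("infeasible layout: external_len ", external_len,
         " too short for donor + branch + ", ext_bp, "-nt gap + acceptor")
  }
  .with_seed(seed, {
    for (try in 1:100) {
      internal <- paste0(donor, ntire_tail, .random_dna(f_int, gc), branch,
                         .random_py(internal_bp_dist), acc_int)
      ext_gap <- if (is.null(ntire)) .random_py(ext_bp)
                 else paste0(.random_py(sp5), three, .random_py(sp3))
      ext_tail <- paste0(substr(donor, 2L, 6L), .random_dna(f_ext, gc),
                         branch, ext_gap, acc_ext)
      seq <- paste0("G", internal, ext_tail)
      L <- nchar(seq)
      int_start <- 2L; int_end <- 1L + internal_len
      truth <- list(
        stw_len = L,
        internal = c(int_start, int_end),
        internal_donor = c(int_start, int_start + 5L),
        internal_branch = c(int_end - internal_bp_dist - 3L - 5L,
                            int_end - internal_bp_dist - 3L),
        internal_acceptor = c(int_end - 2L, int_end),
        ext_donor_rest = c(int_end + 1L, int_end + 5L),
        external_branch = c(L - ext_bp - 8L, L - ext_bp - 3L),
        external_acceptor = c(L - 2L, L),
        internal_len = internal_len, external_len = external_len,
        internal_bp_dist = as.integer(internal_bp_dist),
        external_bp_dist = ext_bp,
        ntire5 = if (is.null(ntire)) NULL else c(6L, 5L + nchar(five)),
        ntire3 = if (is.null(ntire)) NULL
                 else c(L - 2L - sp3 - nchar(three), L - 3L - sp3),
        layout = if (is.null(ntire)) NULL
                 else list(spacer5 = sp5, element_len = nchar(three),
                           spacer3 = sp3, total = ext_bp),
        elements = if (is.null(ntire)) NULL
                   else list(five = as_rna(five), three = as_rna(three))
      )
      if (.template_branches_ok(seq, truth, motifs)) {
        return(structure(list(seq = seq, truth = truth),
                         class = "stw_template"))
      }
    }
    stop("could not assemble a template whose intended branch elements are ",
         "proximal; widen the layout or change the seed")
  })
}

#' @export
print.stw_template <- function(x, ...) {
  t <- x$truth
  cat(sprintf("synthetic [D1,2] stwintron, %d nt (internal %d + external %d)\n",
              t$stw_len, t$internal_len, t$external_len))
  if (!is.null(t$layout)) {
    cat(sprintf("  3' NTIRE layout: %d + %d + %d = %d nt bp-to-acceptor\n",
                t$layout$spacer5, t$layout$element_len, t$layout$spacer3,
                t$layout$total))
  }
  invisible(x)
}

# positions of a template protected from SNPs: terminal G, consensus
# elements, and NTIREs
.protected_positions <- function(truth) {
  iv <- list(c(1L, 1L), truth$internal_donor, truth$internal_branch,
             truth$internal_acceptor, truth$ext_donor_rest,
             truth$external_branch, truth$external_acceptor,
             truth$ntire5, truth$ntire3)
  unique(unlist(lapply(iv[!vapply(iv, is.null, TRUE)],
                       function(x) seq(x[1], x[2]))))
}

# apply n substitutions uniformly outside protected positions
.apply_snps <- function(template, n_snps) {
  ch <- strsplit(template$seq, "")[[1]]
  ok <- setdiff(seq_along(ch), .protected_positions(template$truth))
  if (n_snps > length(ok)) stop("more SNPs requested than mutable positions")
  pos <- sort(sample(ok, n_snps))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  list(seq = paste(ch, collapse = ""), snp_positions = pos)
}

.random_orf <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1L, paste, collapse = "")
  codons <- setdiff(codons, stops)
  paste0("ATG", paste(sample(codons, n_codons, replace = TRUE),
                      collapse = ""), "TAA")
}

#' Build a synthetic genome of coding genes with implanted stwintrons
#'
#' Generates random-codon ORFs (one FASTA record per gene) and implants a
#' stwintron seamlessly (no target-site duplication) at a uniformly chosen
#' exonic position in a fraction of them. Optionally a sister cluster is
#' emulated: several genes receive SNP-diverged copies of one template, the
#' substitutions placed uniformly outside consensus elements and NTIREs.
#' Decoy partial motifs (a donor hexamer without downstream structure, or a
#' branch+acceptor without a donor) can be sprinkled in to stress candidate
#' ranking. Every implant is the sole intronic sequence in its gene.
#'
#' @param n_genes number of genes.
#' @param implant_rate fraction of genes receiving an implant (1 = all).
#' @param sisters `NULL`, or list(copies, snps): number of genes carrying
#'   SNP-diverged copies of one shared template and the per-copy
#'   substitution count (scalar or vector; the first copy can be 0 = exact).
#' @param decoy_rate fraction of genes receiving one decoy partial motif.
#' @param template an `stw_template`, a preset name, or `NULL` to build an
#'   independent randomized template per implant.
#' @param tsd_len 0 for seamless integration (default); a positive length
#'   duplicates that many nucleotides at the insertion site, for
#'   negative-control testing of [check_tsd()].
#' @param n_codons_range range of ORF lengths in codons.
#' @param gc background GC content.
#' @param seed integer seed.
#' @return list of class `synthetic_genome`: `genome` (named character
#'   vector of gene sequences), `truth` (data.frame, one row per implant:
#'   gene, start, end, internal/external segment coordinates, phase,
#'   lengths, NTIRE layout, snps), `templates` (per-gene `stw_template`),
#'   `decoys` (data.frame).
#' @export
build_genome <- function(n_genes = 10L, implant_rate = 1, sisters = NULL,
                         decoy_rate = 0, template = NULL, tsd_len = 0L,
                         n_codons_range = c(80L, 140L), gc = 0.5,
                         seed = NULL) {
  stopifnot(n_genes >= 1L)
  .with_seed(seed, {
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
    n_implant <- round(n_genes * implant_rate)
    implant_in <- gene_ids[seq_len(n_implant)]
    sister_template <- NULL
    sister_genes <- character(0)
    if (!is.null(sisters)) {
      copies <- sisters$copies
      if (copies > n_implant) stop("sister copies exceed implanted genes")
      sister_genes <- implant_in[seq_len(copies)]
      sister_template <- if (is.null(template)) {
        do.call(build_stwintron, stw_preset("xylariaceae"))
      } else if (is.character(template)) {
        do.call(build_stwintron, stw_preset(template))
      } else template
      snps <- rep_len(sisters$snps, copies)
    }
    genome <- character(0)
    templates <- list()
    truth <- list()
    decoys <- list()
    for (g in gene_ids) {
      orf <- .random_orf(sample(seq(n_codons_range[1], n_codons_range[2]), 1L))
      row <- NULL
      if (g %in% implant_in) {
        if (g %in% sister_genes) {
          i <- match(g, sister_genes)
          tpl <- sister_template
          mut <- .apply_snps(tpl, snps[i])
          stw_seq <- mut$seq
          snp_pos <- mut$snp_positions
        } else if (!is.null(template)) {
          tpl <- if (is.character(template)) {
            do.call(build_stwintron, stw_preset(template))
          } else template
          stw_seq <- tpl$seq
          snp_pos <- integer(0)
        } else {
          tpl <- build_stwintron(
            internal_len = sample(45:90, 1L),
            external_len = sample(60:140, 1L),
            ntire = stw_preset("xylariaceae")$ntire, gc = gc)
          stw_seq <- tpl$seq
          snp_pos <- integer(0)
        }
        # insertion point: uniform exonic position with >= 40 nt context
        p <- sample(seq(40L, nchar(orf) - 40L), 1L)
        dup <- if (tsd_len > 0L) substr(orf, p - tsd_len + 1L, p) else ""
        gene_seq <- paste0(substr(orf, 1L, p), stw_seq, dup,
                           substr(orf, p + 1L, nchar(orf)))
        t <- tpl$truth
        st <- p + 1L; en <- p + t$stw_len
        row <- data.frame(
          gene = g, start = st, end = en,
          internal_start = st + 1L, internal_end = st + t$internal_len,
          external_part2_start = st + t$internal_len + 1L,
          external_part2_end = en,
          phase = p %% 3L,
          stw_len = t$stw_len, internal_len = t$internal_len,
          external_len = t$external_len,
          external_bp_dist = t$external_bp_dist,
          has_ntire = !is.null(t$ntire3),
          spacer5 = if (is.null(t$layout)) NA_integer_ else t$layout$spacer5,
          element_len = if (is.null(t$layout)) NA_integer_ else t$layout$element_len,
          spacer3 = if (is.null(t$layout)) NA_integer_ else t$layout$spacer3,
          sister = g %in% sister_genes,
          n_snps = length(snp_pos),
          tsd_len = as.integer(tsd_len),
          stringsAsFactors = FALSE)
        templates[[g]] <- tpl
      } else {
        gene_seq <- orf
      }
      if (stats::runif(1) < decoy_rate) {
        decoy <- sample(c("GTATGT", "GCTAACCTCAG"), 1L)
        occupied <- if (is.null(row)) c(0L, 0L) else c(row$start, row$end)
        dp <- sample(setdiff(seq(10L, nchar(gene_seq) - 20L),
                             seq(max(1L, occupied[1] - 20L),
                                 min(nchar(gene_seq), occupied[2] + 20L))), 1L)
        gene_seq <- paste0(substr(gene_seq, 1L, dp), decoy,
                           substr(gene_seq, dp + 1L, nchar(gene_seq)))
        if (!is.null(row) && dp <= row$start) {
          shift <- nchar(decoy)
          row[c("start", "end", "internal_start", "internal_end",
                "external_part2_start", "external_part2_end")] <-
            row[c("start", "end", "internal_start", "internal_end",
                  "external_part2_start", "external_part2_end")] + shift
        }
        decoys[[length(decoys) + 1L]] <- data.frame(gene = g, pos = dp,
                                                    motif = decoy,
                                                    stringsAsFactors = FALSE)
      }
      genome[[g]] <- gene_seq
      if (!is.null(row)) truth[[length(truth) + 1L]] <- row
    }
    structure(
      list(genome = genome,
           truth = if (length(truth)) do.call(rbind, truth)
                   else data.frame(),
           templates = templates,
           decoys = if (length(decoys)) do.call(rbind, decoys)
                    else data.frame()),
      class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d genes, %d implanted stwintrons, %d decoys\n",
              length(x$genome), nrow(x$truth), nrow(x$decoys)))
  invisible(x)
}

#' Emit junction-spanning reads for one stwintron locus
#'
#' Samples reads across the diagnostic junction of each splice product:
#' read offsets uniform among positions that cover the junction with at
#' least `min_overhang` nt on both sides, strand random, substitution
#' errors applied at `error_rate` per base.
#'
#' @param products list of `splice_product` records from
#'   [splice_products()].
#' @param counts named integer vector: reads per kind, e.g.
#'   `c(mature = 10, splinter = 4, misspliced = 2, pre_mRNA = 1)`.
#' @param read_len read length; must be at least `2 * min_overhang`.
#' @param error_rate per-base substitution probability.
#' @param min_overhang minimal junction overhang guaranteed per read.
#' @param seed integer seed.
#' @return list: `reads` (named character vector; names encode kind and
#'   index), `truth` (data.frame kind/count as actually written).
#' @export
emit_reads <- function(products, counts, read_len = 80L, error_rate = 0,
                       min_overhang = 8L, seed = NULL) {
  read_len <- as.integer(read_len)
  if (read_len < 2L * min_overhang) {
    stop("read length must be at least 2 * min_overhang (",
         2L * min_overhang, ")")
  }
  .with_seed(seed, {
    reads <- character(0)
    for (kind in names(counts)) {
      n <- counts[[kind]]
      if (n == 0L) next
      prod <- products[[kind]]
      if (is.null(prod)) stop("no product of kind ", kind)
      j <- prod$junctions$left[1]
      L <- nchar(prod$sequence)
      lo <- max(1L, j - read_len + min_overhang + 1L)
      hi <- min(L - read_len + 1L, j - min_overhang + 1L)
      if (hi < lo) stop("product too short to sample ", kind, " reads")
      for (i in seq_len(n)) {
        st <- if (hi == lo) lo else sample(seq(lo, hi), 1L)
        r <- substr(prod$sequence, st, st + read_len - 1L)
        if (error_rate > 0) {
          ch <- strsplit(r, "")[[1]]
          err <- which(stats::runif(length(ch)) < error_rate)
          for (p in err) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1L)
          r <- paste(ch, collapse = "")
        }
        if (stats::runif(1) < 0.5) r <- revcomp(r)
        reads[[paste0(kind, "_", i)]] <- r
      }
    }
    truth <- data.frame(kind = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}
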