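# Pipeline driver: compose detection, splicing, NTIRE/symmetry, integration
# context, clustering and read evidence into one run with a per-stwintron
# master report.

#' Default pipeline configuration
#'
#' @param fasta path to a genomic FASTA, or `NULL` to simulate.
#' @param reads path to junction reads (FASTA/FASTQ), or `NULL`.
#' @param out_dir output directory, or `NULL` for no files.
#' @param seed integer seed governing all randomness in the run.
#' @param simulate list of [build_genome()] arguments used when `fasta` is
#'   `NULL`.
#' @param detection list of [detection_config()] arguments.
#' @param motifs list of [motif_set()] arguments.
#' @param query_len junction query length.
#' @param max_mismatches,min_overhang read-classification settings.
#' @param cluster_threshold identity threshold for sister clusters.
#' @return config list.
#' @export
pipeline_config <- function(fasta = NULL, reads = NULL, out_dir = NULL,
                            seed = 1L,
                            simulate = list(n_genes = 6L, implant_rate = 1),
                            detection = list(), motifs = list(),
                            query_len = 60L, max_mismatches = 1L,
                            min_overhang = 8L, cluster_threshold = 0.97) {
  list(fasta = fasta, reads = reads, out_dir = out_dir, seed = seed,
       simulate = simulate, detection = detection, motifs = motifs,
       query_len = query_len, max_mismatches = max_mismatches,
       min_overhang = min_overhang, cluster_threshold = cluster_threshold)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; keys as in [pipeline_config()].
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed config ", path, ": ", conditionMessage(e))
  })
  do.call(pipeline_config, cfg)
}

#' Run the stwintron analysis pipeline
#'
#' Executes detect -> splice -> NTIRE/symmetry -> integration context ->
#' cluster -> evidence over a genomic FASTA (or a simulated genome when no
#' FASTA is configured) and assembles a per-stwintron master table:
#' coordinates, constituent intron bounds, branch-to-acceptor distances,
#' NTIRE pair and complementarity, phase (when ground truth is available),
#' sole-intron flag, TSD check, cluster membership and read-support verdict.
#' Without reads, the evidence columns read `"no data"`. Reruns with the
#' same config and seed produce identical outputs.
#'
#' @param config a [pipeline_config()] list, or a path to a YAML file.
#' @return (invisibly) list: `master` (data.frame), `hits`, `clusters`,
#'   `identity`, `tree`, `flank_bias`, `log`. Files are written under
#'   `config$out_dir` when set: master.tsv, stwintrons.gff3, ntire.tsv,
#'   identity_matrix.tsv, clusters.tsv, tree.nwk, products.fasta,
#'   queries.fasta, verdicts.tsv, log.txt.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  t0 <- Sys.time()
  log_lines <- c(sprintf("seed: %s", config$seed))
  stage <- function(name, expr) {
    st <- Sys.time()
    val <- force(expr)
    log_lines <<- c(log_lines, sprintf("%s: %.2fs", name,
                                       as.numeric(Sys.time() - st, units = "secs")))
    val
  }
  motifs <- do.call(motif_set, config$motifs)
  det_cfg <- do.call(detection_config, config$detection)

  truth <- NULL
  if (!is.null(config$fasta)) {
    genome <- stage("load", read_fasta(config$fasta))
  } else {
    sim <- stage("simulate", do.call(build_genome,
                                     c(config$simulate, list(seed = config$seed))))
    genome <- sim$genome
    truth <- sim$truth
  }

  hits <- stage("detect", {
    h <- lapply(genome, detect_stwintrons, motifs = motifs, cfg = det_cfg)
    h[vapply(h, length, 0L) > 0L]
  })

  rows <- list(); products_fa <- character(0); queries_fa <- character(0)
  ntire_rows <- list(); locus_queries <- list()
  stage("splice+ntire+context", {
    for (rec in names(hits)) {
      for (i in seq_along(hits[[rec]])) {
        m <- hits[[rec]][[i]]
        id <- sprintf("%s.stw%02d", rec, i)
        rseq <- genome[[rec]]
        exon5 <- substr(rseq, 1L, m$start - 1L)
        exon3 <- substr(rseq, m$end + 1L, nchar(rseq))
        if (m$strand == "-") {
          rs <- revcomp(rseq)
          exon5 <- substr(rs, 1L, m$start - 1L)
          exon3 <- substr(rs, m$end + 1L, nchar(rs))
        }
        enough <- nchar(exon5) >= 30L && nchar(exon3) >= 30L
        phase <- NA_integer_
        if (!is.null(truth)) {
          tr <- truth[truth$gene == rec & truth$start == m$plus_start, ]
          if (nrow(tr) == 1L) phase <- tr$phase
        }
        prods <- if (enough) splice_products(m, exon5, exon3, phase) else NULL
        qs <- if (enough && nchar(exon5) >= config$query_len / 2)
          make_junction_queries(m, exon5, exon3, config$query_len) else NULL
        if (!is.null(prods)) {
          for (p in prods) {
            products_fa[[paste(id, p$kind, sep = "|")]] <- p$sequence
          }
        }
        if (!is.null(qs)) {
          locus_queries[[id]] <- qs
          for (k in seq_len(nrow(qs))) {
            queries_fa[[paste(id, qs$kind[k], "junction", sep = "|")]] <-
              qs$query[k]
          }
        }
        pairs <- scan_ntire(m, threshold = 1.0)
        lay <- if (length(pairs)) bp_acceptor_layout(m$external, pairs[[1]])
               else bp_acceptor_layout(m$external)
        if (length(pairs)) {
          ntire_rows[[id]] <- data.frame(
            id = id, five_elem = pairs[[1]]$five_elem,
            three_elem = pairs[[1]]$three_elem,
            five_offset = pairs[[1]]$five_offset,
            fraction = pairs[[1]]$complementarity_fraction,
            classes = paste(pairs[[1]]$pair_classes, collapse = ","),
            stringsAsFactors = FALSE)
        }
        tsd <- if (nchar(m$flank5) >= 10L && nchar(m$flank3) >= 10L)
          check_tsd(m$flank5, m$flank3) else NULL
        rows[[id]] <- data.frame(
          record = rec, id = id, start = m$plus_start, end = m$plus_end,
          strand = m$strand, length = m$len, rank = m$rank,
          internal_start = m$internal$start, internal_end = m$internal$end,
          internal_len = m$internal$len, external_len = m$external$len,
          internal_bp_dist = m$internal$bp_to_acceptor_distance,
          external_bp_dist = m$external$bp_to_acceptor_distance,
          ntire = if (length(pairs))
            paste0(pairs[[1]]$five_elem, "/", pairs[[1]]$three_elem)
            else "none",
          ntire_fraction = if (length(pairs))
            pairs[[1]]$complementarity_fraction else NA_real_,
          layout = sprintf("%d+%d+%d=%d", lay$spacer5, lay$element_len,
                           lay$spacer3, lay$total),
          phase = phase,
          sole_intron = length(hits[[rec]][vapply(hits[[rec]], `[[`, 0L,
                                                  "rank") == 1L]) == 1L,
          tsd = if (is.null(tsd)) "none" else tsd$seq,
          stringsAsFactors = FALSE)
      }
    }
  })
  master <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(master) <- NULL

  flank_bias <- NULL
  top <- if (nrow(master)) master[master$rank == 1L, ] else master
  stage("context", {
    fl <- lapply(names(hits), function(rec) {
      lapply(hits[[rec]], function(m) {
        if (nchar(m$flank5) >= 2L && nchar(m$flank3) >= 2L)
          data.frame(flank5 = m$flank5, flank3 = m$flank3,
                     stringsAsFactors = FALSE)
        else NULL
      })
    })
    fl <- do.call(rbind, unlist(fl, recursive = FALSE))
    if (!is.null(fl) && nrow(fl)) flank_bias <- flank_dinucleotide_bias(fl)
  })

  clusters <- list(); ident <- NULL; tree <- NULL
  stage("cluster", {
    top_ids <- if (nrow(master)) master$id[master$rank == 1L] else character(0)
    seqs <- stats::setNames(
      unlist(lapply(names(hits), function(rec) {
        lapply(hits[[rec]], function(m) if (m$rank == 1L) m$seq else NULL)
      })), NULL)
    seqs <- unlist(seqs)
    if (length(seqs) >= 2L) {
      names(seqs) <- top_ids
      ident <- identity_matrix(seqs)
      clusters <- near_identical_clusters(ident, config$cluster_threshold)
      if (length(seqs) >= 3L) tree <- nj_tree(ident)
    }
  })
  if (nrow(master)) {
    master$cluster <- NA_integer_
    for (ci in seq_along(clusters)) {
      master$cluster[master$id %in% clusters[[ci]]] <- ci
    }
  }

  verdicts <- NULL
  stage("evidence", {
    if (!is.null(config$reads) && length(locus_queries)) {
      reads <- read_reads(config$reads)
      vr <- list()
      for (id in names(locus_queries)) {
        cl <- classify_reads(reads, locus_queries[[id]],
                             config$max_mismatches, config$min_overhang)
        v <- locus_verdict(cl$counts)
        vr[[id]] <- data.frame(
          id = id,
          mature = cl$counts[["mature"]], splinter = cl$counts[["splinter"]],
          misspliced = cl$counts[["misspliced"]],
          pre_mRNA = cl$counts[["pre_mRNA"]],
          stwintron_confirmed = v$stwintron_confirmed,
          splinter_confirmed = v$splinter_confirmed,
          missplice_observed = v$missplice_observed,
          stringsAsFactors = FALSE)
      }
      verdicts <- do.call(rbind, vr)
      rownames(verdicts) <- NULL
    }
  })
  if (nrow(master)) {
    if (is.null(verdicts)) {
      master$stwintron_confirmed <- "no data"
      master$splinter_confirmed <- "no data"
      master$missplice_observed <- "no data"
    } else {
      idx <- match(master$id, verdicts$id)
      master$stwintron_confirmed <- as.character(verdicts$stwintron_confirmed[idx])
      master$splinter_confirmed <- as.character(verdicts$splinter_confirmed[idx])
      master$missplice_observed <- as.character(verdicts$missplice_observed[idx])
    }
  }

  log_lines <- c(log_lines, sprintf("total: %.2fs",
                                    as.numeric(Sys.time() - t0, units = "secs")))
  out <- list(master = master, hits = hits, clusters = clusters,
              identity = ident, tree = tree, flank_bias = flank_bias,
              verdicts = verdicts, truth = truth, log = log_lines)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- function(f) file.path(config$out_dir, f)
    write_tsv_report(master, od("master.tsv"))
    write_stwintron_gff3(hits, od("stwintrons.gff3"))
    if (length(ntire_rows)) {
      write_tsv_report(do.call(rbind, ntire_rows), od("ntire.tsv"))
    }
    if (!is.null(ident)) {
      utils::write.table(round(unclass(ident), 5), od("identity_matrix.tsv"),
                         sep = "\t", quote = FALSE)
      cl_df <- if (length(clusters)) {
        do.call(rbind, lapply(seq_along(clusters), function(i) {
          data.frame(cluster = i, id = clusters[[i]], stringsAsFactors = FALSE)
        }))
      } else data.frame(cluster = integer(0), id = character(0))
      write_tsv_report(cl_df, od("clusters.tsv"))
    }
    if (!is.null(tree)) writeLines(as.character(tree), od("tree.nwk"))
    if (length(products_fa)) write_fasta(products_fa, od("products.fasta"))
    if (length(queries_fa)) write_fasta(queries_fa, od("queries.fasta"))
    if (!is.null(verdicts)) write_tsv_report(verdicts, od("verdicts.tsv"))
    writeLines(log_lines, od("log.txt"))
  }
  invisible(out)
}
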