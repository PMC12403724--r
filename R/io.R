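# File interchange: FASTA/FASTQ via Biostrings, GFF3 via rtracklayer.

#' Read a (multi-record) FASTA file
#' @param path file path.
#' @return named character vector of sequences (DNA alphabet).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as_dna(as.character(x)), names(x))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(as_dna(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequencing reads from FASTA or FASTQ
#' @param path file path; format chosen by extension (`.fastq`/`.fq` vs
#'   FASTA otherwise).
#' @return named character vector of reads.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("input reads not found: ", path)
  fmt <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) "fastq"
         else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as_dna(as.character(x)), names(x))
}

#' Write reads to FASTQ (uniform maximal quality)
#' @param reads named character vector.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(as_dna(reads))
  names(x) <- names(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads),
                                     function(n) strrep("I", n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Detected stwintrons as a GFF3-ready GRanges
#'
#' One `stwintron` feature per model plus child features `internal_intron`,
#' `external_intron_part1` (the single G1) and `external_intron_part2`.
#' Coordinates are 1-based inclusive on the plus strand; minus-strand hits
#' carry `strand == "-"`.
#'
#' @param hits named list: per record id, a list of `stwintron_model`s.
#' @return a `GRanges` with `type`, `ID`, `Parent` and `rank` columns.
#' @export
stwintrons_as_granges <- function(hits) {
  rows <- list()
  for (rec in names(hits)) {
    for (i in seq_along(hits[[rec]])) {
      m <- hits[[rec]][[i]]
      id <- sprintf("%s.stw%02d", rec, i)
      # convert scanned-strand constituent coordinates to plus strand
      conv <- function(a, b) {
        if (m$strand == "+") c(a, b)
        else {
          L <- m$plus_end + m$start - 1L   # record length relation
          c(m$plus_start + (m$end - b), m$plus_start + (m$end - a))
        }
      }
      stw <- c(m$plus_start, m$plus_end)
      int <- conv(m$internal$start, m$internal$end)
      p1 <- conv(m$external$part1[1], m$external$part1[2])
      p2 <- conv(m$external$part2[1], m$external$part2[2])
      add <- function(type, iv, suffix, parent = NA) {
        rows[[length(rows) + 1L]] <<- data.frame(
          seqnames = rec, start = iv[1], end = iv[2], strand = m$strand,
          type = type, ID = paste0(id, suffix),
          Parent = if (is.na(parent)) NA_character_ else parent,
          rank = m$rank, stringsAsFactors = FALSE)
      }
      add("stwintron", stw, "")
      add("internal_intron", int, ".int", id)
      add("external_intron_part1", p1, ".ext1", id)
      add("external_intron_part2", p2, ".ext2", id)
    }
  }
  if (!length(rows)) {
    return(GenomicRanges::GRanges())
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  S4Vectors::mcols(gr)$rank <- df$rank
  gr
}

#' Write detected stwintrons to GFF3
#' @param hits named list of `stwintron_model` lists (per record).
#' @param path output path.
#' @export
write_stwintron_gff3 <- function(hits, path) {
  gr <- stwintrons_as_granges(hits)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a data.frame as a TSV report
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
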