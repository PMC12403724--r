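# In-silico splicing of [D1,2] stwintrons: product enumeration, junction
# query construction, and frameshift assessment.

#' Enumerate splice products of a [D1,2] stwintron
#'
#' Returns the four sequence outcomes of a [D1,2] stwintron in its exonic
#' context:
#' \describe{
#'   \item{pre_mRNA}{unspliced: exon5' + stwintron + exon3'.}
#'   \item{splinter}{the splicing intermediate lacking the internal intron
#'     but still containing the external intron: exon5' + external + exon3'.}
#'   \item{mature}{both constituent introns excised; the exons ligated.}
#'   \item{misspliced}{single canonical excision from the internal donor to
#'     the external acceptor, removing the whole stwintron except exactly one
#'     intronic G (the external donor's G1) left between the exons.}
#' }
#' Lariat/branch biochemistry is not modelled; products are pure sequence
#' outcomes.
#'
#' @param stw a `stwintron_model` (or any list with `seq` and
#'   `internal$len`).
#' @param exon5,exon3 flanking exonic sequence, at least 30 nt each.
#' @param phase intron phase 0/1/2 if known (`NA` allowed); used for the
#'   `frameshift` field.
#' @return named list of four `splice_product` records, each with fields
#'   `kind`, `sequence`, `junctions` (data.frame: left, right, label),
#'   `retained_intronic_nt`, `frameshift`.
#' @export
splice_products <- function(stw, exon5, exon3, phase = NA_integer_) {
  exon5 <- as_dna(exon5); exon3 <- as_dna(exon3)
  if (nchar(exon5) < 30L) stop("exon5 context must be at least 30 nt")
  if (nchar(exon3) < 30L) stop("exon3 context must be at least 30 nt")
  s <- as_dna(stw$seq)
  int_len <- stw$internal$len
  if (is.null(int_len) || nchar(s) < int_len + 1L) {
    stop("malformed stwintron model: internal intron does not fit")
  }
  if (substr(s, 1L, 1L) != "G") stop("malformed stwintron model: no terminal G1")
  e5 <- nchar(exon5)
  ext_seq <- paste0("G", substr(s, int_len + 2L, nchar(s)))
  jx <- function(pos, label) data.frame(left = pos, right = pos + 1L,
                                        label = label,
                                        stringsAsFactors = FALSE)
  prod <- function(kind, sequence, junctions, retained) {
    structure(list(kind = kind, sequence = sequence, junctions = junctions,
                   retained_intronic_nt = as.integer(retained),
                   frameshift = if (is.na(phase)) NA else (retained %% 3L != 0L)),
              class = "splice_product")
  }
  list(
    pre_mRNA = prod("pre_mRNA", paste0(exon5, s, exon3),
                    rbind(jx(e5, "exon5|stwintron"),
                          jx(e5 + nchar(s), "stwintron|exon3")),
                    nchar(s)),
    splinter = prod("splinter", paste0(exon5, ext_seq, exon3),
                    rbind(jx(e5, "exon5|external_intron"),
                          jx(e5 + nchar(ext_seq), "external_intron|exon3")),
                    nchar(ext_seq)),
    mature = prod("mature", paste0(exon5, exon3),
                  jx(e5, "exon5|exon3"), 0L),
    misspliced = prod("misspliced", paste0(exon5, "G", exon3),
                      rbind(jx(e5, "exon5|G"), jx(e5 + 1L, "G|exon3")),
                      1L)
  )
}

#' @export
print.splice_product <- function(x, ...) {
  cat(sprintf("%s product, %d nt, %d intronic nt retained\n",
              x$kind, nchar(x$sequence), x$retained_intronic_nt))
  invisible(x)
}

#' Build junction-spanning query sequences for read verification
#'
#' Constructs fixed-length queries centred on each diagnostic fusion site,
#' the in-silico analog of screening expression reads with junction queries:
#' the mature exon/exon fusion, the splinter exon/external-intron fusion,
#' the misspliced exon-G-exon fusion, and (for completeness of read
#' classification) the unspliced exon/stwintron boundary. Each query has the
#' fusion point between positions `query_len/2` and `query_len/2 + 1`.
#'
#' @param stw a `stwintron_model`.
#' @param exon5,exon3 flanking exonic sequence.
#' @param query_len even query length, >= 20; default 60.
#' @param kinds which queries to build.
#' @return data.frame of class `junction_queries` with columns `kind`,
#'   `query`, `fusion_pos`.
#' @export
make_junction_queries <- function(stw, exon5, exon3, query_len = 60L,
                                  kinds = c("mature", "splinter",
                                            "misspliced", "pre_mRNA")) {
  query_len <- as.integer(query_len)
  if (query_len %% 2L != 0L) stop("query_len must be even")
  if (query_len < 20L) stop("query_len must be at least 20")
  kinds <- match.arg(kinds, several.ok = TRUE)
  exon5 <- as_dna(exon5); exon3 <- as_dna(exon3)
  half <- query_len %/% 2L
  s <- as_dna(stw$seq)
  ext_seq <- paste0("G", substr(s, stw$internal$len + 2L, nchar(s)))
  downstream <- c(mature = exon3,
                  splinter = paste0(ext_seq, exon3),
                  misspliced = paste0("G", exon3),
                  pre_mRNA = paste0(s, exon3))
  if (nchar(exon5) < half) {
    stop("insufficient context on the 5' side: need ", half, " nt, have ",
         nchar(exon5))
  }
  qs <- vapply(kinds, function(k) {
    down <- downstream[[k]]
    if (nchar(down) < half) {
      stop("insufficient context on the 3' side for ", k, " query: need ",
           half, " nt, have ", nchar(down))
    }
    paste0(substr(exon5, nchar(exon5) - half + 1L, nchar(exon5)),
           substr(down, 1L, half))
  }, "")
  structure(data.frame(kind = kinds, query = unname(qs), fusion_pos = half,
                       stringsAsFactors = FALSE),
            class = c("junction_queries", "data.frame"))
}

#' Does missplicing (or any partial retention) shift the reading frame?
#'
#' A [D1,2] missplice retains exactly one intronic G between the exons, and
#' 1 mod 3 != 0, so the answer for missplicing is always `TRUE`.
#'
#' @param stw a `stwintron_model` (unused beyond its class; the retained
#'   length of a [D1,2] missplice is always 1).
#' @param phase intron phase, one of 0, 1, 2.
#' @param retained number of intronic nucleotides retained (default 1, the
#'   misspliced case).
#' @return `TRUE` iff `retained %% 3 != 0`.
#' @export
assess_frameshift <- function(stw, phase, retained = 1L) {
  if (!phase %in% c(0L, 1L, 2L)) stop("phase must be 0, 1 or 2")
  (as.integer(retained) %% 3L) != 0L
}
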