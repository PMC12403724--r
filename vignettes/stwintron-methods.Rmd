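---
title: "Detecting and analysing [D1,2] spliceosomal twin introns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing [D1,2] spliceosomal twin introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stwintronr)
```

## The biological model

Fungal U2 introns are defined by three short consensus elements: a 6-nt 5'
donor (consensus GURWGY, occasionally GC-initiated), an internal branch
element containing the branch-point adenosine (RYURAY, branch A at the
fifth position), and a 3' acceptor triplet (HAG). A *spliceosomal twin
intron* (stwintron) is a pair of nested U2 introns. In the [D1,2] class the
internal intron interrupts the donor of the external intron between its
first nucleotide (G1) and its second, so the external donor only becomes
contiguous — and the external intron excisable — after the internal intron
has been removed. Four RNA species follow from this arrangement:

* **pre-mRNA** — nothing excised;
* **splinter** — the splicing intermediate lacking the internal intron but
  still containing the external intron;
* **mature mRNA** — both constituent introns excised, exons ligated;
* **misspliced mRNA** — a single canonical excision from the *internal*
  donor to the *external* branch/acceptor removes the whole stwintron
  except one intronic G (the external G1), which remains between the exons.
  One retained nucleotide is never a multiple of three, so missplicing
  always shifts the reading frame.

`detect_stwintrons()` implements this grammar directly: internal-intron
candidates are enumerated from (donor, branch, acceptor) triples; each
candidate must be preceded by a G and followed by 5 nt that complete an
external donor; the detector then walks 3' for an external branch element
and acceptor within a length window. All overlapping parses are reported
and ranked (see below) rather than silently resolved.

A second strand of analysis concerns *near-terminal inverted repeat
elements* (NTIRE-9/10): a 9-10-nt element within 5 nt of the stwintron's
5' end whose partner lies between the external branch element and the
acceptor. Under Watson-Crick plus G:U wobble pairing the two elements can
be 100% complementary and fold the excised (misspliced) intron RNA into a
near-terminal stem that juxtaposes the two terminal G's. The
branch-to-acceptor distance of the external intron then decomposes as
spacer + element + spacer; the two recurring layouts are 2+10+2 = 14 nt
and 7+10+2 = 19 nt, and the package ships these as the `"xylariaceae"` and
`"hypoxylaceae"` presets of the synthetic generator.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| donor patterns | GURWGY, GCRWGY | 6-nt IUPAC donor consensus; the GC variant applies to internal introns only unless widened |
| branch pattern | RYURAY (A at offset 4) | branch element; the proximal match (nearest the acceptor) is used, the standard branch-point convention |
| acceptor | HAG | superset of YAG; strict YAG via `motif_set(acceptor_pattern = "YAG")` |
| intron length windows | 40–200 nt each | the validated near-identical stwintrons are 184–185 nt in total; no explicit bounds are established for the general case, so the windows are deliberately generous and fully configurable |
| branch-to-acceptor window | 2–25 nt | observed external distances cluster at 14 and 19 nt; internal introns are shorter |
| `near_terminal_limit` | 5 nt | maximal offset of the 5' NTIRE from the terminal G |
| NTIRE threshold | 1.0 | report only fully complementary pairs; 0.8 is the suggested partial-pair setting |
| `query_len` | 60 nt | junction queries with the fusion site at the centre; even values only (odd values are rejected rather than rounded) |
| `max_mismatches` | 1 | "near-perfect" read matching; 0 = exact |
| `min_overhang` | 8 nt | minimal read coverage of each side of a fusion point, for junction specificity |
| cluster threshold | 0.97 | strict `>`; encodes "not more than five SNPs" on a ~185-nt pair |

Candidate **ranking** (within groups of mutually overlapping parses)
prefers external branch-to-acceptor distances in {14, 19}, then the
presence of a fully complementary NTIRE pair, then shorter total length,
with ties broken by the leftmost start. This mirrors a manual preference
for consensus-perfect, NTIRE-bearing structures while keeping every
alternative on the record.

Open grammar choices resolved here: the GC-initiated donor is restricted
to internal introns by default (`external_allow_gc` widens it), and N
never matches any IUPAC class, so assembly gaps cannot produce spurious
splice sites.

## Numerical and algorithmic choices

**Coordinates** are 1-based inclusive everywhere (reports, GFF3, and the
in-memory models); minus-strand hits carry scanning-frame constituent
coordinates plus a plus-strand interval and a strand flag.

**Missplicing** retains the stwintron's *first* nucleotide (the external
G1): the misspliced intron runs from the internal donor to the external
acceptor, which excludes exactly G1. Lariat biochemistry is not modelled;
products are pure sequence outcomes.

**Self-reverse-complement alignment** (`self_revcomp_align()`) renders the
diagnostic terminal-symmetry view: `*` for identity columns, `#` for GU
interactions (G aligned to A, or U aligned to C), `|` at the centre column
of odd-length sequences. The alignment is built palindromically: the 5'
half is aligned to the reverse complement of the 3' half by
Needleman-Wunsch (match +1, mismatch/GU 0, gap −2; deterministic
tie-break) and mirrored, so the consensus line is exactly symmetric — the
property the annotation semantics require. This restriction can cost a
point or two against an unrestricted global alignment; a test asserts the
score never exceeds the unrestricted optimum and attains it for perfect
palindromes. Which genomic G the symmetry centre denotes is ambiguous in
the [D1,2] arrangement, so the centre is simply the alignment midpoint
(for even lengths no centre column exists and `center_pos` is `NA`).

**Identity** is computed from a global alignment (match +1, mismatch −1,
gap −2, free opening) as matched columns over all alignment columns, gap
columns included. On equal-length near-identical pairs this coincides with
1 − SNPs/length, which is what makes 5 SNPs on 185 nt pass the 0.97
threshold (180/185 ≈ 0.973) and 6 fail (≈ 0.968). The neighbor-joining
tree on 1 − identity is a deliberately simple summary of sister-stwintron
relatedness — maximum-likelihood phylogenetics, substitution-model
selection and bootstrap support are out of scope. Negative NJ branch
lengths are clamped to zero and flagged.

**Read classification** is alignment-free sliding Hamming comparison of
reads against 60-nt junction queries: indels make a read fail, mirroring a
perfect/near-perfect criterion; both orientations are tried. Reads
matching queries of more than one kind are counted `ambiguous` rather than
resolved. Verdicts are presence/absence flags only — read counts are never
compared across loci. One addition beyond the three verification queries:
a fourth query for the unspliced exon/stwintron boundary, so pre-mRNA
support is assessed with the same machinery.

## What the synthetic generator emulates — and what it does not

`build_genome()` produces random-codon ORFs with stwintrons implanted
seamlessly (no target-site duplication; a TSD mode exists purely as a
positive control for `check_tsd()`) at uniformly chosen exonic positions,
each implant the sole intronic sequence in its gene. Sister clusters are
SNP-diverged copies of one template with substitutions placed uniformly
*outside* consensus elements and NTIREs, matching the observation that
near-identical sisters keep their functional elements intact. Decoys are
partial motifs (a donor without downstream structure, or a branch+acceptor
without a donor) that stress candidate ranking. Template fillers are
random with a GC-content knob; spacers flanking branch elements are
pyrimidine-only, and a bounded re-draw guarantees the intended branch
element is the proximal one, so the generated truth tables are exact. All
randomness flows from a single seed; a fixed seed gives byte-identical
output.

The generator does **not** emulate realistic fungal genome composition,
codon usage, additional ordinary introns within the same gene, sequencing
error profiles beyond uniform substitutions, or RNA secondary-structure
energetics (no folding ΔG — thermodynamic prediction is out of scope
throughout). Passing the implant-and-recover and closure tests therefore
demonstrates the correctness of the grammar, arithmetic and
classification machinery under the stated statistical structure; it does
not by itself establish sensitivity or specificity on real assemblies,
where gene density, repeat content and decoy motif frequency differ.

Preset problem sizes used by the analysis scripts and tests: cohorts of
10–20 genes of 80–140 codons, 185-nt (Xylariaceae layout) and 190-nt
(Hypoxylaceae layout) templates over a 60-nt internal intron, read sets of
a few dozen 36–80-nt reads per locus, and a 10^4-model corpus for the
missplice arithmetic property. These keep every check well under a minute
or two while exercising each code path; all sizes are plain function
arguments.

## Degenerate inputs and edge behaviour

* Sequences containing `N` never match any motif class.
* `enumerate_introns()` requires `min_len >= 20`; below that the donor,
  branch and acceptor cannot coexist with a sane gap.
* `scan_ntire()` returns an empty list when the branch-to-acceptor region
  is shorter than the requested element — the situation of virtually all
  internal introns, which is why 3' NTIREs live in external introns.
* `bp_acceptor_layout()` refuses an element that does not fit the
  distance; with no element the total is the raw distance.
* `make_junction_queries()` names the deficient side when exonic context
  is too short; `emit_reads()` rejects read lengths below twice the
  overhang.
* An identity of exactly 0.97 is *not* near-identical (strict inequality),
  pinned by a boundary test.

## Known limitations

Only the [D1,2] stwintron class is detected; [A1,2]/[D2,3] and other
arrangements are out of scope, as are similarity-based genome mining,
gene-model prediction, spliced alignment, and ML phylogenetics. Reads with
indels are not classified. The pipeline's sole-intron flag reflects
detection within a record, not gene annotation. Identity values from the
built-in pairwise aligner can differ marginally from MSA-based values on
gapped pairs; the threshold semantics (SNP counting on near-identical
pairs) are unaffected.

## A worked example

```{r example, eval = FALSE}
tpl <- do.call(build_stwintron, c(stw_preset("xylariaceae"), list(seed = 7)))
gene <- paste0(strrep("A", 40), tpl$seq, strrep("C", 40))
m <- Filter(function(h) h$rank == 1, detect_stwintrons(gene))[[1]]
m
pair <- scan_ntire(m, threshold = 1)[[1]]
pair
bp_acceptor_layout(m$external, pair)
```

The analysis scripts under `analysis/` run this machinery end to end on
two simulated cohorts and write their tables under `results/`; see the
README for the sequence of steps and for how `scripts/acceptance.R`
recomputes the headline quantities.
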