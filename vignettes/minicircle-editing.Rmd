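---
title: "Calling and interpreting RNA editing in plastid minicircle genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and interpreting RNA editing in plastid minicircle genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minied)
```

## The problem

Peridinin dinoflagellates carry the most reduced plastid genomes known:
each remaining gene sits on its own small DNA minicircle (1.8–3.3 kb)
together with a conserved noncoding core. The transcripts of these genes
are heavily edited — at hundreds of positions the RNA base differs from the
genomic base (an RNA–DNA difference, RDD), across as many as nine of the
twelve possible substitution categories, including types unknown in plants
and animals. `minied` re-implements, as a tested pipeline, the analysis
such a study needs:

1. **Editing-site calling** from mapped RNA-seq and DNA-seq read pileups,
   with explicit artefact filters.
2. **Classification** of each site into one of the 12 ordered editing
   types "X/Y" (genomic X read as transcript Y, RNA side in U notation).
3. **Codon-level consequence annotation**, including joint evaluation of
   multiply edited codons and stop-codon restoration.
4. **Summary statistics** per gene (count table style) and in aggregate
   (type spectrum, transversion share, codon-position distribution, GC
   shift, homolog identity, molecular-weight and GRAVY hydropathy shifts,
   Spearman rank tests).
5. **Core-region feature scanning**: GC-rich inverted repeats, the
   conserved `CACCAATGCACC` RNA-binding motif (which contains a CCAAT-box),
   and TSS candidates from 5′-end count tracks.
6. A **planted-truth simulator** standing in for raw sequencing data, so
   every stage is testable offline.

## The calling model

A position is called an editing site when all of the following hold
(`calling_params()`):

* RNA depth ≥ `min_coverage` (default **11**, i.e. strictly "more than 10
  reads"). Organellar data easily exceed 300-fold coverage, so this is a
  floor against sparse artefacts, not a typical operating point.
* The dominant non-reference base reaches `min_edited_fraction` (default
  **0.5**) of the depth with at least `min_edited_reads` (default **3**)
  reads. The original manual-curation protocol states no fraction
  threshold; a majority rule is the conservative, reproducible proxy and is
  configurable for partial-editing studies.
* The position is not a genomic variant: any non-reference base supported
  by ≥ 2 DNA reads above `max_dna_alt_fraction` (default **1%**, matching
  the near-zero polymorphism of haploid organellar clones) disqualifies the
  position.
* Neither bias filter trips. The **strand test** is a two-sided Fisher
  exact test on ref/alt × forward/reverse counts, but it only fails a site
  when the p-value is below `strand_bias_p` (default 0.005) *and* every
  edited observation sits on a single strand while both strands carry
  coverage — a pure p-value rejection at organellar depths would discard
  legitimate sites on strand-skewed genes. The **position test** fails a
  site when ≥ `max_end_fraction` (default 0.9) of edited observations lie
  within `end_window_nt` (default 10 nt) of a read end, the classic
  misalignment signature. The original study applied these two criteria by
  manual inspection; the implemented tests are explicit, documented
  stand-ins, and both decisions are reported per site.

Multi-allelic positions (a second alternate base with ≥ `min_edited_reads`
and > 10% of depth) are withheld from calls and reported in a side channel,
because the per-site type classification is single-alternate.

## Codon annotation and counting conventions

All edits within one codon are applied **jointly**: a codon edited at
positions 1 and 2 is translated once with both substitutions (AUG → GCN,
Met → Ala), and each of its sites is then flagged against that joint
translation. Amino-acid substitutions are counted **per edited site**: a
doubly edited codon whose translation changes contributes each of its
non-synonymous sites. This is the only convention consistent with the
reference count table this package ships (e.g. 84 substitutions from 100
edits in the *psaA* row). Stop restoration is flagged where the reference
codon is a stop and the edited codon is not.

Genes with alternative start codons (UUG, AUA, UUU are observed in this
system) carry a `start_override`; translation renders the first residue as
methionine when the first codon equals the override, and the codon
assignments otherwise follow the bacterial/plastid code (table 11), the
natural choice for genes of cyanobacterial ancestry.

Percentages are rounded half-up — one decimal for frequencies, integers
for identities — matching the conventions of the published table the
fixture encodes. rRNA edits enter the type spectrum and totals but not
codon or protein statistics.

## Protein descriptors and rank tests

GRAVY is the mean Kyte–Doolittle hydropathy per residue (the documented
ProtParam default; the study does not state its scale, so Kyte–Doolittle is
assumed and fixed in a constants file). Molecular weight uses
ProtParam-compatible *average* residue masses plus one water. Pre-editing
premature stops are removed from the translation (not truncated at) before
computing descriptors, and flagged; this matches the full-length
substitution denominators of the reference table. `spearman_rank()` uses
average ranks for ties and the two-sided t approximation for its p-value.

Homolog identity uses global Needleman–Wunsch alignment with BLOSUM62, gap
open 10 / extend 0.5, identity = identical columns / alignment length. The
original method is unstated; these parameters are conventional, logged and
configurable in the sense that the alignment layer is a single function.

## The synthetic world

`simulation_config()` defaults *are* the stated conditions of the system
being emulated, chosen once:

* **Coverage 300×** for both RNA and DNA (the organellar "more than
  300-fold" regime), reads 100 nt, uniformly random start positions on the
  linearized minicircle, an even strand mix.
* **Gene**: 1200 nt CDS (mid-range for these genes) at 37% GC (plastid
  ORFs here are AT-rich; 36.94% pre-editing is the reference value).
* **Editing**: 24 edits (2% of the CDS, inside the observed 0.4–6.9%
  per-gene band), drawn from a 12-category spectrum whose default weights
  follow the observed plastid spectrum (A/G 55%, C/U and U/C 13% each,
  G/A ~7%, G/C ~8%, rare A/C, G/U, U/G, A/U; the three never-observed
  types at weight 0). `edited_fraction` defaults to 1 (complete editing);
  partial editing is supported though unquantified in the source system.
* **DNA polymorphism**: `n_snps` defaults to 0 ("0–0.01% SNP"); planted
  SNPs are carried by both DNA and RNA molecules at `snp_alt_fraction`
  (default 0.5), which is what makes them a calling hazard worth filtering.
* **Core region**: 17 GC-rich inverted repeats (inside the described
  15–20 band), arms 8–12 nt sampled GC-rich (≥ 75%), AT-rich loops and
  spacers; a promoter-like element just upstream of the TSS; a 1–41 nt
  variable spacer between the TSS and the single planted
  `CACCAATGCACC` motif (the described V-region length range); then the ORF.
* Edit placement excludes the start codon and any edit that would *create*
  a transcript stop, unless a stop-restoration scenario is explicitly
  requested.

Everything is deterministic given the config seed; independent operations
use decoupled substreams derived from it.

What the simulator does **not** model: indels, quality scores, duplicate
reads, poly(U) tails, library-prep artefacts, circular wrap-around reads
(the analysis targets linearized regions, so wrapped reads would be dead
weight), or mapping error. A green recovery test therefore establishes the
correctness of pileup accounting, filtering logic and coordinate handling —
not robustness to alignment pathology, which is out of scope along with
mapping itself.

## Numerical and design choices in the open

* **Coverage threshold** is strict: depth ≥ 11 means "more than 10 reads".
* **IR counting**: the scanner seeds exact `min_arm`-length matches,
  extends them maximally, and merges repeats sharing ≥ 50% of their span,
  keeping the longest arm — repeat *density* is a count of discrete
  elements. Because AT-rich sequence is intrinsically palindrome-prone
  (A pairs T), `annotate_minicircle()` counts repeats with arm GC ≥ 60%
  by default (`ir_min_gc`); `find_inverted_repeats()` itself reports all
  repeats unless asked to filter. Arm-length and loop defaults (≥ 8 nt,
  ≤ 60 nt) are chosen so the generator and scanner round-trip, and are
  configurable.
* **TSS rule** is strict: 5′-end count > 50, never ≥.
* **GC monotonicity**: with the realistic spectrum, editing *tends* to
  raise GC but single runs can lose a coin-flip (C/U and G/A edits lower
  it). The asserted invariant therefore uses an A/G-dominant spectrum
  restricted to GC-gaining/neutral types, for which monotonicity is
  structural rather than statistical.
* **Double substitutions** are reported as the share of mRNA edited sites
  lying in codons edited at both positions 1 and 2.
* Degenerate inputs: empty pileups yield empty call sets; empty alignments
  warn and produce empty outputs; constant vectors make the rank
  correlation an explicit error; a motif longer than its sequence is a
  no-hit, not an error.

## Known limitations

* The bias filters are reproducible stand-ins for a manual protocol; their
  thresholds are defensible but not derived from the source study.
* The per-type counts of the packaged table encode one published dataset;
  its 16S rRNA row stores only a row total because the published per-type
  digits are internally inconsistent (flagged in the TSV header).
* Identity percentages depend mildly on alignment parameters; only the
  shipped parameter set has been validated against constructed examples.
* No deduplication layer: the caller neither collapses duplicate reads nor
  needs to for simulator input; real libraries should be deduplicated
  upstream.
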