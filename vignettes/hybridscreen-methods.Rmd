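---
title: "Processing two-hybrid Sanger screens with hybridscreen"
author: "hybridscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing two-hybrid Sanger screens with hybridscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscreen)
```

## The problem

Yeast two-hybrid (Y2H) screens identify interaction partners of a bait
protein; the reverse variant (RY2H) applies negative selection to recover
interaction-defective alleles (IDAs) — mutants of a prey that no longer
bind the bait. Both end in Sanger sequencing of positive clones. The raw
sequencing products are awkward: they begin with low-quality base calls
(N), they contain vector sequence flanked by short translated tags (for
the pAD vector, `STHAS` at the 5′ end and `DPAFL` at the 3′ end), and
inserts longer than the ~500–800 bp Sanger range are sequenced from both
ends and must be assembled. For RY2H, the analysis additionally has to
align every reconstructed clone to the wild-type reference and collate the
substitutions that abrogated the interaction.

`hybridscreen` implements this pipeline: N-based quality trimming, vector
tag localization and trimming with a one-mismatch fallback, translation
with IUPAC-ambiguity handling, assembly of paired forward (`AD`) and
reverse (`TERM`) products by strict local alignment, local best-hit clone
identification, and per-residue mutation mapping against a reference
model.

## Quality trimming

Sanger reads often open with a stretch of poor signal. The rule is
deliberately simple: only the sequence *following the first N* is used,
and the read is truncated toward the 3′ end once the tolerated number of
Ns (`n_cutoff`, default 2, counted including the trimmed leading N) would
be exceeded. The output never starts or ends with N. An empty result
excludes the read with reason `"quality"`.

```{r}
qualityTrim("NACGTNAA")
```

A subtlety we fixed by convention: `n_cutoff` counts Ns globally, so the
default of 2 means "trim after the first N, truncate before the second".
Setting `n_cutoff = 1` cannot tolerate fewer Ns than that (the leading N
is always consumed by the 5′ rule) and therefore behaves like the default.

## Vector trimming

Tags are searched exactly first; only when a tag has no exact match
anywhere is the search repeated allowing up to one mismatch (Hamming
distance, at the amino-acid level for protein tags). The leftmost
qualifying hit wins, because the vector sequence precedes the insert in
both forward and reverse products. Protein tags are located by translating
all six strand/frame combinations (`locateProteinTag()`); if a tag occurs
in several frames the forward strand and lowest frame win with a warning.

`trimToOrf()` then discards everything outside the insert: for a 5′ tag
the retained sequence starts at tag end plus `distance_to_orf` (in
residues for protein tags, so 3 bases per residue); for a 3′ tag it ends
at tag start minus that distance, and leading remainder bases are dropped
so the result is in frame. The returned sequence is always in sense
orientation — this is where a reverse sequencing product gets
orientation-corrected. All user-facing coordinates in this package are
1-based inclusive, the R convention.

## Translation

Translation uses the universal genetic code by default; a bacterial code
is provided for bacterial two-hybrid material, where `GTG` and `TTG`
initiators are documented and recoded to methionine only at a declared ORF
start, never internally. Codons containing N translate to the unique amino
acid when all resolutions agree (`GTN` is valine) and to `X` otherwise;
`X` is treated as ambiguity downstream and never reported as a mutation.

The optional global reading-frame analysis (`findBestOrf()`) translates
every loaded sequence in all six frames and picks the combination with the
highest mean translated size. The size of one sequence is defined here as
its *longest stop-free stretch* — robust to sequencing errors near the
read ends; counting to the first stop would be dominated by early
miscalls. Ties break to the forward strand and lowest frame. The selection
is global across sequences because a library is cloned in one frame; a
per-sequence choice would let chance frames win on noisy reads.

## Assembly of forward and reverse products

After trimming, the forward and reverse sequences of a clone are aligned
with a strict Smith–Waterman regime and merged when the overlap is
credible. The defaults follow the screening convention: minimum overlap of
6 amino acids or 18 bp (the smallest complete-codon stretch expected to be
unique in the human genome) and at least 5 identical aligned columns. The
alignment must also sit where a true overlap sits: ending within 3
residues of the forward end and starting within 3 residues of the reverse
start. In accepted merges the forward read wins over the overlap, since 5′
Sanger quality is higher near the junction; any forward residues dangling
past the aligned span are dropped as likely end-of-read errors.

Status labels follow the screen convention and are carried into output
FASTA identifiers: `AD-TERM OVERLAPPED` (merge accepted),
`TERM NON-OVERLAPPED` (reverse product without matching forward sequence,
retained for model alignment), and `AD DISCARDED` (forward product without
usable reverse partner; no translation or overlap is attempted). Merging
defaults to the protein level; a DNA-level merge is available via
`OverlapParams(level = "dna")`.

## The two alignment regimes

The same affine-gap local alignment engine (compiled, Gotoh recurrences)
serves three stages under two scoring regimes:

* **overlap_strict** — identity matrix (match +1, mismatch −10), gap open
  −20, gap extend −10. Read overlap must be near-exact; the IUPAC variant
  of the matrix scores a match whenever the two symbols' ambiguity sets
  intersect, so N never breaks an overlap.
* **model_permissive** — BLOSUM62 with gap open −12, gap extend −8. Clone
  versus model (and clone versus database) must tolerate point mutations
  but reject indels, which would indicate frameshifts.

The exact penalty magnitudes are this package's declared defaults — the
regime (strict vs permissive substitutions, prohibitive gaps) is the
specified behaviour; all four numbers are arguments of `overlapScheme()`
and `modelScheme()`. When several cells attain the maximal score, the
traceback with the longest aligned span is returned ("the largest possible
alignment with the best score"); remaining ties break to the smallest
start on the first, then the second sequence, and within one traceback
diagonal moves are preferred over vertical over horizontal. A gap of
length $k$ costs $g_{open} + (k-1)\,g_{extend}$.

## Model alignment and mutation calling (RY2H)

Each translated clone — including non-overlapped C-terminal fragments —
is aligned to the model with the permissive regime. Clones are kept when
the score reaches

$$s_{\min} = 5 \times L \times 80\%$$

for a model of $L$ residues (`defaultModelScore()`); since the smallest
BLOSUM62 diagonal entry is 4 = 0.8 × 5, a clone identical to the model
always passes. The gate is implemented as ≥ for that reason; a strict `>`
is available (`strict_gt`). Mutation retrieval additionally requires the
clone (trailing stop stripped) to have *exactly* the model length: length
differences indicate frameshifts or premature termination and would
otherwise flood the report with false positives. Non-overlapped fragments
are therefore aligned and reported but can never contribute mutations —
consistent behaviour, not an accident.

Under the equal-length gate and gap-rejecting penalties the clone-model
correspondence is positional, so mutations are called by direct
position-wise comparison over the full length (this also recovers
substitutions in the terminal residues, which a local alignment may clip
when they score negatively). `X` is skipped. Summaries aggregate counts by
position and mutation nature; reports include a per-clone TSV, an
aggregated table, a 50-residue block text report and a per-position
total-count table for the heatmap view (`plotMutationHeatmap()` renders
it; any monotone colormap is adequate).

## Clone identification (Y2H)

The original workflow posted each translated clone to a remote BLAST
service. Network services are deliberately out of scope here:
`identifyClones()` performs a local best-hit search against a user-supplied
protein FASTA with identical downstream semantics — the best hit's
description is appended to the clone identifier, misses are reported as
such, and the output can be sorted alphabetically by hit so clones of the
same prey group together (stable sort, misses last). The "no hit" floor is
0.5 × 5 × query length by default and configurable; a remote backend could
be plugged in by replacing `bestHit()`.

## The simulator and what passing tests mean

`simulateScreen()` generates the screen the pipeline is validated on:
random substitutions of a model protein at `sub_rate` per residue (never
recreating the reference, never creating a stop, so the equal-length gate
stays satisfiable), back-translation with a fixed codon map, embedding in
a vector construct with the 5′/3′ tags and their ORF distances, forward
and reverse reads with a designed overlap, an optional low-quality leader
(junk bases and a leading N) and per-base miscalls. Identifiers follow the
`"cloneK AD"` / `"cloneK TERM"` convention; output is deterministic under
a seed.

Defaults mirror the full-length screen the tool targets: a 298-residue
(897-bp cDNA) model, 90 clones, 1% substitution rate, 600-nt reads, tags
`STHAS` (distance 6 residues) and `DPAFL` (distance 0). The end-to-end
test asserts *exact* recovery of the simulated mutation table at these
conditions, and a 189-read configuration (91 pairs, 4 unmatched forward, 3
unmatched reverse products) reproduces the composition such a screen
reports: 91 full-length proteins from 182 of 189 sequences, 7
non-overlapping of which 4 are unmatched forward fragments.

The simulator does not emulate chromatogram noise, realistic Sanger error
spectra, indels, chimeric clones, or scattered internal Ns. Passing tests
therefore demonstrate the correctness of the processing logic under the
stated read model, not robustness to every failure mode of real traces;
the `seq_error_rate` knob exists to probe sensitivity to miscalls. With
the default `n_cutoff = 2`, at most one leading N per read is generated
(`n_prefix_max = 1`), since a second N would truncate the read by the
quality rule.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere (R convention), including
  `LocalAlignment` spans and tag hits.
* The quality rule counts Ns globally (see above); boundary Ns remaining
  after truncation are stripped.
* The mismatch fallback for tags is all-or-nothing per read: an exact scan
  over all six frames precedes any mismatch scan.
* Degenerate inputs: empty trim results exclude the read (`"quality"`),
  missing tags exclude it (`"no-vector-tag"`); a clone whose reads are all
  excluded is dropped with a logged reason and counted, never silently
  lost.
* `assembleClone()` treats a pair whose reverse read fails trimming the
  same as a missing reverse read (`AD DISCARDED`), mirroring the rule that
  without a C-terminus neither translation nor overlap is attempted.
* Test and simulation problem sizes (15–91 clones, 60–298-residue models)
  are chosen as representative of a single RY2H screen.

## Known limitations

* Only N-based quality trimming; chromatogram (AB1) traces are not read.
* Two genetic codes (universal, bacterial); not the full NCBI catalogue.
* Pairwise assembly of exactly one forward and one reverse product; no
  multi-read contigs.
* Identification quality is bounded by the user-supplied database; there
  are no E-value statistics.
* 3D mapping of mutation positions onto structures is out of scope.
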