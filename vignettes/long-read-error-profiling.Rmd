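---
title: "Profiling errors in long sequencing reads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling errors in long sequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`lrprofile` characterizes the error structure of long sequencing reads
(Oxford Nanopore, PacBio) relative to a reference genome. It does not
align reads and it does not correct them: it consumes alignments (SAM
with CIGAR, and MD tags where available), decomposes them into per-column
edit scripts, and summarizes the error structure at three levels —
per-type rates and match-length statistics for a read set, error rates
along read coordinates, and k-mer representation relative to the
reference. A seeded simulator generates reads under a configurable error
model together with *exact* truth alignments, which is what makes the
whole pipeline testable without external data.

# The edit-script model

Every mapped SAM record is expanded into an ordered list of alignment
columns, each classified as exactly one of

* **match** — read base equals reference base,
* **sub** — aligned but different bases,
* **ins** — a read base with no reference counterpart (counted per base,
  not per event),
* **del** — a reference base with no read counterpart,
* **ambiguous** — a column touching an `N` on either side.

M segments are split into match/sub using the MD tag, or by base
comparison when a reference is supplied; `=`/`X` operators are accepted
as pre-split. When both MD and a reference are available they are
cross-validated and any disagreement is an error, not a silent choice.
Ambiguous columns are excluded from both the match and the error tallies;
the underlying aligner behavior for `N` is not standardized, and counting
such columns as substitutions would inflate rates on references with
masked regions.

Coordinates: reference positions are 0-based half-open internally and
1-based in every report; read positions are 1-based **in the original
read orientation**, i.e. for a reverse-strand alignment the stored
position $s$ maps to $L - s + 1$ where $L$ is the full read length
including hard clips. This is the convention a 5′-end analysis needs:
the noisy end of a nanopore read is a property of the molecule, not of
the reference strand it happened to map to.

# Read-set error profile

Per-type rates are **pooled**: e.g.
$\mathrm{sub\,\%} = 100 \cdot \sum_r n^{(r)}_{\mathrm{sub}} / \sum_r n^{(r)}_{\mathrm{col}}$,
with the denominator the total number of alignment columns. Pooling (as
opposed to averaging per-read rates) is robust to the heavy-tailed read
length distribution of long-read data, and makes the three error shares
add up to the total error rate by construction. `longest_perfect_match`
is the longest run of consecutive match columns anywhere in the set
(runs are broken by any non-match column, including ambiguous);
`longest_alignment` is the largest reference span, and the stretch
statistic reports by how much that alignment's reference span exceeds
its aligned read span.

The substitution matrix accumulates (reference base → read base) counts
over match and sub columns, in reference-forward orientation exactly as
the stored SAM sequence reads. Conditional rates are row-normalized;
transition (A↔G, C↔T) and transversion rates are fractions of all
aligned columns, and the transition *share* is the fraction of
substitutions only.

# Positional profile

Error rates along reads are computed in sliding windows (defaults:
1000 bp windows, 500 bp step, positions 1–7500, reads ≥ 7500 bp — 14
windows). Each column is assigned a read position; a deletion column has
none, so it borrows the position of the next non-deletion column *in
original read orientation* (the previous one for terminal deletions).
Taking the neighbor in original orientation rather than in SAM record
order keeps the profile exactly strand-invariant, which the test suite
asserts. The per-window rate of a read is `columns of that type / all
columns assigned to the window`, in percent; the read set summary is the
mean and the sample standard deviation ($n-1$) of per-read rates — the
error bars describe read-to-read spread, so windows are summarized
per-read-then-averaged, not pooled.

# K-mer representation

K-mers (default $k=6$, matching the ~6 nt sensing window of the R9.4
nanopore) are counted on both strands; circular references additionally
count the $k-1$ junction-bridging k-mers, so a circular reference of
length $G$ yields exactly $2G$ k-mers — an identity the tests exploit.
Reads are counted as linear sequences, also on both strands, which makes
the representation difference strand-invariant (whether the original
study counted reads single- or double-stranded is not documented; the
symmetric choice is the one that does not depend on library strand
balance).

The representation difference is **relative**:
$\mathrm{diff} = (f_{\mathrm{reads}} - f_{\mathrm{ref}}) / f_{\mathrm{ref}}$
with $f$ = count/total. The magnitudes reported for real data (a few
times $10^{-2}$ for the most distorted 6-mers) are only consistent with
this relative scale, not with absolute frequency differences. The
outlier band is $3\sigma$ where $\sigma$ is the sample standard
deviation of diff over k-mers present in the reference (k-mers absent
from the reference have undefined diff and are reported but never
flagged). Ranked over/under-represented lists break ties
lexicographically and can exclude homopolymers before truncation, which
is also how the logo (position frequency matrix) input is formed.

# The simulator and its calibration

The generator draws, for each reference position walked in original read
orientation: a deletion, otherwise an emitted base that is substituted
with a replacement drawn from the row of a zero-diagonal preference
matrix; and, before each position, an insertion event with geometric
length (extension parameter 0.25, mean event length 1.33 — long-read
insertions are predominantly single-base). **Calibration:** the
configured `p_sub`, `p_ins`, `p_del` are expected *column fractions* —
the same quantities the profiling side reports — and the event
probabilities are solved from them ($\lambda = p_{ins}/(1-p_{ins})$
inserted bases per position, $d = p_{del}(1+\lambda)$, etc.). This makes
parameter-recovery tests meaningful at tight tolerances (±0.1
percentage points over ≥4 Mbp) rather than only up to an uncontrolled
model-dependent offset.

Presets follow published cross-aligner averages for raw reads:
ONT-like 4.33/3.69/4.54 % (sub/ins/del) with 70 % of substitution mass
on the transition partner, PacBio-like 1.68/8.04/3.16 % with 40 % on the
favored transversion partner (A↔C, G↔T). The 70/40 weights are free
parameters — published data show the qualitative ranking, not a
numerical matrix — chosen once so that the transition share is sharply
recoverable for the ONT preset while the PacBio preference stays
"slight".

Other stated-world choices, fixed once:

* **Read lengths** are truncated lognormal; defaults give mean ≈10.5 kbp
  (ONT, max 140 kbp) and ≈8.9 kbp (PacBio, max 45 kbp), echoing the
  scale of real raw-read censuses. The drawn length is the reference
  span; the emitted read differs by the net indel balance (<1 %).
* **5′ noise**: all error rates are multiplied by `multiplier` for the
  first `n5` (default 1000) *emitted* read bases, counted in original
  orientation; an insertion event initiated before the boundary keeps
  the multiplier for its whole length. Because the boundary is defined
  on emitted bases, the noisy region is exactly read positions
  1–`n5`, and the first-window/plateau ratio converges to the
  multiplier itself.
* **Homopolymers**: reference runs of ≥ `min_run` (default 4) identical
  bases are perturbed by ±1 base with probabilities
  `p_expand`/`p_contract` (expansion inserts the run base adjacent to
  the run end; contraction deletes the last not-already-deleted run
  base). This is a deliberately minimal model — no quantitative run
  length error distribution is available to fit — but it reproduces the
  qualitative signature: with expansion bias on an AT-rich genome,
  polyA/polyT 6-mers become positive 3σ outliers, and disabling the
  model removes the flags.
* **Qualities** are constant placeholders; no part of the analysis uses
  them.
* The truth CIGAR uses `M`/`I`/`D` only (match and sub merged into `M`,
  detail carried by MD), insertions sit before the position they precede
  and runs are normalized left-to-right, so the truth alignment is in
  canonical SAM form and `expand_edit_script()` must reproduce the truth
  column list *exactly* — the oracle chain that anchors the test suite.

What the simulator does **not** emulate: chimeras and adapters, quality
score structure, signal-level artifacts, GC-dependent accuracy, and
correlated error bursts beyond homopolymer runs. A green test therefore
establishes the correctness of the bookkeeping (parsing, expansion,
aggregation, windowing, counting) and the self-consistency of the
model — not that the model is a complete portrait of any instrument.

# Numerical and interface choices

* Downsampling to a target coverage permutes reads with a seeded RNG and
  takes them until the cumulative bases cross `coverage × genome_length`
  (the crossing read included). This is deterministic and hits the
  target exactly up to one read — byte-compatibility with external
  Bernoulli samplers was deliberately not pursued.
* The read length filter is strict (`> min_len`, default 200 bp).
* Reports round percentages to 2 decimals; JSON bundles keep raw counts
  so downstream arithmetic is lossless.
* Degenerate inputs are defined, not fatal: an empty SAM body yields an
  empty profile with a warning; fewer than 2 reads in the window module
  reports means with `NA` standard deviations; ranked lists longer than
  the table warn and return everything.
* Errors are classed conditions; the CLI maps usage errors to exit 1 and
  input format/validation errors to exit 2.

# Known limitations

Dense k-mer tables limit $k \le 12$. SAM is read as text (no BAM/CRAM,
no random access). Insertion counts are inserted bases, not events, so
they are not directly comparable to event-level tools. The per-aligner
harness of a full benchmark study (running blasr/graphmap/last/minimap2,
or the correction tools themselves) is out of scope: patched or
corrected read sets enter the comparison simply as additional inputs to
`lrprofile profile` / `lrprofile compare`.
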