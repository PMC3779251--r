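---
title: "Designing organism-specific rRNA depletion probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing organism-specific rRNA depletion probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ribosomal RNA makes up more than 90% of prokaryotic total RNA, so RNA-seq
libraries built from total RNA spend almost all of their reads on rRNA.
Probe-based subtractive hybridization removes rRNA before sequencing:
biotinylated probes complementary to the 16S and 23S genes capture the rRNA
onto streptavidin beads. Universal probes targeting conserved rRNA regions,
however, also pull down organism-specific mRNAs that happen to resemble
them, and the extent of that off-target loss differs between organisms.

`riboprobe` designs *organism-specific* capture probes: candidate windows
are drawn from the organism's own rRNA genes and kept only if they have no
qualifying similarity to any other transcript of the same organism. A probe
selected this way can bind its rRNA target at full complementarity while
having no near-complement among the mRNAs it must not deplete.

## The design pipeline

For a genome with an annotation supplying `CDS` and `rRNA` features:

1. **Extract** (`collect_sets()`): the target rRNA genes and the subject
   set — every coding sequence — are sliced out of the genome,
   strand-correctly (minus-strand features are reverse-complemented).
   Target genes are excluded from the subject set by construction.
2. **Fragment** (`fragment_sequences()`): each target is cut into
   overlapping windows of `window` nucleotides every `leap` nucleotides,
   giving `floor((L - window)/leap) + 1` uniform-length candidates. No
   shorter tail window is emitted: capture probes must all have the full
   length, and a right-anchored tail would duplicate an existing window's
   3' content.
3. **Screen** (`align_fragments()` + `tally_hits()`): every window is
   locally aligned against both strands of every subject; a hit *qualifies*
   when all three filters pass — E-value strictly below `max_evalue`,
   identity over aligned columns at least `min_identity_pct`, and alignment
   length at least `min_hitlen_pct` of the window.
4. **Structure screen** (`screen_hairpins()`): windows are scanned for
   inverted repeats able to fold into hairpins that would compete with
   probe-target hybridization.
5. **Select** (`select_probes()`): windows are ranked by ascending
   qualifying-hit count; hairpin-free windows outrank flagged ones at equal
   tally, and remaining ties break on `(parent, offset)`. The top `k`
   windows per target become the probes.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `window` | 100 | nt | capture-probe length; long enough for stable hybrids, short enough to tile the gene densely |
| `leap` | 5 | nt | window start spacing; 5 nt gives 20x coverage of each position without an excessive candidate count |
| `max_evalue` | 1 | — | chance-similarity cutoff, strict `<` |
| `min_identity_pct` | 90 | % | identity over aligned columns |
| `min_hitlen_pct` | 90 | % of window | coverage requirement; with identity this defines a "qualifying" off-target |
| `min_stem` / `min_loop` | 6 / 3 | nt | smallest inverted repeat flagged as a hairpin |
| `k` | 5 | probes | probes per target gene |

The two 90% thresholds are deliberately interpreted as *identity over
aligned columns* and *alignment length relative to the query window*. For
near-full-length hits the distinction from identities-over-query-length
vanishes; for short high-identity hits the coverage filter is what keeps
them from counting, which is the behaviour a probe designer wants — a
20-nt perfect match cannot capture an mRNA on its own.

## The alignment backend

The screen is a nucleotide local-alignment search, implemented in compiled
code with affine gaps (match +1, mismatch −2, gap open 5, gap extend 2).
Two modes share the same scoring engine:

* `seed_extend` (default): only fragment/subject/strand pairs sharing at
  least one exact 11-mer are aligned in full. A hit passing 90% identity
  over ≥90 nt virtually always contains an exact 11-mer run, so the seed
  gate discards only pairs that could not qualify anyway.
* `exhaustive`: full Smith–Waterman on every pair. This is the oracle the
  seeded mode is tested against (their qualifying tallies must be
  identical on seeded fixtures).

Within an aligned pair, further high-scoring segment pairs are recovered by
masking the reported subject interval and re-aligning, so duplicated
homology at two loci of one subject counts twice (HSP counting, matching
how a BLAST report would be tallied). Both subject strands are always
searched: annotated CDS are sense-strand, but probes hybridize by
complementarity.

E-values use the ungapped Karlin–Altschul form `E = K·m·n·exp(−λS)` with
λ = 1.28, K = 0.46 (the standard values for the +1/−2 scheme), `m` the
window length and `n` the total subject length. The E-value filter is very
insensitive to these constants here: any hit reaching the 90%/90%
thresholds on a 100-nt window scores S ≥ 63, i.e. E below 10⁻²⁰ for any
realistic database size, while the filter's bound is 1. Exact parity with a
particular aligner's gapped statistics is therefore unnecessary for the
internal backend; when it matters, pre-computed hits in 12-column tabular
format can be supplied (`hits_file =` / `parse_tabular_hits()`) and the
rest of the pipeline is unchanged.

The reporting floor is derived from an E-value cap of 10 (scores below it
are never close to qualifying), and alignments are reported per
fragment/subject/strand up to 16 HSPs.

## Hairpin screening semantics

A hairpin match is a stem of `stem_len` Watson–Crick pairs between an arm
at `arm1_start` and the reverse complement of an arm at `arm2_start`,
separated by a loop (`arm1_start + stem_len + loop_len = arm2_start`). The
finder enumerates *maximal* stems: a match is reported only if it cannot be
extended outward or inward within the mismatch budget.

One subtlety is deliberate: maximality ignores the loop floor. A stem is
extended inward as long as its innermost flanking bases pair, even if that
would shrink the loop below `min_loop`; `min_loop` then filters which
maximal stems are reported. The alternative — stopping inward extension at
the loop floor — would make the reported set non-monotone in `min_loop`
(raising the floor could *create* matches), which breaks the natural
expectation that stricter parameters only remove structures. The
consequence is that a stem whose maximal form has a very tight loop is
treated as that tight-loop structure (and not reported), rather than as a
trimmed version with a compliant loop.

G·T (G·U) wobble pairs are excluded by default — DNA probe chemistry —
and can be enabled with `allow_gu = TRUE` for RNA probes. Flagged probes
are demoted, not excluded, during selection (`exclude_hairpins = TRUE`
makes exclusion strict): a mild hairpin in an otherwise unique window may
still be preferable to a cross-hybridizing one.

Defaults (stem ≥ 6 bp, loop ≥ 3 nt, no mismatches) flag structures stable
near hybridization temperatures. In GC-rich genomes a 6-bp stem inside a
100-nt window is common, so with these defaults the flag mainly acts as a
tie-breaker between zero-hit windows.

## Selection

`spacing = "none"` reproduces a pure minimal-hit sort. `spacing = "greedy"`
additionally spreads the chosen probes along the gene: candidates are
consumed stratum by stratum (tally, then hairpin flag — a worse stratum is
never entered while a better one has candidates), and within a stratum each
pick maximizes its minimum distance to the probes already chosen on that
parent. Spread probes capture both full-length rRNA and its degradation
fragments; the default remains `"none"` because minimal-hit ranking is the
method's defining rule and spacing is an optional refinement.

All tie-breaks are total (offset, then lexicographic ids), so the whole
pipeline is a deterministic function of its inputs — reruns are
byte-identical.

## The simulator and what it does (not) show

`simulate_genome()` builds the test bed for everything above: random CDS,
two identical copies of an rRNA gene at distinct loci (mimicking
paralogous operons), random intergenic spacers, and optional *plants* —
rRNA windows copied into a chosen CDS with substitutions at per-base rate
`1 − identity`. Substitution-only mutation keeps expected identity
analytic. The per-window truth table distinguishes windows fully covered
by a high-identity plant (must hit: an alignment over ≥90% of the window
at ≥90% identity is forced), windows not touching any plant (must not hit:
a few hundred bases of random sequence cannot reach 90%/90 by chance), and
partially overlapping windows (ambiguous — a window sharing, say, 50 nt
with a plant cannot achieve 90% coverage and is not a guaranteed hit, so
no claim is made).

Defaults are a deliberately scaled-down bacterial layout: 20 CDS of
300–900 nt, a 1500-nt rRNA in two copies, GC 0.67 (an actinobacterial,
*Mycobacterium*-like composition). These sizes keep a full pipeline run in
seconds while exercising every code path; the real use case (thousands of
CDS, a 3-kb 23S gene) differs only in scale, not in behaviour. What the
simulator does **not** model: codon structure and real coding composition,
slightly diverged (rather than identical) rRNA operon copies, indels in
off-target homology, and multi-contig assemblies. Passing tests on
fixtures therefore demonstrate the pipeline's correctness and its
detection thresholds, not the biological uniqueness of any real probe —
that claim always requires running on the organism's actual genome.

At the 95%-expected-identity boundary the recovery guarantee is
stochastic: a 100-nt plant draws Binomial(100, 0.05) substitutions, and
local alignment may trim mismatch-dense ends, so the probability that a
fully covered window fails the 90%/90 filter is well below 1% and not
observed across the seeds exercised in the tests.

## Degenerate inputs and numerical choices

* Multi-record genome files, compound (`join`) feature locations and
  origin-spanning features are rejected with explicit errors; coordinate
  conventions are 1-based inclusive at every file boundary, 0-based
  offsets internally (fragment offsets).
* Residues outside `A/C/G/T/N` are an error in strict mode, mapped to `N`
  otherwise; `N` never matches and never pairs.
* Targets shorter than the window are an error, not silently skipped.
* The E-value comparison is strict (`<`), the two percentage filters are
  inclusive (`≥`).
* Best-hit ties break by bit score, then subject id; hairpin output is
  ordered by arm positions, then stem length.

## Validation arithmetic

`fold_change()` implements the comparative-Ct estimate
`2^(−ΔΔCt)` used to quantify depletion by qPCR, with
`ΔΔCt = (Ct_target,treated − Ct_ref,treated) − (Ct_target,control −
Ct_ref,control)`; `ddct_fold_changes()` applies it to a tidy Ct table,
averaging technical replicates first and using the plain form without
amplification-efficiency correction. It is invariant to uniform Ct shifts
and inverts under role swapping.

## Known limitations

* No thermodynamic folding model: the hairpin screen is combinatorial
  (stem/loop geometry), not a free-energy minimizer, and probe–probe
  cross-dimers are not screened.
* The internal aligner's gapped statistics are approximate (ungapped
  Karlin–Altschul constants); use the tabular-hit path for exact parity
  with an external search engine.
* Single-replicon genomes only; translated (protein-level) similarity is
  out of scope.
* Melting-temperature balancing across the probe set is not attempted.
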