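# riboprobe

Organism-specific rRNA depletion probe design for prokaryotic RNA-seq.

Ribosomal RNA is >90% of bacterial total RNA, so rRNA must be removed
before sequencing — usually by hybridization capture with biotinylated
probes. Universal probes built from conserved rRNA regions also capture
organism-specific mRNAs that resemble them. `riboprobe` designs probes the
other way around: it takes the organism's **own** 16S/23S genes, slides a
fixed window along them, screens every window by local alignment against
**all coding sequences of the same genome**, and keeps the windows with the
smallest number of *qualifying* off-target hits. A hit qualifies when

* E-value < 1 (Karlin–Altschul, `E = K·m·n·e^{−λS}`),
* identity ≥ 90% over aligned columns, and
* alignment length ≥ 90% of the window.

With the default 100-nt window and 5-nt leap, a target of length *L*
yields `⌊(L − 100)/5⌋ + 1` candidates. Candidates are also screened for
self-annealing hairpins (inverted repeats with stem ≥ 6 bp, loop ≥ 3 nt),
which demote but do not exclude a window. Selection is a deterministic
minimal-hit sort with optional greedy spacing so probes tile the gene.

The package is written tidyverse-style: tabular inputs and outputs
(tibbles), a `probe_design` result with `tidy()`, `glance()`, `print()`
and `autoplot()` methods, and a deterministic synthetic-genome simulator
(`simulate_genome()`) with planted homology for validation. A
comparative-Ct calculator (`fold_change()`, 2^−ΔΔCt) covers the qPCR
arithmetic used to validate depletion experimentally.

## Worked example

Design probes for a simulated bacterial genome that carries two identical
rRNA operon copies among 20 CDS, one of which contains an exact copy of an
rRNA window (an engineered off-target):

```r
library(riboprobe)

sim <- simulate_genome(seed = 42,
                       plants = data.frame(window_offset = 300,
                                           identity = 1, host_cds = 7))
design <- run_design(genome = sim$genome, annotation = sim$annotations, k = 3)
design
#> <probe_design>
#>   targets: 2 gene(s), 562 candidate window(s) of 100 nt (leap 5)
#>   subjects: 20 transcript(s), 11765 nt screened (backend seed_extend)
#>   zero-hit windows: 552/562; selected probes: 6 (max tally 0)

tidy(design)[, c("fragment_id", "offset", "qualifying_hits", "rank")]
#> # A tibble: 6 × 4
#>   fragment_id   offset qualifying_hits  rank
#> 1 RRNA_0001:315    315               0     1
#> 2 RRNA_0001:410    410               0     2
#> 3 RRNA_0001:415    415               0     3
#> 4 RRNA_0002:315    315               0     1
#> 5 RRNA_0002:410    410               0     2
#> 6 RRNA_0002:415    415               0     3
```

562 windows were fragmented from the two rRNA copies; 10 windows — those
sharing ≥ 90 nt with the planted copy — picked up qualifying hits and were
avoided; the 6 selected probes (3 per operon copy) all have **0
qualifying hits**, the property that makes them safe capture probes.
`autoplot(design)` draws the per-window hit profile with the selected
probes marked. Real genomes work the same way from files:

```r
run_design(genome = "genome.fasta", annotation = "annotation.gff3",
           targets = "kind:rRNA", k = 5, out_dir = "probes_out")
# or a single GenBank file carrying sequence + features:
run_design(genome = "genome.gbk", k = 5)
```

writing `probes.fasta`, ranked TSV reports, a JSON summary and a run log.
Pre-computed 12-column tabular alignment hits can replace the internal
aligner via `hits_file =`. The nine previously validated *M. smegmatis*
probes ship with the package (`msmeg_probes()`), and the qPCR side is one
call:

```r
fold_change(22, 18, 20, 18)   # two extra target cycles after depletion
#> [1] 0.25
```

A thin command-line front end (`inst/scripts/riboprobe.R`) exposes
`design`, `simulate` and `ddct` subcommands over the same functions.

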