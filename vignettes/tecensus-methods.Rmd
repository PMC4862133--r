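---
title: "Counting collapsed repeats: the tecensus models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting collapsed repeats: the tecensus models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecensus)
```

# The census and its bias

`tecensus` estimates how much of a genome assembly is transposable-element
sequence, and how much of the *genome's* TE content the assembly actually
missed. The second question exists because assemblers collapse
near-identical repeat copies: a family that transposed recently has copies
so similar that short reads cannot separate them, and the assembly graph
resolves them into one consensus locus. The annotation of such an assembly
is correct about *where* TEs are but wrong about *how much* TE there is.

The correction rests on one observation: reads do not disappear when copies
collapse. Mapping the sequencing reads back to the assembly, the reads of
all `n` true copies stack onto the `m` assembled ones. If `C̄` is the mean
depth over single-copy sequence, the depth over a collapsed copy is
`C̄ × (copies absorbed)`, so

$$\mathrm{corrected\ bp} \;=\; \frac{\sum_{p \in \mathrm{TE}} d(p)}{\bar C},
\qquad \mathrm{factor} \;=\; \frac{\mathrm{corrected\ bp}}{\mathrm{annotated\ bp}},$$

where $d(p)$ is the aligned read-base depth at annotated position $p$. The
estimate needs no knowledge of where the missing copies are — which is also
its main limitation: the extra mass is attributed to gaps or unassembled
sequence without placement.

Two conventions for the resulting genome fraction are supported, because
the extra mass can be accounted to the existing assembly span (the `"gaps"`
variant, `corrected / assembly_size`) or added to it (the `"inflate"`
variant, `corrected / (assembly_size + delta)`). Both are reported by
`genome_fraction()`; they bracket the truth.

## Reference coverage

$\bar C$ comes from one of two sources, both first-class:

* `mean_feature_coverage()` — the length-weighted mean depth over gene
  intervals. Genes are essentially single-copy, so their depth estimates
  the true per-copy coverage; this is the preferred route when a gene set
  exists.
* `reference_coverage()` — an external scalar (an assembler's own coverage
  estimate, or the sequencing design), for assemblies without a usable
  annotation.

The correction is invariant to a joint rescaling of all depths and $\bar
C$ (tested), so systematic mapping-rate effects cancel as long as they hit
genes and TEs alike. What does *not* cancel is mapping policy: depth counts
all primary mapped alignments and keeps multi-mapped placements (MAPQ
filter defaulting to 0), because reads from collapsed copies are exactly
the multi-mapping reads — filtering them by mapping quality would delete
the signal being measured. Duplicates are not removed. Deletions in an
alignment contribute no read base; insertions and clips contribute nothing.

# Annotation input and overlap policy

`parse_repeatmasker_out()` reads the standard 15-column `.out` report,
applies a Smith–Waterman score cutoff (default 250, the cutoff used when
masking with a curated library), drops simple/low-complexity/satellite/RNA
classes, and converts the 1-based inclusive coordinates to the package's
internal convention, 0-based half-open, at the boundary. All interval
arithmetic downstream is half-open; coordinates only revert to 1-based in
the `.out` writer.

RepeatMasker hits can overlap, and the masker's own `*` flag marks hits
overlapped by better ones. Rather than trusting that flag, the parser keeps
every record and `resolve_overlaps()` applies the policy explicitly:

* `"score"` (default): every base belongs to the highest-scoring hit
  covering it; ties break by earlier start, then lexicographic family
  name. The output intervals are pairwise disjoint (tested against a
  per-base brute-force oracle), so category masses never double-count.
* `"union"`: per-family interval union — a sensitivity variant for asking
  how much the resolution policy matters, since published pipelines rarely
  state theirs.

Family names map to (order, superfamily) through an editable TSV taxonomy
(`default_taxonomy()`), with the RepeatMasker `class/family` string as
fallback; names that resolve nowhere become `Unknown/Unknown` and are
counted, not dropped. The non-core classes (SINE, DIRS, Penelope, Crypton)
route to an `Others` order; this membership is a package decision, since
the category is conventionally a catch-all.

# Windowed chromosomal densities

`make_windows()` lays consecutive 50-kb half-open windows over chromosomes
defined by a scaffold map (ordered, oriented scaffolds abutted without gap
padding — maps rarely state inter-scaffold gap sizes, and padding would
only dilute densities). The final sub-width window exists only in plotting
mode; all statistics use whole windows, so means are comparable across
chromosomes.

Chromosome coordinates run telomere → centromere. `partition_regions()`
therefore takes the *highest* coordinates — the default 3 Mb nearest the
centromere — as the proximal region of each major chromosome, and treats
the dot chromosome as one region of its own, since it is recombination-poor
and TE-dense along its whole length. In pooled summary rows the dot
chromosome is grouped with the proximal windows (both are the
low-recombination compartment); per-chromosome rows keep it separate. A
chromosome shorter than the span is entirely proximal, with a warning.

Distributional differences between regions use the two-sample
Kolmogorov–Smirnov test (`ks_compare()`, `stats::ks.test` underneath; the D
statistic is verified against a pooled-support ECDF-gap oracle). P-values
are reported raw — the convention for this comparison — with Holm
adjustment as an extra column in `ks_matrix()`.

# Technology comparison

`group_means()` and `mann_whitney()` compare TE fractions of assemblies
grouped by sequencing technology. The rank-sum test uses the exact null
distribution whenever both groups have ≤ 25 observations and the pooled
values are tie-free — for the bundled 12-vs-15 survey this is the exact
two-sided p = 0.001421 — and otherwise the normal approximation with
continuity correction; the variant used is recorded in the output. The
records are not phylogenetically independent, so the within-subgroup
pairing (`paired_subgroups()`) is deliberately descriptive: no test is
attached to it.

`nx_stats()` implements the cumulative-fraction definition: sort scaffold
lengths descending; the Nx index is the rank of the first scaffold at which
the running total reaches x % of the assembly, the Nx length that
scaffold's length. N50/N90 monotonicity is property-tested on random
length lists. The N50/N90 of the real assemblies discussed alongside the
bundled survey require the assemblies themselves and are out of desk-scale
scope, as are the real genomes' per-window density tables: the windowed
analysis is validated on synthetic landscapes instead.

# The synthetic worlds

Two generators make every stage testable offline.

**`build_world()`** is the sequence-level collapse model. From a seed it
builds: a true genome (default 5 × 200 kb) with all `n` copies of each
family placed without overlap, each copy mutated from the family consensus
by substitutions at rate `1 − identity`; a collapsed assembly with the last
`n − m` copies of each family excised and their reads absorbed round-robin
by the `m` survivors; annotations describing only the collapsed assembly
(what an annotator would see); and TE-free gene intervals present
identically in both genomes. Substitution-only divergence is deliberate:
it keeps `true_bp = n × unit_len` exact, so the recovery test can demand
exact equality rather than a tolerance. Indels, nested insertions,
fragmented copies and read errors are not modeled — passing tests show the
correction arithmetic is right, not that real mapping pipelines are
unbiased. The default six families (LTR/Gypsy and Copia, LINE/Jockey and
R2, TIR/hAT, Helitron) total 111.4 kb of true TE in a 1-Mb genome (~11 %,
a realistic mobile fraction), with collapse factors from 1 (no collapse)
to 4.

**`simulate_alignments()`** realizes depth at mean coverage C (default
50x): in `"noiseless"` mode reads tile each scaffold exactly C deep and
each survivor gets `(multiplicity − 1) × C` extra tiled reads, so expected
depth is realized exactly; in `"poisson"` mode read counts are Poisson and
starts uniform. Extra-copy reads start inside the survivor's interval, so
per-category read mass is exact in expectation even though depth ramps at
copy edges — the correction only consumes aggregate mass, so the ramps are
irrelevant. SAM and depth-TSV emissions are generated from the same read
set under the same derived seed and agree base-by-base (tested), which
exercises the BAM path without making it load-bearing.

**`simulate_te_landscape()`** is the chromosome-scale companion for the
window analysis, which needs no sequence: annotations are dropped into
2-kb slots with binomial bp counts at region-dependent rates — 5 %
background, 16 % in the proximal 3 Mb, 41 % on the dot chromosome,
mirroring the pericentromeric accumulation and dot saturation measured in
repleta-group genomes. The default map (`repleta_like_map()`) has five
23–27 Mb chromosomes split into 2–3 scaffolds plus a 1.5-Mb dot, the scale
of a mapped N90 scaffold set; ~2 500 full windows compute in about a
second.

# Numerical choices and degenerate inputs

* Score ties in overlap resolution break by start then family name, making
  resolution order-independent and reproducible.
* `category_totals()` always emits all seven orders (zero-filled), and
  reports shares as 0 rather than undefined on an empty annotation set.
* A zero reference coverage refuses to divide; a category with read mass
  but no annotation reports corrected mass with an undefined factor.
* Published-table kb values are reported rounded to 2 decimals (the
  table's own precision); factors to 2 decimals; all internal arithmetic
  is unrounded.
* Degenerate rank-sum input (all values identical) short-circuits to
  p = 1 with a warning instead of erroring.
* Windows of a chromosome shorter than one width vanish in statistics
  mode; the empty chromosome map yields an empty window set.

# Problem sizes

The suite's study conditions are: the 1-Mb default collapse world (exact
and Poisson recovery, the Poisson bound being ≤ 5 % relative error per
category of ≥ 10 kb at C = 50), the ~126-Mb annotation-only landscape
(~2 500 full 50-kb windows), and 200-case randomized oracle comparisons
per operation (per-base overlap assignment, per-base window intersection,
ECDF-gap KS D, full-enumeration exact Mann–Whitney at n ≤ 5 per group).
The full test suite runs in about a minute.

# Known limitations

* The correction redistributes no sequence: it says how much is missing
  per category, never where it belongs.
* It inherits the annotation's blind spots — families absent from the
  library are invisible before and after correction.
* A biased reference coverage (e.g. genes in unusually accessible
  chromatin for the library preparation) scales every corrected value.
* The synthetic worlds validate arithmetic, not mapping behavior: real
  multi-mapping, paired-end placement and error models are out of scope.
* The technology comparison treats assemblies as independent samples; the
  shared phylogeny of the surveyed species is acknowledged but not
  modeled.
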