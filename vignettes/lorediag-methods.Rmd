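---
title: "lorediag: models and methods"
author: "lorediag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lorediag: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lorediag)
```

# Scope

`lorediag` implements the interpretive layers that sit on top of aligned
clinical long-read genome sequencing data for rare neurological disease
diagnostics: short tandem repeat (STR) expansion profiling with
interruption motifs and promoter methylation, imprinted-region
methylation screening against a control pool, read-backed phasing of
compound-heterozygous variants, paralog (SMN1/SMN2-style) copy-number
resolution, derivative-chromosome reconstruction from split-read
junctions with mosaic-fraction estimation, and gene-panel triage with
cohort findings aggregation. Alignment, basecalling and small-variant
calling are upstream of this package and out of scope.

Because patient-level long-read datasets are access-restricted, every
analysis stage is exercised against synthetic aligned reads with planted
ground truth. The simulator is a first-class, tested module, not a test
fixture: all recovery claims in the test suite are claims about what the
analysis code recovers from data whose truth is known exactly.

# The read simulator

## What it emulates

The simulator reproduces the data characteristics of nanopore genome
runs from routine clinical DNA extractions: a 5 kb median read length
with a 16 kb N50 at 34X mean coverage (the package defaults in
`simulationConfig()`), two haplotypes per locus, per-CpG methylation
probability calls on each read, and chimeric (primary + supplementary)
alignments across rearrangement breakpoints.

Read lengths are drawn from a log-normal distribution. The two printed
statistics pin the two parameters: the median of a log-normal
$(\mu, \sigma)$ is $e^{\mu}$, and the N50 -- the median of the
length-biased distribution, which is log-normal $(\mu + \sigma^2,
\sigma)$ -- is $e^{\mu + \sigma^2}$, so

$$\mu = \log(\text{median}), \qquad
  \sigma = \sqrt{\log(\text{N50}/\text{median})}.$$

Each molecule is drawn from a template: one per haplotype per
chromosome, plus one per derivative-chromosome plan. Sampling
probability is proportional to cell weight times template length (DNA
mass), so a derivative present in a fraction $f$ of cells in place of
one homolog contributes depth in exact proportion to $f$ -- the property
the mosaic-fraction estimator depends on. Reads accumulate until the
total emitted bases reach coverage times reference length, which makes
the coverage-conservation property hold by construction.

Sequencing errors are applied per base (substitution, insertion,
deletion rates are independent knobs; real platform error rates vary by
chemistry and basecaller, so no default is hard-coded beyond zero).
Alignments are emitted analytically from the known template-to-reference
map: within-block indels become CIGAR I/D operations, and template block
boundaries (rearrangement junctions) split a read into a primary plus
supplementary alignments with consistent soft-clips, ordered by position
in the read. Methylation is emitted per CpG per read as a modification
probability (the standard MM/ML tag convention in the SAM writer): each
CpG is methylated with the haplotype's regional probability, and the
emitted call is `1 - |e|` or `|e|` with `e ~ N(0, methyl_call_noise)`.
Reverse-strand molecules report the bottom-strand cytosine, one base
offset from the top-strand CpG, as real callers do.

## What it does not emulate

No pore-level signal or homopolymer-specific error structure; no
mapping ambiguity (alignments are derived from the generative truth, so
there are no mismapped reads, and MAPQ is constant); no segmental
duplications or repeat-mediated alignment failure; read length is
independent of genomic position. Consequently, passing the recovery
suites demonstrates correctness of the interpretive algorithms under
idealised alignment, not robustness to alignment artefacts in real
genomes -- the appropriate reading for a desk-scale reimplementation.

# STR profiling

Per-read repeat counting is anchor-based greedy tiling, deliberately not
an HMM: it is deterministic and verifiable against an exhaustive
sliding-window oracle, which the test suite does for every motif word of
length up to 3. The two locus flanks (default 30 bp) are located in the
read -- exactly first, then fuzzily at one mismatch or indel per 8 bp of
anchor -- and the tract between them is tiled left-to-right by the
canonical motif. A window with at most `max_unit_mismatch` mismatches
counts as a canonical unit; any other full-length window is recorded as
an interruption with its observed motif, and both kinds count toward the
total. The default mismatch budget is 0 because the clinically
informative interruption motifs (AGG inside CGG, CAT inside CAG) differ
from the canonical unit by a single base and would otherwise be silently
absorbed. A trailing partial unit is floored; counts are reported in
units, not base pairs.

Spanning calls are grouped by haplotype tags when present. Untagged
calls are split by an exact two-cluster partition of the counts
(deterministic scan over the sorted values minimising within-cluster
sum of squares), accepted only when the two cluster medians differ by
more than max(2 units, 10%) -- the bimodality criterion that prevents
spurious splits on noisy single-allele loci. Classification compares
the per-haplotype median against the locus threshold ladder
(normal/intermediate/premutation/full) with inclusive lower boundaries.

The shipped catalog carries FMR1-like (CGG, thresholds 44/54/200 units)
and ATXN1-like (CAG, thresholds 35/44/48 units) entries. The FMR1
thresholds follow the worked examples the package reproduces; the ATXN1
ladder follows the field convention that interrupted alleles up to the
mid-40s are benign. Both are catalog data, not code: real deployments
load their own BED + JSON catalog via `readStrCatalog()`.

# Methylation

A CpG call with probability $\ge 0.8$ counts methylated, $\le 0.2$
unmethylated; the symmetric band in between is discarded. The 0.8
default is standard practice for probability-tagged modification calls
and is configurable. Region fractions are computed pooled and per
haplotype -- imprinting is parent-of-origin, so the allelic fraction is
what distinguishes a uniparental pattern (both alleles methylated,
fraction near 1) from the biparental norm (one allele, fraction near
0.5).

Imprinted-region screening is a z-score against a control pool:

$$z = \frac{x_{\text{case}} - \bar{x}_{\text{controls}}}{s_{\text{controls}}}$$

with the sample (n-1) standard deviation, chosen because control pools
are small. Calls use $|z| \ge 3$ by default, below the smallest
magnitude this screen is expected to flag. The scored quantity is
configurable (`methylated_fraction`, the default, under which
hypermethylation gives positive z; or `unmethylated_fraction`, which
flips the sign) because both conventions circulate in practice; the
convention used is echoed in every output row. A zero-variance pool is
a no-call, and a pool below five controls per region is a configuration
error rather than a silent weak screen.

STR promoter status uses fixed bands: fraction $\ge 0.7$ is
hypermethylated (the silenced-full-mutation pattern), $\le 0.3$
unmethylated (active premutation alleles), otherwise intermediate.

# Phasing

Haplotype assignment is greedy agreement partitioning over heterozygous
sites: the read covering the most sites seeds haplotype 1, the second
partition's consensus is the allelic complement (all sites are
heterozygous), and reads join the side they match at the majority of
shared determinate sites, growing the consensus as they are assigned.
Ties and reads sharing fewer than `min_informative` (default 1) sites
stay unassigned. Labels are arbitrary up to a global 1/2 swap, and all
downstream calls are invariant to that swap.

Cis/trans resolution of a variant pair prefers direct evidence: reads
covering both positions vote cis when they carry both alternate alleles
or neither, trans when exactly one. When no read spans both positions
-- variant pairs 100 kb apart under a 5 kb median read length -- votes
are routed through haplotype tags, locating each variant on a haplotype
by majority. A phase is declared at `min_support` 3 winning votes
(matched to the ~34X regime while tolerating sparse overlap; the
clinical pipelines rarely publish such thresholds, so this
default is declared, not inferred) and a conflict fraction of at most
0.1. When direct and tag-routed evidence disagree, the result is
unknown with a conflict flag: a conservative clinical posture.

Paralog copy number clusters reads over the collapsed family region by
their allele strings at discriminating sites, labels each cluster by
gene through the gene-defining allele, and corroborates the cluster
count with relative depth: total copies = max(number of clusters,
round(2 x region depth / diploid baseline)), surplus copies going to
the largest clusters. Four SMN2 copies with no SMN1 therefore resolve
as four clusters at twice diploid depth.

# SV reconstruction

Junction ends are encoded by the retained flank: "+" keeps reference
bases at or below the position (stored as the 0-based exclusive end of
the retained segment), "-" keeps bases at or above it. This encoding is
unambiguous under composition, and an export to standard VCF breakend
bracket notation is provided for interoperability. Junctions are read
off adjacent alignments in each read's chain; raw junctions merge when
both ends agree within `pos_tolerance` (50 bp) with compatible
orientations, the cluster position is the per-end median, and clusters
below 3 supporting reads are dropped but counted.

Copy number is binned depth normalised to the genome median and
doubled; adjacent bins within 0.35 copies of the running segment mean
merge. Losses, gains and triplications are called at 1.5 / 2.5 / 3.5
copies. Because long-read depth is bursty (a single 30 kb molecule
moves a whole bin), motif classification only consults copy-number
segments within 10 kb of a junction end.

The derivative walk is greedy: from a caller-chosen anchor (a telomere
of the intact arm, or the neo-telomere of a terminal event) it travels
along the reference to the nearest unused junction end facing the walk,
jumps to the partner end, flips direction as the partner's orientation
dictates, and repeats; ties at the same position break by higher
support, then lexicographic partner. Each junction is consumed once per
traversal. The walk ends at a chromosome end, or when it re-enters its
starting state -- a ring. Exceeding 50 segments yields a
complex-unresolved result rather than an error, which is also the
honest answer for recurrent events flanked by segmental duplications
where breakpoints cannot be read from alignments at all.

Motif classification pattern-matches the junction set and the
junction-adjacent copy-number profile: (+,-) with a loss is DEL; (-,+)
with a gain is DUP; a matched like-oriented pair with neutral copy
number is INV, annotating any gap between the paired breakpoints that
coincides with a loss as a breakpoint deletion; a like-oriented
junction beside a terminal loss and adjacent gain is DEL-INV-DUP;
gains reaching triplication beside a duplication with an inverted
junction is DUP-TRP/INV-DUP; one junction bridging two chromosomes is
an unbalanced translocation; a circular walk is a RING; anything else
is COMPLEX.

Mosaic fraction: under the model that the derivative replaces one of
two homologs in carrier cells, junction-supporting reads are an
unbiased fraction cell_fraction/2 of reads spanning the breakpoint, so
the estimator doubles the observed fraction, caps at 1, and reports
both the raw value and the integer percent truncated (not rounded) --
6 of 28 supporting reads report 42%.

# Panel triage and cohort reporting

SVs are triaged in two tiers: derivatives whose affected span reaches
10 kb are reported genome-wide; smaller ones only when a breakpoint or
segment falls inside (or within 2 kb of) a panel region, with an
override keeping any event with more than two breakpoints. The
affected span is the sum of |copy number - 2|-weighted segment lengths
plus inverted segment lengths, so balanced inversions are sized by what
they invert instead of scoring zero. Every dropped event is logged with
the rule that dropped it, and filtering is idempotent.

The local SV-frequency database merges junction signatures across
cohort samples with the same 50 bp tolerance used for clustering (one
knob for one merge semantic) and records the set of samples per
signature; query junctions are kept when rare or seen only in the query
sample itself.

Cohort aggregation deduplicates on (individual, variant), counts
distinct variants and individuals, and assigns each individual their
best classification in the order P > LP > hot VUS > VUS > LB > B, so an
individual with both a pathogenic variant and a VUS counts once, under
the pathogenic heading. Because a category breakdown can legitimately
count variants or individuals, both views are reported. Rendered
reports exclude non-reported (NR) findings from the clinical section --
NR is only permitted for likely-benign/benign records -- but retain
them in the audit section, and identical inputs render byte-identical
reports.

# Numerical choices and problem sizes

Degenerate inputs resolve to no-calls, not errors, wherever a real
sample could produce them (no spanning reads at an STR locus, an empty
methylation region, a zero-variance control pool, no reads over a
paralog region); errors are reserved for configuration mistakes
(missing thresholds, undersized pools, out-of-bounds plans).
Determinism is enforced end to end: one seed in `simulationConfig()`
drives all randomness of a simulation, and repeated runs are
byte-identical including SAM output.

The test and acceptance suites run on toy references of 12-100 kb per
chromosome at 20-60X, with 20-seed replication for the noisy-recovery
claims (5% indel noise for STR sizing, 5% per-base error for phasing)
and untouched ballast chromosomes wherever copy-number normalisation
would otherwise be dominated by a large planted duplication. Depth
statistics are validated with 2 kb-median reads because depth noise
scales with molecule length; read-level analyses use the 5 kb/16 kb
defaults. These sizes are the package's own choice of a desk-scale
regime in which every planted truth is recoverable in minutes on one
core.

# Known limitations

The simulator's idealised alignments mean mapping artefacts are out of
scope, as noted above. The derivative walk requires a caller-supplied
anchor and resolves one derivative at a time; multi-derivative genomes
are walked per chromosome. Copy-number corroboration assumes the
genome median is diploid, which holds for genomes but must be arranged
(ballast) on toy references. The paralog module assumes discriminating
sites are spanned by single reads; families whose informative sites are
farther apart than a read length need assembly-based approaches.
Genome-wide methylation episignatures and population-scale phasing are
explicitly out of scope.
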