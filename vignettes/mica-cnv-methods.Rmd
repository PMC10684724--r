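---
title: "Methods: ratio-based MICA copy-number calling, NAHR breakpoint mapping and population linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratio-based MICA copy-number calling, NAHR breakpoint mapping and population linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micacnv)
```

This vignette is the package's account of the science it implements: the
models and decision rules, the tunable parameters and why their defaults
are what they are, what the synthetic-data generators do and do not
emulate, and the numerical and design choices made where the procedure
was genuinely open.

## 1. The measurement model

*MICA* and *MICB* are amplified by identical primer pairs in one
multiplex PCR that yields three amplicons per gene (exon 2, exon 3, and
a combined exon 4/5 amplicon). Within a sample, the two genes compete in
the same reaction, so the per-amplicon read-count ratio

$$ r_e = \frac{n_{\mathrm{MICA},e}}{n_{\mathrm{MICB},e}}, \qquad
   e \in \{\text{exon2}, \text{exon3}, \text{exon45}\} $$

is, to first order, proportional to the *MICA* copy number with *MICB*
fixed at two copies as the internal reference. The calling statistic is
the arithmetic mean $\bar r$ of the three ratios; their standard
deviation $s_r$ flags uneven amplification.

A diploid (two-copy) sample centers at $\bar r \approx 0.82$ rather than
1 because the two loci amplify with different efficiency; one-copy
samples center at $0.41 = 0.82/2$. Under pure linearity three-copy
samples would center at $1.23 = 1.5 \times 0.82$; observed data center
slightly higher, near 1.27. We treat this as a real feature of
amplification competition that the linear model does not capture: the
count generator exposes a `duplication_competition` factor (default 1,
i.e. the linear model; $1.27/1.23$ reproduces the observed center), and
the discrepancy is documented rather than silently absorbed.

### Decision rules

* **QC** (`qc_thresholds()`): exclude a sample if any of the six counts
  is below 100 reads or $s_r > 0.3$. Both comparisons are strict, so
  exactly 100 reads and exactly $s_r = 0.3$ pass.
* **Classification** (`class_thresholds()`): $\bar r < 0.53$ →
  hemizygous; $\bar r \ge 1.045$ → duplication; otherwise diploid. The
  hemizygous cut is the published operating threshold. The duplication
  threshold is this package's own choice: the production system detected
  duplications through allele-level genotyping rather than the ratio, so
  for ratio-only calling we take the midpoint of the two- and
  three-copy centers, $(0.82 + 1.27)/2 = 1.045$ (configurable).
* **Copy number 0**: a ratio near zero is *flagged* (`below_hemizygous`,
  cut 0.1) rather than called hemizygous — the ratio method was never
  validated for total loss, and silently merging it into hemizygosity
  would be wrong in both directions.
* **Heterozygous discordance**: a sample whose allele-level genotyping
  already shows two distinct *MICA* alleles cannot be hemizygous; if its
  ratio is nevertheless below 0.53 it is excluded
  (`excluded_heterozygous`) rather than called, mirroring the production
  exclusion. The genotype enters as a hint column; this module does not
  re-derive genotypes.
* **sd estimator**: sample standard deviation ($n-1$ denominator) over
  the three ratios. The source procedure says only "standard deviation";
  with three values the choice matters, so it is explicit and
  configurable (`sd_fun`).
* **Amplicons, not exons**: the mean and sd are taken over the three
  *amplicons* (exon 4/5 is one amplicon), not over four exons. This is
  the reading consistent with the assay design; the alternative would
  double-weight the exon 4/5 measurement.

The caller does not attempt copy numbers above three — the ratio peaks
overlap increasingly and the reference method itself is blind there —
and performs no GC or per-amplicon correction beyond the bias built into
the ratio itself.

## 2. EAG phasing

Each amplicon genotypes to a set of exon allele groups (EAGs); an EAG is
the set of alleles sharing an identical sequence over that amplicon.
`phase_eags()` enumerates every multiset of 1–3 *distinct* database
alleles whose per-amplicon EAG union equals the observation in all three
amplicons; a single consistent allele is reported as a homozygous pair.
Three distinct EAGs in any amplicon can only be explained by three
alleles, so the copy-number inference is 3; if both two- and
three-allele explanations exist the inference is reported `ambiguous`
rather than resolved by fiat. An observation no combination explains
raises an `unresolvable genotype` error — the signal for a novel allele
or an artifact — rather than being silently dropped.

Ambiguity groups (alleles identical in all three amplicons) are
abbreviated with the most-frequent-allele `#` convention. The frequency
ranking is an input table, not a constant: the convention depends on
cohort allele frequencies, which differ between populations.

`detect_duplication_by_coverage()` handles the second route to a
three-copy call: with exactly two distinct alleles, a duplicated third
copy makes the major EAG's read share ≈ 2/3 in *all three* amplicons.
"About 2:1" is operationalized as the major fraction lying within ±0.05
of 2/3 (configurable; the source gives no number). Requiring all three
amplicons keeps single-amplicon amplification noise from producing
spurious duplications.

## 3. Marker SNPs and breakpoint localization

NAHR between the segmental duplications upstream of *MICA* and *MICB*
produces recombinant haplotypes. In an alignment of the two haplotype
panels, a **marker SNP** is a column where *every* upstream-*MICA*
haplotype carries one base and *every* upstream-*MICB* haplotype carries
a different base; columns with gaps or ambiguity codes are excluded
outright (the source does not say how indel columns were treated; we
exclude them because a half-open gap cannot be assigned a paralog
state). The exclusivity requirement is what makes a marker diagnostic —
a single shared-polymorphism haplotype disqualifies the column.

Along a recombinant consensus, each marker reads `A`, `B`, or `other`
(neither panel base, e.g. a private variant). `other` states are
reported but ignored for switch detection. A single B→A switch is a
duplication-type recombinant, a single A→B switch deletion-type, no
switch non-recombinant, and more than one switch `complex` — flagged,
never force-fitted to a single crossover, since multi-switch patterns
indicate gene conversion or sequencing error, not a simple NAHR event.

`localize_breakpoint()` returns the interval between the last marker in
the 5′-paralog state and the first marker in the 3′-paralog state.
Widths use the difference convention, width = end − start, which matches
the published arithmetic (markers at relative positions 1510 and 1725
bound a region of width 215; genomic bounds 31,388,981 and 31,391,803
span 2,822 bases). For file output, intervals are 0-based half-open
(BED); human-readable reports are 1-based inclusive, and a single
converter pair (`interval_to_report()` / `interval_from_report()`) owns
the off-by-one in both directions. Relative positions count from the
declared panel origin at offset 0.

`group_by_pattern()` partitions samples by exact marker-state pattern;
within a group, byte-identity of the consensus across the breakpoint
region (`consensus_identical`) distinguishes a single ancestral
recombination event from recurrent events at the same interval.

`scan_motif()` reports all, possibly overlapping, matches of an IUPAC
motif (default the PRDM9 hotspot motif 5′-CCNCCNTNNCCNC-3′), forward
strand by default; reverse-complement hits can be requested and are
flagged by strand. Matching is delegated to Biostrings; the test suite
holds it to a hand-written sliding-window oracle.

Producing the alignment itself is out of scope: panels and consensus
sequences arrive pre-aligned, as standard multiple-sequence-alignment
practice lives outside this package.

## 4. Population frequencies, linkage and EM

`population_frequencies()` reports *carrier* (sample-level) frequencies
per self-assigned ethnic group — "sample population frequency" is read
as the fraction of samples carrying the class, not an allele frequency.
Groups are reported only above 2,500 samples (strict inequality);
smaller groups are listed with a suppression reason rather than dropped
invisibly. Ethnicity strings are opaque labels: groups from different
donor centers are never merged, because the questionnaires differ.

`linkage_table()` reports, per *HLA-B* allele: carrier count among
class carriers, its share of all class carriers, and the linkage (the
fraction of allele carriers in the class). Rows require linkage ≥ 50%
and ≥ 10 genotyped allele carriers (both configurable; they are the
published table's inclusion rule), with the remainder aggregated as
`Other` so the share column totals 1. Percent columns are rounded to
whole percent for table parity; fraction columns keep full precision.

`estimate_haplotype_frequencies()` is a standard EM estimator under
random mating for unphased multilocus genotypes: each genotype expands
into its compatible haplotype pairs; the E step weights pairs by
$2f_if_j$ (or $f_i^2$), the M step re-estimates $f$ from expected
counts. Iteration stops at a relative log-likelihood change below
1e-8 or 1,000 iterations (non-convergence returns the last iterate with
a warning, never silently). Haplotypes estimated below 1e-4 are reported
but flagged unresolvable — population-frequency phasing cannot resolve
rare haplotypes, and the flag makes that limitation explicit. This EM is
a stand-in: the production haplotype calls come from a proprietary
frequency-correlation procedure that is not published in reproducible
detail; EM under Hardy–Weinberg is the standard open equivalent and is
labelled as such here.

## 5. What the generators emulate — and what they do not

**Counts** (`simulate_counts()`). Per cell,
$n_{g,e} \sim \mathrm{NB}(\mu = d \cdot c_g \cdot b_{g,e}/2, \;
\mathrm{size} = \phi)$ with depth $d = 1000$ reads per amplicon per copy
pair, bias $b$ calibrated so the diploid ratio centers at 0.82, and
*MICB* fixed at two copies (an override exists precisely to probe the
ratio method's failure mode when the reference assumption breaks).
Choices made once, as study conditions:

* **Dispersion** $\phi = 150$ (size parameterization; `Inf` gives the
  Poisson limit; `noise = FALSE` gives deterministic expected counts).
  The source reports only "moderate variability" with three clearly
  separated ratio peaks; $\phi = 150$ yields a diploid mean-ratio sd of
  about 0.06, which separates the peaks as clearly as the published
  description requires. It is a documented guess, not a fit.
* **Dropout** probability 0.0085 per cell, drawing a near-zero count.
  Over six cells this fails ~5% of samples at the coverage filter,
  matching the published ~95% QC pass rate.
* **Copy-number mix** default {1: 0.44%, 2: 98.51%, 3: 1.05%}, the
  published cohort fractions. Four-copy samples are generable even
  though the caller cannot detect them — that blindness is a documented
  property worth testing, not hiding.

Not emulated: read-level data (FASTQ), basecalling error, primer-binding
kinetics, GC effects. Tests passing on these counts therefore show the
calling logic is correct under the stated noise model, not that the
model captures every failure mode of a real sequencing run.

**Panels** (`generate_paralog_panels()`). Two aligned panels (defaults:
30 kb, 93% identity, 37 + 34 haplotypes — the real panel sizes) derive
from one ancestral sequence. Planted features: marker SNPs at random
non-protected columns; the PRDM9 motif (N's instantiated once) at offset
1969 in both panels, the real motif offset relative to the region
origin; a CT dinucleotide repeat at offset 936, the real repeat's
offset. Background divergence (the identity budget beyond the markers)
is deliberately made *non-diagnostic*: at each background column one
randomly chosen haplotype carries the other paralog's base, so the
planted markers are exactly the paralog-exclusive columns and the
marker finder can be held to the planted truth as an oracle.
Within-panel diversity (default 0.001/base) never touches marker, motif
or repeat columns; real haplotype panels are not that tidy, which is
why `classify_recombinant()` tolerates `other` states anyway.

**Recombinants** (`generate_recombinant()`). One crossover point drawn
uniformly from $(\mathrm{start}, \mathrm{end}]$; the point $p$ is the
first column taken from the suffix donor, so an interval $(k, k+1)$
forces the switch exactly at boundary $k$, and "the region contains the
truth" means $\mathrm{start} < p \le \mathrm{end}$. Duplication-type =
B-prefix/A-suffix; deletion-type is the mirror. No gene conversion
tracts, no template switching — `complex` patterns in real data have
causes this generator does not produce.

**Populations** (`generate_population()`). Two haplotypes per sample,
drawn independently from group-specific pools (random mating within
group); copy number is the sum of the haplotype contributions (0, 1
or 2); genotypes are unphased. The default configuration plants the
study's linkage structure — a duplication haplotype on B\*27:02:01G
frequent in Eastern European groups, deletion haplotypes on
B\*48:01:01G, B\*15:16:01G and B\*39:06:02G frequent in the Mexican and
Chilean groups — with haplotype frequencies chosen so carrier
frequencies land in the published ranges (e.g. duplication carriers
~2.6% in the Polish group, deletion carriers ~9% in the Mexican group).
No admixture, no inbreeding, no genotyping error.

## 6. Numerical choices and degenerate inputs

* Zero *MICB* counts make a ratio undefined; `compute_ratios()` errors
  naming the amplicon. In cohort calling this state is unreachable when
  the coverage filter is active (a zero count fails coverage first); if
  thresholds are relaxed to admit it, the error surfaces rather than
  propagating `Inf`.
* Classification boundaries: all cuts are applied exactly as stated
  (strict `<` for hemizygous and QC, `>=` for duplication), and the
  monotonicity of call vs. mean ratio is a tested invariant.
* EM initialization is uniform over observed-compatible haplotypes;
  with all-homozygous input it converges in one step to the observed
  genotype frequencies. Ties between equally likely expansions are
  resolved by the likelihood itself, never by order.
* Pattern grouping orders groups by first occurrence, making outputs
  deterministic under a fixed input order.
* All generators take explicit integer seeds and are byte-reproducible;
  the test suite asserts file-level identity.

## 7. Problem sizes

The shipped analysis uses a 50,000-sample cohort (stage 1–2), 76
recombinant consensus sequences over 30 kb panels (stage 4), and a
23,000-sample six-group population (stage 5); the test suite uses
10,000-sample cohorts, 500 recombinants and n = 20,000 EM recovery.
These sizes give binomial/Monte-Carlo error well below every tested
tolerance while keeping a full run in minutes on one core; all scale
linearly if larger runs are wanted.

## 8. Known limitations

* The ratio caller cannot see copy numbers above three, and `MICB`
  CNVs violate its reference assumption (the generator can produce
  both; the caller's documented behavior under them is mis-calling).
* The three-copy center (1.27 observed vs 1.23 linear) is reproduced
  only with the optional competition factor; the default generator is
  deliberately the plain linear model.
* EAG phasing trusts the allele database: alleles absent from it make a
  sample unresolvable, and candidate ranking beyond the `#` convention
  (e.g. by joint population likelihood) is not attempted — all
  candidates are reported.
* Breakpoint resolution is bounded by marker density; between two
  adjacent markers the method is blind, which is exactly why widths are
  reported rather than point estimates.
* The EM estimator assumes random mating within group and complete
  genotypes; population stratification within a self-assigned group
  biases it, as it does the production procedure it stands in for.
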