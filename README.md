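# micacnv

Copy-number variation (CNV) analysis of the *MICA* gene from multiplex
amplicon genotyping data, with NAHR breakpoint mapping and population
linkage tables.

## The problem

*MICA* encodes a stress-induced ligand of the NKG2D receptor and sits in
the MHC between *HLA-B* and its close paralog *MICB*. Registry-scale
genotyping amplifies *MICA* and *MICB* with the same primer pairs in one
multiplex PCR, producing three amplicons per gene (exon 2, exon 3, exon
4/5). Because the two genes compete in the same reaction, the ratio of
*MICA* to *MICB* read counts is a stable proxy for *MICA* copy number —
*MICB* acts as a two-copy internal reference. Both deletions
(hemizygosity) and duplications (three gene copies) of *MICA* segregate
at appreciable population frequencies, arise by nonallelic homologous
recombination (NAHR) between two ~30 kb segmental duplications (~93%
identity) upstream of *MICA* and *MICB*, and travel on haplotypes tightly
linked to particular *HLA-B* alleles.

This package implements, as tested reusable functions plus an analysis
workflow, every computational stage of that study design:

1. **Ratio-based CNV calling** (`call_cohort()`): per-amplicon ratios
   `r_e = n_MICA,e / n_MICB,e`, their mean and sd over the three
   amplicons; QC excludes samples with any coverage < 100 or sd > 0.3;
   mean ratio < 0.53 calls hemizygous (one copy, peak center 0.41),
   ≥ 1.045 calls duplication (three copies, peak center 1.27), otherwise
   diploid (center 0.82).
2. **Exon-allele-group (EAG) phasing** (`phase_eags()`,
   `detect_duplication_by_coverage()`): enumerates the allele multisets
   (1–3 distinct alleles) consistent with the observed EAG sets in all
   amplicons; three distinct EAGs in one amplicon, or a 2:1 read split in
   all three amplicons, indicate three gene copies. Ambiguity groups are
   reported with the most-frequent-allele `#` convention.
3. **Breakpoint mapping** (`find_marker_snps()`, `map_breakpoints()`,
   `group_by_pattern()`, `scan_motif()`): paralog-specific marker SNPs
   are alignment columns where all upstream-*MICA* haplotypes carry one
   base and all upstream-*MICB* haplotypes a different one. A
   duplication-type recombinant reads B,…,B,A,…,A along its markers, a
   deletion-type the mirror; the breakpoint region is the interval
   between the last 5′-state and the first 3′-state marker (width =
   end − start). Includes an IUPAC scanner for the PRDM9 hotspot motif
   5′-CCNCCNTNNCCNC-3′.
4. **Population linkage** (`population_frequencies()`,
   `linkage_table()`, `estimate_haplotype_frequencies()`): carrier
   frequencies per self-assigned ethnic group (reported for n > 2500),
   *HLA-B* linkage tables (alleles ≥ 50% class-linked in ≥ 10 genotyped
   samples, plus an `Other` remainder), and EM haplotype-frequency
   estimation under random mating for unphased genotypes.
5. **Synthetic data** (`simulate_counts()`, `generate_paralog_panels()`,
   `generate_recombinant()`, `generate_population()`): generators with
   the statistical structure the analysis assumes — negative-binomial
   counts with ratio centers 0.41/0.82/1.23–1.27, paralog panels with
   planted marker SNPs, CT repeat and hotspot motif, and multi-ethnic
   populations with CNV haplotypes in Hardy–Weinberg proportions — so
   every stage is testable end to end with known truth.

## Worked example

The analysis workflow lives in `analysis/01_simulate_cohort.R` …
`analysis/05_linkage.R`; each stage reads the previous stage's tables
from `results/`. Stages 1–2 simulate a 50,000-sample cohort and call
copy number:

```
$ Rscript analysis/01_simulate_cohort.R
$ Rscript analysis/02_call_cnv.R
QC pass rate: 95.1% (47536 of 50000)
  class           n pct_of_qc_pass pct_of_processed
1 diploid     46807         98.5             93.6
2 duplication   494          1.04             0.988
3 hemizygous    235          0.494            0.47
4 qc_fail      2464          5.18             4.93

classification accuracy among QC-pass calls: 0.9994
```

The QC pass rate (~95%), duplication fraction (~1%) and hemizygous
fraction (~0.5%) match the simulated cohort mix, which in turn is the
mix reported for the real two-million-donor registry cohort; accuracy is
against the generator's hidden truth. Stage 4 maps breakpoints for 53
duplication- and 23 deletion-type recombinant consensus sequences drawn
from 15 crossover templates:

```
$ Rscript analysis/04_breakpoints.R
marker SNPs discovered: 40 (planted: 40 )
samples: 76 -> 15 breakpoint region groups; all groups consensus-identical: TRUE
true crossover inside the localized region: 76 / 76
PRDM9 motif offsets in upstream-MICA haplotype 1: 1969
```

Every localized region contains the true crossover, samples regroup
exactly into the 15 planted templates, and the hotspot motif is found at
its planted offset (1969 relative to the region origin). Stage 5
tabulates population frequencies (e.g. duplication carriers ~2.7% in the
simulated Croatian and Polish groups, hemizygous carriers ~8.8% in the
Mexican group) and recovers planted haplotype frequencies by EM.

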