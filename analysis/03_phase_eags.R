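#!/usr/bin/env Rscript
# Stage 3 — exon-allele-group phasing demonstrations.
#
# Reproduces the two sequencing-based routes to a three-copy genotype:
# (a) three distinct EAGs in one amplicon phase only to three-allele
#     combinations;
# (b) two distinct alleles at a ~2:1 read-coverage split in all three
#     amplicons also indicate three gene copies.

suppressPackageStartupMessages(library(micacnv))

dir.create("results", showWarnings = FALSE)

# toy allele database: eight alleles over shared EAG pools, including an
# ambiguity group (MICA*004 / MICA*028 share every amplicon)
db <- tibble::tibble(
  allele_name = c("MICA*001", "MICA*002", "MICA*004", "MICA*028",
                  "MICA*007", "MICA*008", "MICA*009", "MICA*011"),
  eag_exon2 = c("e2_1", "e2_2", "e2_3", "e2_3", "e2_4", "e2_5", "e2_2",
                "e2_1"),
  eag_exon3 = c("e3_1", "e3_2", "e3_3", "e3_3", "e3_4", "e3_5", "e3_2",
                "e3_6"),
  eag_exon45 = c("e45_1", "e45_2", "e45_3", "e45_3", "e45_4", "e45_5",
                 "e45_6", "e45_1"))
freq <- tibble::tibble(allele_name = db$allele_name,
                       frequency = c(0.20, 0.10, 0.08, 0.002, 0.05,
                                     0.42, 0.03, 0.01))

# (a) three distinct EAGs per amplicon: a 007 + 008 + 001 carrier
obs3 <- eag_observation(
  exon2 = c(e2_4 = 310, e2_5 = 300, e2_1 = 290),
  exon3 = c(e3_4 = 305, e3_5 = 295, e3_1 = 300),
  exon45 = c(e45_4 = 315, e45_5 = 290, e45_1 = 295))
res3 <- phase_eags(obs3, db, freq_table = freq)
cat("three-EAG sample:\n  candidates:",
    res3$ambiguity_string, "\n  copy-number inference:",
    res3$copy_number_inference, "\n")

# (b) two distinct alleles at 2:1 coverage in every amplicon
obs21 <- eag_observation(
  exon2 = c(e2_5 = 660, e2_4 = 340),
  exon3 = c(e3_5 = 670, e3_4 = 330),
  exon45 = c(e45_5 = 655, e45_4 = 345))
res21 <- phase_eags(obs21, db, freq_table = freq)
cn_cov <- detect_duplication_by_coverage(obs21)
cat("\ntwo-allele 2:1 sample:\n  candidates:", res21$ambiguity_string,
    "\n  coverage-based copy number:", cn_cov, "\n")

# (c) an ambiguity group reported with the # convention
obs_amb <- eag_observation(exon2 = c(e2_3 = 600), exon3 = c(e3_3 = 610),
                           exon45 = c(e45_3 = 590))
res_amb <- phase_eags(obs_amb, db, freq_table = freq)
cat("\nambiguity-group sample:\n  reported genotype:",
    res_amb$ambiguity_string, "\n")

out <- tibble::tibble(
  sample = c("three_eag", "two_allele_2to1", "ambiguity_group"),
  genotype = c(res3$ambiguity_string, res21$ambiguity_string,
               res_amb$ambiguity_string),
  copy_number = c(res3$copy_number_inference, as.character(cn_cov),
                  res_amb$copy_number_inference))
write_table_output(out, "results/phasing_examples.tsv", "tsv")
cat("\nwritten: results/phasing_examples.tsv\n")
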