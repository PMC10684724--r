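two_group_records <- function(n1, c1, n2, c2, class_cn = 3L) {
  tibble::tibble(
    sample_id = sprintf("P%05d", seq_len(n1 + n2)),
    ethnicity = rep(c("G1", "G2"), c(n1, n2)),
    hla_b_1 = "B*07:02:01G", hla_b_2 = "B*08:01:01G",
    mica_alleles = "MICA*008,MICA*008",
    copy_number_call = c(rep(c(class_cn, 2L), c(c1, n1 - c1)),
                         rep(c(class_cn, 2L), c(c2, n2 - c2))))
}

test_that("population frequencies are carrier fractions with strict group-size filtering", {
  rec <- two_group_records(1000, 10, 3000, 30)
  fr <- population_frequencies(rec, "duplication")
  expect_equal(fr$frequency[fr$ethnicity == "G1"], 0.01)
  expect_true(fr$suppressed[fr$ethnicity == "G1"])   # 1000 <= 2500
  expect_false(fr$suppressed[fr$ethnicity == "G2"])  # 3000 > 2500
  expect_match(fr$reason[fr$ethnicity == "G1"], "group size")
  # boundary: exactly min_n is suppressed (strict inequality)
  rec2 <- two_group_records(2500, 5, 2501, 5)
  fr2 <- population_frequencies(rec2, "duplication")
  expect_true(fr2$suppressed[fr2$ethnicity == "G1"])
  expect_false(fr2$suppressed[fr2$ethnicity == "G2"])
  expect_error(population_frequencies(rec, "triploid"), "unknown")
})

test_that("population frequency totals ignore record order and label names", {
  rec <- two_group_records(800, 12, 900, 7)
  f1 <- population_frequencies(rec, "duplication", min_n = 100)
  f2 <- population_frequencies(rec[sample(nrow(rec)), ], "duplication",
                               min_n = 100)
  expect_equal(f1, f2)
  rec3 <- rec
  rec3$ethnicity <- sub("G", "Group_", rec3$ethnicity)
  f3 <- population_frequencies(rec3, "duplication", min_n = 100)
  expect_equal(f3$carriers, f1$carriers)
})

test_that("a single haplotype at frequency 1 gives homozygotes with deterministic CN", {
  cfg <- population_sim_config(
    groups = tibble::tibble(ethnicity = "G", n = 200L),
    haplotypes = tibble::tibble(ethnicity = "G", haplotype_id = "dup",
                                hla_b = "B*27:02:01G",
                                mica_alleles = "MICA*007,MICA*008",
                                cn_contribution = 2L, frequency = 1),
    seed = 4)
  pop <- generate_population(cfg)
  expect_true(all(pop$copy_number_call == 4L))
  expect_true(all(pop$hla_b_1 == pop$hla_b_2))
})

test_that("carrier fractions follow Hardy-Weinberg expectations", {
  f_dup <- 0.013
  f_del <- 0.05
  cfg <- population_sim_config(
    groups = tibble::tibble(ethnicity = "G", n = 50000L),
    haplotypes = tibble::tibble(
      ethnicity = "G",
      haplotype_id = c("dup", "del", "bg"),
      hla_b = c("B*27:02:01G", "B*48:01:01G", "B*07:02:01G"),
      mica_alleles = c("MICA*007,MICA*008", "", "MICA*008"),
      cn_contribution = c(2L, 0L, 1L),
      frequency = c(f_dup, f_del, 1 - f_dup - f_del)),
    seed = 12)
  pop <- generate_population(cfg)
  # duplication carriers: at least one dup haplotype
  p_carrier <- 1 - (1 - f_dup)^2
  got <- mean(pop$true_hap_1 == "dup" | pop$true_hap_2 == "dup")
  expect_lt(abs(got - p_carrier),
            4 * sqrt(p_carrier * (1 - p_carrier) / 50000))
  # deletion homozygotes: expected n * f^2
  n_hom <- sum(pop$copy_number_call == 0L)
  expect_lt(abs(n_hom - 50000 * f_del^2),
            4 * sqrt(50000 * f_del^2))
  # invalid pools are rejected
  expect_error(population_sim_config(
    groups = tibble::tibble(ethnicity = "G", n = 10L),
    haplotypes = tibble::tibble(ethnicity = "G", haplotype_id = "h",
                                hla_b = "B*07", mica_alleles = "x",
                                cn_contribution = 1L, frequency = 0.7)),
    "sum to 1")
})

test_that("linkage tables apply the 50%-linkage and 10-sample filters with an Other row", {
  # 30 hemizygous carriers: 18 via allele LNK (linkage 18/20 = 90%),
  # 9 via allele RARE (9/9 = 100% but only 9 genotyped samples),
  # 3 via allele WEAK (3/100 genotyped, 3% linkage)
  rec <- tibble::tibble(
    sample_id = sprintf("P%04d", 1:129),
    ethnicity = "G",
    hla_b_1 = c(rep("LNK", 20), rep("RARE", 9), rep("WEAK", 100)),
    hla_b_2 = "B*07:02:01G",
    mica_alleles = "",
    copy_number_call = c(rep(1L, 18), 2L, 2L, rep(1L, 9),
                         rep(1L, 3), rep(2L, 97)))
  lt <- linkage_table(rec, "hemizygous")
  al <- lt$alleles
  expect_identical(al$hla_b[1], "LNK")
  expect_false("RARE" %in% al$hla_b)  # fails the 10-sample minimum
  expect_false("WEAK" %in% al$hla_b)  # fails the 50% linkage minimum
  expect_equal(al$fraction_of_allele_carriers_with_cnv[1], 0.9)
  expect_equal(al$fraction_of_cnv_carriers[al$hla_b == "LNK"], 18 / 30)
  expect_equal(al$n_carriers_with_allele[al$hla_b == "Other"], 12)
  # listed fractions plus Other sum to 1
  listed <- al[!al$hla_b %in% "Total", ]
  expect_equal(sum(listed$fraction_of_cnv_carriers), 1)
  expect_equal(al$fraction_of_cnv_carriers[al$hla_b == "Total"], 1)
})

test_that("EM with fully homozygous samples returns the observed genotype frequencies", {
  g <- data.frame(b = c(rep("B27/B27", 30), rep("B07/B07", 70)),
                  m = c(rep("M007/M007", 30), rep("M008/M008", 70)))
  em <- estimate_haplotype_frequencies(g)
  fr <- em$frequencies
  expect_equal(fr$frequency[fr$haplotype == "B27~M007"], 0.3)
  expect_equal(fr$frequency[fr$haplotype == "B07~M008"], 0.7)
  expect_true(em$converged)
})

test_that("EM recovers complete-LD two-locus frequencies to closed form", {
  # only haplotypes A~B (p) and a~b (1-p) exist
  p <- 0.3
  set.seed(44)
  n <- 2000
  h1 <- ifelse(runif(n) < p, "AB", "ab")
  h2 <- ifelse(runif(n) < p, "AB", "ab")
  g <- data.frame(
    l1 = paste(substr(h1, 1, 1), substr(h2, 1, 1), sep = "/"),
    l2 = paste(substr(h1, 2, 2), substr(h2, 2, 2), sep = "/"))
  em <- estimate_haplotype_frequencies(g)
  fr <- em$frequencies
  p_hat <- sum(h1 == "AB") + sum(h2 == "AB")
  expect_equal(fr$frequency[fr$haplotype == "A~B"],
               p_hat / (2 * n), tolerance = 1e-6)
  # repulsion haplotypes are absent and flagged unresolvable
  low <- fr$frequency[fr$haplotype %in% c("A~b", "a~B")]
  expect_true(all(low < 1e-4))
  expect_true(all(!fr$resolvable[fr$haplotype %in% c("A~b", "a~B")]))
})

test_that("the EM log-likelihood never decreases", {
  set.seed(55)
  for (i in 1:5) {
    g <- data.frame(
      l1 = sample(c("A/A", "A/a", "a/a"), 300, TRUE),
      l2 = sample(c("B/B", "B/b", "b/b"), 300, TRUE),
      l3 = sample(c("C/C", "C/c", "c/c"), 300, TRUE))
    em <- estimate_haplotype_frequencies(g)
    expect_true(all(diff(em$loglik) >= -1e-9))
    expect_equal(sum(em$frequencies$frequency), 1, tolerance = 1e-9)
  }
})

test_that("population simulation is reproducible under a fixed seed", {
  cfg <- default_population_config(seed = 99)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1, p2)
})
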