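test_that("marker finding recovers exactly the planted truth set", {
  pan <- generate_paralog_panels(small_panel_config(seed = 14,
                                                    n_marker_snps = 8))
  found <- find_marker_snps(pan$panel_a, pan$panel_b)
  expect_equal(found$position, pan$markers$position)
  expect_equal(found$base_a, pan$markers$base_a)
  expect_equal(found$base_b, pan$markers$base_b)
  # still exact with within-panel diversity (protected marker columns)
  pan2 <- generate_paralog_panels(small_panel_config(seed = 15,
                                                     n_marker_snps = 8,
                                                     diversity = 0.01))
  found2 <- find_marker_snps(pan2$panel_a, pan2$panel_b)
  expect_equal(found2$position, pan2$markers$position)
})

test_that("identical panels yield no markers and empty panels error", {
  cfg <- paralog_sim_config(length = 300, identity = 1, n_marker_snps = 0,
                            motif_position_a = 20, motif_position_b = 20,
                            ct_repeat_position = 100, ct_repeat_units = 4,
                            n_haplotypes_a = 3, n_haplotypes_b = 3,
                            intra_paralog_diversity = 0, seed = 2)
  pan <- generate_paralog_panels(cfg)
  expect_identical(unname(pan$panel_a[1]), unname(pan$panel_b[1]))
  expect_equal(nrow(pan$markers), 0)
  expect_equal(nrow(find_marker_snps(pan$panel_a, pan$panel_b)), 0)
  expect_error(find_marker_snps(character(0), pan$panel_b), "non-empty")
})

test_that("contaminated, gapped or ambiguous columns are never markers", {
  a <- c("ACGTA", "ACGTA", "ACGTA")
  b <- c("ATGCA", "ATGCA", "ATGCA")
  expect_equal(find_marker_snps(a, b)$position, c(1L, 3L))
  # one panel-A haplotype carrying the panel-B base kills the column
  a2 <- c("ACGTA", "ATGTA", "ACGTA")
  expect_equal(find_marker_snps(a2, b)$position, 3L)
  # gap and ambiguity codes disqualify a column
  a3 <- c("AC--A", "AC--A", "AC--A")
  expect_equal(find_marker_snps(a3, b)$position, 1L)
  b2 <- c("ATGNA", "ATGNA", "ATGNA")
  expect_equal(find_marker_snps(a, b2)$position, 1L)
  # agreement with the brute-force column scan
  set.seed(42)
  for (i in 1:20) {
    pa <- vapply(1:3, function(i) random_dna(60), character(1))
    pb <- vapply(1:3, function(i) random_dna(60), character(1))
    expect_equal(as.data.frame(find_marker_snps(pa, pb)),
                 as.data.frame(oracle_markers(pa, pb)))
  }
})

test_that("marker finding is symmetric in the two panels", {
  pan <- generate_paralog_panels(small_panel_config(seed = 19,
                                                    n_marker_snps = 6,
                                                    diversity = 0.005))
  ab <- find_marker_snps(pan$panel_a, pan$panel_b)
  ba <- find_marker_snps(pan$panel_b, pan$panel_a)
  expect_equal(ab$position, ba$position)
  expect_equal(ab$base_a, ba$base_b)
  expect_equal(ab$base_b, ba$base_a)
})

mk_markers <- function(positions, base_a = "A", base_b = "G") {
  tibble::tibble(position = positions,
                 base_a = rep(base_a, length(positions)),
                 base_b = rep(base_b, length(positions)))
}

consensus_from_states <- function(states, positions, length,
                                  base_a = "A", base_b = "G") {
  s <- rep("T", length)
  s[positions + 1] <- c(A = base_a, B = base_b, other = "C")[states]
  paste(s, collapse = "")
}

test_that("marker-state patterns classify recombinant kinds", {
  pos <- c(10L, 20L, 30L, 40L, 50L)
  mk <- mk_markers(pos)
  dup <- consensus_from_states(c("B", "B", "B", "A", "A"), pos, 60)
  expect_equal(classify_recombinant(dup, mk)$kind, "duplication")
  del <- consensus_from_states(c("A", "A", "B", "B", "B"), pos, 60)
  expect_equal(classify_recombinant(del, mk)$kind, "deletion")
  flat <- consensus_from_states(rep("A", 5), pos, 60)
  expect_equal(classify_recombinant(flat, mk)$kind, "non_recombinant")
  cx <- classify_recombinant(
    consensus_from_states(c("B", "A", "B", "A", "A"), pos, 60), mk)
  expect_equal(cx$kind, "complex")
  expect_equal(cx$switch_positions, c(20L, 30L, 40L))
  # 'other' states are reported but ignored for switch detection
  oth <- classify_recombinant(
    consensus_from_states(c("B", "other", "B", "A", "A"), pos, 60), mk)
  expect_equal(oth$kind, "duplication")
  expect_equal(oth$pattern$state[2], "other")
  expect_error(classify_recombinant(substr(dup, 1, 20), mk), "shorter")
  expect_error(classify_recombinant(dup, mk[0, ]), "non-empty")
})

test_that("breakpoint localization brackets the switch with the difference convention", {
  pos <- c(1000L, 1510L, 1725L, 2000L)
  mk <- mk_markers(pos)
  dup <- consensus_from_states(c("B", "B", "A", "A"), pos, 2100)
  bp <- localize_breakpoint(classify_recombinant(dup, mk))
  expect_equal(bp$start, 1510L)
  expect_equal(bp$end, 1725L)
  expect_equal(bp$width, 215L)
  # adjacent markers give the tightest possible localization
  mk2 <- mk_markers(c(7L, 8L))
  dup2 <- consensus_from_states(c("B", "A"), c(7L, 8L), 20)
  expect_equal(localize_breakpoint(classify_recombinant(dup2, mk2))$width,
               1L)
  flat <- consensus_from_states(rep("A", 4), pos, 2100)
  expect_error(localize_breakpoint(classify_recombinant(flat, mk)),
               "single-switch")
})

test_that("localized regions always contain the true crossover", {
  pan <- generate_paralog_panels(small_panel_config(seed = 23,
                                                    length = 1500L,
                                                    n_marker_snps = 12))
  mk <- find_marker_snps(pan$panel_a, pan$panel_b)
  set.seed(5)
  lo <- min(mk$position)
  hi <- max(mk$position)
  for (i in 1:50) {
    kind <- sample(c("duplication", "deletion"), 1)
    w <- sample(50:300, 1)
    # keep the crossover between the outermost markers so the pattern
    # shows both paralog states (the single-crossover precondition)
    s <- sample(lo:(hi - w - 1), 1)
    rec <- generate_recombinant(pan$panel_a[sample(4, 1)],
                                pan$panel_b[sample(3, 1)],
                                c(s, s + w), kind)
    cl <- classify_recombinant(rec$sequence, mk)
    expect_equal(cl$kind, kind)
    bp <- localize_breakpoint(cl)
    expect_true(rec$crossover > bp$start && rec$crossover <= bp$end)
  }
})

test_that("duplication and deletion from one crossover give mirror patterns", {
  pan <- generate_paralog_panels(small_panel_config(seed = 29,
                                                    length = 1200L,
                                                    n_marker_snps = 10))
  mk <- find_marker_snps(pan$panel_a, pan$panel_b)
  dup <- generate_recombinant(pan$panel_a[1], pan$panel_b[1],
                              c(400, 401), "duplication")
  del <- generate_recombinant(pan$panel_a[1], pan$panel_b[1],
                              c(400, 401), "deletion")
  sd_ <- classify_recombinant(dup$sequence, mk)$pattern$state
  sl <- classify_recombinant(del$sequence, mk)$pattern$state
  flip <- c(A = "B", B = "A", other = "other")
  expect_identical(unname(flip[sd_]), sl)
})

test_that("samples are grouped by identical patterns with region-identity flags", {
  pos <- c(5L, 15L, 25L)
  mk <- mk_markers(pos)
  s1 <- consensus_from_states(c("B", "B", "A"), pos, 40)
  s2 <- s1
  seqs <- c(g1a = s1, g1b = s2)
  bp <- map_breakpoints(seqs, mk)
  grp <- group_by_pattern(bp, seqs)
  expect_equal(nrow(grp), 1)
  expect_true(grp$consensus_identical)
  # same pattern, one mismatching base inside the region
  s3 <- s1
  substr(s3, 21, 21) <- "G"  # position 20, inside (15, 25]
  seqs2 <- c(g1a = s1, g1b = s3)
  grp2 <- group_by_pattern(map_breakpoints(seqs2, mk), seqs2)
  expect_equal(nrow(grp2), 1)
  expect_false(grp2$consensus_identical)
})

test_that("cohorts built from crossover templates regroup into the template count", {
  pan <- generate_paralog_panels(small_panel_config(seed = 31,
                                                    length = 3000L,
                                                    n_marker_snps = 35))
  mk <- find_marker_snps(pan$panel_a, pan$panel_b)
  # 15 planted crossover templates in 15 distinct inter-marker gaps:
  # 10 duplication-type, 5 deletion-type
  set.seed(6)
  gaps <- which(diff(mk$position) > 1)
  stopifnot(length(gaps) >= 15)
  picked <- sort(sample(gaps, 15))
  kinds <- rep(c("duplication", "deletion"), c(10, 5))
  seqs <- character(0)
  counter <- 0
  for (t in 1:15) {
    anchor <- mk$position[picked[t]] +
      (mk$position[picked[t] + 1] - mk$position[picked[t]]) %/% 2
    template <- generate_recombinant(pan$panel_a[1], pan$panel_b[1],
                                     c(anchor, anchor + 1), kinds[t])
    n_members <- if (kinds[t] == "duplication") 5 else 4  # 50 dup + 20 del
    for (m in seq_len(n_members)) {
      counter <- counter + 1
      seqs[sprintf("S%03d", counter)] <- template$sequence
    }
  }
  bp <- map_breakpoints(seqs, mk)
  grp <- group_by_pattern(bp, seqs)
  expect_equal(nrow(grp), 15)
  expect_true(all(grp$consensus_identical))
  expect_equal(sum(grp$n[grp$kind == "duplication"]), 50)
  expect_equal(sum(grp$n[grp$kind == "deletion"]), 20)
})

test_that("motif scanning matches hand-checked and degenerate cases", {
  expect_equal(scan_motif("TTCCACCGTAACCGCTT"), 2L)
  expect_equal(scan_motif(paste(rep("ATG", 20), collapse = "")),
               integer(0))
  expect_error(scan_motif("ACGT", motif = "CCXCC"), "IUPAC")
  both <- scan_motif("TTCCACCGTAACCGCTT", strand = "both")
  expect_true(all(both$offset[both$strand == "+"] == 2L))
})

test_that("motif scanning equals the sliding-window brute force", {
  set.seed(71)
  seqs <- c(random_dna(10000),
            vapply(1:20, function(i) random_dna(500), character(1)))
  for (s in seqs) {
    expect_identical(scan_motif(s), oracle_scan_motif(s, PRDM9_MOTIF))
  }
  # and for a second, unrelated degenerate motif
  expect_identical(scan_motif(seqs[1], motif = "RYSWKM"),
                   oracle_scan_motif(seqs[1], "RYSWKM"))
})

test_that("region spans aggregate to the printed overall stretch", {
  regions <- tibble::tibble(start = c(31388981, 31390000, 31389500),
                            end = c(31389200, 31391803, 31390100))
  span <- aggregate_span(regions)
  expect_equal(span$start, 31388981)
  expect_equal(span$end, 31391803)
  expect_equal(span$width, 2822)
  one <- aggregate_span(tibble::tibble(start = 10, end = 25))
  expect_equal(one$width, 15)
  set.seed(3)
  st <- sample(1e5, 50)
  en <- st + sample(1000, 50)
  rs <- tibble::tibble(start = st, end = en)
  expect_equal(aggregate_span(rs)$width, max(en) - min(st))
  expect_error(aggregate_span(tibble::tibble(start = 1, end = 2,
                                             coord = c("rel")) |>
                                rbind(tibble::tibble(start = 1, end = 2,
                                                     coord = "genomic"))),
               "mixed")
})
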