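# Independent oracles and random-instance generators. These deliberately
# re-derive each quantity with straightforward loop-based code, separate
# from the package's implementation paths.

# -- ratio profile ----------------------------------------------------------

oracle_ratio_profile <- function(record) {
  amps <- c("exon2", "exon3", "exon45")
  r <- numeric(3)
  for (i in seq_along(amps)) {
    a <- record$read_count[record$gene == "MICA" &
                             record$amplicon == amps[i]]
    b <- record$read_count[record$gene == "MICB" &
                             record$amplicon == amps[i]]
    r[i] <- a / b
  }
  m <- sum(r) / 3
  s <- sqrt(sum((r - m)^2) / 2)  # n - 1 denominator, spelled out
  list(ratios = r, mean = m, sd = s)
}

random_count_record <- function(sample_id = "S1") {
  tibble::tibble(
    sample_id = sample_id,
    gene = rep(c("MICA", "MICB"), each = 3),
    amplicon = rep(c("exon2", "exon3", "exon45"), 2),
    read_count = sample(100:5000, 6, replace = TRUE))
}

# classify one profile exactly as the published rules read
oracle_classify <- function(mean_ratio, hemi = 0.53, dup = 1.045,
                            low = 0.1) {
  if (mean_ratio < low) return("below_hemizygous")
  if (mean_ratio < hemi) return("hemizygous")
  if (mean_ratio >= dup) return("duplication")
  "diploid"
}

# -- EAG phasing ------------------------------------------------------------

# Exhaustive enumeration over all multisets of 1..3 distinct alleles,
# written as plain index loops with no pruning.
oracle_phase <- function(observed_sets, db) {
  n <- nrow(db)
  eag_cols <- c(exon2 = "eag_exon2", exon3 = "eag_exon3",
                exon45 = "eag_exon45")
  consistent_set <- function(idx) {
    for (amp in names(eag_cols)) {
      got <- unique(db[[eag_cols[amp]]][idx])
      want <- observed_sets[[amp]]
      if (length(got) != length(want) || !all(sort(got) == sort(want))) {
        return(FALSE)
      }
    }
    TRUE
  }
  out <- list()
  for (i in seq_len(n)) {
    if (consistent_set(i)) out <- c(out, list(sort(db$allele_name[i])))
    if (i < n) {
      for (j in (i + 1):n) {
        if (consistent_set(c(i, j))) {
          out <- c(out, list(sort(db$allele_name[c(i, j)])))
        }
        if (j < n) {
          for (k in (j + 1):n) {
            if (consistent_set(c(i, j, k))) {
              out <- c(out, list(sort(db$allele_name[c(i, j, k)])))
            }
          }
        }
      }
    }
  }
  out
}

random_allele_db <- function(n_alleles, n_eags_per_amplicon = 4) {
  tibble::tibble(
    allele_name = sprintf("MICA*%03d", seq_len(n_alleles)),
    eag_exon2 = sample(sprintf("e2_%d", seq_len(n_eags_per_amplicon)),
                       n_alleles, replace = TRUE),
    eag_exon3 = sample(sprintf("e3_%d", seq_len(n_eags_per_amplicon)),
                       n_alleles, replace = TRUE),
    eag_exon45 = sample(sprintf("e45_%d", seq_len(n_eags_per_amplicon)),
                        n_alleles, replace = TRUE))
}

# Induce the EAG observation a given allele multiset would produce
induce_observation <- function(db, alleles) {
  idx <- match(alleles, db$allele_name)
  mk <- function(col) {
    eags <- unique(db[[col]][idx])
    stats::setNames(rep(500, length(eags)), eags)
  }
  eag_observation(mk("eag_exon2"), mk("eag_exon3"), mk("eag_exon45"))
}

# strip candidates to comparable canonical form (sorted distinct alleles)
canonical_candidates <- function(multisets) {
  keys <- vapply(multisets, function(m) paste(sort(unique(m)),
                                              collapse = "|"),
                 character(1))
  sort(unique(keys))
}

# -- motif scan -------------------------------------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_scan_motif <- function(sequence, motif) {
  s <- strsplit(toupper(sequence), "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  hits <- integer(0)
  if (length(s) < length(m)) return(hits)
  for (off in 0:(length(s) - length(m))) {
    ok <- TRUE
    for (i in seq_along(m)) {
      if (!s[off + i] %in% IUPAC_SETS[[m[i]]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# -- marker SNPs ------------------------------------------------------------

oracle_markers <- function(panel_a, panel_b) {
  ma <- do.call(rbind, strsplit(panel_a, ""))
  mb <- do.call(rbind, strsplit(panel_b, ""))
  pos <- integer(0)
  base_a <- character(0)
  base_b <- character(0)
  for (p in seq_len(ncol(ma))) {
    ca <- unique(ma[, p])
    cb <- unique(mb[, p])
    if (length(ca) == 1 && length(cb) == 1 && ca != cb &&
        ca %in% c("A", "C", "G", "T") && cb %in% c("A", "C", "G", "T")) {
      pos <- c(pos, p - 1L)
      base_a <- c(base_a, ca)
      base_b <- c(base_b, cb)
    }
  }
  tibble::tibble(position = pos, base_a = base_a, base_b = base_b)
}

small_panel_config <- function(seed, length = 400L, n_marker_snps = 5L,
                               diversity = 0) {
  paralog_sim_config(length = length, identity = 0.93,
                     n_marker_snps = n_marker_snps,
                     motif_position_a = 50L, motif_position_b = 50L,
                     ct_repeat_position = 150L, ct_repeat_units = 5L,
                     n_haplotypes_a = 4L, n_haplotypes_b = 3L,
                     intra_paralog_diversity = diversity, seed = seed)
}
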