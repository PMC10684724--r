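# Population frequencies and HLA-B linkage of MICA CNV haplotypes.
#
# CNV carriers are tabulated per self-assigned ethnic group and per
# linked HLA-B allele. Because amplicon genotyping yields no physical
# phase, haplotype frequencies are estimated from population-level
# frequency correlations; here an expectation-maximization estimator
# under random mating (Hardy-Weinberg) stands in for that procedure.

#' Configuration for the synthetic population generator
#'
#' @param groups Tibble with `ethnicity` and `n` (samples per group).
#' @param haplotypes Tibble with `ethnicity`, `haplotype_id`, `hla_b`,
#'   `mica_alleles` (comma-separated; empty string for a deleted MICA),
#'   `cn_contribution` (0, 1 or 2 MICA copies contributed) and
#'   `frequency`. Frequencies must sum to 1 within each ethnicity.
#' @param seed Integer seed.
#' @return Config list of class `population_sim_config`.
#' @export
population_sim_config <- function(groups, haplotypes, seed = 1L) {
  stopifnot(all(c("ethnicity", "n") %in% names(groups)),
            all(c("ethnicity", "haplotype_id", "hla_b", "mica_alleles",
                  "cn_contribution", "frequency") %in% names(haplotypes)))
  if (!all(haplotypes$cn_contribution %in% 0:2)) {
    stop("cn_contribution must be 0, 1 or 2")
  }
  sums <- tapply(haplotypes$frequency, haplotypes$ethnicity, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("haplotype frequencies must sum to 1 within each ethnicity: ",
         paste(names(sums)[abs(sums - 1) > 1e-9], collapse = ", "))
  }
  if (!all(groups$ethnicity %in% haplotypes$ethnicity)) {
    stop("every group needs a haplotype pool")
  }
  structure(list(groups = as_tibble(groups),
                 haplotypes = as_tibble(haplotypes),
                 seed = as.integer(seed)),
            class = "population_sim_config")
}

#' Default synthetic population emulating the cohort structure
#'
#' Six self-assigned ethnic groups with group-specific haplotype pools:
#' a duplication haplotype linked to HLA-B*27:02:01G (frequent in Eastern
#' Europe), deletion haplotypes linked to B*48:01:01G, B*15:16:01G and
#' B*39:06:02G (frequent in Mexican/South American groups), and common
#' two-copy background haplotypes. Haplotype frequencies are chosen so
#' carrier frequencies fall in the ranges reported for the corresponding
#' real populations.
#'
#' @param seed Integer seed.
#' @return A [population_sim_config()].
#' @export
default_population_config <- function(seed = 1L) {
  pool <- function(ethnicity, dup_f, del48_f, del15_f, del39_f) {
    bg <- 1 - dup_f - del48_f - del15_f - del39_f
    tibble(ethnicity = ethnicity,
           haplotype_id = c("dupB27", "delB48", "delB15", "delB39",
                            "bgB07", "bgB08", "bgB44"),
           hla_b = c("B*27:02:01G", "B*48:01:01G", "B*15:16:01G",
                     "B*39:06:02G", "B*07:02:01G", "B*08:01:01G",
                     "B*44:02:01G"),
           mica_alleles = c("MICA*007,MICA*008", "", "", "",
                            "MICA*008", "MICA*008", "MICA*004"),
           cn_contribution = c(2L, 0L, 0L, 0L, 1L, 1L, 1L),
           frequency = c(dup_f, del48_f, del15_f, del39_f,
                         bg * 0.5, bg * 0.3, bg * 0.2))
  }
  haplotypes <- bind_rows(
    pool("DE_German",   0.0045, 0.0010, 0.0005, 0.0000),
    pool("PL_Poland",   0.0131, 0.0010, 0.0005, 0.0000),
    pool("HR_Croatia",  0.0146, 0.0010, 0.0005, 0.0000),
    pool("GB_British",  0.0015, 0.0010, 0.0005, 0.0000),
    pool("US_Mexico",   0.0005, 0.0300, 0.0020, 0.0180),
    pool("CL_Chile",    0.0020, 0.0140, 0.0020, 0.0020))
  groups <- tibble(ethnicity = c("DE_German", "PL_Poland", "HR_Croatia",
                                 "GB_British", "US_Mexico", "CL_Chile"),
                   n = c(6000L, 4000L, 3000L, 4000L, 3000L, 3000L))
  population_sim_config(groups, haplotypes, seed = seed)
}

#' Simulate an unphased population with CNV haplotypes
#'
#' Each sample draws two haplotypes from its group's pool (random
#' mating); the MICA copy number is the sum of the two contributions and
#' genotypes are reported unphased.
#'
#' @param config A [population_sim_config()].
#' @return Tibble with `sample_id`, `ethnicity`, `hla_b_1`, `hla_b_2`
#'   (unordered pair), `mica_alleles` (comma-joined multiset),
#'   `copy_number_call` and truth columns `true_hap_1`, `true_hap_2`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_sim_config"))
  set.seed(config$seed)
  out <- vector("list", nrow(config$groups))
  offset <- 0L
  for (g in seq_len(nrow(config$groups))) {
    eth <- config$groups$ethnicity[g]
    n <- config$groups$n[g]
    pool <- config$haplotypes[config$haplotypes$ethnicity == eth, ]
    h1 <- sample(nrow(pool), n, replace = TRUE, prob = pool$frequency)
    h2 <- sample(nrow(pool), n, replace = TRUE, prob = pool$frequency)
    mica <- mapply(function(i, j) {
      alleles <- c(strsplit(pool$mica_alleles[i], ",")[[1]],
                   strsplit(pool$mica_alleles[j], ",")[[1]])
      paste(sort(alleles), collapse = ",")
    }, h1, h2)
    out[[g]] <- tibble(
      sample_id = sprintf("P%06d", offset + seq_len(n)),
      ethnicity = eth,
      hla_b_1 = pool$hla_b[h1],
      hla_b_2 = pool$hla_b[h2],
      mica_alleles = unname(mica),
      copy_number_call = pool$cn_contribution[h1] +
        pool$cn_contribution[h2],
      true_hap_1 = pool$haplotype_id[h1],
      true_hap_2 = pool$haplotype_id[h2])
    offset <- offset + n
  }
  bind_rows(out)
}

cnv_class_to_cn <- function(class) {
  cn <- c(hemizygous = 1L, diploid = 2L, duplication = 3L)[class]
  if (is.na(cn)) {
    stop("unknown CNV class: ", class,
         " (expected hemizygous, diploid or duplication)")
  }
  cn
}

#' Per-ethnicity sample population frequencies of a CNV class
#'
#' Carrier (sample-level) frequencies per self-assigned ethnic group;
#' groups at or below `min_n` samples are suppressed (strictly greater
#' than `min_n` is required for reporting) but listed with a reason.
#'
#' @param records Population records (see [generate_population()]).
#' @param class `"hemizygous"`, `"diploid"` or `"duplication"`.
#' @param min_n Minimum group size for reporting (default 2500,
#'   exclusive).
#' @return Tibble with `ethnicity`, `n`, `carriers`, `frequency`,
#'   `suppressed`, `reason`.
#' @export
population_frequencies <- function(records, class, min_n = 2500L) {
  if (is.null(records) || nrow(records) == 0L) stop("no records")
  cn <- cnv_class_to_cn(class)
  eth <- sort(unique(records$ethnicity))
  rows <- lapply(eth, function(e) {
    sub <- records[records$ethnicity == e, ]
    carriers <- sum(sub$copy_number_call == cn)
    suppressed <- nrow(sub) <= min_n
    tibble(ethnicity = e, n = nrow(sub), carriers = carriers,
           frequency = carriers / nrow(sub), suppressed = suppressed,
           reason = if (suppressed) {
             sprintf("group size %d <= min_n %d", nrow(sub), min_n)
           } else {
             ""
           })
  })
  bind_rows(rows)
}

#' HLA-B linkage table for a CNV class
#'
#' For each HLA-B allele: the number of class carriers carrying the
#' allele, that count as a fraction of all class carriers, and the
#' fraction of all allele carriers that are in the class (the linkage).
#' Rows are included when the linkage is at least `min_linkage` and the
#' allele is seen in at least `min_samples` genotyped samples; remaining
#' carriers are aggregated into an `Other` row so the fraction column
#' totals 1. Percent columns are rounded for table display; the fraction
#' columns keep full precision.
#'
#' @param records Population records with `hla_b_1`/`hla_b_2`.
#' @param class CNV class (see [population_frequencies()]).
#' @param min_linkage Minimum fraction of allele carriers in the class
#'   (default 0.5).
#' @param min_samples Minimum genotyped allele carriers (default 10).
#' @param haplotype_col Optional name of a column holding per-sample
#'   haplotype strings; if present, the most frequent haplotypes among
#'   carriers are tabulated as well.
#' @return List with `alleles` (tibble incl. `Other` and `Total` rows)
#'   and `haplotypes` (tibble or `NULL`).
#' @export
linkage_table <- function(records, class, min_linkage = 0.5,
                          min_samples = 10L, haplotype_col = NULL) {
  cn <- cnv_class_to_cn(class)
  carriers <- records[records$copy_number_call == cn, ]
  n_carriers <- nrow(carriers)
  if (n_carriers == 0L) stop("no carriers of class ", class)

  has_allele <- function(df, allele) {
    df$hla_b_1 == allele | df$hla_b_2 == allele
  }
  alleles <- sort(unique(c(carriers$hla_b_1, carriers$hla_b_2)))
  rows <- lapply(alleles, function(a) {
    n_with <- sum(has_allele(carriers, a))
    n_total <- sum(has_allele(records, a))
    tibble(hla_b = a, n_carriers_with_allele = n_with,
           fraction_of_cnv_carriers = n_with / n_carriers,
           n_allele_carriers = n_total,
           fraction_of_allele_carriers_with_cnv = n_with / n_total)
  })
  tab <- bind_rows(rows)
  keep <- tab$fraction_of_allele_carriers_with_cnv >= min_linkage &
    tab$n_allele_carriers >= min_samples
  kept <- tab[keep, ]
  kept <- kept[order(-kept$n_carriers_with_allele), ]

  in_listed <- rep(FALSE, n_carriers)
  for (a in kept$hla_b) in_listed <- in_listed | has_allele(carriers, a)
  other <- tibble(hla_b = "Other",
                  n_carriers_with_allele = sum(!in_listed),
                  fraction_of_cnv_carriers = sum(!in_listed) / n_carriers,
                  n_allele_carriers = NA_integer_,
                  fraction_of_allele_carriers_with_cnv = NA_real_)
  total <- tibble(hla_b = "Total",
                  n_carriers_with_allele = n_carriers,
                  fraction_of_cnv_carriers =
                    sum(kept$fraction_of_cnv_carriers) +
                    other$fraction_of_cnv_carriers,
                  n_allele_carriers = NA_integer_,
                  fraction_of_allele_carriers_with_cnv = NA_real_)
  out <- bind_rows(kept, other, total)
  out$pct_of_carriers <- round(100 * out$fraction_of_cnv_carriers)
  out$pct_of_allele_carriers <-
    round(100 * out$fraction_of_allele_carriers_with_cnv)

  haplotypes <- NULL
  if (!is.null(haplotype_col) && haplotype_col %in% names(records)) {
    h <- c(carriers[[haplotype_col]])
    ht <- sort(table(h), decreasing = TRUE)
    haplotypes <- tibble(haplotype = names(ht), n = as.integer(ht),
                         fraction_of_cnv_carriers =
                           as.integer(ht) / n_carriers)
  }
  list(alleles = out, haplotypes = haplotypes)
}

#' EM haplotype-frequency estimation from unphased genotypes
#'
#' Standard expectation-maximization under random mating: each unphased
#' multilocus genotype is expanded into its compatible haplotype pairs;
#' the E step distributes each genotype's count over pairs in proportion
#' to their current pair probabilities (2 f_i f_j, or f_i^2 when
#' homozygous), the M step re-estimates frequencies from the expected
#' haplotype counts. The log-likelihood is non-decreasing. Haplotypes
#' whose estimated frequency falls below `call_threshold` are reported
#' but flagged unresolvable: population-frequency phasing cannot resolve
#' rare haplotypes.
#'
#' @param genotypes Data frame, one column per locus, entries `"X/Y"`
#'   (unordered allele pairs).
#' @param loci Columns to use (default: all columns), in haplotype
#'   order.
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param call_threshold Frequency below which a haplotype is flagged
#'   unresolvable (default 1e-4).
#' @return List with `frequencies` (tibble: `haplotype`, `frequency`,
#'   `resolvable`), `loglik` (trace), `converged`, `n_iter`.
#' @export
estimate_haplotype_frequencies <- function(genotypes,
                                           loci = colnames(genotypes),
                                           tol = 1e-8, max_iter = 1000L,
                                           call_threshold = 1e-4) {
  if (length(loci) < 2L) stop("at least two loci required")
  g <- as.data.frame(genotypes)[loci]
  if (nrow(g) == 0L) stop("no genotypes")
  split_pair <- function(x) {
    p <- strsplit(x, "/", fixed = TRUE)
    if (any(lengths(p) != 2L)) stop("genotype entries must be 'X/Y' pairs")
    p
  }
  pairs <- lapply(g, split_pair)

  # collapse to unique genotype patterns (order within a pair ignored)
  norm <- vapply(seq_len(nrow(g)), function(i) {
    paste(vapply(pairs, function(locus) {
      paste(sort(locus[[i]]), collapse = "/")
    }, character(1)), collapse = ";")
  }, character(1))
  patt <- table(norm)
  patt_counts <- as.numeric(patt)
  patt_geno <- strsplit(names(patt), ";", fixed = TRUE)

  # expand each pattern into compatible unordered haplotype pairs
  expansions <- lapply(patt_geno, function(gt) {
    per_locus <- strsplit(gt, "/", fixed = TRUE)
    het <- vapply(per_locus, function(a) a[1] != a[2], logical(1))
    n_het <- sum(het)
    if (n_het <= 1L) {
      h1 <- vapply(per_locus, `[`, character(1), 1L)
      h2 <- vapply(per_locus, `[`, character(1), 2L)
      return(list(cbind(paste(h1, collapse = "~"),
                        paste(h2, collapse = "~"))))
    }
    het_idx <- which(het)
    # fix the first heterozygous locus to break the pair symmetry
    combos <- expand.grid(rep(list(c(1L, 2L)), n_het - 1L))
    lapply(seq_len(nrow(combos)), function(k) {
      pick <- c(1L, as.integer(combos[k, ]))
      h1 <- vapply(per_locus, `[`, character(1), 1L)
      h2 <- vapply(per_locus, `[`, character(1), 2L)
      h1[het_idx] <- vapply(seq_along(het_idx), function(j) {
        per_locus[[het_idx[j]]][pick[j]]
      }, character(1))
      h2[het_idx] <- vapply(seq_along(het_idx), function(j) {
        per_locus[[het_idx[j]]][3L - pick[j]]
      }, character(1))
      cbind(paste(h1, collapse = "~"), paste(h2, collapse = "~"))
    })
  })
  expansions <- lapply(expansions, function(e) do.call(rbind, e))
  haplotypes <- sort(unique(unlist(expansions)))
  hap_idx <- setNames(seq_along(haplotypes), haplotypes)
  exp_idx <- lapply(expansions, function(e) {
    cbind(hap_idx[e[, 1]], hap_idx[e[, 2]])
  })

  n_chrom <- 2 * sum(patt_counts)
  f <- rep(1 / length(haplotypes), length(haplotypes))
  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    expected <- numeric(length(haplotypes))
    ll <- 0
    for (k in seq_along(exp_idx)) {
      e <- exp_idx[[k]]
      w <- ifelse(e[, 1] == e[, 2], f[e[, 1]]^2,
                  2 * f[e[, 1]] * f[e[, 2]])
      tot <- sum(w)
      ll <- ll + patt_counts[k] * log(tot)
      post <- patt_counts[k] * w / tot
      for (r in seq_len(nrow(e))) {
        expected[e[r, 1]] <- expected[e[r, 1]] + post[r]
        expected[e[r, 2]] <- expected[e[r, 2]] + post[r]
      }
    }
    f <- expected / n_chrom
    loglik <- c(loglik, ll)
    if (iter > 1L) {
      delta <- abs(ll - loglik[iter - 1L]) /
        max(abs(loglik[iter - 1L]), 1e-12)
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning("EM did not converge within ", max_iter,
            " iterations; returning the last iterate")
  }
  list(frequencies = tibble(haplotype = haplotypes, frequency = f,
                            resolvable = f >= call_threshold),
       loglik = loglik, converged = converged, n_iter = length(loglik))
}
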