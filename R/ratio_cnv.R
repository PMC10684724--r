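# Ratio-based MICA copy-number calling.
#
# MICA and MICB are amplified by the same primer pairs in one multiplex
# PCR, so the MICA/MICB read-count ratio per amplicon is a stable proxy
# for MICA copy number (MICB is the two-copy reference). The diploid ratio
# centers at 0.82; hemizygous samples center at 0.41 and three-copy
# samples at 1.27.

#' Quality-control thresholds for ratio-based calling
#'
#' Samples are excluded when any of the six read counts is below
#' `min_coverage` or the standard deviation of the three per-amplicon
#' ratios exceeds `max_sd` (uneven PCR amplification). Both comparisons
#' are strict, so a coverage of exactly 100 and an sd of exactly 0.3 pass.
#'
#' @param min_coverage Minimum read coverage per amplicon (default 100).
#' @param max_sd Maximum ratio standard deviation (default 0.3).
#' @export
qc_thresholds <- function(min_coverage = 100, max_sd = 0.3) {
  stopifnot(min_coverage > 0, max_sd > 0)
  structure(list(min_coverage = min_coverage, max_sd = max_sd),
            class = "qc_thresholds")
}

#' Classification thresholds for ratio-based calling
#'
#' A mean MICA/MICB ratio below `hemizygous_below` (default 0.53) calls a
#' hemizygous (one-copy) sample; at or above `duplication_at_or_above`
#' calls a duplication (three copies). The duplication default is the
#' midpoint of the diploid and three-copy ratio centers,
#' (0.82 + 1.27) / 2 = 1.045. Ratios below `below_hemizygous_under`
#' (default 0.1) are flagged separately rather than called hemizygous:
#' they suggest total MICA loss, which the ratio method does not resolve.
#'
#' @param hemizygous_below Upper (exclusive) bound for hemizygous calls.
#' @param duplication_at_or_above Lower (inclusive) bound for duplication
#'   calls.
#' @param below_hemizygous_under Bound under which a sample is flagged
#'   `below_hemizygous` instead.
#' @param centers Reference ratio centers for reporting, copy numbers
#'   1, 2 and 3.
#' @export
class_thresholds <- function(hemizygous_below = 0.53,
                             duplication_at_or_above = 1.045,
                             below_hemizygous_under = 0.1,
                             centers = c(0.41, 0.82, 1.27)) {
  stopifnot(hemizygous_below < duplication_at_or_above,
            below_hemizygous_under < hemizygous_below)
  structure(list(hemizygous_below = hemizygous_below,
                 duplication_at_or_above = duplication_at_or_above,
                 below_hemizygous_under = below_hemizygous_under,
                 centers = centers),
            class = "class_thresholds")
}

#' Compute the per-amplicon MICA/MICB ratio profile of one sample
#'
#' @param record Data frame with columns `gene`, `amplicon`, `read_count`
#'   holding the six count cells of one sample.
#' @param sd_fun Estimator for the ratio spread; default [stats::sd()]
#'   (sample standard deviation, n - 1 denominator).
#' @return List with `per_amplicon_ratio` (named length-3 vector),
#'   `mean_ratio` and `sd_ratio`.
#' @export
compute_ratios <- function(record, sd_fun = stats::sd) {
  counts <- count_matrix(record)
  zero_b <- AMPLICONS[counts["MICB", ] == 0]
  if (length(zero_b)) {
    stop("MICB read count is zero in amplicon ",
         paste(zero_b, collapse = ", "), "; ratio undefined")
  }
  r <- counts["MICA", ] / counts["MICB", ]
  list(per_amplicon_ratio = r, mean_ratio = mean(r), sd_ratio = sd_fun(r))
}

count_matrix <- function(record) {
  stopifnot(all(c("gene", "amplicon", "read_count") %in% names(record)))
  if (nrow(record) != 6L ||
      any(table(record$gene, record$amplicon) != 1L)) {
    stop("record must contain exactly one count per gene x amplicon cell")
  }
  m <- matrix(NA_real_, 2, 3, dimnames = list(GENES, AMPLICONS))
  m[cbind(record$gene, record$amplicon)] <- record$read_count
  m
}

#' Apply coverage and ratio-dispersion quality control to one sample
#'
#' @param record Six-cell count record (see [compute_ratios()]).
#' @param profile Ratio profile from [compute_ratios()], or `NULL` when a
#'   zero MICB count makes the profile undefined (coverage then fails).
#' @param thresholds A [qc_thresholds()].
#' @return List with `pass` (logical) and `reasons` (character).
#' @export
qc_filter <- function(record, profile, thresholds = qc_thresholds()) {
  counts <- count_matrix(record)
  reasons <- character(0)
  if (any(counts < thresholds$min_coverage)) {
    reasons <- c(reasons, sprintf("coverage < %g in at least one amplicon",
                                  thresholds$min_coverage))
  }
  if (!is.null(profile) && profile$sd_ratio > thresholds$max_sd) {
    reasons <- c(reasons, sprintf("ratio sd %.3g > %g", profile$sd_ratio,
                                  thresholds$max_sd))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Classify MICA copy number from a ratio profile
#'
#' Mean ratio below the hemizygous threshold calls one copy, at or above
#' the duplication threshold calls three, otherwise two. Samples whose
#' amplicon genotyping already detected two distinct MICA alleles cannot
#' be hemizygous; a low ratio there is excluded as discordant rather than
#' called (mirroring the production exclusion of heterozygous results).
#'
#' @param profile Ratio profile from [compute_ratios()].
#' @param thresholds A [class_thresholds()].
#' @param genotype_hint Optional: `"heterozygous"` if independent
#'   genotyping detected two distinct MICA alleles, else
#'   `"homozygous"`/`NULL`.
#' @return List with `call` (one of `hemizygous`, `diploid`,
#'   `duplication`, `below_hemizygous`, `excluded_heterozygous`) and
#'   `reasons`.
#' @export
classify_copy_number <- function(profile, thresholds = class_thresholds(),
                                 genotype_hint = NULL) {
  m <- profile$mean_ratio
  if (m < thresholds$below_hemizygous_under) {
    return(list(call = "below_hemizygous",
                reasons = "mean ratio near zero; possible total MICA loss"))
  }
  if (m < thresholds$hemizygous_below) {
    if (identical(genotype_hint, "heterozygous")) {
      return(list(call = "excluded_heterozygous",
                  reasons = "low ratio but two distinct alleles genotyped"))
    }
    return(list(call = "hemizygous", reasons = character(0)))
  }
  if (m >= thresholds$duplication_at_or_above) {
    return(list(call = "duplication", reasons = character(0)))
  }
  list(call = "diploid", reasons = character(0))
}

#' Call MICA copy number across a cohort
#'
#' Vectorized cohort version of [compute_ratios()], [qc_filter()] and
#' [classify_copy_number()]; per-record and cohort paths agree exactly.
#'
#' @param counts Long tibble (`sample_id`, `gene`, `amplicon`,
#'   `read_count`) with six cells per sample.
#' @param qc A [qc_thresholds()].
#' @param cls A [class_thresholds()].
#' @param genotype_hints Optional tibble (`sample_id`, `heterozygous`
#'   logical).
#' @return List with `calls` (tibble: `sample_id`, `call`, `mean_ratio`,
#'   `sd_ratio`, `reasons`) and `summary` (see
#'   [summarize_class_counts()]).
#' @export
call_cohort <- function(counts, qc = qc_thresholds(),
                        cls = class_thresholds(), genotype_hints = NULL) {
  if (is.null(counts) || nrow(counts) == 0L) stop("empty count table")
  key <- paste(counts$gene, counts$amplicon, sep = ".")
  cells <- table(counts$sample_id, key)
  if (any(cells != 1L)) {
    off <- rownames(cells)[apply(cells != 1L, 1, any)]
    stop("every sample needs exactly one count per gene x amplicon cell; ",
         "offending sample(s): ", paste(head(off, 5), collapse = ", "))
  }
  wide <- tapply(counts$read_count, list(counts$sample_id, key), identity)
  wide <- wide[, paste(rep(GENES, each = 3), AMPLICONS, sep = "."),
               drop = FALSE]
  a <- wide[, paste("MICA", AMPLICONS, sep = "."), drop = FALSE]
  b <- wide[, paste("MICB", AMPLICONS, sep = "."), drop = FALSE]

  cov_fail <- apply(wide < qc$min_coverage, 1, any)
  zero_b <- apply(b == 0, 1, any)
  if (any(zero_b & !cov_fail)) {
    stop("MICB read count is zero in a sample passing the coverage filter: ",
         paste(head(rownames(wide)[zero_b & !cov_fail], 5), collapse = ", "))
  }
  ratio <- a / b  # NaN/Inf only in coverage-failed rows
  mean_ratio <- rowMeans(ratio)
  sd_ratio <- apply(ratio, 1, sd)
  sd_fail <- !is.na(sd_ratio) & sd_ratio > qc$max_sd

  het <- rep(FALSE, nrow(wide))
  if (!is.null(genotype_hints)) {
    het <- rownames(wide) %in%
      genotype_hints$sample_id[genotype_hints$heterozygous]
  }

  call <- character(nrow(wide))
  reasons <- character(nrow(wide))
  qc_fail <- cov_fail | sd_fail
  call[qc_fail] <- "qc_fail"
  reasons[qc_fail] <- paste0(
    ifelse(cov_fail[qc_fail], "coverage;", ""),
    ifelse(sd_fail[qc_fail], "ratio sd;", ""))
  ok <- !qc_fail
  m <- mean_ratio
  call[ok & m < cls$below_hemizygous_under] <- "below_hemizygous"
  hemi <- ok & m >= cls$below_hemizygous_under & m < cls$hemizygous_below
  call[hemi & !het] <- "hemizygous"
  call[hemi & het] <- "excluded_heterozygous"
  reasons[hemi & het] <- "low ratio but two distinct alleles genotyped"
  call[ok & m >= cls$hemizygous_below & m < cls$duplication_at_or_above] <-
    "diploid"
  call[ok & m >= cls$duplication_at_or_above] <- "duplication"

  calls <- tibble(sample_id = rownames(wide), call = call,
                  mean_ratio = unname(ifelse(qc_fail & !is.finite(m),
                                             NA_real_, m)),
                  sd_ratio = unname(ifelse(is.finite(sd_ratio), sd_ratio,
                                           NA_real_)),
                  reasons = reasons)
  list(calls = calls,
       summary = summarize_class_counts(table(calls$call)))
}

#' Summarize copy-number class counts into cohort fractions
#'
#' Computes the cohort summary from class counts alone, so printed cohort
#' tallies can be turned into the same fractions the cohort caller
#' reports. The QC-pass denominator excludes both `qc_fail` and
#' `excluded_heterozygous` samples (heterozygous-discordant samples are
#' removed before the pass tally, as in the production workflow); class
#' fractions are percentages of QC-pass samples, and `pct_of_processed`
#' uses all processed samples as denominator.
#'
#' @param class_counts Named vector of per-class sample counts (may
#'   include `qc_fail` and `excluded_heterozygous`).
#' @param n_processed Total samples processed; defaults to
#'   `sum(class_counts)`.
#' @return List with `n_processed`, `n_qc_pass`, `qc_pass_rate_pct` and a
#'   `classes` tibble (`class`, `n`, `pct_of_qc_pass`,
#'   `pct_of_processed`).
#' @export
summarize_class_counts <- function(class_counts,
                                   n_processed = sum(class_counts)) {
  cc <- c(class_counts)
  cc <- setNames(as.numeric(cc), names(class_counts))
  if (any(cc < 0) || is.null(names(cc))) {
    stop("class_counts must be a named vector of non-negative counts")
  }
  n_qc_pass <- sum(cc[setdiff(names(cc),
                              c("qc_fail", "excluded_heterozygous"))])
  classes <- tibble(class = names(cc), n = unname(cc),
                    pct_of_qc_pass = 100 * unname(cc) / n_qc_pass,
                    pct_of_processed = 100 * unname(cc) / n_processed)
  list(n_processed = n_processed, n_qc_pass = n_qc_pass,
       qc_pass_rate_pct = 100 * n_qc_pass / n_processed,
       classes = classes)
}
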