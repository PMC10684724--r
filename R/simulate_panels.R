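# Synthetic segmental-duplication panels.
#
# The real substrate is a ~30 kb segmental duplication upstream of MICA and
# upstream of MICB at ~93% sequence identity. Recombination between the two
# copies (NAHR) creates MICA duplication and deletion haplotypes. The
# generator emulates: two aligned haplotype panels with planted
# paralog-diagnostic marker SNPs, a CT dinucleotide repeat, the PRDM9
# hotspot motif, shared (non-diagnostic) background divergence, and
# within-panel diversity.

#' Configuration for the paralog haplotype-panel simulator
#'
#' @param length Aligned length of the simulated region in bases
#'   (default 30000, the approximate length of the real segmental
#'   duplication).
#' @param identity Fraction of identical columns between the two paralog
#'   root sequences (default 0.93).
#' @param n_marker_snps Number of planted paralog-exclusive marker columns.
#' @param motif_position_a,motif_position_b 0-based offsets at which the
#'   PRDM9 hotspot motif 5'-CCNCCNTNNCCNC-3' is planted in each panel. The
#'   default 1969 is the offset of the real upstream-MICA motif occurrence
#'   relative to the region origin used for reporting.
#' @param ct_repeat_position 0-based offset of a planted CT dinucleotide
#'   repeat (default 936, matching the real repeat's offset).
#' @param ct_repeat_units Number of CT units (default 20).
#' @param n_haplotypes_a,n_haplotypes_b Panel sizes (defaults 37 and 34,
#'   the sizes of the curated upstream-MICA and upstream-MICB haplotype
#'   panels).
#' @param intra_paralog_diversity Per-base substitution probability among
#'   haplotypes of the same paralog (never applied to planted marker,
#'   motif or repeat columns).
#' @param seed Integer seed.
#' @return A validated config list of class `paralog_sim_config`.
#' @export
paralog_sim_config <- function(length = 30000L,
                               identity = 0.93,
                               n_marker_snps = 40L,
                               motif_position_a = 1969L,
                               motif_position_b = 1969L,
                               ct_repeat_position = 936L,
                               ct_repeat_units = 20L,
                               n_haplotypes_a = 37L,
                               n_haplotypes_b = 34L,
                               intra_paralog_diversity = 0.001,
                               seed = 1L) {
  stopifnot(length > 0, identity > 0, identity <= 1,
            n_marker_snps >= 0, n_haplotypes_a >= 2, n_haplotypes_b >= 2,
            intra_paralog_diversity >= 0, intra_paralog_diversity < 1,
            ct_repeat_units >= 1)
  motif_len <- nchar(PRDM9_MOTIF)
  if (motif_position_a + motif_len > length ||
      motif_position_b + motif_len > length) {
    stop("motif footprint extends past the sequence end")
  }
  if (ct_repeat_position + 2L * ct_repeat_units > length) {
    stop("CT repeat footprint extends past the sequence end")
  }
  structure(list(length = as.integer(length), identity = identity,
                 n_marker_snps = as.integer(n_marker_snps),
                 motif_position_a = as.integer(motif_position_a),
                 motif_position_b = as.integer(motif_position_b),
                 ct_repeat_position = as.integer(ct_repeat_position),
                 ct_repeat_units = as.integer(ct_repeat_units),
                 n_haplotypes_a = as.integer(n_haplotypes_a),
                 n_haplotypes_b = as.integer(n_haplotypes_b),
                 intra_paralog_diversity = intra_paralog_diversity,
                 seed = as.integer(seed)),
            class = "paralog_sim_config")
}

#' The PRDM9 recombination hotspot motif (IUPAC)
#' @export
PRDM9_MOTIF <- "CCNCCNTNNCCNC"

other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
}

#' Simulate two aligned paralog haplotype panels with planted markers
#'
#' Builds a shared ancestral sequence, derives a panel-A and a panel-B root
#' that differ at exactly the planted marker columns plus background
#' divergence columns (to the configured overall identity), plants the
#' hotspot motif and a CT repeat, then adds within-panel diversity. At
#' every planted marker column all A-haplotypes share one base and all
#' B-haplotypes share a different base. Background divergence columns are
#' deliberately made non-diagnostic: at each one, at least one haplotype
#' carries the other paralog's base, so only the planted markers are
#' paralog-exclusive.
#'
#' @param config A [paralog_sim_config()].
#' @return List with `panel_a`, `panel_b` (named character vectors of
#'   aligned sequences), `markers` (tibble: `position` 0-based, `base_a`,
#'   `base_b`) and the `config`.
#' @export
generate_paralog_panels <- function(config) {
  stopifnot(inherits(config, "paralog_sim_config"))
  set.seed(config$seed)
  L <- config$length
  motif_len <- nchar(PRDM9_MOTIF)

  protected <- unique(c(
    config$motif_position_a + seq_len(motif_len) - 1L,
    config$motif_position_b + seq_len(motif_len) - 1L,
    config$ct_repeat_position +
      seq_len(2L * config$ct_repeat_units) - 1L)) + 1L  # 1-based

  ancestral <- sample(DNA_BASES, L, replace = TRUE)
  repeat_seq <- rep(c("C", "T"), config$ct_repeat_units)
  ancestral[config$ct_repeat_position + seq_along(repeat_seq)] <- repeat_seq
  # one motif instantiation (N drawn randomly), planted in both roots
  motif_chars <- strsplit(PRDM9_MOTIF, "")[[1]]
  motif_inst <- ifelse(motif_chars == "N",
                       sample(DNA_BASES, motif_len, replace = TRUE),
                       motif_chars)

  root_a <- ancestral
  root_a[config$motif_position_a + seq_len(motif_len)] <- motif_inst
  root_b <- ancestral
  root_b[config$motif_position_b + seq_len(motif_len)] <- motif_inst

  # divergence budget between the two roots
  n_div <- round((1 - config$identity) * L)
  free <- setdiff(seq_len(L), protected)
  if (config$n_marker_snps > length(free)) {
    stop("n_marker_snps exceeds the number of available positions")
  }
  if (n_div < config$n_marker_snps) {
    stop("divergence budget (1 - identity) smaller than n_marker_snps")
  }
  div_pos <- sort(sample(free, n_div))
  marker_pos <- sort(sample(div_pos, config$n_marker_snps))
  background_pos <- setdiff(div_pos, marker_pos)
  root_b[div_pos] <- other_base(root_b[div_pos])

  untouched <- unique(c(protected, marker_pos))  # never mutated within panels
  mutate_panel <- function(root, n_hap, prefix) {
    seqs <- character(n_hap)
    for (i in seq_len(n_hap)) {
      h <- root
      if (config$intra_paralog_diversity > 0) {
        hit <- which(runif(L) < config$intra_paralog_diversity)
        hit <- setdiff(hit, untouched)
        if (length(hit)) h[hit] <- other_base(h[hit])
      }
      seqs[i] <- paste(h, collapse = "")
    }
    names(seqs) <- sprintf("%s_hap%02d", prefix, seq_len(n_hap))
    seqs
  }
  panel_a <- mutate_panel(root_a, config$n_haplotypes_a, "upstreamMICA")
  panel_b <- mutate_panel(root_b, config$n_haplotypes_b, "upstreamMICB")

  # background divergence is shared polymorphism, not paralog-exclusive:
  # plant the opposite paralog's base in one randomly chosen haplotype
  if (length(background_pos)) {
    a_mat <- do.call(rbind, strsplit(panel_a, ""))
    b_mat <- do.call(rbind, strsplit(panel_b, ""))
    for (p in background_pos) {
      if (runif(1) < 0.5) {
        i <- sample(nrow(a_mat), 1L)
        a_mat[i, p] <- root_b[p]
      } else {
        i <- sample(nrow(b_mat), 1L)
        b_mat[i, p] <- root_a[p]
      }
    }
    panel_a <- setNames(apply(a_mat, 1, paste, collapse = ""), names(panel_a))
    panel_b <- setNames(apply(b_mat, 1, paste, collapse = ""), names(panel_b))
  }

  markers <- tibble(position = marker_pos - 1L,
                    base_a = root_a[marker_pos],
                    base_b = root_b[marker_pos])
  list(panel_a = panel_a, panel_b = panel_b, markers = markers,
       config = config)
}

#' Generate a recombinant consensus sequence with a known crossover
#'
#' Emulates a single NAHR crossover between one upstream-MICA and one
#' upstream-MICB haplotype. A duplication-type recombinant starts with
#' B-derived sequence and switches to A-derived sequence at the crossover;
#' a deletion-type recombinant is the mirror image.
#'
#' @param hap_a,hap_b Aligned sequences (equal length) from panels A and B.
#' @param crossover_interval 0-based interval `c(start, end)` with
#'   `end > start`; the crossover point is drawn uniformly from
#'   `(start, end]`, i.e. the prefix covers columns `0..p-1`. An interval
#'   `c(k, k + 1)` forces the switch exactly at boundary `k`.
#' @param kind `"duplication"` (B prefix, A suffix) or `"deletion"`
#'   (A prefix, B suffix).
#' @param seed Optional integer seed for the crossover draw.
#' @return List with `sequence`, `crossover` (the 0-based point `p`: the
#'   first column taken from the suffix donor) and `kind`.
#' @export
generate_recombinant <- function(hap_a, hap_b, crossover_interval,
                                 kind = c("duplication", "deletion"),
                                 seed = NULL) {
  kind <- match.arg(kind)
  L <- nchar(hap_a)
  if (nchar(hap_b) != L) stop("haplotypes must be aligned to equal length")
  start <- crossover_interval[1]
  end <- crossover_interval[2]
  if (end <= start) stop("crossover interval must have positive width")
  if (start < 0 || end > L) stop("crossover interval outside sequence bounds")
  if (!is.null(seed)) set.seed(seed)
  p <- if (end - start == 1) start + 1L else sample((start + 1L):end, 1L)
  prefix_donor <- if (kind == "duplication") hap_b else hap_a
  suffix_donor <- if (kind == "duplication") hap_a else hap_b
  seq <- paste0(substr(prefix_donor, 1L, p), substr(suffix_donor, p + 1L, L))
  list(sequence = seq, crossover = as.integer(p), kind = kind)
}
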