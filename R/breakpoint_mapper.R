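# NAHR breakpoint mapping from paralog-specific marker SNPs.
#
# In an alignment of upstream-MICA and upstream-MICB haplotype panels, a
# marker SNP is a column where every A-panel haplotype carries one base
# and every B-panel haplotype carries a different base. Along a
# recombinant consensus sequence, the ordered marker states reveal the
# donor paralog of each segment; a duplication-type recombinant starts in
# the B state and switches once to A, a deletion-type the other way
# around. The crossover is bounded by the last marker of the 5' paralog
# state and the first marker of the 3' paralog state.

#' Find paralog-specific marker SNPs in two aligned haplotype panels
#'
#' Returns exactly the alignment columns where all panel-A sequences agree
#' on one base, all panel-B sequences agree on a different base, and no
#' gap or ambiguity code occurs (only A/C/G/T columns qualify).
#'
#' @param panel_a,panel_b Character vectors of aligned sequences (equal
#'   aligned length across both panels).
#' @param origin Offset added to the 0-based column index for reporting
#'   (default 0: relative coordinates; pass a genomic origin to report
#'   genomic positions).
#' @return Tibble with `position` (0-based plus `origin`), `base_a`,
#'   `base_b`, ordered by position.
#' @export
find_marker_snps <- function(panel_a, panel_b, origin = 0L) {
  if (length(panel_a) == 0L || length(panel_b) == 0L) {
    stop("both panels must be non-empty")
  }
  lens <- unique(nchar(c(panel_a, panel_b)))
  if (length(lens) != 1L) stop("all sequences must have equal aligned length")
  ma <- do.call(rbind, strsplit(toupper(panel_a), ""))
  mb <- do.call(rbind, strsplit(toupper(panel_b), ""))
  uniform <- function(m) {
    base <- m[1, ]
    ok <- colSums(m != matrix(base, nrow(m), ncol(m), byrow = TRUE)) == 0L
    list(ok = ok, base = base)
  }
  ua <- uniform(ma)
  ub <- uniform(mb)
  keep <- ua$ok & ub$ok & ua$base != ub$base &
    ua$base %in% DNA_BASES & ub$base %in% DNA_BASES
  tibble(position = which(keep) - 1L + as.integer(origin),
         base_a = ua$base[keep], base_b = ub$base[keep])
}

#' Classify a recombinant consensus by its marker-state pattern
#'
#' Assigns each marker position the state `A` (consensus carries the
#' A-panel base), `B` (B-panel base) or `other` (neither; private variant
#' or error). States other than A/B are ignored for switch detection but
#' retained in the pattern. A single B-to-A switch classifies the
#' consensus as a duplication-type recombinant, a single A-to-B switch as
#' deletion-type, a uniform pattern as non-recombinant, and more than one
#' switch as complex.
#'
#' @param consensus One consensus sequence aligned to the panel
#'   coordinates.
#' @param markers Marker table from [find_marker_snps()] (in relative,
#'   0-based coordinates).
#' @return List of class `recombinant_pattern`: `pattern` (tibble
#'   `position`, `state`), `kind` (`duplication`, `deletion`,
#'   `non_recombinant` or `complex`) and `switch_positions` (0-based
#'   positions of the first marker after each state change).
#' @export
classify_recombinant <- function(consensus, markers) {
  if (is.null(markers) || nrow(markers) == 0L) stop("markers must be non-empty")
  markers <- markers[order(markers$position), ]
  if (nchar(consensus) < max(markers$position) + 1L) {
    stop("consensus shorter than the marker span")
  }
  base <- substring(toupper(consensus), markers$position + 1L,
                    markers$position + 1L)
  state <- ifelse(base == markers$base_a, "A",
                  ifelse(base == markers$base_b, "B", "other"))
  pattern <- tibble(position = markers$position, state = state)
  inf <- pattern[pattern$state != "other", ]
  if (nrow(inf) == 0L) {
    kind <- "non_recombinant"
    switch_positions <- integer(0)
  } else {
    runs <- rle(inf$state)
    n_switch <- length(runs$values) - 1L
    switch_positions <-
      inf$position[cumsum(runs$lengths)[-length(runs$lengths)] + 1L]
    kind <- if (n_switch == 0L) {
      "non_recombinant"
    } else if (n_switch > 1L) {
      "complex"
    } else if (runs$values[1] == "B") {
      "duplication"
    } else {
      "deletion"
    }
  }
  structure(list(pattern = pattern, kind = kind,
                 switch_positions = as.integer(switch_positions)),
            class = "recombinant_pattern")
}

#' Localize the breakpoint region of a single-switch recombinant
#'
#' The crossover must lie between the last marker still matching the 5'
#' paralog and the first marker matching the 3' paralog; the region width
#' is the difference of those two positions.
#'
#' @param classified A `recombinant_pattern` from [classify_recombinant()]
#'   with kind `duplication` or `deletion`.
#' @return List with `start` (position of the last 5'-state marker), `end`
#'   (position of the first 3'-state marker), `width = end - start` and
#'   `kind`.
#' @export
localize_breakpoint <- function(classified) {
  stopifnot(inherits(classified, "recombinant_pattern"))
  if (!classified$kind %in% c("duplication", "deletion")) {
    stop("breakpoint localization requires a single-switch ",
         "(duplication or deletion) pattern, got: ", classified$kind)
  }
  inf <- classified$pattern[classified$pattern$state != "other", ]
  five_prime <- if (classified$kind == "duplication") "B" else "A"
  start <- max(inf$position[inf$state == five_prime])
  end <- min(inf$position[inf$state != five_prime])
  list(start = start, end = end, width = end - start,
       kind = classified$kind)
}

#' Classify and localize a set of recombinant consensus sequences
#'
#' Convenience driver over [classify_recombinant()] and
#' [localize_breakpoint()].
#'
#' @param consensus_seqs Named character vector of aligned consensus
#'   sequences.
#' @param markers Marker table from [find_marker_snps()].
#' @return Tibble with `sample_id`, `kind`, `start`, `end`, `width` (NA
#'   for non-recombinant/complex patterns) and a list column `pattern`.
#' @export
map_breakpoints <- function(consensus_seqs, markers) {
  if (length(consensus_seqs) == 0L) stop("no consensus sequences")
  rows <- lapply(names(consensus_seqs), function(id) {
    cl <- classify_recombinant(consensus_seqs[[id]], markers)
    if (cl$kind %in% c("duplication", "deletion")) {
      bp <- localize_breakpoint(cl)
      tibble(sample_id = id, kind = cl$kind, start = bp$start,
             end = bp$end, width = bp$width, pattern = list(cl$pattern))
    } else {
      tibble(sample_id = id, kind = cl$kind, start = NA_integer_,
             end = NA_integer_, width = NA_integer_,
             pattern = list(cl$pattern))
    }
  })
  bind_rows(rows)
}

#' Group recombinant samples by identical marker-state patterns
#'
#' Samples sharing the exact same ordered marker-state pattern form one
#' breakpoint-region group. Within a group, `consensus_identical` reports
#' whether all members' consensus sequences are byte-identical across the
#' breakpoint region (identity there indicates a single ancestral
#' recombination event rather than recurrent ones).
#'
#' @param bp Tibble from [map_breakpoints()].
#' @param consensus_seqs The same named sequences passed to
#'   [map_breakpoints()].
#' @return Tibble with `group_id`, `kind`, `n`, `sample_ids` (list
#'   column), `pattern_string`, `consensus_identical` (NA for groups
#'   without a localized region).
#' @export
group_by_pattern <- function(bp, consensus_seqs) {
  if (nrow(bp) == 0L) stop("no classified samples")
  key <- vapply(seq_len(nrow(bp)), function(i) {
    paste(bp$kind[i], paste(bp$pattern[[i]]$state, collapse = ""),
          sep = ":")
  }, character(1))
  groups <- split(seq_len(nrow(bp)), key)
  # stable, deterministic ordering: by first occurrence
  groups <- groups[order(vapply(groups, min, integer(1)))]
  rows <- lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    ids <- bp$sample_id[idx]
    kind <- bp$kind[idx[1]]
    ci <- NA
    if (kind %in% c("duplication", "deletion")) {
      s <- bp$start[idx[1]]
      e <- bp$end[idx[1]]
      region <- vapply(ids, function(id) {
        substr(consensus_seqs[[id]], s + 1L, e + 1L)
      }, character(1))
      ci <- length(unique(region)) == 1L
    }
    tibble(group_id = g, kind = kind, n = length(idx),
           sample_ids = list(ids),
           pattern_string = paste(bp$pattern[[idx[1]]]$state,
                                  collapse = ""),
           consensus_identical = ci)
  })
  bind_rows(rows)
}

#' Scan a sequence for an IUPAC motif
#'
#' Reports all (possibly overlapping) 0-based offsets where the sequence
#' matches the motif, with IUPAC codes (e.g. N) matching their base sets.
#' The default motif is the PRDM9 recombination-hotspot binding motif
#' 5'-CCNCCNTNNCCNC-3'.
#'
#' @param sequence A DNA sequence (character scalar).
#' @param motif IUPAC motif string.
#' @param strand `"forward"` (default) returns an integer vector of
#'   forward-strand offsets; `"both"` returns a tibble (`offset`,
#'   `strand`) including reverse-complement matches, reported by the
#'   forward-strand offset of the matched window.
#' @return Integer vector of 0-based offsets, or a tibble for
#'   `strand = "both"`.
#' @export
scan_motif <- function(sequence, motif = PRDM9_MOTIF,
                       strand = c("forward", "both")) {
  strand <- match.arg(strand)
  if (!nzchar(motif)) stop("motif must be non-empty")
  bad <- setdiff(strsplit(toupper(motif), "")[[1]],
                 names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad)) {
    stop("invalid IUPAC letter(s) in motif: ", paste(bad, collapse = ", "))
  }
  subject <- Biostrings::DNAString(toupper(sequence))
  fwd <- Biostrings::start(
    Biostrings::matchPattern(motif, subject, fixed = FALSE)) - 1L
  if (strand == "forward") return(as.integer(fwd))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(toupper(motif))))
  rev <- Biostrings::start(
    Biostrings::matchPattern(rc, subject, fixed = FALSE)) - 1L
  out <- rbind(tibble(offset = as.integer(fwd), strand = "+"),
               tibble(offset = as.integer(rev), strand = "-"))
  out[order(out$offset, out$strand), ]
}

#' Aggregate breakpoint regions into an overall recombination span
#'
#' @param regions Data frame with `start` and `end` columns in a common
#'   coordinate system; an optional `coord` column must be constant.
#' @return List with `start` (minimum start), `end` (maximum end) and
#'   `width = end - start`.
#' @export
aggregate_span <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0L) stop("no regions")
  if ("coord" %in% names(regions) &&
      length(unique(regions$coord)) > 1L) {
    stop("regions use mixed coordinate systems")
  }
  start <- min(regions$start)
  end <- max(regions$end)
  list(start = start, end = end, width = end - start)
}
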