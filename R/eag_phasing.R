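# Exon-allele-group (EAG) phasing.
#
# Amplicon genotyping resolves each of the three amplicons (exon 2,
# exon 3, exon 4/5) to a set of EAGs: an EAG is the set of alleles that
# share an identical sequence over that amplicon. Phasing reconstructs
# which allele combinations are consistent with the observed EAG sets,
# assuming only allele (EAG-triple) combinations present in the allele
# database are valid. Up to three distinct EAGs per amplicon are allowed,
# so three MICA gene copies are detectable.

#' Read an allele database mapping alleles to EAGs per amplicon
#'
#' @param path TSV with columns `allele_name`, `eag_exon2`, `eag_exon3`,
#'   `eag_exon45`.
#' @return Tibble with those four columns.
#' @export
read_allele_db <- function(path) {
  db <- read.delim(path, stringsAsFactors = FALSE)
  validate_allele_db(db)
  as_tibble(db)
}

validate_allele_db <- function(db) {
  req <- c("allele_name", "eag_exon2", "eag_exon3", "eag_exon45")
  if (!all(req %in% names(db))) {
    stop("allele database needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(db$allele_name)) stop("duplicate allele names")
  if (anyNA(db[req]) || any(db[req] == "")) {
    stop("all three amplicons must be mapped for every allele")
  }
  invisible(db)
}

#' Construct an EAG observation for one sample
#'
#' @param exon2,exon3,exon45 Named numeric vectors: names are EAG
#'   identifiers, values are read counts (1-3 EAGs per amplicon, counts
#'   positive).
#' @return List of class `eag_observation`.
#' @export
eag_observation <- function(exon2, exon3, exon45) {
  obs <- list(exon2 = exon2, exon3 = exon3, exon45 = exon45)
  for (amp in names(obs)) {
    x <- obs[[amp]]
    if (is.null(names(x)) || any(names(x) == "")) {
      stop("EAG counts for ", amp, " must be named by EAG identifier")
    }
    if (length(x) < 1L || length(x) > 3L) {
      stop(amp, ": between 1 and 3 EAGs expected")
    }
    if (any(x <= 0)) stop(amp, ": read counts must be positive")
    if (anyDuplicated(names(x))) stop(amp, ": duplicated EAG identifiers")
  }
  structure(obs, class = "eag_observation")
}

eag_key <- c(exon2 = "eag_exon2", exon3 = "eag_exon3", exon45 = "eag_exon45")

#' Phase observed EAG sets into allele multisets
#'
#' Enumerates every multiset of one to three distinct database alleles
#' whose per-amplicon EAG union equals the observed EAG set in all three
#' amplicons. A single consistent allele is reported as a homozygous pair.
#' If any amplicon shows three distinct EAGs, only three-allele multisets
#' can be consistent, so the copy-number inference is 3.
#'
#' @param obs An [eag_observation()].
#' @param db Allele database (see [read_allele_db()]).
#' @param freq_table Optional tibble (`allele_name`, `frequency`) used to
#'   pick each ambiguity group's reporting representative (the group's
#'   most frequent allele, suffixed `#`); without it the lexicographically
#'   first allele represents the group.
#' @return List of class `phasing_result` with `allele_multisets` (list of
#'   character vectors, each of length 2 or 3), `copy_number_inference`
#'   (`2`, `3` or `"ambiguous"`) and `ambiguity_string`.
#' @export
phase_eags <- function(obs, db, freq_table = NULL) {
  stopifnot(inherits(obs, "eag_observation"))
  validate_allele_db(db)
  if (nrow(db) == 0L) stop("allele database is empty")
  observed <- lapply(obs, names)

  # prune: an allele is usable only if its EAG is observed in every amplicon
  usable <- rep(TRUE, nrow(db))
  for (amp in names(eag_key)) {
    usable <- usable & db[[eag_key[amp]]] %in% observed[[amp]]
  }
  cand_db <- db[usable, ]
  n <- nrow(cand_db)

  consistent <- list()
  if (n > 0) {
    for (size in 1:min(3L, n)) {
      idx_sets <- combn(n, size, simplify = FALSE)
      for (idx in idx_sets) {
        ok <- TRUE
        for (amp in names(eag_key)) {
          if (!setequal(unique(cand_db[[eag_key[amp]]][idx]),
                        observed[[amp]])) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          consistent <- c(consistent,
                          list(sort(cand_db$allele_name[idx])))
        }
      }
    }
  }
  if (length(consistent) == 0L) {
    stop("unresolvable genotype: no database allele combination ",
         "reproduces the observed EAG sets (novel allele or artifact?)")
  }
  multisets <- lapply(consistent, function(a) {
    if (length(a) == 1L) c(a, a) else a
  })
  sizes <- lengths(consistent)
  cn <- if (all(sizes == 3L)) "3" else if (all(sizes <= 2L)) "2"
        else "ambiguous"
  list_out <- list(allele_multisets = multisets,
                   copy_number_inference = cn,
                   ambiguity_string = ambiguity_string(multisets, db,
                                                       freq_table))
  structure(list_out, class = "phasing_result")
}

#' Abbreviate candidate multisets with the most-frequent-allele# convention
#'
#' Alleles sharing the same EAG in every amplicon cannot be distinguished
#' by amplicon genotyping; such an ambiguity group is reported as its most
#' frequent member followed by `#`.
#'
#' @param multisets List of allele multisets (character vectors).
#' @param db Allele database.
#' @param freq_table Optional tibble (`allele_name`, `frequency`).
#' @return A single string; candidate multisets joined by `|`, alleles
#'   within one multiset joined by `+`.
#' @export
ambiguity_string <- function(multisets, db, freq_table = NULL) {
  triple <- paste(db$eag_exon2, db$eag_exon3, db$eag_exon45, sep = "|")
  groups <- split(db$allele_name, triple)
  rep_of <- unlist(unname(lapply(groups, function(members) {
    rep_allele <- if (!is.null(freq_table)) {
      f <- freq_table$frequency[match(members, freq_table$allele_name)]
      f[is.na(f)] <- -Inf
      members[which.max(f)]
    } else {
      sort(members)[1]
    }
    label <- if (length(members) > 1L) paste0(rep_allele, "#") else rep_allele
    setNames(rep(label, length(members)), members)
  })))
  labelled <- vapply(multisets, function(m) {
    paste(sort(unname(rep_of[m])), collapse = "+")
  }, character(1))
  paste(unique(labelled), collapse = " | ")
}

#' Distinguish two from three gene copies by read-coverage balance
#'
#' When exactly two distinct alleles are resolved, a duplicated third copy
#' duplicates one of them, which shifts the per-amplicon read share of the
#' major EAG to about 2:1. Returns 3 if and only if in all three amplicons
#' the major EAG read fraction lies within `tolerance` of 2/3; a balanced
#' heterozygote (about 1:1) returns 2.
#'
#' @param obs An [eag_observation()] with exactly two EAG counts per
#'   amplicon.
#' @param tolerance Allowed deviation of the major fraction from 2/3
#'   (default 0.05).
#' @return Integer, `2L` or `3L`.
#' @export
detect_duplication_by_coverage <- function(obs, tolerance = 0.05) {
  stopifnot(inherits(obs, "eag_observation"))
  frac <- vapply(obs, function(x) {
    if (length(x) != 2L) {
      stop("coverage-based duplication detection needs exactly two EAG ",
           "counts per amplicon")
    }
    max(x) / sum(x)
  }, numeric(1))
  if (all(abs(frac - 2 / 3) <= tolerance)) 3L else 2L
}
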