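MATCH_LEVELS <- c("nt_strict", "nt", "aa_vj", "aa", "aa_not_nt")

#' Declarative clonotype matching rule
#'
#' Combines (by conjunction) a matching level, optional V/J segment filters,
#' a frame filter, an anchored CDR3 pattern with `X` wildcards and a mismatch
#' budget, and a minimum frequency.
#'
#' Levels: `nt_strict` (CDR3nt + V + J), `nt` (CDR3nt only), `aa_vj`
#' (CDR3aa + V + J), `aa` (CDR3aa only) and `aa_not_nt` (amino-acid match
#' with distinct nucleotide variants, resolved at join time).
#'
#' @param level matching level (see above).
#' @param v_filter,j_filter optional sets of accepted segment names.
#' @param frame_filter `"all"`, `"in_frame"` or `"out_of_frame"`.
#' @param pattern optional full-length CDR3 motif; `X` is a wildcard
#'   position. Nucleotide patterns (levels `nt`, `nt_strict`) use A/C/G/T/X,
#'   amino-acid patterns use the amino-acid alphabet. Substring search is
#'   expressed with explicit leading/trailing `X` padding.
#' @param max_mismatches mismatch budget at non-`X` pattern positions.
#' @param min_freq minimum clonotype frequency.
#' @return object of class `match_spec`.
#' @export
match_spec <- function(level = "nt_strict", v_filter = NULL, j_filter = NULL,
                       frame_filter = c("all", "in_frame", "out_of_frame"),
                       pattern = NULL, max_mismatches = 0L, min_freq = 0) {
  level <- match.arg(level, MATCH_LEVELS)
  frame_filter <- match.arg(frame_filter)
  if (!is.null(pattern)) {
    pattern <- toupper(pattern)
    nt_level <- level %in% c("nt", "nt_strict")
    alphabet <- if (nt_level) "ACGTX" else "ACDEFGHIKLMNPQRSTVWY*X"
    if (grepl(sprintf("[^%s]", gsub("\\*", "\\\\*", alphabet)), pattern))
      stop("pattern alphabet inconsistent with level '", level, "'")
    if (max_mismatches >= nchar(pattern))
      stop("max_mismatches must be smaller than the pattern length")
  }
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")
  structure(list(level = level, v_filter = v_filter, j_filter = j_filter,
                 frame_filter = frame_filter, pattern = pattern,
                 max_mismatches = as.integer(max_mismatches),
                 min_freq = min_freq),
            class = "match_spec")
}

#' Compute match keys for clonotypes
#'
#' Deterministic key under the chosen matching level. `aa_not_nt` keys are
#' amino-acid keys (the nucleotide payload is compared at join time).
#'
#' @param table a [clonotype_table()] (or data.frame with the needed columns).
#' @param level a matching level, see [match_spec()].
#' @return character vector of keys.
#' @export
make_match_key <- function(table, level = "nt_strict") {
  level <- match.arg(level, MATCH_LEVELS)
  if (level %in% c("aa", "aa_vj", "aa_not_nt")) {
    if (any(!nzchar(table$cdr3aa)))
      stop("amino-acid matching on clonotypes with empty cdr3aa")
  }
  switch(level,
         nt_strict = paste(table$cdr3nt, table$v, table$j, sep = "|"),
         nt = table$cdr3nt,
         aa_vj = paste(table$cdr3aa, table$v, table$j, sep = "|"),
         aa = ,
         aa_not_nt = table$cdr3aa)
}

# Anchored pattern match with X wildcards and a mismatch budget.
pattern_match <- function(seqs, pattern, max_mismatches) {
  hit <- rep(FALSE, length(seqs))
  L <- nchar(pattern)
  cand <- which(nchar(seqs) == L)
  if (length(cand) == 0L) return(hit)
  pat <- strsplit(pattern, "")[[1]]
  fixed <- pat != "X"
  sm <- matrix(unlist(strsplit(seqs[cand], "")), nrow = L)
  mism <- colSums(sm[fixed, , drop = FALSE] != pat[fixed])
  hit[cand] <- mism <= max_mismatches
  hit
}

#' Search clonotypes with combinable filters
#'
#' Returns the clonotypes passing every active criterion of the
#' [match_spec()] (segment filters, frame filter, anchored pattern with
#' wildcards and mismatch budget, minimum frequency), in canonical order.
#' An empty spec returns the whole table.
#'
#' @param table a normalized [clonotype_table()].
#' @param spec a [match_spec()].
#' @return a `clonotype_table` subset (frequencies kept from the source).
#' @export
search_clonotypes <- function(table, spec = match_spec()) {
  stopifnot(inherits(table, "clonotype_table"), inherits(spec, "match_spec"))
  keep <- rep(TRUE, nrow(table))
  if (!is.null(spec$v_filter)) keep <- keep & table$v %in% spec$v_filter
  if (!is.null(spec$j_filter)) keep <- keep & table$j %in% spec$j_filter
  if (spec$frame_filter == "in_frame") keep <- keep & table$frame == "in"
  if (spec$frame_filter == "out_of_frame") keep <- keep & table$frame == "out"
  if (spec$min_freq > 0) keep <- keep & table$freq >= spec$min_freq
  if (!is.null(spec$pattern)) {
    target <- if (spec$level %in% c("nt", "nt_strict")) table$cdr3nt else
      table$cdr3aa
    keep <- keep & pattern_match(target, spec$pattern, spec$max_mismatches)
  }
  rebuild_table(table, which(keep), normalize = FALSE)
}

#' Join clonotype tables across samples
#'
#' Builds the multi-sample matrix keyed by the chosen matching level: one
#' row per key present in at least one sample, with per-sample aggregated
#' counts and frequencies (clonotypes collapsing onto one key are summed)
#' and the incidence (number of samples containing the key). At level
#' `aa_not_nt` rows are joined by amino-acid key and then restricted to keys
#' shared by at least two samples with no nucleotide variant in common.
#'
#' @param tables list of [clonotype_table()]s with distinct sample ids.
#' @param level matching level, see [match_spec()].
#' @return object of class `joined_table`: list with `rows` (data.frame
#'   `key`, `incidence`, `total_freq`), matrices `counts` and `freqs`
#'   (keys x samples), `sample_ids`, `level` and `members` (long data.frame
#'   retaining the underlying clonotypes).
#' @export
join_samples <- function(tables, level = "nt_strict") {
  level <- match.arg(level, MATCH_LEVELS)
  if (length(tables) < 2L) stop("at least 2 tables are required")
  ids <- vapply(tables, function(t) attr(t, "sample_id"), character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ","))
  members <- do.call(rbind, lapply(tables, function(t) {
    data.frame(sample_id = attr(t, "sample_id"),
               key = make_match_key(t, level),
               cdr3nt = t$cdr3nt, cdr3aa = t$cdr3aa, v = t$v, j = t$j,
               count = t$count, freq = t$freq, stringsAsFactors = FALSE)
  }))
  keys <- sort(unique(members$key))
  counts <- freqs <- matrix(0, length(keys), length(ids),
                            dimnames = list(keys, ids))
  agg_c <- tapply(members$count, list(members$key, members$sample_id), sum)
  agg_f <- tapply(members$freq, list(members$key, members$sample_id), sum)
  counts[rownames(agg_c), colnames(agg_c)] <- ifelse(is.na(agg_c), 0, agg_c)
  freqs[rownames(agg_f), colnames(agg_f)] <- ifelse(is.na(agg_f), 0, agg_f)
  if (level == "aa_not_nt") {
    keep <- vapply(keys, function(k) {
      mm <- members[members$key == k, ]
      if (length(unique(mm$sample_id)) < 2L) return(FALSE)
      # no nucleotide variant may be shared between two samples
      !any(tapply(mm$sample_id, mm$cdr3nt,
                  function(s) length(unique(s))) > 1L)
    }, logical(1))
    keys <- keys[keep]
    counts <- counts[keys, , drop = FALSE]
    freqs <- freqs[keys, , drop = FALSE]
    members <- members[members$key %in% keys, , drop = FALSE]
  }
  rows <- data.frame(key = keys,
                     incidence = rowSums(counts > 0),
                     total_freq = rowSums(freqs),
                     stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  structure(list(rows = rows, counts = counts, freqs = freqs,
                 sample_ids = ids, level = level, members = members),
            class = "joined_table")
}

#' @export
print.joined_table <- function(x, ...) {
  cat(sprintf("joined_table (%s level): %d keys x %d samples\n",
              x$level, nrow(x$rows), length(x$sample_ids)))
  invisible(x)
}

#' Public clonotypes
#'
#' Subsets a join to keys shared by at least `min_incidence` samples,
#' sorted by incidence and then total frequency (both descending).
#'
#' @param joined a [join_samples()] result (typically at `aa` level).
#' @param min_incidence minimum number of samples sharing the key
#'   (`>= 2`).
#' @return a `joined_table` restricted to the public keys.
#' @export
public_clonotypes <- function(joined, min_incidence = 2L) {
  stopifnot(inherits(joined, "joined_table"))
  if (min_incidence < 2L) stop("min_incidence must be >= 2")
  if (min_incidence > length(joined$sample_ids))
    warning("min_incidence exceeds the number of samples; result is empty")
  keep <- joined$rows$incidence >= min_incidence
  rows <- joined$rows[keep, , drop = FALSE]
  rows <- rows[order(-rows$incidence, -rows$total_freq, rows$key), ,
               drop = FALSE]
  rownames(rows) <- NULL
  out <- joined
  out$rows <- rows
  out$counts <- joined$counts[rows$key, , drop = FALSE]
  out$freqs <- joined$freqs[rows$key, , drop = FALSE]
  out$members <- joined$members[joined$members$key %in% rows$key, ,
                                drop = FALSE]
  out
}

#' Screen shared amino-acid clonotypes for cross-sample contamination
#'
#' For every amino-acid key shared across at least two donors: when exactly
#' one nucleotide variant underlies all occurrences the sharing is flagged
#' `possible_contamination` (a single rearrangement appearing in unrelated
#' donors); when two or more distinct nucleotide variants occur the sharing
#' is consistent with convergent recombination and flagged `convergent`.
#' Keys confined to one donor are not flagged.
#'
#' @param joined a [join_samples()] result at an amino-acid level.
#' @param donor_map named character vector mapping sample_id -> donor.
#' @return data.frame with columns `key`, `flag`, `n_donors`,
#'   `n_nt_variants`, `nt_variants`.
#' @export
flag_cross_sample_nt_identity <- function(joined, donor_map) {
  stopifnot(inherits(joined, "joined_table"))
  if (!joined$level %in% c("aa", "aa_vj", "aa_not_nt"))
    stop("contamination screening requires an amino-acid level join")
  missing <- setdiff(joined$sample_ids, names(donor_map))
  if (length(missing) > 0L)
    stop("missing donor assignment for sample(s): ",
         paste(missing, collapse = ","))
  mm <- joined$members
  mm$donor <- unname(donor_map[mm$sample_id])
  out <- lapply(split(mm, mm$key), function(grp) {
    donors <- unique(grp$donor)
    if (length(donors) < 2L) return(NULL)
    nts <- unique(grp$cdr3nt)
    data.frame(key = grp$key[1],
               flag = if (length(nts) == 1L) "possible_contamination" else
                 "convergent",
               n_donors = length(donors),
               n_nt_variants = length(nts),
               nt_variants = paste(sort(nts), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(key = character(0), flag = character(0),
                      n_donors = integer(0), n_nt_variants = integer(0),
                      nt_variants = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
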