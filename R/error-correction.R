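# Phred+33 decoding of a vector of quality strings -> list of integer vectors
phred_values <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

correction_report <- function(strategy, before, after, reassigned, dropped,
                              parameters) {
  structure(list(strategy = strategy,
                 clonotypes_before = before, clonotypes_after = after,
                 reads_reassigned = reassigned, reads_dropped = dropped,
                 parameters = parameters),
            class = "correction_report")
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("%s correction: %d -> %d clonotypes (%g reads reassigned, %g dropped)\n",
              x$strategy, x$clonotypes_before, x$clonotypes_after,
              x$reads_reassigned, x$reads_dropped))
  invisible(x)
}

#' Quality-based clonotype filtering
#'
#' Removes every clonotype whose CDR3 contains at least one base below the
#' Phred threshold (Phred+33 encoding, CDR3 bases only); survivors are
#' renormalized.
#'
#' @param table a [clonotype_table()] in which every clonotype carries a
#'   quality string.
#' @param phred_threshold minimum acceptable per-base Phred score (e.g. 20
#'   or 35).
#' @return list with elements `table` (filtered) and `report`
#'   (a `correction_report`).
#' @export
quality_filter <- function(table, phred_threshold) {
  stopifnot(inherits(table, "clonotype_table"))
  if (nrow(table) == 0L) stop("empty clonotype table")
  missing_q <- which(is.na(table$quality))
  if (length(missing_q) > 0L)
    stop("clonotypes without quality strings (rows ",
         paste(utils::head(missing_q, 5L), collapse = ","), ")")
  min_q <- vapply(phred_values(table$quality), min, numeric(1))
  keep <- min_q >= phred_threshold
  out <- rebuild_table(table, which(keep), normalize = any(keep))
  report <- correction_report("quality", nrow(table), nrow(out),
                              reassigned = 0,
                              dropped = sum(table$count[!keep]),
                              parameters = list(phred_threshold = phred_threshold))
  list(table = out, report = report)
}

# For each sequence of length L, the L single-position masks used to find
# Hamming-distance-1 neighbours by hash join.
position_masks <- function(seqs) {
  L <- nchar(seqs[1])
  out <- vector("list", L)
  for (p in seq_len(L))
    out[[p]] <- paste0(substr(seqs, 1L, p - 1L), "\x01",
                       substr(seqs, p + 1L, L))
  out
}

#' Frequency-ratio single-mismatch error correction
#'
#' Merges low-abundance "child" clonotypes into a "parent" clonotype when
#' the two CDR3 nucleotide sequences have equal length and Hamming distance
#' 1, the V and J calls agree (optional), and the child-to-parent count
#' ratio is at most `ratio_threshold` (default 1:20, i.e. merging requires
#' more than a 20-fold abundance difference). Parents are scanned in
#' descending count order and each child merges at most once, into its
#' largest eligible parent; passes repeat until no merge applies, so the
#' operation is idempotent. Total reads are conserved exactly.
#'
#' @param table a normalized [clonotype_table()].
#' @param ratio_threshold maximum child/parent count ratio for merging
#'   (in `(0, 1)`, default `1/20`).
#' @param require_same_vj require identical V and J for merging
#'   (default `TRUE`).
#' @return list with elements `table` (corrected) and `report`.
#' @export
frequency_merge_correct <- function(table, ratio_threshold = 1 / 20,
                                    require_same_vj = TRUE) {
  stopifnot(inherits(table, "clonotype_table"))
  if (nrow(table) == 0L) stop("empty clonotype table")
  if (!is.numeric(ratio_threshold) || ratio_threshold <= 0 ||
      ratio_threshold >= 1)
    stop("ratio_threshold must lie in (0, 1)")
  before <- nrow(table)
  reassigned <- 0
  df <- as.data.frame(normalize_frequencies(table))
  repeat {
    df <- df[canonical_order(df$count, df$cdr3nt), , drop = FALSE]
    n <- nrow(df)
    merged_into <- rep(NA_integer_, n)
    grp_key <- if (require_same_vj)
      paste(nchar(df$cdr3nt), df$v, df$j, sep = "\r") else
        as.character(nchar(df$cdr3nt))
    for (g in split(seq_len(n), grp_key)) {
      if (length(g) < 2L) next
      seqs <- df$cdr3nt[g]
      masks <- position_masks(seqs)
      for (p in seq_along(masks)) {
        for (bucket in split(seq_along(g), masks[[p]])) {
          if (length(bucket) < 2L) next
          idx <- g[bucket]  # global row indices, canonical order preserved
          # smallest-index row = largest count = parent candidate chain
          for (ci in rev(seq_along(idx))) {
            child <- idx[ci]
            if (!is.na(merged_into[child])) next
            for (pi in seq_len(ci - 1L)) {
              parent <- idx[pi]
              if (!is.na(merged_into[parent])) next
              if (df$count[child] / df$count[parent] <= ratio_threshold) {
                cur <- merged_into[child]
                if (is.na(cur) || df$count[parent] > df$count[cur])
                  merged_into[child] <- parent
                break  # idx sorted by descending count: first is largest
              }
            }
          }
        }
      }
    }
    hits <- which(!is.na(merged_into))
    # never let a row act as parent and child in the same pass (chains are
    # resolved over successive passes)
    hits <- hits[is.na(merged_into[merged_into[hits]])]
    if (length(hits) == 0L) break
    add <- tapply(df$count[hits], merged_into[hits], sum)
    tgt <- as.integer(names(add))
    df$count[tgt] <- df$count[tgt] + as.numeric(add)
    reassigned <- reassigned + sum(as.numeric(add))
    df <- df[-hits, , drop = FALSE]
  }
  out <- clonotype_table(df, sample_id = attr(table, "sample_id"),
                         source_format = attr(table, "source_format"))
  report <- correction_report("frequency_merge", before, nrow(out),
                              reassigned = reassigned, dropped = 0,
                              parameters = list(ratio_threshold = ratio_threshold,
                                                require_same_vj = require_same_vj))
  list(table = out, report = report)
}

#' Replicate-intersection error correction
#'
#' Keeps, in each of two replicate tables, only clonotypes whose strict key
#' (CDR3 nucleotide sequence, V, J) occurs in the other replicate; survivors
#' are renormalized. Reproducible errors shared by both replicates survive
#' this filter, which is its known limitation.
#'
#' @param table_a,table_b replicate [clonotype_table()]s.
#' @return list with elements `table_a`, `table_b` (filtered; possibly
#'   empty data.frames when the replicates are disjoint) and `report`.
#' @export
replicate_intersect_filter <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "clonotype_table"),
            inherits(table_b, "clonotype_table"))
  key_a <- paste(table_a$cdr3nt, table_a$v, table_a$j, sep = "\r")
  key_b <- paste(table_b$cdr3nt, table_b$v, table_b$j, sep = "\r")
  keep_a <- key_a %in% key_b
  keep_b <- key_b %in% key_a
  sub <- function(tbl, keep) {
    df <- as.data.frame(tbl)[keep, , drop = FALSE]
    clonotype_table(df, sample_id = attr(tbl, "sample_id"),
                    source_format = attr(tbl, "source_format"),
                    normalize = any(keep))
  }
  report <- correction_report(
    "replicate_intersect",
    before = nrow(table_a) + nrow(table_b),
    after = sum(keep_a) + sum(keep_b),
    reassigned = 0,
    dropped = sum(table_a$count[!keep_a]) + sum(table_b$count[!keep_b]),
    parameters = list())
  list(table_a = sub(table_a, keep_a), table_b = sub(table_b, keep_b),
       report = report)
}
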