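#' CDR3 length spectratype
#'
#' Distribution of CDR3 nucleotide lengths, weighted either by clonotype
#' frequency (read mass) or by clonotype count (each clonotype contributes
#' equally). Lengths that are not multiples of 3 correspond to out-of-frame
#' clonotypes and form their own bins. The top-N most abundant clonotypes are
#' reported with their bin assignment, as in the highlighted-bar spectratype
#' display.
#'
#' @param table a normalized [clonotype_table()].
#' @param top_n number of most abundant clonotypes to highlight (default 10).
#' @param weighting `"frequency"` (read-mass weighting, default) or
#'   `"clonotype"` (each unique clonotype weighs 1/number of clonotypes).
#' @param functional_only drop out-of-frame and stop-containing clonotypes
#'   before binning (default `FALSE`: all clonotypes are included, so
#'   out-of-frame bins are visible).
#' @return object of class `spectratype`: list with `bins` (data.frame
#'   `length`, `weight`), `highlighted` (data.frame of top clonotypes) and
#'   `weighting`.
#' @export
compute_spectratype <- function(table, top_n = 10L,
                                weighting = c("frequency", "clonotype"),
                                functional_only = FALSE) {
  stopifnot(inherits(table, "clonotype_table"))
  weighting <- match.arg(weighting)
  if (nrow(table) == 0L) stop("empty clonotype table")
  if (top_n < 0L) stop("top_n must be >= 0")
  table <- normalize_frequencies(table)
  if (functional_only) {
    table <- rebuild_table(table, which(table$functional), normalize = FALSE)
    if (nrow(table) == 0L) stop("no functional clonotypes left")
  }
  len <- nchar(table$cdr3nt)
  w <- if (weighting == "frequency") table$freq else
    rep(1 / nrow(table), nrow(table))
  agg <- tapply(w, len, sum)
  bins <- data.frame(length = as.integer(names(agg)),
                     weight = as.numeric(agg))
  bins <- bins[order(bins$length), , drop = FALSE]
  rownames(bins) <- NULL
  k <- min(top_n, nrow(table))
  highlighted <- data.frame(cdr3nt = character(0), cdr3aa = character(0),
                            length = integer(0), freq = numeric(0))
  if (k > 0L) {
    idx <- seq_len(k)  # table already in canonical (count-descending) order
    highlighted <- data.frame(cdr3nt = table$cdr3nt[idx],
                              cdr3aa = table$cdr3aa[idx],
                              length = len[idx], freq = table$freq[idx],
                              stringsAsFactors = FALSE)
  }
  structure(list(bins = bins, highlighted = highlighted,
                 weighting = weighting,
                 sample_id = attr(table, "sample_id")),
            class = "spectratype")
}

#' @export
print.spectratype <- function(x, ...) {
  cat(sprintf("spectratype of '%s' (%s-weighted), %d length bins\n",
              x$sample_id, x$weighting, nrow(x$bins)))
  print(x$bins)
  invisible(x)
}

#' Variable-segment spectratype
#'
#' Joint distribution of CDR3 nucleotide length and Variable segment,
#' frequency-weighted. Segments beyond the `top_v` most abundant (by total
#' frequency) are collapsed into `"other"`.
#'
#' @param table a normalized [clonotype_table()].
#' @param top_v number of V segments kept explicit (default 12).
#' @return matrix with CDR3 lengths as rows and V segments as columns;
#'   cell values sum to 1 over the full table.
#' @export
compute_v_spectratype <- function(table, top_v = 12L) {
  stopifnot(inherits(table, "clonotype_table"))
  if (nrow(table) == 0L) stop("empty clonotype table")
  table <- normalize_frequencies(table)
  len <- nchar(table$cdr3nt)
  v <- table$v
  v_tot <- sort(tapply(table$freq, v, sum), decreasing = TRUE)
  keep <- utils::head(names(v_tot), top_v)
  v[!v %in% keep] <- "other"
  lv <- sort(unique(len))
  vlev <- c(keep[keep %in% v], if (any(v == "other")) "other")
  m <- matrix(0, nrow = length(lv), ncol = length(vlev),
              dimnames = list(as.character(lv), vlev))
  for (i in seq_along(len))
    m[as.character(len[i]), v[i]] <- m[as.character(len[i]), v[i]] +
      table$freq[i]
  m
}

#' V-J segment usage matrix
#'
#' Frequency-weighted co-occurrence of Variable and Joining segments (the
#' chord-diagram substrate) together with per-segment marginals. Clonotypes
#' with an undefined V or J are excluded and their total mass reported.
#'
#' @param table a normalized [clonotype_table()].
#' @return object of class `segment_usage`: list with `matrix` (V x J),
#'   `v_marginal`, `j_marginal`, `excluded_mass`.
#' @export
compute_segment_usage <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  if (nrow(table) == 0L) stop("empty clonotype table")
  table <- normalize_frequencies(table)
  ok <- table$v != "." & table$j != "."
  if (!any(ok)) stop("all clonotypes lack a defined V or J segment")
  excluded <- sum(table$freq[!ok])
  v <- table$v[ok]; j <- table$j[ok]; w <- table$freq[ok]
  vl <- sort(unique(v)); jl <- sort(unique(j))
  m <- matrix(0, length(vl), length(jl), dimnames = list(vl, jl))
  for (i in seq_along(w)) m[v[i], j[i]] <- m[v[i], j[i]] + w[i]
  structure(list(matrix = m,
                 v_marginal = rowSums(m),
                 j_marginal = colSums(m),
                 excluded_mass = excluded,
                 sample_id = attr(table, "sample_id")),
            class = "segment_usage")
}

#' @export
print.segment_usage <- function(x, ...) {
  cat(sprintf("V-J usage of '%s': %d V x %d J segments, excluded mass %.4g\n",
              x$sample_id, nrow(x$matrix), ncol(x$matrix), x$excluded_mass))
  invisible(x)
}

# Long-form TSV/JSON export payloads -------------------------------------

#' Export a spectratype or usage matrix as a long-form data.frame
#'
#' @param x a `spectratype` or `segment_usage` object.
#' @return data.frame suitable for TSV/JSON serialization.
#' @export
as_export_frame <- function(x) {
  if (inherits(x, "spectratype")) return(x$bins)
  if (inherits(x, "segment_usage")) {
    idx <- which(x$matrix > 0, arr.ind = TRUE)
    return(data.frame(v = rownames(x$matrix)[idx[, 1]],
                      j = colnames(x$matrix)[idx[, 2]],
                      weight = x$matrix[idx],
                      stringsAsFactors = FALSE))
  }
  stop("no export rule for class ", paste(class(x), collapse = "/"))
}
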