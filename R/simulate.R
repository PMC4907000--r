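# Seeded synthetic repertoire generator. CDR3 sequences are built as a fixed
# V stub + random junction bases + a fixed J stub so they look CDR3-like;
# realism beyond length/segment/junction structure is out of scope.

V_STUB <- "TGTGCCAGC"   # Cys-Ala-Ser motif opening a CDR3
J_STUB <- "TTT"         # conserved Phe closing a TCR-beta CDR3

#' Simulation configuration
#'
#' Parameters of the synthetic repertoire generator: ground-truth clone
#' count, abundance model (Zipf-type power law over clone ranks with
#' exponent `alpha > 1`, or uniform), V/J segment pools with usage
#' probabilities, a discrete distribution of CDR3 lengths in codons, a mean
#' number of non-templated junction insertions (recorded in the markup),
#' a per-base substitution error rate, and a quality model
#' (`high_q`/`low_q` Phred values and the probability that an error position
#' receives low quality).
#'
#' @param n_clones number of ground-truth clonotypes.
#' @param abundance_model `"power_law"` or `"uniform"`.
#' @param alpha power-law exponent (`> 1`), used for `"power_law"`.
#' @param v_pool,j_pool named numeric vectors: segment usage probabilities.
#' @param cdr3_codons named numeric vector: distribution over CDR3 codon
#'   counts (names are codon counts).
#' @param n_insertion_rate mean number of added N bases (Poisson), bounded by
#'   the junction room available.
#' @param error_rate per-base substitution probability in `[0, 0.1]`.
#' @param high_q,low_q Phred scores assigned to correct/error bases.
#' @param error_low_q_prob probability that an error position is flagged by a
#'   low quality score.
#' @param seed integer seed; all generator functions are pure in
#'   (config, seed).
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(n_clones = 1000L,
                       abundance_model = c("power_law", "uniform"),
                       alpha = 2,
                       v_pool = c(TRBV9 = 0.3, `TRBV5-1` = 0.25,
                                  TRBV28 = 0.2, `TRBV12-3` = 0.15,
                                  `TRBV6-5` = 0.1),
                       j_pool = c(`TRBJ2-7` = 0.4, `TRBJ1-1` = 0.35,
                                  `TRBJ2-3` = 0.25),
                       cdr3_codons = c(`12` = 0.15, `13` = 0.25, `14` = 0.3,
                                       `15` = 0.2, `16` = 0.1),
                       n_insertion_rate = 4,
                       error_rate = 0.001,
                       high_q = 37L, low_q = 15L,
                       error_low_q_prob = 0.3,
                       seed = 42L) {
  abundance_model <- match.arg(abundance_model)
  if (n_clones < 1L) stop("n_clones must be >= 1")
  if (abundance_model == "power_law" && alpha <= 1)
    stop("alpha must be > 1 for the power-law abundance model")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must lie in [0, 0.1]")
  stopifnot(abs(sum(v_pool) - 1) < 1e-9, abs(sum(j_pool) - 1) < 1e-9,
            abs(sum(cdr3_codons) - 1) < 1e-9)
  structure(list(n_clones = as.integer(n_clones),
                 abundance_model = abundance_model, alpha = alpha,
                 v_pool = v_pool, j_pool = j_pool,
                 cdr3_codons = cdr3_codons,
                 n_insertion_rate = n_insertion_rate,
                 error_rate = error_rate,
                 high_q = as.integer(high_q), low_q = as.integer(low_q),
                 error_low_q_prob = error_low_q_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic 31-bit hash of a string (used to derive per-clonotype error
# maps that are shared across replicates).
string_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' Generate a ground-truth repertoire
#'
#' Draws `n_clones` distinct clonotypes with CDR3s assembled as
#' V stub + random junction + J stub, lengths from the codon-count model,
#' V/J segments from the usage pools, and abundances from the abundance
#' model (stored directly in `freq`). Deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return a [clonotype_table()] whose `freq` column holds the true clone
#'   abundances.
#' @export
generate_repertoire <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_clones
    lens <- 3L * as.integer(sample(names(cfg$cdr3_codons), n, replace = TRUE,
                                   prob = cfg$cdr3_codons))
    seqs <- character(n)
    pending <- seq_len(n)
    while (length(pending) > 0L) {
      mids <- lens[pending] - nchar(V_STUB) - nchar(J_STUB)
      cand <- vapply(mids, function(mid)
        paste0(V_STUB,
               paste(sample(c("A", "C", "G", "T"), mid, replace = TRUE),
                     collapse = ""),
               J_STUB), character(1))
      # productive rearrangements only: junctions are resampled until
      # stop-free, as real repertoires are dominated by functional clones
      ok <- !grepl("*", translate_cdr3(cand), fixed = TRUE) &
        !duplicated(cand) & !cand %in% seqs
      seqs[pending[ok]] <- cand[ok]
      pending <- pending[!ok]
    }
    v <- sample(names(cfg$v_pool), n, replace = TRUE, prob = cfg$v_pool)
    j <- sample(names(cfg$j_pool), n, replace = TRUE, prob = cfg$j_pool)
    ab <- switch(cfg$abundance_model,
                 uniform = rep(1 / n, n),
                 power_law = {
                   w <- seq_len(n)^(-cfg$alpha)
                   w / sum(w)
                 })
    n_ins <- pmin(rpois(n, cfg$n_insertion_rate),
                  lens - nchar(V_STUB) - nchar(J_STUB))
    v_end <- nchar(V_STUB) + pmax(0L, (lens - nchar(V_STUB) -
                                         nchar(J_STUB) - n_ins) %/% 2L)
    tbl <- data.frame(count = pmax(1, round(ab * 1e6)),
                      cdr3nt = seqs, v = v, j = j,
                      v_end = pmin(v_end, lens - nchar(J_STUB)),
                      j_start = lens - nchar(J_STUB),
                      stringsAsFactors = FALSE)
    out <- clonotype_table(tbl, sample_id = "truth",
                           source_format = "simulated", normalize = FALSE,
                           sort = FALSE)
    out$freq <- ab
    out <- out[canonical_order(out$count, out$cdr3nt), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "sample_id") <- "truth"
    attr(out, "source_format") <- "simulated"
    attr(out, "total_count") <- sum(out$count)
    class(out) <- c("clonotype_table", "data.frame")
    out
  })
}

#' Sample sequencing reads from a ground-truth repertoire
#'
#' Multinomial sample of `n_reads` over the true clone abundances; clones
#' drawn zero times are absent. Sampled clonotypes receive uniform
#' high-quality strings (errors are introduced separately by
#' [inject_errors()]).
#'
#' @param truth a ground-truth [clonotype_table()] (from
#'   [generate_repertoire()]).
#' @param n_reads number of reads to draw (`>= 1`).
#' @param seed integer seed.
#' @param sample_id identifier for the resulting sample.
#' @param cfg optional [sim_config()] supplying the quality model
#'   (defaults to `sim_config()` defaults).
#' @return a normalized [clonotype_table()] with `total_count == n_reads`.
#' @export
sample_reads <- function(truth, n_reads, seed = NULL, sample_id = "sim",
                         cfg = sim_config()) {
  stopifnot(inherits(truth, "clonotype_table"))
  if (n_reads < 1L) stop("n_reads must be >= 1")
  counts <- with_seed(seed,
                      as.vector(rmultinom(1L, n_reads, truth$freq)))
  keep <- counts > 0
  df <- as.data.frame(truth)[keep, , drop = FALSE]
  df$count <- counts[keep]
  df$quality <- vapply(nchar(df$cdr3nt), function(L)
    paste(rep(intToUtf8(cfg$high_q + 33L), L), collapse = ""), character(1))
  clonotype_table(df, sample_id = sample_id, source_format = "simulated")
}

# Deterministic list of single-mismatch variants of a parent sequence, in an
# order derived from the parent sequence (and config seed) only, so that two
# replicates share the same variant sequence and per-variant quality flags.
variant_plan <- function(parent, cfg, reproducible, max_variants) {
  L <- nchar(parent)
  bases <- c("A", "C", "G", "T")
  seed <- if (reproducible) (string_hash(parent) + cfg$seed) %% 2147483647L
  else NULL
  gen <- function() {
    pos <- sample.int(L, max_variants, replace = TRUE)
    alt <- vapply(pos, function(p)
      sample(setdiff(bases, substr(parent, p, p)), 1L), character(1))
    low <- runif(max_variants) < cfg$error_low_q_prob
    data.frame(pos = pos, alt = alt, low = low, stringsAsFactors = FALSE)
  }
  plan <- if (is.null(seed)) gen() else with_seed(seed, gen())
  # distinct variants only, order preserved
  plan[!duplicated(paste(plan$pos, plan$alt)), , drop = FALSE]
}

#' Inject sequencing/PCR errors into a read sample
#'
#' Models substitution errors that create artificial single-mismatch "child"
#' clonotypes next to each parent. For each parent the number of error
#' molecules is Binomial(count x CDR3 length, `error_rate`); error molecules
#' are added to the table (PCR amplification artifacts add error-bearing
#' molecules rather than consuming parent molecules) and distributed over
#' single-mismatch variants so that no child exceeds
#' `max(1, floor(parent_count / 20))` molecules, keeping child/parent
#' abundance ratios within the frequency-merging regime by construction.
#' With `reproducible = TRUE` the variant sequences and their quality flags
#' are a pure function of the parent sequence and config seed, emulating
#' PCR errors shared across replicates; the per-replicate error counts
#' still vary with `seed`.
#'
#' Child quality strings copy the parent's high-quality string, with the
#' error position downgraded to `low_q` with probability `error_low_q_prob`.
#'
#' @param sample a [clonotype_table()] from [sample_reads()].
#' @param cfg a [sim_config()] (supplies `error_rate`, quality model and the
#'   shared-error seed).
#' @param reproducible share the error map across replicate calls
#'   (default `TRUE`).
#' @param seed per-replicate seed for the error counts.
#' @return a normalized [clonotype_table()] containing parents and error
#'   children.
#' @export
inject_errors <- function(sample, cfg, reproducible = TRUE, seed = NULL) {
  stopifnot(inherits(sample, "clonotype_table"), inherits(cfg, "sim_config"))
  if (cfg$error_rate == 0) return(sample)
  hi <- intToUtf8(cfg$high_q + 33L)
  lo <- intToUtf8(cfg$low_q + 33L)
  children <- with_seed(seed, {
    out <- vector("list", nrow(sample))
    for (i in seq_len(nrow(sample))) {
      parent <- sample$cdr3nt[i]
      L <- nchar(parent)
      n_err <- rbinom(1L, sample$count[i] * L, cfg$error_rate)
      if (n_err == 0L) next
      cap <- max(1L, floor(sample$count[i] / 20))
      need <- ceiling(n_err / cap)
      plan <- variant_plan(parent, cfg, reproducible,
                           max_variants = max(need * 3L, 8L))
      plan <- utils::head(plan, need)
      k <- nrow(plan)  # may fall short of `need` after de-duplication
      counts <- n_err %/% k + as.integer(seq_len(k) <= n_err %% k)
      seqs <- vapply(seq_len(nrow(plan)), function(r)
        paste0(substr(parent, 1L, plan$pos[r] - 1L), plan$alt[r],
               substr(parent, plan$pos[r] + 1L, L)), character(1))
      qual <- vapply(seq_len(nrow(plan)), function(r) {
        q <- strrep(hi, L)
        if (plan$low[r])
          q <- paste0(substr(q, 1L, plan$pos[r] - 1L), lo,
                      substr(q, plan$pos[r] + 1L, L))
        q
      }, character(1))
      out[[i]] <- data.frame(count = counts, cdr3nt = seqs,
                             v = sample$v[i], d = sample$d[i],
                             j = sample$j[i], quality = qual,
                             v_end = sample$v_end[i],
                             d_start = sample$d_start[i],
                             d_end = sample$d_end[i],
                             j_start = sample$j_start[i],
                             stringsAsFactors = FALSE)
    }
    out
  })
  children <- do.call(rbind, children[!vapply(children, is.null, logical(1))])
  if (is.null(children)) return(sample)
  base <- as.data.frame(sample)[, c("count", "cdr3nt", "v", "d", "j",
                                    "quality", "v_end", "d_start", "d_end",
                                    "j_start")]
  merged <- merge_duplicate_rows(rbind(base, children))
  clonotype_table(merged, sample_id = attr(sample, "sample_id"),
                  source_format = "simulated")
}

#' Spike a contaminant clonotype into samples
#'
#' Inserts the identical nucleotide clonotype into each sample at
#' approximately the target frequency (`count = round(freq * total)`, at
#' least 1) and renormalizes — the cross-sample contamination scenario.
#' If the sequence is already present its counts are summed with a warning.
#'
#' @param samples list of [clonotype_table()]s.
#' @param clonotype one-row data.frame (or list) with at least `cdr3nt`;
#'   optional `v`, `j`, `cdr3aa`.
#' @param freq target spike-in frequency, in `(0, 0.01)`.
#' @param seed unused placeholder for interface symmetry (the spike is
#'   deterministic).
#' @return list of spiked `clonotype_table`s.
#' @export
inject_contaminant <- function(samples, clonotype, freq, seed = NULL) {
  if (freq <= 0 || freq >= 0.01)
    stop("contaminant freq must lie in (0, 0.01)")
  clonotype <- as.data.frame(as.list(unlist(clonotype)),
                             stringsAsFactors = FALSE)
  lapply(samples, function(tbl) {
    total <- sum(tbl$count)
    spike <- clonotype
    spike$count <- max(1, round(freq * total))
    if (spike$cdr3nt %in% tbl$cdr3nt)
      warning("contaminant sequence already present; counts summed")
    df <- merge_duplicate_rows(
      rbind(as.data.frame(tbl)[, c("count", "cdr3nt", "v", "j")],
            spike[, c("count", "cdr3nt", "v", "j")]))
    clonotype_table(df, sample_id = attr(tbl, "sample_id"),
                    source_format = attr(tbl, "source_format"))
  })
}
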