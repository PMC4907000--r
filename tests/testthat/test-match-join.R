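three_samples <- function() {
  mk <- function(id, seqs, counts, v = "TRBV9", j = "TRBJ2-7")
    clonotype_table(data.frame(count = counts, cdr3nt = seqs, v = v, j = j,
                               stringsAsFactors = FALSE), sample_id = id)
  list(
    A = mk("A", c("TGTGCCAGCTTT", "TGTGCCAAATTT"), c(8, 2)),
    B = mk("B", c("TGCGCCAGCTTT", "TGTGCCAAATTT"), c(5, 5)),  # CASF, nt variant
    C = mk("C", "TGTGCCGGGTTT", 4))
}

test_that("match keys are deterministic and level-dependent", {
  t1 <- toy_table()
  k_strict <- make_match_key(t1, "nt_strict")
  expect_equal(length(unique(k_strict)), 4)
  expect_identical(k_strict, make_match_key(t1, "nt_strict"))
  # same nt, different V -> different strict key
  df <- clonotype_table(data.frame(count = c(2, 2),
                                   cdr3nt = c("TGTGCCAGCTTT", "TGTGCCAGCTTT"),
                                   v = c("TRBV9", "TRBV5-1"), j = "TRBJ2-7"),
                        normalize = TRUE)
  expect_length(unique(make_match_key(df, "nt_strict")), 2)
  expect_length(unique(make_match_key(df, "nt")), 1)
  # aa level collapses synonymous nt variants
  df2 <- clonotype_table(data.frame(count = c(2, 2),
                                    cdr3nt = c("TGTGCCAGCTTT", "TGCGCCAGCTTT")))
  expect_length(unique(make_match_key(df2, "aa")), 1)
  # empty aa rejected at aa level
  oof <- clonotype_table(data.frame(count = 1, cdr3nt = "TG"))
  expect_error(make_match_key(oof, "aa"), "empty cdr3aa")
})

test_that("search applies pattern, wildcard and mismatch budget", {
  seqs <- c("TGTGCCAGCTTT",  # CASF
            "TGTGCCAGATTT",  # CARF
            "TGTGCCGGGGGG",  # CAGG
            "TGTACCAGCTTT")  # CTSF
  tbl <- clonotype_table(data.frame(count = c(4, 3, 2, 1), cdr3nt = seqs,
                                    v = "TRBV9", j = "TRBJ2-7"))
  hits <- search_clonotypes(tbl, match_spec(level = "aa", pattern = "CASF",
                                            max_mismatches = 1))
  expect_setequal(hits$cdr3aa, c("CASF", "CARF", "CTSF"))
  hits0 <- search_clonotypes(tbl, match_spec(level = "aa", pattern = "CXSF",
                                             max_mismatches = 0))
  expect_setequal(hits0$cdr3aa, c("CASF", "CTSF"))
  # alphabet validation
  expect_error(match_spec(level = "nt", pattern = "CASF"), "alphabet")
  expect_error(match_spec(level = "aa", pattern = "CAS",
                          max_mismatches = 3), "smaller than")
})

test_that("combined filters shrink results monotonically on the toy table", {
  t1 <- toy_table()
  all_hits <- search_clonotypes(t1, match_spec())
  expect_equal(nrow(all_hits), nrow(t1))
  # TRBV9 clonotypes at freq >= 0.2: counts 12 (12/21) and 6 (6/21)
  hits <- search_clonotypes(t1, match_spec(v_filter = "TRBV9",
                                           min_freq = 0.2))
  expect_equal(hits$count, c(12, 6))
  # raising the floor isolates the dominant clonotype
  hits2 <- search_clonotypes(t1, match_spec(v_filter = "TRBV9",
                                            min_freq = 0.5))
  expect_equal(hits2$cdr3nt, "TGTGCCAGCTTT")
  # frame filter
  oof <- search_clonotypes(t1, match_spec(frame_filter = "out_of_frame"))
  expect_equal(oof$cdr3nt, "TGTGCCAGCTTTA")
  # filters only shrink
  set.seed(101)
  for (i in 1:10) {
    tbl <- random_table(n_clones = sample(5:30, 1))
    base_n <- nrow(search_clonotypes(tbl, match_spec()))
    filt_n <- nrow(search_clonotypes(tbl, match_spec(v_filter = "TRBV9")))
    expect_lte(filt_n, base_n)
  }
})

test_that("joining aggregates per-sample counts with incidence", {
  s <- three_samples()
  j_aa <- join_samples(s, level = "aa")
  casf <- j_aa$rows[j_aa$rows$key == "CASF", ]
  expect_equal(casf$incidence, 2)           # A and B share CASF
  j_nt <- join_samples(s, level = "nt")
  # nt level splits the two nt variants of CASF
  expect_equal(sum(grepl("^TG[TC]GCCAGCTTT$", j_nt$rows$key)), 2)
  # per-sample freq of a key equals the sum of member freqs
  expect_equal(j_aa$freqs["CASF", "A"], 0.8)
  expect_equal(j_aa$freqs["CAKF", "B"], 0.5)
  expect_equal(j_aa$freqs["CAGF", "A"], 0)  # absent key has zero mass
  expect_error(join_samples(list(s$A, s$A)), "duplicate")
  expect_error(join_samples(list(s$A)), "at least 2")
})

test_that("joining is invariant to sample order", {
  s <- three_samples()
  j1 <- join_samples(s, level = "aa")
  j2 <- join_samples(rev(s), level = "aa")
  expect_equal(j1$rows[order(j1$rows$key), ],
               j2$rows[order(j2$rows$key), ], ignore_attr = TRUE)
  expect_equal(j1$counts[, sort(colnames(j1$counts))],
               j2$counts[, sort(colnames(j2$counts))])
})

test_that("strict-key join of two samples reproduces replicate intersection", {
  set.seed(103)
  for (i in 1:5) {
    truth <- generate_repertoire(sim_config(n_clones = 60, seed = 300 + i))
    a <- sample_reads(truth, 400, seed = i, sample_id = "A")
    b <- sample_reads(truth, 400, seed = 100 + i, sample_id = "B")
    joined <- join_samples(list(a, b), level = "nt_strict")
    shared <- joined$rows$key[joined$rows$incidence == 2]
    res <- replicate_intersect_filter(a, b)
    expect_setequal(shared, make_match_key(res$table_a, "nt_strict"))
  }
})

test_that("public clonotypes are selected by incidence with sane ordering", {
  s <- three_samples()
  joined <- join_samples(s, level = "aa")
  pub <- public_clonotypes(joined, min_incidence = 2)
  expect_setequal(pub$rows$key, c("CASF", "CAKF"))  # both shared by A and B
  # min_incidence = 1 is rejected (public means shared)
  expect_error(public_clonotypes(joined, 1), ">= 2")
  expect_warning(empty <- public_clonotypes(joined, 4), "exceeds")
  expect_equal(nrow(empty$rows), 0)
  # incidence-4 key dropped at threshold 5, kept at 5 of 5
  mk <- function(id) clonotype_table(
    data.frame(count = 3, cdr3nt = "TGTGCCAGCTTT", v = "TRBV9",
               j = "TRBJ2-7"), sample_id = id)
  five <- lapply(paste0("s", 1:5), mk)
  j5 <- join_samples(five, level = "aa")
  expect_equal(public_clonotypes(j5, 5)$rows$incidence, 5)
  four <- c(lapply(paste0("s", 1:4), mk), list(clonotype_table(
    data.frame(count = 3, cdr3nt = "TGTGCCGGGTTT", v = "TRBV9",
               j = "TRBJ2-7"), sample_id = "s5")))
  j4 <- join_samples(four, level = "aa")
  expect_equal(nrow(public_clonotypes(j4, 5)$rows), 0)
})

test_that("amino-acid-not-nucleotide joining drops shared-nt keys", {
  s <- three_samples()
  j <- join_samples(s, level = "aa_not_nt")
  # CASF is shared by A and B through two different nt variants -> kept
  expect_true("CASF" %in% j$rows$key)
  # the identical-nt shared key CKF/TGTGCCAAATTT is excluded
  expect_false("CAKF" %in% j$rows$key)
})

test_that("contamination screening separates identical-nt from convergent", {
  s <- three_samples()
  donor_map <- c(A = "d1", B = "d2", C = "d3")
  joined <- join_samples(s, level = "aa")
  flags <- flag_cross_sample_nt_identity(joined, donor_map)
  # CASF: two nt variants across donors -> convergent recombination
  expect_equal(flags$flag[flags$key == "CASF"], "convergent")
  # CKF (TGTGCCAAATTT): one nt variant in two donors -> contamination signal
  expect_equal(flags$flag[flags$key == "CAKF"], "possible_contamination")
  # single-donor keys unflagged
  expect_false("CAGF" %in% flags$key)
  # replicates of one donor do not raise flags
  flags_same <- flag_cross_sample_nt_identity(joined,
                                              c(A = "d1", B = "d1", C = "d1"))
  expect_equal(nrow(flags_same), 0)
  expect_error(flag_cross_sample_nt_identity(joined, c(A = "d1")),
               "missing donor")
  nt_join <- join_samples(s, level = "nt")
  expect_error(flag_cross_sample_nt_identity(nt_join, donor_map),
               "amino-acid level")
})
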