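# Brute-force oracle: expected distinct clonotypes in a subsample of size m,
# averaged over all C(n, m) read subsets via complete enumeration of reads.
brute_rarefaction <- function(counts, m) {
  reads <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(reads), m)
  mean(apply(subsets, 2, function(ix) length(unique(reads[ix]))))
}

test_that("frequency-count table satisfies its identities", {
  fct <- frequency_count_table(c(2, 1, 1))
  expect_equal(fct$n, 4)
  expect_equal(fct$s_obs, 3)
  expect_equal(fct$f, c(`1` = 2, `2` = 1))
  expect_equal(frequency_count_table(c(5))$f, c(`5` = 1))
  set.seed(53)
  for (i in 1:200) {
    counts <- sample.int(30, sample.int(40, 1), replace = TRUE)
    fct <- frequency_count_table(counts)
    expect_equal(sum(as.numeric(names(fct$f)) * fct$f), sum(counts))
    expect_equal(sum(fct$f), length(counts))
  }
})

test_that("analytic rarefaction equals the exhaustive subset average", {
  counts <- c(2, 1, 1)
  fct <- frequency_count_table(counts)
  expect_equal(clonkit:::expected_diversity(fct, 2), 11 / 6,
               tolerance = 1e-12)
  for (m in 0:4)
    expect_equal(clonkit:::expected_diversity(fct, m),
                 if (m == 0) 0 else brute_rarefaction(counts, m),
                 tolerance = 1e-10)
  counts2 <- c(3, 2, 1, 1)
  fct2 <- frequency_count_table(counts2)
  for (m in 1:7)
    expect_equal(clonkit:::expected_diversity(fct2, m),
                 brute_rarefaction(counts2, m), tolerance = 1e-10)
})

test_that("rarefaction endpoints, monotonicity and linear anchor hold", {
  set.seed(59)
  for (i in 1:10) {
    tbl <- random_table(n_clones = sample(5:40, 1))
    fct <- frequency_count_table(tbl)
    rc <- rarefaction_curve(fct, grid_points = 15,
                            extrapolate_to = 2 * fct$n)
    pts <- rc$points
    expect_equal(pts$expected_diversity[pts$m == 0], 0)
    expect_equal(pts$expected_diversity[pts$m == fct$n], fct$s_obs,
                 tolerance = 1e-9)
    expect_true(all(diff(pts$expected_diversity) > -1e-9))
  }
  # error-free uniform repertoire: curve is exactly linear
  fct1 <- frequency_count_table(rep(1, 300))
  ms <- c(0, 1, 7, 50, 150, 299, 300)
  expect_equal(clonkit:::expected_diversity(fct1, ms), ms,
               tolerance = 1e-10)
})

test_that("rarefaction matches the seeded Monte-Carlo downsampling mean", {
  set.seed(61)
  tbl <- random_table(n_clones = 15, max_count = 20)
  n <- sum(tbl$count)
  m <- floor(n / 2)
  n_rep <- 1500L
  obs <- vapply(seq_len(n_rep), function(i)
    nrow(downsample_table(tbl, m, seed = 5000 + i)), numeric(1))
  analytic <- clonkit:::expected_diversity(frequency_count_table(tbl), m)
  se <- stats::sd(obs) / sqrt(n_rep)
  expect_lt(abs(mean(obs) - analytic), 3 * se)
})

test_that("Chao1 extrapolation is continuous and approaches its asymptote", {
  fct <- frequency_count_table(c(2, 1, 1))
  # f0 = f1^2 / (2 f2) = 4/2 = 2, asymptote 3 + 2 = 5
  rc <- rarefaction_curve(fct, grid_points = 10, extrapolate_to = 4000)
  expect_equal(rc$chao1_asymptote, 5)
  tail_val <- rc$points$expected_diversity[nrow(rc$points)]
  expect_equal(tail_val, 5, tolerance = 1e-3)
  # continuity at m = n: extrapolation at m* = 0 equals s_obs
  rc2 <- rarefaction_curve(fct, grid_points = 4, extrapolate_to = 8)
  expect_equal(rc2$points$expected_diversity[rc2$points$m == 4], 3,
               tolerance = 1e-9)
  # f2 = 0 fallback: f0 = f1 (f1 - 1) / 2
  fct2 <- frequency_count_table(c(1, 1, 1))
  rc3 <- rarefaction_curve(fct2, grid_points = 4, extrapolate_to = 6)
  expect_equal(rc3$chao1_asymptote, 3 + 3)
  expect_error(rarefaction_curve(fct, extrapolate_to = 2), "at least")
})

test_that("Efron-Thisted estimate reproduces the hand-evaluated weights", {
  fct <- frequency_count_table(c(2, 1, 1))
  et <- efron_thisted_estimate(fct, depth = 2)
  # b_{1,2} = 3/4, b_{2,2} = 1/4; Delta = 2*3/4 - 1/4 = 1.25
  expect_equal(et$value, 4.25, tolerance = 1e-9)
  expect_equal(et$std_error, sqrt(9 / 16 * 2 + 1 / 16), tolerance = 1e-9)
  expect_equal(et$depth_used, 2)
  # no singletons/doubletons: zero rare-count terms contribute nothing
  fct2 <- frequency_count_table(c(5, 4, 3))
  expect_equal(efron_thisted_estimate(fct2, depth = 2)$value, 3)
  # estimate never falls below the observed diversity
  set.seed(67)
  for (i in 1:50) {
    fct3 <- frequency_count_table(sample.int(10, sample.int(30, 1),
                                             replace = TRUE))
    expect_gte(efron_thisted_estimate(fct3)$value, fct3$s_obs)
  }
})

test_that("Efron-Thisted recovers richness unobservable to s_obs", {
  # 2,000 reads from 1,000 equal-abundance clones: ~14% of clones unseen
  set.seed(71)
  n_seeds <- 30L
  est <- sobs <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    counts <- tabulate(sample.int(1000, 2000, replace = TRUE))
    counts <- counts[counts > 0]
    fct <- frequency_count_table(counts)
    est[i] <- efron_thisted_estimate(fct)$value
    sobs[i] <- fct$s_obs
  }
  expect_lt(abs(mean(est) - 1000), abs(mean(sobs) - 1000))
})

test_that("clonality breakdown splits quantiles per the stated rule", {
  counts <- c(20, 10, 8, 6, 5, 5, 4, 4, 3, 3, 2, 2, 1, 1, 1, 1)
  # deterministic distinct sequences of equal length
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_along(counts), function(i)
    paste0("TGTGCC", bases[(i - 1) %/% 4 + 1], bases[(i - 1) %% 4 + 1], "T"),
    character(1))
  tbl <- clonotype_table(data.frame(count = counts, cdr3nt = seqs))
  cb <- clonality_breakdown(tbl)
  expect_equal(cb$quantile_freqs, c(30, 14, 10, 8, 6) / 76)
  expect_equal(cb$singleton_freq, 4 / 76)
  expect_equal(cb$doubleton_freq, 4 / 76)
  expect_equal(cb$singleton_freq + cb$doubleton_freq +
                 sum(cb$quantile_freqs), 1, tolerance = 1e-9)
  # all-singleton table
  tbl1 <- clonotype_table(data.frame(
    count = rep(1, 4), cdr3nt = paste0("TGTGC", bases, "TT")))
  cb1 <- clonality_breakdown(tbl1)
  expect_equal(cb1$singleton_freq, 1)
  expect_equal(sum(cb1$quantile_freqs) + cb1$doubleton_freq, 0)
})

test_that("clonality masses sum to one and ignore row order", {
  set.seed(73)
  for (i in 1:20) {
    tbl <- random_table(n_clones = sample(5:50, 1))
    cb <- clonality_breakdown(tbl)
    expect_lt(abs(cb$singleton_freq + cb$doubleton_freq +
                    sum(cb$quantile_freqs) - 1), 1e-9)
    perm <- clonotype_table(as.data.frame(tbl)[sample.int(nrow(tbl)), ])
    cb2 <- clonality_breakdown(perm)
    expect_equal(cb2$quantile_freqs, cb$quantile_freqs)
  }
})

test_that("saturation model recovers true parameters and exposes degeneracy", {
  n <- seq(0, 1000, by = 50)
  fit <- fit_saturation_model(
    data.frame(n = n, diversity = 100 * (1 - exp(-0.01 * n))), seed = 1)
  expect_lt(abs(fit$a - 100) / 100, 0.01)
  expect_lt(abs(fit$b - 0.01) / 0.01, 0.01)
  expect_lt(fit$rss, 1e-6)
  # all-zero data fits exactly
  fit0 <- fit_saturation_model(data.frame(n = n, diversity = 0), seed = 2)
  expect_equal(fit0$rss, 0, tolerance = 1e-12)
  # exactly linear data: multiple materially different optima at RSS ~ 0
  fitl <- fit_saturation_model(data.frame(n = n, diversity = n), seed = 3)
  good <- fitl$restarts[fitl$restarts$rss < 1e-6, ]
  expect_gte(nrow(good), 2)
  spread <- max(abs(outer(good$a, good$a, "-"))) +
    max(abs(outer(good$k, good$k, "-")))
  expect_gt(spread, 1)
  expect_error(fit_saturation_model(data.frame(n = 1:2, diversity = 1:2)),
               "at least 3")
})
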