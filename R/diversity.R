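#' Frequency-count table
#'
#' Collapses a clonotype table into the mapping `k -> f_k` (number of
#' clonotypes observed exactly `k` times), the substrate of all richness
#' estimators. Satisfies `sum(k * f_k) = n` and `sum(f_k) = s_obs`.
#'
#' @param table a [clonotype_table()], or a bare vector of positive counts.
#' @return object of class `freq_count_table`: list with `n`, `s_obs` and
#'   `f` (named numeric vector, names are the multiplicities `k`).
#' @export
frequency_count_table <- function(table) {
  counts <- if (inherits(table, "clonotype_table")) table$count else
    as.numeric(table)
  if (length(counts) == 0L) stop("empty clonotype table")
  if (any(counts < 1)) stop("counts must be >= 1")
  tab <- base::table(counts)
  f <- as.numeric(tab)
  names(f) <- names(tab)
  structure(list(n = sum(counts), s_obs = length(counts), f = f),
            class = "freq_count_table")
}

#' @export
print.freq_count_table <- function(x, ...) {
  cat(sprintf("frequency-count table: n = %d reads, s_obs = %d clonotypes\n",
              x$n, x$s_obs))
  print(x$f)
  invisible(x)
}

#' Clonality breakdown (nested pie)
#'
#' Splits repertoire read mass into singletons (count 1), doubletons
#' (count 2) and five quantiles of high-order clonotypes (count >= 3): Q1 is
#' the top 20% of unique high-order clonotypes by abundance, and so on.
#' When the high-order clonotype count is not divisible by 5 the remainder is
#' assigned to the highest quantiles first. The ten most abundant clonotypes
#' are listed explicitly.
#'
#' @param table a normalized [clonotype_table()].
#' @return object of class `clonality_breakdown`: list with `singleton_freq`,
#'   `doubleton_freq`, `quantile_freqs` (length 5) and `top_clonotypes`.
#' @export
clonality_breakdown <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  if (nrow(table) == 0L) stop("empty clonotype table")
  table <- normalize_frequencies(table)
  singleton <- sum(table$freq[table$count == 1])
  doubleton <- sum(table$freq[table$count == 2])
  hi <- which(table$count >= 3)  # table already canonical (count-descending)
  q <- numeric(5)
  if (length(hi) > 0L) {
    nh <- length(hi)
    base <- nh %/% 5L
    sizes <- base + as.integer(seq_len(5L) <= nh %% 5L)
    grp <- rep(seq_len(5L), times = sizes)
    q <- as.numeric(tapply(table$freq[hi], factor(grp, levels = 1:5), sum))
    q[is.na(q)] <- 0
  }
  k <- min(10L, nrow(table))
  top <- data.frame(cdr3nt = table$cdr3nt[seq_len(k)],
                    cdr3aa = table$cdr3aa[seq_len(k)],
                    freq = table$freq[seq_len(k)],
                    stringsAsFactors = FALSE)
  structure(list(singleton_freq = singleton, doubleton_freq = doubleton,
                 quantile_freqs = q, top_clonotypes = top,
                 sample_id = attr(table, "sample_id")),
            class = "clonality_breakdown")
}

#' @export
print.clonality_breakdown <- function(x, ...) {
  cat(sprintf("clonality of '%s':\n", x$sample_id))
  cat(sprintf("  singletons %.4f, doubletons %.4f\n",
              x$singleton_freq, x$doubleton_freq))
  cat("  high-order quantiles:",
      paste(sprintf("%.4f", x$quantile_freqs), collapse = " "), "\n")
  invisible(x)
}

# Probability that a clonotype seen k times in n reads is absent from a
# hypergeometric subsample of size m: C(n-k, m) / C(n, m).
# Exact product form for small k; log-gamma otherwise.
absent_prob <- function(k, n, m) {
  if (m == 0) return(1)
  if (n - k < m) return(0)
  if (k <= 64) {
    j <- seq_len(k) - 1
    prod((n - m - j) / (n - j))
  } else {
    exp(lchoose(n - k, m) - lchoose(n, m))
  }
}

# Analytic (Hurlbert-style) rarefaction: E[S(m)] from a frequency-count table.
expected_diversity <- function(fct, m) {
  vapply(m, function(mm) {
    ks <- as.numeric(names(fct$f))
    sum(fct$f * (1 - vapply(ks, absent_prob, numeric(1), n = fct$n, m = mm)))
  }, numeric(1))
}

# Chao1 unseen-species count from singletons/doubletons.
chao1_f0 <- function(f1, f2) {
  if (f1 == 0) return(0)
  if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / 2
}

#' Analytic rarefaction curve with extrapolation
#'
#' For subsample sizes `m <= n` the expected clonotype count is the exact
#' hypergeometric expectation
#' `E[S(m)] = s_obs - sum_i C(n - n_i, m) / C(n, m)`,
#' computed from the frequency-count table with numerically stable
#' binomial-coefficient ratios. Beyond the observed depth the curve is
#' extended with the Chao1-conditioned extrapolation
#' `E[S(n + m*)] = s_obs + f0 * (1 - (1 - f1 / (n f0 + f1))^m*)`,
#' where `f0 = f1^2 / (2 f2)` (or `f1 (f1 - 1) / 2` when `f2 = 0`).
#' For an error-free uniform repertoire (all counts 1) the interpolated curve
#' is exactly linear: `E[S(m)] = m`.
#'
#' @param fct a [frequency_count_table()] (or a `clonotype_table`).
#' @param grid_points number of grid intervals spanning `0..extrapolate_to`.
#' @param extrapolate_to largest depth on the grid; defaults to `n`
#'   (no extrapolation). Must be at least `n`.
#' @return object of class `rarefaction_curve`: data.frame `points` with
#'   columns `m`, `expected_diversity`, `kind`; plus `s_obs`, `n`.
#' @export
rarefaction_curve <- function(fct, grid_points = 20L, extrapolate_to = NULL) {
  if (inherits(fct, "clonotype_table")) fct <- frequency_count_table(fct)
  stopifnot(inherits(fct, "freq_count_table"))
  n <- fct$n
  if (is.null(extrapolate_to)) extrapolate_to <- n
  if (extrapolate_to < n)
    stop("extrapolate_to must be at least the observed depth n = ", n)
  grid <- unique(sort(c(0, n, round(seq(0, extrapolate_to,
                                        length.out = grid_points + 1L)))))
  interp <- grid[grid <= n]
  extrap <- grid[grid > n]
  ed_i <- expected_diversity(fct, interp)
  f1 <- if ("1" %in% names(fct$f)) fct$f[["1"]] else 0
  f2 <- if ("2" %in% names(fct$f)) fct$f[["2"]] else 0
  f0 <- chao1_f0(f1, f2)
  ed_e <- if (length(extrap) > 0L) {
    mstar <- extrap - n
    if (f0 == 0) rep(fct$s_obs, length(mstar)) else
      fct$s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^mstar)
  } else numeric(0)
  pts <- data.frame(
    m = c(interp, extrap),
    expected_diversity = c(ed_i, ed_e),
    kind = c(rep("interpolated", length(interp)),
             rep("extrapolated", length(extrap))),
    stringsAsFactors = FALSE)
  structure(list(points = pts, s_obs = fct$s_obs, n = n,
                 chao1_asymptote = fct$s_obs + f0),
            class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("rarefaction curve: n = %d, s_obs = %d, Chao1 asymptote %.1f\n",
              x$n, x$s_obs, x$chao1_asymptote))
  print(x$points)
  invisible(x)
}

#' Efron-Thisted estimate of total diversity
#'
#' Unseen-species estimator based on the Euler transformation of the
#' alternating series over frequency counts: the unseen mass at depth `d` is
#' `Delta_d = sum_{x=1..d} (-1)^(x+1) f_x b_{x,d}` with weights
#' `b_{x,d} = P[Binomial(d, 1/2) >= x]`, and
#' `SE_d = sqrt(sum_x b_{x,d}^2 f_x)`. The depth used is the largest
#' `d <= max_depth` whose coefficient of variation
#' `SE_d / (s_obs + Delta_d)` is at most `cv_threshold`; if none qualifies,
#' the depth minimizing `SE_d` is used. The unseen mass is clamped at 0, so
#' the estimate is never below the observed diversity.
#'
#' @param fct a [frequency_count_table()] (or a `clonotype_table`).
#' @param max_depth maximum Euler depth considered (default 20).
#' @param cv_threshold coefficient-of-variation cutoff for depth selection
#'   (default 0.05).
#' @param depth optional fixed Euler depth, bypassing depth selection.
#' @return object of class `diversity_estimate`: list with `method`,
#'   `value`, `std_error`, `depth_used`, `s_obs`.
#' @export
efron_thisted_estimate <- function(fct, max_depth = 20L,
                                   cv_threshold = 0.05, depth = NULL) {
  if (inherits(fct, "clonotype_table")) fct <- frequency_count_table(fct)
  stopifnot(inherits(fct, "freq_count_table"))
  if (fct$s_obs < 1L) stop("empty frequency-count table")
  ks <- as.numeric(names(fct$f))
  if (!is.null(depth)) max_depth <- max(max_depth, depth)
  delta <- se <- numeric(max_depth)
  for (d in seq_len(max_depth)) {
    xs <- ks[ks <= d]
    if (length(xs) == 0L) { delta[d] <- 0; se[d] <- 0; next }
    fx <- fct$f[as.character(xs)]
    b <- pbinom(xs - 1, d, 0.5, lower.tail = FALSE)
    delta[d] <- sum((-1)^(xs + 1) * fx * b)
    se[d] <- sqrt(sum(b^2 * fx))
  }
  if (is.null(depth)) {
    cv <- se / (fct$s_obs + delta)
    ok <- which(cv <= cv_threshold)
    depth <- if (length(ok) > 0L) max(ok) else which.min(se)
  }
  structure(list(method = "efron_thisted",
                 value = fct$s_obs + max(0, delta[depth]),
                 std_error = se[depth],
                 depth_used = depth,
                 s_obs = fct$s_obs),
            class = "diversity_estimate")
}

#' Observed and Chao1 diversity estimates
#'
#' @param fct a [frequency_count_table()] (or a `clonotype_table`).
#' @param method `"observed"` or `"chao1"`.
#' @return a `diversity_estimate` object. For Chao1 the standard error is the
#'   classic variance formula of the bias-corrected estimator.
#' @export
diversity_estimate <- function(fct, method = c("observed", "chao1")) {
  if (inherits(fct, "clonotype_table")) fct <- frequency_count_table(fct)
  stopifnot(inherits(fct, "freq_count_table"))
  method <- match.arg(method)
  f1 <- if ("1" %in% names(fct$f)) fct$f[["1"]] else 0
  f2 <- if ("2" %in% names(fct$f)) fct$f[["2"]] else 0
  if (method == "observed") {
    out <- list(method = "observed", value = fct$s_obs, std_error = 0,
                depth_used = NA_integer_, s_obs = fct$s_obs)
  } else {
    f0 <- chao1_f0(f1, f2)
    var <- if (f2 > 0) {
      r <- f1 / f2
      f2 * (r^2 / 2 + r^3 + r^4 / 4)
    } else if (f1 > 0) {
      f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * (f0 + fct$s_obs))
    } else 0
    out <- list(method = "chao1", value = fct$s_obs + f0,
                std_error = sqrt(max(0, var)),
                depth_used = NA_integer_, s_obs = fct$s_obs)
  }
  structure(out, class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("%s diversity estimate: %.1f +/- %.1f (s_obs = %d%s)\n",
              x$method, x$value, x$std_error, x$s_obs,
              if (!is.na(x$depth_used))
                sprintf(", depth %d", x$depth_used) else ""))
  invisible(x)
}

#' Fit the saturating diversity-vs-depth model
#'
#' Fits `S(n) = a (1 - exp(-b n)) + k n` to (depth, diversity) points by
#' nonlinear least squares with non-negativity constraints and multiple
#' seeded random restarts (Levenberg-Marquardt, with a box-constrained
#' quasi-Newton fallback). Here `a` plays the role of a total clonotype
#' count and `k` of a linear error-rate slope. All restart solutions are
#' retained: on data where the model is degenerate (e.g. an exactly linear
#' rarefaction curve from an error-free uniform repertoire) distinct
#' parameter vectors reach the same residual sum of squares, which is the
#' known failure mode of this model.
#'
#' @param points data.frame with columns `n` (strictly increasing depth) and
#'   `diversity`; at least 3 rows.
#' @param restarts number of random restarts (default 10).
#' @param seed optional integer seed for restart initialization.
#' @return object of class `imex_fit`: list with `a`, `b`, `k`, `rss` of the
#'   best fit and `restarts`, a data.frame of all restart solutions.
#' @export
fit_saturation_model <- function(points, restarts = 10L, seed = NULL) {
  points <- as.data.frame(points)
  if (!all(c("n", "diversity") %in% names(points)))
    stop("points must have columns 'n' and 'diversity'")
  if (nrow(points) < 3L) stop("at least 3 points are required")
  if (any(diff(points$n) <= 0)) stop("n must be strictly increasing")
  x <- points$n; y <- points$diversity
  ymax <- max(y, 1e-12); xmax <- max(x, 1)
  rss_fun <- function(p) sum((y - (p[1] * (1 - exp(-p[2] * x)) +
                                     p[3] * x))^2)
  one_fit <- function(start) {
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(
        y ~ a * (1 - exp(-b * x)) + k * x,
        start = list(a = start[1], b = start[2], k = start[3]),
        lower = c(0, 0, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      p <- coef(m)
      c(p[["a"]], p[["b"]], p[["k"]])
    }, error = function(e) NULL)
    if (is.null(fit)) {
      o <- optim(start, rss_fun, method = "L-BFGS-B",
                 lower = c(0, 0, 0),
                 control = list(maxit = 500, factr = 1e3))
      fit <- o$par
    }
    fit
  }
  res <- with_seed(seed, {
    out <- vector("list", restarts)
    for (r in seq_len(restarts)) {
      start <- c(a = runif(1, 0.1, 3) * ymax,
                 b = 10^runif(1, -2, 1) / xmax,
                 k = runif(1, 0, 2) * ymax / xmax)
      p <- one_fit(start)
      out[[r]] <- data.frame(a = p[1], b = p[2], k = p[3],
                             rss = rss_fun(p))
    }
    do.call(rbind, out)
  })
  best <- res[which.min(res$rss), ]
  # polish: refit from the best restart until the RSS stops improving
  repeat {
    p <- one_fit(c(max(best$a, 1e-8), max(best$b, 1e-8), best$k))
    r <- rss_fun(p)
    if (r < best$rss * (1 - 1e-10)) {
      best <- data.frame(a = p[1], b = p[2], k = p[3], rss = r)
    } else break
  }
  structure(list(a = best$a, b = best$b, k = best$k, rss = best$rss,
                 restarts = res),
            class = "imex_fit")
}

#' @export
print.imex_fit <- function(x, ...) {
  cat(sprintf("saturation model fit: a = %.4g, b = %.4g, k = %.4g (RSS %.3g)\n",
              x$a, x$b, x$k, x$rss))
  cat(sprintf("  %d restarts, RSS range [%.3g, %.3g]\n",
              nrow(x$restarts), min(x$restarts$rss), max(x$restarts$rss)))
  invisible(x)
}

#' @export
coef.imex_fit <- function(object, ...) {
  c(a = object$a, b = object$b, k = object$k)
}
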