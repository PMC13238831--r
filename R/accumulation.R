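# Allele-accumulation bootstraps, hypothetical-population matching of total
# allele numbers, extrapolated richness, and Michaelis-Menten saturation
# fits of diversity against sample size.

stat_fun <- function(statistic) {
  switch(statistic,
    alleles = function(a1, a2) length(unique(c(a1, a2))),
    shannon = function(a1, a2) shannon_index(table(c(a1, a2)))
  )
}

#' Bootstrapped accumulation curve of a diversity statistic
#'
#' By default each iteration leaves out a uniform random third of the
#' individuals (`ceiling(n/3)`) and recomputes the statistic at the retained
#' size, alongside the full-data point. Supplying `n_grid` instead draws
#' subsamples at each grid size, giving a smooth curve of the statistic
#' against sample size.
#'
#' @param genotypes Long genotype tibble, one locus.
#' @param statistic `"alleles"` (unique allele count) or `"shannon"`
#'   (Shannon-Weaver H' on allele copies).
#' @param iters Subsample iterations per size.
#' @param frac_out Fraction left out in the default leave-out scheme.
#' @param n_grid Optional vector of subsample sizes (individuals).
#' @param seed Integer seed.
#' @return An `accum_curve` tibble: `n`, `mean`, `sd`, `q2.5`, `q97.5`,
#'   `reps`, plus the `statistic` as an attribute.
#' @export
accumulation_curve <- function(genotypes, statistic = c("alleles", "shannon"),
                               iters = 1000, frac_out = 1 / 3, n_grid = NULL,
                               seed = 1) {
  statistic <- match.arg(statistic)
  cc <- complete_calls(genotypes)
  if (length(unique(cc$locus)) != 1) stop("supply genotypes for a single locus")
  n <- nrow(cc)
  if (n < 3) stop("need at least 3 called individuals")
  f <- stat_fun(statistic)
  set.seed(derive_seed(seed, paste0("accum", statistic)))
  sizes <- n_grid %||% (n - ceiling(n * frac_out))
  sizes <- sort(unique(pmin(sizes, n)))
  rows <- purrr::map_dfr(sizes, function(m) {
    if (m >= n) {
      v <- f(cc$allele1, cc$allele2)
      return(tibble::tibble(n = m, mean = v, sd = 0, q2.5 = v, q97.5 = v,
                            reps = 1L))
    }
    v <- vapply(seq_len(iters), function(b) {
      idx <- sample.int(n, m)
      f(cc$allele1[idx], cc$allele2[idx])
    }, numeric(1))
    v <- v[!is.na(v)]
    qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    tibble::tibble(n = m, mean = mean(v), sd = stats::sd(v),
                   q2.5 = qs[1], q97.5 = qs[2], reps = length(v))
  })
  full <- f(cc$allele1, cc$allele2)
  if (!n %in% rows$n) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(n = n, mean = full, sd = 0,
                                                  q2.5 = full, q97.5 = full,
                                                  reps = 1L))
  }
  out <- dplyr::arrange(rows, .data$n)
  class(out) <- c("accum_curve", class(out))
  attr(out, "statistic") <- statistic
  out
}

sim_match_curve <- function(logp, bw, K, N, g) {
  draw <- exp(sample(logp, K, replace = TRUE) + stats::rnorm(K, 0, bw))
  q <- draw / sum(draw)
  cnt <- stats::rmultinom(1, N, q)[, 1]
  cnt <- cnt[cnt > 0]
  list(q = q, curve = vapply(g, function(gg) allelic_richness(cnt, gg), numeric(1)))
}

#' Match the observed allele accumulation to hypothetical populations
#'
#' Estimates the total number of alleles in the source population by
#' simulation: the empirical distribution of observed allele frequencies is
#' smoothed with a Gaussian kernel on the log scale, hypothetical
#' populations with increasing allele numbers K draw their frequencies from
#' it, diploid samples of the observed size are simulated, and the K whose
#' mean accumulation curve is closest (L2 on a common sample-size grid) to
#' the observed curve wins (ties take the smaller K). Accumulation curves
#' are the exact expected-value (hypergeometric rarefaction) curves of each
#' dataset.
#'
#' @param counts Observed allele copy counts for one population and locus.
#' @param K_grid Candidate allele numbers; defaults to observed count up to
#'   observed + 50.
#' @param reps Simulated datasets per K (>= 200 recommended).
#' @param grid_n Sample-size grid (individuals) for curve comparison.
#' @param bw Kernel bandwidth on log frequencies; Silverman default.
#' @param seed Integer seed.
#' @return A `k_match` list: `best_k`, `n_extra` (best K minus observed),
#'   `profile` (tibble `K`, `l2`), `obs_curve`, `grid_n`, `freq_draws`
#'   (replicate frequency vectors at the best K), and inputs.
#' @export
match_allele_count <- function(counts, K_grid = NULL, reps = 200,
                               grid_n = NULL, bw = NULL, seed = 1) {
  counts <- counts[counts > 0]
  n_all <- length(counts)
  N <- sum(counts)
  n_ind <- N %/% 2L
  if (n_all == 1) {
    out <- list(best_k = 1L, n_extra = 0L,
                profile = tibble::tibble(K = 1L, l2 = 0),
                obs_curve = NULL, grid_n = NULL, counts = counts,
                n_ind = n_ind, freq_draws = list(1), reps = reps, bw = 0)
    class(out) <- "k_match"
    return(out)
  }
  K_grid <- K_grid %||% (n_all:(n_all + 50L))
  stopifnot(all(K_grid >= 1), reps >= 1)
  grid_n <- grid_n %||% unique(round(seq(2, n_ind, length.out = 8)))
  g <- 2L * as.integer(grid_n)
  obs_curve <- vapply(g, function(gg) allelic_richness(counts, gg), numeric(1))
  logp <- log(counts / N)
  bw <- bw %||% stats::bw.nrd0(logp)

  profile <- purrr::map_dfr(K_grid, function(K) {
    set.seed(derive_seed(seed, paste0("matchK", K)))
    curves <- vapply(seq_len(reps),
                     function(b) sim_match_curve(logp, bw, K, N, g)$curve,
                     numeric(length(g)))
    mean_curve <- rowMeans(matrix(curves, nrow = length(g)))
    tibble::tibble(K = K, l2 = sum((obs_curve - mean_curve)^2))
  })
  best_k <- profile$K[which.min(profile$l2)]

  set.seed(derive_seed(seed, paste0("matchK", best_k)))
  freq_draws <- lapply(seq_len(reps),
                       function(b) sim_match_curve(logp, bw, best_k, N, g)$q)

  out <- list(best_k = as.integer(best_k),
              n_extra = as.integer(best_k - n_all),
              profile = profile, obs_curve = obs_curve, grid_n = grid_n,
              counts = counts, n_ind = n_ind, freq_draws = freq_draws,
              reps = reps, bw = bw)
  class(out) <- "k_match"
  out
}

#' @export
print.k_match <- function(x, ...) {
  cat("Hypothetical-population allele-number match\n")
  cat("  observed alleles:", length(x$counts), "in", x$n_ind, "individuals\n")
  cat("  best K:", x$best_k, " (", x$n_extra, "unseen )\n")
  invisible(x)
}

#' Extrapolate allelic richness beyond the observed sample size
#'
#' Expected allele count at `n_prime` individuals, anchored at the observed
#' count: for each hypothetical-population replicate (frequency vector q
#' from [match_allele_count()] at the best K), the expected number of
#' newly discovered alleles between the observed size n and n' is
#' \eqn{\sum_j [(1-q_j)^{2n} - (1-q_j)^{2n'}]}; the estimate is the observed
#' allele count plus the replicate mean, with 2.5/97.5 percentile bounds.
#' At `n_prime = n` the observed count is returned exactly; `n_prime = Inf`
#' gives the asymptotic estimate (close to the best K).
#'
#' @param counts Observed allele copy counts.
#' @param n_prime Target sample sizes in individuals (>= observed n;
#'   `Inf` allowed).
#' @param match Optional precomputed [match_allele_count()] result.
#' @param ... Passed to [match_allele_count()] when `match` is `NULL`.
#' @return Tibble `n_prime`, `expected`, `lo`, `hi`, `best_k`.
#' @export
extrapolate_richness <- function(counts, n_prime, match = NULL, ...) {
  counts <- counts[counts > 0]
  match <- match %||% match_allele_count(counts, ...)
  n <- match$n_ind
  if (any(n_prime < n)) stop("n_prime must be at least the observed sample size")
  n_all <- length(counts)
  purrr::map_dfr(n_prime, function(np) {
    est <- vapply(match$freq_draws, function(q) {
      base <- (1 - q)^(2 * n)
      tgt <- if (is.infinite(np)) 0 else (1 - q)^(2 * np)
      n_all + sum(base - tgt)
    }, numeric(1))
    qs <- stats::quantile(est, c(0.025, 0.975), names = FALSE)
    tibble::tibble(n_prime = np, expected = mean(est), lo = qs[1], hi = qs[2],
                   best_k = match$best_k)
  })
}

#' Fit a Michaelis-Menten saturation curve to an accumulation curve
#'
#' Nonlinear least squares fit of \eqn{D(n) = D_{max} n / (K_{1/2} + n)}
#' with multi-start initials from the Lineweaver-Burk linearization plus
#' perturbations; the asymptote \eqn{D_{max}} estimates saturation
#' diversity. A leave-half-out bootstrap (refitting on random halves of the
#' points) gives a percentile confidence interval for \eqn{D_{max}}.
#'
#' @param curve An `accum_curve` tibble, or any data frame with sample sizes
#'   and statistic values.
#' @param n_col,value_col Column names holding sample size and statistic.
#' @param boot Bootstrap replicates (0 to skip; needs >= 6 points).
#' @param seed Integer seed.
#' @return An object of class `mm_fit` with elements `dmax`, `k_half`,
#'   `rss`, `ci_dmax`, `boot_dmax`, `data`, `fit`. Use [tidy()], [glance()]
#'   and [autoplot()] on it.
#' @export
fit_michaelis_menten <- function(curve, n_col = "n", value_col = "mean",
                                 boot = 200, seed = 1) {
  df <- tibble::tibble(n = as.numeric(curve[[n_col]]),
                       D = as.numeric(curve[[value_col]]))
  df <- df[is.finite(df$n) & is.finite(df$D), ]
  if (length(unique(df$n)) < 3) stop("need at least 3 distinct sample sizes")

  lb_start <- function(d) {
    pos <- d[d$D > 0, ]
    st <- tryCatch({
      co <- stats::coef(stats::lm(I(1 / D) ~ I(1 / n), data = pos))
      dmax <- 1 / co[[1]]
      c(dmax = dmax, k = co[[2]] * dmax)
    }, error = function(e) c(dmax = NA_real_, k = NA_real_))
    if (!all(is.finite(st)) || any(st <= 0)) {
      st <- c(dmax = 1.2 * max(d$D), k = stats::median(d$n))
    }
    st
  }
  fit_one <- function(d, starts) {
    fits <- list()
    for (s in starts) {
      f <- tryCatch(
        minpack.lm::nlsLM(D ~ dmax * n / (k + n), data = d,
                          start = list(dmax = s[[1]], k = s[[2]]),
                          lower = c(1e-9, 1e-9),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
    if (length(fits) == 0) return(NULL)
    rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
    fits[[which.min(rss)]]
  }
  st <- lb_start(df)
  starts <- list(st, st * c(0.5, 0.5), st * c(2, 2), st * c(1, 0.25))
  fit <- fit_one(df, starts)
  if (is.null(fit)) {
    stop("Michaelis-Menten fit failed from all starts (n range ",
         min(df$n), "-", max(df$n), ", D range ", min(df$D), "-", max(df$D), ")")
  }
  co <- stats::coef(fit)

  boot_dmax <- numeric(0)
  if (boot > 0 && nrow(df) >= 6) {
    set.seed(derive_seed(seed, "mmboot"))
    m <- nrow(df)
    for (b in seq_len(boot)) {
      for (try in 1:20) {
        idx <- sample.int(m, floor(m / 2))
        if (length(unique(df$n[idx])) >= 3) break
      }
      fb <- fit_one(df[idx, ], list(co, co * c(0.5, 0.5), co * c(2, 2)))
      if (!is.null(fb)) boot_dmax <- c(boot_dmax, stats::coef(fb)[["dmax"]])
    }
  }
  ci <- if (length(boot_dmax) >= 20) {
    stats::quantile(boot_dmax, c(0.025, 0.975), names = FALSE)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(dmax = co[["dmax"]], k_half = co[["k"]],
                 rss = sum(stats::residuals(fit)^2),
                 ci_dmax = ci, boot_dmax = boot_dmax,
                 data = df, fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten accumulation fit\n")
  cat(sprintf("  Dmax   = %.4g", x$dmax))
  if (all(is.finite(x$ci_dmax))) {
    cat(sprintf("  [%.4g, %.4g] (leave-half-out bootstrap)", x$ci_dmax[1],
                x$ci_dmax[2]))
  }
  cat("\n")
  cat(sprintf("  K_half = %.4g\n", x$k_half))
  cat(sprintf("  RSS    = %.4g on %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}
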