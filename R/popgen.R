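# Per-population diversity statistics: allele spectra, observed/expected
# heterozygosity, hypergeometric rarefied allelic richness, Nei's FST,
# Hardy-Weinberg heterozygote-deficit permutation test.

complete_calls <- function(genotypes) {
  dplyr::filter(genotypes, !is.na(.data$allele1), !is.na(.data$allele2))
}

#' Allele copy-count spectra per population and locus
#'
#' Individuals with a missing call at a locus are excluded from that locus
#' entirely, so every counted individual contributes exactly two copies.
#'
#' @param genotypes Long genotype tibble.
#' @return Tibble `locus`, `population`, `allele`, `count`, `freq`, plus
#'   per-group totals `n_copies` and `n_ind`.
#' @export
allele_spectrum <- function(genotypes) {
  complete_calls(genotypes) %>%
    dplyr::select("locus", "population", "allele1", "allele2") %>%
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") %>%
    dplyr::count(.data$locus, .data$population, .data$allele, name = "count") %>%
    dplyr::group_by(.data$locus, .data$population) %>%
    dplyr::mutate(n_copies = sum(.data$count),
                  n_ind = .data$n_copies %/% 2L,
                  freq = .data$count / .data$n_copies) %>%
    dplyr::ungroup()
}

#' Observed heterozygosity
#'
#' Fraction of called individuals whose two alleles differ.
#'
#' @param genotypes Long genotype tibble (any subset of rows).
#' @return Tibble `locus`, `population`, `n_ind`, `ho`.
#' @export
obs_heterozygosity <- function(genotypes) {
  complete_calls(genotypes) %>%
    dplyr::group_by(.data$locus, .data$population) %>%
    dplyr::summarise(n_ind = dplyr::n(),
                     ho = mean(.data$allele1 != .data$allele2),
                     .groups = "drop")
}

#' Homozygosity rates per population and pooled per group
#'
#' The complement of observed heterozygosity, reported per population and
#' per pooled group (e.g. wild vs farmed escapees).
#'
#' @param genotypes Long genotype tibble.
#' @return Tibble `locus`, `unit`, `level`, `n_ind`, `homozygosity`.
#' @export
homozygosity_rate <- function(genotypes) {
  cc <- complete_calls(genotypes)
  one <- function(unit) {
    cc %>%
      dplyr::group_by(.data$locus, level = .data[[unit]]) %>%
      dplyr::summarise(n_ind = dplyr::n(),
                       homozygosity = mean(.data$allele1 == .data$allele2),
                       .groups = "drop") %>%
      dplyr::mutate(unit = unit, .after = "locus")
  }
  dplyr::bind_rows(one("population"), one("group"))
}

#' Expected heterozygosity (unbiased gene diversity)
#'
#' \eqn{H_e = \frac{N}{N-1} (1 - \sum_i (N_i/N)^2)} over allele copy counts:
#' the small-sample-corrected probability that two copies drawn without
#' replacement differ.
#'
#' @param counts Integer vector of allele copy counts (N >= 2 copies).
#' @return Expected heterozygosity in \[0, 1\].
#' @export
exp_heterozygosity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 allele copies")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` allele
#' copies, by hypergeometric rarefaction:
#' \eqn{AR(g) = \sum_i [1 - \binom{N - N_i}{g} / \binom{N}{g}]}, evaluated
#' in log space. `AR(N)` equals the observed allele count; for diploid data
#' `g` is twice the standardized number of individuals.
#'
#' @param counts Integer vector of allele copy counts.
#' @param g Subsample size in allele copies, `1 <= g <= sum(counts)`.
#' @return Expected allele count at size `g`.
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (g > n) stop("rarefaction size g exceeds the number of allele copies")
  stopifnot(g >= 1)
  lf <- lchoose(n - counts, g) - lchoose(n, g)
  lf[n - counts < g] <- -Inf
  sum(1 - exp(lf))
}

#' Shannon-Weaver diversity index
#'
#' \eqn{H' = -\sum_i p_i \ln p_i} over allele frequencies (natural log by
#' default).
#'
#' @param counts Allele copy counts or frequencies.
#' @param base Logarithm base.
#' @return Index value (0 for a single allele).
#' @export
shannon_index <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Nei's multi-population fixation index
#'
#' Nei's estimator \eqn{F_{ST} = (H_T - \bar H_S)/H_T} with the Nei &
#' Chesser sample-size corrections (harmonic mean sample size, observed
#' heterozygosity correction) applied to both the within-population and
#' total gene diversities. Loci monomorphic across all populations are
#' undefined and reported as `NA`.
#'
#' @param genotypes Long genotype tibble with at least 2 populations of at
#'   least 2 called individuals each.
#' @param pairwise Also return per-locus pairwise population matrices.
#' @return Tibble `locus`, `hs`, `ht`, `fst`; with `pairwise = TRUE`, a
#'   list-column `fst_pairwise` of named matrices.
#' @export
fst_nei <- function(genotypes, pairwise = FALSE) {
  cc <- complete_calls(genotypes)
  one_locus <- function(df) {
    pops <- split(df, df$population)
    if (length(pops) < 2 || any(vapply(pops, nrow, integer(1)) < 2)) {
      stop("need >= 2 populations with >= 2 called individuals each")
    }
    alleles <- sort(unique(c(df$allele1, df$allele2)))
    s <- length(pops)
    nk <- vapply(pops, nrow, integer(1))
    ntilde <- s / sum(1 / nk)
    p <- vapply(pops, function(d) {
      tab <- table(factor(c(d$allele1, d$allele2), levels = alleles))
      as.numeric(tab) / (2 * nrow(d))
    }, numeric(length(alleles)))
    p <- matrix(p, nrow = length(alleles))
    ho <- mean(vapply(pops, function(d) mean(d$allele1 != d$allele2), numeric(1)))
    if (length(alleles) < 2) {
      return(tibble::tibble(hs = 0, ht = 0, fst = NA_real_))
    }
    hs0 <- 1 - mean(colSums(p^2))
    hs <- ntilde / (ntilde - 1) * (hs0 - ho / (2 * ntilde))
    pbar <- rowMeans(p)
    ht <- 1 - sum(pbar^2) + hs / (ntilde * s) - ho / (2 * ntilde * s)
    tibble::tibble(hs = hs, ht = ht, fst = (ht - hs) / ht)
  }
  global <- cc %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::group_modify(~ one_locus(.x)) %>%
    dplyr::ungroup()
  if (!pairwise) return(global)
  pw <- cc %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::group_map(function(df, key) {
      pops <- sort(unique(df$population))
      m <- matrix(NA_real_, length(pops), length(pops),
                  dimnames = list(pops, pops))
      for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
        sub <- df[df$population %in% pops[c(i, j)], ]
        m[i, j] <- m[j, i] <- one_locus(sub)$fst
      }
      m
    })
  global$fst_pairwise <- pw
  global
}

#' Permutation test for Hardy-Weinberg heterozygote deficit
#'
#' Monte-Carlo exact test: the observed allele copies are randomly re-paired
#' into diploid genotypes; the one-sided p-value is the fraction of
#' permutations with at least as many homozygotes as observed (the
#' heterozygote-deficit direction), with the standard +1 correction.
#' Monomorphic samples return p = 1.
#'
#' @param allele1,allele2 Allele vectors of the called individuals (n >= 5).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Tibble `n_ind`, `hom_obs`, `p_value`.
#' @export
hwe_test <- function(allele1, allele2, n_perm = 10000, seed = 1) {
  ok <- !is.na(allele1) & !is.na(allele2)
  allele1 <- allele1[ok]; allele2 <- allele2[ok]
  n <- length(allele1)
  if (n < 5) stop("need at least 5 called individuals")
  copies <- c(allele1, allele2)
  if (length(unique(copies)) == 1) {
    return(tibble::tibble(n_ind = n, hom_obs = n, p_value = 1))
  }
  obs <- sum(allele1 == allele2)
  set.seed(derive_seed(seed, "hwe"))
  odd <- seq(1, 2 * n, by = 2)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(copies)
    if (sum(perm[odd] == perm[odd + 1L]) >= obs) ge <- ge + 1L
  }
  tibble::tibble(n_ind = n, hom_obs = obs,
                 p_value = (ge + 1) / (n_perm + 1))
}

#' Per-population diversity summary
#'
#' One row per locus and population: number of called individuals, allele
#' count, observed and expected heterozygosity, and rarefied allelic
#' richness standardized to `rarefaction_n` individuals (`2 * rarefaction_n`
#' allele copies). Populations with fewer copies than the rarefaction size
#' get `NA` richness.
#'
#' @param genotypes Long genotype tibble.
#' @param rarefaction_n Standard sample size in individuals.
#' @return Tibble `locus`, `population`, `n_ind`, `n_alleles`, `ho`, `he`,
#'   `ar`.
#' @export
diversity_summary <- function(genotypes, rarefaction_n = 17) {
  g <- 2L * rarefaction_n
  spec <- allele_spectrum(genotypes)
  hos <- obs_heterozygosity(genotypes)
  spec %>%
    dplyr::group_by(.data$locus, .data$population) %>%
    dplyr::summarise(
      n_ind = .data$n_ind[1],
      n_alleles = dplyr::n(),
      he = exp_heterozygosity(.data$count),
      ar = if (sum(.data$count) >= g) allelic_richness(.data$count, g) else NA_real_,
      .groups = "drop"
    ) %>%
    dplyr::left_join(hos[, c("locus", "population", "ho")],
                     by = c("locus", "population")) %>%
    dplyr::select("locus", "population", "n_ind", "n_alleles", "ho", "he", "ar")
}
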