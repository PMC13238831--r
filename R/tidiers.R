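# broom-style tidiers for fitted objects.

#' Tidy a Michaelis-Menten accumulation fit
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `conf.low`,
#'   `conf.high` (bootstrap interval, `dmax` only).
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("dmax", "k_half"),
    estimate = c(x$dmax, x$k_half),
    conf.low = c(x$ci_dmax[1], NA_real_),
    conf.high = c(x$ci_dmax[2], NA_real_)
  )
}

#' @rdname tidy.mm_fit
#' @return `glance()` returns a one-row model summary.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    dmax = x$dmax,
    k_half = x$k_half,
    rss = x$rss,
    sigma = sqrt(x$rss / max(nrow(x$data) - 2, 1)),
    nobs = nrow(x$data),
    n_boot = length(x$boot_dmax)
  )
}

#' Tidy a hypothetical-population match
#'
#' @param x A `k_match` object.
#' @param ... Unused.
#' @return The K-vs-discrepancy profile with a `best` indicator.
#' @export
tidy.k_match <- function(x, ...) {
  dplyr::mutate(x$profile, best = .data$K == x$best_k)
}

#' @rdname tidy.k_match
#' @export
glance.k_match <- function(x, ...) {
  tibble::tibble(
    best_k = x$best_k,
    n_observed = length(x$counts),
    n_extra = x$n_extra,
    n_ind = x$n_ind,
    reps = x$reps,
    bw = x$bw
  )
}
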