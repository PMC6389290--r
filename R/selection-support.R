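#' Likelihood-ratio statistic for a pair of nested codon models
#'
#' `2 * (l_alt - l_null)` with degrees of freedom equal to the difference
#' in parameter counts. The alternative must nest the null (`p_alt >
#' p_null`); a slightly negative statistic (within `tolerance`, a
#' numerical-optimisation artefact) is clamped to 0 with a warning.
#'
#' @param null,alt One-row lists/tibbles with `name`, `l` (log-likelihood)
#'   and `p` (parameter count).
#' @param tolerance Clamp tolerance on negative statistics.
#' @return A list `statistic, df`.
#' @export
lrt_statistic <- function(null, alt, tolerance = 1e-6) {
  if (alt$p <= null$p) {
    stop("models are not nested: alternative must have more parameters",
         call. = FALSE)
  }
  stat <- 2 * (alt$l - null$l)
  if (stat < 0) {
    if (stat < -tolerance) {
      stop("alternative model less likely than the null beyond tolerance",
           call. = FALSE)
    }
    warning("negative LRT statistic within tolerance clamped to 0")
    stat <- 0
  }
  list(statistic = stat, df = alt$p - null$p)
}

#' Upper-tail chi-square P-value
#'
#' @param stat Non-negative statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail probability.
#' @export
chi_square_pvalue <- function(stat, df) {
  stopifnot(all(stat >= 0), all(df >= 1))
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio tests over a table of model fits
#'
#' Computes `2 * delta-l`, degrees of freedom and the chi-square P-value
#' for each requested null/alternative pair, always from the supplied
#' log-likelihoods. When a `published` statistic is given for a
#' comparison, a discrepancy against the recomputed value is flagged
#' rather than silently trusted.
#'
#' @param fits Tibble with columns `name, p, l` (one row per fitted
#'   model).
#' @param comparisons Tibble with columns `null, alt` (model names) and
#'   optionally `published` (published `2 * delta-l` values to check).
#' @return Tibble `null, alt, statistic, df, p_value, significant` plus
#'   `published, discrepant` when published values were supplied.
#' @export
lrt_test <- function(fits, comparisons) {
  get_fit <- function(nm) {
    i <- match(nm, fits$name)
    if (is.na(i)) stop("unknown model: ", nm, call. = FALSE)
    list(name = fits$name[i], l = fits$l[i], p = fits$p[i])
  }
  out <- purrr::map2(comparisons$null, comparisons$alt, function(n0, n1) {
    lr <- lrt_statistic(get_fit(n0), get_fit(n1))
    tibble::tibble(null = n0, alt = n1, statistic = lr$statistic,
                   df = lr$df,
                   p_value = chi_square_pvalue(lr$statistic, lr$df))
  }) |> dplyr::bind_rows()
  out$significant <- out$p_value < 0.05
  if ("published" %in% names(comparisons)) {
    out$published <- comparisons$published
    out$discrepant <- !is.na(out$published) &
      abs(out$published - out$statistic) > 0.5
  }
  out
}

#' Count positively selected sites from posterior probabilities
#'
#' Sites whose Bayes-empirical-Bayes posterior strictly exceeds the cutoff
#' are counted as positively selected.
#'
#' @param beb Numeric vector of per-site posteriors in `[0, 1]`.
#' @param cutoff Posterior cutoff in `(0, 1)` (default 0.95).
#' @return Tibble `n_selected, n_sites, fraction`.
#' @export
count_selected_sites <- function(beb, cutoff = 0.95) {
  stopifnot(all(beb >= 0), all(beb <= 1), cutoff > 0, cutoff < 1)
  n <- sum(beb > cutoff)
  tibble::tibble(n_selected = n, n_sites = length(beb),
                 fraction = n / length(beb))
}
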