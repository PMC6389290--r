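#' Pearson correlation of two expression profiles
#'
#' Product-moment correlation on raw TPM (no transform by default; pass
#' `log1p = TRUE` for log-scale correlation).
#'
#' @param x,y Numeric profiles of equal length >= 3.
#' @param log1p Correlate `log1p()`-transformed values.
#' @return The correlation coefficient.
#' @export
pearson_correlation <- function(x, y, log1p = FALSE) {
  if (length(x) != length(y)) stop("profiles differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 libraries", call. = FALSE)
  if (isTRUE(log1p)) { x <- log1p(x); y <- log1p(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance profile", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Asymptotic two-sided P-value for a Pearson correlation
#'
#' Student-t tail: `t = pcc * sqrt((n - 2) / (1 - pcc^2))` with `n - 2`
#' degrees of freedom, assuming normal samples. `|pcc| = 1` returns an
#' exact 0 with the `exact` attribute set.
#'
#' @param pcc Correlation coefficient.
#' @param n Number of paired observations (>= 3).
#' @return Two-sided P-value.
#' @export
asymptotic_pvalue <- function(pcc, n) {
  stopifnot(n >= 3, abs(pcc) <= 1)
  if (abs(pcc) == 1) {
    return(structure(0, exact = TRUE))
  }
  t <- pcc * sqrt((n - 2) / (1 - pcc^2))
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Randomization null distribution of pairwise correlations
#'
#' Builds the genomic-background null for co-expression: in each of
#' `n_permutations` rounds, every library's values are permuted across rows
#' (independently per column by default, destroying inter-row correlation
#' while preserving each library's value distribution), a random subset of
#' `subset_size` rows is drawn, and the Pearson correlations of all
#' unordered pairs in the subset (self-comparisons excluded) are pooled.
#'
#' @param x An [expr_set()] or a numeric matrix (rows = TSS, columns =
#'   libraries, >= 3 columns).
#' @param n_permutations Number of permutation rounds (default 1000).
#' @param subset_size Rows sampled per round (default 1000; clamped to the
#'   row count).
#' @param seed Integer seed; fixed seed gives a bit-identical null.
#' @param shared_permutation Use one shared row permutation for all columns
#'   instead of independent per-column permutations.
#' @return An object of class `coexpr_null`: sorted null values plus the
#'   configuration.
#' @export
randomization_null <- function(x, n_permutations = 1000, subset_size = 1000,
                               seed = NULL, shared_permutation = FALSE) {
  m <- if (inherits(x, "expr_set")) x$tpm else x
  if (nrow(m) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (ncol(m) < 3L) stop("need at least 3 libraries", call. = FALSE)
  subset_size <- min(subset_size, nrow(m))
  if (!is.null(seed)) set.seed(seed)
  vals <- vector("list", n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- if (isTRUE(shared_permutation)) {
      m[sample.int(nrow(m)), , drop = FALSE]
    } else {
      apply(m, 2, sample)
    }
    rows <- sample.int(nrow(perm), subset_size)
    cc <- suppressWarnings(stats::cor(t(perm[rows, , drop = FALSE])))
    vals[[b]] <- cc[lower.tri(cc)]
  }
  vals <- unlist(vals, use.names = FALSE)
  vals <- vals[!is.na(vals)] # constant permuted rows have no defined cor
  structure(list(values = sort(vals), n_permutations = n_permutations,
                 subset_size = subset_size, seed = seed,
                 shared_permutation = shared_permutation),
            class = "coexpr_null")
}

#' @export
print.coexpr_null <- function(x, ...) {
  cat(sprintf("<coexpr_null> %d values (%d permutations x subsets of %d)\n",
              length(x$values), x$n_permutations, x$subset_size))
  invisible(x)
}

#' Empirical P-value of a correlation against a randomization null
#'
#' With the default `tail = "directed"` rule the P-value is one-sided in
#' the direction of the observation: the lower-tail fraction
#' `F = #(null <= pcc) / N` when the observation falls below the null
#' median, `1 - F` otherwise. The raw fraction is reported (no
#' pseudocount), so a value outside the null range gives an exact 0;
#' `corrected = TRUE` applies the `(r + 1) / (N + 1)` estimator instead.
#'
#' @param null A `coexpr_null`.
#' @param pcc Observed correlation.
#' @param tail `"directed"` (default) or `"lower"`.
#' @param corrected Use the add-one permutation estimator.
#' @return The randomization P-value.
#' @export
empirical_pvalue <- function(null, pcc, tail = c("directed", "lower"),
                             corrected = FALSE) {
  tail <- match.arg(tail)
  vals <- null$values
  if (length(vals) == 0L) stop("empty null distribution", call. = FALSE)
  n <- length(vals)
  r <- sum(vals <= pcc)
  f <- if (corrected) (r + 1) / (n + 1) else r / n
  if (tail == "lower") return(f)
  if (pcc < stats::median(vals)) f else {
    if (corrected) (n - r + 1) / (n + 1) else 1 - f
  }
}

#' Co-expression test for TSS pairs
#'
#' For each requested pair of rows: Pearson correlation, asymptotic t-based
#' P-value, and the randomization P-value against the supplied (or freshly
#' built) null.
#'
#' @param x An [expr_set()] or numeric matrix.
#' @param pairs Two-column data frame / tibble of row identifiers
#'   (`tss_a`, `tss_b`), or `NULL` for all unordered pairs.
#' @param null A `coexpr_null`; built from `x` with `...` when omitted.
#' @param ... Passed to [randomization_null()] when `null` is missing.
#' @return Tibble `tss_a, tss_b, pcc, p_asymptotic, p_randomization, n`.
#' @export
coexpression_test <- function(x, pairs = NULL, null = NULL, ...) {
  m <- if (inherits(x, "expr_set")) x$tpm else x
  if (is.null(pairs)) {
    ids <- rownames(m)
    cmb <- utils::combn(ids, 2)
    pairs <- tibble::tibble(tss_a = cmb[1, ], tss_b = cmb[2, ])
  } else {
    pairs <- tibble::tibble(tss_a = pairs[[1]], tss_b = pairs[[2]])
  }
  if (is.null(null)) null <- randomization_null(m, ...)
  res <- purrr::pmap(pairs, function(tss_a, tss_b) {
    xa <- m[tss_a, ]; xb <- m[tss_b, ]
    pcc <- pearson_correlation(xa, xb)
    tibble::tibble(
      tss_a = tss_a, tss_b = tss_b, pcc = pcc,
      p_asymptotic = as.numeric(asymptotic_pvalue(pcc, length(xa))),
      p_randomization = empirical_pvalue(null, pcc),
      n = length(xa))
  })
  dplyr::bind_rows(res)
}

#' Maximal expression of each TSS profile
#'
#' The highest TPM a TSS attains in any library (ME), with the library that
#' attains it. Ties take the first library in column order and are flagged.
#'
#' @param x An [expr_set()] or numeric matrix.
#' @return Tibble `tss_id, me, library, tie`.
#' @export
maximal_expression <- function(x) {
  m <- if (inherits(x, "expr_set")) x$tpm else x
  if (ncol(m) < 1L) stop("empty profile", call. = FALSE)
  idx <- apply(m, 1, which.max)
  tibble::tibble(
    tss_id = rownames(m),
    me = m[cbind(seq_len(nrow(m)), idx)],
    library = colnames(m)[idx],
    tie = apply(m, 1, function(r) sum(r == max(r)) > 1))
}

#' Group enrichment ratio of expression profiles
#'
#' Fold-enrichment of mean expression inside a library group over the mean
#' outside it (e.g. endothelial over non-endothelial libraries). A zero
#' out-group mean with positive in-group mean yields `Inf` with the
#' `infinite` flag.
#'
#' @param x An [expr_set()] (group defaults to its endothelial libraries)
#'   or numeric matrix.
#' @param group Character vector of library ids forming the in-group.
#' @return Tibble `tss_id, mean_in, mean_out, fold_ratio, infinite`.
#' @export
group_enrichment_ratio <- function(x, group = NULL) {
  m <- if (inherits(x, "expr_set")) x$tpm else x
  if (is.null(group) && inherits(x, "expr_set")) {
    group <- x$meta$library_id[x$meta$endothelial]
  }
  if (length(setdiff(group, colnames(m))) > 0L) {
    stop("group contains unknown libraries", call. = FALSE)
  }
  ing <- colnames(m) %in% group
  if (!any(ing) || all(ing)) {
    stop("group and complement must both be non-empty", call. = FALSE)
  }
  mean_in <- unname(rowMeans(m[, ing, drop = FALSE]))
  mean_out <- unname(rowMeans(m[, !ing, drop = FALSE]))
  ratio <- ifelse(mean_out == 0, ifelse(mean_in == 0, NaN, Inf),
                  mean_in / mean_out)
  tibble::tibble(tss_id = rownames(m), mean_in = mean_in,
                 mean_out = mean_out, fold_ratio = ratio,
                 infinite = is.infinite(ratio))
}

#' Enrichment rank of a target row among all fold ratios
#'
#' Competition ranking: rank 1 is the most enriched; ties share the minimum
#' rank. The percentile is `1 - (rank - 1) / N`.
#'
#' @param ratios Numeric vector of fold ratios, named by row id.
#' @param target Row id (or index) of the target.
#' @return Tibble `rank, percentile, n`.
#' @export
enrichment_rank <- function(ratios, target) {
  if (is.character(target)) {
    if (!target %in% names(ratios)) stop("target not among rows", call. = FALSE)
    tval <- ratios[[target]]
  } else {
    tval <- ratios[[target]]
  }
  rank <- 1L + sum(ratios > tval)
  tibble::tibble(rank = rank,
                 percentile = 1 - (rank - 1) / length(ratios),
                 n = length(ratios))
}

#' Rank-sum enrichment z-score of a profile in a library category
#'
#' Wilcoxon-Mann-Whitney U of the in-category values against the rest,
#' standardised with the tie-corrected null standard deviation:
#' `z = (U - mu_U) / sigma_U`, positive when the category ranks higher.
#' All-tied profiles return `z = 0` with the `degenerate` flag.
#'
#' @param profile Numeric expression profile, named by library.
#' @param category Character vector of library ids (non-empty, proper
#'   subset).
#' @return A number with attribute `degenerate`.
#' @export
ranksum_enrichment_z <- function(profile, category) {
  inc <- names(profile) %in% category
  n1 <- sum(inc); n2 <- sum(!inc)
  if (n1 == 0L || n2 == 0L) {
    stop("category and complement must both be non-empty", call. = FALSE)
  }
  r <- rank(profile)
  u <- sum(r[inc]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(profile)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure((u - mu) / sqrt(sigma2), degenerate = FALSE)
}

#' Rank-sum enrichment z-scores across all metadata categories
#'
#' Applies [ranksum_enrichment_z()] to every category label present in the
#' expression set's library metadata, for each TSS.
#'
#' @param x An [expr_set()].
#' @param tss_ids Rows to score (default: all).
#' @return Tibble `tss_id, category, n_libraries, z`, sorted by `z` within
#'   TSS.
#' @export
category_enrichment <- function(x, tss_ids = NULL) {
  stopifnot(inherits(x, "expr_set"))
  if (is.null(tss_ids)) tss_ids <- rownames(x$tpm)
  cats <- sort(unique(unlist(x$meta$categories)))
  out <- purrr::map(tss_ids, function(id) {
    profile <- x$tpm[id, ]
    names(profile) <- colnames(x$tpm)
    purrr::map(cats, function(ct) {
      libs <- x$meta$library_id[vapply(x$meta$categories,
                                       function(s) ct %in% s, TRUE)]
      if (length(libs) == 0L || length(libs) == length(profile)) return(NULL)
      tibble::tibble(tss_id = id, category = ct, n_libraries = length(libs),
                     z = as.numeric(ranksum_enrichment_z(profile, libs)))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  dplyr::arrange(out, .data$tss_id, dplyr::desc(.data$z))
}

#' Is a TSS conserved by the expressed-promoter rule?
#'
#' A promoter (e.g. the orthologous region in another species) counts as
#' conserved when its maximal expression strictly exceeds the
#' expressed-gene cutoff (10 TPM by default).
#'
#' @param me Maximal expression in TPM (>= 0).
#' @param threshold Cutoff (default 10).
#' @return Logical vector.
#' @examples
#' tss_conserved(c(305, 3, 10)) # TRUE FALSE FALSE
#' @export
tss_conserved <- function(me, threshold = 10) {
  stopifnot(all(me >= 0))
  me > threshold
}
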