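#' Manhattan distance between two architecture vectors
#'
#' Sum over the panel of absolute coordinate differences. For binary vectors
#' this equals the cardinality of the symmetric difference of the two TF
#' sets, i.e. `|union| - |intersection|`.
#'
#' @param v,w Numeric vectors over the same panel (same length; if both are
#'   named the names must agree).
#' @return Non-negative number.
#' @export
manhattan_distance <- function(v, w) {
  if (length(v) != length(w)) stop("panel mismatch", call. = FALSE)
  if (!is.null(names(v)) && !is.null(names(w)) && !identical(names(v), names(w))) {
    stop("panel mismatch", call. = FALSE)
  }
  sum(abs(v - w))
}

#' All pairwise Manhattan distances between architecture vectors
#'
#' @param vectors Promoters-by-panel matrix from [arch_vectors()].
#' @return A symmetric matrix with zero diagonal, class `arch_dist`,
#'   attribute `metric = "manhattan"`.
#' @export
arch_distance_matrix <- function(vectors) {
  d <- as.matrix(stats::dist(vectors, method = "manhattan"))
  structure(d, metric = "manhattan", class = c("arch_dist", class(d)))
}

#' Jaccard index of two TF sets
#'
#' `|intersection| / |union|`; defined as 1 when both sets are empty
#' (identical sets at distance zero).
#'
#' @param a,b Character vectors (sets; duplicates ignored).
#' @return Number in `[0, 1]`.
#' @examples
#' jaccard_index(c("a", "b"), c("a", "c")) # 1/3
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Shared-TF report for one focal architecture against others
#'
#' Venn-style summary of TF sets: the TFs common to all architectures
#' (focal plus others), the TFs unique to the focal promoter (absent from
#' every other), the maximum pairwise intersection size between the focal
#' set and any single other, and the full per-pair intersections.
#'
#' @param focal Character vector: the focal promoter's TF set.
#' @param others Named list of TF sets (at least one).
#' @return A list with elements `common_to_all`, `unique_to_focal`,
#'   `max_pairwise_shared` and `pairwise` (tibble `other, n_shared,
#'   shared`).
#' @export
shared_tf_report <- function(focal, others) {
  if (length(others) < 1L) stop("need at least one other architecture",
                                call. = FALSE)
  focal <- unique(focal)
  others <- lapply(others, unique)
  common <- Reduce(intersect, others, init = focal)
  uniq <- setdiff(focal, Reduce(union, others))
  pairwise <- tibble::tibble(
    other = names(others) %||% paste0("other", seq_along(others)),
    n_shared = vapply(others, function(s) length(intersect(focal, s)), 0L),
    shared = lapply(others, function(s) sort(intersect(focal, s))))
  list(common_to_all = sort(common),
       unique_to_focal = sort(uniq),
       max_pairwise_shared = max(pairwise$n_shared),
       pairwise = pairwise)
}

#' Background distribution of pairwise architecture distances
#'
#' All pairwise Manhattan distances between the given vectors excluding
#' self-comparisons, or a uniform sample of unordered pairs without
#' replacement when `max_pairs` is set (for genome-scale backgrounds where
#' full enumeration is pointless).
#'
#' @param vectors Promoters-by-panel matrix.
#' @param max_pairs Optional cap on the number of sampled pairs.
#' @param seed Optional integer seed for the pair sampling.
#' @return A list with `distances` (numeric vector), `mean`, `median`,
#'   `n_pairs`.
#' @export
background_distances <- function(vectors, max_pairs = NULL, seed = NULL) {
  n <- nrow(vectors)
  if (n < 2L) stop("need at least two architectures", call. = FALSE)
  n_all <- n * (n - 1) / 2
  if (is.null(max_pairs) || max_pairs >= n_all) {
    d <- as.vector(stats::dist(vectors, method = "manhattan"))
  } else {
    if (!is.null(seed)) set.seed(seed)
    pick <- sample.int(n_all, max_pairs)
    # unrank column-major lower-triangle indices of dist()
    j <- rep(seq_len(n - 1), times = (n - 1):1)
    i <- sequence((n - 1):1) + j
    d <- vapply(pick, function(k) {
      sum(abs(vectors[i[k], ] - vectors[j[k], ]))
    }, 0)
  }
  list(distances = d, mean = mean(d), median = stats::median(d),
       n_pairs = length(d))
}

#' Compare two groups of distances with a rank-sum test
#'
#' Two-sided Wilcoxon-Mann-Whitney test: exact enumeration when both groups
#' have at most 8 values and there are no ties, otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param group_a,group_b Numeric vectors of distances (non-empty).
#' @return Two-sided P-value.
#' @export
compare_distance_groups <- function(group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  exact <- length(group_a) <= 8 && length(group_b) <= 8
  p <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)$p.value)
  # fully tied data carry no evidence either way
  if (is.nan(p)) p <- 1
  p
}

#' Marginal presence probabilities of each TF across promoters
#'
#' @param binary Promoters-by-panel 0/1 matrix.
#' @return Named vector `p_k` = fraction of promoters with TF `k` present.
#' @export
marginal_tf_probabilities <- function(binary) {
  if (nrow(binary) < 1L) stop("need at least one promoter", call. = FALSE)
  colMeans(binary > 0)
}

#' Expected probability of a binary architecture under site independence
#'
#' The independence model scores a binary architecture as the product of
#' per-TF marginals: present TFs contribute `p_k`, absent TFs `1 - p_k`.
#' Over any fixed panel the probabilities of all `2^n` architectures sum
#' to 1.
#'
#' @param arch_binary 0/1 vector over the panel.
#' @param marginals Per-TF presence probabilities over the same panel.
#' @return `P_E` in `[0, 1]`.
#' @export
expected_architecture_probability <- function(arch_binary, marginals) {
  if (length(arch_binary) != length(marginals)) {
    stop("panel mismatch", call. = FALSE)
  }
  stopifnot(all(arch_binary %in% c(0, 1)),
            all(marginals >= 0), all(marginals <= 1))
  prod(ifelse(arch_binary == 1, marginals, 1 - marginals))
}

#' Observed probability of a binary architecture in a population
#'
#' Exact-match frequency of the binary pattern among all promoters.
#'
#' @param arch_binary 0/1 vector over the panel.
#' @param all_binary Promoters-by-panel 0/1 matrix (non-empty).
#' @return `P_O` in `[0, 1]`.
#' @export
observed_architecture_probability <- function(arch_binary, all_binary) {
  if (nrow(all_binary) < 1L) stop("empty population", call. = FALSE)
  mean(apply(all_binary, 1, function(r) all(r == arch_binary)))
}

#' Per-promoter architecture probabilities and enrichment
#'
#' For every promoter: the independence-model expected probability `P_E` of
#' its binary architecture, the observed population frequency `P_O`, and
#' the enrichment ratio `P_O / P_E`. A zero `P_E` with positive `P_O` is
#' reported as `Inf` with `enrichment_infinite = TRUE` rather than an
#' error.
#'
#' @param binary Promoters-by-panel 0/1 matrix.
#' @param marginals Optional marginals; estimated from `binary` by default.
#' @return Tibble `tss_id, n_present, p_expected, p_observed, enrichment,
#'   enrichment_infinite`.
#' @export
architecture_probabilities <- function(binary, marginals = NULL) {
  if (is.null(marginals)) marginals <- marginal_tf_probabilities(binary)
  keys <- apply(binary, 1, paste, collapse = "")
  p_o <- as.vector(table(keys)[keys]) / nrow(binary)
  p_e <- apply(binary, 1, expected_architecture_probability, marginals)
  enr <- ifelse(p_e == 0 & p_o > 0, Inf,
                ifelse(p_e == 0, 0, p_o / p_e))
  tibble::tibble(
    tss_id = rownames(binary) %||% as.character(seq_len(nrow(binary))),
    n_present = rowSums(binary),
    p_expected = p_e, p_observed = p_o, enrichment = enr,
    enrichment_infinite = is.infinite(enr))
}

#' Moments of the architecture-size distribution
#'
#' Summarises per-promoter TF-set cardinalities: mean, median, variance,
#' skewness (Fisher-Pearson moment coefficient, e1071 type 1), excess
#' kurtosis (same convention), min and max.
#'
#' @param sizes Integer vector of cardinalities, or a 0/1 matrix whose row
#'   sums are used.
#' @return One-row tibble of the moments.
#' @export
architecture_size_summary <- function(sizes) {
  if (is.matrix(sizes)) sizes <- rowSums(sizes > 0)
  if (length(sizes) < 2L) stop("need at least two architectures", call. = FALSE)
  tibble::tibble(
    mean = mean(sizes), median = stats::median(sizes),
    variance = stats::var(sizes),
    skewness = e1071::skewness(sizes, type = 1),
    kurtosis = e1071::kurtosis(sizes, type = 1),
    min = min(sizes), max = max(sizes))
}

#' Heatmap of an architecture distance matrix
#'
#' @param object An `arch_dist` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arch_dist <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("a", "b", "distance")
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste(attr(object, "metric"), "distance")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
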