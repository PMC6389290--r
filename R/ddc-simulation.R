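#' Build an ancestral promoter for duplication-loss simulation
#'
#' Under the duplication-degeneration-complementation (DDC) null, the
#' ancestral promoter carries every TF bound by either extant paralog. Two
#' representations are supported: `independent` mode keeps only the union
#' of the TF sets (sites lost independently), `clustered` mode keeps the
#' sites with their window-relative coordinates (sites lost by random DNA
#' deletions, so co-located sites are lost together).
#'
#' @param arch_a,arch_b For `independent` mode: character vectors (TF
#'   sets). For `clustered` mode: tibbles `tf, start, end` with
#'   window-relative half-open coordinates inside `[0, region_length)`.
#' @param mode `"independent"` or `"clustered"`.
#' @param region_length Simulated DNA region length in bases (default
#'   6000, a 6-kb promoter window).
#' @return An object of class `ddc_ancestral`.
#' @export
ddc_ancestral <- function(arch_a, arch_b, mode = c("independent", "clustered"),
                          region_length = 6000) {
  mode <- match.arg(mode)
  if (mode == "independent") {
    tfs <- union(unique(arch_a), unique(arch_b))
    if (length(tfs) == 0L) stop("empty ancestral TF set", call. = FALSE)
    anc <- list(mode = mode, tfs = sort(tfs), region_length = region_length)
  } else {
    sites <- dplyr::bind_rows(tibble::as_tibble(arch_a),
                              tibble::as_tibble(arch_b))
    if (nrow(sites) == 0L) stop("empty ancestral site list", call. = FALSE)
    if (any(sites$start < 0) || any(sites$end > region_length) ||
        any(sites$start >= sites$end)) {
      stop("site coordinates must lie inside [0, region_length)",
           call. = FALSE)
    }
    anc <- list(mode = mode, sites = sites,
                tfs = sort(unique(sites$tf)), region_length = region_length)
  }
  structure(anc, class = "ddc_ancestral")
}

#' @export
print.ddc_ancestral <- function(x, ...) {
  cat(sprintf("<ddc_ancestral> %s mode, %d TFs%s\n", x$mode, length(x$tfs),
              if (x$mode == "clustered")
                sprintf(", %d sites in %d bp", nrow(x$sites), x$region_length)
              else ""))
  invisible(x)
}

#' Simulate post-duplication TF loss with independent sites
#'
#' Each run creates two descendant copies of the ancestral TF set; each
#' copy independently loses uniformly random TFs one at a time until its
#' cardinality is at most its target (equivalent to keeping a uniform
#' random subset of the target size; the equivalence is unit-tested). The
#' per-run statistic is the cardinality of the intersection of the two
#' surviving TF sets.
#'
#' @param anc A `ddc_ancestral` (either mode; only the TF set is used).
#' @param target_n1,target_n2 Target cardinalities of the two descendants
#'   (the observed paralog TF-set sizes); must not exceed the ancestral
#'   size.
#' @param runs Number of Monte-Carlo runs (default 10000).
#' @param seed Integer seed.
#' @return A `ddc_sim` object with per-run `shared_counts`.
#' @export
simulate_ddc_independent <- function(anc, target_n1, target_n2,
                                     runs = 10000, seed = NULL) {
  tfs <- anc$tfs
  n <- length(tfs)
  if (target_n1 > n || target_n2 > n) {
    stop("target cardinality exceeds ancestral set size", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  shared <- integer(runs)
  for (r in seq_len(runs)) {
    d1 <- lose_until(tfs, target_n1)
    d2 <- lose_until(tfs, target_n2)
    shared[r] <- length(intersect(d1, d2))
  }
  new_ddc_sim(shared, mode = "independent", anc = anc, seed = seed,
              config = list(target_n1 = target_n1, target_n2 = target_n2))
}

# sequential uniform losses without replacement down to the target size
lose_until <- function(tfs, target) {
  while (length(tfs) > target) {
    tfs <- tfs[-sample.int(length(tfs), 1L)]
  }
  tfs
}

#' Simulate post-duplication TF loss with clustered sites
#'
#' Each run creates two descendant copies of the ancestral site layout.
#' Each copy independently accumulates random deletions of
#' `deletion_size` bases (start uniform on `[0, region_length -
#' deletion_size]`, positions on the original coordinate system, overlaps
#' between deletions allowed); a site is destroyed when any deletion
#' overlaps it by at least one base. Deletions accumulate until the
#' descendant's distinct-TF cardinality is at most its target. Co-located
#' sites are therefore lost together more often than under the
#' independent-site model.
#'
#' @param anc A clustered-mode `ddc_ancestral`.
#' @param target_n1,target_n2 Target distinct-TF cardinalities.
#' @param deletion_size Deletion length in bases (default 100).
#' @param runs Number of Monte-Carlo runs (default 10000).
#' @param seed Integer seed.
#' @param max_cycles Abort a run with a diagnostic if the target is still
#'   unreached after this many deletion cycles.
#' @return A `ddc_sim` object.
#' @export
simulate_ddc_clustered <- function(anc, target_n1, target_n2,
                                   deletion_size = 100, runs = 10000,
                                   seed = NULL, max_cycles = 10000) {
  stopifnot(anc$mode == "clustered")
  if (deletion_size >= anc$region_length) {
    stop("deletion_size must be smaller than the region", call. = FALSE)
  }
  n <- length(anc$tfs)
  if (target_n1 > n || target_n2 > n) {
    stop("target cardinality exceeds ancestral TF count", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  shared <- integer(runs)
  for (r in seq_len(runs)) {
    d1 <- delete_until(anc, target_n1, deletion_size, max_cycles)
    d2 <- delete_until(anc, target_n2, deletion_size, max_cycles)
    shared[r] <- length(intersect(d1, d2))
  }
  new_ddc_sim(shared, mode = "clustered", anc = anc, seed = seed,
              config = list(target_n1 = target_n1, target_n2 = target_n2,
                            deletion_size = deletion_size))
}

delete_until <- function(anc, target, deletion_size, max_cycles) {
  alive <- rep(TRUE, nrow(anc$sites))
  s <- anc$sites$start
  e <- anc$sites$end
  surviving <- unique(anc$sites$tf)
  cycles <- 0L
  while (length(surviving) > target) {
    cycles <- cycles + 1L
    if (cycles > max_cycles) {
      stop("deletion target unreachable within max_cycles", call. = FALSE)
    }
    del_start <- stats::runif(1, 0, anc$region_length - deletion_size)
    del_end <- del_start + deletion_size
    alive <- alive & !(s < del_end & e > del_start)
    surviving <- unique(anc$sites$tf[alive])
  }
  surviving
}

new_ddc_sim <- function(shared, mode, anc, seed, config) {
  structure(list(shared_counts = shared, runs = length(shared), mode = mode,
                 ancestral_size = length(anc$tfs), seed = seed,
                 config = config),
            class = "ddc_sim")
}

#' @export
print.ddc_sim <- function(x, ...) {
  cat(sprintf("<ddc_sim> %s model, %d runs, ancestral set of %d TFs\n",
              x$mode, x$runs, x$ancestral_size))
  print(summary(x$shared_counts))
  invisible(x)
}

#' Empirical P-value of an observed shared-TF count under a DDC simulation
#'
#' The fraction of runs in which the simulated intersection cardinality is
#' at most the observed number of TFs shared between the two paralog
#' promoters. Small values mean the paralogs share fewer TFs than
#' complementary loss from a common ancestor would produce.
#'
#' @param result A `ddc_sim`.
#' @param observed_shared Observed shared-TF count.
#' @return P-value in `[0, 1]`.
#' @export
ddc_pvalue <- function(result, observed_shared) {
  stopifnot(result$runs >= 1)
  mean(result$shared_counts <= observed_shared)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ddc_sim <- function(x, ...) {
  tibble::tibble(shared = as.integer(names(table(x$shared_counts))),
                 n_runs = as.integer(table(x$shared_counts)),
                 proportion = as.numeric(table(x$shared_counts)) / x$runs)
}

#' @export
glance.ddc_sim <- function(x, ...) {
  tibble::tibble(mode = x$mode, runs = x$runs,
                 ancestral_size = x$ancestral_size,
                 mean_shared = mean(x$shared_counts),
                 median_shared = stats::median(x$shared_counts))
}

#' Histogram of simulated shared-TF counts
#'
#' @param object A `ddc_sim`.
#' @param observed_shared Optional observed count drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddc_sim <- function(object, observed_shared = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$shared, .data$proportion)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "shared TFs between descendants",
                  y = "proportion of runs",
                  title = sprintf("DDC %s-site model (%d runs)",
                                  object$mode, object$runs)) +
    ggplot2::theme_minimal()
  if (!is.null(observed_shared)) {
    p <- p + ggplot2::geom_vline(xintercept = observed_shared,
                                 linetype = "dashed", colour = "red")
  }
  p
}
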