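# small in-code builders shared across test files

tiny_peaks <- function() {
  tibble::tibble(
    chrom = c("chr11", "chr11", "chr11", "chr12"),
    start = c(124764000, 124765000, 124765100, 500),
    end = c(124764800, 124765300, 124765400, 900),
    tf = c("GATA2", "CTCF", "CTCF", "MAX"),
    qs = c(704, 800, 650, 120),
    cell_type = c("HUVEC", "HUVEC", "K562", "K562"))
}

tiny_windows <- function() {
  tibble::tibble(
    tss_id = c("T1", "T2"),
    chrom = c("chr11", "chr12"),
    start = c(124764760, 0),
    end = c(124770760, 6000),
    cluster_start = c(124767260, 2500),
    cluster_end = c(124768260, 3500),
    strand = c("-", "+"))
}

tiny_expr <- function(n_tss = 6, n_lib = 10, n_endo = 4, seed = 42) {
  set.seed(seed)
  libs <- sprintf("L%02d", seq_len(n_lib))
  tpm <- matrix(stats::rlnorm(n_tss * n_lib, log(5), 1), nrow = n_tss,
                dimnames = list(sprintf("T%d", seq_len(n_tss)), libs))
  meta <- tibble::tibble(
    library_id = libs,
    categories = lapply(seq_len(n_lib), function(i)
      if (i <= n_endo) c("endothelial cell") else c("other cell")),
    endothelial = seq_len(n_lib) <= n_endo)
  expr_set(tpm, meta)
}

# brute-force all-pairs half-open interval overlap, the oracle for the
# IRanges-backed assignment
brute_force_overlaps <- function(windows, peaks) {
  out <- list()
  for (i in seq_len(nrow(windows))) {
    for (j in seq_len(nrow(peaks))) {
      if (windows$chrom[i] == peaks$chrom[j] &&
          windows$start[i] < peaks$end[j] &&
          peaks$start[j] < windows$end[i]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0L) matrix(integer(), ncol = 2)
  else do.call(rbind, out)
}

# exhaustive-enumeration oracle for the independent-loss shared-count
# distribution: every pair of (subset of size n1, subset of size n2) is
# equally likely
enumerate_shared_distribution <- function(n_ancestral, n1, n2) {
  anc <- seq_len(n_ancestral)
  subs1 <- utils::combn(anc, n1, simplify = FALSE)
  subs2 <- utils::combn(anc, n2, simplify = FALSE)
  counts <- table(unlist(lapply(subs1, function(a)
    vapply(subs2, function(b) length(intersect(a, b)), 0L))))
  probs <- as.numeric(counts) / (length(subs1) * length(subs2))
  stats::setNames(probs, names(counts))
}
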