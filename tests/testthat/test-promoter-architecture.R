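test_that("promoter windows are symmetric 6-kb spans around the cluster midpoint", {
  tss <- robo_tss_clusters()
  w <- build_promoter_windows(tss)
  r4 <- w[w$tss_id == "ROBO4-TSS1", ]
  expect_equal(r4$start, 124764760)
  expect_equal(r4$end, 124770760)
  expect_equal(r4$chrom, "chr11")

  # published windows match the midpoint rule for every promoter except the
  # one with a typo'd printed start
  pub <- robo_promoter_windows()
  m <- merge(w, pub, by = "tss_id", suffixes = c("", "_pub"))
  agree <- m$start == m$start_pub
  expect_equal(sum(!agree), 1L)
  expect_equal(m$tss_id[!agree], "ROBO2-TSS2")
})

test_that("windows clamp at contig boundaries and reject degenerate clusters", {
  tss <- tibble::tibble(tss_id = "T", chrom = "chr1", start = 0, end = 1000,
                        strand = "+")
  w <- build_promoter_windows(tss, halfwidth = 3000,
                              contig_lengths = c(chr1 = 10000))
  expect_equal(w$start, 0)
  expect_equal(w$end, 3500)

  bad <- tibble::tibble(tss_id = "T", chrom = "chr1", start = 5, end = 5,
                        strand = "+")
  expect_error(build_promoter_windows(bad), "start >= end")
})

test_that("upstream-only mode places the span by strand", {
  tss <- tibble::tibble(tss_id = c("P", "M"), chrom = "chr1",
                        start = c(10000, 10000), end = c(11000, 11000),
                        strand = c("+", "-"))
  w <- build_promoter_windows(tss, halfwidth = 1500, upstream_only = TRUE)
  expect_equal(w$start[w$tss_id == "P"], 10500 - 3000)
  expect_equal(w$end[w$tss_id == "P"], 10500)
  expect_equal(w$start[w$tss_id == "M"], 10500)
  expect_equal(w$end[w$tss_id == "M"], 10500 + 3000)
})

test_that("strength classification is strict at the cutoff", {
  expect_equal(classify_strength(c(704, 119, 500, 501)),
               c("strong", "weak", "weak", "strong"))
  expect_error(classify_strength(-1), "negative")
})

test_that("peak-to-window assignment follows half-open overlap on one chromosome", {
  windows <- tiny_windows()
  peaks <- tibble::tibble(
    chrom = c("chr11", "chr12", "chr11", "chr11", "chr11"),
    start = c(124764000, 1000, 124765000, 124765100, 124770760),
    end = c(124764800, 2000, 124765300, 124765400, 124771000),
    tf = c("GATA2", "MAX", "CTCF", "CTCF", "FOS"),
    qs = c(704, 120, 800, 650, 900),
    cell_type = c("HUVEC", "K562", "HUVEC", "K562", "HUVEC"))
  arch <- assemble_architectures(windows, peaks)

  t1 <- arch[arch$tss_id == "T1", ]
  # 40-base overlap at the left edge assigns the GATA2 peak
  expect_true("GATA2" %in% t1$tf)
  # two strong CTCF peaks inside the window count twice
  expect_equal(t1$n[t1$tf == "CTCF" & t1$strength == "strong"], 2L)
  # abutting half-open intervals (peak starts at window end) do not overlap
  expect_false("FOS" %in% t1$tf)
  # chr12 peak goes to the chr12 window only
  expect_equal(arch$tf[arch$tss_id == "T2"], "MAX")
  # endothelial peak counting
  expect_equal(t1$n_endothelial[t1$tf == "CTCF" & t1$strength == "strong"], 1L)
})

test_that("blacklisted TFs are dropped and stray panel symbols are an error", {
  windows <- tiny_windows()
  peaks <- tibble::tibble(chrom = "chr11", start = 124765000,
                          end = 124765300, tf = c("POLR2A", "CTCF"),
                          qs = c(900, 800), cell_type = "HUVEC")
  arch <- assemble_architectures(windows, peaks)
  expect_false("POLR2A" %in% arch$tf)
  expect_error(assemble_architectures(windows, peaks, panel = c("GATA2")),
               "CTCF")
})

test_that("interval assignment agrees with the brute-force all-pairs oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n_w <- 20; n_p <- 60
    windows <- tibble::tibble(
      tss_id = sprintf("W%02d", seq_len(n_w)),
      chrom = sample(c("chr1", "chr2"), n_w, replace = TRUE),
      start = sample.int(5000, n_w))
    windows$end <- windows$start + sample.int(800, n_w)
    peaks <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n_p, replace = TRUE),
      start = sample.int(5500, n_p))
    peaks$end <- peaks$start + sample.int(300, n_p)
    peaks$tf <- sample(LETTERS[1:4], n_p, replace = TRUE)
    peaks$qs <- sample.int(1000, n_p)
    peaks$cell_type <- "X"

    got <- promdiv:::overlap_pairs(windows, peaks)
    want <- brute_force_overlaps(windows, peaks)
    got_keys <- sort(paste(got$tss_id, got$tf, got$qs))
    want_keys <- sort(paste(windows$tss_id[want[, 1]], peaks$tf[want[, 2]],
                            peaks$qs[want[, 2]]))
    expect_equal(got_keys, want_keys)
  }
})

test_that("assigned-peak counts never exceed peaks times overlapping windows", {
  set.seed(11)
  windows <- tibble::tibble(tss_id = c("A", "B"), chrom = "chr1",
                            start = c(0, 500), end = c(1000, 1500))
  peaks <- tibble::tibble(chrom = "chr1", start = c(600, 2000),
                          end = c(700, 2100), tf = "CTCF", qs = 800,
                          cell_type = "X")
  arch <- assemble_architectures(windows, peaks)
  # the first peak overlaps both windows (once per window), the second none
  expect_equal(sum(arch$n), 2L)
})

test_that("vector encodings follow the panel, the mode and the weak flag", {
  sites <- tibble::tibble(
    tss_id = c("T1", "T1", "T1", "T2"),
    tf = c("CTCF", "CTCF", "GATA2", "GATA2"),
    strength = c("strong", "strong", "weak", "strong"))
  arch <- arch_from_sites(sites, panel = c("CTCF", "GATA2", "MAX"))

  cnt <- arch_vectors(arch, mode = "count", include_weak = FALSE)
  expect_equal(unname(cnt["T1", ]), c(2, 0, 0))
  cnt_w <- arch_vectors(arch, mode = "count", include_weak = TRUE)
  expect_equal(unname(cnt_w["T1", ]), c(2, 1, 0))

  bin <- arch_vectors(arch, mode = "binary", include_weak = TRUE)
  expect_equal(unname(bin["T1", ]), c(1, 1, 0))
  # binary vector equals the indicator of the TF set
  expect_equal(unname(bin["T2", ]), c(0, 1, 0))
  # count vector dominates the binary vector elementwise
  expect_true(all(cnt_w >= bin))

  # a promoter with no sites is an all-zero row, not a dropped row
  arch2 <- assemble_architectures(tiny_windows(), tiny_peaks()[0, ])
  v <- arch_vectors(arch2, mode = "count")
  expect_equal(nrow(v), 2L)
  expect_true(all(v == 0))
})

test_that("strong TF sets match the fixture architecture lists", {
  arch <- arch_from_sites(robo_tfbs_sites())
  sets <- arch_sets(arch, strength = "strong")
  expect_length(sets[["ROBO4-TSS1"]], 7L)
  expect_setequal(sets[["ROBO2-TSS1"]], c("CTCF", "RAD21", "TCF7L2"))
  expect_length(sets[["ROBO1-TSS2"]], 1L)
  # four of the seven strong ROBO4 sites are endothelial-flagged
  tab <- robo_tfbs_sites()
  r4 <- tab[tab$tss_id == "ROBO4-TSS1" & tab$strength == "strong", ]
  expect_equal(sum(r4$endothelial), 4L)
})
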