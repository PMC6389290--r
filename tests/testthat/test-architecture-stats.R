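test_that("Manhattan distance sums absolute coordinate differences", {
  expect_equal(manhattan_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(manhattan_distance(c(1, 0, 1), c(0, 0, 1)), 1)
  expect_equal(manhattan_distance(c(3, 2, 0), c(1, 0, 1)), 5)
  expect_error(manhattan_distance(c(1, 0), c(1, 0, 1)), "panel mismatch")
})

test_that("on binary vectors Manhattan distance is the symmetric difference", {
  # exhaustive over all pairs of subsets of a 6-TF panel
  panel <- letters[1:6]
  subsets <- lapply(0:63, function(m) panel[bitwAnd(m, 2^(0:5)) > 0])
  as_vec <- function(s) as.numeric(panel %in% s)
  for (a in subsets[seq(1, 64, by = 7)]) {
    for (b in subsets) {
      d <- manhattan_distance(as_vec(a), as_vec(b))
      expect_equal(d, length(union(a, b)) - length(intersect(a, b)))
    }
  }
})

test_that("distance matrices satisfy the metric axioms", {
  set.seed(1)
  vecs <- matrix(rpois(40 * 8, 1.5), nrow = 40,
                 dimnames = list(sprintf("P%02d", 1:40), letters[1:8]))
  d <- arch_distance_matrix(vecs)
  expect_true(all(diag(d) == 0))
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
  for (k in seq_len(nrow(d))) {
    expect_true(all(unclass(d) <= outer(d[, k], d[k, ], `+`) + 1e-9))
  }
})

test_that("Jaccard index handles the worked example and the edge cases", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "c")), 1 / 3)
  expect_equal(jaccard_index(c("x", "y"), c("y", "x")), 1)
  expect_equal(jaccard_index(c("x"), c("y")), 0)
  expect_equal(jaccard_index(character(), character()), 1)
})

test_that("jaccard and manhattan rank neighbours identically for equal-size sets", {
  set.seed(5)
  panel <- letters[1:12]
  focal <- panel[1:5]
  others <- replicate(15, sample(panel, 5), simplify = FALSE)
  as_vec <- function(s) as.numeric(panel %in% s)
  man <- vapply(others, function(s) manhattan_distance(as_vec(focal),
                                                       as_vec(s)), 0)
  jac <- vapply(others, function(s) jaccard_index(focal, s), 0)
  # larger similarity must pair with smaller distance, ties included
  expect_equal(rank(man), rank(-jac))
})

test_that("shared-TF report reproduces the roundabout Venn facts", {
  sets <- arch_sets(arch_from_sites(robo_tfbs_sites()), "strong")
  five <- c("ROBO4-TSS1", "ROBO1-TSS1", "ROBO2-TSS1", "ROBO3-TSS1",
            "ROBO3-TSS2")
  rep5 <- shared_tf_report(sets[[five[1]]], sets[five[-1]])
  expect_equal(rep5$common_to_all, "CTCF")

  rep_all <- shared_tf_report(sets[["ROBO4-TSS1"]],
                              sets[setdiff(names(sets), "ROBO4-TSS1")])
  expect_setequal(rep_all$unique_to_focal,
                  c("FOS", "GATA2", "JUN", "STAT3"))
  expect_equal(rep_all$max_pairwise_shared, 2L)
  expect_error(shared_tf_report(c("A"), list()), "at least one")
})

test_that("background distances match a double-loop oracle and sample stably", {
  set.seed(9)
  vecs <- matrix(rbinom(50 * 10, 1, 0.4), nrow = 50,
                 dimnames = list(sprintf("P%02d", 1:50), letters[1:10]))
  bg <- background_distances(vecs)
  oracle <- c()
  for (i in 1:49) for (j in (i + 1):50) {
    oracle <- c(oracle, sum(abs(vecs[i, ] - vecs[j, ])))
  }
  expect_equal(sort(bg$distances), sort(oracle))
  expect_equal(bg$mean, mean(oracle))
  expect_equal(bg$n_pairs, choose(50, 2))

  s1 <- background_distances(vecs, max_pairs = 100, seed = 3)
  s2 <- background_distances(vecs, max_pairs = 100, seed = 3)
  expect_identical(s1$distances, s2$distances)
  expect_equal(s1$n_pairs, 100L)
  expect_true(all(s1$distances %in% oracle))

  # degenerate summaries
  same <- matrix(1, 3, 4, dimnames = list(1:3, letters[1:4]))
  expect_equal(background_distances(same)$mean, 0)
  two <- matrix(c(0, 0, 1, 1), 2, byrow = TRUE, dimnames = list(1:2, 1:2))
  expect_equal(background_distances(two)$mean, 2)
})

test_that("rank-sum group comparison is exact below 8 per group", {
  expect_equal(compare_distance_groups(c(1, 2, 3), c(101, 102, 103)), 0.1)
  expect_equal(compare_distance_groups(1, 1), 1)
  a <- c(3, 9, 2, 14); b <- c(5, 7, 21)
  expect_equal(compare_distance_groups(a, b), compare_distance_groups(b, a))
})

test_that("marginals, expected and observed architecture probabilities", {
  bin <- rbind(c(1, 0, 1), c(1, 0, 0), c(1, 0, 1))
  colnames(bin) <- c("A", "B", "C")
  p <- marginal_tf_probabilities(bin)
  expect_equal(unname(p), c(1, 0, 2 / 3))

  expect_equal(expected_architecture_probability(c(1, 0, 0),
                                                 c(0.5, 0.5, 0.5)), 0.125)
  expect_equal(expected_architecture_probability(c(1, 0), c(1, 0)), 1)

  expect_equal(observed_architecture_probability(c(1, 0, 1), bin), 2 / 3)
  expect_equal(observed_architecture_probability(c(0, 1, 0), bin), 0)
  expect_equal(observed_architecture_probability(c(1, 1), rbind(c(1, 1))), 1)
})

test_that("expected probabilities normalise over the architecture space", {
  set.seed(13)
  marg <- runif(8)
  grid <- as.matrix(expand.grid(rep(list(0:1), 8)))
  total <- sum(apply(grid, 1, expected_architecture_probability, marg))
  expect_equal(total, 1, tolerance = 1e-12)

  # mean P_E over observed architectures stays a probability
  bin <- matrix(rbinom(30 * 8, 1, 0.3), nrow = 30,
                dimnames = list(sprintf("P%d", 1:30), letters[1:8]))
  tab <- architecture_probabilities(bin)
  expect_true(all(tab$p_expected >= 0 & tab$p_expected <= 1))
  expect_true(all(tab$p_observed > 0 & tab$p_observed <= 1))
  expect_lte(mean(tab$p_expected), 1)
})

test_that("zero expected probability with observed support flags infinity", {
  bin <- rbind(c(1, 0), c(1, 0))
  colnames(bin) <- c("A", "B")
  tab <- architecture_probabilities(bin, marginals = c(0, 0))
  expect_true(all(tab$enrichment_infinite))
  expect_true(all(is.infinite(tab$enrichment)))
})

test_that("architecture-size summary matches textbook moment formulas", {
  expect_equal(architecture_size_summary(c(4, 4, 4))$mean, 4)
  expect_equal(architecture_size_summary(c(4, 4, 4))$variance, 0)
  s <- architecture_size_summary(c(0, 8))
  expect_equal(s$min, 0); expect_equal(s$max, 8); expect_equal(s$median, 4)

  set.seed(21)
  x <- rpois(200, 6)
  s <- architecture_size_summary(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  expect_equal(s$skewness, m3 / m2^1.5)
  expect_equal(s$kurtosis, m4 / m2^2 - 3)
  expect_equal(s$variance, var(x))
})
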