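test_that("Pearson correlation matches hand computation and guards input", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 4)),
               3 / sqrt(2 * 14 / 3))
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("asymptotic P-value equals the t-distribution tail", {
  expect_equal(asymptotic_pvalue(0, 10), 1)
  p1 <- asymptotic_pvalue(1, 5)
  expect_equal(as.numeric(p1), 0)
  expect_true(attr(p1, "exact"))

  # oracle: cor.test on random profiles
  set.seed(3)
  for (n in c(5, 20, 100)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(asymptotic_pvalue(cor(x, y), n),
                 cor.test(x, y)$p.value, tolerance = 1e-12)
  }
  expect_equal(asymptotic_pvalue(3 / sqrt(2 * 14 / 3), 3),
               cor.test(c(1, 2, 3), c(1, 2, 4))$p.value, tolerance = 1e-12)
})

test_that("randomization null is deterministic and has the right size", {
  set.seed(1)
  m <- matrix(rlnorm(4 * 5), nrow = 4,
              dimnames = list(paste0("T", 1:4), paste0("L", 1:5)))
  n1 <- randomization_null(m, n_permutations = 3, subset_size = 4, seed = 7)
  n2 <- randomization_null(m, n_permutations = 3, subset_size = 4, seed = 7)
  expect_identical(n1$values, n2$values)
  expect_equal(length(n1$values), 3 * choose(4, 2))
  expect_true(all(n1$values >= -1 & n1$values <= 1))

  # i.i.d. noise gives a null centred near zero
  big <- matrix(rlnorm(60 * 30), nrow = 60,
                dimnames = list(paste0("T", 1:60), paste0("L", 1:30)))
  nb <- randomization_null(big, n_permutations = 20, subset_size = 30,
                           seed = 2)
  expect_lt(abs(median(nb$values)), 0.1)
})

test_that("empirical P-values follow the direction-aware tail rule", {
  null <- structure(list(values = c(-0.5, 0, 0.5)), class = "coexpr_null")
  expect_equal(empirical_pvalue(null, -0.9), 0)
  expect_equal(empirical_pvalue(null, -0.4), 1 / 3)

  even <- structure(list(values = c(-0.6, -0.2, 0.2, 0.6)),
                    class = "coexpr_null")
  expect_equal(empirical_pvalue(even, 0), 0.5)
  expect_equal(empirical_pvalue(even, 0.9), 0)
  expect_equal(empirical_pvalue(even, 0.9, tail = "lower"), 1)
  expect_equal(empirical_pvalue(even, 0.9, corrected = TRUE), 1 / 5)
})

test_that("maximal expression reports the top library, tie-flagged", {
  libs <- c("renal glomerular endothelial cells 1",
            "endothelial cells - microvascular", "aortic")
  m <- rbind("ROBO4-TSS1" = c(979, 662, 577),
             FLAT = c(5, 5, 5),
             SOLO = c(0, 0, 3))
  colnames(m) <- libs
  me <- maximal_expression(m)
  expect_equal(me$me[1], 979)
  expect_equal(me$library[1], "renal glomerular endothelial cells 1")
  expect_false(me$tie[1])
  expect_true(me$tie[2])
  expect_equal(me$library[2], libs[1])
  expect_equal(me$me[3], 3)
})

test_that("group enrichment ratio and rank behave as specified", {
  m <- rbind(A = c(10, 10, 1, 1, 1), B = c(2, 2, 2, 2, 2))
  colnames(m) <- paste0("L", 1:5)
  r <- group_enrichment_ratio(m, group = c("L1", "L2"))
  expect_equal(r$fold_ratio[1], 10)
  expect_equal(r$fold_ratio[2], 1)
  expect_error(group_enrichment_ratio(m, group = c("L1", "NOPE")),
               "unknown libraries")
  expect_error(group_enrichment_ratio(m, group = paste0("L", 1:5)),
               "non-empty")
  # headline arithmetic: endothelial mean 1188 over non-endothelial 12.122
  m2 <- rbind(X = c(1188, 1188, 12.122, 12.122))
  colnames(m2) <- paste0("L", 1:4)
  r2 <- group_enrichment_ratio(m2, group = c("L1", "L2"))
  expect_equal(r2$fold_ratio, 1188 / 12.122, tolerance = 1e-12)
  expect_equal(round(r2$fold_ratio), 98)

  ratios <- c(a = 5, b = 100, c = 1)
  expect_equal(enrichment_rank(ratios, "b")$rank, 1L)
  expect_equal(enrichment_rank(ratios, "b")$percentile, 1)
  med <- setNames(seq_len(101), paste0("g", 1:101))
  expect_equal(enrichment_rank(med, "g51")$rank, 51L)
  tied <- c(a = 3, b = 3, c = 1)
  expect_equal(enrichment_rank(tied, "a")$rank,
               enrichment_rank(tied, "b")$rank)
  expect_equal(enrichment_rank(tied, "a")$rank, 1L)
})

test_that("rank-sum enrichment z-score hits the closed-form extreme", {
  prof <- setNames(c(rep(10, 10) + (1:10) / 100, rep(1, 10) + (1:10) / 100),
                   paste0("L", 1:20))
  cat10 <- paste0("L", 1:10)
  z <- ranksum_enrichment_z(prof, cat10)
  # U = 100 (all category values above), sigma = sqrt(100 * 21 / 12)
  expect_equal(as.numeric(z), 50 / sqrt(175))
  # antisymmetry under swapping category and complement
  z2 <- ranksum_enrichment_z(prof, paste0("L", 11:20))
  expect_equal(as.numeric(z2), -as.numeric(z))
  # degenerate all-tied profile
  flat <- setNames(rep(2, 6), paste0("L", 1:6))
  zf <- ranksum_enrichment_z(flat, paste0("L", 1:3))
  expect_equal(as.numeric(zf), 0)
  expect_true(attr(zf, "degenerate"))
  expect_error(ranksum_enrichment_z(flat, paste0("L", 1:6)), "non-empty")
})

test_that("z-scores under random labels stay near zero", {
  set.seed(17)
  prof <- setNames(rlnorm(40), paste0("L", 1:40))
  zs <- replicate(100, {
    as.numeric(ranksum_enrichment_z(prof, sample(names(prof), 10)))
  })
  # a null z is approximately standard normal: its mean over shuffles is
  # near 0 and |z| averages near sqrt(2/pi) ~ 0.8
  expect_lt(abs(mean(zs)), 0.3)
  expect_lt(mean(abs(zs)), 1.1)
})

test_that("category enrichment scans metadata categories", {
  x <- tiny_expr()
  out <- category_enrichment(x, tss_ids = "T1")
  expect_setequal(out$category, c("endothelial cell", "other cell"))
  expect_equal(out$z[out$category == "endothelial cell"],
               -out$z[out$category == "other cell"])
})

test_that("TSS conservation calls use a strict expressed cutoff", {
  expect_equal(tss_conserved(c(305, 3, 10)), c(TRUE, FALSE, FALSE))
  expect_true(tss_conserved(10.0001))
  expect_error(tss_conserved(-1))
})

test_that("implanted fold enrichment and latent correlations are recovered", {
  spec <- generator_spec(seed = 101, n_promoters = 60, n_libraries = 500,
                         n_endothelial = 28)
  gen <- generate_expression(spec)
  x <- gen$expr

  # fold recovery within 3 delta-method standard errors
  r <- group_enrichment_ratio(x)
  got <- r$fold_ratio[r$tss_id == gen$truth$implanted_fold$tss_id]
  cv <- exp(spec$background_sdlog^2 / 2) *
    sqrt(exp(spec$background_sdlog^2) - 1) / exp(spec$background_sdlog^2 / 2)
  se <- 98 * sqrt(cv^2 / 28 + cv^2 / (500 - 28))
  expect_lt(abs(got - 98), 3 * se)

  # correlation recovery within 3 standard errors on the Fisher scale
  for (i in seq_len(nrow(gen$truth$implanted_rho))) {
    tr <- gen$truth$implanted_rho[i, ]
    pcc <- pearson_correlation(x$tpm[tr$tss_a, ], x$tpm[tr$tss_b, ])
    expect_lt(abs(atanh(pcc) - atanh(tr$rho)), 3 / sqrt(500 - 3))
  }
})

test_that("coexpression_test returns the pair-level summary table", {
  set.seed(31)
  m <- matrix(rlnorm(20 * 15), nrow = 20,
              dimnames = list(paste0("T", 1:20), paste0("L", 1:15)))
  null <- randomization_null(m, n_permutations = 10, subset_size = 20,
                             seed = 5)
  out <- coexpression_test(m, tibble::tibble(tss_a = c("T1", "T2"),
                                             tss_b = c("T3", "T4")),
                           null = null)
  expect_equal(nrow(out), 2L)
  expect_equal(out$n, c(15L, 15L))
  expect_true(all(out$p_asymptotic >= 0 & out$p_asymptotic <= 1))
  expect_true(all(out$p_randomization >= 0 & out$p_randomization <= 1))
  expect_equal(out$pcc[1], cor(m["T1", ], m["T3", ]))
})
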