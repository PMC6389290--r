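#' Specification of the synthetic-data generators
#'
#' Bundles every knob of the ground-truth generators emulating the
#' statistical structure of the real inputs: a merged multi-TF ChIP-seq
#' peak track over promoter windows, a CAGE-style TSS-by-library TPM
#' matrix with an endothelial library subset, and per-species ortholog
#' scenarios. Defaults follow the study conditions of the emulated
#' resources: a 161-TF panel, 513 primary-cell libraries of which 28 are
#' endothelial, per-TF marginals with mean set so the expected
#' architecture size is 9.2 TFs, a 98-fold implanted endothelial
#' enrichment, and a 7-species synteny scenario with conservation
#' probability 0.6.
#'
#' @param seed Master seed.
#' @param panel TF universe; defaults to the distinct fixture TF symbols
#'   padded with `TFnnn` fillers to 161 symbols, so synthetic data and the
#'   in-built fixtures share a namespace.
#' @param marginal_probs Per-TF presence probabilities. The default is a
#'   deterministic heavy-tailed profile (`k^-0.8`, rescaled) whose mean
#'   matches an average architecture size of 9.2 TFs.
#' @param n_promoters Number of promoters / TSSes.
#' @param n_libraries,n_endothelial Library count and endothelial subset
#'   size.
#' @param frac_strong Fraction of peaks drawn with quality score above
#'   500.
#' @param extra_peak_rate Poisson rate of extra peaks per present TF
#'   (every present TF has at least one peak).
#' @param halfwidth Promoter window halfwidth in bases.
#' @param background_meanlog,background_sdlog Log-normal background TPM
#'   parameters.
#' @param implant_fold Fold enrichment of implanted endothelial-specific
#'   TSSes.
#' @param implant_rho Latent correlations of implanted co-expressed TSS
#'   pairs.
#' @param species Species labels of the synteny scenario.
#' @param conservation_prob Per-species probability that a human pair's
#'   orthologs stay clustered.
#' @param ortholog_prob Per-gene, per-species probability of having a
#'   one-to-one ortholog.
#' @param n_pairs Number of human gene pairs in the synteny scenario.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           panel = default_tf_panel(),
                           marginal_probs = default_marginals(length(panel)),
                           n_promoters = 2000,
                           n_libraries = 513, n_endothelial = 28,
                           frac_strong = 0.3, extra_peak_rate = 0.5,
                           halfwidth = 3000,
                           background_meanlog = log(5),
                           background_sdlog = 1,
                           implant_fold = 98,
                           implant_rho = c(0.3, 0.7, 0.87),
                           species = c("mouse", "cat", "dog", "cow",
                                       "horse", "frog", "zebrafish"),
                           conservation_prob = 0.6,
                           ortholog_prob = 0.9,
                           n_pairs = 500) {
  stopifnot(length(marginal_probs) == length(panel),
            all(marginal_probs >= 0), all(marginal_probs <= 1),
            implant_fold > 0, all(abs(implant_rho) < 1),
            conservation_prob >= 0, conservation_prob <= 1,
            n_endothelial < n_libraries)
  structure(list(
    seed = seed, panel = panel, marginal_probs = marginal_probs,
    n_promoters = n_promoters, n_libraries = n_libraries,
    n_endothelial = n_endothelial, frac_strong = frac_strong,
    extra_peak_rate = extra_peak_rate, halfwidth = halfwidth,
    background_meanlog = background_meanlog,
    background_sdlog = background_sdlog,
    implant_fold = implant_fold, implant_rho = implant_rho,
    species = species, conservation_prob = conservation_prob,
    ortholog_prob = ortholog_prob, n_pairs = n_pairs),
    class = "generator_spec")
}

#' @rdname generator_spec
#' @param size Panel size (default 161).
#' @export
default_tf_panel <- function(size = 161) {
  real <- sort(unique(robo_tfbs_sites()$tf))
  n_fill <- max(0L, size - length(real))
  sort(c(real, sprintf("TF%03d", seq_len(n_fill))))
}

#' @rdname generator_spec
#' @param n_tfs Number of TFs.
#' @param mean_size Target expected architecture size.
#' @export
default_marginals <- function(n_tfs = 161, mean_size = 9.2) {
  w <- seq_len(n_tfs)^-0.8
  p <- w * mean_size / sum(w)
  pmin(p, 0.95)
}

#' Generate a synthetic peak track over promoter windows
#'
#' Places `n_promoters` TSS clusters (1 kb wide, 1 Mb apart along a
#' synthetic chromosome so windows never overlap), builds their 6-kb
#' windows, and for every window draws each panel TF present with its
#' marginal probability. A present TF receives `1 + Poisson(rate)` peaks
#' of width 200 at uniform positions inside the window; peak quality
#' scores exceed 500 with probability `frac_strong` (uniform within each
#' stratum); cell types are `"HUVEC"` for an arbitrary third of peaks and
#' `"K562"` otherwise.
#'
#' @param spec A [generator_spec()].
#' @param seed Seed (defaults to `spec$seed`).
#' @return A list `tss` (cluster tibble), `windows`, `peaks` (peaks
#'   tibble), and `truth` (list with the per-TF marginals used).
#' @export
generate_peaks <- function(spec, seed = spec$seed) {
  set.seed(seed)
  n <- spec$n_promoters
  tss <- tibble::tibble(
    tss_id = sprintf("TSS%05d", seq_len(n)),
    chrom = "chrS",
    start = seq_len(n) * 1e6,
    end = seq_len(n) * 1e6 + 1000,
    strand = rep(c("+", "-"), length.out = n))
  windows <- build_promoter_windows(tss, halfwidth = spec$halfwidth)
  present <- matrix(stats::runif(n * length(spec$panel)) <
                      rep(spec$marginal_probs, each = n),
                    nrow = n)
  idx <- which(present, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(tss = tss, windows = windows, peaks = empty_peaks(),
                truth = list(marginals = stats::setNames(spec$marginal_probs,
                                                         spec$panel))))
  }
  counts <- 1L + stats::rpois(nrow(idx), spec$extra_peak_rate)
  row_i <- rep(idx[, 1], counts)
  tf_i <- rep(idx[, 2], counts)
  w_start <- windows$start[row_i]
  w_end <- windows$end[row_i]
  p_start <- floor(stats::runif(length(row_i), w_start, w_end - 200))
  strong <- stats::runif(length(row_i)) < spec$frac_strong
  qs <- ifelse(strong, floor(stats::runif(length(row_i), 501, 1001)),
               floor(stats::runif(length(row_i), 0, 501)))
  peaks <- tibble::tibble(
    chrom = windows$chrom[row_i],
    start = p_start, end = p_start + 200,
    tf = spec$panel[tf_i], qs = qs,
    cell_type = ifelse(seq_along(row_i) %% 3 == 0, "HUVEC", "K562"))
  list(tss = tss, windows = windows, peaks = peaks,
       truth = list(marginals = stats::setNames(spec$marginal_probs,
                                                spec$panel)))
}

#' Generate a synthetic CAGE-style expression set with implanted signals
#'
#' Background TPM values are log-normal i.i.d. noise. One TSS per entry of
#' `spec$implant_fold` is made endothelial-specific: its endothelial
#' values are scaled so the expected in-group mean is `fold` times the
#' out-group mean. One TSS pair per entry of `spec$implant_rho` is built
#' from a shared latent Gaussian factor calibrated to the requested
#' Pearson correlation (affine-scaled to a positive TPM range, so the
#' correlation survives the scaling).
#'
#' @param spec A [generator_spec()].
#' @param seed Seed (defaults to `spec$seed`).
#' @param n_tss Number of TSS rows (defaults to `spec$n_promoters`).
#' @return A list `expr` (an [expr_set()]) and `truth` (tibbles
#'   `implanted_fold` and `implanted_rho`).
#' @export
generate_expression <- function(spec, seed = spec$seed,
                                n_tss = spec$n_promoters) {
  set.seed(seed)
  n_lib <- spec$n_libraries
  libs <- sprintf("LIB%04d", seq_len(n_lib))
  endo <- c(rep(TRUE, spec$n_endothelial),
            rep(FALSE, n_lib - spec$n_endothelial))
  tpm <- matrix(stats::rlnorm(n_tss * n_lib, spec$background_meanlog,
                              spec$background_sdlog),
                nrow = n_tss,
                dimnames = list(sprintf("TSS%05d", seq_len(n_tss)), libs))
  folds <- spec$implant_fold
  fold_rows <- sprintf("TSS%05d", seq_along(folds))
  for (i in seq_along(folds)) {
    tpm[fold_rows[i], endo] <- tpm[fold_rows[i], endo] * folds[i]
  }
  rhos <- spec$implant_rho
  rho_rows_a <- sprintf("TSS%05d", length(folds) + seq_along(rhos) * 2 - 1)
  rho_rows_b <- sprintf("TSS%05d", length(folds) + seq_along(rhos) * 2)
  for (i in seq_along(rhos)) {
    z <- stats::rnorm(n_lib)
    a <- sqrt(rhos[i]) * z + sqrt(1 - rhos[i]) * stats::rnorm(n_lib)
    b <- sqrt(rhos[i]) * z + sqrt(1 - rhos[i]) * stats::rnorm(n_lib)
    tpm[rho_rows_a[i], ] <- pmax(0, 100 + 10 * a)
    tpm[rho_rows_b[i], ] <- pmax(0, 100 + 10 * b)
  }
  meta <- tibble::tibble(
    library_id = libs,
    categories = purrr::map(endo, function(e)
      if (e) c("endothelial cell", "primary cell")
      else c("non-endothelial", "primary cell")),
    endothelial = endo)
  list(expr = expr_set(tpm, meta),
       truth = list(
         implanted_fold = tibble::tibble(tss_id = fold_rows, fold = folds),
         implanted_rho = tibble::tibble(tss_a = rho_rows_a,
                                        tss_b = rho_rows_b, rho = rhos)))
}

#' Generate a synthetic synteny scenario with known conservation rate
#'
#' Human gene pairs are placed on one chromosome with start gaps below
#' 100 kb. Per species, each gene has a one-to-one ortholog with
#' probability `ortholog_prob`; a pair with both orthologs present stays
#' clustered (same chromosome, < 200 kb apart) with probability
#' `conservation_prob`, otherwise the orthologs are separated onto
#' different chromosomes.
#'
#' @param spec A [generator_spec()].
#' @param seed Seed (defaults to `spec$seed`).
#' @return A list `human_genes`, `species_genes` (named list of tibbles),
#'   `orthologs` (map tibble) and `truth` (logical matrix pairs x species
#'   of implanted conservation).
#' @export
generate_ortholog_scenario <- function(spec, seed = spec$seed) {
  set.seed(seed)
  n <- spec$n_pairs
  base <- seq_len(n) * 1e6
  gap <- floor(stats::runif(n, 1000, 99000))
  human <- tibble::tibble(
    gene_id = c(sprintf("HSA%04d_A", seq_len(n)),
                sprintf("HSA%04d_B", seq_len(n))),
    species = "human",
    chrom = "chr1",
    start = c(base, base + gap),
    end = c(base, base + gap) + 500,
    strand = rep(c("+", "-"), each = n))
  species_genes <- list()
  ortho <- list()
  truth <- matrix(FALSE, n, length(spec$species),
                  dimnames = list(sprintf("pair%04d", seq_len(n)),
                                  spec$species))
  for (sp in spec$species) {
    has_a <- stats::runif(n) < spec$ortholog_prob
    has_b <- stats::runif(n) < spec$ortholog_prob
    conserved <- stats::runif(n) < spec$conservation_prob & has_a & has_b
    truth[, sp] <- conserved
    sp_gap <- floor(stats::runif(n, 1000, 199000))
    chr_a <- ifelse(conserved, "chr1", "chr2")
    start_a <- base
    start_b <- ifelse(conserved, base + sp_gap, base + 5e5)
    rows <- list()
    if (any(has_a)) {
      rows$a <- tibble::tibble(
        gene_id = sprintf("%s%04d_A", toupper(sp), which(has_a)),
        species = sp, chrom = chr_a[has_a], start = start_a[has_a],
        end = start_a[has_a] + 500, strand = "+")
    }
    if (any(has_b)) {
      rows$b <- tibble::tibble(
        gene_id = sprintf("%s%04d_B", toupper(sp), which(has_b)),
        species = sp, chrom = "chr1", start = start_b[has_b],
        end = start_b[has_b] + 500, strand = "-")
    }
    species_genes[[sp]] <- dplyr::bind_rows(rows)
    ortho[[sp]] <- dplyr::bind_rows(
      tibble::tibble(human_id = sprintf("HSA%04d_A", which(has_a)),
                     species = sp,
                     ortholog_id = sprintf("%s%04d_A", toupper(sp),
                                           which(has_a))),
      tibble::tibble(human_id = sprintf("HSA%04d_B", which(has_b)),
                     species = sp,
                     ortholog_id = sprintf("%s%04d_B", toupper(sp),
                                           which(has_b))))
  }
  list(human_genes = human, species_genes = species_genes,
       orthologs = dplyr::bind_rows(ortho), truth = truth)
}

#' Generate a paralog promoter pair with known duplication history
#'
#' `mode = "ddc"` emulates duplication-degeneration-complementation: both
#' descendant TF sets are uniform random subsets of a common ancestral
#' site set (complementary retention of ancestral modules). `mode = "neo"`
#' emulates regulatory neo-functionalization: the first descendant retains
#' ancestral sites while the second is rebuilt from TFs absent from the
#' ancestor (`novelty_fraction` of its sites), apart from a small forced
#' shared core.
#'
#' @param mode `"ddc"` or `"neo"`.
#' @param spec A [generator_spec()].
#' @param seed Seed (defaults to `spec$seed`).
#' @param n_ancestral Ancestral TF-set size.
#' @param n1,n2 Descendant TF-set sizes.
#' @param novelty_fraction Fraction of the second descendant's TFs drawn
#'   from outside the ancestor in `neo` mode.
#' @param core_size Number of forced shared TFs in `neo` mode.
#' @return A list `set_a`, `set_b` (TF sets), `sites_a`, `sites_b`
#'   (clustered-mode tibbles `tf, start, end`), `ancestral` (TF set) and
#'   `mode`.
#' @export
generate_paralog_promoters <- function(mode = c("ddc", "neo"), spec,
                                       seed = spec$seed,
                                       n_ancestral = 12, n1 = 7, n2 = 9,
                                       novelty_fraction = 1,
                                       core_size = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  stopifnot(n1 <= n_ancestral, n2 <= n_ancestral,
            n_ancestral + n2 <= length(spec$panel))
  ancestral <- sample(spec$panel, n_ancestral)
  anc_pos <- stats::setNames(
    floor(stats::runif(n_ancestral, 0, 2 * spec$halfwidth - 10)), ancestral)
  if (mode == "ddc") {
    set_a <- sample(ancestral, n1)
    set_b <- sample(ancestral, n2)
  } else {
    set_a <- sample(ancestral, n1)
    core <- sample(set_a, min(core_size, n1))
    n_novel <- round(novelty_fraction * (n2 - length(core)))
    novel <- sample(setdiff(spec$panel, ancestral), n_novel)
    n_old <- n2 - length(core) - n_novel
    old <- if (n_old > 0) sample(setdiff(ancestral, c(set_a, core)),
                                 min(n_old, length(setdiff(ancestral, c(set_a, core)))))
           else character()
    set_b <- unique(c(core, novel, old))
  }
  site_tbl <- function(tfs) {
    pos <- vapply(tfs, function(tf) {
      if (tf %in% names(anc_pos)) anc_pos[[tf]]
      else floor(stats::runif(1, 0, 2 * spec$halfwidth - 10))
    }, 0)
    tibble::tibble(tf = tfs, start = pos, end = pos + 10)
  }
  list(set_a = sort(set_a), set_b = sort(set_b),
       sites_a = site_tbl(set_a), sites_b = site_tbl(set_b),
       ancestral = sort(ancestral), mode = mode)
}

#' Write a full synthetic bundle to disk
#'
#' Emits every file the pipeline readers consume: peaks, TSS clusters,
#' expression matrix and metadata, human and per-species gene tables, the
#' ortholog map, and a `truth.json` with the implanted ground truth.
#'
#' @param spec A [generator_spec()].
#' @param outdir Output directory (created if needed).
#' @param seed Seed (defaults to `spec$seed`).
#' @return Named list of the file paths written, invisibly.
#' @export
simulate_data_bundle <- function(spec, outdir, seed = spec$seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pk <- generate_peaks(spec, seed = seed)
  ex <- generate_expression(spec, seed = seed + 1L)
  sy <- generate_ortholog_scenario(spec, seed = seed + 2L)
  paths <- list(
    peaks = file.path(outdir, "peaks.tsv"),
    tss = file.path(outdir, "tss.tsv"),
    matrix = file.path(outdir, "expression.tsv"),
    meta = file.path(outdir, "libraries.tsv"),
    human_genes = file.path(outdir, "genes_human.tsv"),
    orthologs = file.path(outdir, "orthologs.tsv"),
    truth = file.path(outdir, "truth.json"))
  write_peaks(pk$peaks, paths$peaks)
  write_tss_clusters(pk$tss, paths$tss)
  write_expression(ex$expr, paths$matrix, paths$meta)
  write_gene_table(sy$human_genes, paths$human_genes)
  for (sp in names(sy$species_genes)) {
    paths[[paste0("genes_", sp)]] <- file.path(outdir,
                                               sprintf("genes_%s.tsv", sp))
    write_gene_table(sy$species_genes[[sp]], paths[[paste0("genes_", sp)]])
  }
  write_ortholog_map(sy$orthologs, paths$orthologs)
  jsonlite::write_json(
    list(marginals = pk$truth$marginals,
         implanted_fold = ex$truth$implanted_fold,
         implanted_rho = ex$truth$implanted_rho,
         conservation_prob = spec$conservation_prob,
         seed = seed),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
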