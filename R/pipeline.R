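#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file read with
#' [read_pipeline_config()]) with `paths` (peaks, tss, matrix, meta,
#' human_genes, orthologs, and per-species gene tables under
#' `species_genes`), `stages` (logical toggles), `thresholds` and a master
#' `seed`. Missing thresholds are filled with the defaults used throughout
#' the package (halfwidth 3000, qs_cutoff 500, max_gap 100000, max_span
#' 200000, me_threshold 10, n_permutations 1000, subset_size 1000, runs
#' 10000, deletion_size 100).
#'
#' @param config Named list.
#' @return The completed configuration, invisibly; errors on missing
#'   files or non-positive thresholds.
#' @export
validate_pipeline_config <- function(config) {
  defaults <- list(halfwidth = 3000, qs_cutoff = 500, max_gap = 100000,
                   max_span = 200000, me_threshold = 10,
                   n_permutations = 1000, subset_size = 1000,
                   runs = 10000, deletion_size = 100)
  config$thresholds <- utils::modifyList(defaults,
                                         config$thresholds %||% list())
  if (any(unlist(config$thresholds) <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  stage_defaults <- list(architectures = TRUE, distances = TRUE,
                         probability = TRUE, ddc = TRUE, coexpr = TRUE,
                         synteny = TRUE, lrt = FALSE)
  config$stages <- utils::modifyList(stage_defaults, config$stages %||% list())
  config$seed <- config$seed %||% 1L
  flat_paths <- unlist(config$paths)
  missing <- flat_paths[!file.exists(flat_paths)]
  if (length(missing) > 0L) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(config)
}

#' @rdname validate_pipeline_config
#' @param path YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the toggled stages in order — architectures, distances,
#' probability, DDC simulation, co-expression, synteny — from one
#' configuration, with a deterministic per-stage seed derived from the
#' master seed so toggling one stage never changes another stage's
#' results. The returned bundle carries each stage's output plus a
#' reproducibility manifest (configuration echo, seeds, package version,
#' per-stage row counts).
#'
#' @param config Configuration list, validated by
#'   [validate_pipeline_config()].
#' @return A named list of stage outputs plus `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  th <- config$thresholds
  stage_seed <- function(k) (config$seed * 1000L + k) %% .Machine$integer.max
  out <- list()
  counts <- list()

  tss <- read_tss_clusters(config$paths$tss)
  peaks <- read_peaks(config$paths$peaks)
  windows <- build_promoter_windows(tss, halfwidth = th$halfwidth)
  if (config$stages$architectures) {
    out$architectures <- assemble_architectures(windows, peaks,
                                                qs_cutoff = th$qs_cutoff)
    counts$architectures <- nrow(out$architectures)
  }
  if (config$stages$distances) {
    vecs <- arch_vectors(out$architectures, mode = "count")
    out$distances <- arch_distance_matrix(vecs)
    out$background <- background_distances(vecs,
                                           max_pairs = config$max_pairs,
                                           seed = stage_seed(2L))
    counts$distances <- nrow(vecs)
  }
  if (config$stages$probability) {
    binary <- arch_vectors(out$architectures, mode = "binary")
    out$probability <- architecture_probabilities(binary)
    counts$probability <- nrow(out$probability)
  }
  if (config$stages$ddc) {
    sets <- arch_sets(out$architectures, strength = "strong")
    nonempty <- sets[lengths(sets) > 0]
    if (length(nonempty) >= 2) {
      anc <- ddc_ancestral(nonempty[[1]], nonempty[[2]],
                           mode = "independent")
      sim <- simulate_ddc_independent(anc, length(nonempty[[1]]),
                                      length(nonempty[[2]]),
                                      runs = th$runs, seed = stage_seed(3L))
      out$ddc <- list(
        simulation = sim,
        p_value = ddc_pvalue(sim, length(intersect(nonempty[[1]],
                                                   nonempty[[2]]))))
      counts$ddc <- sim$runs
    }
  }
  if (config$stages$coexpr) {
    expr <- read_expression(config$paths$matrix, config$paths$meta)
    null <- randomization_null(expr,
                               n_permutations = th$n_permutations,
                               subset_size = th$subset_size,
                               seed = stage_seed(4L))
    pair_ids <- utils::head(rownames(expr$tpm), 5)
    cmb <- utils::combn(pair_ids, 2)
    out$coexpr <- coexpression_test(
      expr, tibble::tibble(tss_a = cmb[1, ], tss_b = cmb[2, ]), null = null)
    out$me <- maximal_expression(expr)
    out$enrichment <- group_enrichment_ratio(expr)
    out$conserved <- tibble::tibble(
      tss_id = out$me$tss_id,
      conserved = tss_conserved(out$me$me, th$me_threshold))
    counts$coexpr <- nrow(out$coexpr)
  }
  if (config$stages$synteny) {
    human <- read_gene_table(config$paths$human_genes)
    orthos <- read_ortholog_map(config$paths$orthologs)
    gene_tables <- lapply(config$paths$species_genes, read_gene_table)
    pairs <- find_gene_pairs(human, max_gap = th$max_gap)
    out$synteny <- conservation_summary(pairs, names(gene_tables), orthos,
                                        gene_tables, max_span = th$max_span)
    counts$synteny <- nrow(pairs)
  }
  if (config$stages$lrt && !is.null(config$paths$fits)) {
    fits <- readr::read_tsv(config$paths$fits, col_types = "cdd")
    cmp <- tibble::tibble(null = config$lrt_pairs$null,
                          alt = config$lrt_pairs$alt)
    out$lrt <- lrt_test(fits, cmp)
    counts$lrt <- nrow(out$lrt)
  }
  out$manifest <- list(
    config = config, seed = config$seed,
    package_version = as.character(utils::packageVersion("promdiv")),
    stage_rows = counts,
    stages_run = names(counts))
  out
}
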