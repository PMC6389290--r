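#' Find tightly clustered gene pairs in one genome
#'
#' All unordered pairs of genes on the same chromosome whose transcription
#' starts are strictly less than `max_gap` bases apart. The start is
#' strand-aware by default (5' end: `start` on `+`, `end` on `-`), which is
#' the biologically standard reading; `strand_aware = FALSE` uses the
#' leftmost coordinate. The pair's arrangement is classified from strands:
#' opposite strands with 3' ends facing give `tail-to-tail`, opposite
#' strands facing outward give `head-to-head`, same strand `co-oriented`.
#'
#' @param genes Gene tibble (`gene_id, species, chrom, start, end,
#'   strand`), 0-based half-open, one species.
#' @param max_gap Maximum start-to-start distance (strict; default 100000).
#' @param strand_aware Use the strand-aware transcription start.
#' @return Tibble `gene_a, gene_b, chrom, start_gap, arrangement` with
#'   `gene_a < gene_b` lexicographically.
#' @export
find_gene_pairs <- function(genes, max_gap = 100000, strand_aware = TRUE) {
  g <- genes
  g$tx_start <- gene_tx_start(g, strand_aware)
  out <- g |>
    dplyr::inner_join(g, by = "chrom", suffix = c("_a", "_b"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$gene_id_a < .data$gene_id_b) |>
    dplyr::mutate(start_gap = abs(.data$tx_start_a - .data$tx_start_b)) |>
    dplyr::filter(.data$start_gap < max_gap) |>
    dplyr::mutate(arrangement = classify_arrangement(
      .data$tx_start_a, .data$strand_a, .data$tx_start_b, .data$strand_b)) |>
    dplyr::select(gene_a = "gene_id_a", gene_b = "gene_id_b", "chrom",
                  "start_gap", "arrangement") |>
    dplyr::arrange(.data$chrom, .data$gene_a, .data$gene_b)
  out
}

gene_tx_start <- function(genes, strand_aware = TRUE) {
  if (!strand_aware) return(genes$start)
  ifelse(genes$strand == "-", genes$end, genes$start)
}

classify_arrangement <- function(start_a, strand_a, start_b, strand_b) {
  same <- strand_a == strand_b
  # put a left of b by transcription start
  left_strand <- ifelse(start_a <= start_b, strand_a, strand_b)
  dplyr::case_when(
    same ~ "co-oriented",
    left_strand == "+" ~ "tail-to-tail", # left gene transcribes rightward
    TRUE ~ "head-to-head")
}

#' Is a human gene pair conserved as a cluster in another species?
#'
#' A pair is conserved in a species iff both members have a one-to-one
#' ortholog there, both orthologs lie on the same chromosome, and their
#' transcription starts are strictly less than `max_span` bases apart.
#' Symmetric in the two genes; monotone in `max_span`.
#'
#' @param pairs Pair tibble from [find_gene_pairs()] (or any tibble with
#'   `gene_a, gene_b`).
#' @param species Species label to test.
#' @param orthos One-to-one ortholog map tibble (`human_id, species,
#'   ortholog_id`).
#' @param species_genes Gene tibble for the target species.
#' @param max_span Maximum ortholog start distance (strict; default
#'   200000).
#' @param strand_aware Strand-aware starts, as in [find_gene_pairs()].
#' @return Logical vector, one value per pair.
#' @export
pair_conserved <- function(pairs, species, orthos, species_genes,
                           max_span = 200000, strand_aware = TRUE) {
  omap <- orthos[orthos$species == species, , drop = FALSE]
  o_a <- omap$ortholog_id[match(pairs$gene_a, omap$human_id)]
  o_b <- omap$ortholog_id[match(pairs$gene_b, omap$human_id)]
  sg <- species_genes
  sg$tx_start <- gene_tx_start(sg, strand_aware)
  ia <- match(o_a, sg$gene_id)
  ib <- match(o_b, sg$gene_id)
  ok <- !is.na(ia) & !is.na(ib) &
    sg$chrom[ia] == sg$chrom[ib] &
    abs(sg$tx_start[ia] - sg$tx_start[ib]) < max_span
  ok[is.na(ok)] <- FALSE
  ok
}

#' Cluster-conservation summary across species
#'
#' Tallies, per species, how many human gene pairs are conserved as
#' clusters, plus how many pairs have a one-to-one ortholog for both
#' members in every species and how many are conserved in all species.
#'
#' @param pairs Pair tibble from [find_gene_pairs()].
#' @param species_list Character vector of species labels.
#' @param orthos Ortholog map tibble.
#' @param gene_tables Named list of per-species gene tibbles.
#' @param max_span Passed to [pair_conserved()].
#' @param strand_aware Passed to [pair_conserved()].
#' @return A list with `per_species` (tibble `species, n_pairs,
#'   n_conserved, fraction_conserved`), `n_pairs`,
#'   `n_with_orthologs_in_all`, `n_conserved_in_all`, and the logical
#'   matrix `conserved` (pairs x species).
#' @export
conservation_summary <- function(pairs, species_list, orthos, gene_tables,
                                 max_span = 200000, strand_aware = TRUE) {
  if (nrow(pairs) == 0L) {
    return(list(per_species = tibble::tibble(
      species = species_list, n_pairs = 0L, n_conserved = 0L,
      fraction_conserved = NaN),
      n_pairs = 0L, n_with_orthologs_in_all = 0L, n_conserved_in_all = 0L,
      conserved = matrix(logical(), 0, length(species_list),
                         dimnames = list(NULL, species_list))))
  }
  cons <- vapply(species_list, function(sp) {
    pair_conserved(pairs, sp, orthos, gene_tables[[sp]],
                   max_span = max_span, strand_aware = strand_aware)
  }, logical(nrow(pairs)))
  cons <- matrix(cons, nrow = nrow(pairs),
                 dimnames = list(NULL, species_list))
  has_orth <- vapply(species_list, function(sp) {
    omap <- orthos[orthos$species == sp, , drop = FALSE]
    pairs$gene_a %in% omap$human_id & pairs$gene_b %in% omap$human_id
  }, logical(nrow(pairs)))
  has_orth <- matrix(has_orth, nrow = nrow(pairs))
  list(
    per_species = tibble::tibble(
      species = species_list,
      n_pairs = nrow(pairs),
      n_conserved = unname(colSums(cons)),
      fraction_conserved = unname(colMeans(cons))),
    n_pairs = nrow(pairs),
    n_with_orthologs_in_all = sum(rowSums(has_orth) == length(species_list)),
    n_conserved_in_all = sum(rowSums(cons) == length(species_list)),
    conserved = cons)
}
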