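#' In-built roundabout promoter fixtures
#'
#' Desk-scale reference tables for the seven human roundabout TSS
#' promoters (ROBO1-4), usable as worked examples and ground truth for the
#' set-level analyses: the per-promoter ENCODE TFBS lists with a
#' strong/weak quality split and endothelial (HUVEC) flags, the 1-kb CAGE
#' TSS cluster locations, and the published 6-kb promoter windows with
#' maximal-expression values in human and mouse. Coordinates are hg19
#' (human) / mm9 (mouse) spans stored as printed, interpreted as half-open
#' intervals (cluster width exactly 1000, window width exactly 6000).
#'
#' @return `robo_tfbs_sites()`: tibble `tss_id, tf, strength, endothelial`
#'   (one row per listed site). `robo_tss_clusters()`: tibble `tss_id,
#'   chrom, start, end, strand`. `robo_promoter_windows()`: tibble
#'   `tss_id, chrom, start, end, me_human, mouse_chrom, mouse_start,
#'   mouse_end, me_mouse, conserved_call` (two bracketed human and two
#'   mouse ME values are garbled in the source rendering; they are carried
#'   here from the matching expression-profile table and flagged in the
#'   column `me_garbled`).
#' @name robo_fixtures
NULL

#' @rdname robo_fixtures
#' @export
robo_tfbs_sites <- function() {
  strong <- list(
    "ROBO4-TSS1" = c("CTCF+", "FOS+", "GATA2+", "JUN+", "CEBPB", "REST",
                     "STAT3"),
    "ROBO3-TSS2" = c("CTCF+", "EZH2+", "E2F6", "MAX", "RAD21", "REST",
                     "USF1"),
    "ROBO3-TSS1" = c("CTCF+", "EGR1", "GABPA", "RAD21", "ZNF143"),
    "ROBO2-TSS1" = c("CTCF+", "RAD21", "TCF7L2"),
    "ROBO2-TSS2" = c("CTCF+", "RAD21", "ZNF263"),
    "ROBO1-TSS1" = c("CTCF", "JUND", "BHLHE40", "CEBPB", "CHD1", "EP300",
                     "MAFK", "TAF1", "TBP"),
    "ROBO1-TSS2" = c("CTCF"))
  weak <- list(
    "ROBO4-TSS1" = c("CTCF+", "GATA2+", "JUN+", "MYC+", "EP300", "FOSL2",
                     "FOXA1", "FOXP2", "JUND", "MAFK", "REST", "SIN3AK20",
                     "SP1", "STAT3", "TCF7L2"),
    "ROBO3-TSS2" = c("CTCF+", "CTCFL", "EGR1", "ESR1", "EZH2", "FOXA1",
                     "MYC", "REST", "SETDB1", "SMC3", "SP2", "SUZ12",
                     "USF2", "YY1", "ZBTB7A", "ZNF143"),
    "ROBO3-TSS1" = c("BACH1", "CBX3", "CCNT2", "CREB1", "CTBP2", "CTCFL",
                     "E2F6", "ELF1", "ELK1", "ELK4", "EP300", "ETS1",
                     "FOXP2", "HMGN3", "JUND", "MAX", "MAZ", "MXI1", "MYC",
                     "PAX5", "PHF8", "RAD21", "RBBP5", "REST", "SIN3A",
                     "SIN3AK20", "SMC3", "SP2", "SP4", "TAF1", "TAF7",
                     "TBP", "THAP1", "UBTF", "YY1", "ZBTB7A"),
    "ROBO2-TSS1" = c("CEBPB", "E2F6", "EGR1", "EP300", "EZH2", "FOXP2",
                     "HDAC2", "MAX", "MXI1", "RAD21", "RBBP5", "SMC3",
                     "STAT1", "TAF1", "TBP", "USF1"),
    "ROBO2-TSS2" = c("EGR1", "RBBP5", "TAF1", "TBP", "TEAD4", "YY1",
                     "ZNF143"),
    "ROBO1-TSS1" = c("CTCF+", "ARID3A", "ATF2", "BACH1", "BRCA1", "CEBPD",
                     "CTBP2", "E2F4", "EBF1", "EGR1", "ELF1", "EP300",
                     "FOS", "FOXA1", "FOXP2", "GATA2", "GATA3", "GTF2F1",
                     "HDAC2", "KAP1", "MAFF", "MAX", "MAZ", "MXI1",
                     "MYBL2", "MYC", "NFIC", "RAD21", "RBBP5", "RCOR1",
                     "RELA", "REST", "RFX5", "SIN3A", "SIN3AK20", "SIX5",
                     "SMARCC2", "SMC3", "SP1", "SPI1", "SRF", "STAT1",
                     "STAT3", "TAF1", "TCF12", "TCF7L2", "TEAD4",
                     "TFAP2C", "USF1", "ZBTB33", "ZNF263"),
    "ROBO1-TSS2" = c("CTCF+", "BACH1", "ESR1", "EZH2", "FOSL1", "HDAC2",
                     "SP1", "USF1", "ZNF143"))
  unroll <- function(lst, strength) {
    purrr::imap(lst, function(tfs, id) {
      tibble::tibble(tss_id = id,
                     tf = sub("\\+$", "", tfs),
                     strength = strength,
                     endothelial = grepl("\\+$", tfs))
    }) |> dplyr::bind_rows()
  }
  dplyr::bind_rows(unroll(strong, "strong"), unroll(weak, "weak"))
}

#' @rdname robo_fixtures
#' @export
robo_tss_clusters <- function() {
  tibble::tribble(
    ~tss_id, ~chrom, ~start, ~end, ~strand,
    "ROBO4-TSS1", "chr11", 124767260, 124768260, "-",
    "ROBO3-TSS2", "chr11", 124734800, 124735800, "+",
    "ROBO3-TSS1", "chr11", 124746200, 124747200, "+",
    "ROBO2-TSS2", "chr3", 75955300, 75956300, "+",
    "ROBO2-TSS1", "chr3", 77088794, 77089794, "+",
    "ROBO1-TSS1", "chr3", 79068100, 79069100, "-",
    "ROBO1-TSS2", "chr3", 79816700, 79817700, "-")
}

#' @rdname robo_fixtures
#' @export
robo_promoter_windows <- function() {
  tibble::tribble(
    ~tss_id, ~chrom, ~start, ~end, ~me_human, ~mouse_chrom, ~mouse_start,
    ~mouse_end, ~me_mouse, ~conserved_call, ~me_garbled,
    "ROBO4-TSS1", "chr11", 124764760, 124770760, 979, "chr9", 37208261,
    37212629, 305, TRUE, FALSE,
    "ROBO3-TSS2", "chr11", 124732300, 124738300, 28, "chr9", 37239055,
    37242808, 34, TRUE, TRUE,
    "ROBO3-TSS1", "chr11", 124743700, 124749700, 41, "chr9", 37225070,
    37231494, 3, FALSE, TRUE,
    "ROBO2-TSS2", "chr3", 75952845, 75958845, 8, "chr16", 75420561,
    75421064, 0, FALSE, TRUE,
    "ROBO2-TSS1", "chr3", 77086294, 77092294, 341, "chr16", 74409016,
    74413502, 166, TRUE, FALSE,
    "ROBO1-TSS1", "chr3", 79065600, 79071600, 191, "chr16", 72662054,
    72666244, 115, TRUE, FALSE,
    "ROBO1-TSS2", "chr3", 79814200, 79820200, 135, "chr16", 72024757,
    72029898, 81, TRUE, TRUE)
}

#' Published log-likelihoods of the codon-model fits for the roundabout
#' alignment
#'
#' One row per model: name, number of free parameters `p`, and
#' log-likelihood `l`. Suitable input for [lrt_test()].
#'
#' @return Tibble `name, p, l`.
#' @export
robo_model_fits <- function() {
  tibble::tribble(
    ~name, ~p, ~l,
    "one-ratio", 1, -14869,
    "nearly-neutral", 2, -14849,
    "positive-selection", 4, -14849,
    "beta", 2, -14714,
    "beta-omega", 5, -14715,
    "free-ratio", 15, -14790,
    "branch", 2, -14864,
    "branch-site-null", 2, -14830,
    "branch-site", 4, -14808)
}
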