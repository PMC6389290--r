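#' Build a fixed-width promoter window around a TSS cluster
#'
#' The window is centred on the midpoint of the cluster interval:
#' `[midpoint - halfwidth, midpoint + halfwidth)` with
#' `midpoint = floor((start + end) / 2)`. Windows are strand-agnostic by
#' default; `upstream_only = TRUE` instead places the whole `2 * halfwidth`
#' span upstream of the cluster midpoint by strand (the promoter-proximal
#' variant used for cell-type-focused scans).
#'
#' @param tss Tibble of TSS clusters (`tss_id, chrom, start, end, strand`),
#'   0-based half-open.
#' @param halfwidth Half window width in bases (default 3000, i.e. 6-kb
#'   windows).
#' @param contig_lengths Optional named vector of contig lengths used to
#'   clamp windows to `[0, contig_length)`.
#' @param upstream_only Use the strand-aware upstream-only placement.
#' @return A tibble `tss_id, chrom, start, end, cluster_start, cluster_end,
#'   strand`, one row per cluster.
#' @examples
#' tss <- tibble::tibble(tss_id = "ROBO4-TSS1", chrom = "chr11",
#'                       start = 124767260, end = 124768260, strand = "-")
#' build_promoter_windows(tss)
#' @export
build_promoter_windows <- function(tss, halfwidth = 3000,
                                   contig_lengths = NULL,
                                   upstream_only = FALSE) {
  stopifnot(halfwidth > 0)
  if (any(tss$start >= tss$end)) {
    stop("TSS cluster with start >= end", call. = FALSE)
  }
  mid <- floor((tss$start + tss$end) / 2)
  if (isTRUE(upstream_only)) {
    minus <- tss$strand == "-"
    w_start <- ifelse(minus, mid, mid - 2 * halfwidth)
    w_end <- ifelse(minus, mid + 2 * halfwidth, mid)
  } else {
    w_start <- mid - halfwidth
    w_end <- mid + halfwidth
  }
  w_start <- pmax(w_start, 0)
  if (!is.null(contig_lengths)) {
    len <- unname(contig_lengths[tss$chrom])
    w_end <- ifelse(is.na(len), w_end, pmin(w_end, len))
  }
  tibble::tibble(
    tss_id = tss$tss_id, chrom = tss$chrom,
    start = w_start, end = w_end,
    cluster_start = tss$start, cluster_end = tss$end,
    strand = tss$strand)
}

#' Classify peak strength from its quality score
#'
#' A peak is strong iff its quality score strictly exceeds the cutoff
#' (`qs > 500` by default); `qs == cutoff` is weak.
#'
#' @param qs Numeric vector of quality scores (>= 0).
#' @param cutoff Strong/weak boundary (default 500).
#' @return Character vector of `"strong"` / `"weak"`.
#' @examples
#' classify_strength(c(704, 119, 500))
#' @export
classify_strength <- function(qs, cutoff = 500) {
  if (any(qs < 0)) stop("negative quality score", call. = FALSE)
  ifelse(qs > cutoff, "strong", "weak")
}

#' Assemble per-promoter binding architectures from windows and peaks
#'
#' A peak is assigned to a window iff their half-open intervals share at
#' least one base on the same chromosome (intersectBed semantics: a boundary
#' -spanning peak counts fully). Each assigned peak increments the strong or
#' weak count of its TF per [classify_strength()]. The result is a long
#' architecture table; the TF panel (universe of dimensions for vector
#' encodings) travels with it as an attribute.
#'
#' @param windows Window tibble from [build_promoter_windows()].
#' @param peaks Peak tibble from [read_peaks()].
#' @param panel Character vector of TF symbols defining the universe.
#'   Defaults to the distinct TFs observed in `peaks` (after blacklisting).
#'   A peak TF outside the panel is an error.
#' @param qs_cutoff Strong/weak cutoff passed to [classify_strength()].
#' @param blacklist TFs dropped before assignment (default `"POLR2A"`:
#'   polymerase II peak counts track expression level trivially).
#' @param dedupe Drop fully identical peak records first.
#' @return A tibble `tss_id, tf, strength, n, n_endothelial` (class
#'   `arch_tbl`) with one row per observed tss/TF/strength combination and
#'   attributes `panel` and `tss_ids`. `n_endothelial` counts the subset of
#'   those peaks whose cell type is in `endothelial_cell_types`.
#' @param endothelial_cell_types Cell-type labels flagged as endothelial
#'   (default `"HUVEC"`).
#' @export
assemble_architectures <- function(windows, peaks, panel = NULL,
                                   qs_cutoff = 500, blacklist = "POLR2A",
                                   dedupe = FALSE,
                                   endothelial_cell_types = "HUVEC") {
  if (isTRUE(dedupe)) peaks <- dplyr::distinct(peaks)
  peaks <- peaks[!(peaks$tf %in% blacklist), , drop = FALSE]
  if (is.null(panel)) {
    panel <- sort(unique(peaks$tf))
  } else {
    stray <- setdiff(unique(peaks$tf), panel)
    if (length(stray) > 0L) {
      stop("peak TF not in panel: ", paste(stray, collapse = ", "),
           call. = FALSE)
    }
  }
  hits <- overlap_pairs(windows, peaks)
  arch <- hits |>
    dplyr::mutate(strength = classify_strength(.data$qs, qs_cutoff),
                  endo = .data$cell_type %in% endothelial_cell_types) |>
    dplyr::group_by(.data$tss_id, .data$tf, .data$strength) |>
    dplyr::summarise(n = dplyr::n(), n_endothelial = sum(.data$endo),
                     .groups = "drop") |>
    dplyr::arrange(.data$tss_id, .data$tf, .data$strength)
  new_arch_tbl(arch, panel = panel, tss_ids = windows$tss_id)
}

new_arch_tbl <- function(arch, panel, tss_ids) {
  structure(arch, panel = panel, tss_ids = unique(tss_ids),
            class = c("arch_tbl", class(arch)))
}

#' @export
`[.arch_tbl` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "panel") <- attr(x, "panel")
    attr(out, "tss_ids") <- attr(x, "tss_ids")
  }
  out
}

#' Build an architecture table directly from TF sets
#'
#' Convenience constructor for desk-scale fixtures: takes per-promoter
#' tables of TF symbols with strength (and optional endothelial flags) and
#' returns the same `arch_tbl` shape [assemble_architectures()] produces,
#' with every count equal to the number of listed occurrences.
#'
#' @param sites Tibble with columns `tss_id, tf, strength` and optionally
#'   `endothelial` (logical).
#' @param panel TF universe; defaults to the distinct TFs listed.
#' @return An `arch_tbl`.
#' @export
arch_from_sites <- function(sites, panel = NULL) {
  if (is.null(panel)) panel <- sort(unique(sites$tf))
  stray <- setdiff(unique(sites$tf), panel)
  if (length(stray) > 0L) {
    stop("TF not in panel: ", paste(stray, collapse = ", "), call. = FALSE)
  }
  if (!"endothelial" %in% names(sites)) sites$endothelial <- FALSE
  arch <- sites |>
    dplyr::group_by(.data$tss_id, .data$tf, .data$strength) |>
    dplyr::summarise(n = dplyr::n(), n_endothelial = sum(.data$endothelial),
                     .groups = "drop") |>
    dplyr::arrange(.data$tss_id, .data$tf, .data$strength)
  new_arch_tbl(arch, panel = panel, tss_ids = unique(sites$tss_id))
}

# windows x peaks half-open interval intersection via IRanges, per chromosome
overlap_pairs <- function(windows, peaks) {
  if (nrow(peaks) == 0L || nrow(windows) == 0L) {
    return(tibble::tibble(tss_id = character(), tf = character(),
                          qs = double(), cell_type = character()))
  }
  out <- vector("list", 0L)
  for (chr in intersect(unique(windows$chrom), unique(peaks$chrom))) {
    w <- windows[windows$chrom == chr, , drop = FALSE]
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    # half-open [start, end) -> closed 1-based [start + 1, end]
    wr <- IRanges::IRanges(start = w$start + 1, end = w$end)
    pr <- IRanges::IRanges(start = p$start + 1, end = p$end)
    ov <- IRanges::findOverlaps(wr, pr, minoverlap = 1L)
    if (length(ov) == 0L) next
    out[[length(out) + 1L]] <- tibble::tibble(
      tss_id = w$tss_id[S4Vectors::queryHits(ov)],
      tf = p$tf[S4Vectors::subjectHits(ov)],
      qs = p$qs[S4Vectors::subjectHits(ov)],
      cell_type = p$cell_type[S4Vectors::subjectHits(ov)])
  }
  if (length(out) == 0L) {
    return(tibble::tibble(tss_id = character(), tf = character(),
                          qs = double(), cell_type = character()))
  }
  dplyr::bind_rows(out)
}

#' Encode architectures as vectors over the TF panel
#'
#' Converts an architecture table to a promoters-by-panel numeric matrix.
#' `mode = "count"` gives per-TF peak counts (strong only, or strong + weak
#' with `include_weak = TRUE`); `mode = "binary"` gives 0/1 presence of the
#' same peak selection.
#'
#' @param arch An `arch_tbl`.
#' @param mode `"count"` or `"binary"`.
#' @param include_weak Include weak peaks (default `TRUE`, the encoding used
#'   for distance analysis; probability analysis binarizes and set reports
#'   use strong peaks only).
#' @return Numeric matrix, rownames = tss ids (including all-zero rows for
#'   promoters with no assigned peaks), colnames = panel.
#' @export
arch_vectors <- function(arch, mode = c("count", "binary"),
                         include_weak = TRUE) {
  mode <- match.arg(mode)
  panel <- attr(arch, "panel")
  tss_ids <- attr(arch, "tss_ids")
  if (is.null(panel)) stop("architecture table has no panel", call. = FALSE)
  use <- if (include_weak) arch else arch[arch$strength == "strong", ]
  m <- matrix(0, nrow = length(tss_ids), ncol = length(panel),
              dimnames = list(tss_ids, panel))
  if (nrow(use) > 0L) {
    idx <- cbind(match(use$tss_id, tss_ids), match(use$tf, panel))
    for (i in seq_len(nrow(use))) {
      m[idx[i, 1], idx[i, 2]] <- m[idx[i, 1], idx[i, 2]] + use$n[i]
    }
  }
  if (mode == "binary") m <- (m > 0) + 0
  m
}

#' Extract per-promoter TF sets from an architecture table
#'
#' @param arch An `arch_tbl`.
#' @param strength `"strong"` for strong sites only, `"all"` for both.
#' @return Named list of character vectors (one TF set per promoter, in
#'   panel order; empty sets kept).
#' @export
arch_sets <- function(arch, strength = c("strong", "all")) {
  strength <- match.arg(strength)
  use <- if (strength == "strong") arch[arch$strength == "strong", ] else arch
  tss_ids <- attr(arch, "tss_ids")
  sets <- lapply(tss_ids, function(id) sort(unique(use$tf[use$tss_id == id])))
  names(sets) <- tss_ids
  sets
}
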