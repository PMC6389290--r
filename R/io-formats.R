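#' Read ChIP-seq peak calls from a BED-like peaks file
#'
#' Reads a whitespace/tab-delimited peaks file in the "peaks-tsv" dialect:
#' six columns `chrom, start, end, tf, qs, cell_type`, no header. Coordinates
#' are 0-based half-open (BED convention). Column 4 carries the
#' transcription-factor symbol, column 5 the ENCODE-style quality score
#' (0-1000) and column 6 a free-text cell-type label (a non-standard use of
#' BED column 6; the dialect is its own, not BED6).
#'
#' @param path Path to the peaks file.
#' @param dedupe Drop fully identical records? Defaults to `FALSE`: merged
#'   multi-cell-line tracks legitimately repeat TF/interval combinations and
#'   repeats contribute to counts.
#' @return A tibble with columns `chrom` (character), `start`, `end`
#'   (integer-valued doubles, 0-based half-open), `tf` (character), `qs`
#'   (numeric), `cell_type` (character). Input order is preserved.
#' @examples
#' f <- tempfile()
#' writeLines("chr11\t124764900\t124765100\tGATA2\t704\tHUVEC", f)
#' read_peaks(f)
#' @export
read_peaks <- function(path, dedupe = FALSE) {
  if (!file.exists(path)) {
    stop("peaks file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = FALSE, sep = "", quote = "",
                           colClasses = "character",
                           col.names = c("chrom", "start", "end", "tf",
                                         "qs", "cell_type"),
                           blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) {
    return(empty_peaks())
  }
  peaks <- tibble::tibble(
    chrom = raw$chrom,
    start = parse_coord(raw$start, path, "start"),
    end = parse_coord(raw$end, path, "end"),
    tf = raw$tf,
    qs = parse_coord(raw$qs, path, "qs"),
    cell_type = raw$cell_type
  )
  validate_peaks(peaks)
  if (isTRUE(dedupe)) peaks <- dplyr::distinct(peaks)
  peaks
}

empty_peaks <- function() {
  tibble::tibble(chrom = character(), start = double(), end = double(),
                 tf = character(), qs = double(), cell_type = character())
}

parse_coord <- function(x, path, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) | out != floor(out))
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s '%s' at line %d of %s",
                 what, x[bad[1]], bad[1], path), call. = FALSE)
  }
  out
}

validate_peaks <- function(peaks) {
  bad <- which(peaks$start >= peaks$end)
  if (length(bad) > 0L) {
    stop(sprintf("start >= end at record %d (%s:%s-%s)", bad[1],
                 peaks$chrom[bad[1]], format(peaks$start[bad[1]], scientific = FALSE),
                 format(peaks$end[bad[1]], scientific = FALSE)), call. = FALSE)
  }
  if (any(peaks$qs < 0)) {
    stop("negative quality score at record ", which(peaks$qs < 0)[1],
         call. = FALSE)
  }
  if (any(!nzchar(peaks$tf))) {
    stop("empty TF symbol at record ", which(!nzchar(peaks$tf))[1],
         call. = FALSE)
  }
  invisible(peaks)
}

#' Write peaks in the same dialect `read_peaks()` reads
#'
#' @param peaks A peaks tibble as returned by [read_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(
    data.frame(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
               format(peaks$end, scientific = FALSE, trim = TRUE), peaks$tf,
               format(peaks$qs, scientific = FALSE, trim = TRUE), peaks$cell_type),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS-cluster table
#'
#' Tab-separated with header `tss_id, chrom, start, end, strand`; coordinates
#' 0-based half-open; strand one of `+`, `-`, `.` (unknown).
#'
#' @param path Path to the table.
#' @return A tibble of TSS clusters.
#' @export
read_tss_clusters <- function(path) {
  tss <- readr::read_tsv(path, col_types = readr::cols(
    tss_id = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    strand = readr::col_character()))
  if (any(tss$start >= tss$end)) {
    stop("TSS cluster with start >= end at record ",
         which(tss$start >= tss$end)[1], call. = FALSE)
  }
  bad_strand <- setdiff(unique(tss$strand), c("+", "-", "."))
  if (length(bad_strand) > 0L) {
    stop("unknown strand value: ", bad_strand[1], call. = FALSE)
  }
  tss
}

#' @rdname read_tss_clusters
#' @param tss TSS-cluster tibble.
#' @export
write_tss_clusters <- function(tss, path) {
  readr::write_tsv(tss, path)
  invisible(path)
}

#' An expression set: a TSS-by-library TPM matrix plus library metadata
#'
#' Container pairing a non-negative expression matrix (rows = TSS or
#' transcript identifiers, columns = CAGE-style library identifiers, values
#' in tags per million) with per-library metadata: free-form category labels
#' (sample-ontology style) and an endothelial flag.
#'
#' @param tpm Numeric matrix with unique rownames and colnames, values >= 0.
#' @param meta Data frame with columns `library_id`, `categories` (list
#'   column of character vectors, or a single character column), and logical
#'   `endothelial`. Every matrix column must appear.
#' @return An object of class `expr_set`.
#' @export
expr_set <- function(tpm, meta) {
  stopifnot(is.matrix(tpm), is.numeric(tpm))
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop("tpm matrix needs row and column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(tpm)) || anyDuplicated(colnames(tpm))) {
    stop("duplicate row or column identifiers", call. = FALSE)
  }
  if (any(tpm < 0)) {
    stop("negative expression value", call. = FALSE)
  }
  meta <- tibble::as_tibble(meta)
  if (!is.list(meta$categories)) {
    meta$categories <- strsplit(as.character(meta$categories), ",", fixed = TRUE)
  }
  missing_libs <- setdiff(colnames(tpm), meta$library_id)
  if (length(missing_libs) > 0L) {
    stop("library present in matrix but absent from metadata: ",
         missing_libs[1], call. = FALSE)
  }
  meta <- meta[match(colnames(tpm), meta$library_id), , drop = FALSE]
  structure(list(tpm = tpm, meta = meta), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d TSS x %d libraries (%d endothelial)\n",
              nrow(x$tpm), ncol(x$tpm), sum(x$meta$endothelial)))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$tpm)

#' Read an expression matrix and its library metadata
#'
#' The matrix file is tab-separated with the row identifier in the first
#' column (header name arbitrary) and one column per library. The metadata
#' file is tab-separated with header `library_id, categories, endothelial`,
#' where `categories` is a comma-separated label list and `endothelial` is
#' TRUE/FALSE.
#'
#' @param path Matrix file path.
#' @param meta_path Metadata file path.
#' @param min_signal Optional floor: values strictly below it are set to 0
#'   (mirrors browser-style "clusters of >= 3 tags per library" filtering).
#' @return An [expr_set()].
#' @export
read_expression <- function(path, meta_path, min_signal = NULL) {
  mat_df <- utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  ids <- as.character(mat_df[[1]])
  tpm <- as.matrix(mat_df[, -1, drop = FALSE])
  storage.mode(tpm) <- "double"
  rownames(tpm) <- ids
  if (anyNA(tpm)) stop("non-numeric expression value", call. = FALSE)
  if (any(tpm < 0)) stop("negative expression value", call. = FALSE)
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(
    library_id = readr::col_character(),
    categories = readr::col_character(),
    endothelial = readr::col_logical()))
  if (!is.null(min_signal)) {
    tpm[tpm < min_signal] <- 0
  }
  expr_set(tpm, meta)
}

#' @rdname read_expression
#' @param x An `expr_set`.
#' @export
write_expression <- function(x, path, meta_path) {
  df <- data.frame(tss_id = rownames(x$tpm), x$tpm, check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), path)
  meta <- tibble::tibble(
    library_id = x$meta$library_id,
    categories = vapply(x$meta$categories, paste, character(1), collapse = ","),
    endothelial = x$meta$endothelial)
  readr::write_tsv(meta, meta_path)
  invisible(path)
}

#' Read a per-species gene coordinate table
#'
#' Tab-separated with header `gene_id, species, chrom, start, end, strand`;
#' coordinates 0-based half-open.
#'
#' @param path Path to the table.
#' @return A tibble of gene records.
#' @export
read_gene_table <- function(path) {
  genes <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), species = readr::col_character(),
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), strand = readr::col_character()))
  if (any(genes$start >= genes$end)) {
    stop("gene with start >= end at record ",
         which(genes$start >= genes$end)[1], call. = FALSE)
  }
  genes
}

#' @rdname read_gene_table
#' @param genes Gene tibble.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path)
  invisible(path)
}

#' Read a one-to-one ortholog map
#'
#' Tab-separated with header `human_id, species, ortholog_id`. The map must
#' be one-to-one within each species: no human gene maps to two orthologs of
#' the same species, and no ortholog is claimed by two human genes.
#'
#' @param path Path to the map.
#' @return A tibble with columns `human_id, species, ortholog_id`.
#' @export
read_ortholog_map <- function(path) {
  orthos <- readr::read_tsv(path, col_types = readr::cols(
    human_id = readr::col_character(), species = readr::col_character(),
    ortholog_id = readr::col_character()))
  validate_ortholog_map(orthos)
}

validate_ortholog_map <- function(orthos) {
  orthos <- dplyr::distinct(orthos)
  dup_h <- orthos |>
    dplyr::count(.data$human_id, .data$species) |>
    dplyr::filter(.data$n > 1)
  dup_o <- orthos |>
    dplyr::count(.data$ortholog_id, .data$species) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_h) > 0L) {
    stop("one-to-one violation: human gene ", dup_h$human_id[1],
         " maps to multiple orthologs in ", dup_h$species[1], call. = FALSE)
  }
  if (nrow(dup_o) > 0L) {
    stop("one-to-one violation: ortholog ", dup_o$ortholog_id[1],
         " claimed by multiple human genes in ", dup_o$species[1],
         call. = FALSE)
  }
  orthos
}

#' @rdname read_ortholog_map
#' @param orthos Ortholog-map tibble.
#' @export
write_ortholog_map <- function(orthos, path) {
  readr::write_tsv(orthos, path)
  invisible(path)
}
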