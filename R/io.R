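#' Read one SRT slice from disk
#'
#' Loads a spot-by-gene count matrix together with its spot coordinates.
#' The matrix file may be MatrixMarket (`.mtx`) or delimited text (spots in
#' rows, genes in columns; an optional header row of gene names and an
#' optional first column of spot ids are auto-detected). The coordinate file
#' is delimited text with one `(x, y)` row per spot, same order as the
#' matrix.
#'
#' @param matrix_path path to the count matrix (`.mtx` or delimited text).
#' @param coords_path path to the 2-column coordinate table.
#' @param slice_id character label identifying this slice (batch).
#' @return A `"raw_slice"` list with elements `counts` (dense integer-valued
#'   matrix, spots x genes), `coords` (m x 2 numeric matrix), `slice_id`, and
#'   `gene_names`.
#' @export
read_slice <- function(matrix_path, coords_path, slice_id) {
  counts <- read_count_matrix(matrix_path)
  coords <- read_coords(coords_path)
  if (nrow(coords) != nrow(counts)) {
    stop(sprintf(
      "slice '%s': count matrix has %d spots but coordinate table has %d rows",
      slice_id, nrow(counts), nrow(coords)))
  }
  if (any(counts < 0)) stop(sprintf("slice '%s': negative counts", slice_id))
  new_raw_slice(counts, coords, slice_id)
}

new_raw_slice <- function(counts, coords, slice_id, gene_names = colnames(counts)) {
  if (is.null(gene_names))
    gene_names <- paste0("g", seq_len(ncol(counts)) - 1L)
  colnames(counts) <- gene_names
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0(slice_id, "_s", seq_len(nrow(counts)) - 1L)
  structure(list(counts = counts, coords = as.matrix(coords),
                 slice_id = as.character(slice_id), gene_names = gene_names),
            class = "raw_slice")
}

read_count_matrix <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "double"
    return(m)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(fields[-1]))))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          check.names = FALSE, stringsAsFactors = FALSE)
  # a non-numeric first column holds spot ids
  row_ids <- NULL
  if (ncol(df) > 0 && !is.numeric(df[[1]])) {
    row_ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (!has_header) colnames(m) <- NULL
  if (!is.null(row_ids)) rownames(m) <- row_ids
  m
}

read_coords <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(fields))))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE)
  num <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) < 2) stop("coordinate file needs two numeric columns")
  as.matrix(num[, 1:2])
}

#' Write a slice to MTX + TSV files
#'
#' Companion writer for [read_slice()]: emits `<prefix>.counts.mtx`,
#' `<prefix>.coords.tsv` and `<prefix>.genes.tsv`.
#'
#' @param slice a `"raw_slice"`.
#' @param prefix file path prefix (directories are created).
#' @return Invisibly, the named vector of written paths.
#' @export
write_slice <- function(slice, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = paste0(prefix, ".counts.mtx"),
             coords = paste0(prefix, ".coords.tsv"),
             genes  = paste0(prefix, ".genes.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(slice$counts, sparse = TRUE), "generalMatrix"),
                  paths["counts"])
  utils::write.table(data.frame(x = slice$coords[, 1], y = slice$coords[, 2]),
                     paths["coords"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(slice$gene_names, paths["genes"])
  invisible(paths)
}

#' Write embeddings and domain labels to TSV files
#'
#' Produces `embeddings.tsv` (`spot_id`, `slice_id`, `z_1 ... z_d`) and
#' `labels.tsv` (`spot_id`, `slice_id`, `domain`) under `out_dir`, with a
#' deterministic column order.
#'
#' @param embeddings numeric matrix, one row per spot.
#' @param labels integer domain label per spot.
#' @param out_dir output directory, created if needed.
#' @param spot_ids,slice_ids optional identifier vectors; defaults are
#'   generated.
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(embeddings, labels, out_dir,
                          spot_ids = NULL, slice_ids = NULL) {
  embeddings <- as.matrix(embeddings)
  m <- nrow(embeddings)
  if (length(labels) == 0L) stop("empty label vector")
  if (length(labels) != m)
    stop(sprintf("embeddings have %d rows but labels length is %d", m, length(labels)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(m) - 1L)
  if (is.null(slice_ids)) slice_ids <- rep("slice0", m)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  emb <- data.frame(spot_id = spot_ids, slice_id = slice_ids,
                    embeddings, check.names = FALSE)
  names(emb)[-(1:2)] <- paste0("z_", seq_len(ncol(embeddings)))
  for (j in seq_len(ncol(embeddings)) + 2L)
    emb[[j]] <- sprintf("%.17g", emb[[j]])
  emb_path <- file.path(out_dir, "embeddings.tsv")
  utils::write.table(emb, emb_path, sep = "\t", quote = FALSE, row.names = FALSE)

  lab <- data.frame(spot_id = spot_ids, slice_id = slice_ids,
                    domain = as.integer(labels))
  lab_path <- file.path(out_dir, "labels.tsv")
  utils::write.table(lab, lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(embeddings = emb_path, labels = lab_path))
}

#' Read back result tables written by [write_results()]
#' @param out_dir the directory given to [write_results()].
#' @return list with `embeddings` (numeric matrix), `labels` (integer vector),
#'   `spot_ids`, `slice_ids`.
#' @export
read_results <- function(out_dir) {
  emb <- utils::read.table(file.path(out_dir, "embeddings.tsv"),
                           sep = "\t", header = TRUE, check.names = FALSE)
  lab <- utils::read.table(file.path(out_dir, "labels.tsv"),
                           sep = "\t", header = TRUE)
  list(embeddings = as.matrix(emb[, -(1:2), drop = FALSE]),
       labels = as.integer(lab$domain),
       spot_ids = as.character(emb$spot_id),
       slice_ids = as.character(emb$slice_id))
}

#' Export a graph operator as an edge-list TSV
#'
#' Writes columns `i`, `j`, `weight` with 0-based spot indices.
#'
#' @param A a (sparse) matrix.
#' @param path output TSV path.
#' @export
write_edgelist <- function(A, path) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  ord <- order(A@i, A@j)
  utils::write.table(data.frame(i = A@i[ord], j = A@j[ord], weight = A@x[ord]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
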