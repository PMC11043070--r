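#' Construct a gene-by-cell count matrix object
#'
#' The container used by the patch-seq stage: an integer gene x cell matrix
#' plus per-cell metadata (diet condition, pre-selection label) and per-gene
#' flags (mitochondrial / ribosomal, used by the QC summaries).
#'
#' @param counts Integer matrix, genes in rows, cells in columns, with
#'   dimnames.
#' @param cell_meta Tibble with one row per cell; must contain `cell`.
#'   Optional `condition` (e.g. CD/HFD) and `preselect_label`
#'   (typical/ghost).
#' @param gene_flags Tibble with `gene`, `is_mito`, `is_ribo`; derived from
#'   gene-name prefixes when `NULL`.
#' @param mito_prefix,ribo_prefix Gene-name prefixes used to derive flags.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_meta = NULL, gene_flags = NULL,
                         mito_prefix = c("mt-", "Mt-", "MT-"),
                         ribo_prefix = c("Rps", "Rpl", "RPS", "RPL")) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop_ghostmap("counts must be finite non-negative integers",
                  "ghostmap_value_error")
  }
  storage.mode(counts) <- "integer"
  if (is.null(cell_meta)) {
    cell_meta <- tibble::tibble(cell = colnames(counts))
  }
  cell_meta <- tibble::as_tibble(cell_meta)
  if (!"cell" %in% names(cell_meta) ||
      !setequal(cell_meta$cell, colnames(counts)) ||
      nrow(cell_meta) != ncol(counts)) {
    stop_ghostmap("cell_meta$cell must match the matrix columns exactly",
                  "ghostmap_value_error")
  }
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell), ]
  if (is.null(gene_flags)) {
    starts_with_any <- function(x, prefixes) {
      Reduce(`|`, lapply(prefixes, function(p) startsWith(x, p)))
    }
    gene_flags <- tibble::tibble(
      gene = rownames(counts),
      is_mito = starts_with_any(rownames(counts), mito_prefix),
      is_ribo = starts_with_any(rownames(counts), ribo_prefix)
    )
  }
  gene_flags <- tibble::as_tibble(gene_flags)
  if (!setequal(gene_flags$gene, rownames(counts)) ||
      nrow(gene_flags) != nrow(counts)) {
    stop_ghostmap("gene_flags$gene must match the matrix rows exactly",
                  "ghostmap_value_error")
  }
  gene_flags <- gene_flags[match(rownames(counts), gene_flags$gene), ]
  structure(
    list(counts = counts, cell_meta = cell_meta, gene_flags = gene_flags),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if ("condition" %in% names(x$cell_meta)) {
    cat("conditions:",
        paste(names(table(x$cell_meta$condition)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load a count matrix from MTX triplet or dense CSV
#'
#' Accepts either a directory holding a MatrixMarket triplet
#' (`matrix.mtx`, `genes.tsv`, `barcodes.tsv`, optional `cell_meta.csv`)
#' or a dense CSV with gene identifiers in the first column and cell
#' identifiers in the header.
#'
#' @param path Directory (MTX triplet) or CSV file (dense).
#' @inheritParams count_matrix
#' @return A [count_matrix] object with gene flags derived from name
#'   prefixes.
#' @export
load_count_matrix <- function(path,
                              mito_prefix = c("mt-", "Mt-", "MT-"),
                              ribo_prefix = c("Rps", "Rpl", "RPS", "RPL")) {
  if (dir.exists(path)) {
    mtx_path <- file.path(path, "matrix.mtx")
    for (f in c(mtx_path, file.path(path, c("genes.tsv", "barcodes.tsv")))) {
      if (!file.exists(f)) {
        stop_ghostmap(paste0("missing triplet file: ", f), "ghostmap_io_error")
      }
    }
    check_mtx_header(mtx_path)
    m <- as.matrix(Matrix::readMM(mtx_path))
    genes <- readr::read_tsv(file.path(path, "genes.tsv"),
                             col_names = FALSE, show_col_types = FALSE,
                             progress = FALSE)[[1]]
    cells <- readr::read_tsv(file.path(path, "barcodes.tsv"),
                             col_names = FALSE, show_col_types = FALSE,
                             progress = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop_ghostmap("sidecar gene/cell lists do not match matrix dimensions",
                    "ghostmap_format_error")
    }
    dimnames(m) <- list(genes, cells)
    meta_path <- file.path(path, "cell_meta.csv")
    meta <- if (file.exists(meta_path)) {
      readr::read_csv(meta_path, show_col_types = FALSE, progress = FALSE)
    } else {
      NULL
    }
  } else if (file.exists(path)) {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- as.character(raw[[1]])
    meta <- NULL
  } else {
    stop_ghostmap(paste0("count matrix path not found: ", path),
                  "ghostmap_io_error")
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m))) {
    stop_ghostmap("counts must be finite non-negative integers",
                  "ghostmap_value_error")
  }
  count_matrix(m, cell_meta = meta,
               mito_prefix = mito_prefix, ribo_prefix = ribo_prefix)
}

# The MatrixMarket header declares (nrow, ncol, nnz); a truncated or padded
# entry list is a format error rather than a silent misread.
check_mtx_header <- function(mtx_path) {
  lines <- readLines(mtx_path)
  body <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  hdr <- as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]])
  n_entries <- length(body) - 1L
  if (length(hdr) != 3 || hdr[3] != n_entries) {
    stop_ghostmap(
      sprintf("MTX header declares %s entries but %d are present",
              if (length(hdr) == 3) format(hdr[3]) else "?", n_entries),
      "ghostmap_format_error"
    )
  }
  invisible(TRUE)
}

#' Write a count matrix as an MTX triplet directory
#'
#' @param x A [count_matrix] object.
#' @param dir Output directory (created if needed). Writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv` and `cell_meta.csv`.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- methods::as(Matrix::Matrix(x$counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  readr::write_csv(x$cell_meta, file.path(dir, "cell_meta.csv"),
                   progress = FALSE)
  invisible(dir)
}
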