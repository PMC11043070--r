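#' Read a per-cell quantification table
#'
#' Reads a tidy one-row-per-cell CSV/TSV produced by segmentation and
#' quantification (or by an external tool) into a validated cell table.
#' The canonical columns are `cell_id`, `animal_id`, `section_id`, `group`,
#' the centroid `x`, `y`, `z` (micrometres), `size` (area in um^2 for 2D
#' quantification, volume in um^3 for 3D), per-channel intensity columns
#' named `mean_<channel>` and `max_<channel>`, the logical
#' `lineage_positive`, the `class_label` (`typical`, `ghost` or
#' `unassigned`), and logical `marker_<name>` co-positivity calls. A
#' `schema` may map canonical names onto the file's column names; columns
#' not covered by the schema are preserved untouched.
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from the
#'   extension).
#' @param schema Named character vector or list mapping canonical column
#'   names to the file's column names, e.g. `c(cell_id = "ROI", mean_pomc =
#'   "Mean1")`. Identity by default.
#' @return A validated cell-table tibble.
#' @seealso [write_cell_table()], [validate_cell_table()]
#' @export
load_cell_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop_ghostmap(paste0("cell table file not found: ", path),
                  "ghostmap_io_error")
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(schema)) {
    schema <- unlist(schema)
    missing_src <- setdiff(unname(schema), names(tbl))
    if (length(missing_src) > 0) {
      stop_ghostmap(
        paste0("schema refers to absent column(s): ",
               paste(missing_src, collapse = ", ")),
        "ghostmap_schema_error"
      )
    }
    names(tbl)[match(unname(schema), names(tbl))] <- names(schema)
  }
  validate_cell_table(tbl)
}

#' Validate a cell table
#'
#' Checks the structural invariants of a cell table: mandatory identifier
#' columns, at least one intensity column, non-negative finite intensities,
#' finite centroids, cell ids unique within (animal, section), and class
#' labels restricted to lineage-positive cells.
#'
#' @param cells A data frame with at least `cell_id`, `animal_id` and one
#'   `mean_*`/`max_*` intensity column.
#' @return The validated table as a tibble (invisibly unchanged content).
#' @export
validate_cell_table <- function(cells) {
  cells <- tibble::as_tibble(cells)
  for (col in c("cell_id", "animal_id")) {
    if (!col %in% names(cells)) {
      stop_ghostmap(paste0("mandatory column missing: ", col),
                    "ghostmap_schema_error")
    }
  }
  int_cols <- grep("^(mean|max)_", names(cells), value = TRUE)
  if (length(int_cols) == 0) {
    stop_ghostmap("no intensity column (mean_*/max_*) found",
                  "ghostmap_schema_error")
  }
  for (col in int_cols) {
    v <- cells[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop_ghostmap(
        sprintf("non-numeric intensity in column %s (first bad row: %d)",
                col, if (length(bad)) bad[1] else 1L),
        "ghostmap_parse_error"
      )
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop_ghostmap(paste0("negative intensity in column ", col),
                    "ghostmap_value_error")
    }
  }
  for (col in intersect(c("x", "y", "z"), names(cells))) {
    if (!is.numeric(cells[[col]]) || any(!is.finite(cells[[col]]))) {
      stop_ghostmap(paste0("non-finite centroid coordinate in column ", col),
                    "ghostmap_value_error")
    }
  }
  key <- paste(cells$animal_id,
               if ("section_id" %in% names(cells)) cells$section_id else "",
               cells$cell_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_ghostmap("cell_id not unique within (animal_id, section_id)",
                  "ghostmap_value_error")
  }
  if ("class_label" %in% names(cells)) {
    ok <- cells$class_label %in% c("typical", "ghost", "unassigned") |
      is.na(cells$class_label)
    if (!all(ok)) {
      stop_ghostmap("class_label must be typical/ghost/unassigned",
                    "ghostmap_value_error")
    }
    if ("lineage_positive" %in% names(cells)) {
      offender <- !cells$lineage_positive &
        cells$class_label %in% c("typical", "ghost")
      if (any(offender, na.rm = TRUE)) {
        stop_ghostmap(
          "class_label typical/ghost assigned to a lineage-negative cell",
          "ghostmap_value_error"
        )
      }
    }
  }
  cells
}

#' Write a cell table to CSV/TSV
#'
#' @param cells A cell-table tibble.
#' @param path Output path; `.tsv` selects tab delimiting, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  cells <- validate_cell_table(cells)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(cells, path, delim = delim, progress = FALSE)
  invisible(path)
}
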