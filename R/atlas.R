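#' Region tables: reading, validation and node bookkeeping
#'
#' A region table describes a cortical parcellation as a data frame with one
#' row per region and columns `region_id` (unique non-negative integer),
#' `name`, `hemisphere` (`"L"` or `"R"`) and `region_class` (one of
#' `"gyral"`, `"sulcal"`, `"ambiguous"`). Ambiguous regions are carried
#' through loading but dropped from all analyses.
#'
#' @name region-table
NULL

.region_classes <- c("gyral", "sulcal", "ambiguous")

#' Validate a region table
#'
#' Checks column presence, types, uniqueness of `region_id` and class
#' labels. Class labels are lowercased before matching but NOT trimmed:
#' `"gyral "` is rejected, so silent mislabeling from stray whitespace
#' cannot pass.
#'
#' @param table data frame candidate.
#' @return The validated table (classes canonicalized to lower case),
#'   invisibly usable downstream.
#' @keywords internal
validate_region_table <- function(table) {
  required <- c("region_id", "name", "hemisphere", "region_class")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    stop("region table is missing column(s): ", paste(missing, collapse = ", "))
  }
  table$region_id <- as.integer(table$region_id)
  if (anyNA(table$region_id) || any(table$region_id < 0)) {
    stop("region_id must be a non-negative integer")
  }
  dup <- table$region_id[duplicated(table$region_id)]
  if (length(dup) > 0) {
    stop("duplicate region_id: ", paste(unique(dup), collapse = ", "))
  }
  table$region_class <- tolower(as.character(table$region_class))
  bad <- which(!table$region_class %in% .region_classes)
  if (length(bad) > 0) {
    stop(sprintf("row %d has unknown region_class %s (expected gyral/sulcal/ambiguous)",
                 bad[1], dQuote(table$region_class[bad[1]])))
  }
  bad_hemi <- which(!table$hemisphere %in% c("L", "R"))
  if (length(bad_hemi) > 0) {
    stop(sprintf("row %d has unknown hemisphere %s (expected L or R)",
                 bad_hemi[1], dQuote(as.character(table$hemisphere[bad_hemi[1]]))))
  }
  n_g <- sum(table$region_class == "gyral")
  n_s <- sum(table$region_class == "sulcal")
  if (n_g < 2 || n_s < 2) {
    warning(sprintf("only %d gyral and %d sulcal regions: subnetwork analyses need at least 2 of each",
                    n_g, n_s))
  }
  table
}

#' Load a region table from a tab-separated file
#'
#' The file must have a header row naming the four columns `region_id`,
#' `name`, `hemisphere`, `region_class`.
#'
#' @param path path to a TSV file.
#' @return Validated region table data frame; ambiguous rows are retained.
#' @export
#' @examples
#' atlas <- make_default_atlas()
#' f <- tempfile(fileext = ".tsv")
#' write.table(atlas, f, sep = "\t", row.names = FALSE, quote = FALSE)
#' nrow(load_region_table(f)) # 148
load_region_table <- function(path) {
  if (!file.exists(path)) stop("region table not found: ", path)
  table <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character", strip.white = FALSE)
  validate_region_table(table)
}

#' Indices of retained (non-ambiguous) regions
#'
#' Ambiguous regions are excluded; the remaining regions are split into the
#' gyral and sulcal node sets. Indices refer to rows of `table` and are
#' sorted by `region_id`, which fixes the canonical node order used by all
#' network code: gyral nodes first, then sulcal.
#'
#' @param table a validated region table.
#' @return List with integer vectors `gyral` and `sulcal` (row indices into
#'   `table`).
#' @export
retained_indices <- function(table) {
  table <- validate_region_table(table)
  keep <- function(cls) {
    idx <- which(table$region_class == cls)
    idx[order(table$region_id[idx])]
  }
  out <- list(gyral = keep("gyral"), sulcal = keep("sulcal"))
  if (length(out$gyral) == 0 && length(out$sulcal) == 0) {
    warning("no non-ambiguous regions retained")
  }
  out
}

#' Read / write a numeric matrix as TSV
#'
#' Matrices are stored dense, tab-separated, with optional row/column
#' labels. Values are written with enough digits (15 significant) that a
#' write/read round trip is lossless well beyond 10 significant digits.
#' All entries must be finite: similarity matrices never contain NaN.
#'
#' @param path file path.
#' @param labels logical; write row and column names.
#' @return `read_matrix` returns a numeric matrix (with dimnames when the
#'   file has them); `write_matrix` returns `path` invisibly.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty matrix file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  has_labels <- is.na(suppressWarnings(as.numeric(cells[[1]][1]))) &&
    nzchar(cells[[1]][1]) || identical(cells[[1]][1], "")
  if (has_labels) {
    col_labels <- cells[[1]][-1]
    cells <- cells[-1]
    row_labels <- vapply(cells, `[`, character(1), 1)
    cells <- lapply(cells, `[`, -1)
  } else {
    col_labels <- row_labels <- NULL
  }
  widths <- lengths(cells)
  if (length(unique(widths)) != 1) {
    stop(sprintf("ragged matrix file: row %d has %d cells, expected %d",
                 which(widths != widths[1])[1] + has_labels, widths[widths != widths[1]][1],
                 widths[1]))
  }
  m <- matrix(NA_real_, nrow = length(cells), ncol = widths[1])
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v) || any(!is.finite(v))) {
      j <- which(is.na(v) | !is.finite(suppressWarnings(as.numeric(cells[[i]]))))[1]
      stop(sprintf("non-finite or non-numeric cell at row %d, column %d: %s",
                   i + has_labels, j, dQuote(cells[[i]][j])))
    }
    m[i, ] <- v
  }
  if (!is.null(row_labels)) dimnames(m) <- list(row_labels, col_labels)
  m
}

#' @rdname read_matrix
#' @param m numeric matrix with finite entries.
#' @export
write_matrix <- function(m, path, labels = !is.null(dimnames(m))) {
  if (!is.matrix(m) || !is.numeric(m)) stop("m must be a numeric matrix")
  if (any(!is.finite(m))) stop("matrix contains non-finite entries")
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  body <- apply(m, 1, function(r) paste(fmt(r), collapse = "\t"))
  if (labels && !is.null(dimnames(m))) {
    header <- paste(c("", colnames(m)), collapse = "\t")
    body <- paste(rownames(m), body, sep = "\t")
    writeLines(c(header, body), path)
  } else {
    writeLines(body, path)
  }
  invisible(path)
}
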