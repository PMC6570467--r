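# Plain-text writers/readers for the pipeline's exchange formats. All
# writers produce deterministic byte output for identical inputs (fixed
# column order, radix-sorted rows where order is not meaningful, no quoting).

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an omics matrix and its labels as TSV
#'
#' The matrix file has features in rows (first column `feature_id`), samples
#' in columns; the label file has columns `sample_id`, `label`.
#'
#' @param om an [omics_matrix()].
#' @param matrix_path,labels_path output/input TSV paths.
#' @return `matrix_path`, invisibly (writer); an [omics_matrix()] (reader).
#' @export
write_omics_tsv <- function(om, matrix_path, labels_path) {
  stopifnot(inherits(om, "omics_matrix"))
  df <- data.frame(feature_id = rownames(om$values), om$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, matrix_path)
  write_tsv(data.frame(sample_id = colnames(om$values),
                       label = as.character(om$labels)), labels_path)
  invisible(matrix_path)
}

#' @rdname write_omics_tsv
#' @param platform,study_id metadata for the reconstructed matrix.
#' @export
read_omics_tsv <- function(matrix_path, labels_path, platform,
                           study_id = "study") {
  df <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "")
  lab <- utils::read.table(labels_path, sep = "\t", header = TRUE,
                           quote = "", stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$feature_id
  omics_matrix(vals, lab$label[match(colnames(vals), lab$sample_id)],
               platform, study_id)
}

#' Write a differential table (or any record table) as TSV
#'
#' @param tbl a data frame (e.g. a `diff_table`).
#' @param path output path.
#' @export
write_diff_tsv <- function(tbl, path) {
  write_tsv(as.data.frame(tbl), path)
}

#' Read a differential table written by [write_diff_tsv()] or a
#' pre-computed external table with columns `feature_id`, `raw_p`,
#' `fold_change` (so external per-study exports can be ingested verbatim).
#'
#' @param path TSV path.
#' @param study_id,platform metadata attached to the table.
#' @return a `diff_table` data frame.
#' @export
read_diff_tsv <- function(path, study_id = "study", platform = "transcript") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("feature_id", "raw_p", "fold_change")
  if (!all(need %in% names(df)))
    stop("diff table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(df$direction))
    df$direction <- ifelse(df$fold_change > 1, "up",
                           ifelse(df$fold_change < 1, "down", "unchanged"))
  structure(df, study_id = study_id, platform = platform,
            class = c("diff_table", "data.frame"))
}

#' Write a gene-to-EC map as two-column TSV (no header)
#'
#' @param ec_map data frame with columns `gene`, `ec`.
#' @param path output path.
#' @export
write_ec_tsv <- function(ec_map, path) {
  utils::write.table(ec_map[, c("gene", "ec")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
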