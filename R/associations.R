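# Disease-protein association tables: loading, exclusion filtering,
# redundancy statistics, and the binary feature matrix with labels.

.new_dp_table <- function(rows) {
  structure(list(rows = rows,
                 diseases = unique(rows$disease_id),
                 proteins = unique(rows$protein_accession)),
            class = "disease_protein_table")
}

#' Load a disease-protein association table
#'
#' TSV with header columns `disease_id` and `protein_accession`; rows are
#' deduplicated and first-seen order is preserved for the disease and
#' protein indices (so downstream ensembles are deterministic).
#'
#' @param path Path to the TSV.
#' @return A `disease_protein_table`: list with `rows` (data.frame),
#'   `diseases` and `proteins` (ordered unique ids).
#' @export
load_associations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("disease_id", "protein_accession")
  if (!all(need %in% names(df)))
    stop("association table must have columns disease_id, protein_accession")
  df <- df[, need]
  df$disease_id <- as.character(df$disease_id)
  df$protein_accession <- as.character(df$protein_accession)
  if (!nrow(df)) stop("association table is empty: ", path)
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  .new_dp_table(df)
}

#' Build an association table from vectors
#'
#' @param disease_id,protein_accession Parallel character vectors.
#' @return A `disease_protein_table`.
#' @export
association_table <- function(disease_id, protein_accession) {
  stopifnot(length(disease_id) == length(protein_accession))
  if (!length(disease_id)) stop("association table is empty")
  df <- data.frame(disease_id = as.character(disease_id),
                   protein_accession = as.character(protein_accession),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  .new_dp_table(df)
}

#' @export
print.disease_protein_table <- function(x, ...) {
  cat("disease_protein_table:", nrow(x$rows), "associations,",
      length(x$diseases), "diseases,", length(x$proteins), "proteins\n")
  invisible(x)
}

#' Drop diseases by association count or by explicit id
#'
#' Removes diseases with fewer than `min_proteins` or more than
#' `max_proteins` associations (the latter drops umbrella diseases tied
#' to thousands of proteins) plus any explicitly listed ids.
#'
#' @param table A `disease_protein_table`.
#' @param min_proteins Minimum association count (default 1).
#' @param max_proteins Maximum association count (default 2000).
#' @param drop_ids Disease ids to drop regardless of count.
#' @return A new `disease_protein_table`.
#' @export
exclude_diseases <- function(table, min_proteins = 1, max_proteins = 2000,
                             drop_ids = character()) {
  stopifnot(inherits(table, "disease_protein_table"))
  counts <- base::table(factor(table$rows$disease_id,
                               levels = unique(table$rows$disease_id)))
  bad <- names(counts)[counts < min_proteins | counts > max_proteins]
  bad <- union(bad, drop_ids)
  dropped <- intersect(table$diseases, bad)
  if (length(dropped))
    message("excluding ", length(dropped), " disease(s): ",
            paste(dropped, collapse = ", "))
  rows <- table$rows[!table$rows$disease_id %in% bad, , drop = FALSE]
  rownames(rows) <- NULL
  if (!nrow(rows)) message("no diseases left after exclusion")
  .new_dp_table(rows)
}

#' Redundancy of pooled disease-protein associations
#'
#' The share of pooled associations whose protein also occurs for another
#' disease: `100 * (total - unique) / total`. Heavy redundancy is the
#' empirical signature of similar diseases sharing related proteins.
#'
#' @param x A `disease_protein_table`, or the total association count.
#' @param unique_proteins When `x` is a count, the number of distinct
#'   proteins.
#' @return A `redundancy_stats` object: list with `total_associations`,
#'   `unique_proteins`, `redundant_pct` (full precision) and
#'   `redundant_pct_display` (rounded to one decimal).
#' @export
redundancy_stats <- function(x, unique_proteins = NULL) {
  if (inherits(x, "disease_protein_table")) {
    total <- nrow(x$rows)
    uniq <- length(x$proteins)
  } else {
    total <- as.numeric(x)
    uniq <- as.numeric(unique_proteins)
  }
  if (is.na(total) || total < 1) stop("at least one association required")
  if (uniq < 0 || uniq > total)
    stop("unique protein count must lie in [0, total]")
  pct <- 100 * (total - uniq) / total
  structure(list(total_associations = total, unique_proteins = uniq,
                 redundant_pct = pct,
                 redundant_pct_display = round(pct, 1)),
            class = "redundancy_stats")
}

#' @export
print.redundancy_stats <- function(x, ...) {
  cat(x$total_associations, "associations,", x$unique_proteins,
      "unique proteins:", x$redundant_pct_display, "% redundant\n")
  invisible(x)
}

#' Build the binary disease-by-protein feature matrix
#'
#' `X[d, p] = 1` iff disease `d` is associated with protein `p`; `y` is
#' each disease's normalized similarity label. The protein index covers
#' the union of proteins in first-seen order.
#'
#' @param table A `disease_protein_table`.
#' @param labels Named numeric vector (or 2-column data.frame
#'   `disease_id`, `normalized_similarity`) giving every disease's label
#'   in `[0, 1]`.
#' @return A `feature_matrix`: list with binary matrix `X`
#'   (diseases x proteins, dimnames set), label vector `y`,
#'   `disease_index` and `protein_index`.
#' @export
build_feature_matrix <- function(table, labels) {
  stopifnot(inherits(table, "disease_protein_table"))
  if (is.data.frame(labels)) {
    stopifnot(ncol(labels) >= 2)
    labels <- stats::setNames(as.numeric(labels[[2]]),
                              as.character(labels[[1]]))
  }
  missing <- setdiff(table$diseases, names(labels))
  if (length(missing))
    stop("no similarity label for disease(s): ",
         paste(missing, collapse = ", "))
  d_idx <- table$diseases
  p_idx <- table$proteins
  X <- matrix(0L, nrow = length(d_idx), ncol = length(p_idx),
              dimnames = list(d_idx, p_idx))
  X[cbind(match(table$rows$disease_id, d_idx),
          match(table$rows$protein_accession, p_idx))] <- 1L
  y <- unname(labels[d_idx])
  if (any(y < 0 | y > 1)) stop("labels must lie in [0, 1]")
  structure(list(X = X, y = y, disease_index = d_idx,
                 protein_index = p_idx),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$X), "diseases x", ncol(x$X), "proteins\n")
  invisible(x)
}

#' Serialize a feature matrix to TSV
#'
#' Writes two files: the binary matrix with a `disease_id` column plus
#' one column per protein accession, and a label table
#' (`disease_id`, `normalized_similarity`).
#'
#' @param fm A `feature_matrix`.
#' @param matrix_path,labels_path Output TSV paths.
#' @return Invisibly, `matrix_path`.
#' @export
write_feature_matrix <- function(fm, matrix_path, labels_path) {
  df <- data.frame(disease_id = fm$disease_index,
                   fm$X, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(disease_id = fm$disease_index,
               normalized_similarity = fm$y),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param matrix_path,labels_path TSV paths.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(matrix_path, labels_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  d_idx <- as.character(df$disease_id)
  p_idx <- setdiff(names(df), "disease_id")
  X <- as.matrix(df[, p_idx, drop = FALSE])
  storage.mode(X) <- "integer"
  dimnames(X) <- list(d_idx, p_idx)
  y <- stats::setNames(lab$normalized_similarity,
                       as.character(lab$disease_id))[d_idx]
  structure(list(X = X, y = unname(y), disease_index = d_idx,
                 protein_index = p_idx),
            class = "feature_matrix")
}
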