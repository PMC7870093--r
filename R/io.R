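#' Read a continuous data matrix from TSV/CSV
#'
#' Instances as rows, a header row of attribute names, no index column
#' required. Tab-separated is the canonical dialect; comma-separated files
#' are detected by extension.
#'
#' @param path File path.
#' @return A [continuous_matrix()].
#' @export
read_continuous_matrix <- function(path) {
  df <- read_delim_auto(path)
  continuous_matrix(as.matrix(df))
}

#' Write a matrix as TSV
#'
#' @param x Matrix or data frame.
#' @param path Output path.
#' @param row_names Write row names as a leading `id` column.
#' @export
write_matrix_tsv <- function(x, path, row_names = FALSE) {
  if (row_names) {
    df <- data.frame(id = rownames(x) %||% seq_len(nrow(x)),
                     as.data.frame(unclass(x)), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(as.data.frame(unclass(x)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a genotype matrix with optional locus annotation
#'
#' The genotype file holds integers in `{0, 1, 2}` (instances as rows,
#' header of locus IDs). The optional annotation TSV has columns
#' `locus_id`, `maf`, `encoding` (PuPu/PuPy/PyPy), matched to the genotype
#' columns by `locus_id`.
#'
#' @param path Genotype file path.
#' @param annotation Optional annotation file path.
#' @return A [genotype_data()].
#' @export
read_genotype_matrix <- function(path, annotation = NULL) {
  df <- read_delim_auto(path)
  G <- as.matrix(df)
  bad <- which(matrix(!(G %in% 0:2), nrow(G)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid genotype %s at row %d, locus '%s' (must be 0/1/2)",
                 G[bad[1, 1], bad[1, 2]], bad[1, 1],
                 colnames(G)[bad[1, 2]]))
  maf <- encoding <- NULL
  if (!is.null(annotation)) {
    ann <- utils::read.table(annotation, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("locus_id", "maf", "encoding")
    if (!all(need %in% names(ann)))
      stop("annotation needs columns: ", paste(need, collapse = ", "))
    idx <- match(colnames(G), ann$locus_id)
    if (anyNA(idx)) stop("annotation is missing some genotype loci")
    maf <- ann$maf[idx]
    encoding <- ann$encoding[idx]
  }
  genotype_data(G, maf = maf, encoding = encoding)
}

#' Read a correlation stack with its sidecar header
#'
#' The stack TSV holds `p(p-1)` rows by `m` columns (header of subject
#' IDs); the JSON sidecar at `<path>.json` (or given explicitly) declares
#' `p` and `m`. Row-count mismatches are rejected with the expected
#' `p(p-1)`.
#'
#' @param path Stack TSV path.
#' @param sidecar Sidecar JSON path; default `<path>.json`.
#' @return A [correlation_stack()].
#' @export
read_correlation_stack <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$p)) stop("sidecar must declare the ROI count p")
  df <- read_delim_auto(path)
  V <- as.matrix(df)
  p <- as.integer(meta$p)
  if (nrow(V) != p * (p - 1L))
    stop(sprintf("stack has %d rows but p = %d requires p(p-1) = %d",
                 nrow(V), p, p * (p - 1L)))
  if (!is.null(meta$m) && ncol(V) != as.integer(meta$m))
    stop(sprintf("stack has %d columns but sidecar declares m = %d",
                 ncol(V), as.integer(meta$m)))
  correlation_stack(V, p = p,
                    standardized = isTRUE(meta$standardized))
}

#' Write a correlation stack and its sidecar
#'
#' @param S A [correlation_stack()].
#' @param path Output TSV path (sidecar written at `<path>.json`).
#' @export
write_correlation_stack <- function(S, path) {
  stopifnot(inherits(S, "correlation_stack"))
  V <- S$values
  colnames(V) <- colnames(V) %||% paste0("subject_", seq_len(ncol(V)))
  write_matrix_tsv(V, path)
  jsonlite::write_json(list(p = S$p, m = S$m,
                            standardized = S$standardized),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a distance matrix as TSV with instance IDs
#'
#' @param D A `distance_matrix`.
#' @param path Output path.
#' @export
write_distance_matrix <- function(D, path) {
  write_matrix_tsv(as.matrix(D), path, row_names = TRUE)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path File path.
#' @return A `distance_matrix` (metric recorded as unknown).
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- ids
  if (nrow(M) != ncol(M)) stop("distance matrix must be square")
  new_distance_matrix(M, list(family = "unknown"))
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
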