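#' Construct a validated drug-disease association matrix
#'
#' The association matrix is the pipeline's ground truth: a binary matrix
#' with diseases on the rows and drugs on the columns, entry 1 meaning the
#' drug is a known treatment/association for the disease. Row profiles are
#' disease interaction profiles, column profiles are drug interaction
#' profiles; both feed the sigmoid kernels.
#'
#' @param values Numeric matrix of 0/1 values, diseases x drugs.
#' @param disease_ids,drug_ids Character identifiers for rows / columns.
#'   Defaults to the dimnames of `values`.
#' @return A matrix of class `"assoc_matrix"` with disease/drug dimnames.
#' @export
#' @examples
#' A <- association_matrix(rbind(c(1, 0), c(0, 1)),
#'                         disease_ids = c("d1", "d2"),
#'                         drug_ids = c("r1", "r2"))
#' n_associations(A)
association_matrix <- function(values, disease_ids = rownames(values),
                               drug_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(disease_ids) || is.null(drug_ids)) {
    stop("disease and drug identifiers are required", call. = FALSE)
  }
  disease_ids <- as.character(disease_ids)
  drug_ids <- as.character(drug_ids)
  if (nrow(values) != length(disease_ids) || ncol(values) != length(drug_ids)) {
    stop("matrix shape does not match the identifier vectors", call. = FALSE)
  }
  if (anyDuplicated(disease_ids)) {
    stop("duplicate disease identifiers: ",
         paste(unique(disease_ids[duplicated(disease_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(drug_ids)) {
    stop("duplicate drug identifiers: ",
         paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(values %in% c(0, 1)) | !is.finite(values))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf(
      "association matrix must be binary; found %s at row '%s', column '%s'",
      format(values[bad[1]]), disease_ids[i], drug_ids[j]), call. = FALSE)
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(disease_ids, drug_ids)
  class(values) <- c("assoc_matrix", "matrix", "array")
  values
}

#' @rdname association_matrix
#' @param A An `assoc_matrix`.
#' @export
n_associations <- function(A) sum(unclass(A))

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d diseases x %d drugs, %d associations\n",
              nrow(x), ncol(x), n_associations(x)))
  invisible(x)
}

#' Construct a validated similarity matrix
#'
#' A square, approximately symmetric matrix over one entity set (all drugs or
#' all diseases), with unit-free values in `[0, 1]`. Asymmetries up to `tol`
#' are averaged away silently; larger ones are an error in `"strict"` mode or
#' averaged with a message in `"lenient"` mode.
#'
#' @param values Square numeric matrix.
#' @param entity_ids Character identifiers; defaults to rownames.
#' @param mode `"strict"` (default) or `"lenient"` asymmetry handling.
#' @param tol Symmetry tolerance (default `1e-9`).
#' @return A matrix of class `"sim_matrix"`.
#' @export
similarity_matrix <- function(values, entity_ids = rownames(values),
                              mode = c("strict", "lenient"), tol = 1e-9) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop(sprintf("similarity matrix must be square, got %d x %d",
                 nrow(values), ncol(values)), call. = FALSE)
  }
  if (is.null(entity_ids)) entity_ids <- colnames(values)
  if (is.null(entity_ids)) {
    stop("entity identifiers are required", call. = FALSE)
  }
  entity_ids <- as.character(entity_ids)
  if (length(entity_ids) != nrow(values) || anyDuplicated(entity_ids)) {
    stop("entity identifiers must be unique and match the matrix dimension",
         call. = FALSE)
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("similarity values must be finite numbers", call. = FALSE)
  }
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    if (mode == "strict") {
      stop(sprintf("matrix is asymmetric (max |S - t(S)| = %.3g); use mode = 'lenient' to average",
                   asym), call. = FALSE)
    }
    message(sprintf("averaging asymmetric similarity matrix (max deviation %.3g)", asym))
  }
  values <- (values + t(values)) / 2
  out_of_range <- max(0, max(values) - 1, -min(values))
  if (out_of_range > 1e-9) {
    warning(sprintf("clipping similarity values outside [0, 1] by up to %.3g",
                    out_of_range), call. = FALSE)
  }
  values <- pmin(pmax(values, 0), 1)
  dim(values) <- c(length(entity_ids), length(entity_ids))
  dimnames(values) <- list(entity_ids, entity_ids)
  class(values) <- c("sim_matrix", "matrix", "array")
  values
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("<sim_matrix> %d entities, values in [%.3f, %.3f]\n",
              nrow(x), min(x), max(x)))
  invisible(x)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a drug-disease association matrix from TSV/CSV
#'
#' Canonical layout: first row is the drug header, first column the disease
#' header, body cells 0/1. The delimiter is auto-detected unless given.
#'
#' @param path File path.
#' @param delim `NULL` (auto-detect), `"\t"` or `","`.
#' @param transpose If `TRUE` the file stores drugs on the rows and is
#'   transposed on read.
#' @return An [association_matrix()].
#' @export
read_association_matrix <- function(path, delim = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- delim %||% sniff_delim(path)
  raw <- utils::read.delim(path, sep = delim, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) , arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                   m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                   colnames(m)[bad[1, 2]], path), call. = FALSE)
    }
    storage.mode(m) <- "double"
  }
  if (transpose) m <- t(m)
  A <- association_matrix(m)
  message(sprintf("read association matrix: %d diseases, %d drugs, %d associations",
                  nrow(A), ncol(A), n_associations(A)))
  A
}

#' Write an association matrix in the canonical TSV layout
#'
#' @param A An [association_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_matrix <- function(A, path) {
  df <- data.frame(disease_id = rownames(A), unclass(A),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix from TSV/CSV
#'
#' Expects a square numeric matrix whose row and column headers agree.
#' Entries outside `[0, 1]` by more than `1e-6` trigger a warning before
#' clipping; asymmetry handling follows `mode` (see [similarity_matrix()]).
#'
#' @inheritParams read_association_matrix
#' @inheritParams similarity_matrix
#' @return A [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path, delim = NULL,
                                   mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- delim %||% sniff_delim(path)
  raw <- utils::read.delim(path, sep = delim, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    stop(sprintf("similarity matrix in %s is not square (%d x %d)",
                 path, nrow(m), ncol(m)), call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column identifiers disagree in ", path, call. = FALSE)
  }
  similarity_matrix(m, mode = mode)
}

#' @rdname read_similarity_matrix
#' @param S A `sim_matrix`.
#' @export
write_similarity_matrix <- function(S, path) {
  df <- data.frame(id = rownames(S), unclass(S),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug catalog (identifier + SMILES) table
#'
#' Two-column TSV `drug_id<TAB>smiles`; SMILES may be empty for drugs without
#' structures (their structure similarity defaults to 0 against all others).
#'
#' @param path File path.
#' @return A tibble with columns `drug_id`, `smiles` (`NA` when absent).
#' @export
read_drug_catalog <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("drug_id", "smiles")
  df$smiles[!nzchar(trimws(df$smiles))] <- NA_character_
  if (anyDuplicated(df$drug_id)) {
    stop("duplicate drug identifiers in catalog", call. = FALSE)
  }
  tibble::as_tibble(df[, c("drug_id", "smiles")])
}

#' Write ranked drug-disease predictions to TSV
#'
#' Rows are sorted by descending score with a rank column; ties are broken
#' lexicographically by drug identifier so output is stable across runs.
#'
#' @param scores A data frame with columns `drug_id`, `disease_id`, `score`.
#' @param path Output path.
#' @return The ranked tibble, invisibly.
#' @export
write_ranked_predictions <- function(scores, path) {
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("drug_id", "disease_id", "score") %in% names(scores)))
  if (nrow(scores) && any(!is.finite(scores$score))) {
    stop("scores must be finite", call. = FALSE)
  }
  if (nrow(scores) && (min(scores$score) < 0 || max(scores$score) > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  ranked <- dplyr::arrange(scores, dplyr::desc(.data$score), .data$drug_id)
  ranked <- dplyr::mutate(ranked, rank = dplyr::row_number(), .before = 1L)
  utils::write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ranked)
}
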