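#' Tanimoto similarity between binary fingerprints
#'
#' The Tanimoto (Jaccard) coefficient of two binary fingerprints is the size
#' of the intersection of their set bits over the size of the union. Rows
#' whose fingerprint has no set bits (e.g. drugs without a parseable
#' structure) get similarity 0 against everything and 0 on the diagonal is
#' replaced by 1 only when the fingerprint is non-empty.
#'
#' @param fp A binary matrix, one fingerprint per row, rownames = drug ids.
#' @return A [similarity_matrix()] over the rows.
#' @export
#' @examples
#' fp <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
#' tanimoto_similarity(fp)["a", "b"]  # 1 shared bit of 3 in the union
tanimoto_similarity <- function(fp) {
  fp <- as.matrix(fp)
  if (is.null(rownames(fp))) stop("fingerprint rows must be named", call. = FALSE)
  if (!all(fp %in% c(0, 1))) stop("fingerprints must be binary", call. = FALSE)
  storage.mode(fp) <- "double"
  inter <- tcrossprod(fp)
  sizes <- rowSums(fp)
  uni <- outer(sizes, sizes, `+`) - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  diag(S)[sizes > 0] <- 1
  similarity_matrix(S, entity_ids = rownames(fp))
}

#' Drug structure similarity from SMILES via fingerprints
#'
#' Parses SMILES with ChemmineR/ChemmineOB, derives 1024-bit atom-pair
#' fingerprints and returns the pairwise Tanimoto similarity. Drugs whose
#' SMILES is missing or unparseable keep an all-zero fingerprint: their
#' structure similarity is 0 against every other drug (with a warning), and
#' the fusion step can still fall back on kernel similarity for them.
#'
#' @param catalog A data frame with columns `drug_id` and `smiles`
#'   (see [read_drug_catalog()]).
#' @return A [similarity_matrix()] over all drugs in the catalog.
#' @export
tanimoto_structure_similarity <- function(catalog) {
  n_bits <- 1024L  # ChemmineR's standard atom-pair fingerprint length
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("tanimoto_structure_similarity() needs the ChemmineR and ChemmineOB packages",
         call. = FALSE)
  }
  catalog <- tibble::as_tibble(catalog)
  stopifnot(all(c("drug_id", "smiles") %in% names(catalog)), nrow(catalog) > 0)
  ids <- as.character(catalog$drug_id)
  fp <- matrix(0, nrow(catalog), n_bits, dimnames = list(ids, NULL))
  usable <- which(!is.na(catalog$smiles))
  failed <- character()
  for (i in usable) {
    bits <- tryCatch(smiles_fingerprint(catalog$smiles[[i]]),
                     error = function(e) NULL)
    if (is.null(bits) || length(bits) != n_bits) {
      failed <- c(failed, ids[i])
    } else {
      fp[i, ] <- bits
    }
  }
  missing <- union(ids[is.na(catalog$smiles)], failed)
  if (length(missing)) {
    warning("no usable structure for ", length(missing), " drug(s) (",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "",
            "); their structure similarity defaults to 0", call. = FALSE)
  }
  tanimoto_similarity(fp)
}

smiles_fingerprint <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ChemmineR::cid(sdf) <- "query"
  ap <- suppressWarnings(ChemmineR::sdf2ap(sdf))
  # the reference atom-pair vocabulary ships as a lazy dataset
  env <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = env)
  fpset <- ChemmineR::desc2fp(ap, descnames = as.character(env$apfp$AP)[seq_len(1024)])
  as.numeric(ChemmineR::as.matrix(fpset)[1, ])
}
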