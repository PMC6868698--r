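#' Assemble the per-pair similarity descriptor grid
#'
#' A drug-disease pair is described by the concatenation of the drug's fused
#' drug-similarity row and the disease's fused disease-similarity row. The
#' concatenated vector (length = number of drugs + number of diseases) is
#' zero-padded to the next perfect square and reshaped row-major into an
#' `s x s` grid, the input of the convolutional encoder. With 593 drugs and
#' 313 diseases this gives a 31 x 31 grid with 55 padding cells.
#'
#' @param drug_sim Fused drug [similarity_matrix()].
#' @param disease_sim Fused disease [similarity_matrix()].
#' @param drug_id,disease_id Identifiers of the pair.
#' @return A list of class `"pair_descriptor"` with fields `drug_row`,
#'   `disease_row`, `grid` (square matrix), `drug_id`, `disease_id`.
#' @export
build_pair_descriptor <- function(drug_sim, disease_sim, drug_id, disease_id) {
  if (!drug_id %in% rownames(drug_sim)) {
    stop("unknown drug identifier: ", drug_id, call. = FALSE)
  }
  if (!disease_id %in% rownames(disease_sim)) {
    stop("unknown disease identifier: ", disease_id, call. = FALSE)
  }
  drug_row <- unclass(drug_sim)[drug_id, ]
  disease_row <- unclass(disease_sim)[disease_id, ]
  structure(list(drug_row = drug_row, disease_row = disease_row,
                 grid = descriptor_grid(drug_row, disease_row),
                 drug_id = drug_id, disease_id = disease_id),
            class = "pair_descriptor")
}

#' @rdname build_pair_descriptor
#' @param drug_row,disease_row Numeric similarity rows to lay out.
#' @export
descriptor_grid <- function(drug_row, disease_row) {
  v <- c(drug_row, disease_row)
  side <- ceiling(sqrt(length(v)))
  padded <- c(v, rep(0, side^2 - length(v)))
  matrix(padded, nrow = side, byrow = TRUE)  # row-major fill
}

#' Build descriptors for a table of drug-disease pairs
#'
#' Vectorised convenience over [build_pair_descriptor()]: one descriptor per
#' row of `pairs`.
#'
#' @inheritParams build_pair_descriptor
#' @param pairs Data frame with columns `drug_id`, `disease_id`.
#' @return A list of `pair_descriptor` objects.
#' @export
build_pair_descriptors <- function(drug_sim, disease_sim, pairs) {
  purrr::map2(pairs$drug_id, pairs$disease_id,
              function(r, e) build_pair_descriptor(drug_sim, disease_sim, r, e))
}
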