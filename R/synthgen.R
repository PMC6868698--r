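#' Synthetic benchmark configuration
#'
#' Parameters of the planted-block generator. Drugs and diseases are
#' partitioned into `n_blocks` matched co-blocks (equal sizes, remainders
#' dealt round-robin); a drug-disease pair inside a matched block is
#' associated with probability `within_block_rate`, any other pair with
#' `background_rate`. Side similarities encode block identity with strength
#' `similarity_signal` plus Gaussian noise. The defaults (60 drugs, 40
#' diseases, 4 blocks, 0.4 vs 0.02, signal 0.6, noise 0.1) give a compact
#' instance that is clearly learnable but far from trivial, with enough
#' background zeros that some entities have empty interaction profiles and
#' exercise the fusion fallback.
#'
#' @param n_drugs,n_diseases Entity counts (defaults 60, 40).
#' @param n_blocks Number of planted co-blocks (default 4).
#' @param within_block_rate,background_rate Association probabilities
#'   (defaults 0.4, 0.02).
#' @param similarity_signal Same-block bump on side similarities, in
#'   `[0, 1]` (default 0.6).
#' @param noise_sd Gaussian noise on side similarities (default 0.1).
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_drugs = 60L, n_diseases = 40L, n_blocks = 4L,
                         within_block_rate = 0.4, background_rate = 0.02,
                         similarity_signal = 0.6, noise_sd = 0.1) {
  rates <- c(within_block_rate, background_rate, similarity_signal)
  if (any(rates < 0) || any(rates > 1) || noise_sd < 0) {
    stop("rates and signal must lie in [0, 1] and noise_sd must be >= 0",
         call. = FALSE)
  }
  if (within_block_rate < background_rate) {
    warning("within_block_rate below background_rate: the instance carries no learnable signal",
            call. = FALSE)
  }
  structure(list(n_drugs = as.integer(n_drugs),
                 n_diseases = as.integer(n_diseases),
                 n_blocks = as.integer(n_blocks),
                 within_block_rate = within_block_rate,
                 background_rate = background_rate,
                 similarity_signal = similarity_signal,
                 noise_sd = noise_sd),
            class = "synth_config")
}

#' Generate a synthetic drug-repositioning benchmark
#'
#' Produces an association matrix with planted block structure plus
#' consistent drug and disease side similarities (same-block indicator times
#' `similarity_signal`, Gaussian noise added, clipped to `[0, 1]`,
#' symmetrised, unit diagonal) and the ground-truth block labels. Fully
#' reproducible per seed.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return A list with `association` ([association_matrix()]),
#'   `drug_similarity` and `disease_similarity` ([similarity_matrix()]),
#'   and tibbles `drug_blocks`, `disease_blocks`.
#' @export
generate_synthetic <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(seed, "synthgen"))
  drug_ids <- sprintf("drug_%03d", seq_len(config$n_drugs))
  disease_ids <- sprintf("disease_%03d", seq_len(config$n_diseases))
  drug_block <- rep_len(seq_len(config$n_blocks), config$n_drugs)
  disease_block <- rep_len(seq_len(config$n_blocks), config$n_diseases)

  same_block <- outer(disease_block, drug_block, `==`)
  p <- ifelse(same_block, config$within_block_rate, config$background_rate)
  A <- matrix(as.numeric(runif(length(p)) < p), nrow(p), ncol(p),
              dimnames = list(disease_ids, drug_ids))

  side_sim <- function(block, ids) {
    S <- config$similarity_signal * outer(block, block, `==`) +
      matrix(rnorm(length(block)^2, sd = config$noise_sd),
             length(block), length(block))
    S <- (S + t(S)) / 2
    S <- pmin(pmax(S, 0), 1)
    diag(S) <- 1
    similarity_matrix(S, entity_ids = ids)
  }

  list(association = association_matrix(A),
       drug_similarity = side_sim(drug_block, drug_ids),
       disease_similarity = side_sim(disease_block, disease_ids),
       drug_blocks = tibble::tibble(drug_id = drug_ids, block = drug_block),
       disease_blocks = tibble::tibble(disease_id = disease_ids,
                                       block = disease_block))
}

#' Write a synthetic benchmark to a directory in the canonical layout
#'
#' @param synth A [generate_synthetic()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_association_matrix(synth$association, file.path(dir, "association.tsv"))
  write_similarity_matrix(synth$drug_similarity, file.path(dir, "drug_similarity.tsv"))
  write_similarity_matrix(synth$disease_similarity, file.path(dir, "disease_similarity.tsv"))
  utils::write.table(synth$drug_blocks, file.path(dir, "drug_blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(synth$disease_blocks, file.path(dir, "disease_blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
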