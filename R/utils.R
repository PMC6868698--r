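#' Derive a stage seed from a global seed
#'
#' A single run-level seed fans out deterministically to per-stage seeds, so
#' any stage (negative sampling, fold assignment, encoder initialisation,
#' classifier fitting) can be re-run in isolation and still reproduce the
#' full pipeline bit for bit.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label, e.g. `"negatives"` or `"encoder"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "encoder")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # small multiplicative string hash, kept in double precision below 2^31
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 31 + h) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite scalar number", name), call. = FALSE)
  }
  invisible(x)
}
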