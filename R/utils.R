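#' @keywords internal
"_PACKAGE"

# Info-level logging, silent unless options(vesselquant.verbose = TRUE).
vq_log <- function(fmt, ...) {
  if (isTRUE(getOption("vesselquant.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
}

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Deterministic 31-bit polynomial hash of `key` folded into `seed`. Used to
#' give each image (and each pairwise test cell) its own RNG seed, so that
#' adding samples or reordering a batch never perturbs existing results.
#'
#' @param seed Integer master seed.
#' @param key Character scalar (e.g. a sample id).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  mod <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% mod
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% mod
  }
  as.integer(h)
}

# Short stable hex digest of a configuration list, for provenance columns.
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- derive_seed(0L, txt)
  sprintf("%08x", h)
}
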