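#' Derive a reproducible child seed from a master seed and a label
#'
#' One master seed deterministically spawns per-stage substreams so pipeline
#' stages can be rerun independently with identical results.
#'
#' @param master integer master seed.
#' @param label character stage/condition label.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  hash <- (abs(master) %% 1000003) * 2038074743 %% 2147483647
  for (ch in utf8ToInt(paste(label, collapse = "/"))) {
    hash <- (hash * 31 + ch) %% 2147483647
  }
  as.integer(hash %% 2147483645) + 1L
}

# Small-sample corrected AIC from a least-squares fit.
# k counts all estimated quantities including the residual variance.
aicc_ls <- function(rss, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# polynomial rolling hash of a config object, for run manifests
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 12)), collapse = "\n")
  hash <- 2166136261
  for (ch in utf8ToInt(s)) hash <- (hash * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(hash %% 2147483646))
}

clip0 <- function(x) pmax(x, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a
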