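# Internal helpers: typed conditions and seeded RNG sub-streams.

pd_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "preydna_error"), call = call))
}

pd_validation_error <- function(msg) pd_stop(msg, "preydna_validation_error")
pd_parse_error <- function(msg) pd_stop(msg, "preydna_parse_error")
pd_config_error <- function(msg) pd_stop(msg, "preydna_config_error")

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions never
#' disturb the caller's random-number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic sub-stream seeds derived from one master seed.  All values
# stay below 2^31 so they are valid R integer seeds.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Polynomial rolling hash of a character vector; used for run manifests.
# Exact in double precision because the modulus keeps h*31 + b < 2^53.
content_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
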