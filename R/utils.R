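# Shared helpers: classed error conditions, local RNG scoping, seed fan-out.

.phnStop <- function(type, msg, call. = FALSE) {
  cls <- switch(type,
    config = "phn_config_error",
    data = "phn_data_error",
    format = "phn_format_error",
    protocol = "phn_protocol_error",
    contract = "phn_contract_error",
    "phn_error")
  stop(structure(class = c(cls, "phn_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards,
# so generators are pure functions of (config, seed).
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed is fanned out deterministically to the pipeline stages
#' (simulate, embed, train, evaluate) so that each stage is independently
#' reproducible. The result is always a positive 32-bit integer.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
#' @examples
#' stageSeed(42, "train")
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483587 + 1)
}

.isCount <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == floor(x)

.assertCount <- function(x, name) {
  if (!.isCount(x)) .phnStop("config", sprintf("'%s' must be a positive integer", name))
  invisible(TRUE)
}
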