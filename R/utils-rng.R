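# Per-operation RNG streams: each generator draws from its own stream,
# seeded by (global seed, operation name), so adding one generator to a
# workflow never perturbs another's output.

.opSeed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.withOpSeed <- function(seed, op, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.opSeed(seed, op))
  expr
}

.stopf <- function(fmt, ..., class = "taxconsensusError") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
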