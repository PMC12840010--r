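# evaluate `code` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# derive a stream-specific 31-bit child seed from a master seed
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# column lookup that tolerates absent columns in tibbles
col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}
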