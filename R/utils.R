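# Internal helpers shared across modules.

# Evaluate `code` under a seeded RNG. With seed = NULL the caller's RNG stream
# is used (and advanced); with a seed the global RNG state is restored
# afterwards, so seeded calls do not perturb the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("`seed` must be a single finite number or NULL.")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L) # force RNG initialisation so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_invalid <- function(msg) abort(msg, class = "socnet_invalid_config")

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != trunc(x)) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_invalid(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  as.numeric(x)
}
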