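# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's random stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Locale-independent lexicographic sort for identifiers (radix = C collation).
sort_ids <- function(x) sort(unique(as.character(x)), method = "radix")

order_ids <- function(x) order(x, method = "radix")

# Format a numeric for TSV output: stable, locale-free, round-trippable.
fmt_num <- function(x) trimws(formatC(x, format = "g", digits = 15))

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}
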