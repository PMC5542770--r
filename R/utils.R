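# Internal helpers: error conditions, seeded evaluation, constants.

# The 20 canonical amino acids in alphabetical one-letter order.  This fixed
# ordering also drives deterministic signature-residue assignment in the
# synthetic generators.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Encoding alphabet: 20 amino acids, ambiguity placeholder, gap.
AA_ALPHABET_ENC <- c(AA20, "X", "-")

pda_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pda_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_schema  <- function(msg) pda_stop(msg, "pda_schema_error")
stop_format  <- function(msg) pda_stop(msg, "pda_format_error")
stop_input   <- function(msg) pda_stop(msg, "pda_input_error")
stop_lookup  <- function(msg) pda_stop(msg, "pda_lookup_error")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_input("seed must be a single non-missing number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
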