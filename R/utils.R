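# internal helpers

# round half away from zero (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

# evaluate code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# stable polynomial hash of a character string, as 8 hex digits; trailing
# newlines are normalised away (YAML round trips may alter them)
text_hash <- function(txt) {
  txt <- sub("[\r\n]+$", "", paste(txt, collapse = "\n"))
  bytes <- as.integer(charToRaw(txt))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
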