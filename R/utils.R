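# Internal helpers: classed error conditions, seeded RNG streams, formatting.

sc_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "spikechip_error")))
}

#' @noRd
sc_check <- function(ok, class, msg) {
  if (!isTRUE(ok)) sc_error(class, msg)
  invisible(TRUE)
}

# Deterministic 31-bit stream seed from a master seed and character labels.
# Small multiplicative fold so that (seed, "a") and (seed, "b") give
# unrelated streams while staying inside R's integer range.
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(labels)) h <- (h * 131 + c) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# 6-significant-digit decimal formatting used by all text writers; chosen so
# that read(write(x)) reproduces signif(x, 6) exactly.
fmt_sig <- function(x) sprintf("%.6g", x)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

hamming <- function(a, b) {
  sc_check(nchar(a) == nchar(b), "sc_config_error",
           "hamming distance requires equal-length strings")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x)
}
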