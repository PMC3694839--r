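# Internal helpers shared across modules.

# reverse-complement for plain character vectors
rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse a vector of strings character-wise (for quality strings)
str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

# C->T ("plus") and G->A ("minus") in-silico bisulfite conversion
conv_ct <- function(x) chartr("C", "T", x)
conv_ga <- function(x) chartr("G", "A", x)

# Phred string <-> integer scores (offset 33); each quality char is one byte
phred_to_int <- function(qchars) {
  as.integer(charToRaw(paste0(qchars, collapse = ""))) - 33L
}
int_to_phred <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1), USE.NAMES = FALSE)
}

# mismatch counts between two equal-width character vectors of strings,
# fully vectorised through raw matrices; chunked to bound memory
hamming_pairs <- function(a, b, width, chunk = 200000L) {
  n <- length(a)
  if (n == 0L) return(integer(0))
  out <- integer(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    am <- matrix(charToRaw(paste0(a[lo:hi], collapse = "")), nrow = width)
    bm <- matrix(charToRaw(paste0(b[lo:hi], collapse = "")), nrow = width)
    out[lo:hi] <- as.integer(colSums(am != bm))
  }
  out
}

# run code with a private, seeded RNG stream; global .Random.seed untouched
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
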