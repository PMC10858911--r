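# Internal helpers for 0/1 flash-sequence strings.
#
# Sequences are stored in tibbles as character strings over {0,1}; these
# helpers convert to integer vectors and back, and compute run-length
# encodings used throughout for flash/gap statistics.

bits_to_vec <- function(bits) {
  as.integer(strsplit(bits, "", fixed = TRUE)[[1]])
}

bits_to_vecs <- function(bits) {
  lapply(strsplit(bits, "", fixed = TRUE), as.integer)
}

vec_to_bits <- function(x) {
  paste(as.integer(x), collapse = "")
}

assert_bits <- function(bits, arg = "bits") {
  bad <- !grepl("^[01]+$", bits)
  if (any(bad)) {
    abort(sprintf(
      "`%s` must be non-empty strings over {0,1}; offending entry %d: %s",
      arg, which(bad)[1], encodeString(bits[which(bad)[1]], quote = "\"")
    ))
  }
  invisible(bits)
}

# Runs of a binary vector: tibble(value, length), in order.
bit_runs <- function(v) {
  r <- rle(v)
  list(values = r$values, lengths = r$lengths)
}

# Number of flashes (maximal runs of 1s) per bit string; vectorized.
count_flash_runs <- function(bits) {
  vapply(bits_to_vecs(bits), function(v) {
    r <- rle(v)
    sum(r$values == 1L)
  }, integer(1))
}

# Trim leading/trailing zeros so a sequence spans first to last flash.
trim_to_flashes <- function(v) {
  on <- which(v == 1L)
  if (length(on) == 0L) return(integer(0))
  v[on[1]:on[length(on)]]
}

# Round half away from zero (deterministic across platforms, unlike round()).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
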