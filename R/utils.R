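# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes accepted on FASTA input; only ACGTN survive into
# one-hot encoding, the rest are rejected at encode time.
IUPAC_DNA <- c(DNA_BASES, "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

clip01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

# All randomness in the package flows through seeds; with_seed keeps the
# caller's RNG state untouched.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic child seed; kept < 2^31 so it stays a valid R integer.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009L + k) %% 2147483647)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == as.integer(x)
}

stop_pe <- function(...) abort(paste0(...), class = "patternEffect_error")

check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1 || is.na(x)) {
    stop_pe(what, " must be a single string")
  }
  x
}

# Split "a:b" or "a-b" into an integer range (CLI --spacings).
parse_range <- function(x) {
  parts <- strsplit(x, "[:\\-]")[[1]]
  if (length(parts) != 2) stop_pe("expected a range like 0:10, got '", x, "'")
  seq.int(as.integer(parts[1]), as.integer(parts[2]))
}

reverse_complement <- function(seqs) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `*` = "*")
  vapply(seqs, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    out <- comp[ch]
    if (anyNA(out)) stop_pe("cannot reverse-complement '", s, "'")
    paste0(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
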