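# Internal sequence helpers. All coordinates in this package are 0-based,
# half-open; writers convert to the 1-based conventions of VCF etc.

DNA_BASES <- c("A", "C", "G", "T")

# substring of a sequence string, 0-based half-open
seq_sub <- function(x, start, end) {
  substr(x, start + 1L, end)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# replace single bases at 0-based positions
replace_bases <- function(seq, pos, bases) {
  if (length(pos) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos + 1L] <- bases
  paste(chars, collapse = "")
}

# uniform substitution errors at per-base rate; never substitutes to the
# same base
apply_seq_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < error_rate)
    for (i in hit) {
      chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# 0-based positions of all occurrences of dinucleotide "CG"
cpg_positions <- function(seq) {
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

# overlap of 0-based half-open intervals with an anchor-style interval
overlaps_interval <- function(start, end, int_start, int_end) {
  start < int_end & end > int_start
}

stopifnot_scalar_int <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("hamming(): sequences differ in length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
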