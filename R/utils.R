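# Small shared helpers: sequence coercion, RNG substreams, rounding.

DNA_BASES <- c("A", "C", "G", "T")

# Fixed per-stage offsets added to the global seed so each simulation stage
# draws from its own reproducible substream.
SEED_OFFSETS <- c(
  consensus = 101L, history = 202L, diverge = 303L, background = 404L,
  plant = 505L, traces = 606L, genotypes = 707L, genes = 808L
)

.stage_seed <- function(seed, stage) {
  offset <- SEED_OFFSETS[[stage]]
  (as.integer(seed) + offset) %% .Machine$integer.max
}

# Coerce character / DNAString / DNAStringSet to a named character vector.
.as_seq_chr <- function(x) {
  if (is.character(x)) return(x)
  if (inherits(x, "DNAString")) return(as.character(x))
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as DNA sequence(s)")
}

.as_dss <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(.as_seq_chr(x))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Longest common prefix / suffix length of two strings, optionally capped.
.lcp_len <- function(a, b, cap = Inf) {
  n <- min(nchar(a), nchar(b), cap)
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0) as.integer(n) else neq[1] - 1L
}

.lcs_len <- function(a, b, cap = Inf) {
  n <- min(nchar(a), nchar(b), cap)
  if (n == 0) return(0L)
  av <- rev(strsplit(substr(a, nchar(a) - n + 1, nchar(a)), "")[[1]])
  bv <- rev(strsplit(substr(b, nchar(b) - n + 1, nchar(b)), "")[[1]])
  neq <- which(av != bv)
  if (length(neq) == 0) as.integer(n) else neq[1] - 1L
}

.assert_genotype <- function(g) {
  ok <- g %in% c("+/+", "+/-", "-/-", NA_character_, "missing")
  if (!all(ok)) stop("invalid genotype code(s): ",
                     paste(unique(g[!ok]), collapse = ", "))
  invisible(g)
}
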