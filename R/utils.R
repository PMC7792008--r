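# IUPAC ambiguity codes as base bitmasks (A=1, C=2, G=4, T=8)
IUPAC_SYMBOLS <- c(
  "A", "C", "M", "G", "R", "S", "V", "T", "W", "Y", "H", "K", "D", "B", "N"
)

#' Convert a base bitmask to its IUPAC symbol
#'
#' Masks use bits A=1, C=2, G=4, T=8; e.g. mask 5 (A|G) is `R`.
#'
#' @param mask integer vector of base bitmasks in 1..15
#' @return character vector of IUPAC one-letter codes
#' @export
iupac_symbol <- function(mask) {
  stopifnot(all(mask >= 1 & mask <= 15))
  IUPAC_SYMBOLS[mask]
}

#' Convert an IUPAC symbol to its base bitmask
#' @param symbol character vector of IUPAC one-letter codes
#' @return integer vector of base bitmasks
#' @export
iupac_mask <- function(symbol) {
  m <- match(symbol, IUPAC_SYMBOLS)
  if (anyNA(m)) stop("unknown IUPAC symbol: ", paste(symbol[is.na(m)], collapse = ", "))
  as.integer(m)
}

# complement of a base bitmask (A<->T, C<->G)
iupac_complement_mask <- function(mask) {
  r <- integer(length(mask))
  r <- r + ifelse(bitwAnd(mask, 1L) > 0, 8L, 0L)
  r <- r + ifelse(bitwAnd(mask, 8L) > 0, 1L, 0L)
  r <- r + ifelse(bitwAnd(mask, 2L) > 0, 4L, 0L)
  r <- r + ifelse(bitwAnd(mask, 4L) > 0, 2L, 0L)
  r
}

# does base (single character) belong to the mask's base set?
base_in_mask <- function(base, mask) {
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)[base]
  !is.na(bit) & bitwAnd(as.integer(bit), as.integer(mask)) > 0L
}

#' Reverse complement of DNA strings
#'
#' Sequences over A, C, G, T, N; any other symbol becomes N.
#'
#' @param seq character vector of DNA strings
#' @return character vector
#' @export
revcomp <- function(seq) {
  cpp_revcomp(as.character(seq))
}

#' Canonical form of k-mers
#'
#' Returns the lexicographically smaller of each sequence and its reverse
#' complement. Idempotent. Sequences must be over A/C/G/T.
#'
#' @param seq character vector of DNA strings over A, C, G, T
#' @return character vector of canonical sequences
#' @export
canonicalize <- function(seq) {
  if (any(grepl("[^ACGT]", seq))) {
    stop("canonicalize() requires sequences over {A,C,G,T}; split reads at other symbols first")
  }
  rc <- revcomp(seq)
  ifelse(seq <= rc, seq, rc)
}

# split sequences at non-ACGT symbols into clean runs
split_at_ambiguous <- function(seqs) {
  unlist(strsplit(seqs, "[^ACGT]+"), use.names = FALSE)
}

# run code with a private, seed-determined RNG stream, restoring global state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# random DNA of given length under the current RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
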