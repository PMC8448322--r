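#' @keywords internal
"_PACKAGE"

# Base alphabet used throughout: rows of every one-hot / PWM matrix.
BASES <- c("A", "C", "G", "T")

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Plain-character helper for sequences over A, C, G, T, N.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse-complemented strings.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Reverse complement of a character vector of single bases.
revcomp_chars <- function(x) {
  rev(strsplit(chartr("ACGTN", "TGCAN", paste(x, collapse = "")),
               "", fixed = TRUE)[[1]])
}

# Instantiate an IUPAC consensus: each degenerate symbol drawn uniformly
# over its allowed bases (uses the current RNG stream).
instantiate_iupac <- function(consensus) {
  syms <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  vapply(syms, function(s) {
    allowed <- IUPAC[[s]]
    if (is.null(allowed)) stop("unknown IUPAC symbol: ", s)
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1), USE.NAMES = FALSE)
}

# Integer codes for a sequence string: A=1, C=2, G=3, T=4, N/other=5.
seq_codes <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  codes <- match(chars, BASES)
  codes[is.na(codes)] <- 5L
  codes
}

codes_to_seq <- function(codes) {
  paste(c(BASES, "N")[codes], collapse = "")
}

# Derive a child seed from a base seed and a stage tag; kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
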