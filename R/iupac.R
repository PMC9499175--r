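#' IUPAC nucleotide alphabet
#'
#' The 15 IUPAC nucleotide symbols plus the gap character `"-"`. Ambiguity
#' symbols arise here as heteroplasmic consensus calls: a `Y` means the
#' sample's reads support both `C` and `T` at that site.
#'
#' @format Character vector of length 16.
#' @export
IUPAC_SYMBOLS <- c("A", "C", "G", "T",
                   "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-")

# symbol -> set of unambiguous bases it denotes (gap maps to empty set)
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  `-` = character(0)
)

#' Set of unambiguous bases denoted by an IUPAC symbol
#'
#' @param symbol Single character in [IUPAC_SYMBOLS].
#' @return Character vector of unambiguous bases (empty for the gap).
#' @examples
#' iupac_base_set("Y")  # "C" "T"
#' @export
iupac_base_set <- function(symbol) {
  if (!is.character(symbol) || length(symbol) != 1L || is.na(symbol))
    stop("symbol must be a single character", call. = FALSE)
  s <- .IUPAC_SETS[[toupper(symbol)]]
  if (is.null(s)) stop("not an IUPAC symbol: '", symbol, "'", call. = FALSE)
  s
}

# complement is a per-character substitution; W/S/N/- are self-complementary
.IUPAC_FROM <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn-"
.IUPAC_TO   <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn-"

#' Reverse-complement an IUPAC string or character vector
#'
#' Ambiguity symbols are complemented set-wise (R<->Y, K<->M, B<->V, D<->H);
#' gaps are preserved. The operation is an involution.
#'
#' @param x A character string, or a character vector of single bases.
#' @return Object of the same shape, reverse complemented.
#' @export
revcomp <- function(x) {
  if (length(x) == 1L && nchar(x) != 1L) {
    comp <- chartr(.IUPAC_FROM, .IUPAC_TO, x)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  } else {
    rev(chartr(.IUPAC_FROM, .IUPAC_TO, x))
  }
}

#' Complement (without reversal) of IUPAC characters
#' @param x Character vector of single symbols or a string.
#' @return Complemented object of the same shape.
#' @export
iupac_complement <- function(x) chartr(.IUPAC_FROM, .IUPAC_TO, x)

.is_ambiguity <- function(ch) !(ch %in% c("A", "C", "G", "T", "-"))

#' Does a sequence contain any ambiguity (heteroplasmy) symbol?
#' @param x Character vector of single symbols or a single string.
#' @return Logical scalar.
#' @export
has_ambiguity <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1L]]
  any(.is_ambiguity(x))
}

# Precomputed lookups over the 16-symbol alphabet, indexed by
# match(symbol, IUPAC_SYMBOLS).  Gap entries are NA: callers must apply
# their own gap policy before scoring.
.build_identity_matrix <- function() {
  n <- length(IUPAC_SYMBOLS)
  m <- matrix(NA_real_, n, n, dimnames = list(IUPAC_SYMBOLS, IUPAC_SYMBOLS))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- .IUPAC_SETS[[IUPAC_SYMBOLS[i]]]
    b <- .IUPAC_SETS[[IUPAC_SYMBOLS[j]]]
    if (length(a) && length(b))
      m[i, j] <- length(intersect(a, b)) / (length(a) * length(b))
  }
  m
}

.build_conservative_matrix <- function() {
  n <- length(IUPAC_SYMBOLS)
  m <- matrix(NA_real_, n, n, dimnames = list(IUPAC_SYMBOLS, IUPAC_SYMBOLS))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- .IUPAC_SETS[[IUPAC_SYMBOLS[i]]]
    b <- .IUPAC_SETS[[IUPAC_SYMBOLS[j]]]
    if (length(a) && length(b))
      m[i, j] <- as.numeric(length(intersect(a, b)) == 0L)
  }
  m
}

.IDENTITY_MATRIX <- .build_identity_matrix()
.CONSERVATIVE_MATRIX <- .build_conservative_matrix()

.code_chars <- function(ch) {
  i <- match(toupper(ch), IUPAC_SYMBOLS)
  if (anyNA(i)) {
    bad <- unique(ch[is.na(i)])
    stop("illegal symbol(s) outside the IUPAC alphabet: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  i
}
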