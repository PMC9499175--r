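#' Vertebrate mitochondrial genetic code (NCBI translation table 2)
#'
#' Named character vector mapping the 64 codons to single-letter amino
#' acids, with `"*"` for stop. Differs from the standard code in that
#' AGA/AGG are stops, TGA is Trp, and ATA is Met.
#'
#' @return Named character vector of length 64.
#' @export
mito_code <- function() {
  if (is.null(.pkg_cache$code)) {
    code <- tryCatch(
      as.character(Biostrings::getGeneticCode("2")),
      error = function(e) NULL)
    if (is.null(code) || length(code) != 64L) {
      # fall back to the table spelled out (identical content)
      code <- .mito_code_literal()
    } else {
      names(code) <- names(Biostrings::getGeneticCode("2"))
      names(code) <- chartr("U", "T", names(code))
    }
    stopifnot(code[["AGA"]] == "*", code[["AGG"]] == "*",
              code[["TGA"]] == "W", code[["ATA"]] == "M")
    .pkg_cache$code <- code
  }
  .pkg_cache$code
}

.pkg_cache <- new.env(parent = emptyenv())

.mito_code_literal <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), 4L),
                   rep(bases, 16L))
  # NCBI table 2 amino-acid string in TCAG codon order
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CCWW",
    "LLLLPPPPHHQQRRRR",
    "IIMMTTTTNNKKSS**",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  stats::setNames(aa, codons)
}

#' Translate a coding-strand nucleotide sequence under the vertebrate
#' mitochondrial code
#'
#' Trailing bases of an incomplete terminal codon (length not divisible by
#' three, completed in vivo by polyadenylation) are ignored.
#'
#' @param seq Character string or vector of single bases (unambiguous).
#' @return Character string of amino acids, `"*"` marking stops.
#' @export
translate_mito <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1L]]
  seq <- toupper(seq)
  if (!all(seq %in% c("A", "C", "G", "T")))
    stop("translate_mito requires unambiguous, ungapped sequence",
         call. = FALSE)
  n_codon <- length(seq) %/% 3L
  if (n_codon == 0L) return("")
  idx <- seq_len(3L * n_codon)
  codons <- paste0(seq[idx[c(TRUE, FALSE, FALSE)]],
                   seq[idx[c(FALSE, TRUE, FALSE)]],
                   seq[idx[c(FALSE, FALSE, TRUE)]])
  paste(mito_code()[codons], collapse = "")
}

#' Classify codon differences as synonymous or nonsynonymous
#'
#' Compares two unambiguous codons under the vertebrate mitochondrial code.
#' When the codons differ at several positions, each differing position is
#' classified independently by substituting the alternate base into the
#' reference codon at that position only (reference-context counting, as in
#' per-site fixed/polymorphic tallies); mutational-path enumeration is
#' deliberately not attempted.
#'
#' @param codon_ref,codon_alt Three-letter strings over A/C/G/T.
#' @return Character vector, one entry per differing position (named by
#'   codon position 1-3), each `"synonymous"` or `"nonsynonymous"`.
#' @examples
#' classify_site("ATA", "ATG")  # synonymous: both Met
#' classify_site("ATA", "GTA")  # nonsynonymous: Met -> Val
#' @export
classify_site <- function(codon_ref, codon_alt) {
  code <- mito_code()
  ref <- toupper(codon_ref); alt <- toupper(codon_alt)
  if (nchar(ref) != 3L || nchar(alt) != 3L)
    stop("codons must be length-3 strings", call. = FALSE)
  r <- strsplit(ref, "", fixed = TRUE)[[1L]]
  a <- strsplit(alt, "", fixed = TRUE)[[1L]]
  if (!all(c(r, a) %in% c("A", "C", "G", "T")))
    stop("ambiguous or gapped codon: mask ambiguous sites before ",
         "synonymous/nonsynonymous classification", call. = FALSE)
  diff_pos <- which(r != a)
  if (length(diff_pos) == 0L)
    stop("codons are identical; nothing to classify", call. = FALSE)
  out <- character(length(diff_pos))
  for (k in seq_along(diff_pos)) {
    p <- diff_pos[k]
    sub <- r; sub[p] <- a[p]
    out[k] <- if (code[[paste(sub, collapse = "")]] == code[[ref]])
      "synonymous" else "nonsynonymous"
  }
  names(out) <- diff_pos
  out
}

# classification of a single-base change given a reference codon context;
# returns "synonymous"/"nonsynonymous", used by the simulator and popgen
.classify_base_change <- function(codon_ref, pos_in_codon, alt_base) {
  code <- mito_code()
  r <- strsplit(toupper(codon_ref), "", fixed = TRUE)[[1L]]
  s <- r; s[pos_in_codon] <- toupper(alt_base)
  if (code[[paste(s, collapse = "")]] == code[[paste(r, collapse = "")]])
    "synonymous" else "nonsynonymous"
}
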