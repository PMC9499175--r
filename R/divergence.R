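#' Ambiguity-aware per-site identity score
#'
#' Scores two IUPAC symbols as the expected match probability of their
#' base sets, `|S_a intersect S_b| / (|S_a| * |S_b|)`. A heteroplasmic
#' consensus call therefore retains partial identity with either of its
#' alleles: `(Y, C) = 0.5 > (Y, G) = 0`, and `(N, A) = 0.25`.
#'
#' @param a,b Single IUPAC symbols (no gaps; callers exclude gap columns
#'   under their own policy).
#' @return Score in `[0, 1]`.
#' @export
site_identity <- function(a, b) {
  i <- .code_chars(a); j <- .code_chars(b)
  v <- .IDENTITY_MATRIX[cbind(i, j)]
  if (anyNA(v))
    stop("gap passed to site_identity; exclude gap columns first",
         call. = FALSE)
  v
}

.as_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "", fixed = TRUE)[[1L]]
  else x
}

#' Pairwise percent identity over selected columns
#'
#' Mean [site_identity] over the included columns, times 100. Columns
#' where either sequence has a gap are excluded from both numerator and
#' denominator.
#'
#' @param seq_a,seq_b Equal-length strings or character vectors.
#' @param columns Integer vector of columns to compare (1-based);
#'   `NULL` means all.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("ACGC", "ACGY")  # 87.5
#' @export
pairwise_identity <- function(seq_a, seq_b, columns = NULL) {
  a <- .as_chars(seq_a); b <- .as_chars(seq_b)
  if (length(a) != length(b))
    stop("alignment error: sequences of unequal length", call. = FALSE)
  if (!is.null(columns)) { a <- a[columns]; b <- b[columns] }
  i <- .code_chars(a); j <- .code_chars(b)
  v <- .IDENTITY_MATRIX[cbind(i, j)]     # NA at gap columns
  v <- v[!is.na(v)]
  if (!length(v))
    stop("undefined identity: no gap-free columns to compare",
         call. = FALSE)
  100 * mean(v)
}

# per-column identity score vector for one pair of coded rows (NA = gap)
.pair_scores <- function(ci, cj) .IDENTITY_MATRIX[cbind(ci, cj)]

.coded_matrix <- function(aln) {
  m <- matrix(.code_chars(as.vector(aln$mat)), nrow = nrow(aln$mat),
              dimnames = dimnames(aln$mat))
  m
}

# resolve the (sample_a, sample_b) pair list for a pairing mode
.pairing_pairs <- function(aln, pairing, focal, other, ref_label) {
  focal_ids <- .samples_of(aln, mitotype = focal)
  if (!length(focal_ids))
    stop("grouping error: no samples with mitotype '", focal, "'",
         call. = FALSE)
  if (pairing == "vs-reference") {
    if (is.null(ref_label)) {
      cand <- .samples_of(aln, mitotype = other)
      if (!length(cand))
        stop("grouping error: no samples with mitotype '", other,
             "' to act as reference", call. = FALSE)
      ref_label <- if ("TNP_ref" %in% cand) "TNP_ref" else cand[1L]
    }
    data.frame(sample_a = ref_label, sample_b = focal_ids,
               stringsAsFactors = FALSE)
  } else {
    other_ids <- .samples_of(aln, mitotype = other)
    if (!length(other_ids))
      stop("grouping error: no samples with mitotype '", other, "'",
           call. = FALSE)
    expand.grid(sample_a = other_ids, sample_b = focal_ids,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
}

#' Per-element, per-complex and genome-wide identity profiles
#'
#' Computes percent identity for every selected sample pair at three
#' scopes: each annotated element, each OXPHOS complex (pooling its CDS
#' columns), and the whole modelled region ("genome"). The genome-wide
#' mean across pairs is attached as the `baseline` attribute (the "red
#' line" of the per-element profile plot).
#'
#' @param aln An [mt_alignment], trimmed to the coding region.
#' @param model The matching [mt_model].
#' @param pairing `"vs-reference"` (default; reference or first
#'   non-focal sample against every focal sample, as in the published
#'   element profiles) or `"between-mitotypes"` (all cross pairs).
#' @param focal,other Mitotype labels (focal = the clade whose samples
#'   are profiled; default ENA vs TNP).
#' @param ref_label Sample id to use as the reference in
#'   `"vs-reference"` mode; default `"TNP_ref"` when present, else the
#'   first `other`-mitotype sample.
#' @return Data frame of class `mt_profiles` with columns `scope`
#'   (`"element"`, `"complex"`, `"genome"`), `name`, `kind`, `complex`,
#'   `length`, `sample_a`, `sample_b`, `identity`.
#' @export
profile_elements <- function(aln, model,
                             pairing = c("vs-reference",
                                         "between-mitotypes"),
                             focal = "ENA", other = "TNP",
                             ref_label = NULL) {
  pairing <- match.arg(pairing)
  if (any(model$elements$end > ncol(aln$mat)))
    stop("annotation error: model extends beyond the alignment",
         call. = FALSE)
  pairs <- .pairing_pairs(aln, pairing, focal, other, ref_label)
  coded <- .coded_matrix(aln)
  e <- model$elements
  cols_of <- lapply(seq_len(nrow(e)),
                    function(i) (e$start[i] + 1L):e$end[i])
  cx_levels <- as.character(
    intersect(c("I", "III", "IV", "V"), unique(e$complex)))
  cx_names <- if (length(cx_levels)) paste0("Complex_", cx_levels)
              else character(0)
  cx_cols <- lapply(cx_levels, function(cx)
    unlist(cols_of[e$complex == cx & e$kind == "CDS"]))
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    s <- .pair_scores(coded[pairs$sample_a[k], ],
                      coded[pairs$sample_b[k], ])
    elem_id <- vapply(cols_of, function(cc) {
      v <- s[cc]; v <- v[!is.na(v)]
      if (length(v)) 100 * mean(v) else NA_real_
    }, 0)
    cx_id <- vapply(cx_cols, function(cc) {
      v <- s[cc]; v <- v[!is.na(v)]
      if (length(v)) 100 * mean(v) else NA_real_
    }, 0)
    sv <- s[!is.na(s)]
    out[[k]] <- data.frame(
      scope = c(rep("element", nrow(e)), rep("complex", length(cx_levels)),
                "genome"),
      name = c(e$name, cx_names, "genome"),
      kind = c(e$kind, rep("CDS", length(cx_levels)), "genome"),
      complex = c(e$complex, cx_levels, "none"),
      length = c(e$end - e$start,
                 vapply(cx_cols, length, 0L), ncol(aln$mat)),
      sample_a = pairs$sample_a[k], sample_b = pairs$sample_b[k],
      identity = c(elem_id, cx_id, 100 * mean(sv)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "baseline") <- mean(res$identity[res$scope == "genome"])
  class(res) <- c("mt_profiles", class(res))
  res
}

#' Between-mitotype nucleotide divergence summary
#'
#' Per-site divergence `1 - identity/100` for every between-group pair,
#' summarised as mean and min-max range (the form in which whole-genome
#' mitotype divergence is conventionally reported).
#'
#' @param aln An [mt_alignment].
#' @param focal,other Mitotype labels of the two groups.
#' @param columns Optional column subset.
#' @return List with `mean`, `min`, `max`, and `pairs` (data frame of
#'   per-pair divergences).
#' @export
divergence_summary <- function(aln, focal = "ENA", other = "TNP",
                               columns = NULL) {
  a_ids <- .samples_of(aln, mitotype = other)
  b_ids <- .samples_of(aln, mitotype = focal)
  if (!length(a_ids) || !length(b_ids))
    stop("grouping error: both mitotype groups must be non-empty",
         call. = FALSE)
  coded <- .coded_matrix(aln)
  if (!is.null(columns)) coded <- coded[, columns, drop = FALSE]
  pairs <- expand.grid(sample_a = a_ids, sample_b = b_ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs$divergence <- vapply(seq_len(nrow(pairs)), function(k) {
    v <- .pair_scores(coded[pairs$sample_a[k], ],
                      coded[pairs$sample_b[k], ])
    v <- v[!is.na(v)]
    if (!length(v))
      stop("undefined identity: no comparable columns", call. = FALSE)
    1 - mean(v)
  }, 0)
  list(mean = mean(pairs$divergence), min = min(pairs$divergence),
       max = max(pairs$divergence), pairs = pairs)
}
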