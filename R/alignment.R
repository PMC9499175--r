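#' Construct a labeled alignment
#'
#' Equal-length sequences over the IUPAC alphabet (gaps allowed) with a
#' mitotype and population label per sample.
#'
#' @param seqs Named character vector of aligned sequences, or a character
#'   matrix (samples x columns) of single symbols with rownames.
#' @param samples Data frame with columns `sample_id`, `mitotype`,
#'   `population`; every sequence name must appear exactly once.
#' @return Object of class `mt_alignment`: list with `mat` (character
#'   matrix, samples x columns) and `samples`.
#' @export
mt_alignment <- function(seqs, samples) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else if (length(seqs) == 0L) {
    mat <- matrix(character(0), nrow = 0L, ncol = 0L,
                  dimnames = list(character(0), NULL))
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named by sample id", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat))) {
    if (nrow(mat) > 0L)
      stop("sequence matrix must have sample ids as rownames",
           call. = FALSE)
    rownames(mat) <- character(0)
  }
  bad <- setdiff(unique(as.vector(mat)), IUPAC_SYMBOLS)
  if (length(bad))
    stop("alphabet error: illegal symbol(s) ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "mitotype", "population") %in%
                  names(samples)))
  missing <- setdiff(rownames(mat), samples$sample_id)
  if (length(missing))
    stop("labeling error: sample id(s) not in sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  samples <- samples[match(rownames(mat), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  structure(list(mat = mat, samples = samples), class = "mt_alignment")
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("<mt_alignment> ", nrow(x$mat), " samples x ", ncol(x$mat),
      " columns; mitotypes: ",
      paste(names(table(x$samples$mitotype)), table(x$samples$mitotype),
            sep = ":", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of samples / columns of an alignment
#' @param aln An [mt_alignment].
#' @return Integer.
#' @export
n_samples <- function(aln) nrow(aln$mat)

#' @rdname n_samples
#' @export
n_columns <- function(aln) ncol(aln$mat)

#' Alignment rows as strings
#' @param aln An [mt_alignment].
#' @return Named character vector.
#' @export
alignment_strings <- function(aln) {
  if (nrow(aln$mat) == 0L)
    return(stats::setNames(character(0), character(0)))
  stats::setNames(apply(aln$mat, 1L, paste, collapse = ""),
                  rownames(aln$mat))
}

#' Load an aligned FASTA with a sample sheet
#'
#' @param fasta_path Aligned multi-FASTA (IUPAC symbols, gaps allowed).
#' @param sample_sheet_path TSV with header `sample_id`, `mitotype`,
#'   `population`.
#' @param mitotypes Allowed mitotype labels; set to `NULL` to accept any.
#' @return An [mt_alignment].
#' @export
load_alignment <- function(fasta_path, sample_sheet_path,
                           mitotypes = c("TNP", "ENA")) {
  set <- Biostrings::readBStringSet(fasta_path)
  seqs <- stats::setNames(as.character(set),
                          sub("\\s.*$", "", names(set)))
  sheet <- utils::read.delim(sample_sheet_path, sep = "\t",
                             stringsAsFactors = FALSE)
  need <- c("sample_id", "mitotype", "population")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!is.null(mitotypes)) {
    bad <- setdiff(unique(sheet$mitotype), mitotypes)
    if (length(bad))
      stop("labeling error: unknown mitotype(s) ",
           paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  mt_alignment(seqs, sheet)
}

#' Write an alignment as FASTA plus sample sheet
#'
#' @param aln An [mt_alignment].
#' @param fasta_path,sample_sheet_path Output paths.
#' @return Character vector of the two paths, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, sample_sheet_path) {
  set <- Biostrings::BStringSet(alignment_strings(aln))
  Biostrings::writeXStringSet(set, fasta_path, width = 80L)
  utils::write.table(aln$samples, sample_sheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, sample_sheet_path))
}

#' Subset an alignment by samples
#' @param aln An [mt_alignment].
#' @param ids Sample ids to keep.
#' @return An [mt_alignment].
#' @export
subset_samples <- function(aln, ids) {
  missing <- setdiff(ids, rownames(aln$mat))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  mt_alignment(aln$mat[ids, , drop = FALSE],
               aln$samples[aln$samples$sample_id %in% ids, , drop = FALSE])
}

.samples_of <- function(aln, mitotype = NULL, population = NULL) {
  keep <- rep(TRUE, nrow(aln$samples))
  if (!is.null(mitotype)) keep <- keep & aln$samples$mitotype %in% mitotype
  if (!is.null(population))
    keep <- keep & aln$samples$population %in% population
  aln$samples$sample_id[keep]
}

#' Trim an alignment (and model) to the coding region
#'
#' Removes the control-region columns recorded in the model (alignment
#' coordinates, 0-based half-open) and re-bases element coordinates that
#' lie beyond the removed block.
#'
#' @param aln An [mt_alignment].
#' @param model An [mt_model]; its `control_region` field gives the bounds,
#'   `NULL` meaning nothing to trim.
#' @return List with the trimmed `alignment` and the re-based `model`.
#' @export
trim_to_coding <- function(aln, model) {
  cr <- model$control_region
  if (is.null(cr)) return(list(alignment = aln, model = model))
  if (length(cr) != 2L || cr[1L] < 0 || cr[2L] > ncol(aln$mat) ||
      cr[1L] >= cr[2L])
    stop("coordinate error: control region bounds [", cr[1L], ", ",
         cr[2L], ") outside alignment of length ", ncol(aln$mat),
         call. = FALSE)
  drop_cols <- (cr[1L] + 1L):cr[2L]
  mat <- aln$mat[, -drop_cols, drop = FALSE]
  width <- cr[2L] - cr[1L]
  e <- model$elements
  e <- e[e$kind != "control", , drop = FALSE]
  shift <- e$start >= cr[2L]
  e$start[shift] <- e$start[shift] - width
  e$end[shift] <- e$end[shift] - width
  if (any(e$start < cr[1L] & e$end > cr[1L]))
    stop("coordinate error: element straddles the control region",
         call. = FALSE)
  new_model <- mt_model(e, sequence_length = model$sequence_length - width)
  list(alignment = mt_alignment(mat, aln$samples), model = new_model)
}

#' Extract an element's columns as a sub-alignment
#'
#' Minus-strand elements are reverse-complemented (IUPAC-aware) so that
#' downstream codon work sees the coding strand.
#'
#' @param aln An [mt_alignment].
#' @param element A one-row element record (see [mt_element]) or an element
#'   name to look up in `model`.
#' @param model Required when `element` is a name.
#' @return An [mt_alignment] of the element's columns.
#' @export
extract_element <- function(aln, element, model = NULL) {
  if (is.character(element)) {
    if (is.null(model)) stop("model required to look up element by name",
                             call. = FALSE)
    element <- .element_row(model, element)
  }
  if (element$end > ncol(aln$mat) || element$start < 0)
    stop("coordinate error: element [", element$start, ", ", element$end,
         ") outside alignment of length ", ncol(aln$mat), call. = FALSE)
  cols <- (element$start + 1L):element$end
  mat <- aln$mat[, cols, drop = FALSE]
  if (element$strand == "-") {
    mat <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
    mat[] <- iupac_complement(mat)
  }
  mt_alignment(mat, aln$samples)
}
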