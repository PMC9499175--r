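#' Construct a mitogenome element annotation
#'
#' @param name Element label, e.g. `"ND1"`, `"tRNA-cys"`, `"12S-rRNA"`.
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"control"`.
#' @param start,end 0-based half-open coordinates on the (linearised)
#'   coding region.
#' @param strand `"+"` or `"-"`. Minus-strand elements are
#'   reverse-complemented before any codon-level analysis.
#' @param complex OXPHOS complex for CDS elements: `"I"`, `"III"`, `"IV"`,
#'   `"V"`; `"none"` otherwise.
#' @return A one-row data frame (element record).
#' @export
mt_element <- function(name, kind, start, end, strand = "+",
                       complex = "none") {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "control"))
  strand <- match.arg(strand, c("+", "-"))
  complex <- match.arg(complex, c("I", "III", "IV", "V", "none"))
  if (!is.numeric(start) || !is.numeric(end) || start < 0 || start >= end)
    stop("element '", name, "': need 0 <= start < end", call. = FALSE)
  if (kind == "CDS" && complex == "none")
    stop("CDS element '", name, "' must carry an OXPHOS complex",
         call. = FALSE)
  data.frame(name = name, kind = kind, start = as.integer(start),
             end = as.integer(end), strand = strand, complex = complex,
             stringsAsFactors = FALSE)
}

#' Construct a mitogenome model
#'
#' @param elements Data frame of element records ([mt_element] rows),
#'   in genome (5' to 3') order.
#' @param sequence_length Total length in bp of the modelled region.
#' @param control_region Optional `c(start, end)` 0-based half-open bounds
#'   of a control region still present in alignment coordinates, or `NULL`
#'   if already excluded.
#' @return Object of class `mt_model`.
#' @export
mt_model <- function(elements, sequence_length, control_region = NULL) {
  stopifnot(is.data.frame(elements),
            all(c("name", "kind", "start", "end", "strand", "complex")
                %in% names(elements)))
  elements <- elements[order(elements$start), , drop = FALSE]
  rownames(elements) <- NULL
  if (any(elements$end > sequence_length) || any(elements$start < 0))
    stop("element coordinates fall outside [0, sequence_length)",
         call. = FALSE)
  if (anyDuplicated(elements$name))
    stop("duplicate element names", call. = FALSE)
  # overlap check (shared single-base boundaries are not modelled here)
  if (nrow(elements) > 1L) {
    ov <- elements$start[-1L] < elements$end[-nrow(elements)]
    if (any(ov))
      stop("overlapping elements: ",
           paste(elements$name[-1L][ov], collapse = ", "), call. = FALSE)
  }
  intergenic <- sequence_length - sum(elements$end - elements$start)
  structure(list(sequence_length = as.integer(sequence_length),
                 elements = elements,
                 intergenic_bp = as.integer(intergenic),
                 control_region = control_region),
            class = "mt_model")
}

#' @export
print.mt_model <- function(x, ...) {
  k <- table(factor(x$elements$kind, c("CDS", "tRNA", "rRNA", "control")))
  cat("<mt_model> ", x$sequence_length, " bp; ",
      k[["CDS"]], " CDS, ", k[["tRNA"]], " tRNA, ", k[["rRNA"]],
      " rRNA; intergenic ", x$intergenic_bp, " bp\n", sep = "")
  invisible(x)
}

element_lengths <- function(model) {
  stats::setNames(model$elements$end - model$elements$start,
                  model$elements$name)
}

# Default template: standard vertebrate mitochondrial gene order.
# CDS lengths follow the TNP reference protein table; tRNA/rRNA lengths
# follow the non-coding element table where given, typical vertebrate
# lengths otherwise.  The 65 intergenic bp are placed at four junctions
# (the largest standing in for the light-strand replication origin,
# O_L, between tRNA-asn and tRNA-cys); exact placement is not published
# and is an arbitrary but fixed choice.
.DEFAULT_LAYOUT <- list(
  #       name          kind    len  strand complex
  list("tRNA-phe",   "tRNA",   68L, "+", "none"),
  list("12S-rRNA",   "rRNA",  946L, "+", "none"),
  list("tRNA-val",   "tRNA",   72L, "+", "none"),
  list("16S-rRNA",   "rRNA", 1690L, "+", "none"),
  list("tRNA-leu",   "tRNA",   75L, "+", "none"),
  list("ND1",        "CDS",   975L, "+", "I"),
  list("tRNA-ile",   "tRNA",   70L, "+", "none"),
  list("tRNA-gln",   "tRNA",   71L, "-", "none"),
  list("tRNA-met",   "tRNA",   69L, "+", "none"),
  list("ND2",        "CDS",  1047L, "+", "I"),
  list("tRNA-trp",   "tRNA",   70L, "+", "none"),
  list("tRNA-ala",   "tRNA",   69L, "-", "none"),
  list("tRNA-asn",   "tRNA",   73L, "-", "none"),
  list("tRNA-cys",   "tRNA",   65L, "-", "none"),
  list("tRNA-tyr",   "tRNA",   70L, "-", "none"),
  list("COI",        "CDS",  1551L, "+", "IV"),
  list("tRNA-ser",   "tRNA",   71L, "-", "none"),
  list("tRNA-asp",   "tRNA",   73L, "+", "none"),
  list("COII",       "CDS",   691L, "+", "IV"),
  list("tRNA-lys",   "tRNA",   74L, "+", "none"),
  list("ATPase8",    "CDS",   168L, "+", "V"),
  list("ATPase6",    "CDS",   684L, "+", "V"),
  list("COIII",      "CDS",   786L, "+", "IV"),
  list("tRNA-gly",   "tRNA",   69L, "+", "none"),
  list("ND3",        "CDS",   351L, "+", "I"),
  list("tRNA-arg",   "tRNA",   69L, "+", "none"),
  list("ND4L",       "CDS",   297L, "+", "I"),
  list("ND4",        "CDS",  1381L, "+", "I"),
  list("tRNA-his",   "tRNA",   68L, "+", "none"),
  list("tRNA-ser-2", "tRNA",   68L, "+", "none"),
  list("tRNA-leu-2", "tRNA",   73L, "+", "none"),
  list("ND5",        "CDS",  1839L, "+", "I"),
  list("ND6",        "CDS",   522L, "-", "I"),
  list("tRNA-glu",   "tRNA",   69L, "-", "none"),
  list("CytB",       "CDS",  1141L, "+", "III"),
  list("tRNA-thr",   "tRNA",   72L, "+", "none"),
  list("tRNA-pro",   "tRNA",   70L, "-", "none")
)

# intergenic spacer (bp) inserted AFTER the named element; sums to 65
.DEFAULT_SPACERS <- c("tRNA-asn" = 35L, "COIII" = 10L,
                      "tRNA-glu" = 13L, "tRNA-thr" = 7L)

#' Default annotated mitogenome template
#'
#' The standard vertebrate mitochondrial gene order (heavy strand 5' to 3',
#' control region excluded): 13 protein-coding genes assigned to OXPHOS
#' complexes I/III/IV/V, 22 tRNAs, and 2 rRNAs, with ND6 and eight tRNAs on
#' the light (minus) strand, and 65 bp of intergenic spacer.
#'
#' @return An [mt_model].
#' @export
default_mito_model <- function() {
  pos <- 0L
  rows <- vector("list", length(.DEFAULT_LAYOUT))
  for (i in seq_along(.DEFAULT_LAYOUT)) {
    e <- .DEFAULT_LAYOUT[[i]]
    rows[[i]] <- mt_element(e[[1L]], e[[2L]], pos, pos + e[[3L]],
                            e[[4L]], e[[5L]])
    pos <- pos + e[[3L]]
    gap <- .DEFAULT_SPACERS[e[[1L]]]
    if (!is.na(gap)) pos <- pos + gap
  }
  mt_model(do.call(rbind, rows), sequence_length = pos)
}

.element_row <- function(model, name) {
  i <- match(name, model$elements$name)
  if (is.na(i))
    stop("element '", name, "' absent from model", call. = FALSE)
  model$elements[i, , drop = FALSE]
}

# ---- annotation IO ------------------------------------------------------

#' Convert a model to a GRanges annotation (1-based coordinates)
#'
#' @param model An [mt_model].
#' @param seqid Sequence name.
#' @return A `GenomicRanges::GRanges` with `type`, `Name` and
#'   `mito_complex` metadata columns.
#' @export
as_granges <- function(model, seqid = "mitogenome") {
  e <- model$elements
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = e$start + 1L, end = e$end),
    strand = e$strand)
  GenomicRanges::mcols(gr)$type <- c(CDS = "CDS", tRNA = "tRNA",
                                     rRNA = "rRNA",
                                     control = "D_loop")[e$kind]
  GenomicRanges::mcols(gr)$ID <- e$name
  GenomicRanges::mcols(gr)$Name <- e$name
  GenomicRanges::mcols(gr)$mito_complex <- e$complex
  # full-length genes all start in frame; phase silences the GFF3 writer
  GenomicRanges::mcols(gr)$phase <- ifelse(e$kind == "CDS", 0L,
                                           NA_integer_)
  GenomeInfoDb::seqlengths(gr) <- model$sequence_length
  gr
}

#' Write element annotations to GFF3 (1-based inclusive coordinates)
#'
#' @param model An [mt_model].
#' @param path Output file.
#' @param seqid Sequence identifier used in column 1.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(model, path, seqid = "mitogenome") {
  rtracklayer::export(as_granges(model, seqid), path, format = "gff3")
  invisible(path)
}

#' Read element annotations from GFF3
#'
#' @param path GFF3 file as written by [write_gff3] (or any GFF3 whose
#'   features carry `Name` attributes and CDS/tRNA/rRNA types).
#' @param sequence_length Total modelled length; defaults to the
#'   `##sequence-region` pragma when present, else the maximum feature end.
#' @return An [mt_model].
#' @export
read_gff3 <- function(path, sequence_length = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  .granges_to_model(gr, sequence_length)
}

.granges_to_model <- function(gr, sequence_length = NULL) {
  mc <- GenomicRanges::mcols(gr)
  kind <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
            D_loop = "control")[as.character(mc$type)]
  keep <- !is.na(kind)
  gr <- gr[keep]; mc <- mc[keep, , drop = FALSE]; kind <- kind[keep]
  nm <- if (!is.null(mc$Name)) as.character(mc$Name)
        else as.character(mc$ID)
  cx <- if (!is.null(mc$mito_complex)) as.character(mc$mito_complex)
        else mapply(.infer_complex, nm, kind)
  st <- as.character(GenomicRanges::strand(gr))
  st[!st %in% c("+", "-")] <- "+"
  rows <- lapply(seq_along(gr), function(i)
    mt_element(nm[i], kind[i], GenomicRanges::start(gr)[i] - 1L,
               GenomicRanges::end(gr)[i], st[i], cx[i]))
  e <- do.call(rbind, rows)
  if (is.null(sequence_length)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    sequence_length <- if (length(sl) && !is.na(sl[1L])) sl[[1L]]
                       else max(e$end)
  }
  mt_model(e, sequence_length)
}

#' Write element annotations to BED (0-based half-open)
#'
#' BED carries name, coordinates and strand only; kind and complex are
#' re-inferred from element names on reading.
#' @inheritParams write_gff3
#' @return `path`, invisibly.
#' @export
write_bed <- function(model, path, seqid = "mitogenome") {
  gr <- as_granges(model, seqid)
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    name = model$elements$name, score = 0L)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read element annotations from BED
#' @inheritParams read_gff3
#' @return An [mt_model].
#' @export
read_bed <- function(path, sequence_length = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- as.character(GenomicRanges::mcols(gr)$name)
  kind <- vapply(nm, .infer_kind, "")
  st <- as.character(GenomicRanges::strand(gr))
  st[!st %in% c("+", "-")] <- "+"
  rows <- lapply(seq_along(gr), function(i)
    mt_element(nm[i], kind[i], GenomicRanges::start(gr)[i] - 1L,
               GenomicRanges::end(gr)[i], st[i],
               .infer_complex(nm[i], kind[i])))
  e <- do.call(rbind, rows)
  if (is.null(sequence_length)) sequence_length <- max(e$end)
  mt_model(e, sequence_length)
}

.infer_kind <- function(name) {
  if (grepl("^tRNA", name, ignore.case = TRUE)) "tRNA"
  else if (grepl("rRNA", name, ignore.case = TRUE)) "rRNA"
  else if (grepl("D.?loop|control", name, ignore.case = TRUE)) "control"
  else "CDS"
}

.infer_complex <- function(name, kind) {
  if (kind != "CDS") return("none")
  if (grepl("^ND", name, ignore.case = TRUE)) "I"
  else if (grepl("^CytB", name, ignore.case = TRUE)) "III"
  else if (grepl("^CO", name, ignore.case = TRUE)) "IV"
  else if (grepl("^ATP", name, ignore.case = TRUE)) "V"
  else stop("cannot infer OXPHOS complex for CDS '", name, "'",
            call. = FALSE)
}
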