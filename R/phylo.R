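#' Conservative ambiguity-aware p-distance between two sequences
#'
#' Per site, two symbols contribute distance 0 whenever their IUPAC base
#' sets intersect (a heteroplasmic Y is treated as identical to a C or a
#' T), 1 otherwise; the total is divided by the number of gap-free
#' compared columns. This is the conservative heterozygote coding used
#' for tree building: it can only lower, never raise, divergence
#' relative to hard-called bases.
#'
#' @param seq_a,seq_b Equal-length strings or character vectors.
#' @return p-distance in `[0, 1]`.
#' @export
conservative_distance <- function(seq_a, seq_b) {
  a <- .as_chars(seq_a); b <- .as_chars(seq_b)
  if (length(a) != length(b))
    stop("alignment error: sequences of unequal length", call. = FALSE)
  i <- .code_chars(a); j <- .code_chars(b)
  v <- .CONSERVATIVE_MATRIX[cbind(i, j)]
  v <- v[!is.na(v)]
  if (!length(v))
    stop("undefined distance: no gap-free columns to compare",
         call. = FALSE)
  mean(v)
}

#' Conservative p-distance matrix for an alignment
#'
#' @param aln An [mt_alignment].
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
distance_matrix <- function(aln) {
  coded <- .coded_matrix(aln)
  n <- nrow(coded)
  ids <- rownames(coded)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- .CONSERVATIVE_MATRIX[cbind(coded[i, ], coded[j, ])]
    v <- v[!is.na(v)]
    if (!length(v))
      stop("undefined distance between '", ids[i], "' and '", ids[j],
           "'", call. = FALSE)
    d[i, j] <- d[j, i] <- mean(v)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); tie handling is
#' deterministic for a fixed label order. Negative branch-length
#' estimates are clamped to zero with the excess transferred to the
#' adjacent (sibling) branch, preserving leaf-to-leaf path lengths where
#' possible. NJ stands in for a maximum-likelihood search here: the
#' claim it supports is topological (mitotype clustering), not
#' branch-length inference.
#'
#' @param d Symmetric distance matrix (labels as dimnames) or `dist`.
#' @return An \pkg{ape} `phylo` tree (unrooted).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("input error: d must be a square distance matrix", call. = FALSE)
  if (nrow(d) < 3L)
    stop("input error: neighbor joining needs >= 3 labels", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  .clamp_negative_edges(tr)
}

# zero out negative NJ edges, moving the excess onto the sibling edge
.clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    excess <- tr$edge.length[e]
    parent <- tr$edge[e, 1L]
    sibs <- which(tr$edge[, 1L] == parent)
    sibs <- setdiff(sibs, e)
    tr$edge.length[e] <- 0
    if (length(sibs))
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + excess
    if (all(tr$edge.length >= 0)) break
    if (all(tr$edge.length[tr$edge.length < 0] > -1e-12)) {
      tr$edge.length[tr$edge.length < 0] <- 0
      break
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Drop samples showing any evidence of heteroplasmy
#'
#' Removes every sample whose sequence contains an IUPAC ambiguity
#' symbol, the sample-selection rule for the clean tree.
#'
#' @param aln An [mt_alignment].
#' @return An [mt_alignment] without the heteroplasmic carriers.
#' @export
exclude_heteroplasmic <- function(aln) {
  carrier <- apply(matrix(.is_ambiguity(aln$mat), nrow = nrow(aln$mat)),
                   1L, any)
  if (all(carrier))
    stop("empty selection: every sample shows heteroplasmy",
         call. = FALSE)
  if (!any(carrier)) return(aln)
  keep <- rownames(aln$mat)[!carrier]
  subset_samples(aln, keep)
}

#' Build the mitotype tree from an alignment
#'
#' Convenience wrapper: optionally drop heteroplasmic samples, compute
#' the conservative distance matrix, run NJ, and optionally write
#' Newick.
#'
#' @param aln An [mt_alignment].
#' @param drop_heteroplasmic Apply [exclude_heteroplasmic] first?
#' @param newick_path Optional output path for the Newick string.
#' @return List with `tree` (`phylo`), `distances` (matrix), and
#'   `alignment` (the one actually used).
#' @export
mitotype_tree <- function(aln, drop_heteroplasmic = TRUE,
                          newick_path = NULL) {
  if (drop_heteroplasmic) aln <- exclude_heteroplasmic(aln)
  d <- distance_matrix(aln)
  tr <- nj_tree(d)
  if (!is.null(newick_path))
    ape::write.tree(tr, file = newick_path)
  list(tree = tr, distances = d, alignment = aln)
}

#' Are two groups reciprocally monophyletic on an unrooted tree?
#'
#' True when some internal edge bipartitions the leaves exactly into the
#' two groups (equivalently: group B is monophyletic after rooting at
#' any group A tip).
#'
#' @param tree A `phylo` tree.
#' @param group_a,group_b Disjoint tip-label vectors covering all tips.
#' @return Logical scalar.
#' @export
reciprocally_monophyletic <- function(tree, group_a, group_b) {
  stopifnot(setequal(tree$tip.label, c(group_a, group_b)))
  if (length(group_a) < 1L || length(group_b) < 1L) return(FALSE)
  if (length(group_a) == 1L || length(group_b) == 1L) return(TRUE)
  rooted <- ape::root(tree, outgroup = group_a[1L], resolve.root = TRUE)
  ape::is.monophyletic(rooted, group_b)
}
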