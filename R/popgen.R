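#' Remove alignment columns containing any ambiguity symbol
#'
#' The conservative masking rule used for all site-count statistics: a
#' column with a heteroplasmic (non-A/C/G/T, non-gap) call in any sample
#' is removed for all samples, deliberately lowering divergence
#' estimates rather than guessing phases.
#'
#' @param aln An [mt_alignment].
#' @return List with `alignment` (columns removed) and `removed`
#'   (1-based indices of the removed columns, for coordinate
#'   bookkeeping).
#' @export
mask_ambiguous <- function(aln) {
  amb <- matrix(.is_ambiguity(aln$mat), nrow = nrow(aln$mat))
  removed <- which(apply(amb, 2L, any))
  if (length(removed) == 0L)
    return(list(alignment = aln, removed = integer(0)))
  mt <- aln$mat[, -removed, drop = FALSE]
  list(alignment = mt_alignment(mt, aln$samples), removed = removed)
}

# columns unusable for site counting: any ambiguity or any gap
.excluded_columns <- function(mat) {
  bad <- .is_ambiguity(mat) | mat == "-"
  which(apply(matrix(bad, nrow = nrow(mat)), 2L, any))
}

# majority base over a column; ambiguity symbols contribute fractional
# weight to each base of their set, gaps contribute nothing
.consensus_base <- function(bases) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (b in bases) {
    s <- .IUPAC_SETS[[b]]
    if (length(s)) counts[s] <- counts[s] + 1 / length(s)
  }
  if (all(counts == 0)) return("-")
  names(counts)[which.max(counts)]
}

#' Partition sites into fixed and polymorphic, synonymous and
#' nonsynonymous
#'
#' After excluding every column carrying an ambiguity or gap in any
#' sample, classifies each remaining variable column: FIXED if the two
#' mitotype groups are each monomorphic for different bases;
#' POLYMORPHIC within a group if that group is variable. CDS sites are
#' further split synonymous/nonsynonymous with [classify_site] applied
#' in the focal-consensus codon context (minus-strand genes via their
#' coding strand; 1-2 bp incomplete terminal codons are skipped).
#' Non-coding (tRNA/rRNA) sites are tallied as focal-exclusive,
#' other-exclusive, shared polymorphism, or fixed.
#'
#' By default polymorphism is counted in the focal group only
#' (`polymorphism = "focal"`), matching an MK design that takes
#' within-ENA polymorphism against TNP/ENA fixed differences; a pooled
#' mode adds the other group's polymorphic sites to P counts.
#'
#' @param aln An [mt_alignment] (unmasked; masking is applied
#'   internally so element coordinates stay valid).
#' @param model The matching [mt_model].
#' @param focal,other Mitotype labels; focal is the group whose
#'   polymorphism enters P_N/P_S.
#' @param polymorphism `"focal"` or `"pooled"`.
#' @return Object of class `mt_partition`: list with `cds` (data frame
#'   `element, length, D_N, D_S, P_N, P_S`), `noncoding` (data frame
#'   `element, length, P_focal, P_other, P_shared, F`), `excluded`
#'   (1-based masked column indices), `focal`, `other`.
#' @export
partition_sites <- function(aln, model, focal = "ENA", other = "TNP",
                            polymorphism = c("focal", "pooled")) {
  polymorphism <- match.arg(polymorphism)
  f_ids <- .samples_of(aln, mitotype = focal)
  o_ids <- .samples_of(aln, mitotype = other)
  if (!length(f_ids) || !length(o_ids))
    stop("grouping error: empty mitotype group", call. = FALSE)
  mat <- aln$mat
  excluded <- .excluded_columns(mat)
  usable <- !(seq_len(ncol(mat)) %in% excluded)

  fm <- mat[f_ids, , drop = FALSE]
  om <- mat[o_ids, , drop = FALSE]
  f_nalleles <- apply(fm, 2L, function(x) length(unique(x)))
  o_nalleles <- apply(om, 2L, function(x) length(unique(x)))
  f_base <- fm[1L, ]       # group base where monomorphic
  o_base <- om[1L, ]
  is_fixed <- usable & f_nalleles == 1L & o_nalleles == 1L &
    f_base != o_base
  f_poly <- usable & f_nalleles > 1L
  o_poly <- usable & o_nalleles > 1L

  # focal consensus sequence provides the codon context everywhere
  f_cons <- apply(fm, 2L, .consensus_base)

  e <- model$elements
  cds <- e[e$kind == "CDS", , drop = FALSE]
  ncod <- e[e$kind %in% c("tRNA", "rRNA"), , drop = FALSE]

  count_classified <- function(el, site_filter, alt_of) {
    # walk a CDS element; for each selected genome column classify the
    # alternate base(s) in the focal-consensus codon context
    n_syn <- 0L; n_non <- 0L
    cols <- (el$start + 1L):el$end
    sel <- cols[site_filter[cols]]
    for (p in sel) {
      ctx <- .codon_context(f_cons, el, p)
      if (is.null(ctx)) next                   # incomplete terminal codon
      if (!all(ctx$codon %in% .ACGT)) next     # gap in the codon context
      cons_coding <- ctx$codon[ctx$pos_in_codon]
      alts <- alt_of(p)
      alts <- setdiff(alts, f_cons[p])
      if (el$strand == "-") alts <- iupac_complement(alts)
      alts <- setdiff(alts, cons_coding)
      for (a in alts) {
        cl <- .classify_base_change(paste(ctx$codon, collapse = ""),
                                    ctx$pos_in_codon, a)
        if (cl == "synonymous") n_syn <- n_syn + 1L
        else n_non <- n_non + 1L
      }
    }
    c(syn = n_syn, non = n_non)
  }

  cds_rows <- lapply(seq_len(nrow(cds)), function(i) {
    el <- cds[i, ]
    fx <- count_classified(el, is_fixed, function(p) o_base[p])
    pl <- count_classified(el, f_poly, function(p) unique(fm[, p]))
    if (polymorphism == "pooled") {
      pl2 <- count_classified(el, o_poly & !f_poly,
                              function(p) unique(om[, p]))
      pl <- pl + pl2
    }
    data.frame(element = el$name, length = el$end - el$start,
               D_N = unname(fx["non"]), D_S = unname(fx["syn"]),
               P_N = unname(pl["non"]), P_S = unname(pl["syn"]),
               stringsAsFactors = FALSE)
  })

  ncod_rows <- lapply(seq_len(nrow(ncod)), function(i) {
    el <- ncod[i, ]
    cols <- (el$start + 1L):el$end
    data.frame(element = el$name, length = el$end - el$start,
               P_focal = sum(f_poly[cols] & !o_poly[cols]),
               P_other = sum(o_poly[cols] & !f_poly[cols]),
               P_shared = sum(f_poly[cols] & o_poly[cols]),
               F = sum(is_fixed[cols]),
               stringsAsFactors = FALSE)
  })

  structure(list(cds = do.call(rbind, cds_rows),
                 noncoding = do.call(rbind, ncod_rows),
                 excluded = excluded, focal = focal, other = other,
                 polymorphism = polymorphism),
            class = "mt_partition")
}

#' McDonald-Kreitman test with Neutrality Index
#'
#' On the 2x2 table of fixed vs polymorphic by nonsynonymous vs
#' synonymous counts, computes the Neutrality Index
#' `NI = (P_N/P_S)/(D_N/D_S)`, the Yates-corrected chi-square (with its
#' 1-df p-value), and Fisher's exact p. NI > 1 with a significant test
#' is called purifying selection (an excess of segregating relative to
#' fixed nonsynonymous variation), NI < 1 positive selection.
#'
#' @param x Either an `mt_partition` (give `element`), or the four
#'   counts `c(D_N, D_S, P_N, P_S)`.
#' @param element Element name when `x` is a partition.
#' @param alpha Significance threshold for the selection call.
#' @return Object of class `mt_mk`: list with `element`, `table`
#'   (named counts), `NI`, `chi2_yates`, `p_yates`, `p_fisher`, `call`.
#' @examples
#' mk_test(c(D_N = 1, D_S = 35, P_N = 9, P_S = 28))$NI  # 11.25
#' @export
mk_test <- function(x, element = NULL, alpha = 0.05) {
  if (inherits(x, "mt_partition")) {
    if (is.null(element))
      stop("element name required with a partition", call. = FALSE)
    i <- match(element, x$cds$element)
    if (is.na(i))
      stop("element '", element, "' has no CDS partition row",
           call. = FALSE)
    counts <- c(D_N = x$cds$D_N[i], D_S = x$cds$D_S[i],
                P_N = x$cds$P_N[i], P_S = x$cds$P_S[i])
  } else {
    if (length(x) != 4L || !is.numeric(x))
      stop("x must be four counts (D_N, D_S, P_N, P_S)", call. = FALSE)
    counts <- stats::setNames(as.numeric(x),
                              c("D_N", "D_S", "P_N", "P_S"))
    if (is.null(element)) element <- ""
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  dn <- counts[["D_N"]]; ds <- counts[["D_S"]]
  pn <- counts[["P_N"]]; ps <- counts[["P_S"]]

  ni <- if (dn > 0 && ds > 0 && ps > 0) (pn / ps) / (dn / ds)
        else NA_real_

  tab <- matrix(c(dn, ds, pn, ps), nrow = 2L, byrow = TRUE,
                dimnames = list(c("fixed", "polymorphic"),
                                c("nonsyn", "syn")))
  n_tot <- sum(tab)
  margins_ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  if (margins_ok) {
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    num <- n_tot * (abs(a * d - b * cc) - n_tot / 2)^2
    # continuity correction can overshoot for very unbalanced tables
    if (abs(a * d - b * cc) < n_tot / 2) num <- 0
    chi2 <- num / (sum(tab[1, ]) * sum(tab[2, ]) *
                     sum(tab[, 1]) * sum(tab[, 2]))
    p_yates <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
    p_fisher <- stats::fisher.test(tab)$p.value
    skipped <- NULL
  } else {
    chi2 <- NA_real_; p_yates <- NA_real_; p_fisher <- NA_real_
    skipped <- "zero margin: tests skipped"
  }

  call <- if (is.na(ni)) "undefined"
          else if (!is.na(p_yates) &&
                   min(p_yates, p_fisher) < alpha)
            if (ni > 1) "purifying" else "positive"
          else "neutral"

  structure(list(element = element, table = counts, NI = ni,
                 chi2_yates = chi2, p_yates = p_yates,
                 p_fisher = p_fisher, call = call, note = skipped),
            class = "mt_mk")
}

#' @export
print.mt_mk <- function(x, ...) {
  cat("<MK test> ", x$element, "  D_N=", x$table[["D_N"]],
      " D_S=", x$table[["D_S"]], " P_N=", x$table[["P_N"]],
      " P_S=", x$table[["P_S"]],
      "  NI=", ifelse(is.na(x$NI), "NA", sprintf("%.2f", x$NI)),
      "  p_Yates=", signif(x$p_yates, 3),
      "  p_Fisher=", signif(x$p_fisher, 3),
      "  [", x$call, "]\n", sep = "")
  invisible(x)
}

#' Run MK tests for every CDS element of a partition
#' @param partition An `mt_partition`.
#' @param alpha Significance threshold.
#' @return Data frame, one row per CDS element, in genome order.
#' @export
mk_test_all <- function(partition, alpha = 0.05) {
  rows <- lapply(partition$cds$element, function(el) {
    r <- mk_test(partition, el, alpha)
    data.frame(Protein = el,
               Length = partition$cds$length[
                 match(el, partition$cds$element)],
               D_N = r$table[["D_N"]], D_S = r$table[["D_S"]],
               P_N = r$table[["P_N"]], P_S = r$table[["P_S"]],
               NI = round(r$NI, 2L), P_Yates = r$p_yates,
               P_Fisher = r$p_fisher, call = r$call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tajima's D for one population
#'
#' Standard Tajima (1989) formulation on the masked alignment: `S`
#' segregating sites, `pi` the mean number of pairwise differences, and
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the usual constants
#' (`a1 = sum 1/i`, etc.). Columns with gaps or ambiguities are
#' excluded; `D` is undefined (NA, not an error) when `S = 0`.
#' Significance uses the conventional `|D| > 2` beta-approximation
#' bound.
#'
#' @param aln An [mt_alignment].
#' @param population Population label; `NULL` uses all samples.
#' @param mitotype Optional mitotype filter instead of population.
#' @return Object of class `mt_tajima`: list with `population`, `n`,
#'   `S`, `pi`, `D`, `significant`.
#' @export
tajimas_d <- function(aln, population = NULL, mitotype = NULL) {
  ids <- .samples_of(aln, mitotype = mitotype, population = population)
  if (length(ids) < 2L)
    stop("input error: Tajima's D needs n >= 2 sequences", call. = FALSE)
  mat <- aln$mat[ids, , drop = FALSE]
  keep <- setdiff(seq_len(ncol(mat)), .excluded_columns(mat))
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  n_alleles <- apply(mat, 2L, function(x) length(unique(x)))
  S <- sum(n_alleles > 1L)
  # mean pairwise differences
  pair_idx <- utils::combn(n, 2L)
  diffs <- vapply(seq_len(ncol(pair_idx)), function(k)
    sum(mat[pair_idx[1L, k], ] != mat[pair_idx[2L, k], ]), 0L)
  pi <- mean(diffs)
  if (S == 0L) {
    res <- list(population = population %||% "all", n = n, S = 0L,
                pi = pi, D = NA_real_, significant = FALSE)
    class(res) <- "mt_tajima"
    return(res)
  }
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  res <- list(population = population %||% "all", n = n, S = S, pi = pi,
              D = D, significant = abs(D) > 2)
  class(res) <- "mt_tajima"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mt_tajima <- function(x, ...) {
  cat("<Tajima's D> ", x$population, ": n=", x$n, " S=", x$S,
      " pi=", signif(x$pi, 4), " D=",
      ifelse(is.na(x$D), "undefined (S=0)", signif(x$D, 4)),
      if (isTRUE(x$significant)) "  *|D|>2*" else "", "\n", sep = "")
  invisible(x)
}
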