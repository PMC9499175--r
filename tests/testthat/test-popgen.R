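# masking, site partitioning, MK test, Tajima's D

test_that("mask_ambiguous removes whole columns carrying ambiguity", {
  aln <- toy_aln(c(a = "ACGT", b = "ACGT"), c("TNP", "ENA"))
  m0 <- mask_ambiguous(aln)
  expect_identical(m0$alignment$mat, aln$mat)
  expect_identical(m0$removed, integer(0))

  aln1 <- toy_aln(c(a = "ACGT", b = "ACYT"), c("TNP", "ENA"))
  m1 <- mask_ambiguous(aln1)
  expect_identical(m1$removed, 3L)
  expect_identical(unname(alignment_strings(m1$alignment)),
                   c("ACT", "ACT"))

  aln2 <- toy_aln(c(a = "ACGT", b = "NNNN"), c("TNP", "ENA"))
  m2 <- mask_ambiguous(aln2)
  expect_identical(m2$removed, 1:4)
  expect_identical(n_columns(m2$alignment), 0L)
})

test_that("partition_sites classifies engineered fixed changes", {
  # single CDS of 2 codons; third-position ATA->ATG change is synonymous
  mk_seqs <- function(tnp, ena) {
    s <- c(stats::setNames(rep(tnp, 4), paste0("t", 1:4)),
           stats::setNames(rep(ena, 4), paste0("e", 1:4)))
    toy_aln(s, rep(c("TNP", "ENA"), each = 4))
  }
  model <- toy_cds_model(6L)
  p1 <- partition_sites(mk_seqs("ATAATA", "ATAATG"), model,
                        focal = "ENA", other = "TNP")
  expect_identical(p1$cds$D_S, 1L)
  expect_identical(p1$cds$D_N, 0L)
  expect_identical(p1$cds$P_N + p1$cds$P_S, 0L)

  # first-position ATA->GTA is nonsynonymous (Met -> Val)
  p2 <- partition_sites(mk_seqs("ATAATA", "ATAGTA"), model,
                        focal = "ENA", other = "TNP")
  expect_identical(p2$cds$D_N, 1L)
  expect_identical(p2$cds$D_S, 0L)

  # polymorphism within the focal clade only
  s <- c(t1 = "ATAATA", t2 = "ATAATA", e1 = "ATAATA", e2 = "ATAATG")
  p3 <- partition_sites(toy_aln(s, c("TNP", "TNP", "ENA", "ENA")), model,
                        focal = "ENA", other = "TNP")
  expect_identical(p3$cds$P_S, 1L)
  expect_identical(p3$cds$D_N + p3$cds$D_S, 0L)

  # identical clades: all zero
  p0 <- partition_sites(mk_seqs("ATAATA", "ATAATA"), model,
                        focal = "ENA", other = "TNP")
  expect_identical(sum(unlist(p0$cds[, c("D_N", "D_S", "P_N", "P_S")])),
                   0L)
})

test_that("minus-strand CDS changes are classified on the coding strand", {
  # coding sequence ATAATA lives reverse-complemented on the genome:
  # TATTAT; genome change at position 1 (T->C) is coding-strand change
  # at codon 2 position 3 (ATA->ATG), synonymous
  model <- toy_cds_model(6L, strand = "-")
  s <- c(t1 = "TATTAT", t2 = "TATTAT", e1 = "CATTAT", e2 = "CATTAT")
  p <- partition_sites(toy_aln(s, c("TNP", "TNP", "ENA", "ENA")), model,
                       focal = "ENA", other = "TNP")
  expect_identical(p$cds$D_S, 1L)
  expect_identical(p$cds$D_N, 0L)
})

test_that("ambiguous and gapped columns are excluded from all counts", {
  model <- toy_cds_model(6L)
  s <- c(t1 = "ATAATA", t2 = "ATAATA", e1 = "ATAATR", e2 = "ATAATG")
  p <- partition_sites(toy_aln(s, c("TNP", "TNP", "ENA", "ENA")), model,
                       focal = "ENA", other = "TNP")
  expect_identical(6L %in% p$excluded, TRUE)
  expect_identical(sum(unlist(p$cds[, c("D_N", "D_S", "P_N", "P_S")])),
                   0L)
})

test_that("noncoding categories are mutually exclusive and complete", {
  e <- rbind(mt_element("tRNA-phe", "tRNA", 0, 8))
  model <- mt_model(e, 8L)
  #          12345678
  s <- c(t1 = "ACGTACGT",
         t2 = "ACGTACGA",   # col 8 polymorphic in TNP (and in ENA: shared)
         e1 = "ACGTACTT",   # col 7 polymorphic in ENA only
         e2 = "TCGTACGA")   # col 1 polymorphic in ENA only
  # col 8: TNP {T,A}, ENA {T,A} -> shared
  aln <- toy_aln(s, c("TNP", "TNP", "ENA", "ENA"))
  p <- partition_sites(aln, model, focal = "ENA", other = "TNP")
  nc <- p$noncoding
  expect_identical(nc$P_focal, 2L)
  expect_identical(nc$P_other, 0L)
  expect_identical(nc$P_shared, 1L)
  expect_identical(nc$F, 0L)
  # completeness: categories sum to the number of variable usable columns
  mat <- aln$mat
  variable <- sum(vapply(seq_len(ncol(mat)),
                         function(j) length(unique(mat[, j])) > 1L, TRUE))
  expect_identical(nc$P_focal + nc$P_other + nc$P_shared + nc$F, variable)
})

test_that("partition counts are invariant to sample order and labels", {
  ds <- simulate_mitotypes(sim_config(seed = 17, n_tnp = 3, n_ena = 3))
  p1 <- partition_sites(ds$alignment, ds$model)
  perm <- rev(rownames(ds$alignment$mat))
  aln2 <- subset_samples(ds$alignment, perm)
  p2 <- partition_sites(aln2, ds$model)
  expect_identical(p1$cds, p2$cds)
  expect_identical(p1$noncoding, p2$noncoding)
})

test_that("simulator truth nonsynonymous counts reappear in D_N", {
  ds <- simulate_mitotypes(sim_config(seed = 29, het_rate = 0))
  p <- partition_sites(ds$alignment, ds$model)
  truth <- ds$truth$fixed
  # codons hit by two fixed substitutions may legitimately reclassify
  # (the partition sees the final consensus context); exclude them
  e <- ds$model$elements
  codon_id <- function(pos, el) {
    off <- if (el$strand == "+") (pos - 1L) - el$start
           else (el$end - 1L) - (pos - 1L)
    paste(el$name, off %/% 3L)
  }
  cid <- vapply(seq_len(nrow(truth)), function(k) {
    i <- match(truth$element[k], e$name)
    if (is.na(i) || e$kind[i] != "CDS") return(NA_character_)
    codon_id(truth$pos[k], e[i, ])
  }, "")
  clean <- !is.na(cid) & !(cid %in% cid[duplicated(cid)])
  clean_elements <- setdiff(
    unique(truth$element[!is.na(cid)]),
    unique(truth$element[!is.na(cid) & !clean]))
  expect_gte(length(clean_elements), 2L)
  for (el in clean_elements) {
    k_truth <- sum(truth$element == el & truth$class == "nonsynonymous",
                   na.rm = TRUE)
    expect_identical(p$cds$D_N[p$cds$element == el], k_truth,
                     label = paste("D_N of", el))
  }
})

test_that("mk_test reproduces the published neutrality indices", {
  r <- mk_test(c(D_N = 1, D_S = 35, P_N = 9, P_S = 28), element = "ND1")
  expect_equal(r$NI, (9 / 28) / (1 / 35), tolerance = 1e-12)
  expect_equal(round(r$NI, 2), 11.25)
  expect_equal(r$chi2_yates, 5.4588, tolerance = 1e-3)
  expect_identical(r$call, "purifying")
  # symmetric table: NI exactly 1, nothing significant
  r2 <- mk_test(c(5, 5, 5, 5))
  expect_identical(r2$NI, 1)
  expect_identical(r2$call, "neutral")
  expect_gt(r2$p_fisher, 0.9)
  # undefined NI and zero margins
  expect_identical(mk_test(c(0, 6, 2, 6))$call, "undefined")
  r3 <- mk_test(c(0, 0, 2, 6))
  expect_true(is.na(r3$chi2_yates))
  expect_match(r3$note, "zero margin")
})

test_that("Yates and Fisher p agree on significance for the printed tables", {
  tables <- list(ND1 = c(1, 35, 9, 28), ND2 = c(3, 38, 10, 27),
                 ND4 = c(3, 38, 8, 34), ND5 = c(5, 58, 19, 47),
                 ND6 = c(3, 18, 2, 17), CytB = c(1, 26, 5, 28))
  printed_sig <- c(ND1 = TRUE, ND2 = TRUE, ND4 = FALSE, ND5 = TRUE,
                   ND6 = FALSE, CytB = FALSE)
  for (nm in names(tables)) {
    r <- mk_test(tables[[nm]], element = nm)
    expect_identical(r$p_fisher < 0.05, unname(printed_sig[nm]),
                     label = paste("Fisher significance for", nm))
    expect_identical(r$p_yates < 0.05, unname(printed_sig[nm]),
                     label = paste("Yates significance for", nm))
  }
})

test_that("Tajima's D matches the frozen hand-computed example", {
  # n = 4, L = 10: one singleton and one 2/2-frequency site;
  # hand evaluation of the constants gives D = 0.59157 (ledgered)
  s <- c(s1 = "GCAAAAAAAA", s2 = "ACAAAAAAAA",
         s3 = "AAAAAAAAAA", s4 = "AAAAAAAAAA")
  aln <- toy_aln(s, rep("ENA", 4), population = "p1")
  r <- tajimas_d(aln, population = "p1")
  expect_identical(r$n, 4L)
  expect_identical(r$S, 2L)
  expect_equal(r$pi, 7 / 6, tolerance = 1e-12)
  expect_equal(r$D, 0.59157, tolerance = 1e-3)
  expect_false(r$significant)
})

test_that("Tajima's D degenerate inputs behave as documented", {
  mono <- toy_aln(c(a = "ACGT", b = "ACGT", c = "ACGT"), rep("ENA", 3))
  r <- tajimas_d(mono)
  expect_identical(r$S, 0L)
  expect_true(is.na(r$D))
  one <- toy_aln(c(a = "ACGT"), "ENA")
  expect_error(tajimas_d(one), "n >= 2")
  # ambiguous columns are masked before counting
  amb <- toy_aln(c(a = "ACGT", b = "ACGY", c = "ACGT"), rep("ENA", 3))
  expect_identical(tajimas_d(amb)$S, 0L)
})

test_that("star genealogies give negative D (singleton excess) mostly", {
  reps <- default_replicates()
  ds_neg <- vapply(reps, function(ds) {
    r <- tajimas_d(ds$alignment, mitotype = "ENA")
    !is.na(r$D) && r$D < 0
  }, TRUE)
  expect_gt(mean(ds_neg), 0.5)
})
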