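# shared fixtures and independent oracles for the test suite

# -- tiny alignment builders ---------------------------------------------

toy_sheet <- function(ids, mitotype, population = "pop1") {
  data.frame(sample_id = ids, mitotype = mitotype,
             population = rep_len(population, length(ids)),
             stringsAsFactors = FALSE)
}

toy_aln <- function(seqs, mitotype, population = "pop1") {
  mt_alignment(seqs, toy_sheet(names(seqs), mitotype, population))
}

# single-CDS toy model: one plus- or minus-strand gene covering [0, len)
toy_cds_model <- function(len, strand = "+", extra_noncoding = 0L) {
  e <- mt_element("ND1", "CDS", 0L, len, strand, "I")
  if (extra_noncoding > 0L)
    e <- rbind(e, mt_element("tRNA-phe", "tRNA", len,
                             len + extra_noncoding))
  mt_model(e, len + extra_noncoding)
}

# -- independent oracle: IUPAC identity by explicit enumeration ----------
# deliberately re-states the base sets instead of calling package
# internals, so that agreement is a genuine two-route check
.oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_site_identity <- function(a, b) {
  sa <- .oracle_sets[[a]]; sb <- .oracle_sets[[b]]
  hits <- 0L
  for (x in sa) for (y in sb) if (x == y) hits <- hits + 1L
  hits / (length(sa) * length(sb))
}

oracle_pairwise_identity <- function(sa, sb) {
  a <- strsplit(sa, "")[[1L]]; b <- strsplit(sb, "")[[1L]]
  scores <- c()
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") next
    scores <- c(scores, oracle_site_identity(a[k], b[k]))
  }
  100 * mean(scores)
}

rand_iupac_string <- function(n, gap_frac = 0) {
  pool <- names(.oracle_sets)
  s <- sample(pool, n, replace = TRUE)
  if (gap_frac > 0) {
    g <- which(runif(n) < gap_frac)
    s[g] <- "-"
  }
  paste(s, collapse = "")
}

# -- hand-built additive 5-taxon distance matrix -------------------------
# caterpillar tree ((A:2,B:3)U:1,C:4)V:2,(D:1,E:5)W with U-V = 1, V-W = 2
additive_5taxon <- function() {
  d <- matrix(0, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  d["A", "B"] <- 5;  d["A", "C"] <- 7;  d["A", "D"] <- 6
  d["A", "E"] <- 10; d["B", "C"] <- 8;  d["B", "D"] <- 7
  d["B", "E"] <- 11; d["C", "D"] <- 7;  d["C", "E"] <- 11
  d["D", "E"] <- 6
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# -- cached default-parameter simulation replicates ----------------------
# 20 replicates at the default config (seeds fixed a priori), shared by
# the acceptance criteria and the stochastic property tests so the suite
# pays the simulation cost once
.sim_cache <- new.env(parent = emptyenv())

default_replicates <- function() {
  if (is.null(.sim_cache$reps)) {
    .sim_cache$reps <- lapply(101:120, function(s)
      simulate_mitotypes(sim_config(seed = s)))
  }
  .sim_cache$reps
}
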