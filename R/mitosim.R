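#' Simulation configuration for a two-mitotype dataset
#'
#' The generator emulates two divergent mitochondrial haplotype clades
#' (TNP-like and ENA-like) descending from a common reference: a single
#' between-mitotype branch accumulates Poisson substitutions at rate
#' `d_between` per site, then each sample accumulates private
#' substitutions at rate `theta_within` on a star genealogy, and finally
#' heteroplasmy replaces single bases with two-base IUPAC ambiguities at
#' rate `het_rate` per site in carrier samples.
#'
#' @param seed Integer RNG seed; all draws flow from one generator.
#' @param n_tnp,n_ena Samples per mitotype (the ancestral reference can be
#'   added on top, see `include_reference`).
#' @param d_between Expected per-site between-mitotype divergence.
#'   Default 0.033, the midpoint of the observed intraspecific
#'   stickleback band (0.032-0.034).
#' @param theta_within Expected per-site within-mitotype pairwise
#'   diversity (the rate at which two samples of the same clade differ);
#'   each sample branch of the star genealogy accumulates substitutions
#'   at `theta_within / 2` per site so that sample pairs hit this rate.
#'   Default 0.002: low within-clade diversity, about one order of
#'   magnitude under the between-clade signal.
#' @param omega_by_complex Named numeric: probability that a CDS
#'   substitution is nonsynonymous, by OXPHOS complex. Defaults are
#'   anchored to the observed skew: Complex I elevated, IV/V lowest.
#' @param het_rate Per-site probability that a carrier-scope sample
#'   shows a heteroplasmic (ambiguous) call. Default 5e-5, i.e. under
#'   one ambiguous site per mitogenome on average, leaving an
#'   appreciable fraction of samples free of heteroplasmy (as observed:
#'   only some individuals of the allopatric ENA populations carry it).
#' @param het_scope `"ENA"` (default; heteroplasmy observed only in
#'   allopatric ENA fish), `"all"`, or `"none"`.
#' @param control_region Append a fast-evolving control-region block (to
#'   exercise trimming)? Default `FALSE`.
#' @param control_region_length Length of that block in bp.
#' @param include_reference Include the ancestral reference itself as a
#'   TNP sample named `"TNP_ref"` (the vs-reference profiling target)?
#' @return Object of class `mt_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tnp = 6L, n_ena = 6L,
                       d_between = 0.033,
                       theta_within = 0.002,
                       omega_by_complex = c(I = 0.15, III = 0.10,
                                            IV = 0.03, V = 0.05),
                       het_rate = 5e-5,
                       het_scope = c("ENA", "all", "none"),
                       control_region = FALSE,
                       control_region_length = 800L,
                       include_reference = TRUE) {
  het_scope <- match.arg(het_scope)
  rates <- c(d_between = d_between, theta_within = theta_within,
             het_rate = het_rate, omega_by_complex)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  if (n_tnp < 0 || n_ena < 0)
    stop("sample sizes must be >= 0", call. = FALSE)
  if (!all(c("I", "III", "IV", "V") %in% names(omega_by_complex)))
    stop("omega_by_complex must name complexes I, III, IV, V",
         call. = FALSE)
  structure(list(seed = as.integer(seed), n_tnp = as.integer(n_tnp),
                 n_ena = as.integer(n_ena), d_between = d_between,
                 theta_within = theta_within,
                 omega_by_complex = omega_by_complex,
                 het_rate = het_rate, het_scope = het_scope,
                 control_region = isTRUE(control_region),
                 control_region_length = as.integer(control_region_length),
                 include_reference = isTRUE(include_reference)),
            class = "mt_sim_config")
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.ACGT <- c("A", "C", "G", "T")
.PAIR_SYMBOL <- c(AC = "M", AG = "R", AT = "W",
                  CG = "S", CT = "Y", GT = "K")

#' Generate the reference mitogenome and its model
#'
#' Produces the default annotated template with a random sequence whose
#' CDSs are valid under the vertebrate mitochondrial code: a canonical
#' start codon (ATG/ATA/GTG), no internal stop, and a stop codon (or the
#' 1-2 bp of an incomplete stop completed by polyadenylation) at the end.
#'
#' @param seed Integer seed, or `NULL` to draw from the current RNG
#'   stream.
#' @return List with `model` ([mt_model]) and `sequence` (character
#'   vector of single bases).
#' @export
make_reference <- function(seed = 1L) {
  gen <- function() {
    model <- default_mito_model()
    bg <- sample(.ACGT, model$sequence_length, replace = TRUE)
    code <- mito_code()
    stops <- names(code)[code == "*"]
    sense <- setdiff(names(code), stops)
    starts <- c("ATG", "ATA", "GTG")
    for (i in seq_len(nrow(model$elements))) {
      el <- model$elements[i, ]
      if (el$kind != "CDS") next
      len <- el$end - el$start
      n_codon <- len %/% 3L
      tail_len <- len %% 3L
      codons <- c(sample(starts, 1L),
                  sample(sense, n_codon - 2L, replace = TRUE),
                  if (tail_len == 0L) sample(stops, 1L)
                  else sample(sense, 1L))
      cds <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1L]]
      # incomplete terminal stop: trailing T / TA completed in vivo
      if (tail_len == 1L) cds <- c(cds, "T")
      if (tail_len == 2L) cds <- c(cds, "T", "A")
      if (el$strand == "-") cds <- revcomp(cds)
      bg[(el$start + 1L):el$end] <- cds
    }
    list(model = model, sequence = bg)
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

# per-position annotation index: element row index (NA = intergenic)
.site_index <- function(model) {
  idx <- rep(NA_integer_, model$sequence_length)
  for (i in seq_len(nrow(model$elements))) {
    el <- model$elements[i, ]
    idx[(el$start + 1L):el$end] <- i
  }
  idx
}

# coding-strand codon context of genome position p (1-based) inside a CDS;
# NULL when p sits in the incomplete terminal codon
.codon_context <- function(bg, el, p) {
  offset <- if (el$strand == "+") (p - 1L) - el$start
            else (el$end - 1L) - (p - 1L)
  len <- el$end - el$start
  if (offset >= 3L * (len %/% 3L)) return(NULL)
  ci <- offset %/% 3L
  j <- 3L * ci + 0:2               # coding-strand positions of the codon
  gpos <- if (el$strand == "+") el$start + j + 1L else el$end - j
  codon <- bg[gpos]
  if (el$strand == "-") codon <- iupac_complement(codon)
  list(codon = codon, pos_in_codon = offset %% 3L + 1L)
}

# substitute one site; want_class NULL = unconstrained, otherwise
# "synonymous"/"nonsynonymous"; returns NULL if the requested class has
# no single-base alternative at this site
.draw_substitution <- function(bg, model, site_idx, p, want_class = NULL) {
  ei <- site_idx[p]
  el <- if (!is.na(ei)) model$elements[ei, ] else NULL
  in_codon <- FALSE
  if (!is.null(el) && el$kind == "CDS") {
    ctx <- .codon_context(bg, el, p)
    if (!is.null(ctx)) in_codon <- TRUE
  }
  if (!in_codon) {
    cur <- bg[p]
    alt <- sample(setdiff(.ACGT, cur), 1L)
    return(list(to = alt, class = NA_character_,
                element = if (is.null(el)) NA_character_ else el$name))
  }
  cur_coding <- ctx$codon[ctx$pos_in_codon]
  alts <- setdiff(.ACGT, cur_coding)
  classes <- vapply(alts, function(a)
    .classify_base_change(paste(ctx$codon, collapse = ""),
                          ctx$pos_in_codon, a), "")
  pick_from <- if (is.null(want_class)) alts
               else alts[classes == want_class]
  if (!length(pick_from)) return(NULL)
  alt <- if (length(pick_from) == 1L) pick_from else sample(pick_from, 1L)
  list(to = if (el$strand == "+") alt else iupac_complement(alt),
       class = classes[[match(alt, alts)]], element = el$name)
}

# place n substitutions on one branch; CDS sites draw their target class
# from omega_by_complex; sites with no alternative of the requested class
# are re-drawn elsewhere
.place_substitutions <- function(bg, model, site_idx, n, omega,
                                 forbidden = integer(0)) {
  L <- length(bg)
  rec <- vector("list", n)
  used <- forbidden
  placed <- 0L
  guard <- 0L
  while (placed < n) {
    guard <- guard + 1L
    if (guard > 50L * n + 1000L)
      stop("substitution placement failed to converge", call. = FALSE)
    p <- sample.int(L, 1L)
    if (p %in% used) next
    ei <- site_idx[p]
    want <- NULL
    if (!is.na(ei) && model$elements$kind[ei] == "CDS") {
      cx <- model$elements$complex[ei]
      want <- if (stats::runif(1L) < omega[[cx]]) "nonsynonymous"
              else "synonymous"
    }
    d <- .draw_substitution(bg, model, site_idx, p, want)
    if (is.null(d)) next   # no alternative of the requested class here
    rec[[placed + 1L]] <- data.frame(
      pos = p, element = d$element, class = d$class,
      from = bg[p], to = d$to, stringsAsFactors = FALSE)
    bg[p] <- d$to
    used <- c(used, p)
    placed <- placed + 1L
  }
  list(sequence = bg,
       record = if (n) do.call(rbind, rec)
                else data.frame(pos = integer(0), element = character(0),
                                class = character(0), from = character(0),
                                to = character(0)))
}

#' Simulate a two-mitotype aligned dataset
#'
#' See [sim_config] for the generative model. Substitutions are
#' single-nucleotide (no indels, so the simulated sequences are already
#' aligned); within-clade mutations avoid sites carrying the fixed
#' between-clade substitution so that fixed and polymorphic categories
#' stay cleanly separable in the truth record.
#'
#' @param config A configuration from [sim_config].
#' @return Object of class `mt_sim_dataset`: list with `alignment`
#'   ([mt_alignment]), `model` ([mt_model]), `reference` (character
#'   vector), and `truth` (fixed/polymorphic/heteroplasmy records plus
#'   per-element fixed counts).
#' @export
simulate_mitotypes <- function(config = sim_config()) {
  stopifnot(inherits(config, "mt_sim_config"))
  ref <- make_reference(config$seed)
  .with_seed(config$seed, {
    model <- ref$model
    bg <- ref$sequence
    L <- model$sequence_length
    site_idx <- .site_index(model)
    omega <- config$omega_by_complex

    n_fix <- stats::rpois(1L, config$d_between * L)
    anc <- .place_substitutions(bg, model, site_idx, n_fix, omega)
    fixed <- anc$record
    fixed_sites <- fixed$pos

    ids <- c(if (config$include_reference) "TNP_ref",
             if (config$n_tnp) paste0("TNP_", seq_len(config$n_tnp)),
             if (config$n_ena) paste0("ENA_", seq_len(config$n_ena)))
    if (is.null(ids)) ids <- character(0)
    mito <- ifelse(startsWith(ids, "TNP"), "TNP", "ENA")
    pop <- ifelse(ids == "TNP_ref", "Alaska",
                  ifelse(mito == "TNP", "Japan", "Oregon"))
    seqs <- matrix(NA_character_, nrow = length(ids), ncol = L,
                   dimnames = list(ids, NULL))
    poly <- list()
    for (i in seq_along(ids)) {
      base_seq <- if (mito[i] == "TNP") bg else anc$sequence
      if (ids[i] == "TNP_ref") {
        seqs[i, ] <- base_seq
        next
      }
      k <- stats::rpois(1L, config$theta_within / 2 * L)
      s <- .place_substitutions(base_seq, model, site_idx, k, omega,
                                forbidden = fixed_sites)
      seqs[i, ] <- s$sequence
      if (nrow(s$record)) {
        s$record$sample <- ids[i]
        poly[[length(poly) + 1L]] <- s$record
      }
    }
    poly <- if (length(poly)) do.call(rbind, poly)
            else data.frame(pos = integer(0), element = character(0),
                            class = character(0), from = character(0),
                            to = character(0), sample = character(0))

    # heteroplasmy last: replace a base with the two-base symbol joining
    # it to a random alternative allele
    het <- list()
    carriers <- switch(config$het_scope,
                       ENA = ids[mito == "ENA"],
                       all = ids,
                       none = character(0))
    if (config$het_rate > 0 && length(carriers)) {
      for (id in carriers) {
        hs <- which(stats::runif(L) < config$het_rate)
        for (p in hs) {
          b <- seqs[id, p]
          other <- sample(setdiff(.ACGT, b), 1L)
          pair <- paste(sort(c(b, other)), collapse = "")
          seqs[id, p] <- .PAIR_SYMBOL[[pair]]
          het[[length(het) + 1L]] <- data.frame(
            sample = id, pos = p, symbol = .PAIR_SYMBOL[[pair]],
            stringsAsFactors = FALSE)
        }
      }
    }
    het <- if (length(het)) do.call(rbind, het)
           else data.frame(sample = character(0), pos = integer(0),
                           symbol = character(0))

    # optional fast-evolving control region appended at the 3' end
    if (config$control_region) {
      crl <- config$control_region_length
      cr_ref <- sample(.ACGT, crl, replace = TRUE)
      cr_anc <- cr_ref
      n_cr <- stats::rpois(1L, 5 * config$d_between * crl)
      for (p in sample.int(crl, min(n_cr, crl)))
        cr_anc[p] <- sample(setdiff(.ACGT, cr_anc[p]), 1L)
      cr_mat <- matrix(NA_character_, length(ids), crl)
      for (i in seq_along(ids))
        cr_mat[i, ] <- if (mito[i] == "TNP") cr_ref else cr_anc
      seqs <- cbind(seqs, cr_mat)
      e <- rbind(model$elements,
                 mt_element("control-region", "control", L, L + crl))
      model <- mt_model(e, L + crl, control_region = c(L, L + crl))
    }

    samples <- data.frame(sample_id = ids, mitotype = mito,
                          population = pop, stringsAsFactors = FALSE)
    fixed_by_element <- table(factor(fixed$element,
                                     levels = model$elements$name))
    truth <- list(
      seed = config$seed,
      d_between_realized = n_fix / L,
      fixed = fixed, polymorphic = poly, heteroplasmy = het,
      fixed_by_element = as.list(fixed_by_element),
      config = unclass(config))
    structure(list(alignment = mt_alignment(seqs, samples),
                   model = model, reference = ref$sequence,
                   truth = truth),
              class = "mt_sim_dataset")
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the aligned FASTA, the GFF3 annotation, the TSV sample sheet and
#' a truth JSON; the FASTA/sheet pair round-trips through
#' [load_alignment].
#'
#' @param dataset An `mt_sim_dataset` from [simulate_mitotypes].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "mt_sim_dataset"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- c(fasta = file.path(out_dir, "alignment.fasta"),
             sheet = file.path(out_dir, "samples.tsv"),
             gff3 = file.path(out_dir, "annotation.gff3"),
             truth = file.path(out_dir, "truth.json"),
             reference = file.path(out_dir, "reference.fasta"))
  ok <- tryCatch({
    write_alignment(dataset$alignment, paths[["fasta"]],
                    paths[["sheet"]])
    write_gff3(dataset$model, paths[["gff3"]])
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(c(reference = paste(dataset$reference,
                                                 collapse = ""))),
      paths[["reference"]], width = 80L)
    jsonlite::write_json(dataset$truth, paths[["truth"]],
                         auto_unbox = TRUE, digits = NA, null = "null")
    TRUE
  }, error = function(e)
    stop("failed writing dataset under '", out_dir, "': ",
         conditionMessage(e), call. = FALSE))
  paths
}
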