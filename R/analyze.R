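.stop_stats <- function(...) {
  stop(structure(class = c("mt_stats_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}

#' One-way ANOVA with Tukey HSD over identity profiles
#'
#' Tests whether per-pair percent identity differs among elements (or
#' among OXPHOS complexes), with Tukey's honestly-significant-difference
#' post hoc on all unordered group pairs. The genome-wide mean identity
#' is carried along as the baseline the groups deviate from.
#'
#' @param profiles An `mt_profiles` data frame from [profile_elements].
#' @param grouping `"element"` or `"complex"`.
#' @param alpha Significance threshold used by the summary counts.
#' @return Object of class `mt_groupstats`: list with `grouping`,
#'   `anova_F`, `anova_p`, `tukey` (data frame: `pair`, `diff`, `lwr`,
#'   `upr`, `p_adj`), `baseline`, `n_significant`.
#' @export
group_anova <- function(profiles, grouping = c("element", "complex"),
                        alpha = 0.05) {
  grouping <- match.arg(grouping)
  d <- profiles[profiles$scope == grouping, , drop = FALSE]
  d <- d[!is.na(d$identity), , drop = FALSE]
  if (!nrow(d)) .stop_stats("no profile rows at scope '", grouping, "'")
  tab <- table(d$name)
  if (length(tab) < 2L)
    .stop_stats("ANOVA needs >= 2 groups, got ", length(tab))
  small <- names(tab)[tab < 2L]
  if (length(small))
    .stop_stats("degenerate group(s) with < 2 values: ",
                paste(small, collapse = ", "))
  d$group <- factor(d$name)
  fit <- stats::aov(identity ~ group, data = d)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(grouping = grouping,
                 anova_F = an[["F value"]][1L],
                 anova_p = an[["Pr(>F)"]][1L],
                 tukey = tukey,
                 baseline = attr(profiles, "baseline"),
                 n_significant = sum(tukey$p_adj < alpha, na.rm = TRUE)),
            class = "mt_groupstats")
}

#' @export
print.mt_groupstats <- function(x, ...) {
  cat("<group ANOVA by ", x$grouping, "> F=", signif(x$anova_F, 4),
      ", p=", signif(x$anova_p, 3), "; ", x$n_significant,
      " significant Tukey pair(s); baseline identity ",
      signif(x$baseline, 5), "%\n", sep = "")
  invisible(x)
}

#' Regression of per-element mean identity on element length
#'
#' Ordinary least squares of mean percent identity against element
#' length (bp), reported with the adjusted R-squared
#' `1 - (1 - R2) (n - 1) / (n - 2)`; used to ask whether short elements
#' merely look more (or less) divergent because of their size.
#'
#' @param profiles An `mt_profiles` data frame.
#' @param kind `"CDS"` for protein-coding elements, `"noncoding"` for
#'   tRNA + rRNA.
#' @return Object of class `mt_regression`: list with `kind`, `n`,
#'   `slope`, `intercept`, `adjusted_R2`, `p_value`, and the per-element
#'   `points`.
#' @export
identity_length_regression <- function(profiles,
                                       kind = c("CDS", "noncoding")) {
  kind <- match.arg(kind)
  d <- profiles[profiles$scope == "element", , drop = FALSE]
  d <- if (kind == "CDS") d[d$kind == "CDS", , drop = FALSE]
       else d[d$kind %in% c("tRNA", "rRNA"), , drop = FALSE]
  if (!nrow(d)) .stop_stats("no elements of kind '", kind, "'")
  agg <- stats::aggregate(identity ~ name + length, data = d, FUN = mean)
  if (nrow(agg) < 3L)
    .stop_stats("regression needs >= 3 elements, got ", nrow(agg))
  fit <- stats::lm(identity ~ length, data = agg)
  sm <- suppressWarnings(summary(fit))
  coefs <- stats::coef(fit)
  p <- tryCatch(stats::coef(sm)[2L, 4L], error = function(e) NA_real_)
  structure(list(kind = kind, n = nrow(agg),
                 slope = unname(coefs[2L]),
                 intercept = unname(coefs[1L]),
                 adjusted_R2 = sm$adj.r.squared,
                 p_value = p, points = agg),
            class = "mt_regression")
}

#' @export
print.mt_regression <- function(x, ...) {
  cat("<identity ~ length, ", x$kind, "> n=", x$n, ", slope=",
      signif(x$slope, 4), ", adjusted R2=", signif(x$adjusted_R2, 3),
      ", p=", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

# ---- pipeline -----------------------------------------------------------

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full two-mitotype analysis pipeline
#'
#' Orchestrates: data acquisition (simulation or files), control-region
#' trimming, identity profiling, divergence summary, MK tests, Tajima's
#' D per population, the conservative NJ tree, and the group statistics,
#' writing report tables (divergence summary, MK table, non-coding
#' polymorphism table, long-format identity profiles), the Newick tree,
#' the distance matrix, and a run log. Outputs are deterministic for a
#' fixed config and seed. On any stage failure, partial outputs are
#' removed and the stage is named in the error.
#'
#' @param config A list. Either `simulation = list(...)` with
#'   [sim_config] arguments, or `fasta`, `sheet` and `gff3` paths.
#'   Optional entries: `pairing`, `focal`, `other`,
#'   `drop_heteroplasmic`.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the simulation seed.
#' @return Named list of outputs (`paths` plus the in-memory results),
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  emit <- function(d, name) {
    p <- .write_tsv(d, file.path(out_dir, name))
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  focal <- config$focal %||% "ENA"
  other <- config$other %||% "TNP"
  pairing <- config$pairing %||% "vs-reference"

  dataset <- stage("input", {
    if (!is.null(config$simulation)) {
      args <- config$simulation
      if (!is.null(seed)) args$seed <- seed
      cfg <- do.call(sim_config, args)
      note("simulation seed: ", cfg$seed)
      simulate_mitotypes(cfg)
    } else {
      if (is.null(config$fasta) || is.null(config$sheet) ||
            is.null(config$gff3))
        stop("config must give either a simulation block or fasta + ",
             "sheet + gff3 paths")
      list(alignment = load_alignment(config$fasta, config$sheet),
           model = read_gff3(config$gff3), reference = NULL)
    }
  })

  trimmed <- stage("trim", trim_to_coding(dataset$alignment,
                                          dataset$model))
  aln <- trimmed$alignment
  model <- trimmed$model
  note("alignment: ", n_samples(aln), " samples x ", n_columns(aln),
       " columns after trimming")

  profiles <- stage("profile",
                    profile_elements(aln, model, pairing = pairing,
                                     focal = focal, other = other))
  stage("profile", {
    emit(profiles[profiles$scope %in% c("element", "genome"),
                  c("name", "kind", "complex", "length", "sample_a",
                    "sample_b", "identity")], "fig2_identity_long.tsv")
    emit(profiles[profiles$scope == "complex",
                  c("name", "complex", "length", "sample_a", "sample_b",
                    "identity")], "fig3_complex_long.tsv")
  })
  note("genome-wide baseline identity: ",
       format(attr(profiles, "baseline"), digits = 8), "%")

  divergence <- stage("divergence", {
    ds <- divergence_summary(aln, focal = focal, other = other)
    emit(data.frame(comparison = paste0(other, " vs. ", focal),
                    mean = ds$mean, min = ds$min, max = ds$max),
         "table1_divergence.tsv")
    ds
  })

  has_cds <- any(model$elements$kind == "CDS")
  mk <- NULL
  partition <- NULL
  if (has_cds || any(model$elements$kind %in% c("tRNA", "rRNA"))) {
    partition <- stage("popgen",
                       partition_sites(aln, model, focal = focal,
                                       other = other))
    if (has_cds) {
      mk <- stage("popgen", {
        m <- mk_test_all(partition)
        emit(m, "table2_mk.tsv")
        m
      })
    } else note("MK stage skipped: no CDS elements in the model")
    stage("popgen", emit(partition$noncoding, "table3_noncoding.tsv"))
  } else note("popgen stage skipped: no annotated elements")

  tajima <- stage("tajima", {
    pops <- unique(aln$samples$population)
    rows <- lapply(pops, function(p) {
      if (sum(aln$samples$population == p) < 2L) return(NULL)
      r <- tajimas_d(aln, population = p)
      data.frame(population = p, n = r$n, S = r$S, pi = r$pi, D = r$D,
                 significant = r$significant)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    t <- if (length(rows)) do.call(rbind, rows)
         else data.frame(population = character(0), n = integer(0),
                         S = integer(0), pi = numeric(0), D = numeric(0),
                         significant = logical(0))
    emit(t, "tajima.tsv")
    t
  })

  tree <- NULL
  drop_het <- isTRUE(config$drop_heteroplasmic %||% TRUE)
  if (n_samples(aln) >= 3L) {
    tree <- stage("tree", {
      tr <- mitotype_tree(aln, drop_heteroplasmic = drop_het,
                          newick_path = file.path(out_dir, "tree.nwk"))
      written <<- c(written, file.path(out_dir, "tree.nwk"))
      emit(data.frame(sample = rownames(tr$distances),
                      as.data.frame(tr$distances)), "distances.tsv")
      tr
    })
  } else note("tree stage skipped: fewer than 3 samples")

  stats_out <- stage("group-stats", {
    res <- list()
    for (g in c("element", "complex")) {
      gs <- tryCatch(group_anova(profiles, g),
                     mt_stats_error = function(e) {
                       note("ANOVA (", g, ") skipped: ",
                            conditionMessage(e))
                       NULL
                     })
      if (!is.null(gs)) {
        emit(gs$tukey, paste0("tukey_", g, ".tsv"))
        res[[paste0("anova_", g)]] <- gs
      }
    }
    regs <- list()
    for (k in c("CDS", "noncoding")) {
      rg <- tryCatch(identity_length_regression(profiles, k),
                     mt_stats_error = function(e) {
                       note("regression (", k, ") skipped: ",
                            conditionMessage(e))
                       NULL
                     })
      if (!is.null(rg))
        regs[[k]] <- data.frame(kind = k, n = rg$n, slope = rg$slope,
                                intercept = rg$intercept,
                                adjusted_R2 = rg$adjusted_R2,
                                p_value = rg$p_value)
    }
    if (length(regs))
      emit(do.call(rbind, regs), "regression.tsv")
    res$regressions <- regs
    res
  })

  stage("log", {
    hdr <- c(paste0("mitotyper ",
                    as.character(utils::packageVersion("mitotyper"))),
             paste0("pairing: ", pairing, "; focal: ", focal,
                    "; other: ", other),
             paste0("config: ",
                    jsonlite::toJSON(config, auto_unbox = TRUE,
                                     digits = NA, null = "null")))
    writeLines(c(hdr, log_lines), file.path(out_dir, "run_log.txt"))
    written <<- c(written, file.path(out_dir, "run_log.txt"))
  })

  invisible(list(paths = written, alignment = aln, model = model,
                 profiles = profiles, divergence = divergence,
                 partition = partition, mk = mk, tajima = tajima,
                 tree = tree, stats = stats_out, log = log_lines))
}
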