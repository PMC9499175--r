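# group statistics, regression, pipeline orchestration, CLI

fake_profiles <- function(groups, values_by_group, scope = "element") {
  rows <- do.call(rbind, lapply(groups, function(g) {
    v <- values_by_group[[g]]
    data.frame(scope = scope, name = g, kind = "CDS", complex = "I",
               length = 500L, sample_a = "ref",
               sample_b = paste0("s", seq_along(v)), identity = v,
               stringsAsFactors = FALSE)
  }))
  attr(rows, "baseline") <- mean(unlist(values_by_group))
  class(rows) <- c("mt_profiles", class(rows))
  rows
}

test_that("two-group ANOVA agrees with the t-test (F = t^2)", {
  set.seed(23)
  a <- 90 + rnorm(8, sd = 0.5)
  b <- 99 + rnorm(8, sd = 0.5)
  pr <- fake_profiles(c("gA", "gB"), list(gA = a, gB = b))
  gs <- group_anova(pr, "element")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(gs$anova_F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(gs$anova_p, tt$p.value, tolerance = 1e-8)
  expect_identical(nrow(gs$tukey), 1L)
  expect_lt(gs$tukey$p_adj, 0.05)
  expect_identical(gs$n_significant, 1L)
})

test_that("constant groups yield no significant Tukey pairs", {
  pr <- fake_profiles(c("gA", "gB"),
                      list(gA = rep(95, 4), gB = rep(95, 4)))
  gs <- group_anova(pr, "element")
  expect_identical(gs$n_significant, 0L)
})

test_that("ANOVA contract errors name the offending group", {
  pr <- fake_profiles(c("gA", "gB"), list(gA = c(1, 2), gB = 3))
  expect_error(group_anova(pr, "element"), "gB")
  pr1 <- fake_profiles("gA", list(gA = c(1, 2)))
  expect_error(group_anova(pr1, "element"), ">= 2 groups")
})

test_that("Tukey enumerates all unordered group pairs with p in [0,1]", {
  set.seed(29)
  vals <- lapply(1:4, function(i) 90 + i + rnorm(5))
  names(vals) <- paste0("g", 1:4)
  gs <- group_anova(fake_profiles(names(vals), vals), "element")
  expect_identical(nrow(gs$tukey), 6L)
  expect_true(all(gs$tukey$p_adj >= 0 & gs$tukey$p_adj <= 1))
})

test_that("identity-length regression handles exact and degenerate fits", {
  mk_pr <- function(lengths, identities) {
    rows <- data.frame(scope = "element", name = paste0("e", seq_along(lengths)),
                       kind = "CDS", complex = "I", length = lengths,
                       sample_a = "ref", sample_b = "s1",
                       identity = identities, stringsAsFactors = FALSE)
    class(rows) <- c("mt_profiles", class(rows))
    rows
  }
  # perfectly collinear points
  r <- identity_length_regression(mk_pr(c(100, 200, 300, 400),
                                        c(90, 92, 94, 96)), "CDS")
  expect_equal(r$adjusted_R2, 1, tolerance = 1e-9)
  expect_equal(r$slope, 0.02, tolerance = 1e-9)
  # zero slope
  r0 <- identity_length_regression(mk_pr(c(100, 200, 300),
                                         c(95, 95, 95)), "CDS")
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_error(identity_length_regression(mk_pr(c(100, 200), c(1, 2)),
                                          "CDS"), ">= 3 elements")
})

test_that("length carries no identity signal under the uniform simulator", {
  ds <- simulate_mitotypes(sim_config(seed = 43))
  pr <- profile_elements(ds$alignment, ds$model)
  r <- identity_length_regression(pr, "noncoding")
  # per-site rates are length-independent: adjusted R2 stays near zero
  expect_lt(abs(r$adjusted_R2), 0.5)
  expect_identical(r$n, 24L)
})

test_that("run_pipeline writes a complete, parseable, deterministic bundle", {
  cfg <- list(simulation = list(seed = 3, n_tnp = 3, n_ena = 3,
                                control_region = TRUE))
  out1 <- tempfile(); out2 <- tempfile()
  res <- run_pipeline(cfg, out1)
  expected_files <- c("fig2_identity_long.tsv", "fig3_complex_long.tsv",
                      "table1_divergence.tsv", "table2_mk.tsv",
                      "table3_noncoding.tsv", "tajima.tsv", "tree.nwk",
                      "distances.tsv", "tukey_element.tsv",
                      "tukey_complex.tsv", "regression.tsv",
                      "run_log.txt")
  for (f in expected_files)
    expect_true(file.exists(file.path(out1, f)), label = f)
  # tables parse and have the documented shapes
  mk <- utils::read.delim(file.path(out1, "table2_mk.tsv"))
  expect_identical(names(mk)[1:8],
                   c("Protein", "Length", "D_N", "D_S", "P_N", "P_S",
                     "NI", "P_Yates"))
  expect_identical(nrow(mk), 13L)
  t1 <- utils::read.delim(file.path(out1, "table1_divergence.tsv"))
  expect_true(t1$min <= t1$mean && t1$mean <= t1$max)
  expect_s3_class(ape::read.tree(file.path(out1, "tree.nwk")), "phylo")
  # control region was trimmed before analysis
  expect_false("control-region" %in% res$model$elements$name)
  # genome baseline in the long table equals a recomputation
  fig2 <- utils::read.delim(file.path(out1, "fig2_identity_long.tsv"))
  g <- fig2[fig2$name == "genome", ]
  expect_equal(mean(g$identity), attr(res$profiles, "baseline"),
               tolerance = 1e-9)

  run_pipeline(cfg, out2)
  for (f in expected_files)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
})

test_that("pipeline skips the MK stage gracefully without CDS elements", {
  dir <- tempfile(); dir.create(dir)
  seqs <- c(TNP_1 = strrep("ACGT", 30), TNP_2 = strrep("ACGT", 30),
            ENA_1 = strrep("ACGA", 30), ENA_2 = strrep("ACGA", 30))
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), file.path(dir, "aln.fasta"))
  utils::write.table(toy_sheet(names(seqs),
                               c("TNP", "TNP", "ENA", "ENA")),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gff3(mt_model(mt_element("tRNA-phe", "tRNA", 0, 120), 120L),
             file.path(dir, "ann.gff3"))
  out <- tempfile()
  res <- run_pipeline(list(fasta = file.path(dir, "aln.fasta"),
                           sheet = file.path(dir, "samples.tsv"),
                           gff3 = file.path(dir, "ann.gff3")), out)
  expect_false(file.exists(file.path(out, "table2_mk.tsv")))
  expect_true(any(grepl("MK stage skipped", res$log)))
  expect_true(file.exists(file.path(out, "table3_noncoding.tsv")))
})

test_that("pipeline failures name the stage and clean partial outputs", {
  out <- tempfile()
  expect_error(run_pipeline(list(fasta = "nope.fasta"), out),
               "stage 'input'")
  expect_identical(list.files(out), character(0))
})

test_that("the CLI runs simulate and report end to end", {
  out <- tempfile()
  expect_identical(suppressMessages(
    mitotyper_cli(c("simulate", "--out", out, "--seed", "9"))), 0L)
  expect_true(file.exists(file.path(out, "alignment.fasta")))
  rep_out <- tempfile()
  cfgfile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(simulation = list(n_tnp = 2, n_ena = 2)),
                       cfgfile, auto_unbox = TRUE)
  expect_identical(
    suppressMessages(mitotyper_cli(c("report", "--config", cfgfile,
                                     "--out", rep_out, "--seed", "5"))),
    0L)
  expect_true(file.exists(file.path(rep_out, "table2_mk.tsv")))
  expect_identical(suppressMessages(mitotyper_cli("frobnicate")), 2L)
  expect_identical(suppressMessages(
    mitotyper_cli(c("profile", "--out", tempfile()))), 2L)
})
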