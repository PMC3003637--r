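test_that("bundled fixtures carry exactly the printed rows, guarded by checksum", {
  tabs <- all_study_tables()
  expect_equal(vapply(tabs, nrow, integer(1), USE.NAMES = FALSE),
               c(50L, 26L, 8L))
  sums <- tools::md5sum(vapply(
    c("table1_model_peptides.csv", "table2_sasp_dprpE.csv",
      "table3_sasp_168.csv", "average_masses.tsv"),
    qsrrpep_extdata, character(1)))
  expect_equal(unname(sums),
               c("3ba6e4fa01740d912fd4cee1237203db",
                 "935e8fdf7697e121489502fd2f8b0947",
                 "9b4a09cdb3b3e0ed776b8f13fcb906bf",
                 "fa68e03653bfaed54f425dfe1a7da79e"))
  # spot-checks of verbatim transcription, typos included
  t1 <- tabs$calibration
  expect_equal(t1$log_sum_k1[t1$peptide_sequence == "YICENQDTISSKL"], 1.4238)
  expect_equal(t1$delta_t_r[t1$peptide_sequence == "YICENQDTISSKL"], 1.24)
  # the anomaly sidecar documents rather than edits them
  an <- table_anomalies()
  expect_true("YICENQDTISSKL" %in% an$peptide_sequence)
  expect_true("ANNNSGNSNNLLVPGAAQAIDQMK" %in% an$peptide_sequence)
})

test_that("reading validates columns and cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("protein,peptide_sequence,mz\np1,AAK,300.5", f)
  tab <- read_peptide_table(f)
  expect_equal(tab$mz, 300.5)
  expect_error(read_peptide_table(f, required = c("charge")),
               "mandatory column\\(s\\) missing.*charge")
  writeLines("protein,peptide_sequence,mz\np1,AAK,oops", f)
  expect_error(read_peptide_table(f), "row 1, column 'mz'")
  # header-only file reads as zero records
  writeLines("protein,peptide_sequence,mz,charge", f)
  expect_equal(nrow(read_peptide_table(f)), 0L)
  expect_error(read_peptide_table(file.path(tempdir(), "nope.csv")),
               "no such file")
})

test_that("tables round-trip at the declared precision, in both dialects", {
  cl <- classify_table(study_table("dprpE"))
  for (dialect in c("csv", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_peptide_table(cl, f, dialect)
    back <- read_peptide_table(f, dialect)
    expect_equal(table_stage(back), "classified")
    expect_equal(back$peptide_sequence, cl$peptide_sequence)
    expect_equal(back$group, cl$group)
    expect_equal(back$t_r_exp, round(cl$t_r_exp, 2))
    expect_equal(back$log_sum_k1, round(cl$log_sum_k1, 4))
    expect_equal(back$mz, round(cl$mz, 4))
  }
  # rounding convention: descriptors at 4 decimals
  tab <- data.frame(protein = "p", peptide_sequence = "AAK",
                    log_sum_k1 = 1.14613)
  f <- withr::local_tempfile(fileext = ".csv")
  write_peptide_table(tab, f)
  expect_true(any(grepl("1.1461", readLines(f), fixed = TRUE)))
})

test_that("round-trip stability holds for arbitrary generated tables", {
  set.seed(73)
  for (s in 1:3) {
    syn <- generate_synthetic(synthetic_config(n_peptides = 15, seed = s))
    f <- withr::local_tempfile(fileext = ".csv")
    write_peptide_table(syn$table, f)
    back <- read_peptide_table(f)
    f2 <- withr::local_tempfile(fileext = ".csv")
    write_peptide_table(back, f2)
    expect_equal(readLines(f), readLines(f2))  # fixed point after one cycle
  }
})

test_that("the synthetic generator is seed-deterministic with exact descriptors", {
  cfg <- synthetic_config(n_peptides = 30, seed = 99)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$is_true, b$truth$is_true)
  c2 <- generate_synthetic(synthetic_config(n_peptides = 30, seed = 100))
  expect_false(identical(a$table, c2$table))
  # descriptors come exactly from the generating factor table
  ls <- vapply(a$table$peptide_sequence, log_sum_descriptor, numeric(1),
               kt = a$truth$k_table, USE.NAMES = FALSE)
  expect_equal(a$table$log_sum_k1, ls)
  # noise-free retention truth is the model prediction
  expect_equal(a$truth$t_r_true,
               predict_rt(a$truth$model, a$table$log_sum_k1,
                          a$table$clogp))
})

test_that("fitted residual scale concentrates around the generating sigma", {
  # SSE/sigma^2 ~ chi-squared(n-3): s in [1.0, 1.9] nearly always at n=50
  s_fit <- vapply(1:120, function(s) {
    fit_qsrr(generate_synthetic(synthetic_config(seed = s))$table)$stats$s
  }, numeric(1))
  expect_gte(mean(s_fit >= 1.0 & s_fit <= 1.9), 0.95)
})

cli_run <- function(...) qsrrpep_cli(c(...))

test_that("cli fit/predict/classify pipeline runs end to end", {
  dir <- withr::local_tempdir()
  model_f <- file.path(dir, "model.txt")
  expect_equal(suppressMessages(cli_run(
    "fit", "--in", qsrrpep_extdata("table1_model_peptides.csv"),
    "--out", model_f)), 0L)
  model_lines <- readLines(model_f)
  expect_true(any(grepl("^n\t50$", model_lines)))

  pred_f <- file.path(dir, "pred.csv")
  expect_equal(suppressMessages(cli_run(
    "predict", "--model", model_f,
    "--in", qsrrpep_extdata("table2_sasp_dprpE.csv"),
    "--out", pred_f)), 0L)
  expect_true("t_r_pred" %in% names(read_peptide_table(pred_f)))

  class_f <- file.path(dir, "classified.csv")
  report_f <- file.path(dir, "report.txt")
  expect_equal(suppressMessages(cli_run(
    "classify", "--in", qsrrpep_extdata("table3_sasp_168.csv"),
    "--out", class_f, "--report", report_f, "--label", "168")), 0L)
  expect_true(any(grepl("POTENTIAL_FALSE_POSITIVE (none)",
                        readLines(report_f), fixed = TRUE)))
  expect_true("group" %in% names(read_peptide_table(class_f)))
})

test_that("cli handles degenerate inputs and bad invocations", {
  dir <- withr::local_tempdir()
  # predict on a zero-row table exits 0 with empty output
  model_f <- file.path(dir, "m.txt")
  write_qsrr_model(published_model(), model_f)
  empty_f <- file.path(dir, "empty.csv")
  writeLines("protein,peptide_sequence,log_sum_k1,clogp", empty_f)
  out_f <- file.path(dir, "out.csv")
  expect_equal(suppressMessages(cli_run(
    "predict", "--model", model_f, "--in", empty_f, "--out", out_f)), 0L)
  expect_equal(nrow(read_peptide_table(out_f)), 0L)
  # unknown subcommand and missing flags are nonzero with a diagnostic
  diag <- capture.output(st <- cli_run("frobnicate"), type = "message")
  expect_equal(st, 2L)
  expect_true(any(grepl("unknown subcommand", diag)))
  diag <- capture.output(st <- cli_run("fit", "--in"), type = "message")
  expect_equal(st, 1L)
  expect_true(any(grepl("needs a value", diag)))
  diag <- capture.output(st <- cli_run("fit"), type = "message")
  expect_equal(st, 1L)
})

test_that("cli digest, solve-k, report and simulate subcommands work", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "prot.fasta")
  writeLines(c(">prot1", "GAKRLM"), fa)
  dig_f <- file.path(dir, "digest.csv")
  expect_equal(suppressMessages(cli_run(
    "digest", "--fasta", fa, "--out", dig_f, "--max-missed", "1")), 0L)
  dig <- read_peptide_table(dig_f)
  expect_true(all(c("GAK", "GAKR", "R", "RLM", "LM") %in%
                    dig$peptide_sequence))

  k_f <- file.path(dir, "k.tsv")
  expect_equal(suppressMessages(cli_run(
    "solve-k", "--in", qsrrpep_extdata("table1_model_peptides.csv"),
    "--out", k_f)), 0L)
  expect_equal(read_retention_factors(k_f)[["F"]], 10^1.0583 - 5,
               tolerance = 0.05)

  sim_f <- file.path(dir, "sim.csv")
  expect_equal(suppressMessages(cli_run(
    "simulate", "--out", sim_f, "--n", "12", "--seed", "4")), 0L)
  expect_equal(nrow(read_peptide_table(sim_f)), 12L)

  cl2_f <- file.path(dir, "cl2.csv")
  cl3_f <- file.path(dir, "cl3.csv")
  suppressMessages(cli_run("classify",
                           "--in", qsrrpep_extdata("table2_sasp_dprpE.csv"),
                           "--out", cl2_f))
  suppressMessages(cli_run("classify",
                           "--in", qsrrpep_extdata("table3_sasp_168.csv"),
                           "--out", cl3_f))
  rep_f <- file.path(dir, "report.txt")
  expect_equal(suppressMessages(cli_run(
    "report", "--in", cl2_f, "--in", cl3_f,
    "--label", "dprpE", "--label", "168", "--out", rep_f)), 0L)
  expect_true(any(grepl("group counts per sample", readLines(rep_f))))
})
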