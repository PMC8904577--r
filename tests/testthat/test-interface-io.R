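# Score tables, standardization, file dialects, and the CLI surface.

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("score tables validate ids and scores", {
  tab <- score_table(c("a", "b"), c(1.2, -0.5))
  expect_s3_class(tab, "score_table")
  expect_false(attr(tab, "standardized"))
  expect_error(score_table(c("a", "a"), c(1, 2)), class = "pgsabs_domain_error")
  expect_error(score_table(character(0), numeric(0)), class = "pgsabs_domain_error")
  expect_error(score_table("a", NaN), class = "pgsabs_domain_error")
})

test_that("standardization is the reference Z-transform, applied once", {
  tab <- score_table(c("a", "b", "c"), c(10, 12, 8))
  std <- standardize_scores(tab, ref_mean = 10, ref_sd = 2)
  expect_equal(std$score, c(0, 1, -1))
  expect_true(attr(std, "standardized"))
  expect_error(standardize_scores(std, 0, 1), class = "pgsabs_domain_error")
  # identity reference
  ident <- standardize_scores(tab, 0, 1)
  expect_equal(ident$score, tab$score)
  expect_error(standardize_scores(tab, 0, 0), class = "pgsabs_domain_error")
})

test_that("TSV and PLINK2 .sscore dialects are both read", {
  tsv <- write_tmp(c("id\tscore", "s1\t0.12", "s2\t-1.4", "s3\t2.25"))
  tab <- read_score_table(tsv)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$score, c(0.12, -1.4, 2.25))
  ss <- write_tmp(c("#IID\tALLELE_CT\tSCORE1_AVG",
                    "s1\t1000\t0.0004", "s2\t1000\t-0.0011"),
                  ext = ".sscore")
  ptab <- read_score_table(ss)
  expect_equal(ptab$id, c("s1", "s2"))
  expect_equal(ptab$score, c(0.0004, -0.0011))
  # malformed inputs carry line-level diagnostics
  bad <- write_tmp(c("id\tscore", "s1\t0.1", "s2\toops"))
  expect_error(read_score_table(bad), "line 3", class = "pgsabs_domain_error")
  dup <- write_tmp(c("id\tscore", "s1\t0.1", "s1\t0.2"))
  expect_error(read_score_table(dup), "s1", class = "pgsabs_domain_error")
  empty <- write_tmp(character(0))
  expect_error(read_score_table(empty), class = "pgsabs_domain_error")
  header_only <- write_tmp("id\tscore")
  expect_error(read_score_table(header_only), class = "pgsabs_domain_error")
  expect_error(read_score_table(tempfile()), class = "pgsabs_domain_error")
})

test_that("quantile tables round-trip through TSV at full precision", {
  tab <- risk_by_quantile(build_binary_model(0.01, auc_to_d(0.67)), 20)
  path <- tempfile(fileext = ".tsv")
  write_quantile_table(tab, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$case_probability, tab$case_probability, tolerance = 1e-10)
  expect_equal(back$lower[-1], tab$lower[-1], tolerance = 1e-10)
})

test_that("CLI worked examples emit the published absolute values", {
  out <- capture.output(code <- run_cli(c(
    "binary", "--prevalence", "0.01", "--auc", "0.67", "--z", "1.96")))
  expect_identical(code, 0L)
  res <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(round(100 * res$case_probability, 1), 2.7)
  expect_equal(round(res$percentile, 1), 97.5)
  out2 <- capture.output(code2 <- run_cli(c(
    "continuous", "--mean", "100", "--sd", "15", "--r2", "0.10",
    "--z", "-1.96")))
  expect_identical(code2, 0L)
  res2 <- jsonlite::fromJSON(paste(out2, collapse = "\n"))
  expect_equal(round(res2$predicted_mean, 1), 90.7)
  expect_equal(round(res2$interval_lower, 1), 62.8)
  expect_equal(round(res2$interval_upper, 1), 118.6)
})

test_that("CLI convert and validate subcommands run end to end", {
  out <- capture.output(code <- run_cli(c(
    "convert", "--from", "or_per_sd", "--to", "auc", "--value", "2")))
  expect_identical(code, 0L)
  res <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(res$output, d_to_auc(or_per_sd_to_d(2)), tolerance = 1e-10)
  tmp <- tempfile(fileext = ".json")
  tbl <- tempfile(fileext = ".tsv")
  code2 <- run_cli(c("validate", "--mode", "binary", "--prevalence", "0.1",
                     "--auc", "0.6", "--n", "20000", "--seed", "7",
                     "--n-quantiles", "10", "--out", tmp, "--table", tbl))
  expect_identical(code2, 0L)
  v <- jsonlite::fromJSON(tmp)
  expect_lt(v$mean_abs_diff, 5)
  expect_equal(nrow(read.table(tbl, header = TRUE, sep = "\t")), 10L)
})

test_that("CLI batch scoring and standardization work from files", {
  raw <- write_tmp(c("id\tscore", "p1\t0.02", "p2\t-0.01", "p3\t0.05"))
  out <- capture.output(code <- run_cli(c(
    "binary", "--prevalence", "0.01", "--auc", "0.67",
    "--scores", raw, "--ref-mean", "0.01", "--ref-sd", "0.02")))
  expect_identical(code, 0L)
  res <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(nrow(res), 3L)
  expect_equal(res$z, c(0.5, -1, 2))
  std_out <- tempfile(fileext = ".tsv")
  code2 <- run_cli(c("standardize", "--scores", raw, "--ref-mean", "0.01",
                     "--ref-sd", "0.02", "--out", std_out))
  expect_identical(code2, 0L)
  std <- read.table(std_out, header = TRUE, sep = "\t")
  expect_equal(std$score, c(0.5, -1, 2))
})

test_that("CLI outputs are byte-identical across repeated runs", {
  args <- c("binary", "--prevalence", "0.02", "--auc", "0.62", "--n-quantiles", "20")
  a <- capture.output(run_cli(args))
  b <- capture.output(run_cli(args))
  expect_identical(a, b)
  vargs <- c("validate", "--mode", "continuous", "--mean", "100", "--sd", "15",
             "--r2", "0.1", "--n", "5000", "--seed", "99")
  va <- capture.output(run_cli(vargs))
  vb <- capture.output(run_cli(vargs))
  expect_identical(va, vb)
})

test_that("CLI rejects bad input with a diagnostic, not a traceback", {
  expect_message(code <- run_cli(c("binary", "--prevalence", "1.5",
                                   "--auc", "0.67", "--z", "1")),
                 "between 0 and 1")
  expect_identical(code, 1L)
  expect_message(code2 <- run_cli(c("frobnicate")), "unknown command")
  expect_identical(code2, 1L)
  expect_message(code3 <- run_cli(c("binary", "--prevalence", "0.01", "--z", "1")),
                 "metric")
  expect_identical(code3, 1L)
  expect_silent(out <- capture.output(code4 <- run_cli("--version")))
  expect_identical(code4, 0L)
  expect_match(capture.output(run_cli("--help"))[1], "usage")
})
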