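# Score-table handling: reading batch polygenic score files and
# standardization against a reference population.

#' Construct a score table
#'
#' @param id Character vector of unique individual identifiers.
#' @param score Numeric vector of polygenic scores (raw or standardized).
#' @param standardized Whether `score` is already a Z-score.
#' @return An object of class `score_table` (a data frame with columns `id`,
#'   `score` and a `standardized` attribute).
#' @export
score_table <- function(id, score, standardized = FALSE) {
  id <- as.character(id)
  if (length(id) == 0L) abort_domain("score table is empty")
  if (length(id) != length(score))
    abort_domain("`id` and `score` must have equal length")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1]
    abort_domain("duplicate individual id: '%s'", dup)
  }
  if (!is.numeric(score) || any(!is.finite(score)))
    abort_domain("all scores must be finite numbers")
  structure(data.frame(id = id, score = as.numeric(score),
                       stringsAsFactors = FALSE),
            class = c("score_table", "data.frame"),
            standardized = isTRUE(standardized))
}

#' Read a table of polygenic scores
#'
#' Two dialects are supported. `"tsv"`: tab-separated with a header naming an
#' `id` (or `IID`/`FID`) column and a `score` column. `"plink_sscore"`: the
#' PLINK2 `--score` output, recognized by its `#IID`/`IID` header token; the
#' score column is `SCORE1_AVG` (or the first `SCORE*` column present).
#' With `format = "auto"` (default), `.sscore` files and files whose header
#' starts with `#IID` are parsed as PLINK2 output, anything else as plain TSV.
#'
#' @param path Path to the file.
#' @param format `"auto"`, `"tsv"` or `"plink_sscore"`.
#' @param standardized Whether the stored scores are already Z-scores.
#' @return A [score_table()].
#' @export
read_score_table <- function(path, format = c("auto", "tsv", "plink_sscore"),
                             standardized = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_domain("score file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort_domain("score file is empty: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.sscore$", path) || grepl("^#?IID\\t", first))
      "plink_sscore" else "tsv"
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) abort_domain("score file has a header but no rows: %s", path)
  names(df) <- sub("^#", "", names(df))
  cols <- tolower(names(df))
  if (format == "plink_sscore") {
    id_col <- which(cols == "iid")[1]
    score_col <- which(names(df) == "SCORE1_AVG")[1]
    if (is.na(score_col)) score_col <- grep("^SCORE", names(df))[1]
    if (is.na(id_col) || is.na(score_col))
      abort_domain("not a PLINK2 .sscore file (need IID and SCORE* columns): %s", path)
  } else {
    id_col <- which(cols %in% c("id", "iid", "individual_id"))[1]
    score_col <- which(cols %in% c("score", "pgs", "prs"))[1]
    if (is.na(id_col) || is.na(score_col))
      abort_domain("TSV must have an id (id/IID) and a score column: %s", path)
  }
  sc <- suppressWarnings(as.numeric(df[[score_col]]))
  if (any(is.na(sc))) {
    bad <- which(is.na(sc))[1]
    abort_domain("non-numeric score on line %d of %s: '%s'",
                 bad + 1L, path, df[[score_col]][bad])
  }
  score_table(df[[id_col]], sc, standardized = standardized)
}

#' Standardize scores against a reference population
#'
#' Converts raw polygenic scores to Z-scores using the mean and SD of the same
#' score computed in an ancestry-matched reference sample:
#' `z = (score - ref_mean) / ref_sd`. Standardizing a table twice is an error.
#'
#' @param table A [score_table()] of raw scores.
#' @param ref_mean,ref_sd Reference mean and SD (`ref_sd > 0`).
#' @return A standardized [score_table()].
#' @export
standardize_scores <- function(table, ref_mean, ref_sd) {
  stopifnot(inherits(table, "score_table"))
  if (isTRUE(attr(table, "standardized")))
    abort_domain("score table is already standardized")
  check_finite(ref_mean, "ref_mean")
  if (!is.numeric(ref_sd) || length(ref_sd) != 1L || !is.finite(ref_sd) || ref_sd <= 0)
    abort_domain("`ref_sd` must be a single positive number (got %s)", format(ref_sd))
  score_table(table$id, (table$score - ref_mean) / ref_sd, standardized = TRUE)
}

#' Write a quantile table as TSV
#'
#' Full-precision (15 significant digits) tab-separated output with a header
#' row, suitable for lossless round-tripping.
#'
#' @param table A data frame (e.g. from [risk_by_quantile()] or
#'   [trait_by_quantile()]).
#' @param path Output path, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_quantile_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
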