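#' Round-half-up percentage from integer counts
#'
#' Computes `100 * correct / total` rounded half-up to 2 decimals using
#' exact integer arithmetic (`floor((20000c + t) / 2t) / 100`), so printed
#' table values are reproduced without floating-point boundary surprises.
#' Undefined (NA) when `total` is 0.
#'
#' @param correct,total integer vectors of counts
#' @return numeric vector of percentages with 2-decimal resolution
#' @export
precision_pct <- function(correct, total) {
  stopifnot(all(correct >= 0, na.rm = TRUE), all(total >= 0, na.rm = TRUE))
  out <- rep(NA_real_, length(total))
  ok <- !is.na(total) & total > 0
  out[ok] <- ((20000 * correct[ok] + total[ok]) %/% (2 * total[ok])) / 100
  out
}

# round half away from zero at `digits` decimals, for values already carrying
# limited precision (e.g. percentages)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a per-query, per-source precision table
#'
#' Takes expert-evaluation cells `(query_id, dataset_id, correct, total)`
#' and derives row totals (per query over sources), column totals (per
#' source over queries), the grand total, and 2-decimal half-up precisions
#' for every cell and margin. Precision of an empty cell (total 0) is
#' undefined (NA), never 0.
#'
#' @param cells data.frame with columns `query_id`, `dataset_id`, `correct`,
#'   `total`
#' @return an object of class `EvaluationTable`: list with data.tables
#'   `cells`, `rows` (per query), `columns` (per source) and one-row
#'   `grand`, each carrying `correct`, `total`, `precision`
#' @export
precision_table <- function(cells) {
  dt <- data.table::as.data.table(cells)
  stopifnot(all(c("query_id", "dataset_id", "correct", "total") %in% names(dt)))
  bad <- which(dt$correct > dt$total | dt$correct < 0 | dt$total < 0)
  if (length(bad)) {
    stop(sprintf("invalid cell (correct > total or negative) at %s/%s: %d:%d",
                 dt$query_id[bad[1]], dt$dataset_id[bad[1]],
                 dt$correct[bad[1]], dt$total[bad[1]]), call. = FALSE)
  }
  dt[, precision := precision_pct(correct, total)]
  rows <- dt[, list(correct = sum(correct), total = sum(total)), by = "query_id"]
  rows[, precision := precision_pct(correct, total)]
  cols <- dt[, list(correct = sum(correct), total = sum(total)), by = "dataset_id"]
  cols[, precision := precision_pct(correct, total)]
  grand <- data.table::data.table(correct = sum(dt$correct), total = sum(dt$total))
  grand[, precision := precision_pct(correct, total)]
  structure(list(cells = dt[], rows = rows[], columns = cols[], grand = grand[]),
            class = "EvaluationTable")
}

#' @export
print.EvaluationTable <- function(x, ...) {
  cat("<EvaluationTable>\n")
  for (i in seq_len(nrow(x$rows))) {
    cat(sprintf("  %-4s %4d:%-4d  %s\n", x$rows$query_id[i], x$rows$correct[i],
                x$rows$total[i], format(x$rows$precision[i], nsmall = 2)))
  }
  cat(sprintf("  %-4s %4d:%-4d  %s\n", "all", x$grand$correct, x$grand$total,
              format(x$grand$precision, nsmall = 2)))
  invisible(x)
}

#' Relative precision improvement
#'
#' `100 * (new - old) / old`, rounded half-up to 2 decimals. Both inputs are
#' expected to be percentages already rounded to 2 decimals, as printed in
#' evaluation tables; the computation is done on those printed values (an
#' 87.68 -> 89.88 change is a 2.51% relative improvement).
#'
#' @param old_precision,new_precision percentages (0..100)
#' @return relative change in percent, 2 decimals
#' @export
relative_improvement <- function(old_precision, new_precision) {
  if (is.na(old_precision) || old_precision == 0) {
    stop("relative improvement is undefined for a zero or missing baseline", call. = FALSE)
  }
  # work on the 2-decimal grid scaled to integers to keep the quotient exact
  o <- round(old_precision * 100)
  n <- round(new_precision * 100)
  round_half_up(100 * (n - o) / o, 2)
}

#' Load evaluation cells from a counts TSV
#'
#' Format: `query_id<TAB>dataset_id<TAB>correct<TAB>total`, `#` comments
#' ignored.
#'
#' @param path TSV file path
#' @return data.table of cells suitable for [precision_table()]
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop(sprintf("counts file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(vapply(parts, length, integer(1)) >= 4L))
  data.table::data.table(
    query_id = vapply(parts, `[`, character(1), 1L),
    dataset_id = vapply(parts, `[`, character(1), 2L),
    correct = as.integer(vapply(parts, `[`, character(1), 3L)),
    total = as.integer(vapply(parts, `[`, character(1), 4L))
  )
}

#' Packaged expert-evaluation count fixtures
#'
#' The package ships the two per-query, per-source correct:total count
#' tables used to benchmark the integrated method against its
#' workshop-stage baseline: `"baseline"` (the earlier fusion method) and
#' `"integrated"` (this method). Cells cover queries Q1..Q9 over the four
#' sources.
#'
#' @param which `"baseline"` or `"integrated"`
#' @return data.table of cells suitable for [precision_table()]
#' @export
packaged_counts <- function(which = c("integrated", "baseline")) {
  which <- match.arg(which)
  fname <- if (which == "baseline") "counts_baseline.tsv" else "counts_integrated.tsv"
  read_counts(system.file("extdata", fname, package = "kgtrio", mustWork = TRUE))
}

#' Read an expert label table
#'
#' Format: `query_id<TAB>hit_id<TAB>verdict` with verdict `correct` or
#' `false` (a hit id is a CUI when resolvable, else a URI). Labels are
#' assumed to come from majority voting of several experts upstream.
#'
#' @param path TSV file path
#' @return data.table with columns `query_id`, `hit_id`, `verdict`
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("label file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(vapply(parts, length, integer(1)) >= 3L))
  dt <- data.table::data.table(
    query_id = vapply(parts, `[`, character(1), 1L),
    hit_id = vapply(parts, `[`, character(1), 2L),
    verdict = vapply(parts, `[`, character(1), 3L)
  )
  stopifnot(all(dt$verdict %in% c("correct", "false")))
  dt
}

#' Score a query result against expert labels
#'
#' Produces per-source (correct, total) cells for [precision_table()]. A
#' hit's verdict is looked up by its dedup key (CUI or URI); a hit asserted
#' by several sources contributes to each of them. Hits without a verdict
#' are excluded from the cells and reported in the `unscored` field.
#'
#' @param result a `QueryResult`
#' @param labels data.table from [read_labels()]
#' @return list with `cells` (data.table query_id/dataset_id/correct/total)
#'   and `unscored` (character vector of unlabelled hit keys)
#' @export
score_results <- function(result, labels) {
  qid <- result$pattern$id
  lab <- labels[labels$query_id == qid]
  verdicts <- stats::setNames(lab$verdict, lab$hit_id)
  hits <- result$hits
  v <- unname(verdicts[hits$concept_key])
  unscored <- hits$concept_key[is.na(v)]
  scored <- which(!is.na(v))
  if (length(scored)) {
    rows <- data.table::rbindlist(lapply(scored, function(i) {
      data.table::data.table(dataset_id = hits$sources[[i]],
                             correct = as.integer(v[i] == "correct"))
    }))
    cells <- rows[, list(correct = sum(correct), total = .N), by = "dataset_id"]
  } else {
    cells <- data.table::data.table(dataset_id = character(), correct = integer(),
                                    total = integer())
  }
  cells[, query_id := qid]
  data.table::setcolorder(cells, c("query_id", "dataset_id", "correct", "total"))
  list(cells = cells[], unscored = unscored)
}

#' Count deltas between two evaluation tables
#'
#' Reports raw differences in result counts and correct-result counts
#' between a baseline table and a new table; no percentage is imposed
#' because the appropriate denominator depends on the question being asked.
#'
#' @param baseline,new `EvaluationTable` objects
#' @return list with `total_results_delta` and `correct_results_delta`
#' @export
count_deltas <- function(baseline, new) {
  list(total_results_delta = new$grand$total - baseline$grand$total,
       correct_results_delta = new$grand$correct - baseline$grand$correct)
}
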