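#' Confusion counts against a gold standard
#'
#' The positive class is a gold "include". `tp` counts gold includes
#' predicted include, `tn` gold excludes predicted exclude, `fp` gold
#' excludes predicted include, `fn` gold includes predicted exclude; the
#' four counts partition the decision set.
#'
#' @param decisions list of `screening_decision` or a data.frame with
#'   `record_id` and `decision` columns.
#' @param gold named character vector (`record_id` -> `"include"` /
#'   `"exclude"`) or a data.frame with `record_id`, `decision`.
#' @return object of class `confusion_summary` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_from_decisions <- function(decisions, gold) {
  df <- as_decision_df(decisions)
  gold <- as_gold_vector(gold)
  missing <- setdiff(df$record_id, names(gold))
  if (length(missing)) {
    validation_error(paste0("record id(s) absent from the gold standard: ",
                            paste(missing, collapse = ", ")))
  }
  g <- gold[df$record_id]
  confusion_summary(
    tp = sum(g == "include" & df$decision == "include"),
    tn = sum(g == "exclude" & df$decision == "exclude"),
    fp = sum(g == "exclude" & df$decision == "include"),
    fn = sum(g == "include" & df$decision == "exclude")
  )
}

as_decision_df <- function(decisions) {
  if (is.data.frame(decisions)) return(decisions)
  decisions_to_df(decisions)
}

as_gold_vector <- function(gold) {
  if (is.data.frame(gold)) {
    out <- gold$decision
    names(out) <- gold$record_id
    return(out)
  }
  gold
}

#' @rdname confusion_from_decisions
#' @param tp,tn,fp,fn non-negative counts.
#' @export
confusion_summary <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) validation_error("confusion counts must be >= 0")
  structure(as.list(counts), class = "confusion_summary")
}

#' Screening performance metrics
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), Precision = TP/(TP+FP),
#' Recall = TP/(TP+FN). A zero denominator for precision or recall flags
#' the metric as undefined (`NA` with the corresponding
#' `precision_defined`/`recall_defined` flag) rather than silently
#' reporting 0. Percent renderings are half-up at two decimals, matching
#' the conventional reporting style.
#'
#' @param c a [confusion_summary()].
#' @return object of class `metric_set`: fractions `accuracy`,
#'   `precision`, `recall`; definedness flags; and `*_pct` percent values
#'   rounded half-up at 2 decimals.
#' @export
compute_metrics <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total <= 0) validation_error("empty confusion summary")
  precision_defined <- (c$tp + c$fp) > 0
  recall_defined <- (c$tp + c$fn) > 0
  accuracy <- (c$tp + c$tn) / total
  precision <- if (precision_defined) c$tp / (c$tp + c$fp) else NA_real_
  recall <- if (recall_defined) c$tp / (c$tp + c$fn) else NA_real_
  structure(list(
    accuracy = accuracy, precision = precision, recall = recall,
    precision_defined = precision_defined, recall_defined = recall_defined,
    accuracy_pct = round_half_up(100 * accuracy, 2),
    precision_pct = if (precision_defined)
      round_half_up(100 * precision, 2) else NA_real_,
    recall_pct = if (recall_defined)
      round_half_up(100 * recall, 2) else NA_real_,
    n = total), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("accuracy %s, precision %s, recall %s (n = %d)\n",
              format_percent(x$accuracy), format_percent(x$precision),
              format_percent(x$recall), x$n))
  invisible(x)
}

normalize_reason <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Exclusion-reason concordance
#'
#' Compares the tool's exclusion reasons with the gold reasons on the
#' records that \emph{both} the tool and the gold standard excluded -
#' reasons are only comparable where both sides excluded. Labels match
#' after whitespace/case normalization; no semantic matching. When no
#' record was co-excluded the rate is flagged undefined (`NA`), not an
#' error.
#'
#' @param decisions list of `screening_decision` or decision data.frame
#'   (needs `exclusion_reason`).
#' @param gold_reasons named character vector `record_id` -> gold reason
#'   (only excluded records need entries), or a data.frame with
#'   `record_id`, `reason`.
#' @return object of class `concordance_result` with `matched`,
#'   `compared`, `rate` and `defined`.
#' @export
exclusion_reason_concordance <- function(decisions, gold_reasons) {
  df <- as_decision_df(decisions)
  if (is.data.frame(gold_reasons)) {
    gr <- gold_reasons$reason
    names(gr) <- gold_reasons$record_id
  } else gr <- gold_reasons
  gr <- gr[!is.na(gr) & nzchar(gr)]
  co <- df[df$decision == "exclude" & df$record_id %in% names(gr), ,
           drop = FALSE]
  compared <- nrow(co)
  if (compared == 0) {
    return(structure(list(matched = 0L, compared = 0L, rate = NA_real_,
                          defined = FALSE), class = "concordance_result"))
  }
  matched <- sum(normalize_reason(co$exclusion_reason) ==
                   normalize_reason(gr[co$record_id]))
  structure(list(matched = matched, compared = compared,
                 rate = matched / compared, defined = TRUE),
            class = "concordance_result")
}

#' Pearson chi-square test on a 2 x k table
#'
#' Computes the Pearson statistic sum((O-E)^2/E) with expected counts
#' from the product of the margins, df = k - 1, and the upper-tail
#' p-value from the chi-square distribution. No continuity correction
#' (the reference analyses apply none).
#'
#' @param table numeric matrix with 2 rows and k >= 2 columns.
#' @return object of class `chi_square_result` with `statistic`, `df`,
#'   `p_value`.
#' @export
chi_square_2xk <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2 || ncol(table) < 2) {
    validation_error("chi-square table must be 2 x k with k >= 2")
  }
  row_tot <- rowSums(table)
  col_tot <- colSums(table)
  n <- sum(table)
  if (any(row_tot == 0) || any(col_tot == 0)) {
    validation_error("chi-square table has a zero marginal")
  }
  expected <- outer(row_tot, col_tot) / n
  statistic <- sum((table - expected)^2 / expected)
  df <- ncol(table) - 1L
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE)),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Compare screening backends against one gold standard
#'
#' Scores each named decision set (metrics + exclusion-reason
#' concordance) and tests for between-backend differences with two
#' Pearson chi-square tests at alpha = 0.05: one on the recall table
#' (tp/fn per backend, i.e. how the gold includes were classified) and
#' one on the concordance table (matched/unmatched co-excluded reasons).
#' A test whose table has a zero marginal (e.g. all backends perfect) is
#' reported with statistic 0, df k-1 and p 1 when the columns are
#' identical, and skipped with `NULL` otherwise.
#'
#' @param decision_sets named list: backend name -> list of
#'   `screening_decision` (all covering the same record ids).
#' @param gold gold decisions (see [confusion_from_decisions()]).
#' @param gold_reasons gold exclusion reasons (see
#'   [exclusion_reason_concordance()]).
#' @param stage label stored on the report.
#' @param alpha significance level for the difference flags.
#' @return object of class `eval_report`: per-backend `metrics` and
#'   `concordance`, `recall_test`, `concordance_test`, significance
#'   flags, `stage`, `n_records`.
#' @export
compare_models <- function(decision_sets, gold, gold_reasons = NULL,
                           stage = "title_abstract", alpha = 0.05) {
  if (is.null(names(decision_sets)) || any(!nzchar(names(decision_sets)))) {
    validation_error("decision_sets must be a named list")
  }
  id_sets <- lapply(decision_sets, function(d) sort(as_decision_df(d)$record_id))
  for (i in seq_along(id_sets)[-1]) {
    if (!identical(id_sets[[i]], id_sets[[1]])) {
      off <- c(setdiff(id_sets[[i]], id_sets[[1]]),
               setdiff(id_sets[[1]], id_sets[[i]]))
      validation_error(paste0(
        "decision sets cover different records; offending ids: ",
        paste(utils::head(off, 10), collapse = ", ")))
    }
  }
  metrics <- lapply(decision_sets, function(d)
    compute_metrics(confusion_from_decisions(d, gold)))
  concordance <- if (!is.null(gold_reasons)) {
    lapply(decision_sets, exclusion_reason_concordance,
           gold_reasons = gold_reasons)
  }
  confusions <- lapply(decision_sets, confusion_from_decisions, gold = gold)
  recall_tab <- vapply(confusions, function(c) c(c$tp, c$fn), numeric(2))
  recall_test <- safe_chi_square(recall_tab)
  concordance_test <- if (!is.null(concordance)) {
    conc_tab <- vapply(concordance, function(c)
      c(c$matched, c$compared - c$matched), numeric(2))
    safe_chi_square(conc_tab)
  }
  structure(list(
    stage = stage,
    n_records = length(id_sets[[1]]),
    metrics = metrics,
    concordance = concordance,
    recall_test = recall_test,
    recall_differs = !is.null(recall_test) && recall_test$p_value < alpha,
    concordance_test = concordance_test,
    concordance_differs = !is.null(concordance_test) &&
      concordance_test$p_value < alpha,
    alpha = alpha), class = "eval_report")
}

# chi-square that degrades gracefully on degenerate tables: identical
# columns with a zero row give statistic 0 / p 1; otherwise zero marginals
# make the test inapplicable and NULL is returned
safe_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (ncol(tab) < 2) return(NULL)  # nothing to compare
  if (any(colSums(tab) == 0)) return(NULL)
  if (any(rowSums(tab) == 0)) {
    cols_equal <- all(apply(tab, 1, function(r) length(unique(r)) == 1))
    if (cols_equal) {
      return(structure(list(statistic = 0, df = ncol(tab) - 1L, p_value = 1),
                       class = "chi_square_result"))
    }
    return(NULL)
  }
  chi_square_2xk(tab)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(render_report_text(x))
  invisible(x)
}

#' Render an evaluation report as a text table
#'
#' @param report an `eval_report`.
#' @return a single string with the model-by-metric table and the
#'   chi-square comparisons.
#' @export
render_report_text <- function(report) {
  lines <- c(
    sprintf("Stage: %s (n = %d records)", report$stage, report$n_records),
    sprintf("%-24s %-10s %-10s %-10s %-12s", "Model", "Accuracy", "Recall",
            "Precision", "Concordance"))
  for (nm in names(report$metrics)) {
    m <- report$metrics[[nm]]
    conc <- if (!is.null(report$concordance))
      report$concordance[[nm]]$rate else NA
    lines <- c(lines, sprintf("%-24s %-10s %-10s %-10s %-12s", nm,
                              format_percent(m$accuracy),
                              format_percent(m$recall),
                              format_percent(m$precision),
                              format_percent(conc)))
  }
  if (!is.null(report$recall_test)) {
    lines <- c(lines, sprintf(
      "Recall difference: chi-square = %.2f, df = %d, p = %.3g%s",
      report$recall_test$statistic, report$recall_test$df,
      report$recall_test$p_value,
      if (report$recall_differs) " (significant)" else ""))
  }
  if (!is.null(report$concordance_test)) {
    lines <- c(lines, sprintf(
      "Concordance difference: chi-square = %.2f, df = %d, p = %.3g%s",
      report$concordance_test$statistic, report$concordance_test$df,
      report$concordance_test$p_value,
      if (report$concordance_differs) " (significant)" else ""))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read a gold-standard label file
#'
#' CSV with columns `record_id`, `decision` (`include`/`exclude`) and
#' optionally `reason` (empty for includes).
#'
#' @param path CSV file path.
#' @return `data.frame(record_id, decision, reason)`.
#' @export
read_gold_csv <- function(path) {
  if (!file.exists(path)) io_error(paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("record_id", "decision")
  if (!all(need %in% names(df))) {
    parse_error(paste0(path, ": gold CSV needs columns ",
                       paste(need, collapse = ", ")))
  }
  if (!all(df$decision %in% c("include", "exclude"))) {
    parse_error(paste0(path, ": gold decisions must be include/exclude"))
  }
  if (!"reason" %in% names(df)) df$reason <- NA_character_
  df$reason[df$reason == ""] <- NA_character_
  df[c("record_id", "decision", "reason")]
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- list(
    stage = report$stage, n_records = report$n_records,
    models = lapply(names(report$metrics), function(nm) {
      m <- report$metrics[[nm]]
      out <- list(model = nm, accuracy = m$accuracy_pct,
                  recall = m$recall_pct, precision = m$precision_pct)
      if (!is.null(report$concordance)) {
        out$concordance <- report$concordance[[nm]]$rate
      }
      out
    }),
    recall_test = unclass_or_null(report$recall_test),
    concordance_test = unclass_or_null(report$concordance_test),
    alpha = report$alpha)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_or_null <- function(x) if (is.null(x)) NULL else unclass(x)
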