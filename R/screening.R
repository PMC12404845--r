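#' Run the chained eligibility tasks on one document
#'
#' Executes the tasks in chain order. Each task's prompt is rendered with
#' [build_prompt()], completed through the backend and parsed with
#' [parse_model_json()]; a malformed response earns one automatic retry
#' with a "respond with JSON only" reminder appended. The first task whose
#' answer is "no" short-circuits the chain: the record is excluded with
#' that task's reason label and the trace stops there. If every task
#' passes (or the task list is empty) the record is included.
#'
#' @param document non-empty text under assessment.
#' @param tasks ordered list of [chain_task()]s.
#' @param backend backend object.
#' @param criteria scenario [picos_criteria()].
#' @param params a [backend_params()].
#' @param record_id identifier carried on the decision.
#' @return object of class `screening_decision` with fields `record_id`,
#'   `stage`, `decision` (`"include"`/`"exclude"`), `exclusion_reason`
#'   (`NA` for includes), `trace` (data.frame `dimension`, `raw_answer`,
#'   `passed`) and `backend_name`.
#' @export
run_chain <- function(document, tasks, backend, criteria,
                      params = backend_params(), record_id = "record") {
  if (is_absent(document) || !nzchar(trimws(document))) {
    validation_error(paste0("empty document for record ", record_id))
  }
  stage <- if (length(tasks)) tasks[[1]]$stage else "title_abstract"
  trace <- list()
  for (task in tasks) {
    prompt <- build_prompt(task, criteria, document = document)
    ans <- tryCatch({
      res <- complete(backend, prompt, params)
      tryCatch(
        parse_model_json(res$text, task$output_schema),
        malformed_response = function(e) {
          # single repair attempt: re-ask with a JSON-only reminder
          retry_prompt <- paste0(prompt$text,
                                 "\nRespond with JSON only.")
          res2 <- complete(backend, retry_prompt, params)
          parse_model_json(res2$text, task$output_schema)
        })
    },
    backend_unavailable = function(e) {
      e$trace <- finalize_trace(trace)
      stop(e)
    })
    passed <- tolower(trimws(as.character(ans$meets_criterion))) %in%
      c("yes", "y", "true")
    trace[[length(trace) + 1]] <- list(
      dimension = task$dimension,
      raw_answer = as.character(jsonlite::toJSON(ans, auto_unbox = TRUE)),
      passed = passed)
    if (!passed) {
      return(screening_decision(record_id, stage, "exclude",
                                exclusion_reason = task$reason_label,
                                trace = finalize_trace(trace),
                                backend_name = backend_name(backend)))
    }
  }
  screening_decision(record_id, stage, "include",
                     trace = finalize_trace(trace),
                     backend_name = backend_name(backend))
}

finalize_trace <- function(trace) {
  if (!length(trace)) {
    return(data.frame(dimension = character(0), raw_answer = character(0),
                      passed = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(trace, function(t)
    data.frame(dimension = t$dimension, raw_answer = t$raw_answer,
               passed = t$passed, stringsAsFactors = FALSE)))
}

#' @rdname run_chain
#' @param decision `"include"` or `"exclude"`.
#' @param exclusion_reason reason label; mandatory iff excluding.
#' @param trace evaluated-task trace.
#' @param backend_name name of the backend that produced the decision.
#' @export
screening_decision <- function(record_id, stage, decision,
                               exclusion_reason = NA_character_,
                               trace = NULL, backend_name = "unknown") {
  if (decision == "exclude" && is_absent(exclusion_reason)) {
    validation_error("an exclude decision requires an exclusion reason")
  }
  if (decision == "include" && !is_absent(exclusion_reason)) {
    validation_error("an include decision cannot carry an exclusion reason")
  }
  structure(list(record_id = record_id, stage = stage, decision = decision,
                 exclusion_reason = if (decision == "exclude")
                   exclusion_reason else NA_character_,
                 trace = trace, backend_name = backend_name),
            class = "screening_decision")
}

#' @export
print.screening_decision <- function(x, ...) {
  cat(sprintf("[%s] %s: %s%s\n", x$stage, x$record_id, x$decision,
              if (x$decision == "exclude")
                paste0(" (", x$exclusion_reason, ")") else ""))
  invisible(x)
}

#' Title-abstract screening
#'
#' Screens each record of a corpus through the chained tasks, using the
#' concatenation of title and cleaned abstract as chain input (title alone
#' when the abstract is absent). Decisions come back in corpus order.
#'
#' @param records a `screen_corpus`.
#' @param tasks title-abstract stage task suite.
#' @param backend,criteria,params as in [run_chain()].
#' @param progress optional function called as `progress(decision)` after
#'   each record (the CLI uses it for JSON-line logging).
#' @return list of `screening_decision`, one per record.
#' @export
screen_title_abstract <- function(records, tasks, backend, criteria,
                                  params = backend_params(),
                                  progress = NULL) {
  stopifnot(all(vapply(tasks, function(t) t$stage, "") == "title_abstract"))
  lapply(seq_len(nrow(records)), function(i) {
    abs_txt <- records$abstract[[i]]
    doc <- if (is_absent(abs_txt)) records$title[[i]] else
      paste(records$title[[i]], abs_txt, sep = "\n")
    d <- run_chain(doc, tasks, backend, criteria, params,
                   record_id = records$record_id[[i]])
    if (!is.null(progress)) progress(d)
    d
  })
}

# canonical reading order used to linearize a structured article
section_reading_order <- function() {
  c("title", "abstract", "introduction", "methods", "results",
    "discussion", "conclusion", "other", "references")
}

#' Full-text screening
#'
#' Screens a structured article: the chain input is the concatenation of
#' its sections in canonical reading order (title, abstract, introduction,
#' methods, results, discussion, conclusion, other, references), so a
#' criterion whose evidence appears only deep in the results is still
#' visible to its task.
#'
#' @param article a `structured_article` with at least one non-empty
#'   section.
#' @param tasks full-text stage task suite.
#' @inheritParams screen_title_abstract
#' @return a `screening_decision` (stage `full_text`).
#' @export
screen_full_text <- function(article, tasks, backend, criteria,
                             params = backend_params()) {
  stopifnot(all(vapply(tasks, function(t) t$stage, "") == "full_text"))
  secs <- article$sections
  if (!length(secs) || all(!nzchar(trimws(unlist(secs))))) {
    validation_error(paste0("article ", article$record_id,
                            " has no non-empty section"))
  }
  ord <- c(intersect(section_reading_order(), names(secs)),
           setdiff(names(secs), section_reading_order()))
  doc <- paste(unlist(secs[ord]), collapse = "\n")
  run_chain(doc, tasks, backend, criteria, params,
            record_id = article$record_id)
}

#' PRISMA flow counts
#'
#' Assembles the record-flow accounting of a two-stage screening run:
#' records identified, remaining after deduplication, included/excluded
#' at the title-abstract stage, excluded at full text, and finally
#' included. The full-text decisions must cover exactly the
#' title-abstract includes; any mismatch is an accounting error naming
#' the offending ids. Invariants enforced:
#' `after_dedup = ta_included + ta_excluded` and
#' `final_included = ta_included - ft_excluded`.
#'
#' @param dedup_report a [dedup_report()] (or a list with `input_count`
#'   and `unique_count`).
#' @param ta_decisions list of title-abstract `screening_decision`s.
#' @param ft_decisions list of full-text `screening_decision`s.
#' @return object of class `prisma_counts`.
#' @export
prisma_counts <- function(dedup_report, ta_decisions, ft_decisions) {
  ta_ids <- vapply(ta_decisions, function(d) d$record_id, "")
  ta_dec <- vapply(ta_decisions, function(d) d$decision, "")
  ft_ids <- vapply(ft_decisions, function(d) d$record_id, "")
  ft_dec <- vapply(ft_decisions, function(d) d$decision, "")
  included_ids <- ta_ids[ta_dec == "include"]
  extra <- setdiff(ft_ids, included_ids)
  missing <- setdiff(included_ids, ft_ids)
  if (length(extra) || length(missing)) {
    accounting_error(paste0(
      "full-text decisions do not cover exactly the title-abstract ",
      "includes; unexpected: [", paste(extra, collapse = ", "),
      "], missing: [", paste(missing, collapse = ", "), "]"))
  }
  counts <- list(
    identified = dedup_report$input_count,
    after_dedup = dedup_report$unique_count,
    ta_included = sum(ta_dec == "include"),
    ta_excluded = sum(ta_dec == "exclude"),
    ft_excluded = sum(ft_dec == "exclude"),
    final_included = sum(ft_dec == "include")
  )
  validate_prisma(counts)
}

validate_prisma <- function(counts) {
  if (counts$after_dedup != counts$ta_included + counts$ta_excluded) {
    accounting_error("after_dedup != ta_included + ta_excluded")
  }
  if (counts$final_included != counts$ta_included - counts$ft_excluded) {
    accounting_error("final_included != ta_included - ft_excluded")
  }
  structure(counts, class = "prisma_counts")
}

#' @export
print.prisma_counts <- function(x, ...) {
  cat(sprintf(paste0(
    "records identified:        %6d\n",
    "after deduplication:       %6d\n",
    "title-abstract included:   %6d\n",
    "title-abstract excluded:   %6d\n",
    "full-text excluded:        %6d\n",
    "finally included:          %6d\n"),
    x$identified, x$after_dedup, x$ta_included, x$ta_excluded,
    x$ft_excluded, x$final_included))
  invisible(x)
}

#' Write / read screening decisions as JSON lines
#'
#' One JSON object per line with keys `record_id`, `stage`, `decision`,
#' `exclusion_reason`, `backend_name` and the per-task `trace`.
#'
#' @param decisions list of `screening_decision`.
#' @param path file path.
#' @return `path` (writer) or list of `screening_decision` (reader).
#' @export
write_decisions_jsonl <- function(decisions, path) {
  lines <- vapply(decisions, function(d) {
    as.character(jsonlite::toJSON(list(
      record_id = d$record_id, stage = d$stage, decision = d$decision,
      exclusion_reason = if (is_absent(d$exclusion_reason)) NULL else
        d$exclusion_reason,
      backend_name = d$backend_name,
      trace = d$trace), auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_decisions_jsonl
#' @export
read_decisions_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    screening_decision(
      record_id = x$record_id, stage = x$stage, decision = x$decision,
      exclusion_reason = x$exclusion_reason %||% NA_character_,
      trace = if (!is.null(x$trace) && length(x$trace))
        as.data.frame(x$trace) else NULL,
      backend_name = x$backend_name %||% "unknown")
  })
}

#' Decisions as a data frame
#'
#' @param decisions list of `screening_decision`.
#' @return `data.frame(record_id, stage, decision, exclusion_reason,
#'   backend_name)`.
#' @export
decisions_to_df <- function(decisions) {
  do.call(rbind, lapply(decisions, function(d)
    data.frame(record_id = d$record_id, stage = d$stage,
               decision = d$decision,
               exclusion_reason = d$exclusion_reason,
               backend_name = d$backend_name,
               stringsAsFactors = FALSE)))
}
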