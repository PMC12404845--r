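#' End-to-end full-text screening benchmark on synthetic articles
#'
#' Generates `n` gold-labelled records, renders each as a sectioned
#' full-text page stream, rebuilds structured articles through the page
#' segmentation path, screens them with the chained full-text task suite
#' on the deterministic mock backend, and evaluates the decisions against
#' gold. The default 3:1 included-to-excluded mix reflects the prevalence
#' entering a full-text stage after title-abstract triage has removed the
#' bulk of irrelevant records.
#'
#' @param n number of articles.
#' @param seed integer seed controlling the corpus and the mock noise
#'   stream.
#' @param noise mock backend noise level.
#' @param prevalence gold include fraction at the full-text stage.
#' @return list with `metrics` (a `metric_set`), `concordance`,
#'   `decisions` and `gold`.
#' @export
run_fulltext_benchmark <- function(n = 200, seed = 1L, noise = 0,
                                   prevalence = 0.75) {
  cc <- load_criteria(system.file("extdata", "criteria_rsv.json",
                                  package = "picoscreen"))
  tasks <- default_task_suite(cc$criteria, cc$taxonomy, "full_text",
                              cc$config)
  gen <- generate_corpus(corpus_profile(n_records = n,
                                        prevalence = prevalence,
                                        seed = seed))
  backend <- mock_backend(noise = noise, seed = seed + 1)
  decisions <- lapply(seq_len(n), function(i) {
    pages <- generate_fulltext_pages(gen$records[i, ], gen$gold[i, ],
                                     "imrad")
    art <- structure_article(pages,
                             record_id = gen$records$record_id[[i]])
    screen_full_text(art, tasks, backend, cc$criteria)
  })
  gold <- stats::setNames(gen$gold$decision, gen$gold$record_id)
  greasons <- stats::setNames(gen$gold$reason, gen$gold$record_id)
  list(metrics = compute_metrics(confusion_from_decisions(decisions, gold)),
       concordance = exclusion_reason_concordance(decisions, greasons),
       decisions = decisions, gold = gen$gold)
}

#' @rdname run_fulltext_benchmark
#' @export
fulltext_accuracy_pct <- function(n = 200, seed = 1L, noise = 0) {
  run_fulltext_benchmark(n = n, seed = seed, noise = noise)$metrics$accuracy_pct
}
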