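# Shared fixtures: the bundled RSV-vaccine safety scenario and small
# generated corpora. Everything is built in code; nothing binary on disk.

rsv_scenario <- function() {
  path <- system.file("extdata", "criteria_rsv.json", package = "picoscreen")
  load_criteria(path)
}

rsv_tasks <- function(stage = "title_abstract") {
  cc <- rsv_scenario()
  default_task_suite(cc$criteria, cc$taxonomy, stage, cc$config)
}

small_corpus <- function(n = 50, prevalence = 0.1, seed = 42) {
  generate_corpus(corpus_profile(n_records = n, prevalence = prevalence,
                                 seed = seed))
}

gold_vector <- function(gold) stats::setNames(gold$decision, gold$record_id)
gold_reasons <- function(gold) stats::setNames(gold$reason, gold$record_id)

# guillemet sentinels for hand-built fixture documents
s_inc <- function() "\u00abINC\u00bb"
s_exc <- function(dim) paste0("\u00abEXC:", dim, "\u00bb")

# a minimal record corpus built by hand
tiny_corpus <- function() {
  corpus(
    record_id = c("a", "b", "c"),
    title = c("RSV Vaccine Safety.", "rsv vaccine safety",
              "An unrelated influenza study"),
    abstract = c("first", "second", "third"),
    year = c(2020L, 2020L, 2021L),
    authors = list("Smith J", "Smith J", "Jones K")
  )
}
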