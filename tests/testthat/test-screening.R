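test_that("run_chain short-circuits at the first failing dimension", {
  cc <- rsv_scenario()
  tasks <- rsv_tasks()
  b <- mock_backend()

  # monoclonal-antibody style document: fails the intervention task first
  d <- run_chain(paste("Palivizumab prophylaxis surveillance.",
                       s_exc("intervention_comparator")),
                 tasks, b, cc$criteria, record_id = "mab")
  expect_equal(d$decision, "exclude")
  expect_equal(d$exclusion_reason, "Unrelated to RSV vaccine")
  expect_equal(nrow(d$trace), 1)

  # efficacy-only document: intervention passes, outcome fails
  d <- run_chain(paste("Protective efficacy of the vaccine.",
                       s_exc("outcome")),
                 tasks, b, cc$criteria, record_id = "eff")
  expect_equal(d$exclusion_reason, "Not a safety study of RSV vaccine")
  expect_equal(d$trace$dimension,
               c("intervention_comparator", "population", "outcome"))
  expect_true(all(d$trace$passed[1:2]), !d$trace$passed[3])

  # failing two dimensions reports the chain-earlier one
  d <- run_chain(paste("Doc.", s_exc("population"), s_exc("outcome")),
                 tasks, b, cc$criteria)
  expect_equal(d$exclusion_reason,
               cc$taxonomy$reason_label[cc$taxonomy$dimension == "population"])

  # all tasks passing, and the vacuous empty chain, both include
  d <- run_chain(paste("Doc.", s_inc()), tasks, b, cc$criteria)
  expect_equal(d$decision, "include")
  expect_true(is.na(d$exclusion_reason))
  expect_equal(nrow(d$trace), 4)
  d <- run_chain("any document", list(), b, cc$criteria)
  expect_equal(d$decision, "include")
})

test_that("reason-order property: earliest failing dimension always wins", {
  cc <- rsv_scenario()
  tasks <- rsv_tasks()
  b <- mock_backend()
  dims <- chain_dimensions()
  set.seed(31)
  for (rep in 1:20) {
    failing <- sample(dims, sample(2:4, 1))
    doc <- paste(c("Multi-failure document.",
                   vapply(failing, s_exc, character(1))), collapse = " ")
    d <- run_chain(doc, tasks, b, cc$criteria)
    earliest <- dims[min(match(failing, dims))]
    expect_equal(d$exclusion_reason,
                 cc$taxonomy$reason_label[cc$taxonomy$dimension == earliest])
  }
})

test_that("backend failure propagates with the partial trace attached", {
  cc <- rsv_scenario()
  tasks <- rsv_tasks()
  cond <- tryCatch(
    run_chain(paste("Doc.", s_inc()), tasks,
              flaky_backend(fail_times = Inf), cc$criteria,
              backend_params(max_retries = 0, backoff_base_s = 0)),
    backend_unavailable = identity)
  expect_s3_class(cond, "backend_unavailable")
  expect_equal(nrow(cond$trace), 0)
})

test_that("title-abstract screening preserves order and handles empty abstracts", {
  cc <- rsv_scenario()
  tasks <- rsv_tasks()
  gen <- small_corpus(n = 20, seed = 13)
  decisions <- screen_title_abstract(gen$records, tasks, mock_backend(),
                                     cc$criteria)
  expect_length(decisions, 20)
  expect_equal(vapply(decisions, function(d) d$record_id, ""),
               gen$records$record_id)
  expect_true(all(vapply(decisions, function(d) d$stage, "") ==
                    "title_abstract"))
  # abstract-less record runs on the title alone
  rec <- corpus(record_id = "t1",
                title = paste("Title-only record", s_inc()))
  d <- screen_title_abstract(rec, tasks, mock_backend(), cc$criteria)
  expect_equal(d[[1]]$decision, "include")
})

test_that("full-text screening sees evidence buried in the results section", {
  cc <- rsv_scenario()
  ft_tasks <- rsv_tasks("full_text")
  gen <- small_corpus(n = 6, seed = 21)
  # build an include whose only sentinel sits in the results section
  art <- structure_article(generate_fulltext_pages(
    gen$records[1, ], list(decision = "exclude",
                           reason_dimension = "outcome"), "imrad"),
    record_id = "deep")
  expect_match(art$sections$results, "EXC:outcome")
  d <- screen_full_text(art, ft_tasks, mock_backend(), cc$criteria)
  expect_equal(d$stage, "full_text")
  expect_equal(d$exclusion_reason, "Not a safety study of RSV vaccine")
  # pre-results tasks passed: the outcome evidence was visible
  expect_equal(d$trace$dimension[1:2],
               c("intervention_comparator", "population"))

  # methods-borne include sentinel
  art2 <- structure_article(generate_fulltext_pages(
    gen$records[2, ], list(decision = "include",
                           reason_dimension = NA), "imrad"),
    record_id = "inc")
  expect_equal(screen_full_text(art2, ft_tasks, mock_backend(),
                                cc$criteria)$decision, "include")

  # empty article violates the precondition
  empty <- structure(list(record_id = "e", sections = list(),
                          nonprose_elements = data.frame(),
                          provenance = "test"),
                     class = "structured_article")
  expect_error(screen_full_text(empty, ft_tasks, mock_backend(),
                                cc$criteria),
               class = "validation_error")
})

test_that("prisma_counts reproduces the reference flow and its invariants", {
  # 2,156 identified; 1,133 screened after dedup; 182 to full text;
  # 71 excluded there => 111 finally included
  dd <- dedup_report(2156, 1133,
                     clusters = list(k = sprintf("d%04d", 1:1023)))
  ta <- c(lapply(sprintf("inc%03d", 1:182), function(id)
    screening_decision(id, "title_abstract", "include")),
    lapply(sprintf("exc%03d", 1:951), function(id)
      screening_decision(id, "title_abstract", "exclude",
                         exclusion_reason = "r")))
  ft <- c(lapply(sprintf("inc%03d", 1:111), function(id)
    screening_decision(id, "full_text", "include")),
    lapply(sprintf("inc%03d", 112:182), function(id)
      screening_decision(id, "full_text", "exclude",
                         exclusion_reason = "r")))
  pc <- prisma_counts(dd, ta, ft)
  expect_equal(pc$identified, 2156)
  expect_equal(pc$after_dedup, 1133)
  expect_equal(pc$ta_included, 182)
  expect_equal(pc$ft_excluded, 71)
  expect_equal(pc$final_included, 111)
  expect_equal(pc$after_dedup, pc$ta_included + pc$ta_excluded)
  expect_equal(pc$final_included, pc$ta_included - pc$ft_excluded)

  # all-excluded run
  dd0 <- dedup_report(2, 2, list())
  ta0 <- lapply(c("a", "b"), function(id)
    screening_decision(id, "title_abstract", "exclude",
                       exclusion_reason = "r"))
  pc0 <- prisma_counts(dd0, ta0, list())
  expect_equal(pc0$ta_included, 0)
  expect_equal(pc0$final_included, 0)

  # a full-text decision for a ta-excluded id is an accounting error
  expect_error(prisma_counts(dd0, ta0, list(
    screening_decision("a", "full_text", "include"))),
    class = "accounting_error", regexp = "a")
})

test_that("decisions round-trip through JSON lines", {
  cc <- rsv_scenario()
  tasks <- rsv_tasks()
  gen <- small_corpus(n = 10, seed = 2)
  decisions <- screen_title_abstract(gen$records, tasks, mock_backend(),
                                     cc$criteria)
  f <- file.path(tempdir(), "dec.jsonl")
  write_decisions_jsonl(decisions, f)
  back <- read_decisions_jsonl(f)
  expect_equal(decisions_to_df(back), decisions_to_df(decisions))
})
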