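#' Synthetic corpus profile
#'
#' The stated world a generated screening corpus emulates. Defaults mirror
#' a typical drug-safety screening corpus: a 1:9 included-to-excluded
#' prevalence (0.1), exclusion reasons spread evenly over the four chain
#' dimensions, and no injected duplicates.
#'
#' @param n_records number of records.
#' @param prevalence fraction of gold includes, in (0, 1).
#' @param reason_mix named numeric vector over [chain_dimensions()]
#'   summing to 1; the mixture of gold exclusion dimensions.
#' @param duplicate_rate fraction of duplicate copies [inject_duplicates()]
#'   should add, in \[0, 1).
#' @param seed integer RNG seed; every generator output is a deterministic
#'   function of the profile including the seed.
#' @return object of class `corpus_profile`.
#' @export
corpus_profile <- function(n_records = 1000, prevalence = 0.1,
                           reason_mix = NULL, duplicate_rate = 0,
                           seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) {
    config_error("prevalence must be in (0, 1)")
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    config_error("duplicate_rate must be in [0, 1)")
  }
  if (is.null(reason_mix)) {
    reason_mix <- stats::setNames(rep(0.25, 4), chain_dimensions())
  }
  if (!setequal(names(reason_mix), chain_dimensions())) {
    config_error("reason_mix must be named over the four chain dimensions")
  }
  if (abs(sum(reason_mix) - 1) > 1e-8) {
    config_error("reason_mix must sum to 1")
  }
  structure(list(n_records = as.integer(n_records), prevalence = prevalence,
                 reason_mix = reason_mix[chain_dimensions()],
                 duplicate_rate = duplicate_rate, seed = as.integer(seed)),
            class = "corpus_profile")
}

# small word banks for human-plausible (but clearly synthetic) titles and
# abstracts in the respiratory-virus vaccine register
synth_vocab <- function() {
  list(
    vaccine = c("RSVpreF", "RSVPostF", "adjuvanted RSV", "live-attenuated RSV",
                "vector-based RSV", "bivalent RSV", "maternal RSV"),
    population = c("older adults", "infants", "pregnant women",
                   "immunocompromised patients", "healthy volunteers",
                   "preterm neonates"),
    design = c("randomized controlled trial", "cohort study",
               "case-control study", "open-label phase 2 trial",
               "post-marketing surveillance study"),
    outcome = c("local adverse events", "systemic adverse events",
                "serious adverse events", "reactogenicity",
                "solicited adverse reactions"),
    offtopic = c("influenza antiviral stewardship",
                 "measles outbreak surveillance",
                 "pneumococcal carriage dynamics",
                 "palivizumab immunoprophylaxis",
                 "bronchiolitis supportive care")
  )
}

#' Generate a labelled synthetic screening corpus
#'
#' Each record's title and abstract contain human-plausible text plus a
#' machine-readable sentinel consistent with its gold label: a
#' guillemet-wrapped `INC` for includes, `EXC:dimension` for excludes
#' (the dimension drawn from the profile's `reason_mix`). Class counts
#' are `round(n * prevalence)` includes, the remainder excludes; exact
#' reason counts follow a largest-remainder apportionment of the mix.
#' Output is deterministic per profile (seed included) and record titles
#' are unique, so deduplication finds nothing unless duplicates are
#' injected.
#'
#' @param profile a [corpus_profile()].
#' @param taxonomy optional [exclusion_taxonomy()] supplying the gold
#'   reason labels; defaults to the labels of the bundled RSV-vaccine
#'   safety scenario.
#' @return `list(records = screen_corpus, gold = data.frame(record_id,
#'   decision, reason_dimension, reason))`.
#' @export
generate_corpus <- function(profile, taxonomy = NULL) {
  if (is.null(taxonomy)) taxonomy <- default_scenario_taxonomy()
  n <- profile$n_records
  n_inc <- round(n * profile$prevalence)
  n_exc <- n - n_inc
  reason_counts <- apportion(profile$reason_mix, n_exc)
  dims <- rep(names(reason_counts), reason_counts)
  with_seed(profile$seed, {
    v <- synth_vocab()
    # gold labels in randomized order so includes are not clustered
    decision <- sample(c(rep("include", n_inc), rep("exclude", n_exc)))
    dim_pool <- sample(dims)
    out_dim <- character(n)
    out_dim[decision == "exclude"] <- dim_pool
    record_id <- sprintf("syn%04d", seq_len(n))
    title <- character(n)
    abstract <- character(n)
    year <- sample(2008:2024, n, replace = TRUE)
    for (i in seq_len(n)) {
      if (decision[[i]] == "include") {
        title[[i]] <- sprintf(
          "Safety of %s vaccine in %s: a %s (study %04d)",
          sample(v$vaccine, 1), sample(v$population, 1),
          sample(v$design, 1), i)
        abstract[[i]] <- paste(
          sprintf("We assessed %s and %s after vaccination.",
                  sample(v$outcome, 1), sample(v$outcome, 1)),
          sentinel("INC"))
      } else {
        d <- out_dim[[i]]
        title[[i]] <- switch(d,
          intervention_comparator = sprintf(
            "%s in %s (study %04d)", sample(v$offtopic, 1),
            sample(v$population, 1), i),
          population = sprintf(
            "Safety of %s vaccine in a veterinary cohort (study %04d)",
            sample(v$vaccine, 1), i),
          outcome = sprintf(
            "Protective efficacy of %s vaccine in %s (study %04d)",
            sample(v$vaccine, 1), sample(v$population, 1), i),
          study_design = sprintf(
            "In vitro neutralization by %s vaccine sera (study %04d)",
            sample(v$vaccine, 1), i))
        abstract[[i]] <- paste(
          "This report does not satisfy one eligibility dimension.",
          sentinel("EXC", d))
      }
    }
    records <- corpus(record_id = record_id, title = title,
                      abstract = abstract, year = year,
                      source_db = "synthetic")
    reason_label <- stats::setNames(taxonomy$reason_label,
                                    taxonomy$dimension)
    gold <- data.frame(
      record_id = record_id,
      decision = decision,
      reason_dimension = ifelse(decision == "exclude", out_dim,
                                NA_character_),
      reason = ifelse(decision == "exclude",
                      unname(reason_label[out_dim]), NA_character_),
      stringsAsFactors = FALSE)
    list(records = records, gold = gold)
  })
}

# largest-remainder apportionment of integer n over a probability vector
apportion <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

default_scenario_taxonomy <- function() {
  path <- system.file("extdata", "criteria_rsv.json", package = "picoscreen")
  if (nzchar(path)) return(load_criteria(path)$taxonomy)
  # fallback when called from a source checkout
  crit <- picos_criteria(
    population = "individuals who received the RSV vaccine",
    intervention = "administration of the RSV vaccine",
    outcomes = "safety-related outcomes",
    study_design = "experimental and observational studies",
    scenario_name = "rsv_vaccine_safety")
  exclusion_taxonomy(crit)
}

#' Stratified training-set sampling
#'
#' Draws a class-stratified subset of exactly `total` records at an
#' `a:b` included-to-excluded ratio: `total * a/(a+b)` includes and
#' `total * b/(a+b)` excludes, sampled without replacement,
#' seed-deterministic. Non-integral splits and insufficient class pools
#' are errors rather than silently rounded.
#'
#' @param records a `screen_corpus`.
#' @param gold matching gold data.frame (`record_id`, `decision`).
#' @param total subset size.
#' @param ratio integer pair `c(included, excluded)`, e.g. `c(1, 9)`.
#' @param seed RNG seed.
#' @return `list(records, gold)` restricted to the sampled subset, in
#'   sampled order.
#' @export
stratified_sample <- function(records, gold, total, ratio = c(1, 9),
                              seed = 1L) {
  if (total == 0) {
    keep <- records[integer(0), , drop = FALSE]
    class(keep) <- class(records)
    return(list(records = keep, gold = gold[integer(0), , drop = FALSE]))
  }
  a <- ratio[[1]]; b <- ratio[[2]]
  n_inc_raw <- total * a / (a + b)
  n_exc_raw <- total * b / (a + b)
  if (n_inc_raw != floor(n_inc_raw) || n_exc_raw != floor(n_exc_raw)) {
    validation_error(sprintf(
      "total %d does not divide at ratio %d:%d", total, a, b))
  }
  n_inc <- as.integer(n_inc_raw); n_exc <- as.integer(n_exc_raw)
  inc_ids <- gold$record_id[gold$decision == "include"]
  exc_ids <- gold$record_id[gold$decision == "exclude"]
  if (length(inc_ids) < n_inc || length(exc_ids) < n_exc) {
    validation_error(sprintf(
      "pool too small: need %d includes / %d excludes, have %d / %d",
      n_inc, n_exc, length(inc_ids), length(exc_ids)))
  }
  with_seed(seed, {
    ids <- c(sample(inc_ids, n_inc), sample(exc_ids, n_exc))
    keep <- records[match(ids, records$record_id), , drop = FALSE]
    rownames(keep) <- NULL
    class(keep) <- class(records)
    g <- gold[match(ids, gold$record_id), , drop = FALSE]
    rownames(g) <- NULL
    list(records = keep, gold = g)
  })
}

#' Inject near-duplicate records
#'
#' Appends `round(n * rate)` mutated copies of randomly chosen records.
#' Mutations are limited to case changes, punctuation and extra
#' whitespace, so every copy still collides with its source under the
#' [norm_title()] key while remaining textually distinct; distinct titles
#' are never merged. Returns the ground-truth [dedup_report()] that
#' [deduplicate()] must reproduce.
#'
#' @param records a `screen_corpus`.
#' @param rate duplicate fraction in \[0, 1).
#' @param seed RNG seed.
#' @return `list(records = augmented corpus, expected_report =
#'   dedup_report)`.
#' @export
inject_duplicates <- function(records, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) config_error("rate must be in [0, 1)")
  n <- nrow(records)
  n_dup <- round(n * rate)
  if (n_dup == 0) {
    return(list(records = records,
                expected_report = dedup_report(n, n, list())))
  }
  with_seed(seed, {
    src <- sample(n, n_dup, replace = n_dup > n)
    dup_rows <- records[src, , drop = FALSE]
    dup_rows$record_id <- sprintf("%s_dup%d", dup_rows$record_id,
                                  seq_len(n_dup))
    dup_rows$title <- vapply(dup_rows$title, mutate_title, character(1))
    out <- rbind(records, dup_rows)
    rownames(out) <- NULL
    class(out) <- class(records)
    clusters <- split(dup_rows$record_id, records$record_id[src])
    # cluster order follows kept-record (input) order, as deduplicate emits
    kept_order <- records$record_id[sort(unique(src))]
    clusters <- clusters[kept_order]
    list(records = out,
         expected_report = dedup_report(n + n_dup, n, clusters))
  })
}

# case/punctuation/whitespace mutations that are invisible to norm_title
mutate_title <- function(title) {
  x <- title
  op <- sample(3, 1)
  if (op == 1) x <- toupper(x)
  if (op == 2) x <- tolower(x)
  if (op == 3) {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    flip <- stats::runif(length(chars)) < 0.3
    chars[flip] <- ifelse(chars[flip] == toupper(chars[flip]),
                          tolower(chars[flip]), toupper(chars[flip]))
    x <- paste(chars, collapse = "")
  }
  if (stats::runif(1) < 0.5) x <- paste0(x, ".")
  if (stats::runif(1) < 0.5) x <- gsub(" ", "  ", x)
  if (stats::runif(1) < 0.5) x <- gsub(":", " -", x, fixed = TRUE)
  x
}

#' Generate a sectioned full-text page stream for a record
#'
#' Produces a plain-text page stream (character vector, one element per
#' page) for a gold-labelled record. The `imrad` layout carries headings
#' from the default vocabulary plus a table caption; the gold sentinel is
#' placed in the section where the evidence for that dimension naturally
#' lives (outcome evidence in Results; intervention, population and
#' design evidence in Methods; includes in Abstract and Methods). The
#' `headingless` layout emits a single heading-free page, exercising the
#' degenerate front-matter path.
#'
#' @param record one-row `screen_corpus` slice (or list with `title`).
#' @param gold matching gold row (`decision`, `reason_dimension`).
#' @param layout `"imrad"` or `"headingless"`.
#' @return character vector of pages.
#' @export
generate_fulltext_pages <- function(record, gold,
                                    layout = c("imrad", "headingless")) {
  layout <- match.arg(layout)
  title <- if (is.data.frame(record)) record$title[[1]] else record$title
  mark <- if (gold$decision == "include") sentinel("INC") else
    sentinel("EXC", gold$reason_dimension)
  sec_mark <- function(sec) {
    hit <- if (gold$decision == "include") sec %in% c("abstract", "methods")
    else switch(gold$reason_dimension,
                outcome = sec == "results",
                intervention_comparator = sec == "methods",
                population = sec == "methods",
                study_design = sec == "methods")
    if (isTRUE(hit)) mark else ""
  }
  if (layout == "headingless") {
    return(paste(c(title, "",
                   paste("This synthetic report has no section headings.",
                         mark)), collapse = "\n"))
  }
  page1 <- c(
    title, "",
    "Abstract",
    paste("Synthetic abstract text for full-text screening.",
          sec_mark("abstract")),
    "Introduction",
    "Background context for the synthetic study.")
  page2 <- c(
    "Methods",
    paste("Study procedures and eligibility of participants.",
          sec_mark("methods")),
    "Table 1. Baseline characteristics of participants",
    "Results",
    paste("Observed outcomes during follow-up.", sec_mark("results")),
    "Figure 1. Participant flow")
  page3 <- c(
    "Discussion",
    "Interpretation of the synthetic findings.",
    "Conclusion",
    "Summary statement.",
    "References",
    "1. Synthetic reference entry.")
  vapply(list(page1, page2, page3),
         function(p) paste(trimws(p), collapse = "\n"), character(1))
}
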