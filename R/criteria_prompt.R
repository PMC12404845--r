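#' Chain dimensions
#'
#' The four eligibility dimensions, in the fixed order the chained
#' evaluation pathway visits them: interventions/comparators first, then
#' study populations, outcomes, and study designs. The first failing
#' dimension supplies the record's exclusion reason.
#'
#' @return character vector of dimension names in chain order.
#' @export
chain_dimensions <- function() {
  c("intervention_comparator", "population", "outcome", "study_design")
}

# Display phrasing used when deriving a negated exclusion reason from an
# inclusion criterion ("<dimension phrase> not <criterion>").
dimension_phrase <- function(dimension) {
  switch(dimension,
    intervention_comparator = "Intervention measure is not",
    population = "Research subjects are not",
    outcome = "Outcome indicators are not",
    study_design = "Research type is not",
    config_error(paste0("unknown dimension: ", dimension))
  )
}

#' PICOS criteria
#'
#' The inclusion criteria of a screening scenario decomposed along the
#' PICOS framework. `comparison` may be absent; when present it is folded
#' into the intervention/comparator chain task.
#'
#' @param population,intervention,outcomes,study_design non-empty
#'   criterion texts.
#' @param comparison optional comparator criterion.
#' @param scenario_name short label for the scenario.
#' @return an object of class `picos_criteria`.
#' @export
picos_criteria <- function(population, intervention, outcomes, study_design,
                           comparison = NULL, scenario_name = "scenario") {
  for (f in c("population", "intervention", "outcomes", "study_design")) {
    v <- get(f)
    if (is_absent(v) || !nzchar(trimws(v))) {
      config_error(paste0("missing mandatory PICOS dimension: ", f))
    }
  }
  structure(list(population = population, intervention = intervention,
                 comparison = if (is_absent(comparison)) NULL else comparison,
                 outcomes = outcomes, study_design = study_design,
                 scenario_name = scenario_name),
            class = "picos_criteria")
}

criterion_for_dimension <- function(criteria, dimension) {
  switch(dimension,
    intervention_comparator = {
      x <- criteria$intervention
      if (!is.null(criteria$comparison)) {
        x <- paste0(x, " (comparator: ", criteria$comparison, ")")
      }
      x
    },
    population = criteria$population,
    outcome = criteria$outcomes,
    study_design = criteria$study_design
  )
}

#' Derive the exclusion-reason taxonomy
#'
#' One negated exclusion reason per chain dimension, ordered by
#' [chain_dimensions()]. Reasons default to the template
#' `"<dimension phrase> not <criterion>"` unless an explicit
#' `reason_labels[[dimension]]` is supplied.
#'
#' @param criteria a [picos_criteria()].
#' @param reason_labels optional named list of explicit reason labels.
#' @return `data.frame(dimension, reason_label)` in chain order, of class
#'   `exclusion_taxonomy`.
#' @export
exclusion_taxonomy <- function(criteria, reason_labels = list()) {
  dims <- chain_dimensions()
  labels <- vapply(dims, function(d) {
    explicit <- reason_labels[[d]]
    if (!is_absent(explicit)) return(as.character(explicit))
    paste(dimension_phrase(d), criterion_for_dimension(criteria, d))
  }, character(1))
  structure(data.frame(dimension = dims, reason_label = unname(labels),
                       stringsAsFactors = FALSE),
            class = c("exclusion_taxonomy", "data.frame"))
}

#' Load a criteria configuration
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed) criteria
#' file of the form:
#' \preformatted{
#' {
#'   "scenario_name": "...",
#'   "picos": {"population": "...", "intervention": "...",
#'             "comparison": null, "outcomes": "...",
#'             "study_design": "..."},
#'   "reasons": {"intervention_comparator": "Unrelated to ...", ...},
#'   "definitions": {"study_design": "...", ...},
#'   "thought_steps": {"study_design": ["...", "..."], ...}
#' }
#' }
#' and returns the criteria plus the derived taxonomy. Missing mandatory
#' PICOS dimensions are configuration errors.
#'
#' @param path config file path.
#' @return `list(criteria = picos_criteria, taxonomy = exclusion_taxonomy,
#'   config = raw parsed list)`.
#' @export
load_criteria <- function(path) {
  if (!file.exists(path)) config_error(paste0("criteria file not found: ", path))
  cfg <- if (grepl("\\.ya?ml$", path) &&
             requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
             error = function(e) config_error(paste0(path, ": ",
                                                     conditionMessage(e))))
  }
  p <- cfg$picos
  if (is.null(p)) config_error(paste0(path, ": no 'picos' block"))
  criteria <- picos_criteria(
    population = p$population, intervention = p$intervention,
    outcomes = p$outcomes, study_design = p$study_design,
    comparison = p$comparison,
    scenario_name = cfg$scenario_name %||% tools::file_path_sans_ext(basename(path))
  )
  taxonomy <- exclusion_taxonomy(criteria, cfg$reasons %||% list())
  list(criteria = criteria, taxonomy = taxonomy, config = cfg)
}

#' Few-shot example
#'
#' A worked document-to-answer example embedded in a prompt. Provenance
#' records whether it was chosen as representative or harvested from a
#' misclassified case during refinement.
#'
#' @param document_snippet text shown to the model.
#' @param expected_answer named list; must validate against the owning
#'   task's output schema.
#' @param provenance `"representative"` or `"misclassified"`.
#' @return object of class `few_shot_example`.
#' @export
few_shot_example <- function(document_snippet, expected_answer,
                             provenance = c("representative", "misclassified")) {
  provenance <- match.arg(provenance)
  structure(list(document_snippet = document_snippet,
                 expected_answer = expected_answer,
                 provenance = provenance),
            class = "few_shot_example")
}

#' Chain task definition
#'
#' One link of the chained screening pathway: the eligibility dimension it
#' tests, the stage it belongs to, the exclusion reason it emits on
#' failure, and the prompt components (role text, medical definitions,
#' chain-of-thought steps, few-shot store, output schema).
#'
#' @param dimension one of [chain_dimensions()].
#' @param stage `"title_abstract"` or `"full_text"`.
#' @param reason_label exclusion reason emitted when the task fails.
#' @param role_task,definitions free prompt text.
#' @param thought_steps ordered character vector of reasoning steps.
#' @param few_shot list of [few_shot_example()].
#' @param output_schema named character vector mapping each required
#'   response key to its JSON type (`"string"`, `"number"`, ...).
#' @return object of class `chain_task`.
#' @export
chain_task <- function(dimension, stage, reason_label, role_task,
                       definitions = "", thought_steps = character(0),
                       few_shot = list(), output_schema = NULL) {
  if (!dimension %in% chain_dimensions()) {
    config_error(paste0("unknown dimension: ", dimension))
  }
  if (!stage %in% c("title_abstract", "full_text")) {
    config_error(paste0("unknown stage: ", stage))
  }
  if (is.null(output_schema)) {
    output_schema <- c(meets_criterion = "string", rationale = "string")
  }
  structure(list(dimension = dimension, stage = stage,
                 reason_label = reason_label, role_task = role_task,
                 definitions = definitions, thought_steps = thought_steps,
                 few_shot = few_shot, output_schema = output_schema),
            class = "chain_task")
}

#' Default chained task suite for a scenario
#'
#' Builds the four chain tasks of a stage from the criteria and taxonomy,
#' with per-dimension default role text, definitions and chain-of-thought
#' steps (overridable through the criteria config's `definitions` /
#' `thought_steps` blocks). The study-design task additionally asks for
#' the `"Type of literature research"` key. The two stages get distinct
#' task suites by default.
#'
#' The outcome task's default reasoning steps carry the safeguard that a
#' randomized controlled trial is not failed at the title-abstract stage
#' merely because its abstract omits safety outcomes (they are normally
#' reported in the full text).
#'
#' @param criteria a [picos_criteria()].
#' @param taxonomy matching [exclusion_taxonomy()].
#' @param stage `"title_abstract"` or `"full_text"`.
#' @param config optional raw criteria config (for definition overrides).
#' @return list of four [chain_task()]s in chain order.
#' @export
default_task_suite <- function(criteria, taxonomy,
                               stage = c("title_abstract", "full_text"),
                               config = list()) {
  stage <- match.arg(stage)
  doc_kind <- if (stage == "title_abstract") {
    "the title and abstract information of a piece of literature"
  } else {
    "the full text of an article"
  }
  defs <- config$definitions %||% list()
  steps <- config$thought_steps %||% list()
  lapply(seq_len(nrow(taxonomy)), function(i) {
    d <- taxonomy$dimension[[i]]
    crit <- criterion_for_dimension(criteria, d)
    default_steps <- switch(d,
      intervention_comparator = c(
        paste0("Check whether the intervention under study is ", crit, "."),
        "Distinguish the intervention itself from related exposures (e.g. a monoclonal antibody is not a vaccine).",
        "If the document does not concern this intervention, the criterion is not met."),
      population = c(
        paste0("Check whether the research subjects are ", crit, "."),
        "If the subjects are a different population, the criterion is not met."),
      outcome = c(
        paste0("Check whether the reported outcome indicators are ", crit, "."),
        "Distinguish efficacy or protection outcomes from safety outcomes.",
        "A randomized controlled trial must NOT be failed at the screening stage merely because safety outcomes are not mentioned in the abstract; such outcomes are generally reported in the full text."),
      study_design = c(
        "Determine the type of literature research, such as \"clinical research\", \"animal experiment\", or \"basic experiment and research\".",
        "Check if specific research methods and designs, such as randomized controlled trials, cohort studies, or case-control studies, are mentioned.",
        paste0("Check whether the design is ", crit, ".")))
    schema <- c(meets_criterion = "string", rationale = "string")
    if (d == "study_design") {
      schema <- c(`Type of literature research` = "string", schema)
    }
    chain_task(
      dimension = d, stage = stage,
      reason_label = taxonomy$reason_label[[i]],
      role_task = paste0(
        "As an expert in epidemiology and evidence-based medicine, ",
        "familiar with drug intervention studies, you should judge from ",
        doc_kind, " whether it meets this eligibility criterion: ",
        crit, "."),
      definitions = defs[[d]] %||% "",
      thought_steps = steps[[d]] %||% default_steps,
      output_schema = schema
    )
  })
}

#' Assemble a screening prompt
#'
#' Renders the chained-task prompt blocks in fixed order: role/task
#' definition, medical definitions, step-by-step thinking, few-shot
#' examples, output-format instruction (naming every schema key), a
#' machine-readable dimension marker, then the document. Pure and
#' deterministic: identical inputs give byte-identical text.
#'
#' @param task a [chain_task()].
#' @param criteria the scenario [picos_criteria()].
#' @param examples list of [few_shot_example()]; defaults to the task's
#'   own store.
#' @param document the text under assessment (non-empty).
#' @return object of class `rendered_prompt` with fields `text` and
#'   `spec` (role_task, medical_definitions, thought_steps,
#'   few_shot_examples, output_schema).
#' @export
build_prompt <- function(task, criteria, examples = NULL, document) {
  if (is_absent(document) || !nzchar(trimws(document))) {
    validation_error("cannot build a prompt for an empty document")
  }
  if (is.null(examples)) examples <- task$few_shot
  parts <- c(
    "## Role and task", task$role_task,
    if (nzchar(task$definitions)) c("## Medical definition", task$definitions),
    "## Step-by-step thinking",
    paste0(seq_along(task$thought_steps), ". ", task$thought_steps),
    if (length(examples)) c(
      "## Examples",
      unlist(lapply(examples, function(e) c(
        paste0("Document: ", e$document_snippet),
        paste0("Answer: ", jsonlite::toJSON(e$expected_answer,
                                            auto_unbox = TRUE)))))),
    "## Output format",
    "The response must be in JSON format. The return format is as follows:",
    paste0("\"", names(task$output_schema), "\": ",
           unname(task$output_schema)),
    paste0("Answer \"yes\" or \"no\" in \"meets_criterion\"."),
    paste0("DIMENSION: ", task$dimension),
    "## Document",
    document
  )
  structure(list(
    text = paste(parts, collapse = "\n"),
    spec = list(role_task = task$role_task,
                medical_definitions = task$definitions,
                thought_steps = task$thought_steps,
                few_shot_examples = examples,
                output_schema = task$output_schema)),
    class = "rendered_prompt")
}

#' Parse and validate a model JSON response
#'
#' Strips surrounding prose and Markdown code fences, extracts the first
#' balanced JSON object, parses it and validates the required keys and
#' their types against the schema. On failure raises a classed
#' `malformed_response` condition carrying the raw text so the caller can
#' retry.
#'
#' @param response raw backend text.
#' @param schema named character vector key -> JSON type.
#' @return the validated answer as a named list.
#' @export
parse_model_json <- function(response, schema) {
  txt <- gsub("```[a-zA-Z]*", "", response)
  obj_txt <- extract_first_json_object(txt)
  if (is.na(obj_txt)) {
    malformed_response_error("no JSON object found in response", raw = response)
  }
  ans <- tryCatch(jsonlite::fromJSON(obj_txt, simplifyVector = TRUE),
                  error = function(e)
                    malformed_response_error(
                      paste0("unparseable JSON: ", conditionMessage(e)),
                      raw = response))
  missing <- setdiff(names(schema), names(ans))
  if (length(missing)) {
    malformed_response_error(
      paste0("response missing required key(s): ",
             paste(missing, collapse = ", ")), raw = response)
  }
  for (k in names(schema)) {
    ok <- switch(schema[[k]],
                 string = is.character(ans[[k]]),
                 number = is.numeric(ans[[k]]),
                 boolean = is.logical(ans[[k]]),
                 TRUE)
    if (!ok || length(ans[[k]]) != 1) {
      malformed_response_error(
        paste0("key '", k, "' is not a scalar ", schema[[k]]),
        raw = response)
    }
  }
  as.list(ans)
}

extract_first_json_object <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L; start <- NA_integer_; in_str <- FALSE; esc <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (in_str) {
      if (esc) esc <- FALSE
      else if (ch == "\\") esc <- TRUE
      else if (ch == "\"") in_str <- FALSE
      next
    }
    if (ch == "\"" && depth > 0) { in_str <- TRUE; next }
    if (ch == "{") {
      if (depth == 0L) start <- i
      depth <- depth + 1L
    } else if (ch == "}") {
      if (depth > 0L) {
        depth <- depth - 1L
        if (depth == 0L) return(substr(txt, start, i))
      }
    }
  }
  NA_character_
}

#' Grow a few-shot store with misclassified cases
#'
#' Appends misclassified documents with their gold answers to the store
#' (provenance `"misclassified"`), validating each gold answer against the
#' task schema and deduplicating on the document snippet. The prior store
#' order is preserved.
#'
#' @param store list of [few_shot_example()].
#' @param misclassified list of `list(document = , gold = )` pairs.
#' @param schema the owning task's output schema.
#' @return the augmented store.
#' @export
add_error_examples <- function(store, misclassified, schema) {
  for (m in misclassified) {
    ans <- m$gold
    missing <- setdiff(names(schema), names(ans))
    if (length(missing)) {
      validation_error(paste0("gold answer missing key(s): ",
                              paste(missing, collapse = ", ")))
    }
    seen <- vapply(store, function(e) e$document_snippet, character(1))
    if (m$document %in% seen) next
    store[[length(store) + 1]] <-
      few_shot_example(m$document, ans, provenance = "misclassified")
  }
  store
}
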