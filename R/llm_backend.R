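#' Backend request parameters
#'
#' Screening runs use `temperature = 0` so repeated calls are
#' reproducible. `max_retries` bounds transport-failure retries (with
#' exponential backoff starting at `backoff_base_s`); `max_concurrency`
#' is the documented in-flight request bound for HTTP adapters.
#'
#' @param model_name backend model identifier.
#' @param temperature sampling temperature, >= 0.
#' @param timeout_s per-request timeout in seconds.
#' @param max_retries non-negative retry count on transport failure.
#' @param max_concurrency documented in-flight request bound.
#' @param backoff_base_s first backoff delay in seconds.
#' @param cache_dir optional directory for the response cache.
#' @return object of class `backend_params`.
#' @export
backend_params <- function(model_name = "mock", temperature = 0,
                           timeout_s = 60, max_retries = 2,
                           max_concurrency = 1, backoff_base_s = 0.5,
                           cache_dir = NULL) {
  if (temperature < 0) config_error("temperature must be >= 0")
  if (max_retries < 0) config_error("max_retries must be >= 0")
  structure(list(model_name = model_name, temperature = temperature,
                 timeout_s = timeout_s, max_retries = max_retries,
                 max_concurrency = max_concurrency,
                 backoff_base_s = backoff_base_s, cache_dir = cache_dir),
            class = "backend_params")
}

#' Complete a prompt through a backend
#'
#' The uniform completion contract: send the prompt, return the raw text.
#' Transport failures (classed `transport_error`) are retried up to
#' `params$max_retries` times with exponential backoff; when all attempts
#' fail a `backend_unavailable` error is raised. A semantically wrong but
#' well-formed answer is never an error here - that is the parser's job.
#' When `params$cache_dir` is set, responses are cached as JSON files
#' keyed on (backend, model, prompt hash).
#'
#' @param backend a backend object (e.g. [mock_backend()]).
#' @param prompt non-empty prompt text (or a `rendered_prompt`).
#' @param params a [backend_params()].
#' @return object of class `completion_result` with fields `text`,
#'   `backend_name`, `latency_s`, `attempt_count`.
#' @export
complete <- function(backend, prompt, params = backend_params()) {
  if (inherits(prompt, "rendered_prompt")) prompt <- prompt$text
  if (!nzchar(trimws(prompt))) validation_error("empty prompt")
  cached <- cache_get(backend, prompt, params)
  if (!is.null(cached)) return(cached)
  attempts <- 0L
  t0 <- proc.time()[["elapsed"]]
  repeat {
    attempts <- attempts + 1L
    res <- tryCatch(
      list(ok = TRUE, text = backend_transport(backend, prompt, params)),
      transport_error = function(e) list(ok = FALSE, err = e)
    )
    if (res$ok) break
    if (attempts > params$max_retries) {
      backend_unavailable_error(paste0(
        "backend '", backend_name(backend), "' unavailable after ",
        attempts, " attempt(s): ", conditionMessage(res$err)))
    }
    Sys.sleep(params$backoff_base_s * 2^(attempts - 1))
  }
  out <- structure(list(text = res$text,
                        backend_name = backend_name(backend),
                        latency_s = proc.time()[["elapsed"]] - t0,
                        attempt_count = attempts),
                   class = "completion_result")
  cache_put(backend, prompt, params, out)
  out
}

#' Raw transport for a backend (internal dispatch point)
#'
#' @param backend backend object.
#' @param prompt prompt text.
#' @param params a [backend_params()].
#' @return raw response text.
#' @export
backend_transport <- function(backend, prompt, params) {
  UseMethod("backend_transport")
}

backend_name <- function(backend) {
  attr(backend, "backend_name") %||% class(backend)[[1]]
}

cache_key <- function(backend, prompt, params) {
  sprintf("%s_%s_%08x%08x", backend_name(backend), params$model_name,
          as.integer(string_hash(prompt, 1L)),
          as.integer(string_hash(prompt, 2L)))
}

cache_get <- function(backend, prompt, params) {
  if (is.null(params$cache_dir)) return(NULL)
  f <- file.path(params$cache_dir, paste0(cache_key(backend, prompt, params),
                                          ".json"))
  if (!file.exists(f)) return(NULL)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  structure(list(text = x$text, backend_name = x$backend_name,
                 latency_s = 0, attempt_count = 0L),
            class = "completion_result")
}

cache_put <- function(backend, prompt, params, result) {
  if (is.null(params$cache_dir)) return(invisible(NULL))
  dir.create(params$cache_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(params$cache_dir, paste0(cache_key(backend, prompt, params),
                                          ".json"))
  jsonlite::write_json(list(text = result$text,
                            backend_name = result$backend_name),
                       f, auto_unbox = TRUE)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Deterministic offline mock

#' Deterministic mock backend
#'
#' An offline stand-in that answers chained screening prompts from
#' machine-readable sentinels embedded in the document by the synthetic
#' corpus generator: guillemet-wrapped `INC` marks a gold include,
#' `EXC:dimension` a gold exclude on that dimension. The mock
#' locates the `DIMENSION:` marker and the `## Document` block in the
#' prompt and emits schema-conformant JSON.
#'
#' With `noise > 0`, a deterministic pseudo-random subset of documents
#' (a hash of the document text mixed with `seed`, compared against
#' `noise`) is answered as if its gold label were flipped, so a corpus
#' screened at noise level e has expected decision accuracy 1 - e. The
#' flip set depends only on (document, seed): replaying the same prompts
#' reproduces it exactly.
#'
#' @param noise flip probability in \[0, 1).
#' @param seed integer mixed into the flip hash.
#' @return a backend object usable with [complete()].
#' @export
mock_backend <- function(noise = 0, seed = 0L) {
  if (noise < 0 || noise >= 1) config_error("noise must be in [0, 1)")
  structure(list(noise = noise, seed = as.integer(seed)),
            class = "mock_backend", backend_name = "mock")
}

#' @export
backend_transport.mock_backend <- function(backend, prompt, params) {
  mock_complete(prompt, noise = backend$noise, seed = backend$seed)
}

# guillemet-wrapped sentinels; written with escapes so the source stays ASCII
sentinel <- function(kind, dimension = NULL) {
  if (kind == "INC") return("\u00abINC\u00bb")
  paste0("\u00abEXC:", dimension, "\u00bb")
}

#' Mock completion (pure function)
#'
#' @param prompt a rendered chained-task prompt.
#' @param noise,seed see [mock_backend()].
#' @return JSON response text.
#' @export
mock_complete <- function(prompt, noise = 0, seed = 0L) {
  dim_m <- regmatches(prompt, regexpr("DIMENSION: [a-z_]+", prompt))
  dimension <- if (length(dim_m)) sub("DIMENSION: ", "", dim_m) else NA
  doc <- sub(".*## Document\n", "", prompt)
  has_exc_here <- !is.na(dimension) &&
    grepl(sentinel("EXC", dimension), doc, fixed = TRUE)
  has_any_exc <- grepl("\u00abEXC:", doc, fixed = TRUE)
  truthful_pass <- !has_exc_here
  noisy <- noise > 0 && string_unif(doc, seed) < noise
  # a noisy document behaves as if its gold label were flipped: gold
  # excludes pass every task (ending in a wrong include), gold includes
  # fail every task (a wrong exclude at the first link)
  pass <- if (noisy) has_any_exc else truthful_pass
  ans <- list(meets_criterion = if (pass) "yes" else "no",
              rationale = paste0("sentinel assessment for ", dimension))
  if (identical(dimension, "study_design")) {
    ans <- c(list(`Type of literature research` =
                    if (pass) "clinical research"
                    else "basic experiment and research"),
             ans)
  }
  as.character(jsonlite::toJSON(ans, auto_unbox = TRUE))
}

# ---------------------------------------------------------------------------
# Test doubles and thin vendor adapters

#' Flaky backend test double
#'
#' Fails with a transport error for the first `fail_times` calls, then
#' behaves like the mock. Used to exercise the retry contract.
#'
#' @param fail_times number of leading calls that fail (`Inf` = always).
#' @param noise,seed forwarded to [mock_complete()].
#' @return a backend object.
#' @export
flaky_backend <- function(fail_times = 1, noise = 0, seed = 0L) {
  env <- new.env(parent = emptyenv())
  env$calls <- 0
  structure(list(fail_times = fail_times, noise = noise, seed = seed,
                 state = env),
            class = "flaky_backend", backend_name = "flaky")
}

#' @export
backend_transport.flaky_backend <- function(backend, prompt, params) {
  backend$state$calls <- backend$state$calls + 1
  if (backend$state$calls <= backend$fail_times) {
    transport_error(paste0("simulated transport failure #",
                           backend$state$calls))
  }
  mock_complete(prompt, noise = backend$noise, seed = backend$seed)
}

#' OpenAI-compatible HTTP adapter (thin; not used by tests)
#'
#' A minimal chat-completions adapter for OpenAI-compatible endpoints
#' (this dialect also serves Moonshot/Kimi and DeepSeek, which expose the
#' same API shape at different base URLs). Credentials come from the
#' environment variable named in `api_key_env`, never from config files.
#' Requires network access and the `curl` command-line tool; the offline
#' test suite exercises the shared contract through [mock_backend()]
#' only.
#'
#' @param base_url API root, e.g. `https://api.openai.com/v1`.
#' @param api_key_env name of the environment variable holding the key.
#' @param name backend display name.
#' @return a backend object.
#' @export
http_backend <- function(base_url, api_key_env = "OPENAI_API_KEY",
                         name = "openai") {
  structure(list(base_url = base_url, api_key_env = api_key_env),
            class = "http_backend", backend_name = name)
}

#' @export
backend_transport.http_backend <- function(backend, prompt, params) {
  key <- Sys.getenv(backend$api_key_env, unset = "")
  if (!nzchar(key)) {
    transport_error(paste0("no API key in $", backend$api_key_env))
  }
  body <- jsonlite::toJSON(list(
    model = params$model_name,
    temperature = params$temperature,
    messages = list(list(role = "user", content = prompt))
  ), auto_unbox = TRUE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(as.character(body), tmp)
  out <- suppressWarnings(system2(
    "curl",
    c("-sS", "--max-time", params$timeout_s,
      "-H", shQuote(paste0("Authorization: Bearer ", key)),
      "-H", shQuote("Content-Type: application/json"),
      "-d", paste0("@", tmp),
      shQuote(paste0(backend$base_url, "/chat/completions"))),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0
  if (!identical(status, 0)) {
    transport_error(paste0("HTTP transport failed: ",
                           paste(out, collapse = " ")))
  }
  parsed <- tryCatch(jsonlite::fromJSON(paste(out, collapse = "\n")),
                     error = function(e)
                       transport_error("non-JSON HTTP response"))
  txt <- tryCatch(parsed$choices$message$content[[1]],
                  error = function(e) NULL)
  if (is.null(txt)) transport_error("unexpected HTTP response shape")
  txt
}
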