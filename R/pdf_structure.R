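#' Page text container
#'
#' One page of a full-text document as an ordered vector of lines, with a
#' flag recording whether the page carried a machine-readable text layer
#' (OCR output pages do not).
#'
#' @param page_number 1-based page index.
#' @param lines character vector of lines in reading order.
#' @param has_text_layer logical.
#' @return an object of class `page_text`.
#' @export
page_text <- function(page_number, lines, has_text_layer = TRUE) {
  structure(list(page_number = as.integer(page_number),
                 lines = as.character(lines),
                 has_text_layer = isTRUE(has_text_layer)),
            class = "page_text")
}

#' Image-only page stand-in
#'
#' Marks a page with no text layer. `payload` is whatever the OCR contract
#' understands (tests typically store the text the mock OCR should return).
#'
#' @param payload opaque page content handed to the OCR function.
#' @return an object of class `image_page`.
#' @export
image_page <- function(payload = NULL) {
  structure(list(payload = payload), class = "image_page")
}

#' Extract page texts from a page stream
#'
#' Accepts three source shapes:
#' \itemize{
#'   \item a character vector, one element per page (embedded newlines
#'     split into lines); a single element containing form feeds (`\f`)
#'     is split into pages first;
#'   \item a file path to a form-feed separated plain-text page stream;
#'   \item a list mixing character pages and [image_page()] objects.
#' }
#' Pages with a text layer pass through verbatim. Image-only pages are
#' routed through `ocr`, a function `payload -> character lines`; if no
#' OCR contract is supplied, an "unreadable page" error names the pages.
#'
#' @param source page stream (see above).
#' @param ocr optional OCR function.
#' @return list of [page_text()] with strictly increasing page numbers.
#' @export
extract_page_texts <- function(source, ocr = NULL) {
  pages <- as_page_list(source)
  unreadable <- integer(0)
  out <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (inherits(p, "image_page")) {
      if (is.null(ocr)) { unreadable <- c(unreadable, i); next }
      lines <- as.character(ocr(p$payload))
      out[[i]] <- page_text(i, lines, has_text_layer = FALSE)
    } else {
      out[[i]] <- page_text(i, split_lines(p), has_text_layer = TRUE)
    }
  }
  if (length(unreadable)) {
    validation_error(paste0("unreadable page(s) with no text layer and no ",
                            "OCR contract: ",
                            paste(unreadable, collapse = ", ")),
                     pages = unreadable)
  }
  out
}

as_page_list <- function(source) {
  if (is.character(source) && length(source) == 1 && file.exists(source)) {
    raw <- paste(readLines(source, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    source <- strsplit(raw, "\f", fixed = TRUE)[[1]]
  }
  if (is.character(source)) {
    if (length(source) == 1 && grepl("\f", source, fixed = TRUE)) {
      source <- strsplit(source, "\f", fixed = TRUE)[[1]]
    }
    return(as.list(source))
  }
  if (is.list(source)) {
    return(lapply(source, function(p) {
      if (inherits(p, c("image_page", "page_text"))) p else as.character(p)
    }))
  }
  validation_error("unsupported page-stream source")
}

split_lines <- function(x) {
  if (inherits(x, "page_text")) return(x$lines)
  unlist(strsplit(as.character(x), "\n", fixed = TRUE), use.names = FALSE)
}

#' Default heading vocabulary
#'
#' The subtitle vocabulary used to segment articles into canonical
#' sections. Each entry maps a normalized heading string (lowercase, no
#' enumeration, no trailing punctuation) to one of the closed canonical
#' labels: `title`, `abstract`, `introduction`, `methods`, `results`,
#' `discussion`, `conclusion`, `references`, `other`. Editable: pass your
#' own two-column `data.frame(pattern, label)` to [detect_headings()].
#'
#' @return a `data.frame` with columns `pattern` and `label`.
#' @export
default_heading_vocabulary <- function() {
  v <- list(
    abstract = c("abstract", "summary"),
    introduction = c("introduction", "background"),
    methods = c("methods", "method", "methodology",
                "materials and methods", "patients and methods",
                "subjects and methods", "study design and methods"),
    results = c("results", "findings"),
    discussion = c("discussion"),
    conclusion = c("conclusion", "conclusions"),
    references = c("references", "bibliography", "literature cited"),
    other = c("acknowledgments", "acknowledgements", "funding",
              "supplementary material", "conflicts of interest",
              "declarations")
  )
  data.frame(
    pattern = unlist(v, use.names = FALSE),
    label = rep(names(v), lengths(v)),
    stringsAsFactors = FALSE
  )
}

canonical_labels <- function() {
  c("title", "abstract", "introduction", "methods", "results",
    "discussion", "conclusion", "references", "other")
}

# Strip leading enumeration ("2.", "III.", "(b)", "1.2"), trailing
# punctuation, lowercase, collapse spaces. The rule a line must survive
# before vocabulary comparison.
normalize_heading <- function(line) {
  x <- trimws(line)
  x <- sub("^\\(?([0-9]+(\\.[0-9]+)*|[ivxlcIVXLC]+|[A-Za-z])[.)\\]]?\\s+",
           "", x)
  x <- sub("[[:punct:]]+$", "", x)
  x <- tolower(gsub("\\s+", " ", x))
  trimws(x)
}

#' Detect section headings
#'
#' A line is a heading iff its normalized form ([normalize_heading]) is
#' \emph{short} (at most 8 tokens) and matches an entry of the vocabulary
#' exactly. Hits are returned in document order.
#'
#' @param pages list of [page_text()].
#' @param vocabulary `data.frame(pattern, label)`; defaults to
#'   [default_heading_vocabulary()].
#' @return `data.frame` with columns `page_number`, `line_index`,
#'   `raw_text`, `canonical_label`.
#' @export
detect_headings <- function(pages, vocabulary = default_heading_vocabulary()) {
  if (nrow(vocabulary) == 0) config_error("heading vocabulary is empty")
  bad <- setdiff(unique(vocabulary$label), canonical_labels())
  if (length(bad)) {
    config_error(paste0("vocabulary labels outside the canonical set: ",
                        paste(bad, collapse = ", ")))
  }
  hits <- list()
  for (p in pages) {
    for (j in seq_along(p$lines)) {
      norm <- normalize_heading(p$lines[[j]])
      if (!nzchar(norm)) next
      if (length(strsplit(norm, " ", fixed = TRUE)[[1]]) > 8) next
      k <- match(norm, vocabulary$pattern)
      if (!is.na(k)) {
        hits[[length(hits) + 1]] <- data.frame(
          page_number = p$page_number, line_index = j,
          raw_text = p$lines[[j]],
          canonical_label = vocabulary$label[[k]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(page_number = integer(0), line_index = integer(0),
                      raw_text = character(0),
                      canonical_label = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

caption_kind <- function(line) {
  if (grepl("^\\s*(Table)\\s+[0-9IVXivx]+", line)) return("table")
  if (grepl("^\\s*(Fig(ure)?\\.?)\\s+[0-9IVXivx]+", line)) return("figure")
  NA_character_
}

#' Segment pages into a structured article
#'
#' Partitions every non-empty line of the page stream into canonical
#' sections. Text before the first heading hit is front matter: its first
#' non-empty line becomes the `title` section, the remainder the
#' `abstract`. Each span from a heading to the next belongs to that
#' heading's canonical label (the heading line included); consecutive
#' spans with the same label are merged. Lines matching table/figure
#' caption patterns (`Table N`, `Fig(ure) N`) are diverted to
#' `nonprose_elements` instead of section prose.
#'
#' @param pages list of [page_text()].
#' @param hits heading hits from [detect_headings()], in document order.
#' @param record_id identifier carried on the article.
#' @param provenance free-text source description.
#' @return an object of class `structured_article` with fields
#'   `record_id`, `sections` (named list in reading order),
#'   `nonprose_elements` (`data.frame(kind, caption, page_number)`) and
#'   `provenance`.
#' @export
segment_sections <- function(pages, hits, record_id = "article",
                             provenance = "page stream") {
  all_lines <- do.call(rbind, lapply(pages, function(p) {
    data.frame(page_number = rep(p$page_number, length(p$lines)),
               line_index = seq_along(p$lines),
               text = p$lines, stringsAsFactors = FALSE)
  }))
  if (is.null(all_lines) || all(trimws(all_lines$text) == "")) {
    validation_error("empty document: no text on any page")
  }
  # assign a running label to every line: front matter before first hit
  all_lines$label <- NA_character_
  hit_keys <- if (nrow(hits)) paste(hits$page_number, hits$line_index)
  line_keys <- paste(all_lines$page_number, all_lines$line_index)
  current <- "front"
  labels <- character(nrow(all_lines))
  for (i in seq_len(nrow(all_lines))) {
    h <- if (nrow(hits)) match(line_keys[[i]], hit_keys) else NA
    if (!is.na(h)) current <- hits$canonical_label[[h]]
    labels[[i]] <- current
  }
  all_lines$label <- labels

  sections <- list()
  nonprose <- list()
  append_section <- function(label, text) {
    if (!nzchar(text)) return()
    if (length(sections) && names(sections)[length(sections)] == label) {
      sections[[length(sections)]] <<-
        paste(sections[[length(sections)]], text, sep = "\n")
    } else {
      sections[[length(sections) + 1]] <<- text
      names(sections)[length(sections)] <<- label
    }
  }
  title_done <- FALSE
  for (i in seq_len(nrow(all_lines))) {
    txt <- all_lines$text[[i]]
    if (trimws(txt) == "") next
    kind <- caption_kind(txt)
    if (!is.na(kind)) {
      nonprose[[length(nonprose) + 1]] <- data.frame(
        kind = kind, caption = txt,
        page_number = all_lines$page_number[[i]], stringsAsFactors = FALSE)
      next
    }
    lab <- all_lines$label[[i]]
    if (lab == "front") {
      # front-matter rule: first non-empty line is the title, rest abstract
      if (!title_done) { append_section("title", txt); title_done <- TRUE }
      else append_section("abstract", txt)
    } else {
      append_section(lab, txt)
    }
  }
  # merge non-adjacent repeats of a label into the first occurrence,
  # preserving reading order of first appearance
  merged <- list()
  for (i in seq_along(sections)) {
    lab <- names(sections)[[i]]
    if (!is.null(merged[[lab]])) {
      merged[[lab]] <- paste(merged[[lab]], sections[[i]], sep = "\n")
    } else merged[[lab]] <- sections[[i]]
  }
  np <- if (length(nonprose)) do.call(rbind, nonprose) else
    data.frame(kind = character(0), caption = character(0),
               page_number = integer(0), stringsAsFactors = FALSE)
  structure(list(record_id = record_id, sections = merged,
                 nonprose_elements = np, provenance = provenance),
            class = "structured_article")
}

#' Build a structured article from a page stream in one call
#'
#' Convenience composition of [extract_page_texts()], [detect_headings()]
#' and [segment_sections()].
#'
#' @inheritParams extract_page_texts
#' @inheritParams segment_sections
#' @param vocabulary heading vocabulary.
#' @return a `structured_article`.
#' @export
structure_article <- function(source, record_id = "article", ocr = NULL,
                              vocabulary = default_heading_vocabulary(),
                              provenance = "page stream") {
  pages <- extract_page_texts(source, ocr = ocr)
  hits <- detect_headings(pages, vocabulary)
  segment_sections(pages, hits, record_id = record_id,
                   provenance = provenance)
}

#' @export
print.structured_article <- function(x, ...) {
  cat(sprintf("structured_article '%s': sections [%s], %d non-prose\n",
              x$record_id, paste(names(x$sections), collapse = ", "),
              nrow(x$nonprose_elements)))
  invisible(x)
}

#' Serialize / deserialize structured articles as JSON
#'
#' @param article a `structured_article`.
#' @param path file path.
#' @return `path` (writer) or a `structured_article` (reader).
#' @export
write_article_json <- function(article, path) {
  jsonlite::write_json(
    list(record_id = article$record_id,
         sections = as.list(article$sections),
         nonprose_elements = article$nonprose_elements,
         provenance = article$provenance),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_article_json
#' @export
read_article_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  np <- x$nonprose_elements
  if (is.null(np) || length(np) == 0 || nrow(as.data.frame(np)) == 0) {
    np <- data.frame(kind = character(0), caption = character(0),
                     page_number = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(record_id = x$record_id,
                 sections = as.list(x$sections),
                 nonprose_elements = as.data.frame(np),
                 provenance = x$provenance %||% "json"),
            class = "structured_article")
}
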