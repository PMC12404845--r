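#' Bibliographic corpus container
#'
#' A screening corpus is a `data.frame` with one row per bibliographic
#' record and the columns `record_id`, `title`, `abstract`, `authors`
#' (a list-column of character vectors), `year` (integer, `NA` when
#' absent), `journal`, `source_db` and `language` (character, `NA` when
#' absent). `corpus()` validates the invariants: unique non-missing
#' `record_id` and non-empty `title` after cleaning.
#'
#' @param record_id character vector of unique identifiers.
#' @param title,abstract character vectors; `abstract` may be `NA`.
#' @param authors list of character vectors (one per record).
#' @param year integer publication years, `NA` when unknown.
#' @param journal,source_db,language optional character metadata.
#' @return a `data.frame` of class `screen_corpus`.
#' @export
corpus <- function(record_id, title, abstract = NA_character_,
                   authors = NULL, year = NA_integer_,
                   journal = NA_character_, source_db = NA_character_,
                   language = NA_character_) {
  n <- length(record_id)
  if (is.null(authors)) authors <- rep(list(character(0)), n)
  df <- data.frame(
    record_id = as.character(record_id),
    title = as.character(title),
    abstract = rep_len(as.character(abstract), n),
    year = rep_len(as.integer(year), n),
    journal = rep_len(as.character(journal), n),
    source_db = rep_len(as.character(source_db), n),
    language = rep_len(as.character(language), n),
    stringsAsFactors = FALSE
  )
  df$authors <- authors
  validate_corpus(df)
}

validate_corpus <- function(df) {
  if (anyNA(df$record_id) || any(df$record_id == "")) {
    validation_error("every record needs a non-empty record_id")
  }
  if (anyDuplicated(df$record_id)) {
    dup <- unique(df$record_id[duplicated(df$record_id)])
    validation_error(paste0("duplicate record_id: ",
                            paste(dup, collapse = ", ")))
  }
  bad <- which(is.na(df$title) | trimws(df$title) == "")
  if (length(bad)) {
    validation_error(paste0("empty title for record(s): ",
                            paste(df$record_id[bad], collapse = ", ")))
  }
  # empty-string optional fields are normalized to NA, never kept as ""
  for (col in c("abstract", "journal", "source_db", "language")) {
    df[[col]][!is.na(df[[col]]) & trimws(df[[col]]) == ""] <- NA_character_
  }
  class(df) <- c("screen_corpus", "data.frame")
  df
}

#' Read bibliographic records
#'
#' Parses a record file into a [corpus()]. Supported dialects:
#' \describe{
#'   \item{ris}{standard RIS tag set: `TI`/`T1` title, `AB` abstract,
#'     `AU` author (repeatable), `PY`/`Y1` year, `JO`/`JF`/`T2` journal,
#'     `ID` identifier, `ER` end of record.}
#'   \item{csv}{comma-delimited UTF-8 with a header row; recognized
#'     columns `record_id`, `title`, `abstract`, `authors`
#'     (semicolon-separated), `year`, `journal`, `source_db`, `language`.}
#'   \item{medline}{PubMed MEDLINE / .nbib: `PMID`, `TI`, `AB`, `AU`,
#'     `DP`, `JT`, `LA` with 6-space continuation lines.}
#'   \item{corpus_xml}{the internal XML schema written by
#'     [write_corpus_xml()].}
#' }
#' Missing optional fields are `NA`, never the empty string. Records with
#' no identifier in the file are assigned `rec_<index>`.
#'
#' @param path file path.
#' @param format one of `"ris"`, `"csv"`, `"medline"`, `"corpus_xml"`.
#' @return a `screen_corpus`.
#' @export
read_records <- function(path, format = c("ris", "csv", "medline", "corpus_xml")) {
  if (length(format) != 1 || !format %in% c("ris", "csv", "medline", "corpus_xml")) {
    config_error(paste0("unknown corpus format: ",
                        paste(format, collapse = "/")))
  }
  if (!file.exists(path)) io_error(paste0("no such file: ", path))
  switch(format,
    ris = read_ris(path),
    csv = read_corpus_csv(path),
    medline = read_medline(path),
    corpus_xml = read_corpus_xml(path)
  )
}

read_tagged <- function(lines, tag_re, cont_re, end_re, file_label) {
  # generic reader for RIS / MEDLINE tag-per-line formats
  entries <- list()
  cur <- NULL
  cur_tag <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur)) entries[[length(entries) + 1]] <<- cur
    cur <<- NULL
    cur_tag <<- NULL
  }
  for (ln in lines) {
    if (grepl(end_re, ln)) { flush(); next }
    m <- regmatches(ln, regexec(tag_re, ln))[[1]]
    if (length(m)) {
      if (is.null(cur)) cur <- list()
      tag <- m[2]
      val <- m[3]
      cur[[length(cur) + 1]] <- c(tag = tag, value = val)
      cur_tag <- tag
    } else if (grepl(cont_re, ln) && !is.null(cur_tag) && length(cur)) {
      last <- cur[[length(cur)]]
      last["value"] <- paste(last["value"], trimws(ln))
      cur[[length(cur)]] <- last
    } else if (nzchar(trimws(ln)) && !is.null(cur)) {
      parse_error(paste0(file_label, ": unparseable line in entry ",
                         length(entries) + 1, ": ", substr(ln, 1, 60)))
    }
  }
  flush()
  entries
}

tag_values <- function(entry, tags) {
  vals <- vapply(entry, function(x) x[["value"]], character(1))
  names(vals) <- vapply(entry, function(x) x[["tag"]], character(1))
  unname(vals[names(vals) %in% tags])
}

first_or_na <- function(x) if (length(x)) x[[1]] else NA_character_

entries_to_corpus <- function(entries, spec, file_label) {
  n <- length(entries)
  if (n == 0) return(corpus(character(0), character(0)))
  rows <- lapply(seq_len(n), function(i) {
    e <- entries[[i]]
    title <- first_or_na(tag_values(e, spec$title))
    if (is.na(title) || trimws(title) == "") {
      parse_error(paste0(file_label, ": entry ", i, " has no title"))
    }
    year_raw <- first_or_na(tag_values(e, spec$year))
    year <- if (is.na(year_raw)) NA_integer_ else {
      y <- regmatches(year_raw, regexpr("[0-9]{4}", year_raw))
      if (length(y)) as.integer(y) else NA_integer_
    }
    list(
      record_id = first_or_na(tag_values(e, spec$id)) %||% paste0("rec_", i),
      title = title,
      abstract = first_or_na(tag_values(e, spec$abstract)),
      authors = tag_values(e, spec$author),
      year = year,
      journal = first_or_na(tag_values(e, spec$journal)),
      language = first_or_na(tag_values(e, spec$language %||% character(0)))
    )
  })
  corpus(
    record_id = vapply(rows, `[[`, "", "record_id"),
    title = vapply(rows, `[[`, "", "title"),
    abstract = vapply(rows, `[[`, "", "abstract"),
    authors = lapply(rows, `[[`, "authors"),
    year = vapply(rows, `[[`, 1L, "year"),
    journal = vapply(rows, `[[`, "", "journal"),
    language = vapply(rows, `[[`, "", "language")
  )
}

read_ris <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- read_tagged(
    lines,
    tag_re = "^([A-Z][A-Z0-9])  - ?(.*)$",
    cont_re = "^\\s{2,}\\S",
    end_re = "^ER  -",
    file_label = path
  )
  entries_to_corpus(entries, list(
    id = "ID", title = c("TI", "T1"), abstract = c("AB", "N2"),
    author = c("AU", "A1"), year = c("PY", "Y1"),
    journal = c("JO", "JF", "T2"), language = "LA"
  ), path)
}

read_medline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # records separated by blank lines; continuation lines start with 6 spaces
  entries <- list()
  cur <- character(0)
  for (ln in c(lines, "")) {
    if (trimws(ln) == "") {
      if (length(cur)) {
        entries[[length(entries) + 1]] <- parse_medline_entry(cur, path,
                                                              length(entries) + 1)
        cur <- character(0)
      }
    } else cur <- c(cur, ln)
  }
  entries_to_corpus(entries, list(
    id = "PMID", title = "TI", abstract = "AB", author = c("AU", "FAU"),
    year = "DP", journal = "JT", language = "LA"
  ), path)
}

parse_medline_entry <- function(lines, path, idx) {
  entry <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Z]{1,4})\\s*- (.*)$", ln))[[1]]
    if (length(m)) {
      entry[[length(entry) + 1]] <- c(tag = m[2], value = m[3])
    } else if (grepl("^\\s{6}", ln) && length(entry)) {
      last <- entry[[length(entry)]]
      last["value"] <- paste(last["value"], trimws(ln))
      entry[[length(entry)]] <- last
    } else {
      parse_error(paste0(path, ": unparseable line in entry ", idx, ": ",
                         substr(ln, 1, 60)))
    }
  }
  entry
}

read_corpus_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                    colClasses = "character"),
    error = function(e) parse_error(paste0(path, ": ", conditionMessage(e)))
  )
  if (!"title" %in% names(df)) {
    parse_error(paste0(path, ": CSV corpus needs a 'title' column"))
  }
  n <- nrow(df)
  get_col <- function(name) {
    if (name %in% names(df)) {
      x <- df[[name]]
      x[!is.na(x) & trimws(x) == ""] <- NA_character_
      x
    } else rep(NA_character_, n)
  }
  year_raw <- get_col("year")
  authors <- lapply(get_col("authors"), function(a) {
    if (is.na(a)) character(0) else trimws(strsplit(a, ";")[[1]])
  })
  corpus(
    record_id = get_col("record_id") %|na|% paste0("rec_", seq_len(n)),
    title = get_col("title"),
    abstract = get_col("abstract"),
    authors = authors,
    year = suppressWarnings(as.integer(year_raw)),
    journal = get_col("journal"),
    source_db = get_col("source_db"),
    language = get_col("language")
  )
}

`%|na|%` <- function(a, b) { a[is.na(a)] <- b[is.na(a)]; a }

#' Clean bibliographic text
#'
#' Removes markup remnants and normalizes whitespace: decodes common HTML
#' entities (named and numeric), strips simple inline tags such as
#' `<i>`/`<sub>`, drops control characters, collapses internal whitespace
#' runs to single spaces and trims the ends. Idempotent; empty input maps
#' to the empty string.
#'
#' @param raw character vector.
#' @return cleaned character vector of the same length.
#' @export
clean_text <- function(raw) {
  vapply(raw, function(x) {
    if (is.na(x)) return(NA_character_)
    x <- enc2utf8(x)
    # numeric entities first, then named; loop so "&amp;amp;" fully decodes
    repeat {
      y <- decode_numeric_entities(x)
      y <- decode_entities(y)
      if (identical(y, x)) break
      x <- y
    }
    x <- gsub("</?[A-Za-z][A-Za-z0-9]*(\\s[^<>]*)?/?>", " ", x)  # inline tags
    x <- gsub("[\\x01-\\x08\\x0b\\x0c\\x0e-\\x1f\\x7f]", "", x, perl = TRUE)
    x <- gsub("[\t\r\n]", " ", x)
    x <- gsub(" {2,}", " ", x)
    trimws(x)
  }, character(1), USE.NAMES = FALSE)
}

decode_entities <- function(x) {
  ents <- c("&lt;" = "<", "&gt;" = ">", "&quot;" = "\"", "&apos;" = "'",
            "&nbsp;" = " ", "&ndash;" = "-", "&mdash;" = "-", "&amp;" = "&")
  for (k in names(ents)) x <- gsub(k, ents[[k]], x, fixed = TRUE)
  x
}

# numeric character references: decode via codepoint
decode_numeric_entities <- function(x) {
  m <- gregexpr("&#x?[0-9A-Fa-f]+;", x)
  regmatches(x, m) <- lapply(regmatches(x, m), function(hits) {
    vapply(hits, function(h) {
      hex <- grepl("^&#x", h, ignore.case = TRUE)
      num <- gsub("[^0-9A-Fa-f]", "", sub("^&#x?", "", h, ignore.case = TRUE))
      intToUtf8(strtoi(num, base = if (hex) 16L else 10L))
    }, character(1))
  })
  x
}

#' Normalized deduplication key
#'
#' The key on which two records are compared: the title after Unicode NFKC
#' normalization, lowercasing, removal of all non-alphanumeric characters
#' and collapse of space runs; plus the publication year. Idempotent.
#'
#' @param title character vector of titles.
#' @return character vector of normalized titles.
#' @export
norm_title <- function(title) {
  x <- stringi::stri_trans_nfkc(enc2utf8(title))
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", "", x)
  x <- gsub(" {2,}", " ", x)
  trimws(x)
}

#' Deduplicate a corpus
#'
#' Two records are duplicates when their normalized titles ([norm_title()])
#' are equal and their years are compatible (equal, or either absent).
#' The first-seen record of each duplicate cluster is kept; output order
#' preserves the input order of kept records. Year compatibility is
#' evaluated against the kept (cluster head) record, so a year-less record
#' joins the first compatible cluster.
#'
#' Optionally, `fuzzy = TRUE` additionally merges records whose title token
#' sets have Jaccard similarity at or above `jaccard_threshold` (and
#' compatible years); off by default because exact-key matching is the
#' documented rule.
#'
#' @param records a `screen_corpus`.
#' @param fuzzy enable token-Jaccard fallback matching.
#' @param jaccard_threshold similarity threshold in (0, 1] for fuzzy mode.
#' @return `list(records = kept corpus, report = dedup_report)` where the
#'   report has `input_count`, `unique_count`, `removed_count` and
#'   `clusters` (named list: kept id -> character vector of removed ids).
#' @export
deduplicate <- function(records, fuzzy = FALSE, jaccard_threshold = 0.9) {
  n <- nrow(records)
  keys <- norm_title(records$title)
  years <- records$year
  kept_idx <- integer(0)
  owner <- integer(n)  # index of cluster head for each record, 0 = head
  token_sets <- if (fuzzy) lapply(strsplit(keys, " ", fixed = TRUE), unique)
  for (i in seq_len(n)) {
    head_i <- 0L
    for (k in kept_idx) {
      same_key <- keys[[k]] == keys[[i]]
      if (!same_key && fuzzy) {
        inter <- length(intersect(token_sets[[k]], token_sets[[i]]))
        uni <- length(union(token_sets[[k]], token_sets[[i]]))
        same_key <- uni > 0 && inter / uni >= jaccard_threshold
      }
      year_ok <- is.na(years[[k]]) || is.na(years[[i]]) ||
        years[[k]] == years[[i]]
      if (same_key && year_ok) { head_i <- k; break }
    }
    if (head_i == 0L) kept_idx <- c(kept_idx, i) else owner[[i]] <- head_i
  }
  clusters <- list()
  for (k in kept_idx) {
    removed <- records$record_id[which(owner == k)]
    if (length(removed)) clusters[[records$record_id[[k]]]] <- removed
  }
  report <- dedup_report(
    input_count = n,
    unique_count = length(kept_idx),
    clusters = clusters
  )
  kept <- records[kept_idx, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- class(records)
  list(records = kept, report = report)
}

#' @rdname deduplicate
#' @param input_count,unique_count record counts before/after deduplication.
#' @param clusters named list mapping each kept `record_id` that absorbed
#'   duplicates to the character vector of removed `record_id`s.
#' @export
dedup_report <- function(input_count, unique_count, clusters = list()) {
  removed <- input_count - unique_count
  n_listed <- sum(lengths(clusters))
  if (n_listed != removed) {
    accounting_error(sprintf(
      "dedup report inconsistent: %d removed but %d listed in clusters",
      removed, n_listed))
  }
  structure(
    list(input_count = input_count, unique_count = unique_count,
         removed_count = removed, clusters = clusters),
    class = "dedup_report"
  )
}

#' @export
print.dedup_report <- function(x, ...) {
  cat(sprintf("dedup: %d in, %d unique, %d removed (%d clusters)\n",
              x$input_count, x$unique_count, x$removed_count,
              length(x$clusters)))
  invisible(x)
}

#' Write / read the internal corpus XML
#'
#' One `<record id="...">` element per record with `<title>`, `<abstract>`,
#' `<authors><author/>...</authors>`, `<year>`, `<journal>`, `<source_db>`
#' and `<language>` children; absent optional fields emit no element, so
#' `read_records(path, "corpus_xml")` inverts the writer losslessly.
#'
#' @param records a `screen_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_xml <- function(records, path) {
  doc <- xml2::xml_new_root("corpus")
  for (i in seq_len(nrow(records))) {
    rec <- xml2::xml_add_child(doc, "record", id = records$record_id[[i]])
    add <- function(name, value) {
      if (!is_absent(value)) {
        node <- xml2::xml_add_child(rec, name)
        xml2::xml_text(node) <- as.character(value)
      }
    }
    add("title", records$title[[i]])
    add("abstract", records$abstract[[i]])
    auths <- records$authors[[i]]
    if (length(auths)) {
      anode <- xml2::xml_add_child(rec, "authors")
      for (a in auths) {
        node <- xml2::xml_add_child(anode, "author")
        xml2::xml_text(node) <- a
      }
    }
    add("year", records$year[[i]])
    add("journal", records$journal[[i]])
    add("source_db", records$source_db[[i]])
    add("language", records$language[[i]])
  }
  ok <- tryCatch({ xml2::write_xml(doc, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) io_error(paste0("cannot write corpus XML to ", path))
  invisible(path)
}

read_corpus_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) parse_error(paste0(path, ": ",
                                                         conditionMessage(e))))
  recs <- xml2::xml_find_all(doc, "./record")
  if (length(recs) == 0) return(corpus(character(0), character(0)))
  field <- function(rec, name) {
    node <- xml2::xml_find_first(rec, paste0("./", name))
    if (inherits(node, "xml_missing")) NA_character_ else xml2::xml_text(node)
  }
  corpus(
    record_id = xml2::xml_attr(recs, "id"),
    title = vapply(recs, field, "", "title"),
    abstract = vapply(recs, field, "", "abstract"),
    authors = lapply(recs, function(r)
      xml2::xml_text(xml2::xml_find_all(r, "./authors/author"))),
    year = suppressWarnings(as.integer(vapply(recs, field, "", "year"))),
    journal = vapply(recs, field, "", "journal"),
    source_db = vapply(recs, field, "", "source_db"),
    language = vapply(recs, field, "", "language")
  )
}
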