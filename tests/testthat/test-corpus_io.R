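test_that("RIS files round-trip entry counts and fields", {
  ris <- file.path(tempdir(), "t.ris")
  writeLines(c(
    "TY  - JOUR", "ID  - r1", "TI  - First vaccine study",
    "AB  - Some abstract", "AU  - Smith J", "AU  - Doe A",
    "PY  - 2020", "JO  - Vaccine", "ER  - ", "",
    "TY  - JOUR", "TI  - Second study", "PY  - 2019", "ER  - ", "",
    "TY  - JOUR", "TI  - Third study", "ER  - "), ris)
  recs <- read_records(ris, "ris")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$record_id[[1]], "r1")
  expect_equal(recs$authors[[1]], c("Smith J", "Doe A"))
  expect_equal(recs$year, c(2020L, 2019L, NA))
  expect_true(is.na(recs$abstract[[3]]))  # absent, never ""
})

test_that("CSV corpus marks empty optional cells as absent", {
  csv <- file.path(tempdir(), "t.csv")
  writeLines(c("record_id,title,abstract,year",
               "x1,Alpha study,Has an abstract,2021",
               "x2,Beta study,,"), csv)
  recs <- read_records(csv, "csv")
  expect_true(is.na(recs$year[[2]]))
  expect_true(is.na(recs$abstract[[2]]))
  expect_equal(recs$year[[1]], 2021L)
})

test_that("MEDLINE entries parse with continuation lines", {
  nbib <- file.path(tempdir(), "t.nbib")
  writeLines(c("PMID- 123",
               "TI  - A long title that",
               "      continues on the next line",
               "AB  - The abstract",
               "AU  - Smith J",
               "DP  - 2018 Mar",
               "JT  - Journal of Testing",
               "",
               "PMID- 456",
               "TI  - Second record"), nbib)
  recs <- read_records(nbib, "medline")
  expect_equal(nrow(recs), 2)
  expect_equal(recs$title[[1]], "A long title that continues on the next line")
  expect_equal(recs$year[[1]], 2018L)
  expect_equal(recs$record_id, c("123", "456"))
})

test_that("unknown format and malformed entries raise classed errors", {
  f <- file.path(tempdir(), "x.ris")
  writeLines("TI  - ok", f)
  expect_error(read_records(f, "bibtex"), class = "config_error")
  writeLines(c("TI  - has title", "garbage line with no tag", "ER  - "), f)
  expect_error(read_records(f, "ris"), class = "parse_error",
               regexp = "entry 1")
})

test_that("clean_text collapses whitespace, strips markup, is idempotent", {
  expect_equal(clean_text("RSV  vaccine\t safety\n"), "RSV vaccine safety")
  clean <- "Already clean text."
  expect_equal(clean_text(clean), clean)
  # entity decode against a reference XML decoder
  raw <- "Safety &amp; efficacy of &lt;i&gt;RSV&lt;/i&gt; vaccines &#8211; a review"
  ref <- xml2::xml_text(xml2::read_xml(paste0("<x>", raw, "</x>")))
  ref <- trimws(gsub(" {2,}", " ", gsub("</?i>", " ", ref)))
  expect_equal(clean_text(raw), ref)
  expect_equal(clean_text(clean_text(raw)), clean_text(raw))
  expect_equal(clean_text(""), "")
})

test_that("deduplicate applies the normalized-title + compatible-year rule", {
  recs <- tiny_corpus()
  dd <- deduplicate(recs)
  expect_equal(dd$report$removed_count, 1)
  expect_equal(dd$records$record_id, c("a", "c"))  # first-seen kept
  expect_equal(dd$report$clusters, list(a = "b"))

  # same title, different years: both kept
  recs2 <- corpus(record_id = c("p", "q"),
                  title = c("Same title here", "Same title here!"),
                  year = c(2019L, 2021L))
  dd2 <- deduplicate(recs2)
  expect_equal(dd2$report$removed_count, 0)

  # absent year is compatible with any year
  recs3 <- corpus(record_id = c("p", "q"),
                  title = c("Same title here", "Same title here"),
                  year = c(2019L, NA))
  expect_equal(deduplicate(recs3)$report$removed_count, 1)

  # no matching keys: identity
  dd4 <- deduplicate(recs[3, , drop = FALSE])
  expect_equal(dd4$report$removed_count, 0)
  expect_equal(dd4$records$record_id, "c")
})

test_that("fuzzy mode merges near-identical token sets only when enabled", {
  recs <- corpus(record_id = c("p", "q"),
                 title = c("the rsv vaccine safety cohort study report",
                           "the rsv vaccine safety cohort study reports extra"),
                 year = c(2020L, 2020L))
  expect_equal(deduplicate(recs)$report$removed_count, 0)
  expect_equal(deduplicate(recs, fuzzy = TRUE,
                           jaccard_threshold = 0.6)$report$removed_count, 1)
})

test_that("dedup invariants hold on random corpora", {
  for (seed in 1:5) {
    gen <- small_corpus(n = 40, seed = seed)
    inj <- inject_duplicates(gen$records, rate = 0.2, seed = seed + 100)
    dd <- deduplicate(inj$records)
    # conservation
    expect_equal(dd$report$input_count,
                 dd$report$unique_count + dd$report$removed_count)
    expect_equal(sum(lengths(dd$report$clusters)), dd$report$removed_count)
    # idempotence
    dd2 <- deduplicate(dd$records)
    expect_equal(dd2$report$removed_count, 0)
    expect_equal(dd2$records$record_id, dd$records$record_id)
  }
})

test_that("corpus XML writer and reader are inverse on random corpora", {
  xml <- file.path(tempdir(), "c.xml")
  for (seed in 1:3) {
    gen <- small_corpus(n = 25, seed = seed)
    write_corpus_xml(gen$records, xml)
    back <- read_records(xml, "corpus_xml")
    expect_equal(back, gen$records)
  }
  # unicode title round-trips
  uni <- corpus(record_id = "u1",
                title = "Vaccin\u00e9 s\u00fbret\u00e9 \u03b1\u03b2",
                abstract = "r\u00e9sum\u00e9", year = 2022L,
                authors = list("M\u00fcller T"))
  write_corpus_xml(uni, xml)
  expect_equal(read_records(xml, "corpus_xml"), uni)
  # empty corpus produces valid XML with zero records
  empty <- corpus(character(0), character(0))
  write_corpus_xml(empty, xml)
  expect_equal(nrow(read_records(xml, "corpus_xml")), 0)
  # absent year emits no element
  noyr <- corpus(record_id = "n1", title = "No year record")
  write_corpus_xml(noyr, xml)
  doc <- xml2::read_xml(xml)
  expect_equal(length(xml2::xml_find_all(doc, "//year")), 0)
  expect_true(is.na(read_records(xml, "corpus_xml")$year[[1]]))
})

test_that("corpus validation rejects duplicate ids and empty titles", {
  expect_error(corpus(c("a", "a"), c("t1", "t2")),
               class = "validation_error")
  expect_error(corpus("a", "  "), class = "validation_error")
})
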