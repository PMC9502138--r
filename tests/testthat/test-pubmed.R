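fixtures <- make_fixture_dir()
transport <- fixture_transport(fixtures)

test_that("search_pmids truncates, pages and deduplicates", {
  expect_equal(search_pmids("geneA AND epilepsy", 3, transport),
               c("11", "12", "13"))
  expect_equal(search_pmids("geneA AND epilepsy", 100, transport),
               c("11", "12", "13", "14", "15"))
  # paging: page size 2 forces three ESearch calls, same result
  expect_equal(search_pmids("geneA AND epilepsy", 100, transport,
                            page_size = 2L),
               c("11", "12", "13", "14", "15"))
  expect_equal(search_pmids("nothing matches this", 10, transport),
               character())
})

test_that("max_n = 0 short-circuits without touching the transport", {
  expect_equal(search_pmids("geneA AND epilepsy", 0, forbidden_transport),
               character())
})

test_that("search_pmids validates its query", {
  expect_error(search_pmids("", 5, transport),
               class = "litsim_validation_error")
  expect_error(search_pmids("q", -1, transport),
               class = "litsim_validation_error")
})

test_that("fetch_abstracts returns plain text in input order", {
  recs <- fetch_abstracts(c("123"), transport, include_title = FALSE)
  expect_equal(recs, data.frame(pmid = "123", text = "Some abstract."))
  recs <- fetch_abstracts(c("12", "11"), transport)
  expect_equal(recs$pmid, c("12", "11"))
  # title prepended, XML entities decoded, whitespace collapsed
  expect_equal(recs$text[2],
               "Sodium channels. Ion channels mediate seizures & epilepsy.")
  expect_false(any(grepl("[<>]|&amp;|\\s{2}", recs$text)))
})

test_that("PMIDs without abstracts are dropped with a logged skip", {
  expect_message(
    recs <- fetch_abstracts(c("11", "14", "999"), transport),
    "14")
  expect_equal(recs$pmid, "11")
})

test_that("empty PMID input makes no transport call", {
  expect_equal(nrow(fetch_abstracts(character(), forbidden_transport)), 0L)
})

test_that("populate_by_queries fills PMIDs or abstracts per mode", {
  tab <- entity_table(c("geneA", "geneB"),
                      query = c("geneA AND epilepsy", "geneB AND tumor"))
  out <- populate_by_queries(tab, mode = "pmids", max_n = 2,
                             transport = transport)
  expect_equal(out$pmids, list(c("11", "12"), c("21", "22")))
  expect_equal(lengths(out$texts), c(0L, 0L))
  expect_equal(lengths(tab$pmids), c(0L, 0L))  # input not mutated

  out <- populate_by_queries(tab, mode = "abstracts", max_n = 3,
                             transport = transport)
  # abstracts recorded AND the searched PMIDs kept for downstream stages
  expect_equal(out$pmids[[1]], c("11", "12", "13"))
  expect_equal(length(out$texts[[1]]), 3L)
  expect_match(out$texts[[2]][1], "tumor")
})

test_that("queries with no hits leave the record unchanged with a warning", {
  tab <- entity_table("lonely", query = "nothing matches this")
  expect_message(out <- populate_by_queries(tab, mode = "pmids", max_n = 5,
                                            transport = transport),
                 "lonely")
  expect_equal(out$pmids[[1]], character())
})

test_that("populate_by_queries requires a query on every record", {
  tab <- entity_table(c("a", "b"), query = c("q", NA))
  err <- expect_error(populate_by_queries(tab, transport = transport),
                      class = "litsim_validation_error")
  expect_match(conditionMessage(err), "b")
})

test_that("populate_abstracts_by_pmids appends to custom text", {
  tab <- entity_table(c("geneA", "noted"),
                      pmids = list("123", character()),
                      texts = list("my note", "only text"))
  out <- populate_abstracts_by_pmids(tab, transport)
  expect_equal(out$texts[[1]], c("my note", "Some abstract."))
  expect_equal(out$texts[[2]], "only text")  # no PMIDs: unchanged
})

test_that("a PMID shared by two entities is fetched for each", {
  tab <- entity_table(c("x", "y"), pmids = list("123", "123"))
  out <- populate_abstracts_by_pmids(tab, transport)
  expect_equal(out$texts[[1]], out$texts[[2]])
})

test_that("a table with no PMIDs at all is rejected", {
  tab <- entity_table("x", texts = list("note"))
  expect_error(populate_abstracts_by_pmids(tab, transport),
               class = "litsim_validation_error")
})
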