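test_that("tokenize applies the quality-control pipeline in order", {
  expect_equal(tokenize("Ion channels; 2 genes."),
               c("ion", "channels", "genes"))
  expect_equal(tokenize(""), character())
  expect_equal(tokenize("the and of"), character())
  # digit characters are stripped within tokens, not token-dropping
  expect_equal(tokenize("scn1a mutations"), c("scna", "mutations"))
  opts <- tokenization_options(drop_digit_tokens = TRUE)
  expect_equal(tokenize("scn1a mutations", opts), "mutations")
  expect_error(tokenization_options(min_token_length = 0),
               class = "litsim_validation_error")
})

test_that("tokenize is idempotent on its own output without stemming", {
  texts <- c("Ion channels; 2 genes.", "Tumor-suppressor p53 WAS active!",
             "Neuronal KCNQ4 and KCNB1 potassium channels")
  for (tx in texts) {
    once <- tokenize(tx)
    expect_equal(tokenize(paste(once, collapse = " ")), once)
  }
})

test_that("the Porter stemmer matches canonical stem pairs", {
  expect_equal(
    porter_stem(c("caresses", "ponies", "cats", "motoring", "hopping",
                  "happy", "sky", "relational", "adoption", "seizures",
                  "running", "channels", "electrical", "goodness")),
    c("caress", "poni", "cat", "motor", "hop", "happi", "sky", "relat",
      "adopt", "seizur", "run", "channel", "electr", "good"))
  opts <- tokenization_options(stem = TRUE)
  expect_equal(tokenize("Seizures and epilepsies", opts),
               c("seizur", "epilepsi"))
})

test_that("count_terms sums token counts across an entity's texts", {
  counts <- count_terms("E1", c("gene channel", "channel channel seizure"))
  expect_equal(counts[order(names(counts))],
               c(channel = 3L, gene = 1L, seizure = 1L))
  expect_equal(count_terms("E1", character()), integer())
})

test_that("exclude_self removes the entity's own name tokens", {
  counts <- count_terms("channel1", c("channel channel gene"))
  expect_equal(counts, c(gene = 1L))
  counts <- count_terms("channel1", c("channel channel gene"),
                        options = tokenization_options(exclude_self = FALSE))
  expect_equal(counts[order(names(counts))], c(channel = 2L, gene = 1L))
  # the query's tokens are excluded too
  counts <- count_terms("E1", c("tumor gene gene"), query = "tumor AND mice")
  expect_equal(counts, c(gene = 2L))
})

test_that("count_concepts uses per-document presence counting", {
  ann <- data.frame(
    pmid = c("1", "1", "1", "2", "3"),
    category = "gene",
    concept_id = c("6323", "6323", "6323", "6323", "6323"),
    mention = "SCN1A", stringsAsFactors = FALSE)
  # mentioned three times in abstract 1, once in abstract 2: counts 2
  expect_equal(count_concepts(c("1", "2"), ann), c("gene:6323" = 2L))
  expect_equal(count_concepts("1", ann), c("gene:6323" = 1L))
  expect_equal(count_concepts(c("8", "9"), ann), integer())
})

test_that("select_top_terms ranks by count with lexicographic ties", {
  counts <- c(channel = 5L, gene = 3L, seizure = 3L, rare = 1L)
  expect_equal(select_top_terms(counts, 2), c("channel", "gene"))
  expect_equal(select_top_terms(counts, 0), character())
  expect_equal(select_top_terms(c(a = 1L, b = 2L), 50), c("b", "a"))
})

test_that("select_top_terms agrees with the brute-force oracle", {
  set.seed(42)
  vocab <- c(outer(letters, letters, paste0))
  for (i in 1:500) {
    k <- sample(1:40, 1)
    counts <- stats::setNames(sample(1:8, k, replace = TRUE),
                              sample(vocab, k))
    n_top <- sample(0:15, 1)
    expect_identical(select_top_terms(counts, n_top),
                     top_terms_oracle(counts, n_top))
  }
})

test_that("build_matrix assembles the sorted union with 0/1 cells", {
  m <- build_matrix(list(A = c("channel", "gene"), B = c("gene", "tumor")))
  expect_equal(colnames(m), c("channel", "gene", "tumor"))
  expect_equal(unname(unclass(m)["A", ]), c(1L, 1L, 0L))
  expect_equal(unname(unclass(m)["B", ]), c(0L, 1L, 1L))

  single <- build_matrix(list(X = c("b", "a", "c")))
  expect_equal(unname(rowSums(single)), 3)

  with_empty <- build_matrix(list(A = c("gene"), B = character()))
  expect_equal(unname(rowSums(with_empty)), c(1, 0))
  expect_true(all(colSums(with_empty) > 0))
})

test_that("rows are capped at n_top ones and identical texts give identical rows", {
  tab <- toy_entity_table()
  for (n_top in c(1, 2, 50)) {
    m <- text_to_wordmatrix(tab, n_top = n_top)
    expect_true(all(rowSums(m) <= n_top))
    expect_true(all(m %in% c(0L, 1L)))
    expect_true(all(colSums(m) > 0))
  }
  twin <- entity_table(c("L", "R"), texts = list(
    c("channel seizure gene"), c("channel seizure gene")))
  m <- text_to_wordmatrix(twin)
  expect_equal(unname(unclass(m)["L", ]), unname(unclass(m)["R", ]))
})

test_that("the concept pipeline builds a matrix from fixture annotations", {
  transport <- fixture_transport(make_fixture_dir())
  tab <- entity_table(c("SCN1A", "TP53"),
                      pmids = list(c("11", "12", "13"), "21"))
  m <- pmids_to_pubtator_matrix(tab, categories = c("gene", "disease"),
                                transport = transport)
  expect_equal(rownames(m), c("SCN1A", "TP53"))
  expect_equal(colnames(m),
               c("disease:MESH:D004827", "gene:6323", "gene:7157"))
  expect_equal(unname(unclass(m)["SCN1A", ]), c(1L, 1L, 0L))
  expect_equal(unname(unclass(m)["TP53", ]), c(0L, 0L, 1L))
})
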