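# Fixture transport directory built in code at test time, plus the
# independent oracles used across the suite.

make_fixture_dir <- function() {
  dir <- tempfile("fixtures")
  dir.create(dir)
  jsonlite::write_json(list(
    "geneA AND epilepsy" = c("11", "12", "13", "14", "15"),
    "geneB AND tumor" = c("21", "22"),
    "nothing matches this" = character()
  ), file.path(dir, "queries.json"))
  jsonlite::write_json(list(
    "11" = list(title = "Sodium channels.",
                abstract = "Ion channels mediate seizures & epilepsy."),
    "12" = list(title = "Scn1a function.",
                abstract = "Channel loss causes seizure phenotypes."),
    "13" = list(title = "Review of epilepsies.",
                abstract = "Genetic epilepsies involve ion channels."),
    "14" = list(title = "Old citation without body.", abstract = ""),
    "15" = list(title = "Sodium currents.",
                abstract = "Currents in neurons are channel mediated."),
    "21" = list(title = "Tumor suppressors.",
                abstract = "Suppressor genes restrain tumor growth."),
    "22" = list(title = "Oncogene review.",
                abstract = "Oncogenes drive tumor proliferation."),
    "123" = list(title = "", abstract = "Some abstract.")
  ), file.path(dir, "abstracts.json"), auto_unbox = TRUE)
  ann <- data.frame(
    pmid = c("11", "11", "12", "12", "13", "21", "11"),
    type = c("Gene", "Disease", "Gene", "Disease", "Gene", "Gene",
             "Mutation"),
    concept_id = c("6323", "MESH:D004827", "6323", "MESH:D004827", "6323",
                   "7157", "-"),
    mention = c("SCN1A", "epilepsy", "Scn1a", "Epilepsy", "SCN1A", "TP53",
                "p.R1648H"),
    stringsAsFactors = FALSE)
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dir
}

# Transport that fails the test if any request goes out.
forbidden_transport <- function(endpoint, params) {
  stop("transport must not be called")
}

# Brute-force pair-enumeration ARI: classify every entity pair as together
# or apart in each partition and apply the closed form on the four pair
# counts. Independent of the contingency-table implementation.
ari_pair_oracle <- function(p, q) {
  n <- length(p)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same_p <- p[i] == p[j]
      same_q <- q[i] == q[j]
      if (same_p && same_q) n11 <- n11 + 1
      else if (!same_p && !same_q) n00 <- n00 + 1
      else if (same_p) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  denom <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (denom == 0) return(1)
  2 * (n00 * n11 - n01 * n10) / denom
}

# Brute-force top-N selection: sort the full (count, term) table.
top_terms_oracle <- function(counts, n_top) {
  df <- data.frame(term = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$term), ]
  utils::head(df$term, n_top)
}

toy_entity_table <- function() {
  entity_table(
    c("A", "B", "C", "D", "E"),
    grouping = data.frame(CATEGORY = c("ion", "ion", "onco", "onco", "onco")),
    texts = list(
      c("channel channel channel seizure seizure gene",
        "channel sodium seizure"),
      c("channel channel seizure sodium sodium"),
      c("tumor tumor suppressor oncogene growth"),
      c("tumor oncogene oncogene suppressor"),
      c("tumor growth growth oncogene")))
}
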