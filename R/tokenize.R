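# Snowball English stopword list (function words dropped before frequency
# ranking); comparison happens after lowercasing.
STOPWORDS_EN <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
  "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
  "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
  "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
  "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
  "being", "have", "has", "had", "having", "do", "does", "did", "doing",
  "would", "should", "could", "ought", "i'm", "you're", "he's", "she's",
  "it's", "we're", "they're", "i've", "you've", "we've", "they've", "i'd",
  "you'd", "he'd", "she'd", "we'd", "they'd", "i'll", "you'll", "he'll",
  "she'll", "we'll", "they'll", "isn't", "aren't", "wasn't", "weren't",
  "hasn't", "haven't", "hadn't", "doesn't", "don't", "didn't", "won't",
  "wouldn't", "shan't", "shouldn't", "can't", "cannot", "couldn't",
  "mustn't", "let's", "that's", "who's", "what's", "here's", "there's",
  "when's", "where's", "why's", "how's", "a", "an", "the", "and", "but",
  "if", "or", "because", "as", "until", "while", "of", "at", "by", "for",
  "with", "about", "against", "between", "into", "through", "during",
  "before", "after", "above", "below", "to", "from", "up", "down", "in",
  "out", "on", "off", "over", "under", "again", "further", "then", "once",
  "here", "there", "when", "where", "why", "how", "all", "any", "both",
  "each", "few", "more", "most", "other", "some", "such", "no", "nor",
  "not", "only", "own", "same", "so", "than", "too", "very")

#' Tokenization options
#'
#' Bundles the word quality-control settings applied before frequency
#' ranking. The pipeline order is fixed: lowercase, strip punctuation
#' characters, strip digit characters, split on whitespace, drop tokens
#' shorter than `min_token_length`, drop stopwords, then (optionally) stem.
#'
#' @param lowercase lowercase the text first?
#' @param strip_punctuation remove punctuation characters?
#' @param strip_digits remove digit characters inside tokens (so `"scn1a"`
#'   becomes `"scna"` rather than being dropped wholesale)? Set
#'   `drop_digit_tokens = TRUE` to instead drop any token containing a digit.
#' @param drop_digit_tokens drop whole tokens containing digits instead of
#'   stripping the digit characters.
#' @param min_token_length minimum token length kept (default 3).
#' @param stopwords character vector of stopwords (compared after
#'   lowercasing); defaults to a standard English list.
#' @param extra_stopwords additional stopwords appended to `stopwords`.
#' @param stem apply the Porter stemmer ([porter_stem()])?
#' @param exclude_self drop tokens that also occur in the tokenized form of
#'   the entity's own identifier and query (an entity's own name trivially
#'   tops its frequency list and carries no similarity signal)?
#' @return A `tokenization_options` list.
#' @export
tokenization_options <- function(lowercase = TRUE, strip_punctuation = TRUE,
                                 strip_digits = TRUE,
                                 drop_digit_tokens = FALSE,
                                 min_token_length = 3L,
                                 stopwords = STOPWORDS_EN,
                                 extra_stopwords = character(),
                                 stem = FALSE, exclude_self = TRUE) {
  if (min_token_length < 1) stop_validation("min_token_length must be >= 1")
  structure(list(lowercase = lowercase,
                 strip_punctuation = strip_punctuation,
                 strip_digits = strip_digits,
                 drop_digit_tokens = drop_digit_tokens,
                 min_token_length = as.integer(min_token_length),
                 stopwords = unique(c(stopwords, extra_stopwords)),
                 stem = stem, exclude_self = exclude_self),
            class = "tokenization_options")
}

#' Tokenize text
#'
#' Applies the quality-control pipeline described in
#' [tokenization_options()] and returns the surviving tokens in text order.
#'
#' @param text a character scalar (or vector, concatenated in order).
#' @param options a [tokenization_options()] object.
#' @return Character vector of tokens; empty input yields `character(0)`.
#' @examples
#' tokenize("Ion channels; 2 genes.")
#' @export
tokenize <- function(text, options = tokenization_options()) {
  text <- paste(text, collapse = " ")
  if (!nzchar(text)) return(character())
  if (options$lowercase) text <- tolower(text)
  if (options$strip_punctuation) text <- gsub("[[:punct:]]", " ", text)
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  if (options$drop_digit_tokens) {
    tokens <- tokens[!grepl("[0-9]", tokens)]
  } else if (options$strip_digits) {
    tokens <- gsub("[0-9]", "", tokens)
  }
  tokens <- tokens[nchar(tokens) >= options$min_token_length]
  tokens <- tokens[!tokens %in% options$stopwords]
  if (options$stem) tokens <- porter_stem(tokens)
  tokens
}
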