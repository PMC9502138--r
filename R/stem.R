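# Porter (1980) suffix-stripping stemmer, ported from the reference
# algorithm's standard regular-expression formulation. Operates on single
# lowercase words; porter_stem() is vectorized over a character vector.

.porter <- local({
  cns <- "[^aeiou]"
  vwl <- "[aeiouy]"
  C <- paste0(cns, "[^aeiouy]*")
  V <- paste0(vwl, "[aeiou]*")
  list(
    mgr0 = paste0("^(", C, ")?", V, C),                    # measure m > 0
    meq1 = paste0("^(", C, ")?", V, C, "(", V, ")?$"),     # measure m = 1
    mgr1 = paste0("^(", C, ")?", V, C, V, C),              # measure m > 1
    has_v = paste0("^(", C, ")?", vwl),                    # stem contains vowel
    step2 = c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
              izer = "ize", bli = "ble", alli = "al", entli = "ent",
              eli = "e", ousli = "ous", ization = "ize", ation = "ate",
              ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
              ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble",
              logi = "log"),
    step3 = c(icate = "ic", ative = "", alize = "al", iciti = "ic",
              ical = "ic", ful = "", ness = "")
  )
})

porter_stem_word <- function(w) {
  if (nchar(w) < 3) return(w)
  p <- .porter
  first_y <- substr(w, 1, 1) == "y"
  if (first_y) w <- paste0("Y", substr(w, 2, nchar(w)))

  # step 1a
  if (grepl("(ss|i)es$", w)) {
    w <- sub("(ss|i)es$", "\\1", w)
  } else if (grepl("[^s]s$", w)) {
    w <- sub("s$", "", w)
  }
  # step 1b
  if (grepl("eed$", w)) {
    stem <- sub("eed$", "", w)
    if (grepl(p$mgr0, stem)) w <- sub("eed$", "ee", w)
  } else if (grepl("(ed|ing)$", w)) {
    stem <- sub("(ed|ing)$", "", w)
    if (grepl(p$has_v, stem)) {
      w <- stem
      if (grepl("(at|bl|iz)$", w)) {
        w <- paste0(w, "e")
      } else if (grepl("([^aeiouylsz])\\1$", w)) {
        w <- substr(w, 1, nchar(w) - 1)
      } else if (grepl(paste0("^", .porter_C(), "[aeiouy][^aeiouwxy]$"), w)) {
        w <- paste0(w, "e")
      }
    }
  }
  # step 1c
  if (grepl("y$", w)) {
    stem <- sub("y$", "", w)
    if (grepl(p$has_v, stem)) w <- paste0(stem, "i")
  }
  # step 2
  for (suf in names(p$step2)) {
    if (endsWith(w, suf)) {
      stem <- substr(w, 1, nchar(w) - nchar(suf))
      if (grepl(p$mgr0, stem)) w <- paste0(stem, p$step2[[suf]])
      break
    }
  }
  # step 3
  for (suf in names(p$step3)) {
    if (endsWith(w, suf)) {
      stem <- substr(w, 1, nchar(w) - nchar(suf))
      if (grepl(p$mgr0, stem)) w <- paste0(stem, p$step3[[suf]])
      break
    }
  }
  # step 4
  re4 <- "(al|ance|ence|er|ic|able|ible|ant|ement|ment|ent|ou|ism|ate|iti|ous|ive|ize)$"
  if (grepl(re4, w)) {
    stem <- sub(re4, "", w)
    if (grepl(p$mgr1, stem)) w <- stem
  } else if (grepl("(s|t)ion$", w)) {
    stem <- sub("ion$", "", w)
    if (grepl(p$mgr1, stem)) w <- stem
  }
  # step 5a
  if (grepl("e$", w)) {
    stem <- sub("e$", "", w)
    if (grepl(p$mgr1, stem) ||
        (grepl(p$meq1, stem) &&
         !grepl(paste0("^", .porter_C(), "[aeiouy][^aeiouwxy]$"), stem))) {
      w <- stem
    }
  }
  # step 5b
  if (grepl("ll$", w) && grepl(p$mgr1, w)) w <- substr(w, 1, nchar(w) - 1)

  if (first_y) w <- paste0("y", substr(w, 2, nchar(w)))
  w
}

.porter_C <- function() "[^aeiou][^aeiouy]*"

#' Porter stemmer
#'
#' Reduces inflected English word forms to a common stem (e.g. `"channels"`,
#' `"channeling"` -> `"channel"`) so vocabulary frequency ranks reflect stems
#' rather than surface forms. Input is expected to be lowercase.
#'
#' @param words character vector of lowercase words.
#' @return Character vector of stems.
#' @examples
#' porter_stem(c("seizures", "running", "relational"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem_word, character(1), USE.NAMES = FALSE)
}
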