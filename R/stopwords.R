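#' English stopword list
#'
#' The 179-word English stopword list that is the de-facto standard in NLP
#' preprocessing pipelines. It is vendored into the package as a constant so
#' that scores never drift with the version of an external resource. Filler
#' words such as "an" or "the" carry little diagnostic meaning but inflate
#' similarity between otherwise different outputs, so the default scoring
#' pipeline removes them before computing either the semantic or the internal
#' metrics (each switchable, see [score_runs()]).
#'
#' @format A character vector of lowercase words.
#' @seealso [filter_stopwords_text()], [stopword_position_mask()],
#'   [read_stopwords()]
#' @export
stopwords_en <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves",
  "you", "you're", "you've", "you'll", "you'd", "your", "yours",
  "yourself", "yourselves", "he", "him", "his", "himself", "she",
  "she's", "her", "hers", "herself", "it", "it's", "its", "itself",
  "they", "them", "their", "theirs", "themselves", "what", "which",
  "who", "whom", "this", "that", "that'll", "these", "those", "am",
  "is", "are", "was", "were", "be", "been", "being", "have", "has",
  "had", "having", "do", "does", "did", "doing", "a", "an", "the",
  "and", "but", "if", "or", "because", "as", "until", "while", "of",
  "at", "by", "for", "with", "about", "against", "between", "into",
  "through", "during", "before", "after", "above", "below", "to",
  "from", "up", "down", "in", "out", "on", "off", "over", "under",
  "again", "further", "then", "once", "here", "there", "when",
  "where", "why", "how", "all", "any", "both", "each", "few", "more",
  "most", "other", "some", "such", "no", "nor", "not", "only", "own",
  "same", "so", "than", "too", "very", "s", "t", "can", "will",
  "just", "don", "don't", "should", "should've", "now", "d", "ll",
  "m", "o", "re", "ve", "y", "ain", "aren", "aren't", "couldn",
  "couldn't", "didn", "didn't", "doesn", "doesn't", "hadn", "hadn't",
  "hasn", "hasn't", "haven", "haven't", "isn", "isn't", "ma",
  "mightn", "mightn't", "mustn", "mustn't", "needn", "needn't",
  "shan", "shan't", "shouldn", "shouldn't", "wasn", "wasn't",
  "weren", "weren't", "won", "won't", "wouldn", "wouldn't"
)

#' Read a stopword override list from a plain-text file
#'
#' One word per line; blank lines and leading/trailing whitespace are
#' ignored, words are lowercased.
#'
#' @param path Path to a plain-text file.
#' @return A character vector of lowercase words.
#' @export
read_stopwords <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("stopword file not found: ", path))
  }
  words <- tolower(trimws(readLines(path, warn = FALSE)))
  words[nzchar(words)]
}

# Normal form used for stopword matching: strip surrounding whitespace and
# punctuation, lowercase. Internal apostrophes survive so contractions like
# "don't" match the list.
normalize_word <- function(x) {
  x <- tolower(trimws(x))
  # strip leading/trailing punctuation but keep internal characters
  gsub("^[^a-z0-9']+|[^a-z0-9']+$", "", x)
}

#' Remove stopwords from free text
#'
#' Splits `text` on whitespace, drops every word whose lowercased,
#' punctuation-stripped form is in `stopwords`, and reassembles the rest in
#' the original order with single spaces. Applied (by default) to run text
#' before embedding, so that semantic similarity reflects content words.
#'
#' @param text A character vector; each element is filtered independently.
#' @param stopwords Character vector of lowercase stopwords.
#' @return Character vector of the same length as `text`. An all-stopword
#'   input yields `""`; callers decide how to handle empty filtered text.
#' @examples
#' filter_stopwords_text("the diagnosis is meningitis", c("the", "is"))
#' @export
filter_stopwords_text <- function(text, stopwords = stopwords_en) {
  stopifnot(is.character(text))
  if (length(stopwords) == 0) {
    abort("`stopwords` must be a non-empty character vector")
  }
  vapply(text, function(s) {
    words <- strsplit(s, "[[:space:]]+")[[1]]
    words <- words[nzchar(words)]
    keep <- !(normalize_word(words) %in% stopwords)
    paste(words[keep], collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Flag stopword positions in a token sequence
#'
#' Marks which token positions of a run are stopwords, so that the internal
#' (entropy) metrics can skip them. Matching is per token piece: the piece is
#' detokenized by stripping surrounding whitespace and punctuation and
#' lowercasing, then tested for membership in `stopwords`. Subword pieces
#' that happen to spell a stopword are masked too; exact reconstruction of
#' the tokenizer's word boundaries is deliberately out of scope.
#'
#' @param tokens Character vector of token strings as logged
#'   (whitespace-bearing pieces are fine).
#' @param stopwords Character vector of lowercase stopwords.
#' @return Logical vector, same length as `tokens`; `TRUE` marks a stopword
#'   position.
#' @examples
#' stopword_position_mask(c("The", " patient"), c("the"))
#' @export
stopword_position_mask <- function(tokens, stopwords = stopwords_en) {
  if (length(tokens) == 0) {
    return(logical(0))
  }
  normalize_word(tokens) %in% stopwords
}
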