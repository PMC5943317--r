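#' Default English stop-word list
#'
#' Returns the embedded stop-word list (one word per line, shipped under
#' `inst/extdata/stopwords_en.txt`), or reads a custom list from `file`.
#' Because [tokenize()] splits on every non-alphabetic character, the list
#' also carries the alphabetic fragments left behind by common contractions
#' ("don", "ll", "ve", ...).
#'
#' @param file Optional path to a UTF-8 file with one stop word per line.
#' @return Character vector of lowercase stop words.
#' @export
ls_stopwords <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "stopwords_en.txt", package = "lsnb",
                        mustWork = TRUE)
  }
  words <- readLines(file, encoding = "UTF-8", warn = FALSE)
  words <- trimws(tolower(words))
  words[nzchar(words)]
}

#' Tokenize raw message text
#'
#' Lowercases the text, splits on every non-alphabetic character (so
#' punctuation and numerals act as separators and digit-containing tokens
#' such as "$1000" can never survive), then drops single-character tokens
#' and stop words. This is the cleaning applied to every message before
#' feature extraction.
#'
#' @param text Character scalar (or vector, tokenized independently and
#'   concatenated) of raw message text.
#' @param stopwords Character vector of words to drop; defaults to
#'   [ls_stopwords()]. Use `character(0)` to keep everything.
#' @param min_chars Minimum token length kept (default 2).
#' @param invalid How to handle bytes that are not valid UTF-8:
#'   `"replace"` re-decodes as Latin-1 (legacy email corpora are dirty),
#'   `"error"` aborts.
#' @return Character vector of clean lowercase tokens, in document order.
#' @examples
#' tokenize("Win $1000 at the CASINO!!")  # c("win", "casino")
#' @export
tokenize <- function(text, stopwords = ls_stopwords(), min_chars = 2L,
                     invalid = c("replace", "error")) {
  invalid <- match.arg(invalid)
  if (length(text) == 0L) return(character(0))
  text <- paste(text, collapse = "\n")
  if (!all(validUTF8(text))) {
    if (invalid == "error") stop("text is not valid UTF-8", call. = FALSE)
    text <- iconv(text, from = "latin1", to = "UTF-8", sub = " ")
  }
  toks <- strsplit(tolower(text), "[^a-z]+")[[1]]
  toks <- toks[nchar(toks) >= min_chars]
  if (length(stopwords)) toks <- toks[!(toks %in% stopwords)]
  toks
}

#' Build a vocabulary from tokenized documents
#'
#' Collects every token observed across the documents and keeps the words
#' whose total occurrence count (summed over all documents, repeats
#' included) reaches `min_total_count`. The default of 2 drops hapax
#' legomena: content words are bursty and tend to recur, so words seen only
#' once carry little class signal. Counting document frequency instead of
#' token occurrences is available via `count`.
#'
#' @param docs A corpus (see [as_corpus()]) or a list of token vectors.
#' @param min_total_count Minimum summed count to keep a word (default 2).
#' @param count `"tokens"` (default) counts every occurrence;
#'   `"documents"` counts each word at most once per document.
#' @return Character vector of vocabulary words in C-locale lexicographic
#'   order (a stable, platform-independent index).
#' @examples
#' build_vocabulary(list(c("casino", "casino"), c("casino", "money"),
#'                       c("money", "meeting")))
#' @export
build_vocabulary <- function(docs, min_total_count = 2L,
                             count = c("tokens", "documents")) {
  count <- match.arg(count)
  toks <- corpus_tokens(docs)
  if (length(toks) == 0L) {
    warning("no documents supplied; vocabulary is empty", call. = FALSE)
    return(character(0))
  }
  if (min_total_count < 1L) stop("min_total_count must be >= 1", call. = FALSE)
  if (count == "documents") toks <- lapply(toks, unique)
  all_tokens <- unlist(toks, use.names = FALSE)
  if (length(all_tokens) == 0L) {
    warning("documents contain no tokens; vocabulary is empty", call. = FALSE)
    return(character(0))
  }
  counts <- table(all_tokens)
  vocab <- names(counts)[counts >= min_total_count]
  if (length(vocab) == 0L) {
    warning("no word reaches min_total_count; vocabulary is empty",
            call. = FALSE)
  }
  sort(vocab, method = "radix")
}

#' Binary presence feature vector of one document
#'
#' Reduces a token sequence to the set of vocabulary words it contains
#' (Bernoulli presence encoding; repeats collapse, out-of-vocabulary tokens
#' are ignored).
#'
#' @param tokens Character vector of document tokens.
#' @param vocab Vocabulary from [build_vocabulary()].
#' @return Character vector: the subset of `vocab` present in `tokens`,
#'   in vocabulary order.
#' @export
vectorize <- function(tokens, vocab) {
  if (length(vocab) == 0L) stop("vocabulary is empty", call. = FALSE)
  vocab[vocab %in% tokens]
}

#' Construct a labeled corpus
#'
#' A corpus is a data frame with columns `id` (character), `label`
#' (`"spam"`, `"ham"`, or `NA` for unlabeled), and `tokens` (list column of
#' token vectors). Raw texts are run through [tokenize()].
#'
#' @param texts Character vector of raw message texts, or a list of
#'   pre-tokenized character vectors.
#' @param labels Optional character vector of class labels.
#' @param ids Optional character vector of document identifiers.
#' @param ... Passed to [tokenize()] when `texts` holds raw text.
#' @return A `lsnb_corpus` data frame.
#' @export
as_corpus <- function(texts, labels = NULL, ids = NULL, ...) {
  n <- length(texts)
  if (is.null(ids)) ids <- sprintf("doc%05d", seq_len(n))
  if (is.null(labels)) labels <- rep(NA_character_, n)
  labels <- as.character(labels)
  ok <- is.na(labels) | labels %in% c("spam", "ham")
  if (!all(ok)) {
    stop("labels must be 'spam', 'ham', or NA; binary classification only",
         call. = FALSE)
  }
  if (length(labels) != n || length(ids) != n) {
    stop("texts, labels and ids must have equal length", call. = FALSE)
  }
  toks <- if (is.list(texts)) {
    lapply(texts, as.character)
  } else {
    lapply(texts, tokenize, ...)
  }
  out <- data.frame(id = as.character(ids), label = labels,
                    stringsAsFactors = FALSE)
  out$tokens <- toks
  class(out) <- c("lsnb_corpus", "data.frame")
  out
}

## token list of a corpus or plain list of token vectors
corpus_tokens <- function(docs) {
  if (inherits(docs, "lsnb_corpus")) return(docs$tokens)
  if (is.data.frame(docs) && !is.null(docs$tokens)) return(docs$tokens)
  if (is.list(docs)) return(docs)
  stop("expected a corpus or a list of token vectors", call. = FALSE)
}

#' @export
print.lsnb_corpus <- function(x, ...) {
  cat(sprintf("<lsnb_corpus: %d documents (%d spam, %d ham, %d unlabeled)>\n",
              nrow(x), sum(x$label == "spam", na.rm = TRUE),
              sum(x$label == "ham", na.rm = TRUE), sum(is.na(x$label))))
  invisible(x)
}

## document x vocabulary token-count matrix (dense; vocabularies are small)
corpus_count_matrix <- function(docs, vocab) {
  toks <- corpus_tokens(docs)
  m <- matrix(0L, nrow = length(toks), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(toks)) {
    tt <- toks[[i]]
    tt <- tt[tt %in% vocab]
    if (length(tt)) {
      tab <- table(tt)
      m[i, names(tab)] <- as.integer(tab)
    }
  }
  m
}
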