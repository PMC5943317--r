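#' Specification of a synthetic two-class corpus
#'
#' Describes a seeded generator for labeled spam/ham corpora with the
#' statistical structure the classifiers assume: a shared vocabulary used by
#' both classes, a small set of class-exclusive discriminative words, and
#' bursty within-document repetition of content words (so that real content
#' words tend to be observed more than once and survive the min-count
#' vocabulary filter).
#'
#' Word strings are synthetic, purely alphabetic tokens — shared words
#' `caaab, caaac, ...`, spam-exclusive `saaab, ...`, ham-exclusive
#' `haaab, ...` (a class prefix plus a letter-coded index) — so they pass
#' the tokenizer unchanged and never collide with the stop-word list.
#'
#' @param n_spam,n_ham Number of documents per class.
#' @param shared_vocab_size Words available to both classes (default 150).
#' @param spam_vocab_size,ham_vocab_size Class-exclusive word counts
#'   (default 8 each).
#' @param discriminative_strength Probability that each class-exclusive word
#'   appears in a document of its own class (default 0.6). Exclusive words
#'   never appear in the other class. At 1.0 every document contains all of
#'   its class's exclusive words, making the corpus perfectly separable.
#' @param doc_length Mean tokens per document (default 60); controlled in
#'   expectation only.
#' @param burstiness Within-document repetition weight (default 1): each
#'   present word contributes `1 + Geometric(1/(1+burstiness))` tokens, so
#'   the mean token count per present word is `1 + burstiness`. 0 disables
#'   repetition.
#' @param seed Integer seed; identical spec + seed gives identical corpora.
#' @return An object of class `corpus_spec`.
#' @seealso [generate_corpus()]
#' @export
corpus_spec <- function(n_spam, n_ham, shared_vocab_size = 150L,
                        spam_vocab_size = 8L, ham_vocab_size = 8L,
                        discriminative_strength = 0.6, doc_length = 60,
                        burstiness = 1, seed = 1L) {
  spec <- list(n_spam = as.integer(n_spam), n_ham = as.integer(n_ham),
               shared_vocab_size = as.integer(shared_vocab_size),
               spam_vocab_size = as.integer(spam_vocab_size),
               ham_vocab_size = as.integer(ham_vocab_size),
               discriminative_strength = discriminative_strength,
               doc_length = doc_length, burstiness = burstiness,
               seed = as.integer(seed))
  sizes <- unlist(spec[c("n_spam", "n_ham", "shared_vocab_size",
                         "spam_vocab_size", "ham_vocab_size")])
  if (any(sizes < 0L)) stop("sizes must be nonnegative", call. = FALSE)
  if (discriminative_strength < 0 || discriminative_strength > 1) {
    stop("discriminative_strength must be in [0, 1]", call. = FALSE)
  }
  if (burstiness < 0) stop("burstiness must be >= 0", call. = FALSE)
  if (doc_length <= 0) stop("doc_length must be positive", call. = FALSE)
  structure(spec, class = "corpus_spec")
}

## letter-coded index: 1 -> "aaab" (base-10 digits mapped to a..j)
.letter_code <- function(i, width = 4L) {
  digits <- strsplit(sprintf(paste0("%0", width, "d"), i), "")
  vapply(digits, function(d) {
    paste(letters[as.integer(d) + 1L], collapse = "")
  }, "")
}

synthetic_words <- function(prefix, n) {
  if (n == 0L) return(character(0))
  paste0(prefix, .letter_code(seq_len(n)))
}

#' Generate a seeded synthetic spam/ham corpus
#'
#' Draws `n_spam + n_ham` documents from the generative model described in
#' [corpus_spec()]. Each document first samples word presence — every shared
#' word independently with a common probability calibrated so the expected
#' document length matches `doc_length`, and every own-class exclusive word
#' with probability `discriminative_strength` — then draws a bursty token
#' count for each present word and shuffles the tokens into document order.
#'
#' @param spec A [corpus_spec()].
#' @return A labeled `lsnb_corpus` with spam documents first; fully
#'   reproducible from `spec$seed`.
#' @examples
#' corp <- generate_corpus(corpus_spec(10, 10, seed = 7))
#' table(corp$label)
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  shared <- synthetic_words("c", spec$shared_vocab_size)
  spam_w <- synthetic_words("s", spec$spam_vocab_size)
  ham_w <- synthetic_words("h", spec$ham_vocab_size)
  n_total <- spec$n_spam + spec$n_ham
  if (n_total == 0L) {
    return(as_corpus(list(), labels = character(0), ids = character(0)))
  }
  ## expected distinct shared words needed to hit doc_length in expectation
  mean_reps <- 1 + spec$burstiness
  geom_p <- 1 / mean_reps
  excl_per_class <- c(spam = spec$spam_vocab_size, ham = spec$ham_vocab_size)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  make_doc <- function(class) {
    own <- if (class == "spam") spam_w else ham_w
    n_own <- length(own)
    target_shared <- spec$doc_length / mean_reps -
      spec$discriminative_strength * n_own
    p_shared <- if (spec$shared_vocab_size > 0) {
      min(1, max(target_shared, 1) / spec$shared_vocab_size)
    } else 0
    words <- c(shared[stats::runif(length(shared)) < p_shared],
               own[stats::runif(n_own) < spec$discriminative_strength])
    if (length(words) == 0L) return(character(0))
    reps <- 1L + stats::rgeom(length(words), prob = geom_p)
    toks <- rep(words, reps)
    if (length(toks) > 1L) toks <- sample(toks)
    toks
  }
  labels <- c(rep("spam", spec$n_spam), rep("ham", spec$n_ham))
  toks <- lapply(labels, make_doc)
  ids <- sprintf("%s%05d", substr(labels, 1, 1),
                 c(seq_len(spec$n_spam), seq_len(spec$n_ham)))
  as_corpus(toks, labels = labels, ids = ids)
}
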