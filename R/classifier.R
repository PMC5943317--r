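#' Fit an NB, LSNB, or eLSNB spam classifier
#'
#' Fits a binary (spam/ham) Bernoulli text classifier. All three variants
#' share the same sufficient statistics, computed from the training corpus:
#' per-class document frequencies of each vocabulary word (presence/absence,
#' so `P(w|c) + P(!w|c) = 1`), per-class token counts `N(c, w)`, and the
#' derived word densities `WD(c, w) = N(c, w) / sum_k N(c, w_k)` — the share
#' of class `c`'s tokens contributed by `w`. The variants differ only in the
#' per-word weight used in the likelihood product:
#'
#' * `nb`: the plain conditional probability `P(w|c)`.
#' * `lsnb`: the LS strength of the table
#'   `(a, b, c, d) = (P(w|c), P(!w|c), P(w|!c), P(!w|!c))` — the
#'   conditional probability pulled toward its symmetric and mutually
#'   exclusive readings by the pooled correction terms.
#' * `elsnb`: as `lsnb`, but each cell is re-weighted by a word density:
#'   `a = P(w|c) WD(c,w)`, `b = P(!w|c) WD(!c,w)`, `c = P(w|!c) WD(!c,w)`,
#'   `d = P(!w|!c) WD(c,w)`. Note the deliberate cross-pairing of densities
#'   on `b` and `d`; it strengthens the contraposition of the table and is
#'   implemented exactly as defined, not "corrected".
#'
#' Priors default to the deliberately uninformative `P(spam) = P(ham) = 0.5`
#' so that class imbalance in training affects only the conditionals.
#' Smoothing defaults to add-one on document counts for `nb` (whose raw
#' zero estimates are fatal under a product) and to raw estimates for the
#' LS variants (their correction terms already damp zeros); both are
#' switchable.
#'
#' @param corpus Labeled training corpus from [as_corpus()] (every document
#'   must carry a `"spam"` or `"ham"` label; both classes required).
#' @param variant One of `"nb"`, `"lsnb"`, `"elsnb"`.
#' @param vocab Vocabulary to use; defaults to [build_vocabulary()] on the
#'   training corpus with `min_total_count`.
#' @param min_total_count Passed to [build_vocabulary()] when `vocab` is NULL.
#' @param smoothing Logical; add-one smoothing of the per-class document
#'   frequencies. Default: `TRUE` for `nb`, `FALSE` otherwise.
#' @param priors Named numeric vector `c(spam = , ham = )` summing to 1.
#' @param floor Lower bound applied to any zero or near-zero weight before
#'   taking logs (default `1e-12`); keeps log-scores finite while preserving
#'   the ranking.
#' @param no_bias Debug flag: force both LS correction terms to zero, which
#'   collapses the LS weight to the conditional probability `a/(a+b)` and
#'   makes `lsnb` rank documents exactly as `nb` (with matching smoothing).
#' @return An object of class `lsnb_model`.
#' @seealso [predict.lsnb_model()], [word_table()], [word_weight()],
#'   [save_model()]
#' @examples
#' corp <- as_corpus(list(c("casino", "casino", "money"),
#'                        c("casino", "money"),
#'                        c("meeting", "money")),
#'                   labels = c("spam", "spam", "ham"))
#' m <- fit_classifier(corp, "lsnb", vocab = c("casino", "money"))
#' word_weight(m, "money", "spam")  # 2/3
#' @export
fit_classifier <- function(corpus, variant = c("nb", "lsnb", "elsnb"),
                           vocab = NULL, min_total_count = 2L,
                           smoothing = NULL,
                           priors = c(spam = 0.5, ham = 0.5),
                           floor = 1e-12, no_bias = FALSE) {
  variant <- match.arg(variant)
  if (!inherits(corpus, "lsnb_corpus")) {
    stop("corpus must be built with as_corpus()", call. = FALSE)
  }
  labels <- corpus$label
  if (anyNA(labels)) stop("training corpus has unlabeled documents", call. = FALSE)
  extra <- setdiff(unique(labels), c("spam", "ham"))
  if (length(extra)) {
    stop("binary classification only; unknown label(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!all(c("spam", "ham") %in% labels)) {
    stop("training corpus must contain at least one document of each class",
         call. = FALSE)
  }
  if (is.null(vocab)) {
    vocab <- build_vocabulary(corpus, min_total_count = min_total_count)
  }
  if (length(vocab) == 0L) stop("vocabulary is empty", call. = FALSE)
  counts <- corpus_count_matrix(corpus, vocab)
  fit_from_counts(counts, labels, variant = variant, vocab = vocab,
                  smoothing = smoothing, priors = priors, floor = floor,
                  no_bias = no_bias)
}

## core fit on a precomputed document x vocab count matrix; the experiment
## harness subsets one big matrix instead of re-tokenizing per step
fit_from_counts <- function(counts, labels, variant, vocab,
                            smoothing = NULL,
                            priors = c(spam = 0.5, ham = 0.5),
                            floor = 1e-12, no_bias = FALSE) {
  if (is.null(smoothing)) smoothing <- (variant == "nb")
  if (abs(sum(priors) - 1) > 1e-9 || any(priors < 0) ||
      !all(c("spam", "ham") %in% names(priors))) {
    stop("priors must be named c(spam=, ham=) and sum to 1", call. = FALSE)
  }
  is_spam <- labels == "spam"
  n_docs <- c(spam = sum(is_spam), ham = sum(!is_spam))
  present <- counts > 0L
  df <- cbind(spam = colSums(present[is_spam, , drop = FALSE]),
              ham  = colSums(present[!is_spam, , drop = FALSE]))
  ntok <- cbind(spam = colSums(counts[is_spam, , drop = FALSE]),
                ham  = colSums(counts[!is_spam, , drop = FALSE]))
  p <- if (smoothing) {
    sweep(df + 1, 2, n_docs + 2, "/")
  } else {
    sweep(df, 2, n_docs, "/")
  }
  tok_tot <- colSums(ntok)
  wd <- sweep(ntok, 2, ifelse(tok_tot > 0, tok_tot, 1), "/")
  model <- structure(
    list(variant = variant, priors = priors[c("spam", "ham")],
         vocab = vocab, n_docs = n_docs, df = df, ntok = ntok,
         p = p, wd = wd, smoothing = smoothing, floor = floor,
         no_bias = no_bias),
    class = "lsnb_model")
  model$weights <- compute_weights(model)
  model
}

## vocab x class weight matrix for the fitted variant
compute_weights <- function(model) {
  p <- model$p
  wd <- model$wd
  other <- c(spam = "ham", ham = "spam")
  w <- matrix(NA_real_, nrow = length(model$vocab), ncol = 2,
              dimnames = list(model$vocab, c("spam", "ham")))
  n_degenerate <- 0L
  for (cl in c("spam", "ham")) {
    oc <- other[[cl]]
    if (model$variant == "elsnb") {
      a <- p[, cl] * wd[, cl]
      b <- (1 - p[, cl]) * wd[, oc]
      cc <- p[, oc] * wd[, oc]
      d <- (1 - p[, oc]) * wd[, cl]
    } else {
      a <- p[, cl]
      b <- 1 - p[, cl]
      cc <- p[, oc]
      d <- 1 - p[, oc]
    }
    if (model$variant == "nb") {
      w[, cl] <- a / (a + b)
      next
    }
    if (model$no_bias) {
      t_ac <- t_bd <- numeric(length(a))
    } else {
      s_ac <- a + cc
      t_ac <- ifelse(s_ac > 0, a * cc / s_ac, 0)
      s_bd <- b + d
      t_bd <- ifelse(s_bd > 0, b * d / s_bd, 0)
    }
    num <- a + t_bd
    den <- a + b + t_ac + t_bd
    bad <- den <= 0
    n_degenerate <- n_degenerate + sum(bad)
    w[, cl] <- ifelse(bad, 0, num / den)
  }
  if (n_degenerate > 0L) {
    warning(sprintf(
      "%d degenerate all-zero word table(s); their weights were set to 0",
      n_degenerate), call. = FALSE)
  }
  w
}

#' @export
print.lsnb_model <- function(x, ...) {
  cat(sprintf(
    "<lsnb_model: variant=%s, vocab=%d words, trained on %d spam / %d ham docs>\n",
    x$variant, length(x$vocab), x$n_docs[["spam"]], x$n_docs[["ham"]]))
  invisible(x)
}

#' Contingency table of one word in a fitted model
#'
#' Returns the 2x2 table that the LS weight of `word` for `class` is
#' computed from (see [fit_classifier()] for the cell definitions of the
#' `lsnb` and `elsnb` variants; for `nb` the `lsnb`-style table is returned
#' since only `a/(a+b)` is used).
#'
#' @param model A fitted `lsnb_model`.
#' @param word A vocabulary word.
#' @param class `"spam"` or `"ham"`.
#' @return An [ls_table()].
#' @export
word_table <- function(model, word, class = c("spam", "ham")) {
  class <- match.arg(class)
  if (!word %in% model$vocab) {
    stop(sprintf("word '%s' is not in the vocabulary", word), call. = FALSE)
  }
  oc <- if (class == "spam") "ham" else "spam"
  pw <- model$p[word, class]
  po <- model$p[word, oc]
  if (model$variant == "elsnb") {
    ls_table(pw * model$wd[word, class],
             (1 - pw) * model$wd[word, oc],
             po * model$wd[word, oc],
             (1 - po) * model$wd[word, class])
  } else {
    ls_table(pw, 1 - pw, po, 1 - po)
  }
}

#' Likelihood weight of one word in a fitted model
#'
#' The per-word factor contributed to the class likelihood product:
#' `P(w|c)` for `nb`, the LS strength of [word_table()] for `lsnb` and
#' `elsnb`. Degenerate all-zero tables (a vocabulary word with no tokens in
#' either class of the training sample) get weight 0.
#'
#' @inheritParams word_table
#' @return A number in \[0, 1\].
#' @export
word_weight <- function(model, word, class = c("spam", "ham")) {
  class <- match.arg(class)
  if (!word %in% model$vocab) {
    stop(sprintf("word '%s' is not in the vocabulary", word), call. = FALSE)
  }
  unname(model$weights[word, class])
}

#' Classify documents with a fitted model
#'
#' Scores each document in log space:
#' `score(c) = log P(c) + sum over present words of log max(weight(w, c), floor)`.
#' The product runs over the vocabulary words present in the document only
#' (Bernoulli presence; absence factors are not multiplied in), and
#' out-of-vocabulary tokens are ignored. The evidence term is dropped — the
#' scores are unnormalized log-posteriors, valid for ranking classes but not
#' calibrated probabilities. A document whose feature vector is empty falls
#' back to the priors. Exact score ties predict `ham`, the conservative
#' choice for a spam filter.
#'
#' @param object A fitted `lsnb_model`.
#' @param newdata A corpus from [as_corpus()], a list of token vectors, or a
#'   character vector of raw texts (tokenized with default settings).
#' @param ... Unused.
#' @return A data frame with one row per document: `id`, `score_spam`,
#'   `score_ham` (log scale), `label` (predicted), `tie` (logical).
#' @export
predict.lsnb_model <- function(object, newdata, ...) {
  if (is.character(newdata)) newdata <- as_corpus(newdata)
  toks <- corpus_tokens(newdata)
  ids <- if (is.data.frame(newdata) && !is.null(newdata$id)) {
    newdata$id
  } else {
    sprintf("doc%05d", seq_along(toks))
  }
  present <- matrix(FALSE, nrow = length(toks), ncol = length(object$vocab))
  for (i in seq_along(toks)) {
    present[i, ] <- object$vocab %in% toks[[i]]
  }
  logw <- log(pmax(object$weights, object$floor))
  scores <- present %*% logw
  scores <- sweep(scores, 2, log(object$priors[c("spam", "ham")]), "+")
  s <- scores[, 1]; h <- scores[, 2]
  tie <- abs(s - h) <= 1e-10 * pmax(1, abs(s), abs(h))
  label <- ifelse(!tie & s > h, "spam", "ham")
  data.frame(id = as.character(ids), score_spam = s, score_ham = h,
             label = label, tie = tie, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Save or load a fitted model as plain text
#'
#' Serializes the sufficient statistics (variant, options, priors, per-class
#' document counts, and the per-word document-frequency and token-count
#' table) as a human-readable text file. Probabilities, densities and
#' weights are recomputed on load from the integer counts, so models
#' round-trip exactly.
#'
#' @param model A fitted `lsnb_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   reconstructed `lsnb_model`.
#' @export
save_model <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "# lsnb model v1",
    paste0("variant\t", model$variant),
    paste0("prior_spam\t", sprintf("%.17g", model$priors[["spam"]])),
    paste0("prior_ham\t", sprintf("%.17g", model$priors[["ham"]])),
    paste0("smoothing\t", as.integer(model$smoothing)),
    paste0("floor\t", sprintf("%.17g", model$floor)),
    paste0("no_bias\t", as.integer(model$no_bias)),
    paste0("n_doc_spam\t", model$n_docs[["spam"]]),
    paste0("n_doc_ham\t", model$n_docs[["ham"]]),
    "word\tdf_spam\tdf_ham\tntok_spam\tntok_ham"), con)
  tab <- data.frame(word = model$vocab,
                    df_spam = model$df[, "spam"], df_ham = model$df[, "ham"],
                    ntok_spam = model$ntok[, "spam"],
                    ntok_ham = model$ntok[, "ham"])
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!identical(lines[1], "# lsnb model v1")) {
    stop("not an lsnb model file: ", path, call. = FALSE)
  }
  kv <- strsplit(lines[2:9], "\t", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tab <- utils::read.table(text = lines[-(1:10)], sep = "\t",
                           col.names = c("word", "df_spam", "df_ham",
                                         "ntok_spam", "ntok_ham"),
                           colClasses = c("character", rep("integer", 4)))
  n_docs <- c(spam = as.integer(meta[["n_doc_spam"]]),
              ham = as.integer(meta[["n_doc_ham"]]))
  vocab <- tab$word
  df <- cbind(spam = tab$df_spam, ham = tab$df_ham)
  ntok <- cbind(spam = tab$ntok_spam, ham = tab$ntok_ham)
  rownames(df) <- rownames(ntok) <- vocab
  smoothing <- as.integer(meta[["smoothing"]]) == 1L
  p <- if (smoothing) sweep(df + 1, 2, n_docs + 2, "/") else sweep(df, 2, n_docs, "/")
  tok_tot <- colSums(ntok)
  wd <- sweep(ntok, 2, ifelse(tok_tot > 0, tok_tot, 1), "/")
  model <- structure(
    list(variant = meta[["variant"]],
         priors = c(spam = as.numeric(meta[["prior_spam"]]),
                    ham = as.numeric(meta[["prior_ham"]])),
         vocab = vocab, n_docs = n_docs, df = df, ntok = ntok,
         p = p, wd = wd, smoothing = smoothing,
         floor = as.numeric(meta[["floor"]]),
         no_bias = as.integer(meta[["no_bias"]]) == 1L),
    class = "lsnb_model")
  model$weights <- compute_weights(model)
  model
}
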