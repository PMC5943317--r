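#' Biased-sampling training schedules
#'
#' Builds the per-step training sizes of the five experiment designs. The
#' first family varies the class ratio of a growing training set; the second
#' family pins one class at a small constant and grows the other, producing
#' progressively more imbalanced training data:
#'
#' * `"1-1"`: spam = 40t, ham = 40t, t = 1..6 (50% spam).
#' * `"1-2"`: spam = 24t, ham = 40t, t = 1..10 (24/64 = 37.5% spam).
#' * `"1-3"`: spam = 8t, ham = 40t, t = 1..30 (8/48 = 16.7% spam).
#' * `"2-1"`: spam = `fixed_size` (25 or 100), ham = 40t, t = 1..6.
#' * `"2-2"`: spam = 40t, ham = `fixed_size` (25 or 100), t = 1..6.
#'
#' @param experiment_id One of `"1-1"`, `"1-2"`, `"1-3"`, `"2-1"`, `"2-2"`.
#' @param fixed_size Constant class size for the `"2-x"` designs (25 or
#'   100); must be omitted for the `"1-x"` designs.
#' @return An object of class `experiment_schedule`: a data frame with
#'   columns `t`, `n_spam`, `n_ham`, plus attributes `experiment_id` and
#'   `fixed_size`.
#' @examples
#' make_schedule("1-3")[2, ]  # t = 2: 16 spam, 80 ham
#' @export
make_schedule <- function(experiment_id, fixed_size = NULL) {
  ids <- c("1-1", "1-2", "1-3", "2-1", "2-2")
  if (!experiment_id %in% ids) {
    stop("unknown experiment id: ", experiment_id, call. = FALSE)
  }
  fixed_design <- experiment_id %in% c("2-1", "2-2")
  if (fixed_design && is.null(fixed_size)) {
    stop("fixed_size (25 or 100) is required for experiment ", experiment_id,
         call. = FALSE)
  }
  if (!fixed_design && !is.null(fixed_size)) {
    stop("fixed_size applies only to experiments 2-1 and 2-2", call. = FALSE)
  }
  sched <- switch(experiment_id,
    "1-1" = data.frame(t = 1:6, n_spam = 40L * 1:6, n_ham = 40L * 1:6),
    "1-2" = data.frame(t = 1:10, n_spam = 24L * 1:10, n_ham = 40L * 1:10),
    "1-3" = data.frame(t = 1:30, n_spam = 8L * 1:30, n_ham = 40L * 1:30),
    "2-1" = data.frame(t = 1:6, n_spam = as.integer(fixed_size),
                       n_ham = 40L * 1:6),
    "2-2" = data.frame(t = 1:6, n_spam = 40L * 1:6,
                       n_ham = as.integer(fixed_size)))
  structure(sched, experiment_id = experiment_id, fixed_size = fixed_size,
            class = c("experiment_schedule", "data.frame"))
}

#' Per-class accuracy and F-measure of a prediction
#'
#' Confusion-matrix metrics with spam as the positive class: spam accuracy
#' is the recall on spam (`TP / (TP + FN)`), ham accuracy the recall on ham
#' (`TN / (TN + FP)`), and the F-measure is the F1 score
#' `2PR / (P + R)` with precision `P = TP / (TP + FP)`. When nothing is
#' predicted spam the precision is undefined and F is reported as 0.
#'
#' @param predictions Character vector of predicted labels.
#' @param truth Character vector of true labels; both classes must occur.
#' @return A one-row data frame: `tp`, `fp`, `fn`, `tn`, `spam_acc`,
#'   `ham_acc`, `f_measure`.
#' @examples
#' evaluate_predictions(c("spam", "ham"), c("spam", "ham"))
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (length(predictions) == 0L || length(predictions) != length(truth)) {
    stop("predictions and truth must be nonempty and of equal length",
         call. = FALSE)
  }
  if (!all(c("spam", "ham") %in% truth)) {
    stop("truth must contain both classes", call. = FALSE)
  }
  tp <- sum(predictions == "spam" & truth == "spam")
  fp <- sum(predictions == "spam" & truth == "ham")
  fn <- sum(predictions == "ham" & truth == "spam")
  tn <- sum(predictions == "ham" & truth == "ham")
  spam_acc <- tp / (tp + fn)
  ham_acc <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f <- if (is.na(prec) || prec + spam_acc == 0) 0 else {
    2 * prec * spam_acc / (prec + spam_acc)
  }
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             spam_acc = spam_acc, ham_acc = ham_acc, f_measure = f)
}

#' Run a biased-sampling classification experiment
#'
#' For each replicate: a stratified random half of the corpus is held out as
#' the test set; for each schedule step, training samples of the scheduled
#' per-class sizes are drawn uniformly without replacement from the
#' remaining (non-test) half; each classifier variant is fitted on the
#' sample and evaluated on the test half. Per-replicate seeds are derived
#' deterministically from `seed`, so the full result table is reproducible.
#'
#' The vocabulary is built once from the whole corpus before splitting
#' (mirroring a fixed preprocessing pass over the dataset); set
#' `vocab_scope = "train"` to rebuild it per training sample and rule out
#' any vocabulary-level leakage.
#'
#' Steps the corpus cannot support (training sizes exceeding the non-test
#' pool) are skipped with a warning.
#'
#' @param corpus Labeled `lsnb_corpus` with both classes.
#' @param schedule An [make_schedule()] schedule.
#' @param variants Character vector from `c("nb", "lsnb", "elsnb")`.
#' @param replicates Number of replicates (default 10).
#' @param seed Base integer seed.
#' @param vocab_scope `"corpus"` (default) or `"train"`.
#' @param min_total_count Vocabulary min-count filter (default 2).
#' @param extra_classifiers Optional named list of external classifier
#'   adapters, each a `function(train, test)` taking two `lsnb_corpus`
#'   subsets and returning predicted labels for `test`; evaluated alongside
#'   the core variants under the adapter's name. None are shipped.
#' @param keep_indices If TRUE, attach the per-replicate test/train index
#'   sets as attribute `"indices"` (for auditing the split protocol).
#' @param ... Passed to the fitting routine (e.g. `smoothing`, `floor`).
#' @return A data frame of class `experiment_result` with one row per
#'   (step, variant, replicate): columns `experiment_id`, `step_t`,
#'   `n_spam`, `n_ham`, `variant`, `replicate`, `spam_acc`, `ham_acc`,
#'   `f_measure`.
#' @seealso [aggregate_results()], [write_results()]
#' @export
run_experiment <- function(corpus, schedule, variants = c("nb", "lsnb", "elsnb"),
                           replicates = 10L, seed = 42L,
                           vocab_scope = c("corpus", "train"),
                           min_total_count = 2L, extra_classifiers = NULL,
                           keep_indices = FALSE, ...) {
  stopifnot(inherits(corpus, "lsnb_corpus"),
            inherits(schedule, "experiment_schedule"))
  vocab_scope <- match.arg(vocab_scope)
  variants <- match.arg(variants, c("nb", "lsnb", "elsnb"),
                        several.ok = TRUE)
  exp_id <- attr(schedule, "experiment_id")
  labels <- corpus$label
  if (anyNA(labels)) stop("corpus has unlabeled documents", call. = FALSE)
  idx_spam <- which(labels == "spam")
  idx_ham <- which(labels == "ham")
  if (!length(idx_spam) || !length(idx_ham)) {
    stop("corpus must contain both classes", call. = FALSE)
  }
  vocab <- NULL
  counts <- NULL
  if (vocab_scope == "corpus") {
    vocab <- build_vocabulary(corpus, min_total_count = min_total_count)
    counts <- corpus_count_matrix(corpus, vocab)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  rows <- vector("list", 0L)
  indices <- if (keep_indices) vector("list", replicates) else NULL
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    test_idx <- c(sample(idx_spam, floor(length(idx_spam) / 2)),
                  sample(idx_ham, floor(length(idx_ham) / 2)))
    pool_spam <- setdiff(idx_spam, test_idx)
    pool_ham <- setdiff(idx_ham, test_idx)
    truth <- labels[test_idx]
    if (keep_indices) {
      indices[[r]] <- list(test = test_idx, train = list())
    }
    for (s in seq_len(nrow(schedule))) {
      ns <- schedule$n_spam[s]
      nh <- schedule$n_ham[s]
      if (ns > length(pool_spam) || nh > length(pool_ham)) {
        warning(sprintf(
          "step t=%d needs %d spam / %d ham but the pool has %d / %d; skipped",
          schedule$t[s], ns, nh, length(pool_spam), length(pool_ham)),
          call. = FALSE)
        next
      }
      train_idx <- c(sample(pool_spam, ns), sample(pool_ham, nh))
      if (keep_indices) {
        indices[[r]]$train[[as.character(schedule$t[s])]] <- train_idx
      }
      for (v in variants) {
        model <- if (vocab_scope == "corpus") {
          fit_from_counts(counts[train_idx, , drop = FALSE],
                          labels[train_idx], variant = v, vocab = vocab, ...)
        } else {
          fit_classifier(corpus[train_idx, ], variant = v,
                         min_total_count = min_total_count, ...)
        }
        pred <- if (vocab_scope == "corpus") {
          predict_from_counts(model, counts[test_idx, , drop = FALSE])
        } else {
          predict(model, corpus[test_idx, ])$label
        }
        met <- evaluate_predictions(pred, truth)
        rows[[length(rows) + 1L]] <- data.frame(
          experiment_id = exp_id, step_t = schedule$t[s],
          n_spam = ns, n_ham = nh, variant = v, replicate = r,
          spam_acc = met$spam_acc, ham_acc = met$ham_acc,
          f_measure = met$f_measure, stringsAsFactors = FALSE)
      }
      for (nm in names(extra_classifiers)) {
        pred <- extra_classifiers[[nm]](corpus[train_idx, ],
                                        corpus[test_idx, ])
        met <- evaluate_predictions(pred, truth)
        rows[[length(rows) + 1L]] <- data.frame(
          experiment_id = exp_id, step_t = schedule$t[s],
          n_spam = ns, n_ham = nh, variant = nm, replicate = r,
          spam_acc = met$spam_acc, ham_acc = met$ham_acc,
          f_measure = met$f_measure, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no schedule step could be run on this corpus", call. = FALSE)
  }
  class(out) <- c("experiment_result", "data.frame")
  if (keep_indices) attr(out, "indices") <- indices
  out
}

## fast prediction path on a precomputed count matrix
predict_from_counts <- function(model, counts) {
  present <- counts[, model$vocab, drop = FALSE] > 0
  logw <- log(pmax(model$weights, model$floor))
  scores <- present %*% logw
  scores <- sweep(scores, 2, log(model$priors[c("spam", "ham")]), "+")
  s <- scores[, 1]; h <- scores[, 2]
  tie <- abs(s - h) <= 1e-10 * pmax(1, abs(s), abs(h))
  ifelse(!tie & s > h, "spam", "ham")
}

#' Aggregate experiment results across replicates
#'
#' Collapses an [run_experiment()] table to per-(step, variant) means and
#' standard errors (sample standard deviation across replicates divided by
#' the square root of the replicate count) of each metric.
#'
#' @param results An `experiment_result` data frame.
#' @return A data frame with columns `experiment_id`, `step_t`, `n_spam`,
#'   `n_ham`, `variant`, `n_replicates`, and for each metric `m` in
#'   `spam_acc`, `ham_acc`, `f_measure` the columns `m_mean` and `m_se`.
#' @export
aggregate_results <- function(results) {
  stopifnot(is.data.frame(results))
  key <- interaction(results$experiment_id, results$step_t, results$variant,
                     drop = TRUE)
  agg <- lapply(split(results, key), function(g) {
    se <- function(x) {
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
    }
    data.frame(experiment_id = g$experiment_id[1], step_t = g$step_t[1],
               n_spam = g$n_spam[1], n_ham = g$n_ham[1],
               variant = g$variant[1], n_replicates = nrow(g),
               spam_acc_mean = mean(g$spam_acc), spam_acc_se = se(g$spam_acc),
               ham_acc_mean = mean(g$ham_acc), ham_acc_se = se(g$ham_acc),
               f_measure_mean = mean(g$f_measure),
               f_measure_se = se(g$f_measure), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$experiment_id, out$step_t, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}
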