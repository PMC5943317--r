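test_that("schedules reproduce the printed step formulas", {
  s11 <- make_schedule("1-1")
  expect_equal(s11$n_spam, 40 * 1:6)
  expect_equal(s11$n_ham, 40 * 1:6)
  expect_equal(make_schedule("1-2")$n_spam, 24 * 1:10)
  s13 <- make_schedule("1-3")
  expect_equal(nrow(s13), 30)
  expect_equal(unlist(s13[2, c("n_spam", "n_ham")], use.names = FALSE),
               c(16, 80))
  s21 <- make_schedule("2-1", fixed_size = 25)
  expect_equal(unlist(s21[3, c("n_spam", "n_ham")], use.names = FALSE),
               c(25, 120))
  s22 <- make_schedule("2-2", fixed_size = 100)
  expect_equal(s22$n_ham, rep(100L, 6))
  expect_equal(s22$n_spam, 40 * 1:6)
})

test_that("schedule class proportions are constant per design", {
  expect_equal(unique(with(make_schedule("1-1"), n_spam / (n_spam + n_ham))),
               1 / 2)
  expect_equal(unique(with(make_schedule("1-2"), n_spam / (n_spam + n_ham))),
               24 / 64)
  expect_equal(unique(with(make_schedule("1-3"), n_spam / (n_spam + n_ham))),
               8 / 48)
})

test_that("schedule construction validates its arguments", {
  expect_error(make_schedule("3-1"), "unknown experiment")
  expect_error(make_schedule("2-1"), "fixed_size")
  expect_error(make_schedule("1-1", fixed_size = 25), "applies only")
})

test_that("metrics match the confusion-matrix formulas", {
  perfect <- evaluate_predictions(rep(c("spam", "ham"), each = 10),
                                  rep(c("spam", "ham"), each = 10))
  expect_equal(perfect[c("spam_acc", "ham_acc", "f_measure")],
               data.frame(spam_acc = 1, ham_acc = 1, f_measure = 1))
  # TP=8, FN=2, FP=4, TN=6
  pred <- c(rep("spam", 8), rep("ham", 2), rep("spam", 4), rep("ham", 6))
  truth <- c(rep("spam", 10), rep("ham", 10))
  m <- evaluate_predictions(pred, truth)
  expect_equal(m$spam_acc, 0.8)
  expect_equal(m$ham_acc, 0.6)
  expect_equal(m$f_measure, 2 * (8 / 12) * 0.8 / (8 / 12 + 0.8))
  expect_equal(round(m$f_measure, 4), 0.7273)
  # degenerate all-ham predictor on 5 spam / 5 ham truth
  allham <- evaluate_predictions(rep("ham", 10),
                                 rep(c("spam", "ham"), each = 5))
  expect_equal(allham$spam_acc, 0)
  expect_equal(allham$ham_acc, 1)
  expect_equal(allham$f_measure, 0)
  expect_error(evaluate_predictions(character(0), character(0)), "nonempty")
  expect_error(evaluate_predictions(rep("ham", 3), rep("ham", 3)),
               "both classes")
})

sep_corpus <- function(n = 120, seed = 64) {
  generate_corpus(corpus_spec(n, n, shared_vocab_size = 40,
                              spam_vocab_size = 5, ham_vocab_size = 5,
                              discriminative_strength = 1.0,
                              doc_length = 30, seed = seed))
}

test_that("a separable corpus is classified perfectly at every step", {
  corp <- sep_corpus(170)  # non-test pool of 85 per class
  sched <- make_schedule("1-1")[1:2, ]
  class(sched) <- class(make_schedule("1-1"))
  attr(sched, "experiment_id") <- "1-1"
  res <- run_experiment(corp, sched, replicates = 3, seed = 9)
  expect_true(all(res$spam_acc == 1))
  expect_true(all(res$ham_acc == 1))
  expect_true(all(res$f_measure == 1))
  expect_setequal(unique(res$variant), c("nb", "lsnb", "elsnb"))
})

test_that("experiment runs are reproducible and splits are sound", {
  corp <- sep_corpus(80)
  sched <- make_schedule("1-1")[1, ]
  attr(sched, "experiment_id") <- "1-1"
  class(sched) <- c("experiment_schedule", "data.frame")
  r1 <- run_experiment(corp, sched, replicates = 4, seed = 11,
                       keep_indices = TRUE)
  r2 <- run_experiment(corp, sched, replicates = 4, seed = 11,
                       keep_indices = TRUE)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  for (rep_idx in attr(r1, "indices")) {
    # test half is stratified and disjoint from every training draw
    expect_equal(length(rep_idx$test), 80)
    expect_equal(sum(corp$label[rep_idx$test] == "spam"), 40)
    for (tr in rep_idx$train) {
      expect_length(intersect(tr, rep_idx$test), 0)
      expect_false(anyDuplicated(tr) > 0)
    }
  }
  # different seed, different draws
  r3 <- run_experiment(corp, sched, replicates = 4, seed = 12,
                       keep_indices = TRUE)
  expect_false(identical(attr(r1, "indices"), attr(r3, "indices")))
})

test_that("standard errors match direct recomputation from replicates", {
  corp <- generate_corpus(corpus_spec(150, 150,
                                      discriminative_strength = 0.35,
                                      doc_length = 25, seed = 31))
  sched <- make_schedule("1-1")[1, ]
  attr(sched, "experiment_id") <- "1-1"
  class(sched) <- c("experiment_schedule", "data.frame")
  res <- run_experiment(corp, sched, variants = "nb", replicates = 10,
                        seed = 3)
  agg <- aggregate_results(res)
  expect_equal(agg$f_measure_mean, mean(res$f_measure))
  expect_equal(agg$f_measure_se, stats::sd(res$f_measure) / sqrt(10))
  expect_equal(agg$spam_acc_se, stats::sd(res$spam_acc) / sqrt(10))
  expect_equal(agg$n_replicates, 10)
})

test_that("steps the corpus cannot support are skipped with a warning", {
  corp <- sep_corpus(120)  # pool of 60 per class after the half split
  sched <- make_schedule("1-1")  # needs up to 240 per class
  ws <- capture_warnings(res <- run_experiment(corp, sched, variants = "nb",
                                               replicates = 2, seed = 1))
  expect_gt(length(ws), 0)
  expect_true(all(grepl("skipped", ws)))
  expect_equal(sort(unique(res$step_t)), 1L)  # only 40/40 fits in the pool
  # nothing at all runnable is an error, not an empty table
  tiny <- sep_corpus(30)
  expect_error(suppressWarnings(
    run_experiment(tiny, sched, variants = "nb", replicates = 1, seed = 1)),
    "no schedule step")
})

test_that("external classifier adapters are evaluated alongside variants", {
  corp <- sep_corpus(80)
  sched <- make_schedule("1-1")[1, ]
  attr(sched, "experiment_id") <- "1-1"
  class(sched) <- c("experiment_schedule", "data.frame")
  majority <- function(train, test) {
    rep(names(which.max(table(train$label))), nrow(test))
  }
  res <- run_experiment(corp, sched, variants = "nb", replicates = 2,
                        seed = 5, extra_classifiers = list(maj = majority))
  expect_setequal(unique(res$variant), c("nb", "maj"))
  maj_rows <- res[res$variant == "maj", ]
  # balanced training ties the vote toward ham -> no spam predictions
  expect_true(all(maj_rows$f_measure == 0))
  expect_true(all(maj_rows$ham_acc == 1))
})
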