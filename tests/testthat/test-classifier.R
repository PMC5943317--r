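vocab2 <- c("casino", "money")

test_that("fit estimates document-frequency conditionals and densities", {
  m <- fit_classifier(fixture_corpus(), "lsnb", vocab = vocab2)
  expect_equal(m$p["casino", "spam"], 1.0)
  expect_equal(m$p["casino", "ham"], 0.0)
  expect_equal(m$p["money", "spam"], 1.0)
  expect_equal(m$p["money", "ham"], 1.0)
  # presence model: P(w|c) + P(!w|c) = 1 by construction
  expect_true(all(m$p >= 0 & m$p <= 1))
  # word densities from raw token counts 3,2 (spam) / 0,1 (ham)
  expect_equal(m$wd["casino", "spam"], 0.6)
  expect_equal(m$wd["money", "spam"], 0.4)
  expect_equal(m$wd["casino", "ham"], 0.0)
  expect_equal(m$wd["money", "ham"], 1.0)
  expect_equal(colSums(m$wd), c(spam = 1, ham = 1))
  # equal priors by default
  expect_equal(m$priors, c(spam = 0.5, ham = 0.5))
})

test_that("fit rejects degenerate inputs", {
  one_class <- as_corpus(list(c("casino", "casino")), labels = "spam")
  expect_error(fit_classifier(one_class, "nb", vocab = vocab2),
               "each class")
  unlabeled <- as_corpus(list(c("casino", "casino")))
  expect_error(fit_classifier(unlabeled, "nb", vocab = vocab2), "unlabeled")
  expect_error(as_corpus(list("x"), labels = "other"), "binary")
})

test_that("word tables follow the variant's cell mapping", {
  m <- fit_classifier(fixture_corpus(), "lsnb", vocab = vocab2)
  expect_equal(unclass(word_table(m, "casino", "spam")),
               c(a = 1, b = 0, c = 0, d = 1))
  expect_equal(unclass(word_table(m, "money", "spam")),
               c(a = 1, b = 0, c = 1, d = 0))
  me <- fit_classifier(fixture_corpus(), "elsnb", vocab = vocab2)
  # cross-paired densities: b and d swap classes relative to a and c
  expect_equal(unclass(word_table(me, "casino", "spam")),
               c(a = 0.6, b = 0, c = 0, d = 0.6))
  expect_error(word_table(m, "xyzzy", "spam"), "vocabulary")
})

test_that("word weights evaluate the LS strength of the word table", {
  m <- fit_classifier(fixture_corpus(), "lsnb", vocab = vocab2)
  expect_equal(word_weight(m, "casino", "spam"), 1.0)
  expect_equal(word_weight(m, "money", "spam"), 1 / (1 + 0.5))
  expect_equal(word_weight(m, "casino", "ham"), 0.0)
  expect_true(all(m$weights >= 0 & m$weights <= 1))
})

test_that("prediction multiplies present-word weights under equal priors", {
  m <- fit_classifier(fixture_corpus(), "lsnb", vocab = vocab2)
  res <- predict(m, list(c("casino", "money")))
  expect_equal(res$label, "spam")
  expect_equal(res$score_spam, log(0.5) + log(1) + log(2 / 3))
  # floored ham factor for casino keeps the score finite
  expect_true(is.finite(res$score_ham))
  # empty feature vector falls back to priors: tie -> ham
  res0 <- predict(m, list(character(0)))
  expect_equal(res0$label, "ham")
  expect_true(res0$tie)
  # symmetric conditionals tie -> ham
  sym <- as_corpus(list("casino money", "casino money"),
                   labels = c("spam", "ham"))
  ms <- fit_classifier(sym, "nb", vocab = vocab2)
  rs <- predict(ms, list(c("casino", "money")))
  expect_true(rs$tie)
  expect_equal(rs$label, "ham")
})

test_that("forcing the correction terms to zero recovers NB rankings", {
  corp <- generate_corpus(corpus_spec(30, 30, discriminative_strength = 0.5,
                                      seed = 21))
  vocab <- build_vocabulary(corp)
  nb <- fit_classifier(corp, "nb", vocab = vocab, smoothing = FALSE)
  ls0 <- fit_classifier(corp, "lsnb", vocab = vocab, smoothing = FALSE,
                        no_bias = TRUE)
  # Eq. 11 with zero terms is exactly a/(a+b) = P(w|c)
  expect_equal(ls0$weights, nb$weights, tolerance = 1e-15)
  test <- generate_corpus(corpus_spec(20, 20, discriminative_strength = 0.5,
                                      seed = 22))
  expect_identical(predict(ls0, test)$label, predict(nb, test)$label)
})

test_that("fitted scores agree with the brute-force oracle to 1e-10", {
  corp <- generate_corpus(corpus_spec(25, 25, shared_vocab_size = 30,
                                      spam_vocab_size = 4, ham_vocab_size = 4,
                                      doc_length = 20,
                                      discriminative_strength = 0.5,
                                      seed = 33))
  vocab <- build_vocabulary(corp)
  test_docs <- generate_corpus(corpus_spec(5, 5, shared_vocab_size = 30,
                                           spam_vocab_size = 4,
                                           ham_vocab_size = 4,
                                           doc_length = 20,
                                           discriminative_strength = 0.5,
                                           seed = 34))
  for (v in c("nb", "lsnb", "elsnb")) {
    m <- fit_classifier(corp, v, vocab = vocab)
    got <- predict(m, test_docs)
    for (i in seq_len(nrow(test_docs))) {
      want <- oracle_score(corp$tokens, corp$label, vocab, v,
                           test_docs$tokens[[i]])
      expect_equal(got$score_spam[i], want[["spam"]], tolerance = 1e-10)
      expect_equal(got$score_ham[i], want[["ham"]], tolerance = 1e-10)
    }
  }
})

test_that("identical corpus, seed and options give identical predictions", {
  run <- function() {
    corp <- generate_corpus(corpus_spec(40, 40, seed = 55))
    m <- fit_classifier(corp, "elsnb")
    predict(m, generate_corpus(corpus_spec(10, 10, seed = 56)))
  }
  expect_identical(run(), run())
})

test_that("models round-trip exactly through the text format", {
  corp <- generate_corpus(corpus_spec(20, 20, seed = 77))
  f <- withr::local_tempfile(fileext = ".txt")
  for (v in c("nb", "lsnb", "elsnb")) {
    m <- fit_classifier(corp, v)
    save_model(m, f)
    m2 <- load_model(f)
    expect_identical(m2$variant, m$variant)
    expect_identical(m2$vocab, m$vocab)
    expect_equal(m2$weights, m$weights, tolerance = 0)
    expect_equal(m2$priors, m$priors, tolerance = 0)
    probe <- generate_corpus(corpus_spec(5, 5, seed = 78))
    expect_identical(predict(m, probe), predict(m2, probe))
  }
})
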