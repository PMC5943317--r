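# Independent literal transcriptions used as oracles. These are written
# directly from the model definitions, separately from the library code,
# and deliberately use naive per-document loops.

# pooled term with the 0/0 -> 0 convention
.o_pool <- function(x, y) if (x + y == 0) 0 else x * y / (x + y)

# LS strengths, one expression per direction
oracle_ls <- function(a, b, c, d, direction = "Q_GIVEN_P") {
  switch(direction,
    Q_GIVEN_P =
      (a + .o_pool(b, d)) / (a + b + .o_pool(a, c) + .o_pool(b, d)),
    NOTQ_GIVEN_P =
      (b + .o_pool(a, c)) / (a + b + .o_pool(a, c) + .o_pool(b, d)),
    P_GIVEN_Q =
      (a + .o_pool(c, d)) / (a + c + .o_pool(a, b) + .o_pool(c, d)),
    NOTQ_GIVEN_NOTP =
      (d + .o_pool(a, c)) / (c + d + .o_pool(a, c) + .o_pool(b, d)),
    stop("bad direction"))
}

# Brute-force document scorer: rebuilds every word table from raw counts,
# one test document at a time. `train` is a list of token vectors,
# `labels` the matching spam/ham labels.
oracle_score <- function(train, labels, vocab, variant, doc_tokens,
                         smoothing = (variant == "nb"),
                         priors = c(spam = 0.5, ham = 0.5), floor = 1e-12) {
  classes <- c("spam", "ham")
  n_docs <- sapply(classes, function(cl) sum(labels == cl))
  dfreq <- function(cl, w) {
    sum(vapply(train[labels == cl], function(tt) w %in% tt, TRUE))
  }
  pw <- function(cl, w) {
    if (smoothing) (dfreq(cl, w) + 1) / (n_docs[[cl]] + 2)
    else dfreq(cl, w) / n_docs[[cl]]
  }
  ntok <- function(cl, w) {
    sum(vapply(train[labels == cl], function(tt) sum(tt == w), 0))
  }
  wdens <- function(cl, w) {
    tot <- sum(vapply(vocab, function(v) ntok(cl, v), 0))
    if (tot == 0) 0 else ntok(cl, w) / tot
  }
  present <- vocab[vocab %in% doc_tokens]
  scores <- sapply(classes, function(cl) {
    oc <- setdiff(classes, cl)
    s <- log(priors[[cl]])
    for (w in present) {
      if (variant == "nb") {
        wt <- pw(cl, w)
      } else if (variant == "lsnb") {
        wt <- oracle_ls(pw(cl, w), 1 - pw(cl, w),
                        pw(oc, w), 1 - pw(oc, w), "Q_GIVEN_P")
      } else {
        wt <- oracle_ls(pw(cl, w) * wdens(cl, w),
                        (1 - pw(cl, w)) * wdens(oc, w),
                        pw(oc, w) * wdens(oc, w),
                        (1 - pw(oc, w)) * wdens(cl, w), "Q_GIVEN_P")
      }
      if (is.nan(wt)) wt <- 0  # all-zero table
      s <- s + log(max(wt, floor))
    }
    s
  })
  names(scores) <- classes
  scores
}

# Tiny hand-checkable training fixture shared across classifier tests
fixture_corpus <- function() {
  as_corpus(list(c("casino", "casino", "money"),
                 c("casino", "money"),
                 c("meeting", "money")),
            labels = c("spam", "spam", "ham"))
}

# random valid tables; a fraction of cells forced to exact zero
random_tables <- function(n, zero_frac = 0.15) {
  m <- matrix(stats::runif(4 * n), ncol = 4)
  zeros <- matrix(stats::runif(4 * n) < zero_frac, ncol = 4)
  m[zeros] <- 0
  bad <- rowSums(m) == 0
  m[bad, 1] <- 1
  colnames(m) <- c("a", "b", "c", "d")
  m
}
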