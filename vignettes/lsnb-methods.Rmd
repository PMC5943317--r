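---
title: "Methods: the loosely symmetric classifier family and its test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the loosely symmetric classifier family and its test world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsnb)
```

# The model

## LS strength on a 2×2 table

Given a table with cells $a, b, c, d$ (co-occurrence of events $p$ and $q$,
$p$ alone, $q$ alone, joint absence), the LS strength of "if $p$ then $q$"
is

$$LS(q|p) = \frac{a + \frac{bd}{b+d}}{a + b + \frac{ac}{a+c} + \frac{bd}{b+d}}.$$

It is a conditional probability $a/(a+b)$ whose numerator and denominator
are augmented by two pooled terms. When both terms vanish the measure *is*
the conditional probability (no bias). When $b = c$ the converse direction
$LS(p|q)$ coincides with $LS(q|p)$ (complete symmetric bias); when
additionally $a = d$, the contrapositive-like direction
$LS(\bar q|\bar p)$ coincides too (complete mutually exclusive bias).
Between these regimes the model takes intermediate values — unlike the
$\Delta P$ and dual-factor-heuristic comparators, which commit fully to one
bias each. All four directional equations are implemented verbatim,
including the asymmetric pooled terms of the converse and contrapositive
forms; the package's identity tests (normalization, the two coincidence
identities, scale invariance, the no-bias limit, range) are the checkable
consequences of those exact forms.

Numerical conventions:

* a pooled term with a zero denominator is defined as 0, its limit as both
  cells shrink — this keeps the measure defined on sparse tables and makes
  the no-bias limit exact rather than approximate;
* a table whose full LS denominator is 0 (e.g. $a=b=0$ with $c=0$) is
  rejected with an error naming the cells, rather than returning an
  arbitrary value;
* cells may be frequencies or probabilities — every LS direction is
  invariant to scaling all cells by $k>0$, so no normalization is imposed.

## The classifier variants

All variants are Bernoulli naive Bayes at the core: a document is its set
of vocabulary words (presence only), and the class score is

$$\log P(c) + \sum_{w \in W} \log \omega(w, c),$$

with the product running over words **present** in the document. Absence
factors $1 - P(w|c)$ are not multiplied in: the likelihood is indexed over
the message's feature vector, and this keeps scores comparable across
documents of different lengths. The evidence term is dropped, so scores
rank classes but are not calibrated posteriors.

The per-word weight $\omega(w,c)$ is what distinguishes the variants:

| variant | weight |
|---|---|
| `nb`    | $P(w|c)$ |
| `lsnb`  | $LS(q|p)$ of $(P(w|c),\, P(\bar w|c),\, P(w|\bar c),\, P(\bar w|\bar c))$ |
| `elsnb` | $LS(q|p)$ of $(P(w|c)WD(c,w),\, P(\bar w|c)WD(\bar c,w),\, P(w|\bar c)WD(\bar c,w),\, P(\bar w|\bar c)WD(c,w))$ |

$P(w|c)$ is the fraction of class-$c$ training documents containing $w$
(document frequency), so $P(w|c) + P(\bar w|c) = 1$ — the row constraint
the LS table mapping requires. Word density
$WD(c,w) = N(c,w) / \sum_k N(c,w_k)$ is computed from raw **token** counts
over the vocabulary; the presence probabilities and the densities
deliberately coexist on different event models.

Two deliberate subtleties:

* **Cross-paired densities in eLSNB.** The $b$ cell uses $WD(\bar c, w)$
  and the $d$ cell uses $WD(c, w)$ — the densities swap classes relative
  to $a$ and $c$. This is implemented exactly as defined, not "corrected"
  to the aligned pairing: the crossing is what strengthens the
  contraposition of the table, and it is the stated mechanism behind
  eLSNB's robustness to imbalance. A practical consequence: a word with
  zero tokens in class $c$ zeroes both numerator terms of $\omega(w,c)$,
  so eLSNB penalizes such words hard (through the log-floor), while LSNB's
  correction terms partially rescue them.
* **Asymmetric smoothing defaults.** `nb` uses add-one smoothing on
  document counts (raw zero estimates are fatal under a product and the
  source material is silent on smoothing; add-one is the field's default),
  while `lsnb`/`elsnb` use raw estimates because the correction terms
  already damp zeros. Both are switchable (`smoothing =`), and the
  NB-limit test (`no_bias = TRUE`) matches the two by fitting both
  unsmoothed.

## Parameters that matter

| parameter | default | rationale |
|---|---|---|
| priors | 0.5 / 0.5 | avoid any initial class asymmetry; imbalance should act only through the conditionals |
| `floor` | $10^{-12}$ | lower bound on any weight before `log`; keeps scores finite, preserves ranking; one floored word contributes $\approx -27.6$, so floored words act as strong, bounded vetoes |
| `min_total_count` | 2 | content words are bursty and recur; words observed once carry noise, not signal |
| smoothing | `nb`: add-one; LS variants: none | see above |
| tie rule | predict ham | conservative for spam filtering; applies to empty feature vectors, which fall back to equal priors |
| vocabulary scope | whole corpus, pre-split | mirrors a fixed preprocessing pass over the dataset; `vocab_scope = "train"` rebuilds per training sample to rule out vocabulary-level leakage |

Two genuinely open choices were resolved as follows: the min-count filter
counts **token occurrences** (not document frequency — the burstiness
rationale is about recurrence, and `count = "documents"` remains
available), and it is applied **before** the train/test split by default
(matching a preprocessing pass done once per dataset; the alternative is a
flag, not a fork of the protocol).

# The experiment harness

Five schedules are provided: equal growth (40t/40t, t ≤ 6), two fixed-ratio
biased designs (24t/40t, t ≤ 10; 8t/40t, t ≤ 30), and two fixed-class
designs (one class pinned at 25 or 100 while the other grows 40t, t ≤ 6).
Per replicate, a stratified random half of the corpus is held out as the
test set and training samples are drawn uniformly without replacement from
the remaining half — training data never overlaps the test half. The test
half is resampled per replicate (the alternative, one fixed half, would
underestimate variance). Replicate seeds derive deterministically from one
base seed. The replicate count defaults to 10; the source protocol reports
standard errors but not the repetition count, so this is a documented
choice, not a reproduction.

Metrics: spam accuracy (recall on spam), ham accuracy (recall on ham), and
F-measure = F1 with spam as the positive class ($\beta$ and the positive
class are unstated upstream; F1-on-spam is the field's convention). When no
document is predicted spam, precision is undefined and F is reported as 0.

External baselines (SVM, neural network, logistic regression, random
forest) are out of scope as code; `run_experiment(extra_classifiers=)`
accepts adapter functions so a user can plug in e.g. `e1071::svm`. For the
record, the reference configuration used alongside these models elsewhere
is: SVM with Gaussian kernel, cost = 0.1, gamma = 0.1; a three-layer
network with 10 sigmoid hidden nodes; binomial regression with
$\alpha$ = 0.1; random forest with 300 trees and $\sqrt{|W|}$ split
features.

# The synthetic corpus world

`generate_corpus()` emulates the three corpus properties the classifiers
rely on: two classes with a largely shared vocabulary, a small set of
class-discriminative words, and bursty content-word repetition. Each
document samples shared-word presence at a rate calibrated so the expected
length matches `doc_length`, adds each own-class exclusive word with
probability `discriminative_strength`, then draws
$1 + \text{Geometric}(1/(1+\text{burstiness}))$ tokens per present word.

Defaults — 150 shared words, 8 exclusive words per class appearing in 60%
of their class's documents, mean length 60 tokens, burstiness 1 (each
present word averages two tokens) — describe a moderately easy filtering
problem: a typical document carries several marker words, but roughly
$0.4^8 \approx 0.07\%$ of documents carry none and are decided by
shared-word noise. This is a *stated world*, chosen once: green tests
establish that the implementation behaves as derived in this world, *not*
that the variants would rank the same way on real email. Features of real
corpora the generator deliberately omits: topic structure and word
correlations beyond co-presence, header/metadata signal, adversarial
drift of spam vocabulary, Zipfian frequencies, and document-length
heterogeneity beyond the Poisson-like mixing the presence model induces.

Word strings are letter-coded (`saaab`, `haaab`, `caaab`) rather than
digit-suffixed: the cleaning rules eliminate numerals, so digit-bearing
tokens would be destroyed by the tokenizer and the generator → writer →
loader round trip would not be the identity.

One observed property of this world worth recording: under the fixed-spam
growing-ham design both `nb` and `elsnb` operate near ceiling
(F ≈ 0.99–1.0), so the *fraction of replicates where eLSNB's F at least
matches NB's* is dominated by near-ties and fluctuates across base seeds
(60–100% over the seeds we probed). The packaged acceptance test fixes its
seeds a priori and passes at the stated ≥ 70% threshold; the acceptance
script reports the same quantity under the caller's seed as a diagnostic,
not a guarantee.

# Known limitations

* Binary classes only — the complementary class $\bar c$ is structural to
  the LS table mapping; multi-class input is rejected at fit time.
* Scores are unnormalized; do not interpret differences across models as
  probability ratios.
* The loaders handle plain-text, one-message-per-file trees (optionally
  stripping a leading header block); MIME, HTML and mbox parsing are out
  of scope.
* No lemmatization or stemming: the lemmatized corpus variant this
  pipeline mirrors is pre-lemmatized upstream.
* The LS model's intermediacy between the two biases is verified
  empirically (identity and range tests); no theoretical characterization
  is attempted.
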