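#' 2x2 contingency table for association strength measures
#'
#' Builds the contingency table underlying the loosely symmetric (LS) model
#' and its comparators. The cells cross event `p` (rows) with event `q`
#' (columns): `a` counts co-occurrence of `p` and `q`, `b` counts `p` without
#' `q`, `c` counts `q` without `p`, and `d` counts the joint absence. Cells
#' may be raw frequencies or joint probabilities; all LS strengths are
#' invariant to a common positive rescaling, so the two conventions are
#' interchangeable and no normalization is imposed.
#'
#' @param a,b,c,d Nonnegative cell values; at least one must be positive.
#' @return An object of class `ls_table`: a named numeric vector with
#'   elements `a`, `b`, `c`, `d`.
#' @examples
#' ls_table(2, 1, 1, 3)
#' @seealso [ls_strength()], [correction_terms()], [assoc_strength()]
#' @export
ls_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (length(cells) != 4L || !is.numeric(cells)) {
    stop("a, b, c, d must be single numeric values", call. = FALSE)
  }
  if (anyNA(cells) || any(!is.finite(cells))) {
    stop("contingency cells must be finite and non-missing", call. = FALSE)
  }
  if (any(cells < 0)) {
    stop("contingency cells must be nonnegative", call. = FALSE)
  }
  if (all(cells == 0)) {
    stop("degenerate contingency table: all four cells are zero", call. = FALSE)
  }
  structure(as.numeric(cells), names = c("a", "b", "c", "d"),
            class = "ls_table")
}

#' @export
print.ls_table <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(c("p", "!p"), c("q", "!q")))
  print(m, ...)
  invisible(x)
}

as_ls_table <- function(x) {
  if (inherits(x, "ls_table")) return(x)
  if (is.numeric(x) && length(x) == 4L) return(ls_table(x[1], x[2], x[3], x[4]))
  stop("expected an ls_table or a numeric vector of four cells", call. = FALSE)
}

## ratio xy/(x+y) with the sparse-table convention 0/0 -> 0
.pooled_term <- function(x, y) {
  s <- x + y
  if (s == 0) 0 else x * y / s
}

#' LS bias correction terms of a contingency table
#'
#' The LS model is a conditional probability modified by the two pooled
#' terms `ac/(a+c)` and `bd/(b+d)`, which graft a symmetric and a mutually
#' exclusive bias onto `a/(a+b)`. A term whose denominator is zero is
#' defined as 0 (its limit as both cells shrink), which keeps the model
#' defined on sparse tables and preserves the no-bias limit.
#'
#' @param table An [ls_table()] or numeric vector of four cells.
#' @return Named numeric vector with elements `ac` (= ac/(a+c)) and
#'   `bd` (= bd/(b+d)).
#' @examples
#' correction_terms(ls_table(2, 1, 1, 3))  # c(ac = 2/3, bd = 3/4)
#' @export
correction_terms <- function(table) {
  t <- as_ls_table(table)
  c(ac = .pooled_term(t[["a"]], t[["c"]]),
    bd = .pooled_term(t[["b"]], t[["d"]]))
}

#' @rdname ls_strength
#' @format NULL
#' @export
ls_directions <- c("Q_GIVEN_P", "NOTQ_GIVEN_P", "P_GIVEN_Q", "NOTQ_GIVEN_NOTP")

#' Loosely symmetric association strength
#'
#' Evaluates the LS model on a 2x2 contingency table. The LS strength is a
#' conditional probability whose numerator and denominator are augmented by
#' the pooled correction terms (see [correction_terms()]); the model thereby
#' interpolates between plain conditional probability (no bias, both terms 0)
#' and the complete symmetric / mutually exclusive biases. Four directions
#' are available:
#'
#' * `Q_GIVEN_P`: strength of "if p then q",
#'   `(a + bd/(b+d)) / (a + b + ac/(a+c) + bd/(b+d))`.
#' * `NOTQ_GIVEN_P`: complement direction,
#'   `(b + ac/(a+c)) / (a + b + ac/(a+c) + bd/(b+d))`; sums with
#'   `Q_GIVEN_P` to exactly 1.
#' * `P_GIVEN_Q`: the converse,
#'   `(a + cd/(c+d)) / (a + c + ab/(a+b) + cd/(c+d))`; equals `Q_GIVEN_P`
#'   whenever `b == c` (complete symmetric bias).
#' * `NOTQ_GIVEN_NOTP`: the contrapositive-like direction,
#'   `(d + ac/(a+c)) / (c + d + ac/(a+c) + bd/(b+d))`; equals `Q_GIVEN_P`
#'   whenever `a == d` and `b == c` (complete mutually exclusive bias).
#'
#' @param table An [ls_table()] or numeric vector of four cells.
#' @param direction One of `ls_directions`; defaults to `"Q_GIVEN_P"`.
#' @return A number in \[0, 1\].
#' @examples
#' ls_strength(ls_table(1, 1, 1, 1), "Q_GIVEN_P")  # 0.5
#' ls_strength(c(2, 1, 1, 3), "Q_GIVEN_P")         # 0.6226...
#' @export
ls_strength <- function(table, direction = "Q_GIVEN_P") {
  t <- as_ls_table(table)
  direction <- match.arg(direction, ls_directions)
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  ac <- .pooled_term(a, cc)
  bd <- .pooled_term(b, d)
  val <- switch(direction,
    Q_GIVEN_P = {
      num <- a + bd
      den <- a + b + ac + bd
      c(num, den)
    },
    NOTQ_GIVEN_P = {
      num <- b + ac
      den <- a + b + ac + bd
      c(num, den)
    },
    P_GIVEN_Q = {
      ab <- .pooled_term(a, b)
      cd <- .pooled_term(cc, d)
      num <- a + cd
      den <- a + cc + ab + cd
      c(num, den)
    },
    NOTQ_GIVEN_NOTP = {
      num <- d + ac
      den <- cc + d + ac + bd
      c(num, den)
    })
  if (val[2] == 0) {
    stop(sprintf(
      "LS denominator is zero for direction %s on table (a=%g, b=%g, c=%g, d=%g)",
      direction, a, b, cc, d), call. = FALSE)
  }
  unname(val[1] / val[2])
}

#' Comparator association measures on a 2x2 table
#'
#' Classical strength measures from the causal-induction literature, used as
#' points of comparison for the LS model: plain conditional probability
#' (`cp`, no bias), the delta-P contingency measure (`delta_p`, satisfies the
#' mutually exclusive bias), and the dual-factor heuristic (`dh`, satisfies
#' the symmetric bias). Standard literature definitions are used.
#'
#' @param table An [ls_table()] or numeric vector of four cells.
#' @param model One of `"cp"`, `"delta_p"`, `"dh"`.
#' @return A number: `a/(a+b)` for `cp`; `a/(a+b) - c/(c+d)` for `delta_p`;
#'   `sqrt(a/(a+b) * a/(a+c))` for `dh`.
#' @examples
#' assoc_strength(c(2, 1, 1, 3), "delta_p")  # 2/3 - 1/4
#' @export
assoc_strength <- function(table, model = c("cp", "delta_p", "dh")) {
  t <- as_ls_table(table)
  model <- match.arg(model)
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  chk <- function(m, label) {
    if (m == 0) stop(sprintf("zero marginal %s", label), call. = FALSE)
    m
  }
  switch(model,
    cp = a / chk(a + b, "a+b"),
    delta_p = a / chk(a + b, "a+b") - cc / chk(cc + d, "c+d"),
    dh = sqrt(a / chk(a + b, "a+b") * a / chk(a + cc, "a+c")))
}
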