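#' Load a labeled corpus from a directory tree
#'
#' Reads one plain-text message per file and assigns labels according to the
#' layout style:
#'
#' * `"class_subdirs"`: `root/spam/*` and `root/ham/*` (the layout
#'   [write_corpus()] produces, and SpamAssassin-style trees renamed into
#'   two folders).
#' * `"lingspam_parts"`: Ling-Spam layout — `root/part1 ... partN` folders
#'   (or files directly under root); files whose name starts with `spmsg`
#'   are spam, all others ham.
#' * `"filename_prefix"`: like `"lingspam_parts"` with a custom `prefix`,
#'   scanning the whole tree.
#'
#' Files are decoded as UTF-8 with a Latin-1 fallback (legacy email corpora
#' are dirty); hidden files are skipped; unreadable files are skipped with a
#' warning. Per-class counts are reported via `message()`.
#'
#' @param root Corpus root directory.
#' @param style Layout style, see above.
#' @param prefix Spam filename prefix for `"filename_prefix"`
#'   (default `"spmsg"`).
#' @param strip_headers If TRUE, drop all lines up to the first blank line
#'   of each file (SpamAssassin-style raw emails carry header blocks);
#'   default FALSE (Ling-Spam lemm files are subject + body plain text).
#' @param ... Passed to [tokenize()].
#' @return A labeled `lsnb_corpus`; `source_id`s are file paths relative to
#'   `root`.
#' @export
load_corpus <- function(root,
                        style = c("class_subdirs", "lingspam_parts",
                                  "filename_prefix"),
                        prefix = "spmsg", strip_headers = FALSE, ...) {
  style <- match.arg(style)
  root <- sub("/+$", "", root)
  if (!dir.exists(root)) stop("corpus root not found: ", root, call. = FALSE)
  if (style == "class_subdirs") {
    files <- character(0)
    labels <- character(0)
    for (cl in c("spam", "ham")) {
      fs <- list.files(file.path(root, cl), full.names = TRUE)
      fs <- fs[!dir.exists(fs)]
      files <- c(files, fs)
      labels <- c(labels, rep(cl, length(fs)))
    }
  } else {
    files <- list.files(root, recursive = TRUE, full.names = TRUE)
    files <- files[!dir.exists(files)]
    labels <- ifelse(startsWith(basename(files), prefix), "spam", "ham")
  }
  keep <- !startsWith(basename(files), ".")
  files <- files[keep]
  labels <- labels[keep]
  texts <- vector("list", length(files))
  ok <- rep(TRUE, length(files))
  for (i in seq_along(files)) {
    txt <- tryCatch(read_message(files[i], strip_headers = strip_headers),
                    error = function(e) NULL)
    if (is.null(txt)) {
      warning("skipping unreadable file: ", files[i], call. = FALSE)
      ok[i] <- FALSE
    } else {
      texts[[i]] <- txt
    }
  }
  files <- files[ok]
  labels <- labels[ok]
  texts <- texts[ok]
  for (cl in c("spam", "ham")) {
    if (!any(labels == cl)) {
      stop(sprintf("no '%s' messages found under %s (style=%s)",
                   cl, root, style), call. = FALSE)
    }
  }
  message(sprintf("loaded %d messages from %s: %d spam, %d ham",
                  length(files), root, sum(labels == "spam"),
                  sum(labels == "ham")))
  ids <- substring(files, nchar(root) + 2L)
  corp <- as_corpus(vapply(texts, identity, ""), labels = labels, ids = ids,
                    ...)
  ord <- order(corp$id, method = "radix")
  corp <- corp[ord, ]
  rownames(corp) <- NULL
  corp
}

read_message <- function(path, strip_headers = FALSE) {
  raw <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(raw)
  if (!validUTF8(txt)) {
    txt <- iconv(txt, from = "latin1", to = "UTF-8", sub = " ")
  }
  if (strip_headers) {
    lines <- strsplit(txt, "\r?\n")[[1]]
    blank <- which(!nzchar(trimws(lines)))[1]
    if (!is.na(blank)) txt <- paste(lines[-seq_len(blank)], collapse = "\n")
  }
  txt
}

#' Write a corpus to a class-subdirectory tree
#'
#' Writes one file per message under `dir/spam/` and `dir/ham/`, each file
#' holding the document's tokens separated by spaces. The layout round-trips
#' through `load_corpus(dir, "class_subdirs")`.
#'
#' @param corpus A labeled `lsnb_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "lsnb_corpus"))
  if (anyNA(corpus$label)) {
    stop("corpus has unlabeled documents", call. = FALSE)
  }
  for (cl in unique(corpus$label)) {
    dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(nrow(corpus))) {
    path <- file.path(dir, corpus$label[i], paste0(corpus$id[i], ".txt"))
    writeLines(paste(corpus$tokens[[i]], collapse = " "), path,
               useBytes = TRUE)
  }
  invisible(dir)
}

#' Write experiment results as CSV
#'
#' Writes a per-replicate result table with the fixed column contract
#' `experiment_id, step_t, n_spam, n_ham, variant, replicate, spam_acc,
#' ham_acc, f_measure`, rows sorted by (experiment, step, variant,
#' replicate) regardless of input order. Aggregated tables from
#' [aggregate_results()] are written as-is (already sorted).
#'
#' @param results An `experiment_result` or aggregated data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("results must be a nonempty data frame", call. = FALSE)
  }
  if ("replicate" %in% names(results)) {
    cols <- c("experiment_id", "step_t", "n_spam", "n_ham", "variant",
              "replicate", "spam_acc", "ham_acc", "f_measure")
    if (!all(cols %in% names(results))) {
      stop("results lack the required columns", call. = FALSE)
    }
    results <- results[order(results$experiment_id, results$step_t,
                             results$variant, results$replicate),
                       cols, drop = FALSE]
  }
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
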