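#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney correspondence: the probability that a
#' random positive scores above a random negative, with half credit for
#' ties (equivalent to trapezoidal integration of the ROC curve).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), parallel to `scores`.
#' @return AUCROC in \[0, 1\].
#' @export
#' @examples
#' aucroc(c(0.9, 0.8, 0.1), c(1, 1, 0))
aucroc <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("aucroc: needs at least one positive and one negative label")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision style) integration: thresholds sweep the
#' unique score values in decreasing order and each recall increment is
#' credited at the precision attained there. Avoids the optimistic bias of
#' linear PR interpolation. With all-identical scores the curve collapses to
#' the single point (recall 1, precision = prevalence).
#'
#' @inheritParams aucroc
#' @return AUCPR in \[0, 1\].
#' @export
aucpr <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("aucpr: needs at least one positive label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  # keep only the last index of each tied score block (threshold = that score)
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

check_binary_labels <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), length(scores) > 0L)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  labels
}

#' Evaluation metrics for a score vector
#'
#' @inheritParams aucroc
#' @return List with `aucpr`, `aucroc`, `n_pos`, `n_neg`.
#' @export
metric_report <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  list(aucpr = aucpr(scores, labels), aucroc = aucroc(scores, labels),
       n_pos = sum(labels == 1L), n_neg = sum(labels == 0L))
}

#' Section importance scores from attention weights
#'
#' For each named note section, the importance score is the sum of attention
#' weights of its non-stop-word tokens divided by the total attention mass on
#' all non-stop-word content tokens; stop words are excluded from both sides
#' (their importance is not calculated). Spans sharing a canonical section
#' name are aggregated. Scores are invariant to rescaling of `alpha` and sum
#' to 1 when every non-stop-word content token belongs to a section.
#'
#' @param alpha Attention weights (length >= content length; pad positions
#'   zero).
#' @param sections Data.frame with `name`, `start`, `end` (half-open token
#'   spans) as produced by [assemble_bundle_text()].
#' @param stopword_mask Logical vector parallel to `alpha`.
#' @return Data.frame with columns `section` and `score`, sorted by
#'   decreasing score; empty (with a warning) if no non-stop-word attention
#'   mass exists.
#' @export
section_importance <- function(alpha, sections, stopword_mask) {
  stopifnot(length(stopword_mask) >= 1L, nrow(sections) >= 0L)
  w <- alpha
  w[stopword_mask] <- 0
  total <- sum(w)
  if (total <= 0) {
    warning("section_importance: no attention mass on non-stop-word tokens")
    return(data.frame(section = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (nrow(sections) == 0L) {
    return(data.frame(section = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  raw <- vapply(seq_len(nrow(sections)), function(j) {
    i0 <- sections$start[j]; i1 <- sections$end[j] - 1L
    if (i1 < i0) 0 else sum(w[i0:i1])
  }, numeric(1))
  agg <- rowsum(raw, sections$name)
  out <- data.frame(section = rownames(agg), score = agg[, 1] / total,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$score, out$section), , drop = FALSE]
}

#' Export an attention heatmap as standalone HTML
#'
#' Renders each non-stop-word token with a blue background whose opacity is
#' proportional to its attention weight (normalized by the maximum weight),
#' and each section header shaded by its importance score; stop words and
#' pads are unshaded. The intensities are embedded as `data-alpha`
#' attributes so the rendering is machine-checkable.
#'
#' @param tokens Character tokens (content positions).
#' @param alpha Attention weights parallel to `tokens`.
#' @param sections Section span data.frame (`name`, `start`, `end`).
#' @param section_scores Data.frame from [section_importance()].
#' @param out_path Output HTML file path.
#' @param stopword_mask Logical vector parallel to `tokens` (default: shipped
#'   stop-word list).
#' @return `out_path`, invisibly.
#' @export
export_heatmap <- function(tokens, alpha, sections, section_scores, out_path,
                           stopword_mask = tokens %in% stopword_list()) {
  n <- length(tokens)
  stopifnot(length(alpha) >= n, length(stopword_mask) >= n)
  amax <- max(alpha[seq_len(n)][!stopword_mask[seq_len(n)]], 0)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  score_of <- function(nm) {
    i <- match(nm, section_scores$section)
    if (is.na(i)) 0 else section_scores$score[i]
  }
  span_html <- function(i) {
    if (stopword_mask[i] || amax <= 0) {
      sprintf('<span class="tok stop" data-alpha="0">%s</span>',
              esc(tokens[i]))
    } else {
      inten <- alpha[i] / amax
      sprintf(paste0('<span class="tok" data-alpha="%.6f" style=',
                     '"background-color: rgba(30,100,200,%.4f)">%s</span>'),
              inten, 0.85 * inten, esc(tokens[i]))
    }
  }
  body <- character(0)
  covered <- rep(FALSE, n)
  if (nrow(sections) > 0L) {
    for (j in seq_len(nrow(sections))) {
      i0 <- sections$start[j]; i1 <- min(sections$end[j] - 1L, n)
      if (i1 < i0) next
      sc <- score_of(sections$name[j])
      body <- c(body, sprintf(
        paste0('<div class="section"><h3 data-score="%.6f" style=',
               '"background-color: rgba(30,100,200,%.4f)">%s</h3><p>'),
        sc, 0.85 * min(sc, 1), esc(sections$name[j])))
      body <- c(body, vapply(i0:i1, span_html, character(1)), "</p></div>")
      covered[i0:i1] <- TRUE
    }
  }
  if (any(!covered)) {
    body <- c(body, '<div class="section"><h3 data-score="0">UNSECTIONED</h3><p>',
              vapply(which(!covered), span_html, character(1)), "</p></div>")
  }
  html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
            "<title>Attention heatmap</title>",
            "<style>.tok{padding:1px 2px;margin:1px;display:inline-block}",
            ".section h3{padding:2px 4px}</style></head><body>",
            body, "</body></html>")
  ok <- tryCatch({
    writeLines(html, out_path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("export_heatmap: failed to write ", out_path, ": ",
         conditionMessage(ok))
  }
  invisible(out_path)
}
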