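#' Predict mortality probabilities for new episodes
#'
#' Runs the fitted network in inference mode (running batch-normalization
#' statistics, no dropout) on new episodes, preprocessed exactly as at
#' training time with training-split statistics and vocabulary
#' (out-of-vocabulary tokens map to UNK). Labels on the episodes, if any,
#' are never read.
#'
#' @param object A fitted `"mortnet"` model.
#' @param newdata Episodes ([read_cohort()] / [as_episodes()]).
#' @param ... Unused.
#' @return Named numeric vector of death probabilities, one per episode, in
#'   input order.
#' @export
predict.mortnet <- function(object, newdata, ...) {
  cfg <- object$config; flags <- object$flags
  # strip labels defensively: the predict path must not see them
  newdata <- lapply(newdata, function(e) { e$label <- NULL; e })
  prep <- prepare_samples(newdata, cfg, flags)
  samples <- finalize_samples(prep, newdata, cfg, flags, object$train_stats,
                              object$vocab)
  probs <- predict_samples(samples, object$params, cfg, flags)
  names(probs) <- vapply(newdata, `[[`, character(1), "stay_id")
  probs
}

#' Evaluate a fitted model on labelled episodes
#'
#' @param model A fitted `"mortnet"` model.
#' @param episodes Labelled episodes.
#' @return A [metric_report()] list (`aucpr`, `aucroc`, `n_pos`, `n_neg`).
#' @export
evaluate_cohort <- function(model, episodes) {
  labels <- vapply(episodes, function(e) as.numeric(e$label), numeric(1))
  if (any(is.na(labels))) stop("evaluate_cohort: episodes need labels")
  metric_report(predict(model, episodes), labels)
}

#' Attention-based explanation of one episode
#'
#' Runs a forward pass on one episode and returns the per-token attention
#' weights, the section spans, the section-importance scores (stop words
#' excluded) and the predicted probability. Requires a label-aware attention
#' variant.
#'
#' @param model A fitted `"mortnet"` model (variant `multi_atten` or
#'   `multi_atten_chronic`).
#' @param episode One episode.
#' @return Object of class `"mortnet_explanation"`: list with `stay_id`,
#'   `y_hat`, `tokens`, `alpha`, `stopword_mask`, `sections`,
#'   `section_scores`.
#' @export
explain <- function(model, episode) {
  stopifnot(inherits(model, "mortnet"))
  if (!model$flags$attention) {
    stop("explain: variant '", model$config$variant,
         "' has no attention branch")
  }
  cfg <- model$config; flags <- model$flags
  episode$label <- NULL
  prep <- prepare_samples(list(episode), cfg, flags)
  smp <- finalize_samples(prep, list(episode), cfg, flags,
                          model$train_stats, model$vocab)
  fw <- forward_batch(smp, model$params, cfg, flags, training = FALSE)
  n_c <- smp[[1]]$n_c
  alpha <- numeric(cfg$L_max)
  if (n_c > 0L) alpha[seq_len(n_c)] <- fw$alphas[[1]]
  scores <- if (n_c > 0L) {
    section_importance(alpha, smp[[1]]$sections, smp[[1]]$stopword_mask)
  } else {
    data.frame(section = character(0), score = numeric(0))
  }
  structure(list(stay_id = episode$stay_id, y_hat = unname(fw$y_hat),
                 tokens = smp[[1]]$tokens[seq_len(max(n_c, 0L))],
                 alpha = alpha[seq_len(max(n_c, 0L))],
                 stopword_mask = smp[[1]]$stopword_mask[seq_len(max(n_c, 0L))],
                 sections = smp[[1]]$sections, section_scores = scores),
            class = "mortnet_explanation")
}

#' Write the HTML heatmap for an explanation
#'
#' @param x A `"mortnet_explanation"` from [explain()].
#' @param out_path Output HTML path.
#' @return `out_path`, invisibly.
#' @export
explanation_heatmap <- function(x, out_path) {
  stopifnot(inherits(x, "mortnet_explanation"))
  export_heatmap(x$tokens, x$alpha, x$sections, x$section_scores, out_path,
                 stopword_mask = x$stopword_mask)
}

#' @export
print.mortnet_explanation <- function(x, ...) {
  cat("<mortnet_explanation>", x$stay_id, " y_hat =",
      format(x$y_hat, digits = 3), "\n")
  if (nrow(x$section_scores) > 0L) {
    top <- utils::head(x$section_scores, 3L)
    cat("top sections:",
        paste(sprintf("%s (%.2f)", top$section, top$score), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
print.mortnet <- function(x, ...) {
  cat("Multimodal ICU mortality network\n")
  cat("  variant:     ", x$config$variant, "\n")
  cat("  episodes:    ", length(x$labels), " (",
      sum(x$labels == 1), " positive)\n", sep = "")
  cat("  best epoch:  ", x$best_epoch,
      if (!is.na(x$best_val)) sprintf(" (val AUCPR %.3f)", x$best_val),
      "\n", sep = "")
  if (!is.null(x$test_metrics)) {
    cat(sprintf("  test:         AUCPR %.3f | AUCROC %.3f\n",
                x$test_metrics$aucpr, x$test_metrics$aucroc))
  }
  invisible(x)
}

#' @export
summary.mortnet <- function(object, ...) {
  out <- list(config = object$config, n = length(object$labels),
              n_pos = sum(object$labels == 1),
              vocab_size = length(object$vocab),
              n_params = sum(vapply(
                object$params[.trainable(object$flags, object$config)],
                length, numeric(1))),
              best_epoch = object$best_epoch, best_val = object$best_val,
              test_metrics = object$test_metrics,
              history = object$history)
  class(out) <- "summary.mortnet"
  out
}

#' @export
print.summary.mortnet <- function(x, ...) {
  cat("Multimodal ICU mortality network (", x$config$variant, ")\n", sep = "")
  cat("  ", x$n, " episodes, ", x$n_pos, " positive; vocabulary ",
      x$vocab_size, "; ", x$n_params, " trainable parameters\n", sep = "")
  cat("  trained ", nrow(x$history), " epoch(s), best at epoch ",
      x$best_epoch, "\n", sep = "")
  if (!is.null(x$test_metrics)) {
    cat(sprintf("  held-out test: AUCPR %.3f | AUCROC %.3f (%d pos / %d neg)\n",
                x$test_metrics$aucpr, x$test_metrics$aucroc,
                x$test_metrics$n_pos, x$test_metrics$n_neg))
  }
  tail_h <- utils::tail(x$history, 3L)
  cat("  last epochs:\n")
  print(tail_h, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.mortnet <- function(object, ...) {
  object$params[.trainable(object$flags, object$config)]
}

#' @export
residuals.mortnet <- function(object, ...) {
  r <- object$labels - object$fitted
  names(r) <- object$stay_ids
  r
}

#' Plot training history
#'
#' Two panels: training loss (total and cross-entropy term) per epoch, and
#' validation AUCPR/AUCROC with the selected epoch marked.
#'
#' @param x A fitted `"mortnet"` model.
#' @param ... Unused.
#' @export
plot.mortnet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
                 main = "training loss")
  graphics::lines(h$epoch, h$ce, lty = 2, col = "grey40")
  graphics::legend("topright", c("total", "CE term"), lty = c(1, 2),
                   col = c("black", "grey40"), bty = "n", cex = 0.8)
  if (any(!is.na(h$val_aucpr))) {
    graphics::plot(h$epoch, h$val_aucpr, type = "l", ylim = c(0, 1),
                   xlab = "epoch", ylab = "metric", main = "validation")
    graphics::lines(h$epoch, h$val_aucroc, lty = 2, col = "steelblue")
    graphics::abline(v = x$best_epoch, lty = 3)
    graphics::legend("bottomright", c("AUCPR", "AUCROC"), lty = c(1, 2),
                     col = c("black", "steelblue"), bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Simulate labels from fitted probabilities
#'
#' Draws Bernoulli outcomes from the model's fitted death probabilities,
#' the parametric-bootstrap analogue of `simulate()` for a binary outcome
#' model.
#'
#' @param object A fitted `"mortnet"` model.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data.frame with `nsim` columns of simulated 0/1 labels, one row
#'   per episode.
#' @export
simulate.mortnet <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted
  out <- as.data.frame(matrix(stats::rbinom(length(p) * nsim, 1L, rep(p, nsim)),
                              ncol = nsim,
                              dimnames = list(object$stay_ids,
                                              paste0("sim_", seq_len(nsim)))))
  out
}
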