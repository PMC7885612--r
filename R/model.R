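#' Model configuration
#'
#' Hyperparameters of the multimodal network and its training loop. The
#' defaults follow the reference setup: LSTM output dimension 256, note
#' length cap 1000, batch size 5, learning rate 1e-4, dropout 0.9 (fraction
#' dropped — aggressive, hence configurable), early-stopping patience 20
#' epochs, at most 100 epochs, batch normalization on the fused vector.
#' Synthetic-scale runs in the examples and tests use much smaller
#' dimensions.
#'
#' @param variant Model variant: `"multi_atten_chronic"` (full model:
#'   fusion + label-aware attention + chronic history notes),
#'   `"multi_atten"` (fusion + attention, window notes only),
#'   `"multi_cn"` (fusion with a plain text CNN), `"lstm_only"`,
#'   `"cn_only"`.
#' @param H LSTM hidden dimension.
#' @param embed_dim Word-embedding dimension.
#' @param P_joint Joint word-label embedding dimension.
#' @param n_filters Number of convolution filters.
#' @param filter_size Convolution filter width.
#' @param att_window Odd neighborhood width of the word-label similarity map.
#' @param L_max Maximum token-sequence length (longer notes truncated,
#'   shorter zero-padded).
#' @param dropout_rate Fraction of fused-vector units dropped during
#'   training.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_rounds Early-stopping patience (epochs without
#'   validation AUCPR improvement).
#' @param batchnorm Apply batch normalization to the fused vector.
#' @param T_hours Temporal window length in hourly bins.
#' @param window_h Note observation window in hours.
#' @param split Train/validation/test fractions (stratified by label).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return Object of class `"mortnet_config"`.
#' @export
model_config <- function(variant = c("multi_atten_chronic", "multi_atten",
                                     "multi_cn", "lstm_only", "cn_only"),
                         H = 256L, embed_dim = 128L, P_joint = 64L,
                         n_filters = 100L, filter_size = 5L, att_window = 3L,
                         L_max = 1000L, dropout_rate = 0.9,
                         learning_rate = 1e-4, batch_size = 5L,
                         max_epochs = 100L, early_stop_rounds = 20L,
                         batchnorm = TRUE, T_hours = 48L, window_h = 48,
                         split = c(0.7, 0.15, 0.15), seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(H >= 1, embed_dim >= 1, P_joint >= 1, n_filters >= 1,
            filter_size >= 1, att_window >= 1, att_window %% 2 == 1,
            L_max >= 1, dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            early_stop_rounds >= 1, T_hours >= 1, window_h > 0,
            length(split) == 3, all(split > 0), abs(sum(split) - 1) < 1e-8)
  structure(list(variant = variant, H = as.integer(H),
                 embed_dim = as.integer(embed_dim),
                 P_joint = as.integer(P_joint),
                 n_filters = as.integer(n_filters),
                 filter_size = as.integer(filter_size),
                 att_window = as.integer(att_window),
                 L_max = as.integer(L_max), dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_rounds = as.integer(early_stop_rounds),
                 batchnorm = isTRUE(batchnorm), T_hours = as.integer(T_hours),
                 window_h = window_h, split = split, seed = as.integer(seed)),
            class = "mortnet_config")
}

variant_flags <- function(cfg) {
  v <- cfg$variant
  list(time = v != "cn_only",
       text = v != "lstm_only",
       attention = v %in% c("multi_atten", "multi_atten_chronic"),
       history = v == "multi_atten_chronic")
}

fused_dim <- function(cfg) {
  fl <- variant_flags(cfg)
  (if (fl$time) cfg$H else 0L) + (if (fl$text) cfg$n_filters else 0L)
}

.n_labels <- 2L  # binary mortality task: one-hot over {survive, die}

# parameter initialization; caller is responsible for seeding the RNG
init_params <- function(cfg, vocab_size) {
  E <- cfg$embed_dim; P <- cfg$P_joint; O <- .n_labels
  Fn <- cfg$n_filters; s <- cfg$filter_size; w <- cfg$att_window
  Z <- fused_dim(cfg)
  unif <- function(nr, nc) {
    r <- 1 / sqrt(nr)
    matrix(stats::runif(nr * nc, -r, r), nr, nc)
  }
  p <- list(
    emb = matrix(stats::rnorm(vocab_size * E, 0, 0.1), vocab_size, E),
    Wv1 = unif(E, P),
    # binary task: start the two label vectors antipodal (plus noise) so the
    # compatibility axis is informative from the first epoch
    lab = {
      u <- stats::rnorm(P)
      u <- u / sqrt(sum(u^2))
      rbind(-u, u) + matrix(stats::rnorm(O * P, 0, 0.1), O, P)
    },
    # identity-like init on the centre window block: initial attention is a
    # monotone readout of raw word-label compatibility, which the
    # classification gradient can then sharpen
    Wa = {
      W <- unif(w * O, O) * 0.1
      ctr <- ((w - 1L) %/% 2L) * O
      W[ctr + seq_len(O), ] <- W[ctr + seq_len(O), ] + diag(O)
      W
    },
    ba = rep(0, O),
    Wq = unif(s * P, Fn),
    bq = rep(0, Fn),
    gamma = rep(1, Z),
    beta = rep(0, Z),
    Wf = unif(Z, 1L),
    bf = 0,
    bn_mean = rep(0, Z),
    bn_var = rep(1, Z)
  )
  lp <- lstm_init(length(feature_names()), cfg$H)
  p$Wx <- lp$Wx; p$Wh <- lp$Wh; p$bl <- lp$b
  p$emb[1L, ] <- 0  # pad embedding pinned at zero
  p
}

.trainable <- function(flags, cfg) {
  nm <- c("Wf", "bf")
  if (cfg$batchnorm) nm <- c(nm, "gamma", "beta")
  if (flags$time) nm <- c(nm, "Wx", "Wh", "bl")
  if (flags$text) nm <- c(nm, "emb", "Wv1", "Wq", "bq")
  if (flags$attention) nm <- c(nm, "lab", "Wa", "ba")
  nm
}

zero_grads <- function(params, names) {
  gr <- new.env(parent = emptyenv())
  for (nm in names) {
    x <- params[[nm]]
    gr[[nm]] <- if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else
      numeric(length(x))
  }
  gr
}

#' Fuse embeddings and predict mortality probability
#'
#' Concatenates the temporal embedding and the text feature according to the
#' model variant (`lstm_only` ignores the text feature, `cn_only` the
#' temporal embedding), applies the fitted batch-normalization in inference
#' mode, and returns the sigmoid output of the fully connected head. Batch
#' normalization statistics are the running estimates; dropout is inactive
#' (both apply during training only).
#'
#' @param h Temporal embedding (length `H`), or `NULL` for `cn_only`.
#' @param c_text Text feature (length `n_filters`), or `NULL` for
#'   `lstm_only`.
#' @param params Fitted parameter list (e.g. `coef(model)`).
#' @param config The model's [model_config()].
#' @return List with `y_hat` (probability) and `z` (fused vector).
#' @export
fuse_and_predict <- function(h, c_text, params, config) {
  fl <- variant_flags(config)
  z <- numeric(0)
  if (fl$time) {
    if (length(h) != config$H) {
      stop("fuse_and_predict: expected temporal embedding of length ",
           config$H, ", got ", length(h))
    }
    z <- c(z, h)
  }
  if (fl$text) {
    if (length(c_text) != config$n_filters) {
      stop("fuse_and_predict: expected text feature of length ",
           config$n_filters, ", got ", length(c_text))
    }
    z <- c(z, c_text)
  }
  zb <- if (config$batchnorm) {
    params$gamma * (z - params$bn_mean) / sqrt(params$bn_var + 1e-5) +
      params$beta
  } else z
  logit <- sum(zb * params$Wf) + params$bf
  list(y_hat = sigmoid(logit), z = z)
}

#' Training loss: cross-entropy plus joint-embedding regularizer
#'
#' The total loss is the mean binary cross-entropy of the predicted
#' probabilities against the labels, plus the joint-embedding term: the mean
#' over the two label classes of the binary cross-entropy between the
#' one-hot label component and the sigmoid of the auxiliary label-wise text
#' logit (the label-wise max-pooled attention score), averaged over the
#' batch. Predictions are clamped to `[1e-7, 1 - 1e-7]` before logs.
#'
#' @param y_hat Predicted probabilities (length `B`).
#' @param aux_logits `B` x 2 matrix of auxiliary label logits, or `NULL`
#'   (variants without the attention branch; joint term is then 0).
#' @param labels Binary labels (length `B`).
#' @return List with `total`, `ce_term`, `joint_term`
#'   (`total = ce_term + joint_term`).
#' @export
compute_loss <- function(y_hat, aux_logits, labels) {
  stopifnot(length(y_hat) == length(labels), all(labels %in% c(0, 1)))
  eps <- 1e-7
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  ce <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  joint <- 0
  if (!is.null(aux_logits)) {
    stopifnot(nrow(aux_logits) == length(labels),
              ncol(aux_logits) == .n_labels)
    onehot <- cbind(1 - labels, labels)
    s <- pmin(pmax(sigmoid(aux_logits), eps), 1 - eps)
    joint <- -mean(rowMeans(onehot * log(s) + (1 - onehot) * log(1 - s)))
  }
  list(total = ce + joint, ce_term = ce, joint_term = joint)
}

# ---- batched forward / backward over prepared samples ----

forward_batch <- function(samples, params, cfg, flags, training) {
  B <- length(samples)
  out <- list(B = B)
  z <- NULL
  if (flags$time) {
    Fin <- ncol(samples[[1]]$tmat)
    Xarr <- array(0, dim = c(B, cfg$T_hours, Fin))
    for (i in seq_len(B)) Xarr[i, , ] <- samples[[i]]$tmat
    lp <- list(Wx = params$Wx, Wh = params$Wh, b = params$bl, H = cfg$H)
    lf <- lstm_forward_batch(Xarr, lp)
    out$lstm_cache <- lf$cache
    z <- lf$h
  }
  if (flags$text) {
    Cmat <- matrix(0, B, cfg$n_filters)
    aux <- if (flags$attention) matrix(0, B, .n_labels) else NULL
    tcaches <- vector("list", B)
    alphas <- vector("list", B)
    for (i in seq_len(B)) {
      tf <- text_branch_forward(samples[[i]]$ids, samples[[i]]$n_c, params,
                                cfg, flags$attention)
      Cmat[i, ] <- tf$c
      if (flags$attention && !is.null(tf$m_k)) aux[i, ] <- tf$m_k
      tcaches[[i]] <- tf$cache
      alphas[[i]] <- tf$alpha
    }
    out$text_caches <- tcaches
    out$alphas <- alphas
    out$aux <- aux
    z <- if (is.null(z)) Cmat else cbind(z, Cmat)
  }
  out$z <- z
  if (cfg$batchnorm) {
    if (training) {
      mu <- colMeans(z)
      va <- colMeans(sweep(z, 2, mu)^2)
      out$bn_mu <- mu; out$bn_va <- va
      xhat <- sweep(sweep(z, 2, mu), 2, sqrt(va + 1e-5), "/")
    } else {
      xhat <- sweep(sweep(z, 2, params$bn_mean), 2,
                    sqrt(params$bn_var + 1e-5), "/")
    }
    out$xhat <- xhat
    zb <- sweep(sweep(xhat, 2, params$gamma, "*"), 2, params$beta, "+")
  } else {
    zb <- z
  }
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    mask <- matrix(stats::rbinom(length(zb), 1L, keep), nrow(zb)) / keep
    out$drop_mask <- mask
    zb <- zb * mask
  }
  out$zd <- zb
  logit <- drop(zb %*% params$Wf) + params$bf
  out$y_hat <- sigmoid(logit)
  out
}

backward_batch <- function(fw, samples, labels, params, cfg, flags, gr) {
  B <- fw$B
  dlogit <- matrix((fw$y_hat - labels) / B, ncol = 1)
  gr$Wf <- gr$Wf + crossprod(fw$zd, dlogit)
  gr$bf <- gr$bf + sum(dlogit)
  dzd <- dlogit %*% t(params$Wf)
  if (!is.null(fw$drop_mask)) dzd <- dzd * fw$drop_mask
  if (cfg$batchnorm) {
    gr$gamma <- gr$gamma + colSums(dzd * fw$xhat)
    gr$beta <- gr$beta + colSums(dzd)
    dxhat <- sweep(dzd, 2, params$gamma, "*")
    inv_sd <- 1 / sqrt(fw$bn_va + 1e-5)
    dz <- sweep(dxhat - matrix(colMeans(dxhat), B, ncol(dxhat),
                               byrow = TRUE) -
                  fw$xhat * matrix(colMeans(dxhat * fw$xhat), B,
                                   ncol(dxhat), byrow = TRUE),
                2, inv_sd, "*")
  } else {
    dz <- dzd
  }
  col0 <- 0L
  if (flags$time) {
    dh <- dz[, seq_len(cfg$H), drop = FALSE]
    lp <- list(Wx = params$Wx, Wh = params$Wh, b = params$bl, H = cfg$H)
    lg <- lstm_backward_batch(dh, fw$lstm_cache, lp)
    gr$Wx <- gr$Wx + lg$Wx
    gr$Wh <- gr$Wh + lg$Wh
    gr$bl <- gr$bl + lg$b
    col0 <- cfg$H
  }
  if (flags$text) {
    dC <- dz[, col0 + seq_len(cfg$n_filters), drop = FALSE]
    onehot <- cbind(1 - labels, labels)
    for (i in seq_len(B)) {
      d_mk <- NULL
      if (flags$attention && !isTRUE(fw$text_caches[[i]]$empty)) {
        d_mk <- (sigmoid(fw$aux[i, ]) - onehot[i, ]) / (.n_labels * B)
      }
      text_branch_backward(fw$text_caches[[i]], dC[i, ], d_mk, params, cfg,
                           gr)
    }
  }
  invisible(NULL)
}

adam_init <- function(params, names) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names) {
    x <- params[[nm]]
    st$m[[nm]] <- if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else
      numeric(length(x))
    st$v[[nm]] <- st$m[[nm]]
  }
  st
}

adam_step <- function(params, gr, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (nm in names(st$m)) {
    g <- gr[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  params$emb[1L, ] <- 0  # keep pad embedding at zero
  list(params = params, state = st)
}

# ---- sample preparation shared by fit and predict ----

prepare_samples <- function(episodes, cfg, flags, stats = NULL,
                            vocab = NULL) {
  n <- length(episodes)
  bins <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- episodes[[i]]$events
    ev <- ev[ev$time >= 0 & ev$time < cfg$T_hours, , drop = FALSE]
    bins[[i]] <- bin_hourly(ev, cfg$T_hours)
  }
  seqs <- NULL
  if (flags$text) {
    seqs <- vector("list", n)
    for (i in seq_len(n)) {
      e <- episodes[[i]]
      bundle <- select_notes(e, cfg$window_h,
                             chronic = isTRUE(e$chronic) && flags$history)
      seqs[[i]] <- assemble_bundle_text(bundle, cfg$L_max)
    }
  }
  list(bins = bins, seqs = seqs)
}

finalize_samples <- function(prep, episodes, cfg, flags, stats, vocab) {
  n <- length(episodes)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tmat <- NULL
    if (flags$time) {
      tmat <- impute_and_scale(prep$bins[[i]], stats)$values
    }
    ids <- NULL; n_c <- 0L; sw <- NULL; sections <- NULL; toks <- NULL
    if (flags$text) {
      sq <- encode_tokens(prep$seqs[[i]], vocab)
      ids <- sq$ids; n_c <- sq$content_length
      sw <- sq$stopword_mask; sections <- sq$sections
      toks <- sq$tokens
    }
    out[[i]] <- list(stay_id = episodes[[i]]$stay_id, tmat = tmat, ids = ids,
                     n_c = n_c, stopword_mask = sw, sections = sections,
                     tokens = toks)
  }
  out
}

predict_samples <- function(samples, params, cfg, flags, batch = 64L) {
  n <- length(samples)
  probs <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    fw <- forward_batch(samples[i:j], params, cfg, flags, training = FALSE)
    probs[i:j] <- fw$y_hat
    i <- j + 1L
  }
  probs
}

#' Fit the multimodal mortality network
#'
#' Fits the selected model variant on labelled ICU episodes: the temporal
#' branch encodes the 48 x 17 hourly grid with an LSTM, the text branch runs
#' the (optionally label-aware) CNN over the assembled note token sequence,
#' and the fused vector feeds a sigmoid head. Training minimises binary
#' cross-entropy plus the joint-embedding regularizer with Adam, under a
#' stratified train/validation/test split, early-stopping on validation
#' AUCPR; the best-validation parameters are kept. All preprocessing
#' statistics (hourly-grid standardization, vocabulary) come from the
#' training split only.
#'
#' @param episodes Labelled episodes ([read_cohort()] or [as_episodes()]);
#'   the cohort inclusion filters ([filter_cohort()]) are applied first.
#' @param config A [model_config()].
#' @param chronic_list Chronic ICD-9 code set used where chronic status
#'   needs re-deriving.
#' @param embeddings Optional pretrained word vectors used to initialize the
#'   embedding table: a path to a word2vec text-format file (see
#'   [read_word2vec()]) or a numeric matrix with words as rownames and
#'   `embed_dim` columns. Vocabulary words absent from it keep their random
#'   initialization; embeddings remain trainable.
#' @param quiet Suppress per-epoch progress messages.
#' @return An object of class `"mortnet"` with components `params`,
#'   `config`, `vocab`, `train_stats`, `history` (per-epoch data.frame),
#'   `split`, `fitted` (probabilities for all episodes), `labels`,
#'   `stay_ids`, `best_epoch`, `test_metrics`.
#' @seealso [predict.mortnet()], [explain()], [evaluate_cohort()]
#' @export
mortnet <- function(episodes, config = model_config(),
                    chronic_list = chronic_code_list(), embeddings = NULL,
                    quiet = TRUE) {
  stopifnot(inherits(config, "mortnet_config"))
  episodes <- filter_cohort(episodes, quiet = TRUE)
  labels <- vapply(episodes, function(e) as.numeric(e$label), numeric(1))
  if (any(is.na(labels))) stop("mortnet: all training episodes need labels")
  n <- length(episodes)
  if (n < 10L) stop("mortnet: need at least 10 episodes after filtering")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  flags <- variant_flags(config)
  # stratified split
  idx_tr <- idx_va <- idx_te <- integer(0)
  for (cl in c(0, 1)) {
    ids <- sample(which(labels == cl))
    n_cl <- length(ids)
    n_tr <- round(config$split[1] * n_cl)
    n_va <- round(config$split[2] * n_cl)
    idx_tr <- c(idx_tr, ids[seq_len(n_tr)])
    idx_va <- c(idx_va, ids[n_tr + seq_len(min(n_va, n_cl - n_tr))])
    idx_te <- c(idx_te, ids[setdiff(seq_len(n_cl), seq_len(n_tr + n_va))])
  }
  if (length(unique(labels[idx_tr])) < 2L) {
    stop("mortnet: training labels are single-class; loss is degenerate")
  }

  prep <- prepare_samples(episodes, config, flags)
  stats <- temporal_stats(prep$bins[idx_tr])
  vocab <- if (flags$text) build_vocab(prep$seqs[idx_tr]) else c("<pad>", "<unk>")
  samples <- finalize_samples(prep, episodes, config, flags, stats, vocab)

  params <- init_params(config, length(vocab))
  if (!is.null(embeddings) && flags$text) {
    params <- apply_pretrained_embeddings(params, vocab, embeddings, config)
  }
  trainable <- .trainable(flags, config)
  adam <- adam_init(params, trainable)
  monitor_ok <- length(unique(labels[idx_va])) == 2L

  best <- list(metric = -Inf, loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  hist <- list()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(idx_tr)
    tot <- ce <- jt <- 0; nb <- 0L
    i <- 1L
    while (i <= length(ord)) {
      j <- min(i + config$batch_size - 1L, length(ord))
      bidx <- ord[i:j]
      fw <- forward_batch(samples[bidx], params, config, flags,
                          training = TRUE)
      ls <- compute_loss(fw$y_hat, fw$aux, labels[bidx])
      if (config$batchnorm) {
        params$bn_mean <- 0.9 * params$bn_mean + 0.1 * fw$bn_mu
        params$bn_var <- 0.9 * params$bn_var + 0.1 * fw$bn_va
      }
      gr <- zero_grads(params, trainable)
      backward_batch(fw, samples[bidx], labels[bidx], params, config, flags,
                     gr)
      upd <- adam_step(params, gr, adam, config$learning_rate)
      params <- upd$params; adam <- upd$state
      tot <- tot + ls$total; ce <- ce + ls$ce_term; jt <- jt + ls$joint_term
      nb <- nb + 1L
      i <- j + 1L
    }
    val_aucpr <- val_aucroc <- NA_real_
    if (monitor_ok) {
      pv <- predict_samples(samples[idx_va], params, config, flags)
      val_aucpr <- aucpr(pv, labels[idx_va])
      val_aucroc <- aucroc(pv, labels[idx_va])
    }
    hist[[epoch]] <- data.frame(epoch = epoch, loss = tot / nb, ce = ce / nb,
                                joint = jt / nb, val_aucpr = val_aucpr,
                                val_aucroc = val_aucroc)
    if (!quiet) {
      message(sprintf("epoch %3d  loss %.4f  val AUCPR %.3f", epoch,
                      tot / nb, val_aucpr))
    }
    metric <- if (monitor_ok) val_aucpr else -(tot / nb)
    # best validation AUCPR wins; ties broken by training loss, so the
    # snapshot keeps refining (attention sharpening) once the metric saturates
    if (metric > best$metric + 1e-6 ||
        (metric >= best$metric - 1e-9 && tot / nb < best$loss - 1e-6)) {
      improved_metric <- metric > best$metric + 1e-6
      best <- list(metric = max(metric, best$metric), loss = tot / nb,
                   params = params, epoch = epoch)
      stall <- if (improved_metric) 0L else stall + 1L
    } else {
      stall <- stall + 1L
    }
    if (stall >= config$early_stop_rounds) break
  }
  params <- best$params
  history <- do.call(rbind, hist)

  fitted <- predict_samples(samples, params, config, flags)
  names(fitted) <- vapply(episodes, `[[`, character(1), "stay_id")
  test_metrics <- NULL
  if (length(idx_te) > 1L && length(unique(labels[idx_te])) == 2L) {
    test_metrics <- metric_report(fitted[idx_te], labels[idx_te])
  }
  structure(list(params = params, config = config, flags = flags,
                 vocab = vocab, train_stats = stats, history = history,
                 split = list(train = idx_tr, val = idx_va, test = idx_te),
                 fitted = fitted, labels = labels,
                 stay_ids = names(fitted), best_epoch = best$epoch,
                 best_val = if (monitor_ok) best$metric else NA_real_,
                 test_metrics = test_metrics, chronic_list = chronic_list),
            class = "mortnet")
}

# overwrite embedding rows for vocabulary words present in a pretrained
# matrix (rownames = words); the pad row stays zero
apply_pretrained_embeddings <- function(params, vocab, pretrained, cfg) {
  if (is.character(pretrained)) pretrained <- read_word2vec(pretrained)
  if (ncol(pretrained) != cfg$embed_dim) {
    stop("pretrained embeddings have dimension ", ncol(pretrained),
         " but embed_dim is ", cfg$embed_dim)
  }
  hit <- match(vocab, rownames(pretrained))
  rows <- which(!is.na(hit) & seq_along(vocab) > 1L)
  if (length(rows) > 0L) {
    params$emb[rows, ] <- pretrained[hit[rows], , drop = FALSE]
  }
  attr(params, "n_pretrained") <- length(rows)
  params
}
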