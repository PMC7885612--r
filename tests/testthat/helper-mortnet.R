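# shared fixtures and independent oracles for the test suite

# small network configuration used throughout the tests: dimensions sized for
# synthetic corpora so a fit takes seconds, not hours
small_config <- function(variant = "multi_atten_chronic", seed = 1,
                         max_epochs = 15L, early_stop_rounds = 6L,
                         dropout_rate = 0.3, L_max = 160L, ...) {
  model_config(variant = variant, H = 24L, embed_dim = 16L, P_joint = 12L,
               n_filters = 12L, filter_size = 5L, att_window = 3L,
               L_max = L_max, dropout_rate = dropout_rate,
               learning_rate = 5e-3, batch_size = 16L,
               max_epochs = max_epochs,
               early_stop_rounds = early_stop_rounds, seed = seed, ...)
}

# a tiny hand-built episode
make_episode <- function(stay_id = "E1", age = 60, chronic = FALSE,
                         events = NULL, notes = list(), label = 0L) {
  if (is.null(events)) {
    events <- data.frame(feature = "heart_rate", time = c(0.5, 49),
                         value = c(80, 82), stringsAsFactors = FALSE)
  }
  list(stay_id = stay_id, age = age, chronic = chronic,
       icd9_codes = character(0), events = events, notes = notes,
       label = label)
}

make_note <- function(chart_time, text, category = "Nursing") {
  list(chart_time = chart_time, category = category, text = text)
}

# ---- independent loop-level oracles ----

# cosine compatibility, elementwise
oracle_cosine <- function(V, L) {
  G <- matrix(0, nrow(V), nrow(L))
  for (i in seq_len(nrow(V))) {
    for (k in seq_len(nrow(L))) {
      na <- sqrt(sum(V[i, ]^2)); nb <- sqrt(sum(L[k, ]^2))
      if (na > 1e-12 && nb > 1e-12) {
        G[i, k] <- sum(V[i, ] * L[k, ]) / (na * nb)
      }
    }
  }
  G
}

# windowed word-label similarity via an explicit sliding-window loop
oracle_similarity <- function(G, W, b, window) {
  L <- nrow(G); O <- ncol(G)
  hw <- (window - 1) %/% 2
  u <- matrix(0, L, O)
  for (i in seq_len(L)) {
    block <- numeric(0)
    for (o in -hw:hw) {
      r <- i + o
      block <- c(block, if (r >= 1 && r <= L) G[r, ] else rep(0, O))
    }
    u[i, ] <- pmax(as.numeric(block %*% W) + b, 0)
  }
  u
}

# attention weights via direct softmax evaluation over content positions
oracle_attention <- function(u, n_c) {
  L <- nrow(u)
  m <- apply(u, 1, max)
  alpha <- numeric(L)
  alpha[seq_len(n_c)] <- exp(m[seq_len(n_c)]) / sum(exp(m[seq_len(n_c)]))
  list(alpha = alpha, m_k = apply(u[seq_len(n_c), , drop = FALSE], 2, max))
}

# 1-D convolution + global max pool via explicit loops
oracle_conv <- function(q, W, b, s, n_pool = nrow(q)) {
  nf <- length(b)
  A <- matrix(0, n_pool, nf)
  P <- ncol(q)
  for (i in seq_len(n_pool)) {
    block <- numeric(0)
    for (o in 0:(s - 1)) {
      r <- i + o
      block <- c(block, if (r <= nrow(q)) q[r, ] else rep(0, P))
    }
    A[i, ] <- pmax(as.numeric(block %*% W) + b, 0)
  }
  apply(A, 2, max)
}

# section importance via grouped summation over spans
oracle_section_importance <- function(alpha, sections, stopword_mask) {
  w <- alpha
  w[stopword_mask] <- 0
  sums <- list()
  for (j in seq_len(nrow(sections))) {
    nm <- sections$name[j]
    span <- seq(sections$start[j], sections$end[j] - 1L)
    sums[[nm]] <- (if (is.null(sums[[nm]])) 0 else sums[[nm]]) + sum(w[span])
  }
  vapply(sums, function(x) x / sum(w), numeric(1))
}

# AUCROC via O(n^2) pairwise comparison with half credit for ties
oracle_aucroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# AUCPR via exhaustive threshold sweep with step-wise interpolation
oracle_aucpr <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_recall <- 0
  area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  area
}

# measure mean attention on planted signal vs noise tokens over test episodes
alpha_signal_ratio <- function(model, episodes, signal_tokens,
                               idx = model$split$test) {
  rs <- rn <- c()
  for (i in idx) {
    if (model$labels[i] != 1) next
    ex <- explain(model, episodes[[i]])
    is_sig <- ex$tokens %in% signal_tokens
    if (!any(is_sig)) next
    keep <- !ex$stopword_mask
    rs <- c(rs, mean(ex$alpha[is_sig]))
    rn <- c(rn, mean(ex$alpha[keep & !is_sig]))
  }
  mean(rs) / mean(rn)
}

# per-section median importance over test episodes
median_section_scores <- function(model, episodes, idx = model$split$test) {
  acc <- list()
  for (i in idx) {
    ex <- explain(model, episodes[[i]])
    for (j in seq_len(nrow(ex$section_scores))) {
      nm <- ex$section_scores$section[j]
      acc[[nm]] <- c(acc[[nm]], ex$section_scores$score[j])
    }
  }
  sort(vapply(acc, stats::median, numeric(1)), decreasing = TRUE)
}
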