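#' Word-label compatibility matrix
#'
#' Measures the compatibility of each word with each mortality label class in
#' the joint embedding space as the cosine similarity of their projected
#' vectors. Rows beyond `content_length` (padding) are zeroed, and a
#' zero-norm vector yields similarity 0.
#'
#' @param word_vectors `L` x `P` matrix of word vectors in the joint space.
#' @param label_vectors `O` x `P` matrix of label vectors in the joint space
#'   (`O = 2` for the binary mortality task).
#' @param content_length Number of non-pad rows (default all rows).
#' @return `L` x `O` matrix `G` of cosine similarities.
#' @export
compatibility <- function(word_vectors, label_vectors,
                          content_length = nrow(word_vectors)) {
  stopifnot(ncol(word_vectors) == ncol(label_vectors))
  L <- nrow(word_vectors); O <- nrow(label_vectors)
  G <- matrix(0, L, O)
  if (content_length > 0L) {
    V <- word_vectors[seq_len(content_length), , drop = FALSE]
    rn <- sqrt(rowSums(V^2))
    ln <- sqrt(rowSums(label_vectors^2))
    denom <- outer(rn, ln)
    dot <- V %*% t(label_vectors)
    ok <- denom > 1e-12
    g <- matrix(0, content_length, O)
    g[ok] <- dot[ok] / denom[ok]
    G[seq_len(content_length), ] <- g
  }
  G
}

#' Windowed word-label similarity scores
#'
#' Applies a learned linear map with ReLU activation to the width-`window`
#' neighborhood of each row of the compatibility matrix `G` (zero-padded at
#' the borders), yielding non-negative per-word, per-label similarity scores
#' `u`.
#'
#' @param G `L` x `O` compatibility matrix.
#' @param weights List with `W` (`(window*O)` x `O`) and `b` (length `O`).
#' @param window Odd neighborhood width (default 3).
#' @return `L` x `O` matrix `u`, elementwise non-negative.
#' @export
word_label_similarity <- function(G, weights, window = 3L) {
  stopifnot(window %% 2L == 1L, window >= 1L)
  hw <- (window - 1L) %/% 2L
  Win <- make_windows(G, offsets = -hw:hw, n_out = nrow(G))
  pre <- Win %*% weights$W +
    matrix(weights$b, nrow(G), length(weights$b), byrow = TRUE)
  pmax(pre, 0)
}

#' Label attention weights over content words
#'
#' Pools the similarity scores `u` over labels (`m_i = max_k u[i,k]`) and
#' softmax-normalizes over content positions only: pad positions receive
#' weight 0 and are excluded from the denominator, so attention does not
#' depend on padding length. Also returns the label-wise pooled scores
#' `m_k = max_i u[i,k]` used as auxiliary text logits by the joint-embedding
#' regularizer.
#'
#' @param u `L` x `O` non-negative score matrix.
#' @param content_length Number of non-pad rows.
#' @return List with `alpha` (length `L`, sums to 1 over content positions),
#'   `m` (per-word pooled score, length `L`) and `m_k` (per-label pooled
#'   score, length `O`).
#' @export
attention_weights <- function(u, content_length = nrow(u)) {
  L <- nrow(u); O <- ncol(u)
  alpha <- numeric(L)
  m <- numeric(L)
  if (content_length == 0L) {
    warning("attention_weights: zero content length; returning all-zero alpha")
    return(list(alpha = alpha, m = m, m_k = numeric(O)))
  }
  uc <- u[seq_len(content_length), , drop = FALSE]
  mi <- apply(uc, 1, max)
  e <- exp(mi - max(mi))
  alpha[seq_len(content_length)] <- e / sum(e)
  m[seq_len(content_length)] <- mi
  list(alpha = alpha, m = m, m_k = apply(uc, 2, max))
}

#' Apply attention weights to word vectors
#'
#' Rescales each word vector by its attention weight (`q_i = alpha_i v_i`),
#' preserving sequence structure for the convolutional layer.
#'
#' @param word_vectors `L` x `P` matrix.
#' @param alpha Length-`L` attention weights.
#' @return `L` x `P` matrix `q`.
#' @export
attend <- function(word_vectors, alpha) {
  stopifnot(nrow(word_vectors) == length(alpha))
  word_vectors * alpha
}

#' Convolutional text features
#'
#' One-dimensional convolution over the attended sequence with ReLU
#' activation and global max-pooling: filter `f`'s response at position `i`
#' covers rows `i .. i+s-1` (zero-padded past the end), and the feature is
#' the maximum response over pooled positions.
#'
#' @param q `L` x `P` attended word-vector sequence.
#' @param conv_weights List with `W` (`(s*P)` x `n_filters`) and `b`
#'   (length `n_filters`).
#' @param filter_size Filter width `s` (default 5).
#' @param n_pool Number of window start positions pooled over (default
#'   `max(nrow(q), 1)`; the fitted model pools over content positions only).
#' @return List with `c` (length `n_filters` feature vector) and `position`
#'   (pooled argmax position per filter).
#' @export
conv_features <- function(q, conv_weights, filter_size = 5L,
                          n_pool = max(nrow(q), 1L)) {
  s <- as.integer(filter_size)
  stopifnot(s >= 1L, n_pool >= 1L)
  Win <- make_windows(q, offsets = 0L:(s - 1L), n_out = n_pool)
  nf <- length(conv_weights$b)
  pre <- Win %*% conv_weights$W + matrix(conv_weights$b, n_pool, nf, byrow = TRUE)
  A <- pmax(pre, 0)
  pos <- max.col(t(A), ties.method = "first")
  list(c = A[cbind(pos, seq_len(nf))], position = pos)
}

# ---- shared sliding-window helpers ----

# Stack shifted copies of M's rows: block j of the output holds rows
# (1:n_out)+offsets[j] of M, zero where the shift falls outside M.
make_windows <- function(M, offsets, n_out) {
  k <- ncol(M); n <- nrow(M)
  out <- matrix(0, n_out, length(offsets) * k)
  for (j in seq_along(offsets)) {
    r <- seq_len(n_out) + offsets[j]
    ok <- r >= 1L & r <= n
    if (any(ok)) {
      out[ok, ((j - 1L) * k + 1L):(j * k)] <- M[r[ok], , drop = FALSE]
    }
  }
  out
}

# Adjoint of make_windows: accumulate window gradients back onto rows of M.
scatter_windows <- function(dWin, offsets, n, k) {
  dM <- matrix(0, n, k)
  for (j in seq_along(offsets)) {
    r <- seq_len(nrow(dWin)) + offsets[j]
    ok <- r >= 1L & r <= n
    if (any(ok)) {
      dM[r[ok], ] <- dM[r[ok], , drop = FALSE] +
        dWin[ok, ((j - 1L) * k + 1L):(j * k), drop = FALSE]
    }
  }
  dM
}

# ---- internal differentiable text branch (per sample) ----

# Forward pass over one encoded token sequence. Returns the text feature c,
# auxiliary label logits m_k, attention weights over content positions, and
# the cache needed by text_branch_backward.
text_branch_forward <- function(ids, n_c, params, cfg, use_attention) {
  Fn <- cfg$n_filters
  if (n_c == 0L) {
    # all-pad input: the conv sees a zero window, so c = ReLU(bq)
    c_out <- pmax(params$bq, 0)
    return(list(c = c_out, m_k = NULL, alpha = numeric(0),
                cache = list(empty = TRUE)))
  }
  idx <- ids[seq_len(n_c)]
  X <- params$emb[idx, , drop = FALSE]
  Vw <- X %*% params$Wv1
  cache <- list(empty = FALSE, idx = idx, X = X, Vw = Vw)
  if (use_attention) {
    lab <- params$lab
    rn <- sqrt(rowSums(Vw^2))
    ln <- sqrt(rowSums(lab^2))
    denom <- outer(rn, ln)
    dot <- Vw %*% t(lab)
    okn <- denom > 1e-12
    G <- matrix(0, n_c, nrow(lab))
    G[okn] <- dot[okn] / denom[okn]
    hw <- (cfg$att_window - 1L) %/% 2L
    offs_g <- -hw:hw
    Wg <- make_windows(G, offs_g, n_c)
    uPre <- Wg %*% params$Wa +
      matrix(params$ba, n_c, length(params$ba), byrow = TRUE)
    u <- pmax(uPre, 0)
    mi <- apply(u, 1, max)
    ai_row <- max.col(u, ties.method = "first")
    e <- exp(mi - max(mi))
    alpha <- e / sum(e)
    ak_col <- max.col(t(u), ties.method = "first")
    m_k <- u[cbind(ak_col, seq_len(ncol(u)))]
    q <- Vw * alpha
    cache <- c(cache, list(G = G, rn = rn, ln = ln, okn = okn, Wg = Wg,
                           uPre = uPre, alpha = alpha, ai_row = ai_row,
                           ak_col = ak_col, offs_g = offs_g))
  } else {
    alpha <- numeric(0)
    m_k <- NULL
    q <- Vw
  }
  offs_q <- 0L:(cfg$filter_size - 1L)
  Wq_win <- make_windows(q, offs_q, n_c)
  Apre <- Wq_win %*% params$Wq + matrix(params$bq, n_c, Fn, byrow = TRUE)
  A <- pmax(Apre, 0)
  pool_pos <- max.col(t(A), ties.method = "first")
  c_out <- A[cbind(pool_pos, seq_len(Fn))]
  cache <- c(cache, list(q = q, Wq_win = Wq_win, Apre = Apre,
                         pool_pos = pool_pos, offs_q = offs_q,
                         n_c = n_c, use_attention = use_attention))
  list(c = c_out, m_k = m_k, alpha = alpha, cache = cache)
}

# Backward pass for one sample; accumulates parameter gradients into the
# environment `gr`. dc: gradient wrt c (length n_filters); d_mk: gradient wrt
# the auxiliary logits m_k (NULL when unused).
text_branch_backward <- function(cache, dc, d_mk, params, cfg, gr) {
  Fn <- cfg$n_filters
  if (isTRUE(cache$empty)) {
    gr$bq <- gr$bq + dc * (params$bq > 0)
    return(invisible(NULL))
  }
  n_c <- cache$n_c
  P <- ncol(cache$Vw)
  dA <- matrix(0, n_c, Fn)
  sel <- cbind(cache$pool_pos, seq_len(Fn))
  dA[sel] <- dc * (cache$Apre[sel] > 0)
  gr$Wq <- gr$Wq + crossprod(cache$Wq_win, dA)
  gr$bq <- gr$bq + colSums(dA)
  dWin <- dA %*% t(params$Wq)
  dq <- scatter_windows(dWin, cache$offs_q, n_c, P)

  if (cache$use_attention) {
    alpha <- cache$alpha
    Vw <- cache$Vw
    dalpha <- rowSums(dq * Vw)
    dVw <- dq * alpha
    dm <- alpha * (dalpha - sum(alpha * dalpha))
    O <- ncol(cache$G)
    du <- matrix(0, n_c, O)
    du[cbind(seq_len(n_c), cache$ai_row)] <-
      du[cbind(seq_len(n_c), cache$ai_row)] + dm
    if (!is.null(d_mk)) {
      du[cbind(cache$ak_col, seq_len(O))] <-
        du[cbind(cache$ak_col, seq_len(O))] + d_mk
    }
    duPre <- du * (cache$uPre > 0)
    gr$Wa <- gr$Wa + crossprod(cache$Wg, duPre)
    gr$ba <- gr$ba + colSums(duPre)
    dWg <- duPre %*% t(params$Wa)
    dG <- scatter_windows(dWg, cache$offs_g, n_c, O)
    # cosine backward
    lab <- params$lab
    G <- cache$G
    denom <- outer(cache$rn, cache$ln)
    Dn <- matrix(0, n_c, O)
    Dn[cache$okn] <- dG[cache$okn] / denom[cache$okn]
    rfac <- rowSums(dG * G) / pmax(cache$rn^2, 1e-12)
    rfac[cache$rn <= 1e-12] <- 0
    lfac <- colSums(dG * G) / pmax(cache$ln^2, 1e-12)
    lfac[cache$ln <= 1e-12] <- 0
    dVw <- dVw + Dn %*% lab - rfac * Vw
    gr$lab <- gr$lab + crossprod(Dn, Vw) - lfac * lab
  } else {
    dVw <- dq
  }

  gr$Wv1 <- gr$Wv1 + crossprod(cache$X, dVw)
  dX <- dVw %*% t(params$Wv1)
  agg <- rowsum(dX, cache$idx)
  rows <- as.integer(rownames(agg))
  keep <- rows > 1L  # pad embedding (row 1) stays pinned at zero
  if (any(keep)) {
    gr$emb[rows[keep], ] <- gr$emb[rows[keep], , drop = FALSE] +
      agg[keep, , drop = FALSE]
  }
  invisible(NULL)
}
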