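#' Bin irregular events into an hourly feature grid
#'
#' Converts a patient's raw timestamped measurements into a `T` x `F` matrix:
#' cell `(t, f)` is the arithmetic mean of all values of feature `f` charted
#' in hour `t` (i.e. with `floor(time) == t - 1`), mirroring the hourly
#' averaging used when several measurements fall in the same hour. Cells with
#' no measurement are `NA` with `mask = FALSE`; imputation is a separate,
#' leakage-safe step ([impute_and_scale()]).
#'
#' @param events Data.frame with columns `feature`, `time` (hours from
#'   admission) and `value`, or a list of such rows.
#' @param T_hours Number of hourly bins (default 48).
#' @param features Feature name order for the columns (default
#'   [feature_names()]).
#' @return Object of class `"temporal_matrix"`: list with `values`
#'   (`T_hours` x `F`, `NA` where unobserved), `mask` (logical grid) and
#'   `features`.
#' @export
bin_hourly <- function(events, T_hours = 48L, features = feature_names()) {
  T_hours <- as.integer(T_hours)
  ev <- as.data.frame(events, stringsAsFactors = FALSE)
  Fn <- length(features)
  values <- matrix(NA_real_, T_hours, Fn, dimnames = list(NULL, features))
  mask <- matrix(FALSE, T_hours, Fn, dimnames = list(NULL, features))
  if (nrow(ev) > 0L) {
    if (any(ev$time < 0)) {
      stop("bin_hourly: negative event times; window anchoring happens upstream")
    }
    ev <- ev[ev$time < T_hours & ev$feature %in% features, , drop = FALSE]
    if (nrow(ev) > 0L) {
      hr <- floor(ev$time) + 1L
      fi <- match(ev$feature, features)
      key <- (fi - 1L) * T_hours + hr
      sums <- rowsum(as.numeric(ev$value), key)
      cnts <- rowsum(rep(1, nrow(ev)), key)
      idx <- as.integer(rownames(sums))
      values[idx] <- sums[, 1] / cnts[, 1]
      mask[idx] <- TRUE
    }
  }
  structure(list(values = values, mask = mask, features = features),
            class = "temporal_matrix")
}

#' Per-feature training statistics
#'
#' Computes per-feature mean and standard deviation over the *observed* cells
#' of a set of (pre-imputation) temporal matrices, plus the clinical normal
#' value used to fill never-observed cells. Must be computed on the training
#' split only, so validation/test standardization never leaks information.
#'
#' @param mats List of `"temporal_matrix"` objects from [bin_hourly()].
#' @param reference Per-feature reference table (default
#'   [feature_reference()]) supplying normal values.
#' @return List with numeric vectors `mean`, `sd`, `normal` (one per
#'   feature) and `features`.
#' @export
temporal_stats <- function(mats, reference = feature_reference()) {
  stopifnot(length(mats) > 0L)
  features <- mats[[1]]$features
  Fn <- length(features)
  mu <- sdv <- numeric(Fn)
  normal <- vapply(features, function(f) {
    if (!is.null(reference[[f]])) as.numeric(reference[[f]]$normal) else 0
  }, numeric(1))
  for (j in seq_len(Fn)) {
    obs <- unlist(lapply(mats, function(m) m$values[m$mask[, j], j]),
                  use.names = FALSE)
    if (length(obs) == 0L) {
      mu[j] <- normal[j]
      sdv[j] <- 1
    } else {
      mu[j] <- mean(obs)
      s <- stats::sd(obs)
      if (!is.finite(s) || s < 1e-8) {
        s <- 1  # zero-variance feature: clamp so z-scores stay finite
      }
      sdv[j] <- s
    }
  }
  list(mean = mu, sd = sdv, normal = normal, features = features)
}

#' Impute and standardize an hourly feature grid
#'
#' Fills unobserved cells by forward-filling the last observed value within
#' the stay (causal: no future leakage), falling back to the per-feature
#' clinical normal value for hours before the first observation, then
#' z-scores every feature using training-split statistics.
#'
#' @param mat A `"temporal_matrix"` from [bin_hourly()].
#' @param train_stats Statistics from [temporal_stats()] computed on the
#'   training split.
#' @return A `"temporal_matrix"` with finite standardized `values`; the
#'   observation `mask` is preserved.
#' @export
impute_and_scale <- function(mat, train_stats) {
  stopifnot(inherits(mat, "temporal_matrix"))
  v <- mat$values
  Tn <- nrow(v); Fn <- ncol(v)
  for (j in seq_len(Fn)) {
    col <- v[, j]
    last <- train_stats$normal[j]
    for (t in seq_len(Tn)) {
      if (is.na(col[t])) col[t] <- last else last <- col[t]
    }
    v[, j] <- (col - train_stats$mean[j]) / train_stats$sd[j]
  }
  structure(list(values = v, mask = mat$mask, features = mat$features),
            class = "temporal_matrix")
}

#' Initialize LSTM parameters
#'
#' Single-layer unidirectional LSTM with gate order input, forget, output,
#' cell-candidate. Weights are drawn uniformly in
#' `[-1/sqrt(H), 1/sqrt(H)]`; the forget-gate bias starts at 1 (standard
#' practice so early training does not erase state).
#'
#' @param input_dim Number of input features per step.
#' @param H Hidden dimension.
#' @return List with `Wx` (`input_dim` x `4H`), `Wh` (`H` x `4H`), `b`
#'   (length `4H`) and `H`.
#' @export
lstm_init <- function(input_dim, H) {
  r <- 1 / sqrt(H)
  p <- list(
    Wx = matrix(stats::runif(input_dim * 4L * H, -r, r), input_dim, 4L * H),
    Wh = matrix(stats::runif(H * 4L * H, -r, r), H, 4L * H),
    b = rep(0, 4L * H),
    H = as.integer(H)
  )
  p$b[(H + 1L):(2L * H)] <- 1
  p
}

#' Encode a temporal matrix with an LSTM
#'
#' Consumes the `T` x `F` grid one hour at a time in chronological order and
#' returns the last hidden state, which serves as the temporal embedding of
#' the stay.
#'
#' @param mat A `"temporal_matrix"` (standardized) or a plain numeric
#'   `T` x `F` matrix.
#' @param params LSTM parameters from [lstm_init()].
#' @return Numeric vector of length `H` (the final hidden state).
#' @export
lstm_encode <- function(mat, params) {
  x <- if (inherits(mat, "temporal_matrix")) mat$values else mat
  stopifnot(is.matrix(x))
  if (any(!is.finite(x))) stop("lstm_encode: non-finite values in input")
  arr <- array(x, dim = c(1L, nrow(x), ncol(x)))
  drop(lstm_forward_batch(arr, params)$h)
}

# ---- internal batched LSTM with cache for backprop ----

# Xarr: B x T x F array. Returns final hidden state (B x H) and step cache.
lstm_forward_batch <- function(Xarr, params) {
  B <- dim(Xarr)[1]; Tn <- dim(Xarr)[2]
  H <- params$H
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- vector("list", Tn)
  bmat <- matrix(params$b, B, 4L * H, byrow = TRUE)
  for (t in seq_len(Tn)) {
    Xt <- matrix(Xarr[, t, ], nrow = B)
    A <- Xt %*% params$Wx + h %*% params$Wh + bmat
    i <- sigmoid(A[, 1:H, drop = FALSE])
    f <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(A[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(A[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    cache[[t]] <- list(Xt = Xt, hprev = h, cprev = cc, i = i, f = f, o = o,
                       g = g, tc = tc)
    cc <- c_new
    h <- o * tc
  }
  list(h = h, cache = cache)
}

# dH: gradient wrt final hidden state (B x H). Returns parameter gradients.
lstm_backward_batch <- function(dH, cache, params) {
  H <- params$H
  Tn <- length(cache)
  dWx <- matrix(0, nrow(params$Wx), ncol(params$Wx))
  dWh <- matrix(0, nrow(params$Wh), ncol(params$Wh))
  db <- numeric(4L * H)
  dh <- dH
  dc_next <- matrix(0, nrow(dH), H)
  for (t in rev(seq_len(Tn))) {
    st <- cache[[t]]
    do_ <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$cprev
    dg <- dc * st$i
    dA <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_ * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    dWx <- dWx + crossprod(st$Xt, dA)
    dWh <- dWh + crossprod(st$hprev, dA)
    db <- db + colSums(dA)
    dh <- dA %*% t(params$Wh)
    dc_next <- dc * st$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
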