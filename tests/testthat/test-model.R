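test_that("analytic gradients match finite differences across all parameters", {
  set.seed(42)
  cfg <- model_config(variant = "multi_atten_chronic", H = 4L,
                      embed_dim = 5L, P_joint = 3L, n_filters = 3L,
                      filter_size = 2L, att_window = 3L, L_max = 9L,
                      dropout_rate = 0, batch_size = 3L, T_hours = 5L,
                      batchnorm = TRUE)
  flags <- mortnet:::variant_flags(cfg)
  V <- 8L
  params <- mortnet:::init_params(cfg, V)
  mk <- function(n_c) list(
    ids = c(sample(2:V, n_c, replace = TRUE), rep(1L, cfg$L_max - n_c)),
    n_c = n_c, tmat = matrix(rnorm(cfg$T_hours * 17), cfg$T_hours, 17))
  samples <- list(mk(6L), mk(9L), mk(3L))
  labels <- c(1, 0, 1)
  loss_fn <- function(p) {
    fw <- mortnet:::forward_batch(samples, p, cfg, flags, training = TRUE)
    mortnet:::compute_loss(fw$y_hat, fw$aux, labels)$total
  }
  trainable <- mortnet:::.trainable(flags, cfg)
  fw <- mortnet:::forward_batch(samples, params, cfg, flags, training = TRUE)
  gr <- mortnet:::zero_grads(params, trainable)
  mortnet:::backward_batch(fw, samples, labels, params, cfg, flags, gr)
  h <- 1e-5
  for (nm in trainable) {
    idx <- seq_along(params[[nm]])
    if (length(idx) > 25L) idx <- sort(sample(idx, 25L))
    for (k in idx) {
      p1 <- params; p1[[nm]][k] <- p1[[nm]][k] + h
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] - h
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * h)
      expect_equal(gr[[nm]][k], num, tolerance = 1e-4,
                   label = paste("grad", nm, k))
    }
  }
})

test_that("loss decomposes exactly into CE and joint terms", {
  set.seed(61)
  y_hat <- runif(6)
  aux <- matrix(rnorm(12), 6, 2)
  labels <- rbinom(6, 1, 0.5)
  ls <- compute_loss(y_hat, aux, labels)
  expect_equal(ls$total, ls$ce_term + ls$joint_term, tolerance = 1e-12)
  expect_gte(ls$ce_term, 0)
  expect_gte(ls$joint_term, 0)
  # closed-form checks
  expect_equal(compute_loss(0.5, NULL, 1)$ce_term, log(2), tolerance = 1e-9)
  expect_lt(compute_loss(c(1, 0), NULL, c(1, 0))$ce_term, 1e-5)
  near <- compute_loss(0.7, matrix(c(-30, 30), 1), 1)
  expect_lt(near$joint_term, 1e-6)
})

test_that("fusion head respects variants and dimension contracts", {
  cfg <- model_config(variant = "multi_atten_chronic", H = 256L,
                      n_filters = 100L, batchnorm = FALSE)
  set.seed(62)
  params <- list(Wf = matrix(0, 356, 1), bf = 0)
  out <- fuse_and_predict(rnorm(256), rnorm(100), params, cfg)
  expect_equal(out$y_hat, 0.5)
  expect_length(out$z, 356L)
  expect_error(fuse_and_predict(rnorm(10), rnorm(100), params, cfg), "256")
  cfg_l <- model_config(variant = "lstm_only", H = 8L, batchnorm = FALSE)
  out_l <- fuse_and_predict(rnorm(8), NULL, list(Wf = matrix(1, 8, 1),
                                                 bf = 0), cfg_l)
  expect_length(out_l$z, 8L)
})

test_that("training reduces the loss and is seed-deterministic", {
  spec <- cohort_spec(60, prevalence = 0.4, signal_strength = 1,
                      effect_size = 2, seed = 63)
  eps <- as_episodes(generate_cohort(spec))
  cfg <- small_config(max_epochs = 12L, early_stop_rounds = 12L)
  m1 <- mortnet(eps, cfg)
  expect_lt(m1$history$loss[nrow(m1$history)], m1$history$loss[1])
  m2 <- mortnet(eps, cfg)
  expect_equal(m1$history, m2$history, tolerance = 1e-12)
  expect_equal(m1$fitted, m2$fitted, tolerance = 1e-12)
})

test_that("any variant can overfit a tiny sample", {
  spec <- cohort_spec(14, prevalence = 0.5, signal_strength = 1,
                      effect_size = 2, seed = 64)
  eps <- as_episodes(generate_cohort(spec))
  cfg <- small_config(variant = "multi_cn", max_epochs = 200L,
                      early_stop_rounds = 200L, dropout_rate = 0,
                      split = c(0.72, 0.14, 0.14))
  m <- mortnet(eps, cfg)
  expect_lt(min(m$history$loss), 0.05)
})

test_that("the temporal-only variant cannot read note content", {
  spec <- cohort_spec(80, prevalence = 0.4, signal_strength = 1,
                      effect_size = 0, seed = 65)  # text signal only
  eps <- as_episodes(generate_cohort(spec))
  cfg <- small_config(variant = "lstm_only", max_epochs = 8L,
                      early_stop_rounds = 8L)
  m <- mortnet(eps, cfg)
  test_idx <- c(m$split$val, m$split$test)
  auc <- aucroc(m$fitted[test_idx], m$labels[test_idx])
  expect_lt(abs(auc - 0.5), 0.2)
  # perturbing note text changes nothing
  eps2 <- lapply(eps, function(e) {
    e$notes <- list(make_note(1, "CHIEF COMPLAINT: totally different."))
    e
  })
  expect_equal(unname(predict(m, eps2)), unname(predict(m, eps)),
               tolerance = 1e-12)
})

test_that("prediction never touches labels and preserves order", {
  spec <- cohort_spec(50, prevalence = 0.4, signal_strength = 1,
                      effect_size = 1.5, seed = 66)
  eps <- as_episodes(generate_cohort(spec))
  m <- mortnet(eps, small_config(max_epochs = 6L))
  p1 <- predict(m, eps)
  scrambled <- lapply(eps, function(e) { e$label <- sample(0:1, 1); e })
  expect_identical(predict(m, scrambled), p1)
  expect_equal(names(p1), vapply(eps, `[[`, character(1), "stay_id"))
  # eval-mode forward is deterministic
  expect_identical(predict(m, eps), p1)
  # an empty-notes patient still gets a valid probability
  bare <- make_episode("NONOTE", notes = list())
  pb <- predict(m, list(bare))
  expect_true(is.finite(pb) && pb > 0 && pb < 1)
})

test_that("single-class training labels are rejected", {
  eps <- as_episodes(generate_cohort(cohort_spec(20, prevalence = 0,
                                                 seed = 67)))
  expect_error(mortnet(eps, small_config(max_epochs = 2L)), "single-class")
})

test_that("model methods expose the usual interface", {
  spec <- cohort_spec(50, prevalence = 0.4, signal_strength = 1,
                      effect_size = 1.5, seed = 68)
  eps <- as_episodes(generate_cohort(spec))
  m <- mortnet(eps, small_config(max_epochs = 4L))
  expect_output(print(m), "variant")
  expect_output(print(summary(m)), "trainable parameters")
  expect_true(all(c("Wf", "emb") %in% names(coef(m))))
  r <- residuals(m)
  expect_equal(unname(r), m$labels - unname(m$fitted))
  sims <- simulate(m, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(50L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
  # checkpoint round trip
  d <- tempfile()
  save_model(m, d)
  m2 <- load_model(d)
  expect_equal(unname(predict(m2, eps[1:5])), unname(predict(m, eps[1:5])),
               tolerance = 1e-12)
})
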