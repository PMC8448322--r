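test_that("softmax outputs are probabilities, seeded and deterministic", {
  cfg <- tiny_model_config()
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  seqs <- replicate(5, random_seq(21))
  s1 <- score_batch(m1, seqs)
  s2 <- score_batch(m2, seqs)
  expect_identical(s1, s2)           # same seed, same parameters
  expect_true(all(s1 >= 0 & s1 <= 1))
  probs <- regscan:::scorer_probs(m1, regscan:::encode_seqs(seqs))
  expect_equal(colSums(probs), rep(1, 5), tolerance = 1e-6)
  # repeated scoring is bitwise stable
  expect_identical(s1, score_batch(m1, seqs))

  m3 <- build_model(tiny_model_config(seed = 43L))
  expect_false(identical(s1, score_batch(m3, seqs)))

  expect_error(score_batch(m1, replicate(2, random_seq(19))),
               "does not match")
  expect_error(build_model(model_config(window_len = 21L, kernel = 31L)),
               "wider")
})

test_that("scoring is batch-size invariant and tolerates all-N windows", {
  cfg <- tiny_model_config(L = 33L)
  m <- build_model(cfg)
  seqs <- replicate(7, random_seq(33))
  batched <- score_batch(m, seqs)
  single <- vapply(seqs, function(s) score_batch(m, s), numeric(1),
                   USE.NAMES = FALSE)
  expect_equal(batched, single, tolerance = 1e-5)
  dup <- score_batch(m, c(seqs[1], seqs[1]))
  expect_equal(dup[1], dup[2])
  expect_true(is.finite(score_batch(m, strrep("N", 33))))
  expect_length(score_batch(m, character()), 0)
})

test_that("strand calls take the softmax argmax with fixed tie order", {
  cfg <- tiny_model_config(n_outputs = 3L)
  m <- build_model(cfg, role = "strand")
  calls <- strand_call(m, replicate(4, random_seq(21)))
  expect_true(all(calls %in% c("+", "-", ".")))
  # argmax and the +, -, . tie order
  probs <- matrix(c(0.7, 0.2, 0.1,
                    0.4, 0.4, 0.2,
                    0.1, 0.2, 0.7), 3)
  expect_identical(c("+", "-", ".")[apply(probs, 2, which.max)],
                   c("+", "+", "."))
  m2 <- build_model(tiny_model_config())
  expect_error(strand_call(m2, random_seq(21)), "3-output")
  expect_error(build_model(tiny_model_config(), role = "strand"),
               "n_outputs = 3")
})

test_that("adjust_score equals -log(1 - s) and rejects s = 1", {
  expect_equal(adjust_score(0), 0)
  expect_equal(adjust_score(0.5), log(2), tolerance = 1e-12)
  s <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(abs(adjust_score(s) + log(1 - s)) < 1e-12))
  expect_true(all(diff(adjust_score(seq(0, 0.99, 0.01))) > 0))
  expect_error(adjust_score(1), "\\[0, 1\\)")
})

test_that("checkpoints round-trip parameters and configuration", {
  m <- build_model(tiny_model_config())
  path <- tempfile(fileext = ".rds")
  save_scorer(m, path)
  m2 <- load_scorer(path)
  seqs <- replicate(3, random_seq(21))
  expect_identical(score_batch(m, seqs), score_batch(m2, seqs))
  echo <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(echo$window_len, 21)
  expect_equal(echo$role, "scan")
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("regscan")
  cfg <- tiny_model_config()
  geom <- ns$nn_build(cfg)
  params <- ns$nn_init_params(cfg, geom)
  set.seed(7)
  X <- ns$encode_seqs(replicate(5, random_seq(21)))
  y <- sample(1:2, 5, replace = TRUE)
  set.seed(1)
  fwd <- ns$nn_forward(geom, params, cfg, X, train = TRUE)
  grads <- ns$nn_backward(geom, params, cfg, fwd, X, y)
  loss_at <- function(p) {
    set.seed(1)
    ns$nn_loss(ns$nn_forward(geom, p, cfg, X, train = TRUE)$probs, y)
  }
  eps <- 1e-5
  set.seed(11)
  for (nm in c("W1.1", "g1.1", "be1.1", "W2.2", "Wp.1", "Wd", "bd")) {
    for (ii in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
      pm <- params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      ana <- grads[[nm]][ii]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("folded-batchnorm inference matches the training-graph forward", {
  ns <- asNamespace("regscan")
  cfg <- model_config(window_len = 101L, pool = c(4L, 2L, 2L), seed = 5)
  geom <- ns$nn_build(cfg)
  params <- ns$nn_init_params(cfg, geom)
  # push batch-norm running stats away from init so folding is non-trivial
  set.seed(3)
  Xt <- ns$encode_seqs(replicate(16, random_seq(101)))
  for (i in 1:3) {
    fwd <- ns$nn_forward(geom, params, cfg, Xt, train = TRUE)
    params <- fwd$params
  }
  X <- ns$encode_seqs(replicate(4, random_seq(101)))
  slow <- ns$nn_forward(geom, params, cfg, X, train = FALSE)$probs
  fast <- ns$nn_predict(geom, params, cfg, X)
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("a desk-scale model separates planted positives from random negatives", {
  # capacity invariant: balanced synthetic task, validation accuracy >= 0.95
  set.seed(11)
  L <- 301
  mk_pos <- function() {
    ch <- sample(c("A", "C", "G", "T"), L, TRUE,
                 prob = c(0.27, 0.23, 0.23, 0.27))
    ch[120:127] <- strsplit("TATAAAAG", "")[[1]]
    ch[148:153] <- strsplit("GGCCAA", "")[[1]]
    paste(ch, collapse = "")
  }
  n <- 500
  pos <- replicate(n, mk_pos())
  neg <- replicate(n, random_seq(L))
  X <- regscan:::encode_seqs(c(pos, neg))
  y <- c(rep(1L, n), rep(2L, n))
  tr <- c(1:450, n + (1:450))
  va <- setdiff(seq_len(2 * n), tr)
  cfg <- model_config(window_len = L, seed = 3)
  ns <- asNamespace("regscan")
  geom <- ns$nn_build(cfg)
  fit <- ns$nn_fit(geom, ns$nn_init_params(cfg, geom), cfg,
                   function(e) list(X = X[, tr], y = y[tr]),
                   list(X = X[, va], y = y[va]),
                   max_epochs = 6, patience = 3, seed = 5)
  best <- fit$history$val_acc[fit$history$epoch == fit$best_epoch]
  expect_gte(max(fit$history$val_acc), 0.95)
})
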