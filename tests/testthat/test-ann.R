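test_that("weight initialization is seeded uniform on +/- halfwidth", {
  cfg <- ann_config(n_input = 10, n_hidden = 50, n_output = 20, seed = 7)
  m1 <- initialize_model(cfg)
  m2 <- initialize_model(cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)

  cfg0 <- ann_config(n_input = 5, n_hidden = 5, n_output = 5,
                     weight_init_halfwidth = 0)
  expect_true(all(initialize_model(cfg0)$W1 == 0))

  big <- ann_config(n_input = 100, n_hidden = 100, n_output = 10, seed = 3)
  w <- c(initialize_model(big)$W1)  # 10^4 draws
  expect_gte(min(w), -0.1)
  expect_lte(max(w), 0.1)
  se <- 0.1 / sqrt(3) / sqrt(length(w))
  expect_lt(abs(mean(w)), 3 * se)
})

test_that("external phoneme input ramps from zero, monotone in frequency", {
  cfg <- ann_config()
  expect_equal(external_phoneme_input(c(1, 1000), 0, cfg), c(0, 0))
  cfg0 <- ann_config(ramp_gain = 0)
  expect_equal(external_phoneme_input(500, 200, cfg0), 0)
  withr::with_seed(5, {
    for (i in 1:20) {
      f <- sort(runif(2, 0.1, 1e5))
      ep <- sample(1:400, 1)
      expect_gte(external_phoneme_input(f[2], ep, cfg),
                 external_phoneme_input(f[1], ep, cfg))
      expect_gte(external_phoneme_input(f[1], ep + 50, cfg),
                 external_phoneme_input(f[1], ep, cfg))
    }
  })
  expect_error(external_phoneme_input(-1, 10, cfg), "positive")
})

test_that("forward pass matches an independent recomputation", {
  cfg <- ann_config(n_input = 3, n_hidden = 2, n_output = 2,
                    weight_init_halfwidth = 0)
  m <- initialize_model(cfg)
  out <- ann_forward(m, c(1, 0, 1))
  expect_equal(out$hidden, rep(0.5, 2))
  expect_equal(out$output, rep(0.5, 2))
  expect_equal(out$rounded, c(1L, 1L))  # 0.5 ties round up

  # large external input saturates, monotonically in its magnitude
  o1 <- ann_forward(m, c(1, 0, 1), external = c(3, 0))$output[1]
  o2 <- ann_forward(m, c(1, 0, 1), external = c(30, 0))$output[1]
  expect_gt(o2, o1)
  expect_gt(o2, 0.999)

  m$W1 <- matrix(rnorm(6), 2, 3); m$b1 <- rnorm(2)
  m$W2 <- matrix(rnorm(4), 2, 2); m$b2 <- rnorm(2)
  x <- c(1, 0, 1); ext <- c(0.3, 0)
  out <- ann_forward(m, x, ext)
  h_or <- y_or <- numeric(2)
  for (j in 1:2) h_or[j] <- 1 / (1 + exp(-(sum(m$W1[j, ] * x) + m$b1[j])))
  for (k in 1:2) y_or[k] <- 1 / (1 + exp(-(sum(m$W2[k, ] * h_or) + m$b2[k] + ext[k])))
  expect_equal(out$hidden, h_or, tolerance = 1e-12)
  expect_equal(out$output, y_or, tolerance = 1e-12)

  expect_error(ann_forward(m, c(1, 0)), "n_input")
})

test_that("analytic gradients match central finite differences", {
  cfg <- ann_config(n_input = 4, n_hidden = 3, n_output = 3, seed = 11,
                    weight_init_halfwidth = 0.5)
  m <- initialize_model(cfg)
  eps <- 1e-6
  withr::with_seed(2, {
    for (trial in 1:5) {
      x <- rbinom(4, 1, 0.5)
      t <- rbinom(3, 1, 0.5)
      ext <- runif(1, 0, 1)
      g <- ann_gradients(m, x, t, ext)
      for (par in c("W1", "b1", "W2", "b2")) {
        ga <- g[[paste0("g", par)]]
        gn <- if (is.null(dim(ga))) numeric(length(ga)) else array(0, dim(ga))
        for (i in seq_along(m[[par]])) {
          mp <- m; mp[[par]][i] <- mp[[par]][i] + eps
          mm <- m; mm[[par]][i] <- mm[[par]][i] - eps
          gn[i] <- (ann_loss(mp, x, t, ext) - ann_loss(mm, x, t, ext)) / (2 * eps)
        }
        denom <- pmax(abs(gn), 1e-8)
        expect_lt(max(abs(c(ga) - c(gn)) / c(denom)), 1e-5)
      }
      # perturb the model between trials
      m$W1 <- m$W1 + matrix(rnorm(12, sd = 0.2), 3, 4)
      m$W2 <- m$W2 + matrix(rnorm(9, sd = 0.2), 3, 3)
    }
  })
})

test_that("training is reproducible, inert at lr 0, and learns a toy lexicon", {
  lex <- learnable_lex(20)
  X <- encode_lexicon(lex, "orthography")
  P <- encode_lexicon(lex, "phonology")
  f <- frequencies(lex)

  cfg0 <- ann_config(n_input = ncol(X), n_output = ncol(P), epochs = 3,
                     learning_rate = 0, seed = 5)
  m0 <- initialize_model(cfg0)
  fit0 <- ann_train(m0, X, P, f)
  expect_equal(fit0$model$W1, m0$W1)
  expect_equal(fit0$model$W2, m0$W2)

  cfg <- ann_config(n_input = ncol(X), n_output = ncol(P), epochs = 400,
                    seed = 5)
  fit <- ann_train(initialize_model(cfg), X, P, f)
  expect_equal(nrow(fit$history), 400L)
  expect_equal(fit$history$accuracy[400], 1)
  # bit-for-bit reproducibility
  fit2 <- ann_train(initialize_model(cfg), X, P, f)
  expect_identical(fit$model$W1, fit2$model$W1)
})

test_that("training accuracy is nondecreasing on average over seeds", {
  lex <- learnable_lex(20)
  X <- encode_lexicon(lex, "orthography")
  P <- encode_lexicon(lex, "phonology")
  f <- frequencies(lex)
  acc <- sapply(1:10, function(s) {
    cfg <- ann_config(n_input = ncol(X), n_output = ncol(P), epochs = 120,
                      seed = s)
    ann_train(initialize_model(cfg), X, P, f)$history$accuracy[c(10, 60, 120)]
  })
  m <- rowMeans(acc)
  expect_lte(m[1], m[2])
  expect_lte(m[2], m[3])
})

test_that("hidden-layer RDMs are stable across instantiations", {
  lex <- learnable_lex(20)
  X <- encode_lexicon(lex, "orthography")
  P <- encode_lexicon(lex, "phonology")
  f <- frequencies(lex)
  rdms <- lapply(1:6, function(s) {
    cfg <- ann_config(n_input = ncol(X), n_output = ncol(P), epochs = 150,
                      seed = 50 + s)
    fit <- ann_train(initialize_model(cfg), X, P, f)
    compute_rdm(zscore_features(hidden_representations(fit$model, X, P, f)))
  })
  for (i in 1:5) for (j in (i + 1):6)
    expect_gt(rdm_spearman(rdms[[i]], rdms[[j]])$rho, 0)
})

test_that("hidden representations equal per-word forward passes", {
  lex <- toy_lex()
  X <- encode_lexicon(lex, "orthography")
  P <- encode_lexicon(lex, "phonology")
  f <- frequencies(lex)
  cfg <- ann_config(n_input = ncol(X), n_output = ncol(P), epochs = 5, seed = 2)
  fit <- ann_train(initialize_model(cfg), X, P, f)
  H <- hidden_representations(fit$model, X, P, f)
  for (i in seq_len(nrow(X))) {
    ext <- external_phoneme_input(f[i], cfg$epochs, cfg)
    expect_equal(unname(H[i, ]),
                 unname(ann_forward(fit$model, X[i, ], ext * P[i, ])$hidden),
                 tolerance = 1e-12)
  }
  # identical stimuli give identical rows; untrained zero net gives 0.5
  expect_equal(H[1, ], H[1, ])
  m0 <- initialize_model(ann_config(n_input = ncol(X), n_output = ncol(P),
                                    weight_init_halfwidth = 0))
  H0 <- hidden_representations(m0, X, P, f)
  expect_true(all(H0 == 0.5))
})

test_that("word and nonword scoring follow their criteria", {
  expect_true(score_word(c(1, 0, 1), c(1, 0, 1)))
  expect_false(score_word(c(1, 0, 1), c(1, 1, 1)))
  expect_true(score_word(c(0, 0), c(0, 0)))
  expect_error(score_word(c(1, 0), c(1, 0, 0)), "mismatch")

  expect_equal(jaccard_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(jaccard_similarity(c(1, 1), c(1, 1)), 1)
  expect_equal(jaccard_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(jaccard_similarity(c(0, 0), c(0, 0)), 1)

  pool <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(0, 0, 1, 1))
  # output equals an acceptable vector: correct under both criteria
  expect_true(score_nonword(c(1, 1, 0, 0), 1L, pool, "jaccard"))
  expect_true(score_nonword(c(1, 1, 0, 0), 1L, pool, "exact"))
  # equidistant between acceptable and foreign: tie goes to incorrect
  expect_false(score_nonword(c(1, 1, 1, 0), 1L, pool, "jaccard"))
  expect_false(score_nonword(c(0, 1, 1, 0), 1L, pool, "exact"))
  expect_error(score_nonword(c(1, 0, 0, 0), integer(), pool), "empty")
})

test_that("jaccard-criterion decisions match brute-force nearest-neighbor", {
  withr::with_seed(31, {
    for (trial in 1:100) {
      pool <- matrix(rbinom(6 * 10, 1, 0.4), 6, 10)
      acc <- sort(sample(6, sample(1:3, 1)))
      out <- rbinom(10, 1, 0.4)
      got <- score_nonword(out, acc, pool, "jaccard")
      sims <- apply(pool, 1, jaccard_similarity, a = out)
      best <- max(sims)
      oracle <- any(sims[acc] == best) && all(sims[-acc] < best)
      if (length(acc) == 6) oracle <- TRUE
      expect_identical(got, oracle)
    }
  })
})
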