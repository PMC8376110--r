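# Ensemble construction, motif-initialized filters, training contracts,
# prediction, evaluation metrics, and persistence.

test_that("build_ensemble creates members with the configured shapes", {
  cfg <- model_config(window_length = 60, n_classes = 3, ensemble_size = 3,
                      first_layer = list(n_filters = 6, width = 8,
                                         init = "random"),
                      member_second_layers = list(c(4, 3), c(6, 5), c(8, 7)),
                      epochs = 2, seed = 1)
  ens <- build_ensemble(cfg)
  expect_length(ens$members, 3)
  expect_equal(vapply(ens$members, `[[`, integer(1), "F2"), c(4L, 6L, 8L))
  expect_equal(vapply(ens$members, `[[`, integer(1), "w2"), c(3L, 5L, 7L))
  # untrained predictions are strictly inside (0, 1)
  p <- predict(ens, random_dna(5, 60, seed = 2))
  expect_true(all(p > 0 & p < 1))
  expect_equal(dim(p), c(5L, 3L))
})

test_that("config invariants are enforced", {
  expect_error(model_config(ensemble_size = 2,
                            member_second_layers = list(c(8, 5))),
               "must equal")
  expect_error(model_config(window_length = 10,
                            first_layer = list(n_filters = 4, width = 17,
                                               init = "random"),
                            ensemble_size = 1,
                            member_second_layers = list(c(4, 3))),
               "width")
})

test_that("motif-initialized filters equal the centered log-odds matrix", {
  p <- random_pwm(5, seed = 3, name = "m")
  cfg <- model_config(window_length = 30, n_classes = 2, ensemble_size = 1,
                      first_layer = list(n_filters = 1, width = 9,
                                         init = "motif_db"),
                      member_second_layers = list(c(4, 3)), seed = 1)
  ens <- build_ensemble(cfg, list(p))
  W1 <- ens$members[[1]]$params$W1
  lo <- log2((p$matrix + 0.01) / 0.25)
  offset <- floor((9 - 5) / 2)  # centered within the filter
  for (j in 1:5) {
    expect_equal(unname(W1[(offset + j - 1) * 4 + 1:4, 1]), unname(lo[j, ]))
  }
  # zero padding outside the motif span
  expect_equal(unname(W1[1:(offset * 4), 1]), rep(0, offset * 4))
})

test_that("motif filter is maximally activated by its consensus (exhaustive)", {
  p <- random_pwm(4, seed = 8, name = "m", sharpness = 0.7)
  cfg <- model_config(window_length = 20, n_classes = 2, ensemble_size = 1,
                      first_layer = list(n_filters = 1, width = 4,
                                         init = "motif_db"),
                      member_second_layers = list(c(2, 2)), seed = 1)
  ens <- build_ensemble(cfg, list(p))
  W1 <- ens$members[[1]]$params$W1[, 1]
  probes <- all_kmers(4)
  act <- vapply(probes, function(k) sum(one_hot(k) * matrix(W1, 4, 4,
                                                            byrow = TRUE)),
                numeric(1))
  expect_equal(names(which.max(act)), consensus(p)$template)
})

test_that("training improves validation loss and is seed-deterministic", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  log1 <- fx$ensemble$training_log
  for (m in unique(log1$member)) {
    member_log <- log1[log1$member == m, ]
    expect_lt(member_log$validation_loss[nrow(member_log)],
              member_log$validation_loss[1])
  }
  # identical config + seed: identical training log
  ens2 <- build_ensemble(fx_config(seed = 101, epochs = 3),
                         list(fx_motifA(), fx_motifB()),
                         class_names = c("class1", "class2"))
  ens2 <- train_ensemble(ens2, fx$split)
  expect_equal(ens2$training_log, log1)
})

test_that("early stopping with constant validation loss obeys patience", {
  spec <- fx_spec_2class(n = c(60, 60), seed = 4)
  gen <- generate_dataset(spec)
  split <- split_by_chromosome(gen$dataset)
  cfg <- model_config(window_length = 100, n_classes = 2, ensemble_size = 1,
                      first_layer = list(n_filters = 4, width = 8,
                                         init = "random"),
                      member_second_layers = list(c(4, 3)),
                      epochs = 6, early_stopping_patience = 1,
                      learning_rate = 0,  # frozen weights: loss is constant
                      seed = 2)
  ens <- build_ensemble(cfg, class_names = c("class1", "class2"))
  ens <- train_ensemble(ens, split)
  expect_equal(max(ens$training_log$epoch), 2)
})

test_that("training warns when a class has no positive examples", {
  d <- labeled_dataset(random_dna(40, 100, seed = 6),
                       cbind(rep(1L, 40), rep(0L, 40)),
                       class_names = c("pos", "never"))
  cfg <- model_config(window_length = 100, n_classes = 2, ensemble_size = 1,
                      first_layer = list(n_filters = 4, width = 8,
                                         init = "random"),
                      member_second_layers = list(c(4, 3)),
                      epochs = 1, seed = 3)
  ens <- build_ensemble(cfg, class_names = c("pos", "never"))
  expect_warning(train_ensemble(ens, d), "never")
})

test_that("ensemble prediction is the mean of member predictions", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  ens <- fx$ensemble
  seqs <- random_dna(6, 100, seed = 11)
  full <- predict(ens, seqs)
  single <- lapply(seq_along(ens$members), function(i) {
    one <- ens
    one$members <- ens$members[i]
    predict(one, seqs)
  })
  expect_equal(full, Reduce(`+`, single) / length(single))
})

test_that("prediction respects input order and duplicates", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  seqs <- random_dna(8, 100, seed = 12)
  p <- predict(fx$ensemble, seqs)
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  expect_equal(predict(fx$ensemble, seqs[perm]), p[perm, ])
  expect_equal(predict(fx$ensemble, c(seqs[1], seqs[1]))[1, ],
               predict(fx$ensemble, c(seqs[1], seqs[1]))[2, ])
  expect_error(predict(fx$ensemble, substr(seqs[1], 1, 50)), "length")
})

test_that("evaluate_ensemble metrics match brute-force oracles", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  metrics <- evaluate_ensemble(fx$ensemble, fx$split$test)
  probs <- predict(fx$ensemble, fx$split$test)
  for (ci in 1:2) {
    expect_equal(metrics$auroc[ci],
                 bf_auroc(probs[, ci], fx$split$test$labels[, ci]))
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    roc <- suppressMessages(
      pROC::roc(fx$split$test$labels[, 1], probs[, 1], quiet = TRUE,
                levels = c(0, 1), direction = "<")
    )
    expect_equal(metrics$auroc[1], as.numeric(pROC::auc(roc)))
  }
})

test_that("degenerate evaluation cases follow the metric conventions", {
  d <- labeled_dataset(random_dna(10, 100, seed = 13),
                       cbind(c(rep(1L, 5), rep(0L, 5)), rep(1L, 10)),
                       class_names = c("mixed", "allpos"))
  ens <- fx_constant_ensemble(class_names = c("mixed", "allpos"))
  metrics <- evaluate_ensemble(ens, d)
  expect_equal(metrics$auroc[metrics$class == "mixed"], 0.5)  # constant scores
  expect_true(is.na(metrics$auroc[metrics$class == "allpos"]))
})

test_that("save/load round-trips predictions bit-identically", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  dir <- withr::local_tempdir()
  save_ensemble(fx$ensemble, dir)
  back <- load_ensemble(dir)
  seqs <- random_dna(10, 100, seed = 14)
  expect_identical(predict(back, seqs), predict(fx$ensemble, seqs))
  expect_equal(back$config, fx$ensemble$config)
  expect_equal(back$class_names, fx$ensemble$class_names)
  expect_error(load_ensemble(withr::local_tempdir()), "config.dcf")
  # version check
  manifest <- file.path(dir, "MANIFEST")
  writeLines(sub("save_format: .*", "save_format: 0",
                 readLines(manifest)), manifest)
  expect_error(load_ensemble(dir), "format")
})
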