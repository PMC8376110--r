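# Pattern insertion, EPE/DEPE identities and consistency, the GIA comparator,
# screens, spacing scans, saliency, and background sampling.

test_that("insert_pattern centers by default and honors wildcards", {
  expect_equal(insert_pattern("AAAAAAAAAA", pattern("p", "CGT")),
               "AAACGTAAAA")  # start index floor((10-3)/2) = 3
  expect_equal(insert_pattern("AAAAAAAAAA", pattern("p", "C**G"), position = 2),
               "AACAAGAAAA")
  expect_error(insert_pattern("AAAAAAAAAA", pattern("p", strrep("C", 11))),
               "longer")
  expect_error(insert_pattern("AAAAAAAAAA", pattern("p", "CGT"), position = 8),
               "out of range")
  # insertion never changes length
  bg <- random_dna(5, 30, seed = 1)
  out <- insert_pattern(bg, pattern("p", "ACG*T"))
  expect_equal(nchar(out), nchar(bg))
})

test_that("EPE of a pattern identical to background content is exactly null", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  base <- random_dna(1, 100, seed = 21)
  bg <- background_set(rep(base, 4), source = "synthetic")
  center_pat <- pattern("self", substr(base, 47, 54))  # default start 46
  r <- epe(fx$ensemble, bg, center_pat, "class1")
  expect_identical(r$alpha, 1)
  expect_identical(r$W, 0)
  expect_identical(r$p_value, 1)
})

test_that("a constant model gives alpha = 1 and zero GIA for every pattern", {
  ens <- fx_constant_ensemble(class_names = c("class1", "class2"))
  bg <- background_set(random_dna(6, 100, seed = 22), source = "synthetic")
  for (tpl in c("ACGTACGT", "TTTT", "G*G*G")) {
    r <- epe(ens, bg, pattern("p", tpl), "class1")
    expect_equal(r$alpha, 1)
    expect_equal(r$p_value, 1)
    expect_equal(gia_effect(ens, bg, pattern("p", tpl), "class1")$effect, 0)
  }
})

test_that("DEPE is antisymmetric with equal p-values", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  bg <- fx_backgrounds(fx$spec)
  pat <- consensus(fx_motifA())
  d12 <- depe(fx$ensemble, bg, pat, "class1", "class2")
  d21 <- depe(fx$ensemble, bg, pat, "class2", "class1")
  expect_equal(d12$depe, -d21$depe, tolerance = 1e-12)
  expect_equal(d12$per_seq, -d21$per_seq, tolerance = 1e-12)
  expect_equal(d12$p_value, d21$p_value)
  expect_error(depe(fx$ensemble, bg, pat, "class1", "class1"), "differ")
})

test_that("DEPE equals the difference of per-class EPE log ratios", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  bg <- fx_backgrounds(fx$spec)
  pat <- consensus(fx_motifB())
  d <- depe(fx$ensemble, bg, pat, "class1", "class2")
  e1 <- epe(fx$ensemble, bg, pat, "class1")
  e2 <- epe(fx$ensemble, bg, pat, "class2")
  expect_equal(d$per_seq, e1$log2_ratios - e2$log2_ratios)
  expect_equal(d$depe, mean(e1$log2_ratios - e2$log2_ratios))
})

test_that("a model with identical heads gives null DEPE and zero saliency", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  tied <- fx_tie_heads(fx$ensemble)
  bg <- fx_backgrounds(fx$spec)
  d <- depe(tied, bg, consensus(fx_motifA()), "class1", "class2")
  expect_equal(d$depe, 0)
  expect_equal(d$p_value, 1)
  sal <- differential_saliency(tied, random_dna(1, 100, seed = 23),
                               "class1", "class2")
  expect_equal(sal$score, rep(0, 100))
})

test_that("clipping epsilon does not alter results away from the bounds", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  bg <- fx_backgrounds(fx$spec)
  pat <- consensus(fx_motifA())
  probs <- predict(fx$ensemble, bg$sequences)
  expect_true(all(probs > 1e-4 & probs < 1 - 1e-4))
  r1 <- epe(fx$ensemble, bg, pat, "class1", epsilon = 1e-6)
  r2 <- epe(fx$ensemble, bg, pat, "class1", epsilon = 1e-7)
  expect_identical(r1$alpha, r2$alpha)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("motif_screen applies Bonferroni over the motif panel", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  bg <- fx_backgrounds(fx$spec)
  panel <- lapply(1:5, function(k) random_pwm(6, seed = 30 + k,
                                              name = paste0("m", k)))
  scr <- motif_screen(fx$ensemble, bg, panel, classes = "class1")
  expect_equal(nrow(scr), 5)
  expect_equal(scr$p_adjusted, pmin(1, scr$p_value * 5))
  # order invariance
  scr_rev <- motif_screen(fx$ensemble, bg, rev(panel), classes = "class1")
  expect_equal(dplyr::arrange(scr, .data$pattern_id),
               dplyr::arrange(scr_rev, .data$pattern_id))
  # BH alternative is monotone in the raw p-values
  scr_bh <- motif_screen(fx$ensemble, bg, panel, classes = "class1",
                         correction = "bh")
  expect_equal(scr_bh$p_adjusted, stats::p.adjust(scr_bh$p_value, "BH"))
})

test_that("one-vs-rest DEPE uses the mean of the remaining classes", {
  cfg <- fx_config(seed = 9, n_classes = 3)
  ens <- build_ensemble(cfg, list(fx_motifA()),
                        class_names = c("a", "b", "c"))
  bg <- background_set(random_dna(5, 100, seed = 24), source = "synthetic")
  pat <- consensus(fx_motifA())
  r <- depe(ens, bg, pat, "a", one_vs_rest = TRUE)
  probs_bg <- pmin(pmax(predict(ens, bg$sequences), 1e-6), 1 - 1e-6)
  probs_in <- pmin(pmax(predict(ens, insert_pattern(bg$sequences, pat)),
                        1e-6), 1 - 1e-6)
  expected <- log2(probs_in[, "a"] / probs_bg[, "a"]) -
    log2(rowMeans(probs_in[, c("b", "c")]) / rowMeans(probs_bg[, c("b", "c")]))
  expect_equal(r$per_seq, unname(expected))
  expect_equal(r$class_pair[2], "rest")
})

test_that("spacing_scan emits one row per feasible spacing, sorted", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  bg <- fx_backgrounds(fx$spec)
  sc <- spacing_scan(fx$ensemble, bg, fx_motifA(), fx_motifB(), 0:10,
                     "class1")
  expect_equal(nrow(sc), 11)
  expect_equal(sc$spacing, 0:10)
  # infeasible spacing skipped with a warning (8 + 90 + 8 > 100)
  expect_warning(
    sc2 <- spacing_scan(fx$ensemble, bg, fx_motifA(), fx_motifB(),
                        c(2, 90), "class1"),
    "skipped"
  )
  expect_equal(sc2$spacing, 2)
  # both orders doubles the rows
  sc3 <- spacing_scan(fx$ensemble, bg, fx_motifA(), fx_motifB(), 0:3,
                      "class1", both_orders = TRUE)
  expect_equal(nrow(sc3), 8)
})

test_that("differential saliency concentrates on embedded motif positions", {
  fx <- fx_trained_2class(n = c(150, 150), epochs = 3)
  dataset <- generate_dataset(fx$spec)$dataset  # same seed: same sequences
  truth <- fx$truth[fx$truth$embedded & fx$truth$class == "class1", ]
  scores_in <- c()
  scores_out <- c()
  for (row in head(seq_len(nrow(truth)), 15)) {
    sal <- differential_saliency(fx$ensemble,
                                 dataset$sequences[truth$index[row]],
                                 "class1", "class2")
    expect_equal(nrow(sal), 100)
    span <- seq(truth$start[row] + 1, truth$end[row])
    scores_in <- c(scores_in, abs(sal$score[span]))
    scores_out <- c(scores_out, abs(sal$score[-span]))
  }
  expect_gt(mean(scores_in), mean(scores_out))
})

test_that("sample_backgrounds draws reproducibly from the eligible pool", {
  spec <- fx_spec_2class(n = c(40, 40), seed = 6)
  dataset <- generate_dataset(spec)$dataset
  bg1 <- sample_backgrounds(dataset, "closed_random", M = 10, seed = 3)
  bg2 <- sample_backgrounds(dataset, "closed_random", M = 10, seed = 3)
  expect_identical(bg1$sequences, bg2$sequences)
  # closed_random excludes every window labeled in any class
  pos_seqs <- dataset$sequences[rowSums(dataset$labels) > 0]
  expect_false(any(bg1$sequences %in% pos_seqs))
  expect_error(sample_backgrounds(dataset, "closed_random", M = 1000),
               "eligible")
  open <- sample_backgrounds(dataset, "open_random", M = 10, seed = 4)
  expect_true(all(open$sequences %in% pos_seqs))
})

test_that("packaged default backgrounds load with the documented shape", {
  bg <- default_backgrounds()
  expect_s3_class(bg, "background_set")
  expect_length(bg$sequences, 24)
  expect_equal(unique(nchar(bg$sequences)), 100)
  expect_equal(bg$source, "synthetic")
})
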