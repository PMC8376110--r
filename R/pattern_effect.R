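# Expected Pattern Effect (EPE) and Differential Expected Pattern Effect
# (DEPE): insert a concrete pattern into M background sequences, compare
# model predictions with and without the insertion, and score the effect as a
# mean prediction ratio (EPE) or a mean difference of log2 prediction ratios
# between two classes (DEPE), with a normalized Wilcoxon signed-rank
# statistic for significance. The ratio form makes effects comparable across
# classes with very different priors, which is the point of the method.

#' Construct a background sequence set
#'
#' The M sequences approximating the natural sequence distribution into which
#' patterns are inserted. Signed-rank significance needs at least two
#' sequences; the default study size is M = 24.
#'
#' @param sequences Character vector of equal-length sequences.
#' @param source Tag recording where the set came from: one of
#'   `closed_random`, `open_random`, `promoter_closed`, `promoter_open`,
#'   `user`, `synthetic`.
#' @param seed Seed used to draw the set (for the record).
#' @return An object of class `background_set`.
#' @export
background_set <- function(sequences, source = "user", seed = NA_integer_) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 2) {
    stop_pe("a background set needs at least 2 sequences")
  }
  if (length(unique(nchar(sequences))) != 1) {
    stop_pe("background sequences must all have the same length")
  }
  source <- match.arg(source, c("closed_random", "open_random",
                                "promoter_closed", "promoter_open", "user",
                                "synthetic"))
  structure(list(sequences = sequences, source = source,
                 seed = as.integer(seed)),
            class = "background_set")
}

#' @export
print.background_set <- function(x, ...) {
  cat("<background_set> M = ", length(x$sequences), ", ",
      nchar(x$sequences[1]), " bp, source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' @export
length.background_set <- function(x) length(x$sequences)

#' Sample backgrounds from a labeled dataset
#'
#' Draws M windows without replacement from the eligible pool:
#' `closed_random` takes windows labeled 0 in every class (closed/unbound
#' everywhere), `open_random` takes windows labeled 1 in at least one class.
#'
#' @param dataset A [labeled_dataset()].
#' @param source `"closed_random"` (default) or `"open_random"`.
#' @param M Number of sequences (default 24).
#' @param seed Integer seed; fixed seed gives the same draw.
#' @return A [background_set()].
#' @export
sample_backgrounds <- function(dataset, source = "closed_random", M = 24,
                               seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  source <- match.arg(source, c("closed_random", "open_random"))
  eligible <- if (source == "closed_random") {
    which(rowSums(dataset$labels) == 0)
  } else {
    which(rowSums(dataset$labels) > 0)
  }
  if (length(eligible) < M) {
    stop_pe("only ", length(eligible), " eligible ", source,
            " windows for M = ", M)
  }
  idx <- with_seed(seed, sample(eligible, M))
  background_set(dataset$sequences[idx], source = source, seed = seed)
}

#' Read a background set from FASTA
#'
#' @param path FASTA path.
#' @param source Source tag (default `"user"`).
#' @return A [background_set()].
#' @export
read_backgrounds <- function(path, source = "user") {
  background_set(unname(read_fasta(path)), source = source)
}

#' Default packaged background set
#'
#' Twenty-four synthetic 100-nt sequences at GC 0.5, generated by
#' [generate_background_pool()] and shipped with the package as a stand-in
#' for genome-derived closed-chromatin backgrounds. For real analyses, prefer
#' [sample_backgrounds()] on your own data.
#'
#' @return A [background_set()] with `source = "synthetic"`.
#' @export
default_backgrounds <- function() {
  path <- system.file("extdata", "backgrounds_synthetic.fa",
                      package = "patternEffect")
  read_backgrounds(path, source = "synthetic")
}

#' Insert a pattern into a background sequence
#'
#' Substitution in place: the output has the background's length, with the
#' pattern's non-wildcard characters overwriting the background and `*`
#' positions keeping the background base. The default position centers the
#' pattern: `floor((L - len)/2)` (0-based start).
#'
#' @param background A single background sequence (or character vector;
#'   applied elementwise).
#' @param pattern A [pattern()] or template string.
#' @param position Optional 0-based start; default centered.
#' @return Character vector of modified sequences.
#' @export
insert_pattern <- function(background, pattern, position = NULL) {
  template <- if (inherits(pattern, "pattern")) pattern$template else
    toupper(pattern)
  L <- nchar(background)
  k <- nchar(template)
  if (any(k > L)) {
    stop_pe("pattern (", k, " nt) longer than background (", min(L), " nt)")
  }
  pos <- position %||% floor((L - k) / 2)
  if (any(pos < 0) || any(pos + k > L)) {
    stop_pe("insertion position ", pos[1], " out of range for pattern of ",
            k, " nt in background of ", L[1], " nt")
  }
  tpl <- strsplit(template, "", fixed = TRUE)[[1]]
  keep <- tpl == "*"
  vapply(seq_along(background), function(i) {
    ch <- strsplit(background[i], "", fixed = TRUE)[[1]]
    p0 <- if (length(pos) > 1) pos[i] else pos
    tgt <- ch[(p0 + 1):(p0 + k)]
    tgt[!keep] <- tpl[!keep]
    ch[(p0 + 1):(p0 + k)] <- tgt
    paste0(ch, collapse = "")
  }, character(1))
}

#' Normalized Wilcoxon signed-rank statistic and p-value
#'
#' Computes `W = (1/M) * sum(sign(v) * rank(|v|))`, with zeros dropped before
#' ranking (M stays the original count), average ranks for ties, and a
#' two-sided p-value from the Wilcoxon signed-rank null: exact for at most 25
#' tie-free non-zero values, normal approximation with continuity (and tie)
#' correction otherwise. All-zero input returns `W = 0, p = 1`.
#'
#' @param values Numeric vector of signed effects (e.g. log2 ratios).
#' @return List with `W`, `p_value`, `n_zero_dropped`, `method`.
#' @export
signed_rank <- function(values) {
  if (!length(values)) stop_pe("signed_rank needs at least one value")
  M <- length(values)
  v <- values[values != 0]
  n_zero <- M - length(v)
  if (!length(v)) {
    return(list(W = 0, p_value = 1, n_zero_dropped = n_zero,
                method = "degenerate"))
  }
  r <- rank(abs(v))
  W <- sum(sign(v) * r) / M
  m <- length(v)
  ties <- anyDuplicated(abs(v)) > 0
  v_plus <- sum(r[v > 0])
  if (!ties && m <= 25) {
    p <- 2 * min(psignrank(v_plus, m), 1 - psignrank(v_plus - 1, m))
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(abs(v))
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(v_plus - mu) * 0.5
    z <- (v_plus - mu - cc) / sqrt(sigma2)
    p <- 2 * min(pnorm(z), 1 - pnorm(z))
    method <- "normal_approx"
  }
  list(W = W, p_value = min(1, p), n_zero_dropped = n_zero, method = method)
}

# Predictions for backgrounds and pattern-inserted backgrounds, clipped to
# [eps, 1-eps]. Both-strands mode also evaluates the reverse-complement
# pattern. Returns clipped M x C matrices.
epe_predictions <- function(ensemble, backgrounds, pattern, position = NULL,
                            epsilon = 1e-6, both_strands = FALSE) {
  seqs <- backgrounds$sequences
  inserted <- insert_pattern(seqs, pattern, position)
  batch <- c(seqs, inserted)
  if (both_strands) {
    rc <- pattern(paste0(pattern$id, "_rc"),
                  reverse_complement(pattern$template))
    batch <- c(batch, insert_pattern(seqs, rc, position))
  }
  probs <- clip01(predict(ensemble, batch), epsilon)
  M <- length(seqs)
  list(bg = probs[seq_len(M), , drop = FALSE],
       fwd = probs[M + seq_len(M), , drop = FALSE],
       rev = if (both_strands) probs[2 * M + seq_len(M), , drop = FALSE])
}

resolve_class <- function(ensemble, class) {
  if (is.numeric(class)) {
    if (class < 1 || class > length(ensemble$class_names)) {
      stop_pe("class index ", class, " out of range")
    }
    return(as.integer(class))
  }
  i <- match(class, ensemble$class_names)
  if (is.na(i)) {
    stop_pe("unknown class '", class, "'; valid classes: ",
            paste(ensemble$class_names, collapse = ", "))
  }
  i
}

#' Expected Pattern Effect of a pattern on one class
#'
#' Inserts the pattern into each of the M backgrounds (centered by default)
#' and computes `alpha = (1/M) * sum f_c(x^p)/f_c(x)`, the mean per-sequence
#' prediction ratio; `alpha > 1` means the pattern increases predicted
#' activity for the class. Significance is the normalized signed-rank
#' statistic of the per-sequence log2 ratios. Predictions are clipped to
#' `[epsilon, 1 - epsilon]` before ratios.
#'
#' @param ensemble A trained `model_ensemble`.
#' @param backgrounds A [background_set()] (or character vector).
#' @param pattern A [pattern()].
#' @param class Class name or index.
#' @param position Optional 0-based insertion start; default centered.
#' @param epsilon Prediction clipping bound (default 1e-6).
#' @param both_strands If TRUE, use per-background `max` of the forward and
#'   reverse-complement pattern ratios.
#' @return An object of class `epe_result`.
#' @export
epe <- function(ensemble, backgrounds, pattern, class, position = NULL,
                epsilon = 1e-6, both_strands = FALSE) {
  if (is.character(backgrounds)) backgrounds <- background_set(backgrounds)
  c_idx <- resolve_class(ensemble, class)
  pr <- epe_predictions(ensemble, backgrounds, pattern, position, epsilon,
                        both_strands)
  ratios <- pr$fwd[, c_idx] / pr$bg[, c_idx]
  if (both_strands) {
    ratios <- pmax(ratios, pr$rev[, c_idx] / pr$bg[, c_idx])
  }
  sr <- signed_rank(log2(ratios))
  structure(
    list(pattern_id = pattern$id, class_name = ensemble$class_names[c_idx],
         alpha = mean(ratios), log2_ratios = log2(ratios), W = sr$W,
         p_value = sr$p_value, p_adjusted = sr$p_value,
         M = length(backgrounds$sequences),
         n_zero_dropped = sr$n_zero_dropped, method = sr$method),
    class = "epe_result"
  )
}

#' @export
print.epe_result <- function(x, ...) {
  cat("<epe_result> ", x$pattern_id, " on ", x$class_name,
      sprintf(": alpha = %.4g, W = %.3g, p = %.3g (M = %d)\n",
              x$alpha, x$W, x$p_value, x$M), sep = "")
  invisible(x)
}

#' Differential Expected Pattern Effect between two classes
#'
#' Per background sequence, the difference of log2 prediction ratios between
#' `class1` and `class2`; DEPE is the mean of these differences and the
#' signed-rank statistic is computed on them. Positive DEPE means the pattern
#' favors `class1`. With `one_vs_rest = TRUE`, `class2` is replaced by the
#' mean predicted probability over all remaining classes.
#'
#' @inheritParams epe
#' @param class1,class2 Class names or indices; must differ.
#' @param one_vs_rest Compare `class1` against the mean of all other classes.
#' @return An object of class `depe_result`.
#' @export
depe <- function(ensemble, backgrounds, pattern, class1, class2 = NULL,
                 one_vs_rest = FALSE, position = NULL, epsilon = 1e-6) {
  if (is.character(backgrounds)) backgrounds <- background_set(backgrounds)
  c1 <- resolve_class(ensemble, class1)
  pr <- epe_predictions(ensemble, backgrounds, pattern, position, epsilon)
  lr1 <- log2(pr$fwd[, c1] / pr$bg[, c1])
  if (one_vs_rest) {
    rest <- setdiff(seq_along(ensemble$class_names), c1)
    if (!length(rest)) stop_pe("one-vs-rest needs at least 2 classes")
    f2_bg <- rowMeans(pr$bg[, rest, drop = FALSE])
    f2_ins <- rowMeans(pr$fwd[, rest, drop = FALSE])
    lr2 <- log2(f2_ins / f2_bg)
    c2_name <- "rest"
  } else {
    if (is.null(class2)) stop_pe("class2 is required unless one_vs_rest = TRUE")
    c2 <- resolve_class(ensemble, class2)
    if (c1 == c2) stop_pe("class1 and class2 must differ")
    lr2 <- log2(pr$fwd[, c2] / pr$bg[, c2])
    c2_name <- ensemble$class_names[c2]
  }
  diffs <- lr1 - lr2
  sr <- signed_rank(diffs)
  structure(
    list(pattern_id = pattern$id,
         class_pair = c(ensemble$class_names[c1], c2_name),
         depe = mean(diffs), per_seq = diffs, W = sr$W,
         p_value = sr$p_value, p_adjusted = sr$p_value,
         M = length(backgrounds$sequences),
         n_zero_dropped = sr$n_zero_dropped, method = sr$method),
    class = "depe_result"
  )
}

#' @export
print.depe_result <- function(x, ...) {
  cat("<depe_result> ", x$pattern_id, ": ", x$class_pair[1], " vs ",
      x$class_pair[2],
      sprintf(": depe = %.4g, W = %.3g, p = %.3g (M = %d)\n",
              x$depe, x$W, x$p_value, x$M), sep = "")
  invisible(x)
}

#' Difference-based pattern effect (Global Importance Analysis comparator)
#'
#' The mean per-background prediction difference
#' `(1/M) * sum [f_c(x^p) - f_c(x)]`. Provided as the difference-based
#' comparator to the ratio-based EPE: under class imbalance, differences
#' scale with the class prior while ratios do not.
#'
#' @inheritParams epe
#' @return List with `pattern_id`, `class_name`, `effect` (mean difference)
#'   and `per_seq`.
#' @export
gia_effect <- function(ensemble, backgrounds, pattern, class, position = NULL,
                       epsilon = 1e-6) {
  if (is.character(backgrounds)) backgrounds <- background_set(backgrounds)
  c_idx <- resolve_class(ensemble, class)
  pr <- epe_predictions(ensemble, backgrounds, pattern, position, epsilon)
  d <- pr$fwd[, c_idx] - pr$bg[, c_idx]
  list(pattern_id = pattern$id, class_name = ensemble$class_names[c_idx],
       effect = mean(d), per_seq = d)
}

#' Screen a motif panel for class or class-pair effects
#'
#' Computes an EPE (per class) or DEPE (per class pair, or one-vs-rest) for
#' every motif in a database, reducing each PWM to a pattern by consensus
#' (default) or PWM sampling. P-values are corrected across the number of
#' motifs tested (Bonferroni by default, Benjamini-Hochberg optional).
#'
#' @param ensemble A trained `model_ensemble`.
#' @param backgrounds A [background_set()].
#' @param motif_db List of [pwm()] objects (or [pattern()] objects, used
#'   as-is).
#' @param classes Character vector of class names for EPE mode.
#' @param class_pairs List of `c(class1, class2)` pairs for DEPE mode, or the
#'   string `"one_vs_rest"` to screen every class against the rest.
#' @param reduction `"consensus"` or `"sample"` (PWM-sampled site).
#' @param correction `"bonferroni"` or `"bh"`.
#' @param position,epsilon,both_strands As in [epe()].
#' @param seed Seed for the `"sample"` reduction.
#' @return A tibble (class `motif_screen`) with one row per motif x
#'   class/class-pair: `pattern_id`, `class`/`class1,class2`, `effect`, `W`,
#'   `p_value`, `p_adjusted`, `M`, `n_zero_dropped`.
#' @export
motif_screen <- function(ensemble, backgrounds, motif_db, classes = NULL,
                         class_pairs = NULL, reduction = "consensus",
                         correction = "bonferroni", position = NULL,
                         epsilon = 1e-6, both_strands = FALSE, seed = 1) {
  if (!length(motif_db)) stop_pe("motif_db is empty")
  reduction <- match.arg(reduction, c("consensus", "sample"))
  correction <- match.arg(correction, c("bonferroni", "bh"))
  patterns <- lapply(seq_along(motif_db), function(k) {
    m <- motif_db[[k]]
    if (inherits(m, "pattern")) m
    else if (reduction == "consensus") consensus(m)
    else sample_site(m, seed = child_seed(seed, k))
  })
  K <- length(patterns)
  rows <- list()
  if (identical(class_pairs, "one_vs_rest")) {
    class_pairs <- lapply(ensemble$class_names, function(c1) c(c1, "rest"))
  }
  if (is.null(classes) && is.null(class_pairs)) {
    classes <- ensemble$class_names
  }
  for (pat in patterns) {
    for (cls in classes) {
      r <- epe(ensemble, backgrounds, pat, cls, position, epsilon,
               both_strands)
      rows[[length(rows) + 1L]] <- tibble(
        pattern_id = r$pattern_id, class = r$class_name, effect = r$alpha,
        W = r$W, p_value = r$p_value, M = r$M,
        n_zero_dropped = r$n_zero_dropped, mode = "epe"
      )
    }
    for (pair in class_pairs) {
      ovr <- identical(pair[2], "rest")
      r <- depe(ensemble, backgrounds, pat, pair[1],
                class2 = if (!ovr) pair[2], one_vs_rest = ovr,
                position = position, epsilon = epsilon)
      rows[[length(rows) + 1L]] <- tibble(
        pattern_id = r$pattern_id, class1 = r$class_pair[1],
        class2 = r$class_pair[2], effect = r$depe, W = r$W,
        p_value = r$p_value, M = r$M, n_zero_dropped = r$n_zero_dropped,
        mode = "depe"
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  # Bonferroni divisor = number of motifs in this screen (not motifs x
  # comparisons), matching per-comparison panels.
  out$p_adjusted <- if (correction == "bonferroni") {
    pmin(1, out$p_value * K)
  } else {
    stats::p.adjust(out$p_value, method = "BH")
  }
  class(out) <- c("motif_screen", class(out))
  out
}

#' Scan motif-pair spacings
#'
#' Builds `paired_pattern(a, b, s)` for each spacing `s` and computes its EPE
#' for the given class; the spacing with the highest alpha suggests the
#' preferred geometry of the two motifs (e.g. co-binding distance). Spacings
#' that would exceed the window length are skipped with a warning.
#'
#' @param ensemble A trained `model_ensemble`.
#' @param backgrounds A [background_set()].
#' @param motif_a,motif_b [pwm()] or [pattern()] objects.
#' @param spacings Integer vector of gaps (bp) to test.
#' @param class Class name or index.
#' @param both_orders Also test b-then-a at each spacing.
#' @param position,epsilon As in [epe()].
#' @return A tibble (class `spacing_scan`) sorted by spacing: `spacing`,
#'   `order`, `pattern_id`, `alpha`, `W`, `p_value`, `M`.
#' @export
spacing_scan <- function(ensemble, backgrounds, motif_a, motif_b, spacings,
                         class, both_orders = FALSE, position = NULL,
                         epsilon = 1e-6) {
  as_pat <- function(m) if (inherits(m, "pattern")) m else consensus(m)
  a <- as_pat(motif_a); b <- as_pat(motif_b)
  L <- nchar(backgrounds$sequences[1])
  orders <- if (both_orders) list(c("ab"), c("ba")) else list(c("ab"))
  rows <- list()
  for (s in sort(unique(as.integer(spacings)))) {
    for (ord in orders) {
      pat <- if (ord == "ab") paired_pattern(a, b, s) else
        paired_pattern(b, a, s)
      if (nchar(pat$template) > L) {
        warn(paste0("spacing ", s, " makes the pattern ", nchar(pat$template),
                    " nt, longer than the ", L, " nt window; skipped"))
        next
      }
      r <- epe(ensemble, backgrounds, pat, class, position, epsilon)
      rows[[length(rows) + 1L]] <- tibble(
        spacing = s, order = ord, pattern_id = r$pattern_id, alpha = r$alpha,
        W = r$W, p_value = r$p_value, M = r$M
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("spacing_scan", class(out))
  out
}

#' Per-base differential importance between two classes
#'
#' For each position of the input sequence, the gradient of
#' `log f_c1(x) - log f_c2(x)` with respect to the one-hot input, multiplied
#' elementwise by the input and summed over the four channels
#' (gradient-times-input), averaged over ensemble members. Positions whose
#' bases drive the class-1-vs-class-2 difference score away from zero.
#'
#' @param ensemble A trained `model_ensemble`.
#' @param sequence A single window-length sequence.
#' @param class1,class2 Class names or indices.
#' @return A tibble (class `saliency`) with columns `position` (1-based),
#'   `base`, `score`.
#' @export
differential_saliency <- function(ensemble, sequence, class1, class2) {
  sequence <- check_string(sequence, "sequence")
  if (nchar(sequence) != ensemble$config$window_length) {
    stop_pe("sequence length ", nchar(sequence), " != window length ",
            ensemble$config$window_length)
  }
  c1 <- resolve_class(ensemble, class1)
  c2 <- resolve_class(ensemble, class2)
  codes <- seq_to_code(sequence)
  xo <- one_hot(sequence)
  total <- numeric(nchar(sequence))
  for (net in ensemble$members) {
    fwd <- nn_forward(net, codes, keep_cache = TRUE)
    p <- fwd$probs[1, ]
    # d/dlogit log sigmoid(logit) = 1 - p; classes other than c1/c2 get 0
    dlogits <- matrix(0, 1, net$C)
    dlogits[1, c1] <- 1 - p[c1]
    dlogits[1, c2] <- -(1 - p[c2])
    g <- nn_backward(net, fwd$cache, dlogits, input_grad = TRUE)$X[1, , ]
    total <- total + rowSums(g * xo)
  }
  out <- tibble(position = seq_len(nchar(sequence)),
                base = strsplit(sequence, "", fixed = TRUE)[[1]],
                score = total / length(ensemble$members))
  class(out) <- c("saliency", class(out))
  out
}

#' Write screen / scan results as TSV
#'
#' @param results A tibble from [motif_screen()], [spacing_scan()] or
#'   [tidy()] on a result object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
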