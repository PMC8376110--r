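# Shared fixtures and independent oracles. Trained models are cached per test
# run so several test files can reuse them without retraining.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# The two planted motifs used throughout the 2-class fixtures.
fx_motifA <- function() random_pwm(8, seed = 11, name = "motifA")
fx_motifB <- function() random_pwm(8, seed = 22, name = "motifB")

# 2-class dataset spec: motif A marks class 1, motif B marks class 2.
fx_spec_2class <- function(n = c(1500, 1500), seed = 1, embed_prob = 0.9,
                           jitter = 10) {
  synthetic_spec(
    n,
    list(grammar_spec("class1", fx_motifA(), embed_prob = embed_prob,
                      position_jitter = jitter),
         grammar_spec("class2", fx_motifB(), embed_prob = embed_prob,
                      position_jitter = jitter)),
    seed = seed
  )
}

# Standard small training configuration for fixture models.
fx_config <- function(seed = 1, n_classes = 2, epochs = 5,
                      first = list(n_filters = 16, width = 12,
                                   init = "motif_db"),
                      members = list(c(8, 5), c(16, 9))) {
  model_config(
    window_length = 100, n_classes = n_classes,
    ensemble_size = length(members), first_layer = first,
    member_second_layers = members, epochs = epochs,
    learning_rate = 3e-3, batch_size = 64, seed = seed
  )
}

# Train the 2-class fixture model (cached); returns model, split, spec.
fx_trained_2class <- function(data_seed = 1, model_seed = 101,
                              n = c(300, 300), epochs = 3) {
  key <- paste0("trained2_", data_seed, "_", model_seed, "_", n[1], "_",
                epochs)
  cached(key, {
    spec <- fx_spec_2class(n = n, seed = data_seed)
    gen <- generate_dataset(spec)
    split <- split_by_chromosome(gen$dataset)
    ens <- build_ensemble(fx_config(seed = model_seed, epochs = epochs),
                          list(fx_motifA(), fx_motifB()),
                          class_names = c("class1", "class2"))
    list(ensemble = train_ensemble(ens, split), split = split, spec = spec,
         truth = gen$truth)
  })
}

# Untrained ensemble whose members all output exactly 0.5 for every class.
fx_constant_ensemble <- function(n_classes = 2, class_names = NULL) {
  ens <- build_ensemble(
    fx_config(seed = 5, n_classes = n_classes,
              first = list(n_filters = 8, width = 8, init = "random"),
              members = list(c(8, 5))),
    class_names = class_names
  )
  for (i in seq_along(ens$members)) {
    ens$members[[i]]$params$Wd[] <- 0
    ens$members[[i]]$params$bd[] <- 0
  }
  ens
}

# Copy class c1's output head onto c2 so both heads are identical.
fx_tie_heads <- function(ensemble, c1 = 1, c2 = 2) {
  for (i in seq_along(ensemble$members)) {
    ensemble$members[[i]]$params$Wd[, c2] <-
      ensemble$members[[i]]$params$Wd[, c1]
    ensemble$members[[i]]$params$bd[c2] <-
      ensemble$members[[i]]$params$bd[c1]
  }
  ensemble
}

fx_backgrounds <- function(spec, M = 24, seed = 7) {
  generate_background_pool(spec, M = M, seed = seed)
}

# ---- independent oracles -------------------------------------------------

# Brute-force signed-rank: ranks by explicit sorted walk (average ties), W by
# definition, exact two-sided p by enumerating all 2^m sign assignments.
bf_signed_rank <- function(v) {
  M <- length(v)
  nz <- v[v != 0]
  m <- length(nz)
  if (m == 0) return(list(W = 0, p = 1))
  o <- order(abs(nz))
  sorted <- abs(nz)[o]
  ranks_sorted <- as.numeric(seq_len(m))
  i <- 1
  while (i <= m) {
    j <- i
    while (j < m && sorted[j + 1] == sorted[i]) j <- j + 1
    ranks_sorted[i:j] <- mean(i:j)
    i <- j + 1
  }
  r <- numeric(m)
  r[o] <- ranks_sorted
  W <- sum(sign(nz) * r) / M
  p <- NA_real_
  if (m <= 12 && anyDuplicated(abs(nz)) == 0) {
    v_obs <- sum(r[nz > 0])
    masks <- 0:(2^m - 1)
    bits <- vapply(seq_len(m), function(b) bitwAnd(masks, 2^(b - 1)) > 0,
                   logical(length(masks)))
    null_v <- as.vector(bits %*% r)
    p <- min(1, 2 * min(mean(null_v <= v_obs), mean(null_v >= v_obs)))
  }
  list(W = W, p = p)
}

# Brute-force AUROC: pairwise concordance count with half credit for ties.
bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# All DNA strings of length L (for exhaustive filter-activation checks).
all_kmers <- function(L) {
  if (L == 1) return(c("A", "C", "G", "T"))
  shorter <- all_kmers(L - 1)
  as.vector(outer(shorter, c("A", "C", "G", "T"), paste0))
}

random_dna <- function(n, L, seed = 1) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
}
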