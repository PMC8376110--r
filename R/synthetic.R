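# Synthetic fixture generator: fixed-length DNA windows with class-specific
# embedded motif grammars (single motifs or motif pairs at a fixed gap),
# configurable class imbalance, background/negative windows, decoy motif
# panels, and fake chromosome assignments for split testing. Ground truth is
# returned alongside the data so recovery can be scored exactly.

#' Specify a class grammar
#'
#' @param class_name Name of the class receiving this grammar.
#' @param motifs List of [pwm()] (sites are sampled per instance) or
#'   [pattern()] objects (inserted verbatim).
#' @param spacing Optional list `(a, b, gap)`: indices into `motifs` plus a
#'   gap in bp, composing a motif pair at fixed spacing.
#' @param embed_prob Fraction of the class's sequences carrying the grammar
#'   (0 < p <= 1, default 1).
#' @param position_jitter Maximum absolute offset from the centered position
#'   (bp, default 0).
#' @return An object of class `grammar_spec`.
#' @export
grammar_spec <- function(class_name, motifs, spacing = NULL, embed_prob = 1,
                         position_jitter = 0) {
  if (!(embed_prob > 0 && embed_prob <= 1)) {
    stop_pe("embed_prob must be in (0, 1]")
  }
  if (inherits(motifs, c("pwm", "pattern"))) motifs <- list(motifs)
  structure(list(class_name = class_name, motifs = motifs, spacing = spacing,
                 embed_prob = embed_prob,
                 position_jitter = as.integer(position_jitter)),
            class = "grammar_spec")
}

#' Specify a synthetic dataset
#'
#' @param n_per_class Integer vector of positive-sequence counts, one per
#'   class; unequal counts create class imbalance.
#' @param grammars List of [grammar_spec()] objects. Several grammars may
#'   share a `class_name`: each is then embedded independently with its own
#'   `embed_prob`, giving that class a graded motif repertoire.
#' @param class_names Class names in label-column order; defaults to the
#'   unique grammar class names in first-appearance order.
#' @param window_length Window length in bp (default 100).
#' @param gc Background GC fraction (default 0.5).
#' @param decoy_motifs Optional panel of non-embedded [pwm()]s, recorded for
#'   screens; never inserted.
#' @param negatives_frac All-zero-label windows added as this fraction of the
#'   mean per-class positive count (default 0.5).
#' @param seed Integer seed; fully determines the dataset.
#' @param fake_chroms Chromosome names assigned round-robin as provenance.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class, grammars, window_length = 100,
                           gc = 0.5, decoy_motifs = NULL,
                           negatives_frac = 0.5, seed = 1,
                           class_names = NULL,
                           fake_chroms = c("chr1", "chr2", "chr3", "chr18",
                                           "chr19")) {
  grammar_classes <- vapply(grammars, `[[`, character(1), "class_name")
  class_names <- class_names %||% unique(grammar_classes)
  if (length(class_names) < 2) stop_pe("need at least 2 classes")
  if (!all(grammar_classes %in% class_names)) {
    stop_pe("grammar class '",
            setdiff(grammar_classes, class_names)[1],
            "' not among class names")
  }
  if (length(n_per_class) != length(class_names)) {
    stop_pe("n_per_class must have one entry per class")
  }
  structure(list(n_per_class = as.integer(n_per_class), grammars = grammars,
                 class_names = class_names,
                 window_length = as.integer(window_length), gc = gc,
                 decoy_motifs = decoy_motifs, negatives_frac = negatives_frac,
                 seed = as.integer(seed), fake_chroms = fake_chroms),
            class = "synthetic_spec")
}

# i.i.d. background bases at the given GC fraction.
random_sequences <- function(n, length, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  flat <- sample(DNA_BASES, n * length, replace = TRUE, prob = p)
  apply(matrix(flat, n, length), 1, paste0, collapse = "")
}

# Materialize one grammar instance as a concrete pattern (sampling PWM sites
# per instance so recovery is not trivial string matching).
instantiate_grammar <- function(grammar, seed) {
  site <- function(m, k) {
    if (inherits(m, "pattern")) m else sample_site(m, child_seed(seed, k))
  }
  if (!is.null(grammar$spacing)) {
    a <- site(grammar$motifs[[grammar$spacing$a]], 1L)
    b <- site(grammar$motifs[[grammar$spacing$b]], 2L)
    paired_pattern(a, b, grammar$spacing$gap)
  } else {
    site(grammar$motifs[[1]], 1L)
  }
}

#' Generate a synthetic labeled dataset with known ground truth
#'
#' Background bases are i.i.d. at the spec's GC fraction. Each class's
#' positive sequences receive each of that class's grammars independently
#' with its `embed_prob`, at the centered position plus a uniform jitter up
#' to `position_jitter`; when a class carries several grammars, placements
#' are redrawn (within the jitter range) to avoid overlapping an already
#' embedded instance. All-zero-label negatives are appended, and provenance
#' chromosomes are assigned round-robin for split testing.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a [labeled_dataset()]) and `truth` (tibble:
#'   `index`, `class`, `grammar`, `embedded`, `instance`, `start`, `end`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    L <- spec$window_length
    class_names <- spec$class_names
    C <- length(class_names)
    grammar_classes <- vapply(spec$grammars, `[[`, character(1), "class_name")
    n_neg <- round(spec$negatives_frac * mean(spec$n_per_class))
    n_total <- sum(spec$n_per_class) + n_neg
    seqs <- random_sequences(n_total, L, spec$gc)
    labels <- matrix(0L, n_total, C, dimnames = list(NULL, class_names))
    truth <- list()
    idx <- 0L
    for (ci in seq_len(C)) {
      class_grams <- spec$grammars[grammar_classes == class_names[ci]]
      for (k in seq_len(spec$n_per_class[ci])) {
        idx <- idx + 1L
        labels[idx, ci] <- 1L
        occupied <- matrix(integer(0), ncol = 2)
        for (g in class_grams) {
          gname <- if (!is.null(g$spacing)) {
            paste0(g$motifs[[g$spacing$a]]$name, "_gap", g$spacing$gap, "_",
                   g$motifs[[g$spacing$b]]$name)
          } else {
            m1 <- g$motifs[[1]]
            if (inherits(m1, "pattern")) m1$id else m1$name
          }
          if (runif(1) > g$embed_prob) {
            truth[[length(truth) + 1L]] <- tibble(
              index = idx, class = g$class_name, grammar = gname,
              embedded = FALSE, instance = NA_character_,
              start = NA_integer_, end = NA_integer_
            )
            next
          }
          pat <- instantiate_grammar(g, sample.int(2^30, 1))
          klen <- nchar(pat$template)
          if (klen > L) stop_pe("grammar (", klen, " nt) longer than window")
          center <- floor((L - klen) / 2)
          pos <- NA_integer_
          for (try in 1:20) {
            jit <- if (g$position_jitter > 0) {
              sample.int(2L * g$position_jitter + 1L, 1L) -
                g$position_jitter - 1L
            } else 0L
            cand <- min(max(center + jit, 0L), L - klen)
            clash <- nrow(occupied) > 0 &&
              any(cand < occupied[, 2] & cand + klen > occupied[, 1])
            if (!clash) { pos <- cand; break }
          }
          if (is.na(pos)) pos <- min(max(center, 0L), L - klen)  # give up
          occupied <- rbind(occupied, c(pos, pos + klen))
          seqs[idx] <- insert_pattern(seqs[idx], pat, pos)
          truth[[length(truth) + 1L]] <- tibble(
            index = idx, class = g$class_name, grammar = gname,
            embedded = TRUE, instance = pat$template, start = pos,
            end = pos + klen
          )
        }
      }
    }
    n_chrom <- length(spec$fake_chroms)
    chrom <- spec$fake_chroms[((seq_len(n_total) - 1L) %% n_chrom) + 1L]
    pos0 <- (seq_len(n_total) - 1L) %/% n_chrom * L
    provenance <- tibble(chrom = chrom, start = pos0, end = pos0 + L,
                         name = paste0("seq", seq_len(n_total)))
    list(
      dataset = labeled_dataset(seqs, labels, class_names = class_names,
                                provenance = provenance, window_length = L),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Generate a grammar-free background pool
#'
#' M sequences at the spec's GC fraction containing no grammar motif
#' (consensus strings are rejected as exact substrings and the sequence
#' redrawn), emulating closed/background regions. With `gc_range`, each
#' sequence draws its own GC fraction uniformly from the range, emulating the
#' compositional heterogeneity of genomic background regions.
#'
#' @param spec A [synthetic_spec()].
#' @param M Number of sequences (default 24).
#' @param seed Integer seed.
#' @param gc_range Optional length-2 numeric: per-sequence GC is drawn
#'   uniformly from this interval instead of the spec's fixed `gc`.
#' @return A [background_set()] with `source = "synthetic"`.
#' @export
generate_background_pool <- function(spec, M = 24, seed = 1,
                                     gc_range = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cons <- unlist(lapply(spec$grammars, function(g) {
    vapply(g$motifs, function(m) {
      if (inherits(m, "pattern")) m$template else consensus(m)$template
    }, character(1))
  }))
  with_seed(seed, {
    out <- character(M)
    for (i in seq_len(M)) {
      gc_i <- if (is.null(gc_range)) spec$gc else
        runif(1, gc_range[1], gc_range[2])
      repeat {
        s <- random_sequences(1, spec$window_length, gc_i)
        if (!any(vapply(cons, grepl, logical(1), x = s, fixed = TRUE))) break
      }
      out[i] <- s
    }
    background_set(out, source = "synthetic", seed = seed)
  })
}

#' Balanced / imbalanced spec pair
#'
#' Returns the spec unchanged plus a copy whose second class's positive count
#' is multiplied by `factor`, all else identical — the substrate for testing
#' robustness of effect estimates to class imbalance.
#'
#' @param spec A [synthetic_spec()].
#' @param factor Integer imbalance factor (>= 1).
#' @return List with `balanced` and `imbalanced` specs.
#' @export
imbalance_pair <- function(spec, factor) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is_count(factor)) stop_pe("factor must be a positive integer")
  imb <- spec
  imb$n_per_class[2] <- imb$n_per_class[2] * as.integer(factor)
  list(balanced = spec, imbalanced = imb)
}

#' Default decoy panel for screens
#'
#' Random sharp PWMs plus column-shuffled versions of the embedded motifs:
#' a panel in which only the true grammars should screen as significant. Every
#' decoy (random or shuffled) is constrained to at most `max_identity`
#' consensus matches against each embedded motif at any ungapped alignment
#' offset — a decoy resembling a true motif is a motif-family member, not a
#' negative control — and redrawn until the constraint holds.
#'
#' @param embedded List of embedded [pwm()]s to shuffle and screen against.
#' @param n_random Number of random decoys (default 18).
#' @param length Decoy length in bp (default 8).
#' @param seed Integer seed.
#' @param max_identity Maximum consensus identity to any embedded motif
#'   (default: half the decoy length).
#' @return List of [pwm()]s of length `n_random + length(embedded)`.
#' @export
decoy_panel <- function(embedded, n_random = 18, length = 8, seed = 1,
                        max_identity = NULL) {
  max_identity <- max_identity %||% floor(length / 2)
  targets <- vapply(embedded, function(m) consensus(m)$template, character(1))
  dissimilar <- function(p) {
    all(vapply(targets, function(t) {
      max_alignment_identity(consensus(p)$template, t) <= max_identity
    }, logical(1)))
  }
  randoms <- lapply(seq_len(n_random), function(k) {
    for (try in 0:200) {
      cand <- random_pwm(length, seed = child_seed(seed, k + 300L * try),
                         name = sprintf("decoy%02d", k))
      if (dissimilar(cand)) return(cand)
    }
    stop_pe("could not draw a decoy dissimilar to the embedded motifs")
  })
  shuffled <- lapply(seq_along(embedded), function(k) {
    for (try in 0:200) {
      cand <- shuffle_pwm(embedded[[k]],
                          seed = child_seed(seed, 100L + k + 300L * try),
                          max_identity = max_identity)
      if (dissimilar(cand)) return(cand)
    }
    stop_pe("could not shuffle '", embedded[[k]]$name,
            "' away from all embedded motifs")
  })
  c(randoms, shuffled)
}

#' Write a dataset as FASTA + label table
#'
#' @param dataset A [labeled_dataset()].
#' @param fasta_path,labels_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_dataset_fasta <- function(dataset, fasta_path, labels_path) {
  nm <- if (!is.null(dataset$provenance) &&
            !anyNA(dataset$provenance$name)) {
    dataset$provenance$name
  } else {
    paste0("seq", seq_along(dataset$sequences))
  }
  seqs <- dataset$sequences
  names(seqs) <- nm
  write_fasta(seqs, fasta_path)
  write_label_table(dataset$labels, labels_path)
  invisible(list(fasta = fasta_path, labels = labels_path))
}

#' Write a dataset as per-class BED files plus a fake genome FASTA
#'
#' Builds contigs from the dataset's provenance (window sequences placed at
#' their coordinates, gaps filled with random bases) and one BED file per
#' class listing that class's positive windows — exercising the BED ingestion
#' path end-to-end.
#'
#' @param dataset A [labeled_dataset()] with provenance.
#' @param dir Output directory.
#' @param seed Seed for gap filling.
#' @return Invisibly, list with `genome` path and named `bed` paths.
#' @export
write_dataset_bed <- function(dataset, dir, seed = 1) {
  if (is.null(dataset$provenance)) stop_pe("dataset has no provenance")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- dataset$provenance
  genome <- with_seed(seed, {
    vapply(unique(prov$chrom), function(ch) {
      rows <- which(prov$chrom == ch)
      len <- max(prov$end[rows])
      contig <- strsplit(random_sequences(1, len, 0.5), "", fixed = TRUE)[[1]]
      for (i in rows) {
        contig[(prov$start[i] + 1):prov$end[i]] <-
          strsplit(dataset$sequences[i], "", fixed = TRUE)[[1]]
      }
      paste0(contig, collapse = "")
    }, character(1))
  })
  genome_path <- file.path(dir, "genome.fa")
  write_fasta(genome, genome_path)
  bed_paths <- vapply(dataset$class_names, function(cls) {
    rows <- dataset$labels[, cls] == 1
    path <- file.path(dir, paste0(cls, ".bed"))
    write_bed(prov[rows, , drop = FALSE], path)
    path
  }, character(1))
  invisible(list(genome = genome_path, bed = bed_paths))
}
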