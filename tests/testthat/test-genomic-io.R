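# BED/FASTA IO, genome windowing, the >50%-overlap labeling rule, one-hot
# encoding, chromosome-held-out splitting, and class priors.

test_that("read_bed parses regions and rejects malformed lines by number", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t100\t300", "chr2\t0\t50\tpeak1\t960\t+"), path)
  regions <- read_bed(path)
  expect_equal(regions$chrom, c("chr1", "chr2"))
  expect_equal(regions$start, c(100L, 0L))
  expect_equal(regions$end, c(300L, 50L))
  expect_equal(regions$name, c(NA, "peak1"))

  writeLines(c("chr1\t100\t300", "chr1\t300\t100"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("chr1\tx\t300", path)
  expect_error(read_bed(path), "line 1")

  file.create(empty <- withr::local_tempfile())
  expect_equal(nrow(read_bed(empty)), 0)
})

test_that("read_fasta uppercases, concatenates, and enforces contracts", {
  path <- withr::local_tempfile()
  writeLines(c(">s1", "acgt", "ACGT"), path)
  expect_equal(read_fasta(path), c(s1 = "ACGTACGT"))

  writeLines(c(">s1", "ACGT", ">s1", "TTTT"), path)
  expect_error(read_fasta(path), "duplicate")

  writeLines(c(">s1", "ACXT"), path)
  expect_error(read_fasta(path), "s1")
})

test_that("FASTA round-trips through write_fasta", {
  seqs <- c(a = "ACGTACGTAC", b = "TTTTTTTTTT")
  path <- withr::local_tempfile()
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})

test_that("make_windows tiles chromosomes and drops partial windows", {
  expect_equal(nrow(make_windows(c(chrA = 250), 100)), 2)
  w <- make_windows(c(chrA = 250), 100)
  expect_equal(w$start, c(0L, 100L))
  expect_equal(w$end, c(100L, 200L))
  expect_equal(nrow(make_windows(c(chrA = 100), 100)), 1)
  expect_equal(nrow(make_windows(c(chrA = 99), 100)), 0)
})

test_that("label_windows applies the strict >50% union-overlap rule", {
  w <- tibble::tibble(chrom = "chrA", start = 0L, end = 100L)
  lab <- function(peaks) {
    unname(label_windows(w, list(cls = tibble::tibble(
      chrom = "chrA", start = peaks[[1]], end = peaks[[2]]
    )))[1, 1])
  }
  expect_equal(lab(list(40L, 200L)), 1L)   # overlap 60 > 50
  expect_equal(lab(list(50L, 200L)), 0L)   # overlap exactly 50: not > 50
  # union of two disjoint peaks in the same class: 30 + 30 = 60
  expect_equal(lab(list(c(0L, 40L), c(30L, 70L))), 1L)
})

test_that("label_windows overlap is computed per bp against the union", {
  # brute-force oracle: count window bp covered by any peak of the class
  withr::with_seed(42, {
    for (rep in 1:20) {
      n_peaks <- sample(1:5, 1)
      start <- sample(0:180, n_peaks)
      len <- sample(5:80, n_peaks, replace = TRUE)
      peaks <- tibble::tibble(chrom = "chrA", start = start,
                              end = pmin(start + len, 220L))
      w <- tibble::tibble(chrom = "chrA", start = 50L, end = 150L)
      covered <- logical(100)
      for (i in seq_len(n_peaks)) {
        hit <- seq.int(max(peaks$start[i], 50), min(peaks$end[i], 150) - 1)
        hit <- hit[hit >= 50 & hit < 150]
        covered[hit - 49] <- TRUE
      }
      expected <- as.integer(sum(covered) > 50)
      expect_equal(unname(label_windows(w, list(c = peaks))[1, 1]), expected)
    }
  })
})

test_that("label_windows is invariant to peak order and to splitting peaks", {
  w <- make_windows(c(chrA = 500), 100)
  peaks <- tibble::tibble(chrom = "chrA",
                          start = c(30L, 240L, 410L),
                          end = c(130L, 330L, 490L))
  base <- label_windows(w, list(c = peaks))
  shuffled <- label_windows(w, list(c = peaks[c(3, 1, 2), ]))
  expect_identical(base, shuffled)
  # split the first peak into two abutting pieces
  split_peaks <- tibble::tibble(chrom = "chrA",
                                start = c(30L, 80L, 240L, 410L),
                                end = c(80L, 130L, 330L, 490L))
  expect_identical(base, label_windows(w, list(c = split_peaks)))
})

test_that("extract_sequences respects 0-based half-open coordinates", {
  genome <- c(chrA = "AACGTT")
  r <- function(s, e) tibble::tibble(chrom = "chrA", start = s, end = e)
  expect_equal(extract_sequences(r(2L, 5L), genome), "CGT")
  expect_equal(extract_sequences(r(0L, 6L), genome), "AACGTT")
  expect_error(extract_sequences(r(0L, 7L), genome), "bounds")
  expect_error(
    extract_sequences(tibble::tibble(chrom = "chrB", start = 0L, end = 2L),
                      genome),
    "unknown chromosome"
  )
})

test_that("windows round-trip through FASTA and back", {
  genome <- c(chr1 = paste0(random_dna(1, 250, seed = 3)),
              chr2 = paste0(random_dna(1, 130, seed = 4)))
  windows <- make_windows(nchar(genome), 50)
  seqs <- extract_sequences(windows, genome)
  path <- withr::local_tempfile()
  write_fasta(stats::setNames(seqs, paste0("w", seq_along(seqs))), path)
  expect_equal(unname(read_fasta(path)), seqs)
})

test_that("one_hot encodes A,C,G,T as unit rows and N as uniform 0.25", {
  expect_equal(one_hot("AC"),
               matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 2, 4, byrow = TRUE,
                      dimnames = list(NULL, c("A", "C", "G", "T"))))
  expect_equal(unname(one_hot("N")[1, ]), rep(0.25, 4))
  s <- random_dna(1, 40, seed = 9)
  expect_equal(rowSums(one_hot(s)), rep(1, 40))
  expect_error(one_hot("ACXT"), "invalid base")
})

test_that("split_by_chromosome partitions by provenance without leakage", {
  spec <- fx_spec_2class(n = c(40, 40), seed = 2)
  dataset <- generate_dataset(spec)$dataset
  split <- split_by_chromosome(dataset, "chr18", "chr19")
  sizes <- sum(length(split$train$sequences),
               length(split$validation$sequences),
               length(split$test$sequences))
  expect_equal(sizes, length(dataset$sequences))
  expect_false(any(split$train$provenance$chrom %in% c("chr18", "chr19")))
  expect_true(all(split$validation$provenance$chrom == "chr18"))
  expect_true(all(split$test$provenance$chrom == "chr19"))
  expect_error(split_by_chromosome(dataset, "chr18", "chr18"), "overlap")
})

test_that("empty held-out chromosomes warn rather than fail", {
  dataset <- labeled_dataset(
    random_dna(4, 100, seed = 5),
    matrix(c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L), 4, 2),
    class_names = c("a", "b"),
    provenance = tibble::tibble(chrom = "chr1", start = 0:3 * 100L,
                                end = 1:4 * 100L)
  )
  expect_warning(split_by_chromosome(dataset, "chr18", "chr19"), "empty")
})

test_that("class_prior counts positives and averages under concatenation", {
  d1 <- labeled_dataset(random_dna(4, 100, seed = 6),
                        matrix(c(1L, 1L, 0L, 0L), 4, 1),
                        class_names = "c")
  expect_equal(class_prior(d1)$prior, 0.5)
  d0 <- labeled_dataset(random_dna(4, 100, seed = 7),
                        matrix(0L, 4, 1), class_names = "c")
  expect_equal(class_prior(d0)$prior, 0)
  d10 <- labeled_dataset(random_dna(10, 100, seed = 8),
                         matrix(c(1L, rep(0L, 9)), 10, 1),
                         class_names = "c")
  expect_equal(class_prior(d10)$prior, 0.1)
  both <- bind_datasets(d1, d10)
  expect_equal(class_prior(both)$prior,
               (0.5 * 4 + 0.1 * 10) / 14)
  expect_true(all(class_prior(both)$prior >= 0 &
                  class_prior(both)$prior <= 1))
})

test_that("label tables round-trip against FASTA-mode ingestion", {
  spec <- fx_spec_2class(n = c(15, 15), seed = 3)
  dataset <- generate_dataset(spec)$dataset
  fa <- withr::local_tempfile()
  tab <- withr::local_tempfile()
  write_dataset_fasta(dataset, fa, tab)
  back <- read_dataset_fasta(fa, tab)
  expect_equal(back$sequences, dataset$sequences)
  expect_equal(back$labels, dataset$labels)
})
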