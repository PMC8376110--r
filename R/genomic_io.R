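# Reading and writing the standard region/sequence formats, genome windowing,
# window labeling and one-hot encoding. All coordinates are 0-based half-open
# (BED convention) throughout the package.

#' Read a BED file of genomic regions
#'
#' Minimal BED reader: at least three tab-separated columns, 0-based half-open
#' coordinates preserved verbatim, extra columns beyond the optional name
#' ignored. Parse failures report the offending line number.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name` in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_pe("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3)) {
    stop_pe("BED parse error at line ", which(n_col < 3)[1],
            ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    stop_pe("BED parse error at line ", which(is.na(start) | is.na(end))[1],
            ": non-integer coordinates")
  }
  if (any(end <= start)) {
    stop_pe("BED parse error at line ", which(end <= start)[1],
            ": end must be greater than start")
  }
  name <- vapply(seq_along(fields), function(i) {
    if (n_col[i] >= 4) fields[[i]][4] else NA_character_
  }, character(1))
  tibble(chrom = chrom, start = start, end = end, name = name)
}

#' Write genomic regions as BED
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optional `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  nm <- if ("name" %in% names(regions)) regions$name else NA_character_
  has_name <- !is.na(nm)
  lines <- ifelse(
    has_name,
    paste(regions$chrom, regions$start, regions$end, nm, sep = "\t"),
    paste(regions$chrom, regions$start, regions$end, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Sequences are uppercased and multi-line records concatenated. Record names
#' must be unique and sequences must stay within the IUPAC DNA alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in record order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_pe("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) {
    stop_pe("duplicate FASTA record name: ",
            names(seqs)[duplicated(names(seqs))][1])
  }
  ok <- paste(IUPAC_DNA, collapse = "")
  bad <- grepl(sprintf("[^%s]", ok), seqs)
  if (any(bad)) {
    stop_pe("record '", names(seqs)[bad][1],
            "' contains non-nucleotide characters")
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector (names become record headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(sequences), path, width = 80
  )
  invisible(path)
}

#' Tile chromosomes into fixed-width windows
#'
#' Non-overlapping windows `[0,w), [w,2w), ...` per chromosome; a trailing
#' partial window is dropped.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param window Window width in bp.
#' @return Tibble of regions (`chrom`, `start`, `end`, `name`).
#' @export
make_windows <- function(chrom_sizes, window = 100) {
  if (!is_count(window)) stop_pe("window must be a positive integer")
  parts <- lapply(names(chrom_sizes), function(ch) {
    n <- floor(chrom_sizes[[ch]] / window)
    if (n < 1) return(NULL)
    start <- (seq_len(n) - 1L) * as.integer(window)
    tibble(chrom = ch, start = start, end = start + as.integer(window),
           name = NA_character_)
  })
  out <- dplyr::bind_rows(parts)
  if (!nrow(out)) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character())
  }
  out
}

# Merge possibly overlapping intervals of one chromosome into a disjoint
# union: sort by start, sweep, coalesce. Used so that window labeling is
# order-invariant and counts each bp once.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Label windows by majority overlap with class regions
#'
#' A window is labeled 1 for a class when strictly more than half of its
#' length is covered by the union of that class's regions (the >50% rule).
#' Overlap is computed against the merged union, so splitting a region into
#' abutting pieces or reordering regions cannot change a label.
#'
#' @param windows Tibble of equal-length windows (`chrom`, `start`, `end`).
#' @param peak_sets Named list mapping class name to a region tibble.
#' @return Binary integer matrix, one row per window, one column per class.
#' @export
label_windows <- function(windows, peak_sets) {
  L <- unique(windows$end - windows$start)
  if (length(L) > 1) stop_pe("all windows must have the same length")
  labels <- matrix(0L, nrow(windows), length(peak_sets),
                   dimnames = list(NULL, names(peak_sets)))
  if (!nrow(windows)) return(labels)
  for (cls in names(peak_sets)) {
    peaks <- peak_sets[[cls]]
    if (is.null(peaks) || !nrow(peaks)) next
    for (ch in unique(windows$chrom)) {
      wi <- which(windows$chrom == ch)
      pk <- peaks[peaks$chrom == ch, , drop = FALSE]
      if (!nrow(pk)) next
      u <- merge_intervals(pk$start, pk$end)
      ws <- windows$start[wi]; we <- windows$end[wi]
      cov <- numeric(length(wi))
      for (j in seq_along(u$start)) {
        cov <- cov + pmax(0, pmin(we, u$end[j]) - pmax(ws, u$start[j]))
      }
      labels[wi, cls] <- as.integer(cov > L / 2)
    }
  }
  labels
}

#' Extract forward-strand sequences for regions from a genome
#'
#' @param regions Tibble of regions (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param genome Named character vector of contig sequences, or a path to a
#'   genome FASTA.
#' @return Character vector of sequences, one per region.
#' @export
extract_sequences <- function(regions, genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  vapply(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]
    if (!ch %in% names(genome)) stop_pe("unknown chromosome: ", ch)
    contig <- genome[[ch]]
    if (regions$end[i] > nchar(contig) || regions$start[i] < 0) {
      stop_pe("region ", ch, ":", regions$start[i], "-", regions$end[i],
              " outside contig bounds (length ", nchar(contig), ")")
    }
    substr(contig, regions$start[i] + 1L, regions$end[i])
  }, character(1))
}

#' One-hot encode a DNA sequence
#'
#' Column order A, C, G, T. An `N` is encoded as 0.25 in every channel so that
#' every row sums to one and ambiguous bases carry no directional signal.
#'
#' @param sequence A single sequence over `A,C,G,T,N`.
#' @return Numeric matrix of dimension `length x 4`.
#' @export
one_hot <- function(sequence) {
  sequence <- toupper(check_string(sequence, "sequence"))
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(ch, c(DNA_BASES, "N"))
  if (anyNA(idx)) {
    stop_pe("invalid base '", ch[is.na(idx)][1], "' at position ",
            which(is.na(idx))[1])
  }
  m <- matrix(0, length(ch), 4, dimnames = list(NULL, DNA_BASES))
  hit <- idx <= 4
  m[cbind(which(hit), idx[hit])] <- 1
  m[!hit, ] <- 0.25
  m
}

#' Read a label table accompanying a FASTA file
#'
#' Tab-separated, header row of class names, then one row of 0/1 values per
#' sequence in FASTA record order.
#'
#' @param path Path to the label table.
#' @return Integer label matrix with class names as columns.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab)
  if (!all(m %in% c(0, 1))) stop_pe("label table entries must be 0 or 1")
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

#' Write a label table
#'
#' @param labels Binary label matrix with class-name columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a dataset from FASTA + label table
#'
#' @param fasta_path Sequences (FASTA).
#' @param labels_path Label table, rows matching FASTA record order.
#' @return A [labeled_dataset()].
#' @export
read_dataset_fasta <- function(fasta_path, labels_path) {
  seqs <- read_fasta(fasta_path)
  labels <- read_label_table(labels_path)
  if (nrow(labels) != length(seqs)) {
    stop_pe("label table has ", nrow(labels), " rows but FASTA has ",
            length(seqs), " records")
  }
  labeled_dataset(unname(seqs), labels)
}

#' Build a dataset from per-class BED files and a genome
#'
#' Tiles the genome into fixed windows, labels each window per class by the
#' >50%-overlap rule against each BED file's regions, extracts forward-strand
#' sequences, and subsamples all-zero (background) windows.
#'
#' @param bed_paths Named list/vector mapping class name to BED path.
#' @param genome Genome FASTA path or named character vector of contigs.
#' @param window Window length in bp (default 100).
#' @param n_negatives Number of all-zero windows to keep; default equals the
#'   number of positive windows. `Inf` keeps all.
#' @param max_n_frac Windows with more than this fraction of `N` bases are
#'   dropped (default 0.1).
#' @param seed Seed for negative subsampling.
#' @return A [labeled_dataset()] with provenance.
#' @export
read_dataset_bed <- function(bed_paths, genome, window = 100,
                             n_negatives = NULL, max_n_frac = 0.1, seed = 1) {
  if (is.character(genome) && length(genome) == 1) genome <- read_fasta(genome)
  peak_sets <- lapply(bed_paths, read_bed)
  windows <- make_windows(nchar(genome), window)
  labels <- label_windows(windows, peak_sets)
  seqs <- extract_sequences(windows, genome)
  n_frac <- vapply(seqs, function(s) {
    mean(strsplit(s, "", fixed = TRUE)[[1]] == "N")
  }, numeric(1), USE.NAMES = FALSE)
  keep <- n_frac <= max_n_frac
  windows <- windows[keep, , drop = FALSE]
  labels <- labels[keep, , drop = FALSE]
  seqs <- seqs[keep]
  pos <- rowSums(labels) > 0
  n_neg_keep <- n_negatives %||% sum(pos)
  neg_idx <- which(!pos)
  if (length(neg_idx) > n_neg_keep) {
    neg_idx <- with_seed(seed, sort(sample(neg_idx, n_neg_keep)))
  }
  keep2 <- sort(c(which(pos), neg_idx))
  labeled_dataset(seqs[keep2], labels[keep2, , drop = FALSE],
                  provenance = windows[keep2, , drop = FALSE],
                  window_length = window)
}
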