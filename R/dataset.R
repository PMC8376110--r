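#' Construct a labeled sequence dataset
#'
#' The training substrate of the package: `N` fixed-length DNA windows with a
#' multi-hot class label matrix (a window may be active in zero, one, or
#' several classes) and optional genomic provenance used for
#' chromosome-held-out splitting.
#'
#' @param sequences Character vector of equal-length sequences over
#'   `A,C,G,T,N`.
#' @param labels Binary matrix (`N x C`) of 0/1 class memberships. A row of
#'   zeros marks a window inactive in every class.
#' @param class_names Character vector of `C` unique class names; defaults to
#'   `colnames(labels)`.
#' @param provenance Optional data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and one row per sequence.
#' @param window_length Window length in bp; defaults to the common sequence
#'   length.
#'
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(sequences, labels, class_names = colnames(labels),
                            provenance = NULL, window_length = NULL) {
  sequences <- toupper(as.character(sequences))
  labels <- as.matrix(labels)
  if (is.null(window_length)) window_length <- nchar(sequences[1])
  lens <- nchar(sequences)
  if (length(sequences) == 0) stop_pe("dataset must contain at least one sequence")
  if (any(lens != window_length)) {
    stop_pe("all sequences must have length ", window_length,
            "; first offender at index ", which(lens != window_length)[1])
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop_pe("sequence ", which(bad)[1], " contains characters outside {A,C,G,T,N}")
  }
  if (nrow(labels) != length(sequences)) {
    stop_pe("labels must have one row per sequence (", length(sequences),
            "), got ", nrow(labels))
  }
  if (!all(labels %in% c(0, 1))) stop_pe("label entries must be exactly 0 or 1")
  if (is.null(class_names)) class_names <- paste0("class", seq_len(ncol(labels)))
  class_names <- as.character(class_names)
  if (anyDuplicated(class_names)) stop_pe("class_names must be unique")
  if (length(class_names) != ncol(labels)) {
    stop_pe("class_names length must equal ncol(labels)")
  }
  storage.mode(labels) <- "integer"
  dimnames(labels) <- list(NULL, class_names)
  if (!is.null(provenance)) {
    provenance <- as_tibble(provenance)
    if (nrow(provenance) != length(sequences)) {
      stop_pe("provenance must have one row per sequence")
    }
    if (!all(c("chrom", "start", "end") %in% names(provenance))) {
      stop_pe("provenance needs columns chrom, start, end")
    }
  }
  structure(
    list(sequences = sequences, labels = labels, class_names = class_names,
         provenance = provenance, window_length = as.integer(window_length)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", length(x$sequences), " sequences x ",
      length(x$class_names), " classes, window ", x$window_length, " bp\n",
      sep = "")
  cat("  classes: ", paste(x$class_names, collapse = ", "), "\n", sep = "")
  cat("  positives per class: ",
      paste(colSums(x$labels), collapse = ", "), "\n", sep = "")
  if (!is.null(x$provenance)) {
    cat("  provenance chromosomes: ",
        paste(sort(unique(x$provenance$chrom)), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$sequences)

#' Subset a labeled dataset by sequence index
#'
#' @param x A [labeled_dataset()].
#' @param i Integer or logical index over sequences.
#' @param ... Unused.
#' @return A `labeled_dataset` with the selected sequences.
#' @export
`[.labeled_dataset` <- function(x, i, ...) {
  labeled_dataset(
    x$sequences[i],
    x$labels[i, , drop = FALSE],
    class_names = x$class_names,
    provenance = if (!is.null(x$provenance)) x$provenance[i, , drop = FALSE],
    window_length = x$window_length
  )
}

#' @method as_tibble labeled_dataset
#' @export
as_tibble.labeled_dataset <- function(x, ...) {
  out <- tibble(sequence = x$sequences)
  out <- dplyr::bind_cols(out, as_tibble(as.data.frame(x$labels)))
  if (!is.null(x$provenance)) out <- dplyr::bind_cols(out, x$provenance)
  out
}

#' Concatenate labeled datasets
#'
#' @param ... `labeled_dataset` objects sharing class names and window length.
#' @return A single combined `labeled_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  ref <- parts[[1]]
  for (p in parts[-1]) {
    if (!identical(p$class_names, ref$class_names) ||
        p$window_length != ref$window_length) {
      stop_pe("datasets must share class names and window length")
    }
  }
  prov <- lapply(parts, `[[`, "provenance")
  has_prov <- !vapply(prov, is.null, logical(1))
  labeled_dataset(
    unlist(lapply(parts, `[[`, "sequences")),
    do.call(rbind, lapply(parts, `[[`, "labels")),
    class_names = ref$class_names,
    provenance = if (all(has_prov)) dplyr::bind_rows(prov),
    window_length = ref$window_length
  )
}

#' Class prior: the empirical expected probability per class
#'
#' For each class `c`, the fraction of windows labeled 1: the finite-sample
#' estimate of the overall expected probability that a window is active in
#' that class. Class imbalance shifts these priors, which is exactly why the
#' pattern-effect statistics downstream use prediction ratios rather than
#' differences.
#'
#' @param dataset A [labeled_dataset()].
#' @param class Optional class name(s); defaults to all classes.
#' @return A tibble with columns `class`, `n_positive`, `n`, `prior`.
#' @export
class_prior <- function(dataset, class = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- length(dataset$sequences)
  if (n < 1) stop_pe("class_prior needs a non-empty dataset")
  cls <- class %||% dataset$class_names
  miss <- setdiff(cls, dataset$class_names)
  if (length(miss)) stop_pe("unknown class: ", paste(miss, collapse = ", "))
  pos <- unname(colSums(dataset$labels[, cls, drop = FALSE]))
  tibble(class = cls, n_positive = as.integer(pos), n = n, prior = pos / n)
}

#' Split a dataset by held-out chromosomes
#'
#' Partitions a dataset into train/validation/test by the chromosome of each
#' window's genomic provenance, so no chromosome contributes to more than one
#' split and evaluation never sees sequence context adjacent to training
#' windows. Sequences without provenance go to train.
#'
#' @param dataset A [labeled_dataset()] with provenance.
#' @param validation_chroms Chromosomes held out for validation.
#' @param test_chroms Chromosomes held out for testing (disjoint from
#'   `validation_chroms`).
#' @return A `dataset_split`: list with `train`, `validation`, `test`
#'   (`labeled_dataset` or NULL when empty) and `held_out_chroms`.
#' @export
split_by_chromosome <- function(dataset, validation_chroms = "chr18",
                                test_chroms = "chr19") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(intersect(validation_chroms, test_chroms))) {
    stop_pe("validation and test chromosome lists overlap: ",
            paste(intersect(validation_chroms, test_chroms), collapse = ", "))
  }
  if (is.null(dataset$provenance)) {
    stop_pe("split_by_chromosome needs a dataset with provenance")
  }
  chrom <- dataset$provenance$chrom
  in_val <- chrom %in% validation_chroms
  in_test <- chrom %in% test_chroms
  in_train <- !in_val & !in_test
  take <- function(keep) if (any(keep)) dataset[keep] else NULL
  if (!any(in_val) || !any(in_test)) {
    warn("validation or test split is empty: no windows on the held-out chromosomes")
  }
  structure(
    list(train = take(in_train), validation = take(in_val), test = take(in_test),
         held_out_chroms = list(validation = validation_chroms,
                                test = test_chroms)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  sz <- function(d) if (is.null(d)) 0L else length(d$sequences)
  cat("<dataset_split> train ", sz(x$train), " / validation ", sz(x$validation),
      " / test ", sz(x$test), "\n", sep = "")
  cat("  held out: validation = ",
      paste(x$held_out_chroms$validation, collapse = ","),
      "; test = ", paste(x$held_out_chroms$test, collapse = ","), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
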