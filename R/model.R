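#' Configure a sequence-model ensemble
#'
#' Describes an ensemble of multi-task CNNs sharing a first convolutional
#' layer shape (optionally motif-initialized) but differing in their second
#' convolutional layer, so members scan for motif combinations at several
#' receptive-field sizes. The published defaults are stand-ins and every field
#' is configurable.
#'
#' @param window_length Input window length in bp.
#' @param n_classes Number of output classes (tasks).
#' @param ensemble_size Number of members; must match
#'   `length(member_second_layers)`.
#' @param first_layer List with `n_filters`, `width` and `init`
#'   (`"motif_db"` or `"random"`).
#' @param member_second_layers List of `(n_filters, width)` pairs, one per
#'   member.
#' @param epochs Maximum training epochs (default 5).
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before stopping (default 2); best-epoch weights are restored.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed; member `i` trains with `seed + i`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(window_length = 100, n_classes = 2,
                         ensemble_size = 5,
                         first_layer = list(n_filters = 64, width = 17,
                                            init = "motif_db"),
                         member_second_layers = list(c(8, 5), c(16, 9),
                                                     c(32, 13), c(64, 17),
                                                     c(128, 21)),
                         epochs = 5, early_stopping_patience = 2,
                         batch_size = 256, learning_rate = 1e-3, seed = 1) {
  if (ensemble_size != length(member_second_layers)) {
    stop_pe("ensemble_size (", ensemble_size, ") must equal the number of ",
            "member second layers (", length(member_second_layers), ")")
  }
  if (!is_count(epochs)) stop_pe("epochs must be a positive integer")
  if (first_layer$width > window_length) {
    stop_pe("first-layer filter width exceeds window length")
  }
  structure(
    list(window_length = as.integer(window_length),
         n_classes = as.integer(n_classes),
         ensemble_size = as.integer(ensemble_size),
         first_layer = first_layer,
         member_second_layers = member_second_layers,
         epochs = as.integer(epochs),
         early_stopping_patience = as.integer(early_stopping_patience),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Build an untrained model ensemble
#'
#' First-layer filters are initialized from motif log-odds
#' (`log2((p + 0.01)/0.25)`, centered within the filter width, zero padding
#' elsewhere) when a motif database is supplied and `first_layer$init` is
#' `"motif_db"`; otherwise random.
#'
#' @param config A [model_config()].
#' @param motif_db Optional list of [pwm()] objects for first-layer
#'   initialization.
#' @param class_names Optional class names (length `n_classes`).
#' @return An object of class `model_ensemble` (untrained).
#' @export
build_ensemble <- function(config, motif_db = NULL, class_names = NULL) {
  stopifnot(inherits(config, "model_config"))
  use_motifs <- identical(config$first_layer$init, "motif_db") &&
    !is.null(motif_db)
  if (identical(config$first_layer$init, "motif_db") && is.null(motif_db)) {
    warn("first_layer init is 'motif_db' but no motif_db given; using random init")
  }
  members <- lapply(seq_len(config$ensemble_size), function(i) {
    second <- config$member_second_layers[[i]]
    nn_init(
      L = config$window_length, C = config$n_classes,
      F1 = config$first_layer$n_filters, w1 = config$first_layer$width,
      F2 = second[[1]], w2 = second[[2]],
      seed = child_seed(config$seed, i),
      motif_pwms = if (use_motifs) motif_db
    )
  })
  class_names <- class_names %||% paste0("class", seq_len(config$n_classes))
  structure(
    list(members = members, config = config,
         class_names = as.character(class_names),
         training_log = tibble(member = integer(), epoch = integer(),
                               train_loss = numeric(),
                               validation_loss = numeric()),
         trained = FALSE),
    class = "model_ensemble"
  )
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("<model_ensemble> ", length(x$members), " members, ",
      x$config$n_classes, " classes, window ", x$config$window_length,
      " bp, ", if (x$trained) "trained" else "untrained", "\n", sep = "")
  cat("  classes: ", paste(x$class_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Train a model ensemble
#'
#' Each member is trained independently on identical data with binary
#' cross-entropy loss; member `i` derives its randomness from
#' `config$seed + i`. Training stops early when validation loss fails to
#' improve for `early_stopping_patience` epochs and the best-epoch weights
#' are restored.
#'
#' @param ensemble An untrained (or previously trained) [build_ensemble()].
#' @param split A `dataset_split` from [split_by_chromosome()], or a
#'   [labeled_dataset()] (trains without early stopping).
#' @return The trained `model_ensemble` with a filled `training_log`.
#' @export
train_ensemble <- function(ensemble, split) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (inherits(split, "labeled_dataset")) {
    split <- structure(list(train = split, validation = NULL, test = NULL),
                       class = "dataset_split")
  }
  train <- split$train
  if (is.null(train) || !length(train$sequences)) {
    stop_pe("training split is empty")
  }
  if (ncol(train$labels) != ensemble$config$n_classes) {
    stop_pe("label width (", ncol(train$labels), ") does not match n_classes (",
            ensemble$config$n_classes, ")")
  }
  zero_pos <- colSums(train$labels) == 0
  if (any(zero_pos)) {
    warn(paste0("class(es) with zero positive training examples: ",
                paste(colnames(train$labels)[zero_pos], collapse = ", ")))
  }
  codes <- seq_to_code(train$sequences)
  labels <- train$labels
  val <- split$validation
  val_codes <- if (!is.null(val)) seq_to_code(val$sequences)
  val_labels <- if (!is.null(val)) val$labels
  cfg <- ensemble$config
  logs <- list()
  for (i in seq_along(ensemble$members)) {
    fit <- nn_train(
      ensemble$members[[i]], codes, labels, val_codes, val_labels,
      epochs = cfg$epochs, patience = cfg$early_stopping_patience,
      batch_size = cfg$batch_size, learning_rate = cfg$learning_rate,
      seed = cfg$seed + i
    )
    ensemble$members[[i]] <- fit$net
    logs[[i]] <- dplyr::mutate(fit$log, member = i, .before = 1)
  }
  ensemble$training_log <- dplyr::bind_rows(logs)
  ensemble$trained <- TRUE
  ensemble
}

#' Predict class probabilities for sequences
#'
#' Member probabilities are averaged with equal weight; row order matches the
#' input order.
#'
#' @param object A `model_ensemble`.
#' @param sequences Character vector of window-length sequences, or a
#'   [labeled_dataset()].
#' @param ... Unused.
#' @return Numeric matrix (`M x C`) of per-class probabilities.
#' @export
predict.model_ensemble <- function(object, sequences, ...) {
  if (inherits(sequences, "labeled_dataset")) sequences <- sequences$sequences
  lens <- nchar(sequences)
  if (any(lens != object$config$window_length)) {
    stop_pe("sequence ", which(lens != object$config$window_length)[1],
            " has length ", lens[lens != object$config$window_length][1],
            "; expected ", object$config$window_length)
  }
  codes <- seq_to_code(sequences)
  preds <- lapply(object$members, nn_predict, codes = codes)
  out <- Reduce(`+`, preds) / length(preds)
  colnames(out) <- object$class_names
  out
}

# Rank-based AUROC (equivalent to the Mann-Whitney statistic; ties get
# average ranks). Returns NA when only one label value is present.
auroc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision: precision summed over recall steps at each positive, in
# decreasing score order (ties broken by stable order).
average_precision <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) return(NA_real_)
  o <- order(-scores)
  y <- labels[o]
  cum_tp <- cumsum(y)
  prec <- cum_tp / seq_along(y)
  sum(prec[y == 1]) / n1
}

#' Evaluate an ensemble on a labeled dataset
#'
#' Per-class AUROC, average precision (AUPRC) and accuracy at a 0.5
#' threshold, plus a `mean` row averaging the defined per-class values.
#' Classes with a single label value get `NA` metrics rather than an error.
#'
#' @param ensemble A trained `model_ensemble`.
#' @param dataset A [labeled_dataset()] with labels.
#' @return A tibble with columns `class`, `auroc`, `auprc`, `accuracy`.
#' @export
evaluate_ensemble <- function(ensemble, dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  probs <- predict(ensemble, dataset)
  per_class <- purrr::map_dfr(seq_along(ensemble$class_names), function(c) {
    y <- dataset$labels[, c]
    tibble(
      class = ensemble$class_names[c],
      auroc = auroc(probs[, c], y),
      auprc = average_precision(probs[, c], y),
      accuracy = mean((probs[, c] >= 0.5) == (y == 1))
    )
  })
  dplyr::bind_rows(
    per_class,
    tibble(class = "mean",
           auroc = mean(per_class$auroc, na.rm = TRUE),
           auprc = mean(per_class$auprc, na.rm = TRUE),
           accuracy = mean(per_class$accuracy, na.rm = TRUE))
  )
}

SAVE_FORMAT_VERSION <- "1"

#' Save a model ensemble to a directory
#'
#' Writes the configuration as a plain-text key-value file, one serialized
#' weight file per member, and a MANIFEST recording package version, save
#' format and seed. [load_ensemble()] restores a bit-identical predictor.
#'
#' @param ensemble A `model_ensemble`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- ensemble$config
  dcf <- data.frame(
    window_length = cfg$window_length, n_classes = cfg$n_classes,
    ensemble_size = cfg$ensemble_size,
    first_layer = paste(cfg$first_layer$n_filters, cfg$first_layer$width,
                        cfg$first_layer$init, sep = ","),
    member_second_layers = paste(
      vapply(cfg$member_second_layers,
             function(x) paste(x[[1]], x[[2]], sep = ","), character(1)),
      collapse = ";"),
    epochs = cfg$epochs,
    early_stopping_patience = cfg$early_stopping_patience,
    batch_size = cfg$batch_size, learning_rate = cfg$learning_rate,
    seed = cfg$seed,
    class_names = paste(ensemble$class_names, collapse = ","),
    trained = ensemble$trained
  )
  write.dcf(dcf, file.path(dir, "config.dcf"))
  for (i in seq_along(ensemble$members)) {
    saveRDS(ensemble$members[[i]],
            file.path(dir, sprintf("member_%02d.rds", i)))
  }
  saveRDS(ensemble$training_log, file.path(dir, "training_log.rds"))
  writeLines(c(
    paste0("package: patternEffect ", as.character(packageVersion("patternEffect"))),
    paste0("save_format: ", SAVE_FORMAT_VERSION),
    paste0("seed: ", cfg$seed)
  ), file.path(dir, "MANIFEST"))
  invisible(dir)
}

#' Load a model ensemble from a directory
#'
#' @param dir Directory written by [save_ensemble()].
#' @return A `model_ensemble`.
#' @export
load_ensemble <- function(dir) {
  if (is.null(dir) || !length(dir)) stop_pe("no model directory given")
  cfg_path <- file.path(dir, "config.dcf")
  if (!file.exists(cfg_path)) {
    stop_pe("no saved ensemble in ", dir, " (missing config.dcf)")
  }
  manifest <- readLines(file.path(dir, "MANIFEST"), warn = FALSE)
  fmt <- sub("^save_format: ", "", grep("^save_format:", manifest, value = TRUE))
  if (!identical(fmt, SAVE_FORMAT_VERSION)) {
    stop_pe("saved ensemble format '", fmt, "' does not match supported '",
            SAVE_FORMAT_VERSION, "'")
  }
  d <- as.data.frame(read.dcf(cfg_path), stringsAsFactors = FALSE)
  fl <- strsplit(d$first_layer, ",")[[1]]
  msl <- lapply(strsplit(d$member_second_layers, ";")[[1]], function(x) {
    as.integer(strsplit(x, ",")[[1]])
  })
  cfg <- model_config(
    window_length = as.integer(d$window_length),
    n_classes = as.integer(d$n_classes),
    ensemble_size = as.integer(d$ensemble_size),
    first_layer = list(n_filters = as.integer(fl[1]),
                       width = as.integer(fl[2]), init = fl[3]),
    member_second_layers = msl,
    epochs = as.integer(d$epochs),
    early_stopping_patience = as.integer(d$early_stopping_patience),
    batch_size = as.integer(d$batch_size),
    learning_rate = as.numeric(d$learning_rate),
    seed = as.integer(d$seed)
  )
  members <- lapply(sort(list.files(dir, pattern = "^member_\\d+\\.rds$",
                                    full.names = TRUE)), readRDS)
  structure(
    list(members = members, config = cfg,
         class_names = strsplit(d$class_names, ",")[[1]],
         training_log = readRDS(file.path(dir, "training_log.rds")),
         trained = as.logical(d$trained)),
    class = "model_ensemble"
  )
}
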