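# Motif-database parsing (HOCOMOCO and HOMER dialects), and reduction of
# position weight matrices to concrete insertable patterns: consensus strings,
# PWM-sampled sites, and motif pairs with wildcard spacers.

#' Construct a position weight matrix
#'
#' @param name Motif identifier.
#' @param matrix `L x 4` matrix of per-position base probabilities or counts
#'   (column order A, C, G, T); rows are renormalized to sum to 1.
#' @param source Format tag: `"hocomoco"`, `"homer"` or `"raw"`.
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, matrix, source = "raw") {
  m <- as.matrix(matrix)
  if (ncol(m) != 4) stop_pe("PWM '", name, "': matrix must have 4 columns")
  if (nrow(m) < 1) stop_pe("PWM '", name, "': empty matrix")
  if (any(m < 0)) stop_pe("PWM '", name, "': negative entries")
  rs <- rowSums(m)
  if (any(rs == 0)) stop_pe("PWM '", name, "': zero-sum row")
  m <- m / rs
  dimnames(m) <- list(NULL, DNA_BASES)
  structure(list(name = name, matrix = m, source = source), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, " (", nrow(x$matrix), " bp, source: ", x$source,
      ")  consensus: ", consensus(x)$template, "\n", sep = "")
  invisible(x)
}

#' Parse a HOCOMOCO-style motif file
#'
#' Plain-text records: a `>name` header followed by `L` rows of four
#' whitespace-separated non-negative numbers (counts or frequencies); rows are
#' renormalized to probabilities, so PCM and PWM files are handled alike.
#'
#' @param path Path to the motif file.
#' @return List of [pwm()] objects in record order.
#' @export
parse_hocomoco <- function(path) {
  if (!file.exists(path)) stop_pe("motif file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_pe("no motif records (no '>' headers) in ", path)
  bounds <- c(heads, length(lines) + 1L)
  lapply(seq_along(heads), function(i) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[seq.int(heads[i] + 1L, bounds[i + 1L] - 1L)]
    if (!length(body)) stop_pe("motif '", name, "': empty record")
    rows <- lapply(body, function(ln) {
      v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(v) != 4 || anyNA(v)) {
        stop_pe("motif '", name, "': expected 4 numbers per row, got '",
                ln, "'")
      }
      v
    })
    pwm(name, do.call(rbind, rows), source = "hocomoco")
  })
}

#' Parse a HOMER `.motif` file
#'
#' Header lines are `>consensus<TAB>name<TAB>log-odds-threshold`, followed by
#' probability rows; rows drifting from sum 1 are renormalized.
#'
#' @param path Path to the `.motif` file.
#' @return List of [pwm()] objects in record order.
#' @export
parse_homer <- function(path) {
  if (!file.exists(path)) stop_pe("motif file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_pe("no motif records (no '>' headers) in ", path)
  bounds <- c(heads, length(lines) + 1L)
  lapply(seq_along(heads), function(i) {
    fields <- strsplit(sub("^>", "", lines[heads[i]]), "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_pe("HOMER header needs consensus<TAB>name<TAB>threshold, got '",
              lines[heads[i]], "'")
    }
    name <- fields[2]
    body <- lines[seq.int(heads[i] + 1L, bounds[i + 1L] - 1L)]
    if (!length(body)) stop_pe("motif '", name, "': empty record")
    rows <- lapply(body, function(ln) {
      v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(v) != 4 || anyNA(v)) {
        stop_pe("motif '", name, "': expected 4 numbers per row, got '",
                ln, "'")
      }
      v
    })
    pwm(name, do.call(rbind, rows), source = "homer")
  })
}

#' Write motifs in HOCOMOCO plain-text format
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hocomoco <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    utils::write.table(format(p$matrix, digits = 17), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write motifs in HOMER `.motif` format
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @param threshold Log-odds threshold written to each header (unused by this
#'   package).
#' @return `path`, invisibly.
#' @export
write_homer <- function(pwms, path, threshold = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", consensus(p)$template, "\t", p$name, "\t",
                      threshold), con)
    utils::write.table(format(p$matrix, digits = 17), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Construct an insertable pattern
#'
#' A pattern is a concrete nucleotide template over `A,C,G,T,*`, where `*`
#' means "leave the background nucleotide unchanged" on insertion.
#'
#' @param id Pattern identifier.
#' @param template Template string; must contain at least one non-`*`
#'   character.
#' @param parts Optional provenance tibble with columns `motif`, `offset`.
#' @return An object of class `pattern`.
#' @export
pattern <- function(id, template, parts = NULL) {
  template <- toupper(check_string(template, "template"))
  if (!nchar(template) || !grepl("[ACGT]", template)) {
    stop_pe("pattern template must contain at least one A/C/G/T character")
  }
  if (grepl("[^ACGT*]", template)) {
    stop_pe("pattern template may only contain A,C,G,T,*")
  }
  parts <- parts %||% tibble(motif = id, offset = 0L)
  structure(list(id = id, template = template, parts = as_tibble(parts)),
            class = "pattern")
}

#' @export
print.pattern <- function(x, ...) {
  cat("<pattern> ", x$id, ": ", x$template, " (", nchar(x$template), " nt)\n",
      sep = "")
  invisible(x)
}

#' Consensus pattern of a PWM
#'
#' Per-position argmax base; ties broken by the fixed base order A < C < G <
#' T, making the reduction deterministic.
#'
#' @param pwm A [pwm()].
#' @return A [pattern()] whose template is the consensus string.
#' @export
consensus <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  idx <- apply(pwm$matrix, 1, which.max)
  pattern(pwm$name, paste0(DNA_BASES[idx], collapse = ""),
          parts = tibble(motif = pwm$name, offset = 0L))
}

#' Sample a binding site from a PWM
#'
#' Draws each position independently from its probability row; reproducible
#' for a fixed seed. With one-hot rows this equals the consensus.
#'
#' @param pwm A [pwm()].
#' @param seed Integer seed.
#' @return A [pattern()].
#' @export
sample_site <- function(pwm, seed = 1) {
  stopifnot(inherits(pwm, "pwm"))
  bases <- with_seed(seed, {
    apply(pwm$matrix, 1, function(p) sample(DNA_BASES, 1, prob = p))
  })
  pattern(pwm$name, paste0(bases, collapse = ""),
          parts = tibble(motif = pwm$name, offset = 0L))
}

#' Compose two patterns at a fixed spacing
#'
#' Concatenates `a`, a run of `spacing` wildcard positions, then `b`. The
#' wildcards preserve background bases on insertion, so a spacing scan
#' measures geometry rather than spacer content.
#'
#' @param a,b [pattern()] objects.
#' @param spacing Gap in bp between the end of `a` and the start of `b`
#'   (non-negative).
#' @param id Identifier for the composite; default
#'   `"<a>_gap<spacing>_<b>"`.
#' @return A [pattern()].
#' @export
paired_pattern <- function(a, b, spacing, id = NULL) {
  stopifnot(inherits(a, "pattern"), inherits(b, "pattern"))
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing < 0 ||
      spacing != as.integer(spacing)) {
    stop_pe("spacing must be a non-negative integer (overlapping motifs are ",
            "not supported)")
  }
  id <- id %||% paste0(a$id, "_gap", spacing, "_", b$id)
  offset_b <- nchar(a$template) + as.integer(spacing)
  pattern(
    id,
    paste0(a$template, strrep("*", spacing), b$template),
    parts = tibble(motif = c(a$id, b$id), offset = c(0L, offset_b))
  )
}

#' Read patterns from a plain-text file
#'
#' One `id<TAB>template` per line; `*` wildcards allowed.
#'
#' @param path Path to the pattern file.
#' @return List of [pattern()] objects.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2) {
      stop_pe("pattern file line ", i, ": expected id<TAB>template")
    }
    pattern(fields[1], fields[2])
  })
}

#' Generate a random sharp PWM
#'
#' Utility for building decoy panels and synthetic grammars: each position
#' puts probability `sharpness` on one uniformly chosen base and splits the
#' remainder over the others.
#'
#' @param length Motif length (bp).
#' @param seed Integer seed.
#' @param sharpness Probability mass of the dominant base per position.
#' @param name Motif name.
#' @return A [pwm()].
#' @export
random_pwm <- function(length = 8, seed = 1, sharpness = 0.85,
                       name = paste0("random", seed)) {
  m <- with_seed(seed, {
    t(vapply(seq_len(length), function(i) {
      p <- rep((1 - sharpness) / 3, 4)
      p[sample.int(4, 1)] <- sharpness
      p
    }, numeric(4)))
  })
  pwm(name, m, source = "raw")
}

#' Maximum ungapped alignment identity between two sequences
#'
#' Slides one sequence along the other (no gaps) and returns the largest
#' number of matching positions over all offsets with at least `min_overlap`
#' aligned bases. Used to verify that decoy motifs do not resemble embedded
#' motifs: a "decoy" sharing most of a true motif is not a negative control.
#'
#' @param s1,s2 Sequences (strings over A,C,G,T).
#' @param min_overlap Minimum aligned bases for an offset to count.
#' @return Integer: the maximum number of matches.
#' @export
max_alignment_identity <- function(s1, s2, min_overlap = 4) {
  a <- strsplit(toupper(s1), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(s2), "", fixed = TRUE)[[1]]
  best <- 0L
  for (off in seq(-(length(b) - min_overlap), length(a) - min_overlap)) {
    ia <- seq_len(length(a))
    ib <- ia - off
    keep <- ib >= 1 & ib <= length(b)
    if (sum(keep) < min_overlap) next
    best <- max(best, sum(a[keep] == b[ib[keep]]))
  }
  best
}

#' Column-shuffle a PWM
#'
#' Permutes the position order of a motif, preserving base composition while
#' destroying the motif; used for decoy panels. Permutations whose consensus
#' still aligns to the original consensus with more than `max_identity`
#' matching positions (at any ungapped offset) are rejected and redrawn, so
#' the shuffle cannot leave most of the motif intact.
#'
#' @param pwm A [pwm()].
#' @param seed Integer seed.
#' @param max_identity Maximum allowed consensus identity to the original
#'   (default: half the motif length).
#' @param max_tries Resampling attempts before giving up with an error.
#' @return A [pwm()] named `<name>_shuf`.
#' @export
shuffle_pwm <- function(pwm, seed = 1, max_identity = NULL, max_tries = 200) {
  stopifnot(inherits(pwm, "pwm"))
  L <- nrow(pwm$matrix)
  max_identity <- max_identity %||% floor(L / 2)
  orig <- consensus(pwm)$template
  for (k in seq_len(max_tries)) {
    perm <- with_seed(child_seed(seed, k), sample.int(L))
    if (L > 1 && all(perm == seq_len(L))) next
    cand <- pwm(paste0(pwm$name, "_shuf"), pwm$matrix[perm, , drop = FALSE],
                source = pwm$source)
    if (max_alignment_identity(consensus(cand)$template, orig) <=
        max_identity) {
      return(cand)
    }
  }
  stop_pe("could not shuffle '", pwm$name, "' below identity ", max_identity,
          " in ", max_tries, " tries (low-complexity motif?)")
}
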