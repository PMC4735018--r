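# Sequence containers, motif splitting, identity statistics, and Radar-like
# internal tandem-repeat detection.
#
# Coordinates are 0-based half-open internally; all reports/serializations
# use 1-based inclusive coordinates.

.pkg_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

#' Create a protein sequence record
#'
#' @param id record identifier
#' @param residues amino-acid string (canonical 20 letters; `X` is accepted
#'   on input only and must be resolved before analysis)
#' @param source free-text provenance tag
#' @param allow_x tolerate `X` (unknown residue) characters
#' @return an object of class `SequenceRecord`
#' @export
sequence_record <- function(id, residues, source = "", allow_x = FALSE) {
  stopifnot(is.character(id), length(id) == 1L)
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("residues must be non-empty", call. = FALSE)
  ok <- c(AA20, if (allow_x) "X")
  letters_seen <- unique(strsplit(residues, "")[[1]])
  bad <- setdiff(letters_seen, ok)
  if (length(bad)) {
    stop(sprintf("non-canonical residue letter(s) in '%s': %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(id = id, residues = residues, source = source),
            class = "SequenceRecord")
}

#' @export
print.SequenceRecord <- function(x, ...) {
  cat(sprintf("<SequenceRecord %s: %d aa%s>\n", x$id, nchar(x$residues),
              if (nzchar(x$source)) paste0(", ", x$source) else ""))
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file
#' @param source source tag applied to all records
#' @param allow_x tolerate `X` characters
#' @return list of [sequence_record()] objects
#' @export
read_fasta <- function(path, source = basename(path), allow_x = TRUE) {
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop(sprintf(
                   "malformed FASTA '%s': %s", path, conditionMessage(e)),
                   call. = FALSE))
  ids <- sub("\\s.*$", "", names(aa))
  lapply(seq_along(aa), function(i) {
    sequence_record(ids[i], as.character(aa[[i]]), source, allow_x = allow_x)
  })
}

#' Write sequence records to FASTA (wrapped at 60 columns)
#'
#' @param records list of `SequenceRecord` (or named character vector)
#' @param path output file
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    seqs <- Biostrings::AAStringSet(records)
  } else {
    if (inherits(records, "SequenceRecord")) records <- list(records)
    seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "residues"))
    names(seqs) <- vapply(records, `[[`, "", "id")
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

# Batched global-alignment identities of many queries against one subject
# (a single vectorized pairwiseAlignment call; per-call S4 dispatch is the
# dominant cost otherwise).
.pid_batch <- function(queries, subject) {
  if (!length(queries)) return(numeric(0))
  if (!all(nzchar(queries)) || !nzchar(subject)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  # matches over columns where neither sequence is gapped
  mat <- Biostrings::nmatch(pa)
  tot <- mat + Biostrings::nmismatch(pa)
  ifelse(tot == 0, 0, mat / tot)
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend 0.5);
#' identity is the fraction of matching columns among columns where neither
#' sequence carries a gap. Symmetric in its arguments.
#'
#' @param a,b amino-acid strings or `SequenceRecord`s
#' @return identity fraction in \[0, 1\]
#' @export
pairwise_identity <- function(a, b) {
  a <- if (inherits(a, "SequenceRecord")) a$residues else as.character(a)
  b <- if (inherits(b, "SequenceRecord")) b$residues else as.character(b)
  # canonical argument order: co-optimal alignments can differ between the
  # two directions, so symmetry is enforced structurally
  if (a <= b) .pid_batch(a, b) else .pid_batch(b, a)
}

.identity_matrix <- function(motifs) {
  motifs <- as.character(motifs)
  k <- length(motifs)
  m <- diag(1, k)
  for (j in seq_len(k)[-1]) {
    ids <- .pid_batch(motifs[seq_len(j - 1)], motifs[j])
    m[seq_len(j - 1), j] <- ids
    m[j, seq_len(j - 1)] <- ids
  }
  m
}

#' Average of the off-diagonal upper triangle of an identity matrix
#' @param m symmetric identity matrix
#' @export
avg_internal_identity <- function(m) {
  if (nrow(m) < 2) return(NA_real_)
  mean(m[upper.tri(m)])
}

#' Split a parent sequence into aligned tandem motifs
#'
#' @param parent a `SequenceRecord` (or amino-acid string)
#' @param boundaries integer matrix with columns `start`, `end`: 0-based
#'   half-open intervals in parent coordinates, ascending, non-overlapping
#' @return an object of class `MotifSet`: parent id, boundaries, motif
#'   subsequences, pairwise identity matrix and its off-diagonal mean
#' @export
split_motifs <- function(parent, boundaries) {
  if (!inherits(parent, "SequenceRecord")) {
    parent <- sequence_record("parent", parent)
  }
  L <- nchar(parent$residues)
  b <- matrix(as.integer(boundaries), ncol = 2)
  if (any(is.na(b)) || any(b[, 1] >= b[, 2]) || any(b[, 1] < 0) ||
      any(b[, 2] > L)) {
    stop("boundary error: intervals must be 0-based half-open within parent",
         call. = FALSE)
  }
  if (nrow(b) > 1) {
    if (any(diff(b[, 1]) <= 0) || any(b[-nrow(b), 2] > b[-1, 1])) {
      stop("boundary error: intervals must be ascending and non-overlapping",
           call. = FALSE)
    }
  }
  motifs <- substring(parent$residues, b[, 1] + 1L, b[, 2])
  im <- .identity_matrix(motifs)
  structure(list(parent_id = parent$id, boundaries = b, motifs = motifs,
                 identity_matrix = im,
                 avg_internal_identity = avg_internal_identity(im)),
            class = "MotifSet")
}

#' @export
print.MotifSet <- function(x, ...) {
  cat(sprintf("<MotifSet %s: %d motifs, avg internal identity %.3f>\n",
              x$parent_id, length(x$motifs), x$avg_internal_identity))
  invisible(x)
}

# per-period mean self-alignment (ungapped diagonal) score
.period_scores <- function(idx, periods, B) {
  L <- length(idx)
  vapply(periods, function(p) {
    n <- L - p
    if (n < 1) return(-Inf)
    sum(B[cbind(idx[seq_len(n)], idx[seq_len(n) + p])]) / n
  }, numeric(1))
}

#' Detect internal tandem repeats (Radar-like)
#'
#' Scores every candidate period by the mean BLOSUM62 score of the ungapped
#' self-alignment diagonal at that offset, picks the smallest period within
#' 95% of the best mean score, and accepts a multi-motif call only when the
#' per-motif average alignment score against the consensus motif reaches
#' 25% of the consensus self-score. A no-repeat result (`n_motifs = 1`) is
#' valid output, not an error.
#'
#' @param parent `SequenceRecord` or amino-acid string
#' @param min_period,max_period candidate period range (residues);
#'   `max_period` is capped at half the sequence length
#' @return an object of class `RepeatAnnotation`: `parent_id`, `n_motifs`,
#'   `period`, `score` and, for multi-motif calls, a `motif_set`
#' @export
detect_internal_repeats <- function(parent, min_period = 15L,
                                    max_period = 120L) {
  if (!inherits(parent, "SequenceRecord")) {
    parent <- sequence_record("parent", parent)
  }
  L <- nchar(parent$residues)
  B <- .blosum62()[AA20, AA20]
  idx <- match(strsplit(parent$residues, "")[[1]], AA20)
  none <- structure(list(parent_id = parent$id, n_motifs = 1L,
                         period = L, motif_set = NULL, score = 0),
                    class = "RepeatAnnotation")
  max_period <- min(max_period, L %/% 2L)
  if (max_period < min_period) return(none)
  periods <- seq.int(min_period, max_period)
  sc <- .period_scores(idx, periods, B)
  best <- max(sc)
  if (!is.finite(best) || best <= 0) return(none)
  # smallest period within 80% of the best mean score: harmonics of the true
  # period score equally in expectation but on fewer aligned positions, so
  # the fundamental is preferred whenever it is competitive
  p <- periods[which(sc >= 0.8 * best)[1]]
  k <- L %/% p
  if (k < 2) return(none)
  b <- cbind(p * (seq_len(k) - 1L), p * seq_len(k))
  chunks <- substring(parent$residues, b[, 1] + 1L, b[, 2])
  # consensus = per-column modal residue; ties by alphabetical order
  cm <- do.call(rbind, strsplit(chunks, ""))
  consensus <- apply(cm, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1]
  })
  ci <- match(consensus, AA20)
  self_score <- sum(B[cbind(ci, ci)])
  motif_scores <- apply(cm, 1, function(row) sum(B[cbind(match(row, AA20), ci)]))
  if (mean(motif_scores) < 0.25 * self_score) return(none)
  ms <- split_motifs(parent, b)
  structure(list(parent_id = parent$id, n_motifs = k, period = p,
                 motif_set = ms, score = sc[match(p, periods)] * (L - p)),
            class = "RepeatAnnotation")
}

#' @export
print.RepeatAnnotation <- function(x, ...) {
  cat(sprintf("<RepeatAnnotation %s: %d motif(s), period %d>\n",
              x$parent_id, x$n_motifs, x$period))
  invisible(x)
}

#' Filter repeat annotations by average internal identity
#'
#' Keeps annotations with at least 4 motifs and average internal identity at
#' or above the threshold (inclusive bound).
#'
#' @param annotations list of `RepeatAnnotation`
#' @param threshold identity fraction in \[0, 1\]
#' @export
filter_by_internal_identity <- function(annotations, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- vapply(annotations, function(a) {
    a$n_motifs >= 4L && !is.null(a$motif_set) &&
      a$motif_set$avg_internal_identity >= threshold
  }, logical(1))
  annotations[keep]
}

#' Serialize repeat annotations to TSV (1-based inclusive coordinates)
#'
#' @param annotations list of `RepeatAnnotation`
#' @param path output TSV path (optional)
#' @return the table, invisibly if written
#' @export
annotations_to_tsv <- function(annotations, path = NULL) {
  df <- do.call(rbind, lapply(annotations, function(a) {
    bnd <- if (is.null(a$motif_set)) "" else
      paste(sprintf("%d-%d", a$motif_set$boundaries[, 1] + 1L,
                    a$motif_set$boundaries[, 2]), collapse = ";")
    data.frame(parent_id = a$parent_id, n_motifs = a$n_motifs,
               period = a$period,
               avg_internal_identity = if (is.null(a$motif_set)) NA_real_
                 else a$motif_set$avg_internal_identity,
               boundaries = bnd, stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
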