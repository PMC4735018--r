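# Construct design: permutation frames, combinatorial ancestral libraries,
# tandem fusions, frame interconversion, and error-prone mutant libraries.

#' Create a permutation frame
#'
#' A frame places the motif boundary either at the extant Velcro closure
#' (`"V"`) or at an intact structural blade (`"B"`), the latter with an
#' end-polishing offset of up to +/-2 residues around the canonical blade
#' boundary.
#'
#' @param topology `"V"` or `"B"`
#' @param polish_offset integer in \[-2, 2\]; must be 0 for V frames
#' @export
permutation_frame <- function(topology, polish_offset = 0L) {
  topology <- match.arg(topology, c("V", "B"))
  polish_offset <- as.integer(polish_offset)
  if (topology == "V" && polish_offset != 0L) {
    stop("V frame has no polish offset", call. = FALSE)
  }
  if (abs(polish_offset) > 2L) {
    stop("polish offset must lie in [-2, 2]", call. = FALSE)
  }
  structure(list(topology = topology, polish_offset = polish_offset),
            class = "PermutationFrame")
}

#' @export
print.PermutationFrame <- function(x, ...) {
  cat(sprintf("<frame %s>\n", frame_label(x)))
  invisible(x)
}

#' Short label for a frame ("V", "B", "B+1", "B-2", ...)
#' @param frame a `PermutationFrame`
#' @export
frame_label <- function(frame) {
  if (frame$topology == "V") return("V")
  if (frame$polish_offset == 0L) return("B")
  sprintf("B%+d", frame$polish_offset)
}

#' Enumerate permutation frames
#'
#' One Velcro frame plus `2 * polish_range + 1` intact-blade frames; with the
#' default end polishing of +/-2 residues this yields exactly six frames.
#'
#' @param motif_length motif length in residues (must exceed
#'   `2 * polish_range`)
#' @param blade_shift canonical rotation (residues) that moves the permuted
#'   strand to the front; recorded for downstream [apply_frame()] calls
#' @param polish_range end-polishing half-width in residues (>= 0)
#' @return list of `PermutationFrame`s, V first, then B by ascending offset
#' @export
enumerate_frames <- function(motif_length, blade_shift = 12L,
                             polish_range = 2L) {
  if (polish_range < 0) stop("polish_range must be >= 0", call. = FALSE)
  if (motif_length <= 2 * polish_range) {
    stop("motif_length must exceed 2 * polish_range", call. = FALSE)
  }
  offs <- seq.int(-polish_range, polish_range)
  frames <- c(list(permutation_frame("V")),
              lapply(offs, function(o) permutation_frame("B", o)))
  attr(frames, "blade_shift") <- as.integer(blade_shift)
  frames
}

#' Apply a permutation frame to a motif
#'
#' B frames circularly rotate the motif left by
#' `blade_shift + polish_offset` residues (the genetic
#' expansion-then-truncation that moves the boundary onto an intact blade);
#' the V frame is the identity. Length is preserved.
#'
#' @param motif amino-acid string
#' @param frame a `PermutationFrame`
#' @param blade_shift canonical blade rotation in residues
#' @export
apply_frame <- function(motif, frame, blade_shift = 12L) {
  motif <- if (inherits(motif, "SequenceRecord")) motif$residues
           else as.character(motif)
  L <- nchar(motif)
  if (frame$topology == "V") return(motif)
  shift <- blade_shift + frame$polish_offset
  if (abs(shift) >= L) stop("rotation out of range", call. = FALSE)
  r <- ((shift %% L) + L) %% L
  if (r == 0) return(motif)
  paste0(substr(motif, r + 1L, L), substr(motif, 1L, r))
}

#' Combinatorial ancestral substitution library
#'
#' For each position, alternative residues are those whose root posterior
#' strictly exceeds `cutoff` and that differ from the MPA residue. The
#' library size is `|frames| * prod(1 + k_i)` over per-position alternative
#' counts `k_i`.
#'
#' @param posterior an `AncestralPosterior`
#' @param cutoff posterior probability cutoff in (0, 1\]; strict inequality
#' @param frames list of `PermutationFrame`s (e.g. [enumerate_frames()])
#' @return object of class `VariantLibrary`
#' @export
enumerate_library <- function(posterior, cutoff, frames) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("cutoff must lie in (0, 1]", call. = FALSE)
  }
  post <- posterior$posterior
  mpa <- strsplit(posterior$mpa, "")[[1]]
  alts <- lapply(seq_len(ncol(post)), function(j) {
    r <- rownames(post)[post[, j] > cutoff]
    sort(setdiff(r, mpa[j]))
  })
  names(alts) <- seq_len(ncol(post))
  alts <- alts[vapply(alts, length, 1L) > 0]
  n_variants <- length(frames) * prod(1 + vapply(alts, length, 1L))
  structure(list(base = posterior$mpa, alternatives = alts, frames = frames,
                 cutoff = cutoff, n_variants = n_variants),
            class = "VariantLibrary")
}

#' @export
print.VariantLibrary <- function(x, ...) {
  cat(sprintf(
    "<VariantLibrary: %d substitutions at %d positions, %d frame(s), %g variants>\n",
    sum(lengths(x$alternatives)), length(x$alternatives),
    length(x$frames), x$n_variants))
  invisible(x)
}

#' Enumerate every variant of a library
#'
#' Deterministic order: frames in list order (V first, then B by offset when
#' built by [enumerate_frames()]); within a frame, substitution combinations
#' in dictionary order with positions ascending and residues alphabetical
#' (MPA residue first at each position).
#'
#' @param library a `VariantLibrary`
#' @param blade_shift rotation used for B frames
#' @param limit refuse enumeration above this many variants
#' @param base_name prefix for variant names
#' @return data.frame with `name` and `sequence`
#' @export
enumerate_variants <- function(library, blade_shift = 12L, limit = 1e5,
                               base_name = "Anc_1") {
  if (library$n_variants > limit) {
    stop(sprintf("library has %g variants, above the cap of %g",
                 library$n_variants, limit), call. = FALSE)
  }
  base <- strsplit(library$base, "")[[1]]
  pos <- as.integer(names(library$alternatives))
  opts <- lapply(seq_along(pos), function(i) {
    c(base[pos[i]], library$alternatives[[i]])
  })
  if (length(opts)) {
    grid <- do.call(expand.grid,
                    c(rev(opts), list(stringsAsFactors = FALSE)))
    grid <- grid[, rev(seq_along(opts)), drop = FALSE]  # pos 1 most significant
  } else {
    grid <- data.frame(row.names = 1)
  }
  out <- vector("list", length(library$frames))
  for (fi in seq_along(library$frames)) {
    fr <- library$frames[[fi]]
    seqs <- character(nrow(grid)); nm <- character(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      v <- base
      subs <- character(0)
      for (i in seq_along(pos)) {
        res <- grid[g, i]
        if (res != base[pos[i]]) {
          subs <- c(subs, sprintf("%s%d%s", base[pos[i]], pos[i], res))
        }
        v[pos[i]] <- res
      }
      seqs[g] <- apply_frame(paste(v, collapse = ""), fr, blade_shift)
      nm[g] <- paste(c(paste0(base_name, frame_label(fr)), subs),
                     collapse = "+")
    }
    out[[fi]] <- data.frame(name = nm, sequence = seqs,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Duplicate a motif and fuse the copies head-to-tail
#'
#' @param motif amino-acid string (or `SequenceRecord`)
#' @param n number of tandem repeats (>= 1); no linker is inserted
#' @param name construct name; default follows the `<base>_<n><frame>`
#'   nomenclature
#' @param frame the `PermutationFrame` the motif is already in
#' @param base_name stem used when `name` is NULL
#' @return object of class `ConstructSpec`
#' @export
tandem_fuse <- function(motif, n, name = NULL,
                        frame = permutation_frame("V"), base_name = "Anc") {
  motif <- if (inherits(motif, "SequenceRecord")) motif$residues
           else as.character(motif)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (is.null(name)) name <- sprintf("%s_%d%s", base_name, n, frame_label(frame))
  structure(list(name = name, motifs = rep(motif, n), n_repeats = n,
                 frame = frame),
            class = "ConstructSpec")
}

#' Emit the protein sequence of a construct
#' @param spec a `ConstructSpec`
#' @export
construct_protein <- function(spec) paste(spec$motifs, collapse = "")

#' @export
print.ConstructSpec <- function(x, ...) {
  cat(sprintf("<ConstructSpec %s: %d x %d aa, frame %s>\n", x$name,
              x$n_repeats, nchar(x$motifs[1]), frame_label(x$frame)))
  invisible(x)
}

#' Interconvert a construct between permutation frames
#'
#' Models the genetic route of frame interconversion: one motif copy is
#' appended (motif expansion, e.g. a five-motif protein passing through a
#' six-motif intermediate) and new start/stop positions then truncate the
#' expanded gene back to the original motif count in the target frame. The
#' intermediate construct is recorded as an attribute.
#'
#' @param spec a `ConstructSpec` with identical repeats
#' @param target_frame the destination `PermutationFrame`
#' @param blade_shift canonical blade rotation in residues
#' @return the permuted `ConstructSpec`, with `attr(, "intermediate")`
#' @export
permute_construct <- function(spec, target_frame, blade_shift = 12L) {
  if (length(unique(spec$motifs)) != 1L) {
    stop("frame interconversion requires identical repeats", call. = FALSE)
  }
  cur <- spec$frame
  if (identical(cur$topology, target_frame$topology) &&
      identical(cur$polish_offset, target_frame$polish_offset)) {
    warning("construct already in the target frame; no-op")
    return(spec)
  }
  motif <- spec$motifs[1]
  base <- sub("_.*$", "", spec$name)
  intermediate <- tandem_fuse(motif, spec$n_repeats + 1L,
                              name = sprintf("%s_%d%s", base,
                                             spec$n_repeats + 1L,
                                             frame_label(cur)),
                              frame = cur)
  shift_of <- function(fr) {
    if (fr$topology == "V") 0L else blade_shift + fr$polish_offset
  }
  delta <- shift_of(target_frame) - shift_of(cur)
  rot <- permutation_frame("B", 0L)   # carrier for a raw rotation
  L <- nchar(motif)
  new_motif <- apply_frame(motif, rot, blade_shift = ((delta %% L) + L) %% L)
  out <- tandem_fuse(new_motif, spec$n_repeats,
                     name = sprintf("%s_%d%s", base, spec$n_repeats,
                                    frame_label(target_frame)),
                     frame = target_frame)
  attr(out, "intermediate") <- intermediate
  out
}

#' Error-prone mutant library (protein level)
#'
#' Per-clone mutation counts are Poisson(`rate`); mutated positions are
#' drawn uniformly without replacement and each substituted residue
#' uniformly from the 19 alternatives. Reproducible under `seed`.
#'
#' @param seq template amino-acid string
#' @param rate mean mutations per sequence (>= 0)
#' @param n_clones number of clones
#' @param seed RNG seed
#' @return character vector of mutant sequences, named clone1..cloneN
#' @export
mutagenize <- function(seq, rate, n_clones, seed) {
  seq <- if (inherits(seq, "SequenceRecord")) seq$residues
         else as.character(seq)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  set.seed(seed)
  L <- nchar(seq)
  tmpl <- strsplit(seq, "")[[1]]
  counts <- pmin(stats::rpois(n_clones, rate), L)
  out <- vapply(seq_len(n_clones), function(i) {
    k <- counts[i]
    if (k == 0) return(seq)
    v <- tmpl
    posns <- sample.int(L, k)
    for (p in posns) v[p] <- sample(setdiff(AA20, v[p]), 1L)
    paste(v, collapse = "")
  }, character(1))
  names(out) <- paste0("clone", seq_len(n_clones))
  attr(out, "n_mutations") <- counts
  out
}
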