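# Workflow orchestration: the reconstruction/design chain and the genomic
# clock chain, with standard-format outputs (FASTA, Newick, TSV, JSON).

.ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

.log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

#' Run the ancestral-reconstruction workflow
#'
#' Chains repeat detection, motif splitting, progressive alignment,
#' neighbor-joining tree building, and marginal root-posterior inference
#' over one or more repeat proteins, and writes the posterior table, MPA
#' FASTA, Newick tree, and a run log.
#'
#' @param records list of `SequenceRecord`s (or a FASTA path)
#' @param outdir output directory (NULL: nothing written)
#' @param model substitution model id
#' @param min_period,max_period repeat-detection period range
#' @return the `AncestralPosterior` (invisibly carries the tree)
#' @export
run_reconstruct <- function(records, outdir = NULL, model = "jtt",
                            min_period = 15L, max_period = 120L) {
  if (is.character(records)) records <- read_fasta(records)
  if (inherits(records, "SequenceRecord")) records <- list(records)
  logcon <- NULL
  if (!is.null(outdir)) {
    .ensure_dir(outdir)
    logcon <- file(file.path(outdir, "reconstruct.log"), "w")
    on.exit(close(logcon))
  }
  motifs <- character(0)
  for (rec in records) {
    ann <- detect_internal_repeats(rec, min_period, max_period)
    if (ann$n_motifs < 2L) {
      stop(sprintf("no internal repeats detectable in '%s'", rec$id),
           call. = FALSE)
    }
    .log_line(logcon, "%s: %d motifs, period %d, internal identity %.1f%%",
              rec$id, ann$n_motifs, ann$period,
              100 * ann$motif_set$avg_internal_identity)
    mots <- ann$motif_set$motifs
    names(mots) <- sprintf("%s_m%d", rec$id, seq_along(mots))
    motifs <- c(motifs, mots)
  }
  aln <- align_motifs(motifs)
  tree <- build_tree(aln, model)
  post <- root_posteriors(aln, tree, model)
  .log_line(logcon, "%d-leaf tree, %d posterior positions, logLik %.2f",
            length(tree$tip.label), post$n_positions, post$loglik)
  if (!is.null(outdir)) {
    posterior_to_tsv(post, file.path(outdir, "root_posterior.tsv"))
    write_fasta(stats::setNames(post$mpa, "MPA"),
                file.path(outdir, "mpa.fasta"))
    ape::write.tree(post$tree, file.path(outdir, "motif_tree.nwk"))
  }
  invisible(post)
}

#' Run the library/construct design workflow
#'
#' Enumerates permutation frames and the combinatorial substitution library
#' over the posterior, optionally emits the tandem-fusion /
#' frame-interconversion trajectory constructs, and writes a variant FASTA
#' plus a TSV manifest. Libraries above `cap` variants are refused in full
#' and a seeded sample is emitted instead.
#'
#' @param posterior an `AncestralPosterior`
#' @param outdir output directory (NULL: nothing written)
#' @param cutoff library probability cutoff (strict; first round 0.25,
#'   second round 0.1)
#' @param blade_shift,polish_range frame parameters (residues)
#' @param trajectory logical: also emit the single-motif -> 5B -> 6B -> 5V
#'   construct series from the MPA
#' @param cap refuse full enumeration above this library size
#' @param seed seed for the fallback sample
#' @return list with `library`, `variants` (data.frame), and `constructs`
#' @export
run_design <- function(posterior, outdir = NULL, cutoff = 0.25,
                       blade_shift = 12L, polish_range = 2L,
                       trajectory = TRUE, cap = 1e5, seed = 1L) {
  frames <- enumerate_frames(posterior$n_positions, blade_shift, polish_range)
  lib <- enumerate_library(posterior, cutoff, frames)
  if (lib$n_variants <= cap) {
    variants <- enumerate_variants(lib, blade_shift, limit = cap)
  } else {
    warning(sprintf(
      "library of %g variants exceeds cap %g; emitting a seeded sample",
      lib$n_variants, cap))
    set.seed(seed)
    small <- lib
    small$frames <- lib$frames[sample.int(length(lib$frames), 1L)]
    variants <- enumerate_variants(small, blade_shift, limit = cap)
    variants <- variants[sample.int(nrow(variants),
                                    min(nrow(variants), cap)), ]
  }
  constructs <- list()
  if (trajectory) {
    bframe <- permutation_frame("B", 0L)
    m1b <- apply_frame(posterior$mpa, bframe, blade_shift)
    c1b <- tandem_fuse(m1b, 1L, frame = bframe)
    c5b <- tandem_fuse(m1b, 5L, frame = bframe)
    c5v <- permute_construct(c5b, permutation_frame("V"), blade_shift)
    constructs <- list(c1b, c5b, attr(c5v, "intermediate"), c5v)
  }
  if (!is.null(outdir)) {
    .ensure_dir(outdir)
    write_fasta(stats::setNames(variants$sequence, variants$name),
                file.path(outdir, "library.fasta"))
    utils::write.table(
      data.frame(name = variants$name, length = nchar(variants$sequence),
                 n_variants_total = lib$n_variants),
      file.path(outdir, "library_manifest.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(constructs)) {
      write_fasta(stats::setNames(
        vapply(constructs, construct_protein, character(1)),
        vapply(constructs, `[[`, "", "name")),
        file.path(outdir, "constructs.fasta"))
    }
  }
  list(library = lib, variants = variants, constructs = constructs)
}

#' Run the genomic scan and molecular-clock workflow
#'
#' Scans a proteome for internally repetitive propellers, searches for
#' single-motif relatives, computes clock statistics against the
#' single-motif protein hit by most propellers, and runs the
#' directionality test. Writes the hits table, clock points TSV, and a
#' correlation summary JSON.
#'
#' @param proteome list of `SequenceRecord`s (or FASTA path)
#' @param outdir output directory (NULL: nothing written)
#' @param identity_threshold internal-identity retention threshold
#' @param evalue_cutoff homology-search expectation cutoff
#' @param min_period,max_period repeat-detection period range
#' @param seed seed for the directionality null
#' @return list with `propellers`, `hits`, `clock`, `directionality`
#'   (clock entries NULL with a diagnostic when no single-motif hits exist)
#' @export
run_scan_clock <- function(proteome, outdir = NULL, identity_threshold = 0.5,
                           evalue_cutoff = 1e-3, min_period = 15L,
                           max_period = 120L, seed = 1L) {
  if (is.character(proteome)) proteome <- read_fasta(proteome)
  annotations <- lapply(proteome, detect_internal_repeats,
                        min_period = min_period, max_period = max_period)
  props <- filter_by_internal_identity(annotations, identity_threshold)
  if (!length(props)) {
    message("no internally repetitive propellers retained; clock skipped")
    return(list(propellers = list(), hits = NULL, clock = NULL,
                directionality = NULL))
  }
  hits <- do.call(rbind, lapply(props, find_single_motifs, proteome = proteome,
                                evalue_cutoff = evalue_cutoff,
                                annotations = annotations))
  if (is.null(hits) || !nrow(hits)) {
    message("no single-motif relatives at the e-value cutoff; clock skipped")
    return(list(propellers = props, hits = hits, clock = NULL,
                directionality = NULL))
  }
  top_subject <- names(sort(table(hits$subject_id), decreasing = TRUE))[1]
  single <- proteome[[match(top_subject,
                            vapply(proteome, `[[`, "", "id"))]]
  clock <- clock_statistics(props, single)
  dir_res <- if (nrow(clock$points) >= 3) {
    directionality_test(clock$points,
                        motif_length = props[[1]]$period, seed = seed)
  } else NULL
  if (!is.null(outdir)) {
    .ensure_dir(outdir)
    utils::write.table(hits, file.path(outdir, "single_motif_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    clock_points_to_tsv(clock$points, file.path(outdir, "clock_points.tsv"))
    jsonlite::write_json(
      list(single_motif = top_subject,
           correlation = clock$correlation,
           directionality = if (!is.null(dir_res))
             list(verdict = dir_res$verdict,
                  avg_slope = dir_res$avg_slope,
                  max_slope = dir_res$max_slope)),
      file.path(outdir, "clock_summary.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(propellers = props, hits = hits, clock = clock,
       directionality = dir_res, single_motif_id = top_subject)
}
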