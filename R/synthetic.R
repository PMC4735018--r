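# Ground-truthed simulators: duplication-fusion-divergence sequence
# families, synthetic proteomes with decoys, and noisy biophysical curves.
# Every generator is a pure function of its seed and spec.

.evolve_seq <- function(idx, t, model) {
  P <- transition_probs(t, model)
  vapply(idx, function(r) sample.int(20L, 1L, prob = P[r, ]), integer(1))
}

.idx_to_seq <- function(idx) paste(AA20[idx], collapse = "")

#' Simulate a duplication-fusion-divergence propeller family
#'
#' Draws a random ancestor motif from the model's stationary frequencies.
#' Each propeller descends from the ancestor through a short founder branch
#' (`trunk`), is tandem-fused from `k` motif copies at birth, and every
#' motif then diverges independently for the propeller's age (drawn
#' log-uniformly over `age_range`, so the clock plot is populated evenly
#' across divergences). A single-motif protein is also emitted: under
#' scenario `"A"` (motif-first, the default) it evolves directly from the
#' ancestor for `single_motif_age`; under scenario `"B"` (co-option) it is
#' copied from the first repeat of the first propeller and evolves only
#' briefly, so that one repeat resembles it disproportionately. The full
#' truth — boundaries, ages, and the motif tree — is recorded.
#'
#' @param ancestor_length motif length in residues (default 47)
#' @param n_propellers number of propellers
#' @param motif_counts candidate motif counts per propeller (default 5:7)
#' @param age_range range of per-propeller ages, substitutions/site
#' @param model substitution model id
#' @param seed RNG seed
#' @param scenario `"A"` (motif-first) or `"B"` (co-option)
#' @param trunk founder branch length per propeller (subs/site)
#' @param single_motif_age divergence of the single-motif protein
#' @param indel_rate per-motif probability of one short indel (geometric
#'   length, capped at 3 residues); 0 by default, used for repeat-detection
#'   and alignment stress tests
#' @return object of class `SimFamily`: `ancestor_motif`, `propellers`
#'   (SequenceRecords with true `boundaries`, `age`, `n_motifs`),
#'   `single_motif` record, `true_tree` (phylo), and the event table
#' @export
simulate_family <- function(ancestor_length = 47L, n_propellers = 11L,
                            motif_counts = 5:7, age_range = c(0.1, 1.5),
                            model = "jtt", seed = 1L, scenario = c("A", "B"),
                            trunk = 0.05, single_motif_age = 0.05,
                            indel_rate = 0) {
  scenario <- match.arg(scenario)
  stopifnot(all(age_range > 0))
  mod <- substitution_model(model)
  set.seed(seed)
  anc <- sample.int(20L, ancestor_length, replace = TRUE, prob = mod$pi)
  ages <- exp(stats::runif(n_propellers, log(min(age_range)),
                           log(max(age_range))))
  ks <- rep(motif_counts, length.out = n_propellers)
  ks <- ks[sample.int(length(ks))]
  propellers <- vector("list", n_propellers)
  motif_idx <- vector("list", n_propellers)
  newick_parts <- character(n_propellers)
  for (i in seq_len(n_propellers)) {
    founder <- .evolve_seq(anc, trunk, mod)
    k <- ks[i]
    motifs <- lapply(seq_len(k), function(j) .evolve_seq(founder, ages[i], mod))
    motif_idx[[i]] <- motifs
    seqs <- vapply(motifs, .idx_to_seq, character(1))
    if (indel_rate > 0) {
      seqs <- vapply(seqs, function(sq) {
        if (stats::runif(1) >= indel_rate) return(sq)
        len <- min(stats::rgeom(1, 0.5) + 1L, 3L)
        v <- strsplit(sq, "")[[1]]
        if (stats::runif(1) < 0.5 && length(v) > len + 1) {    # deletion
          at <- sample.int(length(v) - len, 1L)
          v <- v[-(at:(at + len - 1L))]
        } else {                                               # insertion
          at <- sample.int(length(v), 1L)
          ins <- sample(AA20, len, replace = TRUE, prob = mod$pi)
          v <- append(v, ins, after = at)
        }
        paste(v, collapse = "")
      }, character(1))
    }
    ends <- unname(cumsum(nchar(seqs)))
    b <- cbind(c(0L, ends[-k]), ends, deparse.level = 0)
    rec <- sequence_record(sprintf("prop%02d", i), paste(seqs, collapse = ""),
                           source = "simulate_family")
    rec$boundaries <- b
    rec$age <- ages[i]
    rec$n_motifs <- k
    propellers[[i]] <- rec
    newick_parts[i] <- sprintf("(%s):%f",
                               paste(sprintf("prop%02d_m%d:%f", i,
                                             seq_len(k), ages[i]),
                                     collapse = ","), trunk)
  }
  if (scenario == "A") {
    single_idx <- .evolve_seq(anc, single_motif_age, mod)
    single_src <- "ancestor"
  } else {
    single_idx <- .evolve_seq(motif_idx[[1]][[1]], single_motif_age, mod)
    single_src <- "prop01_m1"
  }
  single <- sequence_record("single_motif", .idx_to_seq(single_idx),
                            source = sprintf("simulate_family:%s", single_src))
  tree <- ape::read.tree(text = sprintf("(%s,single_motif:%f);",
                                        paste(newick_parts, collapse = ","),
                                        single_motif_age))
  structure(list(ancestor_motif = .idx_to_seq(anc), propellers = propellers,
                 single_motif = single, true_tree = tree,
                 events = data.frame(propeller = vapply(propellers, `[[`,
                                                        "", "id"),
                                     n_motifs = ks, age = ages,
                                     trunk = trunk),
                 scenario = scenario, model = mod$id, seed = seed),
            class = "SimFamily")
}

#' @export
print.SimFamily <- function(x, ...) {
  cat(sprintf("<SimFamily: %d propellers, scenario %s, seed %d>\n",
              length(x$propellers), x$scenario, x$seed))
  invisible(x)
}

#' Repeat annotations from a simulated family's recorded truth
#'
#' Builds `RepeatAnnotation` objects directly from the true motif
#' boundaries the simulator recorded, bypassing detection — the ground
#' truth against which detection and downstream statistics are judged.
#'
#' @param family a `SimFamily`
#' @return list of `RepeatAnnotation`s
#' @export
family_annotations <- function(family) {
  lapply(family$propellers, function(p) {
    ms <- split_motifs(p, p$boundaries)
    structure(list(parent_id = p$id, n_motifs = p$n_motifs,
                   period = nchar(ms$motifs[1]), motif_set = ms,
                   score = NA_real_),
              class = "RepeatAnnotation")
  })
}

#' Embed a simulated family in a decoy proteome
#'
#' Decoys are composition-matched: residues are drawn from the pooled
#' family composition, with lengths uniform over `decoy_length_range`.
#' Planted sequences are interleaved at seeded positions; a truth manifest
#' records what sits where.
#'
#' @param family a `SimFamily`
#' @param n_decoys number of decoy proteins (>= 0)
#' @param decoy_length_range min/max decoy length
#' @param seed RNG seed
#' @return list with `proteome` (SequenceRecord list) and `manifest`
#'   (data.frame: id, type, position)
#' @export
simulate_proteome <- function(family, n_decoys = 50L,
                              decoy_length_range = c(60L, 400L), seed = 1L) {
  stopifnot(n_decoys >= 0)
  set.seed(seed)
  planted <- c(family$propellers, list(family$single_motif))
  pool <- strsplit(paste(c(vapply(family$propellers, `[[`, "", "residues"),
                           family$single_motif$residues), collapse = ""),
                   "")[[1]]
  decoys <- lapply(seq_len(n_decoys), function(i) {
    L <- sample(seq.int(decoy_length_range[1], decoy_length_range[2]), 1L)
    sequence_record(sprintf("decoy%03d", i),
                    paste(sample(pool, L, replace = TRUE), collapse = ""),
                    source = "simulate_proteome")
  })
  all_recs <- c(planted, decoys)
  ord <- sample(seq_along(all_recs))
  proteome <- all_recs[ord]
  manifest <- data.frame(
    id = vapply(proteome, `[[`, "", "id"),
    type = ifelse(grepl("^decoy", vapply(proteome, `[[`, "", "id")), "decoy",
                  ifelse(vapply(proteome, `[[`, "", "id") == "single_motif",
                         "single_motif", "propeller")),
    position = seq_along(proteome), stringsAsFactors = FALSE)
  list(proteome = proteome, manifest = manifest)
}

#' Simulate a noisy biophysical curve
#'
#' Evaluates the requested model exactly and adds Gaussian noise of
#' standard deviation `noise_sd`; byte-reproducible under `seed`.
#'
#' @param spec list with `model` (one of `"two_state"`, `"three_state"`,
#'   `"melt"`, `"calibration"`), `params` (named list for the matching
#'   signal function), `noise_sd`, `n_points`, `x_range`, `seed`
#' @return for unfolding/melt models a [denaturation_dataset()]; for
#'   calibration a data.frame with `x`, `y` (x log-spaced)
#' @export
simulate_curve <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$model))
  noise_sd <- spec$noise_sd %||% 0
  n <- spec$n_points %||% 61L
  stopifnot(noise_sd >= 0, n >= 10)
  p <- spec$params
  if (spec$model %in% c("two_state", "three_state", "melt")) {
    xr <- spec$x_range %||% switch(spec$model, melt = c(25, 95), c(0, 6))
    x <- seq(xr[1], xr[2], length.out = n)
    y0 <- switch(spec$model,
      two_state = two_state_signal(x, p$Cm, p$m, p$aN, p$bN, p$aD, p$bD),
      three_state = three_state_signal(x, p$Cm1, p$m1, p$Cm2, p$m2,
                                       p$aN, p$bN, p$aI, p$aD, p$bD),
      melt = melt_signal(x, p$Tm, p$w, p$aN, p$bN, p$aD, p$bD))
    if (!is.null(spec$seed)) set.seed(spec$seed)
    y <- y0 + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    denaturation_dataset(x, y,
                         mode = if (spec$model == "melt") "thermal"
                                else "chemical",
                         ligand_present = isTRUE(spec$ligand_present),
                         protein_conc = spec$protein_conc %||% 0.5)
  } else if (spec$model == "calibration") {
    xr <- spec$x_range %||% c(0.05, 100)
    x <- exp(seq(log(xr[1]), log(xr[2]), length.out = n))
    y0 <- calibration_signal(x, p)
    if (!is.null(spec$seed)) set.seed(spec$seed)
    y <- y0 + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    data.frame(x = x, y = y)
  } else {
    stop(sprintf("unknown curve model tag: '%s'", spec$model), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical three-state unfolding curve spec
#'
#' The package's reference conditions for simulated chemical-denaturation
#' equilibria of tandem-fusion propellers: first midpoint 2.2 M GdmCl,
#' cooperative transitions (apparent m = 6 kcal/mol/M each), a
#' spectroscopically distinct intermediate (fluorescence above the native
#' baseline), a dense 0-6 M gradient (181 points), and Gaussian noise of 1%
#' of the noiseless signal range. Closely spaced inflections (sub-molar
#' `delta_Cm`) are only identifiable under conditions like these; see the
#' methods vignette.
#'
#' @param delta_Cm inter-inflection interval Cm2 - Cm1 (M GdmCl)
#' @param seed RNG seed
#' @param n_points gradient points
#' @param noise_frac noise SD as a fraction of the signal range
#' @return a spec list for [simulate_curve()]
#' @export
unfolding_curve_spec <- function(delta_Cm, seed = 1L, n_points = 181L,
                                 noise_frac = 0.01) {
  params <- list(Cm1 = 2.2, m1 = 6, Cm2 = 2.2 + delta_Cm, m2 = 6,
                 aN = 1, bN = -0.02, aI = 1.3, aD = 0.1, bD = 0.005)
  x <- seq(0, 6, length.out = n_points)
  y0 <- three_state_signal(x, params$Cm1, params$m1, params$Cm2, params$m2,
                           params$aN, params$bN, params$aI, params$aD,
                           params$bD)
  list(model = "three_state", params = params,
       noise_sd = noise_frac * diff(range(y0)), n_points = n_points,
       x_range = c(0, 6), seed = seed)
}

#' Mechanistic toy model of folding yield vs concentration
#'
#' Oligomer: productive assembly scales with concentration while
#' intermolecular misfolding scales with its square, giving a bell-shaped
#' normalized yield. Monomer: misfolding scales linearly with
#' concentration, giving a monotone decrease.
#'
#' @param conc concentrations (uM)
#' @param mode `"oligomer"` or `"monomer"`
#' @param k_assembly,k_misfold rate-like constants of the toy model
#' @return yields normalized to a maximum of 1
#' @export
folding_yield_curve <- function(conc, mode = c("oligomer", "monomer"),
                                k_assembly = 1, k_misfold = 0.05) {
  mode <- match.arg(mode)
  y <- switch(mode,
    oligomer = (k_assembly * conc) / (1 + k_assembly * conc +
                                        k_misfold * conc^2),
    monomer = 1 / (1 + k_misfold * conc))
  y / max(y)
}
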