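#!/usr/bin/env Rscript
# Stage 3 — design ancestral libraries and permutation constructs.
#
# From the stage-2 posterior: enumerate the six permutation frames (Velcro
# plus five end-polished intact-blade rotations), build the combinatorial
# substitution libraries at the first-round (>0.25) and second-round
# (>0.1) posterior cutoffs, emit the tandem-fusion trajectory
# (1B -> 5B -> 6B -> 5V), and draw an error-prone mutant library at 1.6
# mutations per motif.

suppressPackageStartupMessages(library(propevo))

records <- read_fasta("results/sim/family.fasta")
ids <- vapply(records, function(r) {
  ann <- detect_internal_repeats(r)
  if (is.null(ann$motif_set)) 0 else ann$motif_set$avg_internal_identity
}, numeric(1))
post <- run_reconstruct(records[order(ids, decreasing = TRUE)[1:2]])

outdir <- "results/design"
first <- run_design(post, outdir = outdir, cutoff = 0.25, seed = 1L)
second <- run_design(post, outdir = NULL, cutoff = 0.10, seed = 1L)

cat(sprintf("first-round library (cutoff 0.25): %d substitutions at %d positions, %g variants over %d frames\n",
            sum(lengths(first$library$alternatives)),
            length(first$library$alternatives),
            first$library$n_variants, length(first$library$frames)))
cat(sprintf("second-round library (cutoff 0.10): %g variants\n",
            second$library$n_variants))
cat(sprintf("trajectory constructs: %s (lengths %s)\n",
            paste(vapply(first$constructs, `[[`, "", "name"),
                  collapse = ", "),
            paste(vapply(first$constructs, function(cs)
              nchar(construct_protein(cs)), numeric(1)), collapse = ", ")))

mut <- mutagenize(post$mpa, rate = 1.6, n_clones = 500, seed = 2L)
write_fasta(mut, file.path(outdir, "errorprone_library.fasta"))
cat(sprintf("error-prone library: 500 clones, mean %.2f mutations/motif\n",
            mean(attr(mut, "n_mutations"))))

cat(paste("note: under matched-model simulation the root posterior is far",
          "less ambiguous than real-data reconstructions (which face model",
          "misspecification and alignment uncertainty), so combinatorial",
          "libraries here are small; the count identity",
          "|frames| x prod(1 + k_i) is what the machinery guarantees\n"))
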