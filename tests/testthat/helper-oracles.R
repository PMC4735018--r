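# Independent oracles and small fixture builders used across the suite.

# Brute-force phylogenetic likelihood: enumerate every assignment of states
# to internal nodes and sum products of transition probabilities. Only
# feasible for <= 4 leaves; deliberately independent of the pruning code.
brute_loglik <- function(tree, rows, model = "jtt") {
  mod <- propevo::substitution_model(model)
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)),
              function(k) propevo::transition_probs(tree$edge.length[k], mod))
  cols <- do.call(rbind, strsplit(rows[tree$tip.label], ""))
  combos <- as.matrix(expand.grid(rep(list(1:20), nn)))
  total <- 0
  for (j in seq_len(ncol(cols))) {
    tipstate <- match(cols[, j], propevo::AA20)
    s <- 0
    for (ci in seq_len(nrow(combos))) {
      statev <- c(tipstate, combos[ci, ])
      pr <- mod$pi[statev[nt + 1L]]   # root prior (root = node nt+1)
      for (k in seq_len(nrow(tree$edge))) {
        pr <- pr * P[[k]][statev[tree$edge[k, 1]], statev[tree$edge[k, 2]]]
      }
      s <- s + pr
    }
    total <- total + log(s)
  }
  total
}

# Brute-force marginal root posterior for one gapless column.
brute_root_posterior <- function(tree, column_residues, model = "jtt") {
  mod <- propevo::substitution_model(model)
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)),
              function(k) propevo::transition_probs(tree$edge.length[k], mod))
  tipstate <- match(column_residues[tree$tip.label], propevo::AA20)
  other <- if (nn > 1) as.matrix(expand.grid(rep(list(1:20), nn - 1))) else
    matrix(0, 1, 0)
  post <- numeric(20)
  for (r in 1:20) {
    s <- 0
    for (ci in seq_len(nrow(other))) {
      statev <- c(tipstate, r,
                  if (ncol(other)) other[ci, ] else integer(0))
      pr <- mod$pi[r]
      for (k in seq_len(nrow(tree$edge))) {
        pr <- pr * P[[k]][statev[tree$edge[k, 1]], statev[tree$edge[k, 2]]]
      }
      s <- s + pr
    }
    post[r] <- s
  }
  names(post) <- propevo::AA20
  post / sum(post)
}

# Independent Gotoh affine-gap global alignment score (BLOSUM62, open 10,
# extend 0.5), written directly from the recurrences.
oracle_align_score <- function(a, b, open = 10, ext = 0.5) {
  B <- get_blosum62()
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - ext * (i - 2)
  for (j in 2:(m + 1)) Iy[1, j] <- -open - ext * (j - 2)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- B[a[i - 1], b[j - 1]]
    M[i, j] <- sc + max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
    Ix[i, j] <- max(M[i - 1, j] - open, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open, Iy[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Hamming identity of equal-length ungapped sequences (column-wise truth
# for simulator output, which contains no indels by default).
hamming_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}

# Column-wise true average internal identity of a simulated propeller.
true_internal_identity <- function(propeller) {
  k <- propeller$n_motifs
  L <- nchar(propeller$residues) / k
  motifs <- substring(propeller$residues, (seq_len(k) - 1) * L + 1,
                      seq_len(k) * L)
  pairs <- utils::combn(k, 2)
  mean(apply(pairs, 2, function(p) hamming_identity(motifs[p[1]],
                                                    motifs[p[2]])))
}

# Motifs of a simulated family (from recorded true boundaries), labelled.
sim_motifs <- function(fam) {
  unlist(lapply(fam$propellers, function(p) {
    m <- substring(p$residues, p$boundaries[, 1] + 1, p$boundaries[, 2])
    names(m) <- paste0(p$id, "_m", seq_along(m))
    m
  }))
}

# Minimal AncestralPosterior stand-in with prescribed per-position
# probabilities (named residue -> prob lists; remainder spread uniformly).
make_posterior <- function(position_probs) {
  npos <- length(position_probs)
  post <- matrix(0, 20, npos, dimnames = list(propevo::AA20, NULL))
  for (j in seq_len(npos)) {
    p <- position_probs[[j]]
    post[names(p), j] <- unlist(p)
    rest <- setdiff(propevo::AA20, names(p))
    post[rest, j] <- (1 - sum(unlist(p))) / length(rest)
  }
  structure(list(n_positions = npos, posterior = post,
                 mpa = propevo::extract_mpa(post),
                 max_prob = apply(post, 2, max)),
            class = "AncestralPosterior")
}

# Age (branch length per motif lineage) giving a target expected internal
# identity between sister motifs (pairwise path = 2 * age).
age_for_identity <- function(f) propevo::identity_to_distance(f) / 2
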