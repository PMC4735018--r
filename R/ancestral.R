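# Ancestral motif inference: progressive motif alignment, neighbor-joining
# tree on ML-corrected distances, Felsenstein-pruning marginal posteriors at
# the root, and the most probable ancestor (MPA).

# Merge a new pairwise alignment onto an existing master gap pattern
# ("once a gap, always a gap"). a, b: gapped character vectors that reduce
# to the same master sequence. Returns 0/1 ops per merged column.
.merge_ops <- function(a, b) {
  na <- length(a); nb <- length(b)
  ia <- 1L; ib <- 1L
  opa <- integer(na + nb); opb <- integer(na + nb); k <- 0L
  while (ia <= na || ib <= nb) {
    k <- k + 1L
    ca <- if (ia <= na) a[ia] else NA
    cb <- if (ib <= nb) b[ib] else NA
    if (!is.na(ca) && !is.na(cb) &&
        ((ca != "-" && cb != "-") || (ca == "-" && cb == "-"))) {
      opa[k] <- 1L; opb[k] <- 1L; ia <- ia + 1L; ib <- ib + 1L
    } else if (!is.na(ca) && ca == "-") {
      opa[k] <- 1L; opb[k] <- 0L; ia <- ia + 1L
    } else if (!is.na(cb) && cb == "-") {
      opa[k] <- 0L; opb[k] <- 1L; ib <- ib + 1L
    } else if (is.na(ca)) {
      opa[k] <- 0L; opb[k] <- 1L; ib <- ib + 1L
    } else {
      opa[k] <- 1L; opb[k] <- 0L; ia <- ia + 1L
    }
  }
  list(a = opa[seq_len(k)], b = opb[seq_len(k)])
}

.expand_row <- function(row, op) {
  out <- rep("-", length(op))
  out[op == 1L] <- row
  out
}

#' Progressive global alignment of repeat motifs
#'
#' Center-star progressive alignment: every motif is globally aligned
#' (BLOSUM62, gap open 10, extend 0.5) against the first motif, and gap
#' patterns are merged under the "once a gap, always a gap" rule. Row order
#' is preserved. Near-equal-length, high-identity repeat motifs — the
#' intended inputs — are well inside this strategy's comfort zone.
#'
#' @param motifs list (or character vector) of >= 2 amino-acid sequences,
#'   optionally named; `SequenceRecord`s are accepted
#' @return an object of class `MotifAlignment` with `labels`, `rows`
#'   (equal-length gapped strings) and `n_columns`
#' @export
align_motifs <- function(motifs) {
  if (inherits(motifs, "MotifSet")) motifs <- motifs$motifs
  seqs <- vapply(motifs, function(m) {
    if (inherits(m, "SequenceRecord")) m$residues else as.character(m)
  }, character(1))
  if (length(seqs) < 2) stop("need at least 2 motifs to align", call. = FALSE)
  labels <- names(seqs)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- paste0("motif", seq_along(seqs))
  }
  master <- seqs[[1]]
  rows <- list(strsplit(master, "")[[1]])
  master_aln <- rows[[1]]
  for (i in seq_along(seqs)[-1]) {
    if (seqs[[i]] == master) {           # identical to master: gapless row
      p <- strsplit(master, "")[[1]]; s <- p
    } else {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(master), Biostrings::AAString(seqs[[i]]),
        substitutionMatrix = .blosum62(), gapOpening = 10,
        gapExtension = 0.5, type = "global")
      p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    }
    ops <- .merge_ops(master_aln, p)
    rows <- lapply(rows, .expand_row, op = ops$a)
    master_aln <- .expand_row(master_aln, ops$a)
    rows[[length(rows) + 1L]] <- .expand_row(s, ops$b)
  }
  structure(list(labels = labels,
                 rows = vapply(rows, paste, "", collapse = ""),
                 n_columns = length(rows[[1]])),
            class = "MotifAlignment")
}

#' @export
print.MotifAlignment <- function(x, ...) {
  cat(sprintf("<MotifAlignment: %d rows x %d columns>\n",
              length(x$rows), x$n_columns))
  invisible(x)
}

.alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$rows, ""))
  rownames(m) <- alignment$labels
  m
}

# identity over columns where neither row is gapped
.aligned_identity <- function(m, i, j) {
  keep <- m[i, ] != "-" & m[j, ] != "-"
  if (!any(keep)) return(0)
  mean(m[i, keep] == m[j, keep])
}

#' Neighbor-joining tree from a motif alignment
#'
#' Pairwise distances are maximum-likelihood distances under the requested
#' substitution model, numerically inverted from the observed aligned
#' identity of each pair. The NJ tree is midpoint rooted; negative NJ branch
#' lengths are clamped to zero. Deterministic given row order.
#'
#' @param alignment a `MotifAlignment`
#' @param model substitution model id (see [substitution_model()])
#' @return a rooted, binary `phylo` tree with leaf set = alignment labels
#' @export
build_tree <- function(alignment, model = "jtt") {
  m <- .alignment_matrix(alignment)
  n <- nrow(m)
  mod <- substitution_model(model)
  if (n == 2) {
    d <- identity_to_distance(.aligned_identity(m, 1, 2), mod)
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        alignment$labels[1], d / 2,
                                        alignment$labels[2], d / 2))
    return(tr)
  }
  D <- matrix(0, n, n, dimnames = list(alignment$labels, alignment$labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- identity_to_distance(.aligned_identity(m, i, j), mod)
  }
  if (max(D) == 0) {
    # all rows identical: resolve the star deterministically (input order),
    # zero branch lengths
    hc <- stats::hclust(stats::as.dist(D + 1e-12), method = "average")
    tr <- ape::as.phylo(hc)
    tr$edge.length[] <- 0
    return(tr)
  }
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Leaf conditional-likelihood matrices (20 x n_columns) from an alignment.
# Gaps and X are missing data: a vector of ones.
.tip_conditionals <- function(alignment) {
  m <- .alignment_matrix(alignment)
  lapply(seq_len(nrow(m)), function(i) {
    idx <- match(m[i, ], AA20)
    cm <- matrix(0, 20, ncol(m))
    known <- !is.na(idx)
    cm[cbind(idx[known], which(known))] <- 1
    cm[, !known] <- 1
    cm
  })
}

# Pruning pass: per-column conditional likelihoods at the root plus the
# per-column log scaling accumulated on the way up.
.prune <- function(tree, tips, model) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  ncols <- ncol(tips[[1]])
  conds <- vector("list", nt + nn)
  conds[seq_len(nt)] <- tips
  logscale <- numeric(ncols)
  tr <- if (identical(attr(tree, "order"), "postorder")) tree
        else ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    child <- tr$edge[k, 2]; parent <- tr$edge[k, 1]
    P <- transition_probs(tr$edge.length[k], model)
    msg <- P %*% conds[[child]]
    if (is.null(conds[[parent]])) conds[[parent]] <- msg
    else conds[[parent]] <- conds[[parent]] * msg
    # rescale to avoid underflow on deep trees
    cp <- conds[[parent]]
    mx <- cp[cbind(max.col(t(cp), "first"), seq_len(ncols))]
    if (min(mx) < 1e-30) {
      conds[[parent]] <- cp / rep(mx, each = 20L)
      logscale <- logscale + log(mx)
    }
  }
  root <- nt + 1L
  list(root_cond = conds[[root]], logscale = logscale)
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under the given substitution model; gapped leaves are
#' missing data.
#'
#' @param tree rooted binary `phylo`
#' @param alignment a `MotifAlignment` (leaf set must match tip labels)
#' @param model substitution model id or object
#' @export
tree_loglik <- function(tree, alignment, model = "jtt") {
  mod <- substitution_model(if (is.list(model)) model$id else model)
  tips <- .tip_conditionals(alignment)[match(tree$tip.label, alignment$labels)]
  pr <- .prune(tree, tips, mod)
  sum(log(colSums(mod$pi * pr$root_cond)) + pr$logscale)
}

# One round of per-branch Brent optimization of the total log-likelihood.
.polish_branch_lengths <- function(tree, alignment, model, upper = 5) {
  mod <- substitution_model(if (is.list(model)) model$id else model)
  tree <- ape::reorder.phylo(tree, "postorder")
  tips <- .tip_conditionals(alignment)[match(tree$tip.label, alignment$labels)]
  ll <- function(tr) {
    pr <- .prune(tr, tips, mod)
    sum(log(colSums(mod$pi * pr$root_cond)) + pr$logscale)
  }
  for (k in seq_len(nrow(tree$edge))) {
    f <- function(len) {
      tree$edge.length[k] <- len
      ll(tree)
    }
    opt <- stats::optimize(f, interval = c(1e-8, upper),
                           maximum = TRUE, tol = 1e-3)
    if (opt$objective >= f(tree$edge.length[k])) {
      tree$edge.length[k] <- opt$maximum
    }
  }
  tree
}

#' Marginal ancestral posteriors at the root
#'
#' Computes, for every alignment column, the marginal posterior distribution
#' over the 20 residues at the tree root: conditional likelihoods from
#' Felsenstein pruning combined with the model's stationary frequencies as
#' the root prior. Gapped leaves contribute missing data (a vector of ones).
#' Branch lengths receive one round of per-branch Brent polishing before the
#' posterior pass.
#'
#' @param alignment a `MotifAlignment`
#' @param tree rooted binary `phylo`; leaf set must equal alignment labels
#' @param model substitution model id
#' @param polish_branches logical; apply the branch-length polish round
#' @return an object of class `AncestralPosterior`: `n_positions`,
#'   `posterior` (20 x positions matrix, alphabetical residue rows), `mpa`
#'   (most probable ancestor), `max_prob`, the tree used, and the final
#'   log-likelihood
#' @export
root_posteriors <- function(alignment, tree, model = "jtt",
                            polish_branches = TRUE) {
  mod <- substitution_model(model)   # validates the model id
  if (!setequal(tree$tip.label, alignment$labels)) {
    stop("tree leaves must match alignment labels", call. = FALSE)
  }
  if (polish_branches) {
    tree <- .polish_branch_lengths(tree, alignment, mod)
  }
  tips <- .tip_conditionals(alignment)[match(tree$tip.label, alignment$labels)]
  pr <- .prune(tree, tips, mod)
  post <- mod$pi * pr$root_cond
  post <- sweep(post, 2, colSums(post), "/")
  rownames(post) <- AA20
  mpa <- extract_mpa(post)
  structure(list(n_positions = ncol(post), posterior = post, mpa = mpa,
                 max_prob = apply(post, 2, max), tree = tree,
                 loglik = sum(log(colSums(mod$pi * pr$root_cond)) +
                                pr$logscale)),
            class = "AncestralPosterior")
}

#' @export
print.AncestralPosterior <- function(x, ...) {
  cat(sprintf("<AncestralPosterior: %d positions, MPA %s...>\n",
              x$n_positions, substr(x$mpa, 1, 20)))
  invisible(x)
}

#' Most probable ancestor from a posterior
#'
#' Per-position argmax of the posterior; ties broken alphabetically.
#'
#' @param posterior an `AncestralPosterior` or a 20 x positions probability
#'   matrix with alphabetical residue rows
#' @return the MPA as a single amino-acid string
#' @export
extract_mpa <- function(posterior) {
  post <- if (inherits(posterior, "AncestralPosterior")) posterior$posterior
          else posterior
  paste(AA20[apply(post, 2, which.max)], collapse = "")
}

#' Write a posterior table as TSV (one row per position, 20 columns)
#' @param posterior an `AncestralPosterior`
#' @param path output path
#' @export
posterior_to_tsv <- function(posterior, path) {
  df <- data.frame(position = seq_len(posterior$n_positions),
                   mpa = strsplit(posterior$mpa, "")[[1]],
                   max_prob = posterior$max_prob,
                   t(posterior$posterior), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
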