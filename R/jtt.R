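# Amino-acid substitution models: JTT exchangeabilities, rate matrix,
# transition probabilities, and identity <-> distance conversion.

#' The 20 canonical amino acids, alphabetical
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# PAML residue order used by the published JTT tables
.paml_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Jones, Taylor & Thornton (1992) exchangeabilities, lower triangle
# (column-major in PAML order) and stationary frequencies, as distributed
# with PAML's jones.dat.
.jtt_lower <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

.jtt_freqs <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

.model_cache <- new.env(parent = emptyenv())

#' Build (and cache) an amino-acid substitution model
#'
#' Returns the normalized rate matrix `Q` (expected one substitution per
#' site per unit time at stationarity), stationary frequencies `pi`, and a
#' spectral decomposition used to compute transition probabilities.
#' Residues are indexed alphabetically ([AA20]).
#'
#' @param model model identifier: `"jtt"` (Jones-Taylor-Thornton 1992) or
#'   `"poisson"` (equal rates, uniform frequencies).
#' @return a list with elements `id`, `pi`, `Q`, and eigensystem components.
#' @export
substitution_model <- function(model = "jtt") {
  if (!is.character(model) || length(model) != 1L) {
    stop("model id must be a single string", call. = FALSE)
  }
  id <- tolower(model)
  if (!is.null(.model_cache[[id]])) return(.model_cache[[id]])
  if (id == "jtt") {
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- .jtt_lower
    S <- S + t(S)
    freqs <- .jtt_freqs / sum(.jtt_freqs)
    ord <- match(AA20, .paml_order)
    S <- S[ord, ord]
    freqs <- freqs[ord]
  } else if (id == "poisson") {
    S <- matrix(1, 20, 20); diag(S) <- 0
    freqs <- rep(1 / 20, 20)
  } else {
    stop(sprintf("unknown substitution model id: '%s'", model), call. = FALSE)
  }
  Q <- S * rep(freqs, each = 20)    # Q[i,j] = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))       # mean substitution rate
  Q <- Q / mu
  # symmetrize for a stable eigendecomposition (model is reversible)
  sp <- sqrt(freqs)
  B <- Q * outer(sp, 1 / sp)
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  m <- list(id = id, pi = freqs, Q = Q,
            evals = es$values,
            U = es$vectors * (1 / sp),       # diag(1/sp) %*% V
            Ut = t(es$vectors * sp))         # t(V) %*% diag(sp)
  dimnames(m$Q) <- list(AA20, AA20)
  names(m$pi) <- AA20
  .model_cache[[id]] <- m
  m
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param t branch length in expected substitutions per site (>= 0)
#' @param model a model id or an object from [substitution_model()]
#' @return 20 x 20 stochastic matrix, rows/cols in alphabetical residue order
#' @export
transition_probs <- function(t, model = "jtt") {
  if (!is.list(model)) model <- substitution_model(model)
  if (t < 0) stop("branch length must be >= 0", call. = FALSE)
  P <- model$U %*% (exp(model$evals * t) * model$Ut)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA20, AA20)
  P
}

#' Expected pairwise identity between two sequences at total distance d
#'
#' At stationarity the probability that the two ends of a path of total
#' length `d` carry the same residue is `sum_i pi_i P_ii(d)`.
#'
#' @param d total path length (substitutions/site)
#' @inheritParams transition_probs
#' @export
expected_identity <- function(d, model = "jtt") {
  if (!is.list(model)) model <- substitution_model(model)
  vapply(d, function(di) sum(model$pi * diag(transition_probs(di, model))),
         numeric(1))
}

#' Invert observed identity to a maximum-likelihood pairwise distance
#'
#' Solves `expected_identity(d) = f` for `d`. Identities at or below the
#' stationary floor are capped at `d_max` (saturated divergence).
#'
#' @param f observed identity fraction in \[0, 1\]
#' @param d_max cap for saturated identities (default 10 subs/site)
#' @inheritParams transition_probs
#' @export
identity_to_distance <- function(f, model = "jtt", d_max = 10) {
  if (!is.list(model)) model <- substitution_model(model)
  vapply(f, function(fi) {
    if (is.na(fi)) return(NA_real_)
    if (fi >= 1) return(0)
    floor_id <- expected_identity(d_max, model)
    if (fi <= floor_id) return(d_max)
    stats::uniroot(function(d) expected_identity(d, model) - fi,
                   lower = 0, upper = d_max, tol = 1e-9)$root
  }, numeric(1))
}
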