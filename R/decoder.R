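#' Torsion-state observations of the docked candidates
#'
#' The observable layer of the decoder: for the first grid, the torsion
#' state of each docked single amino acid (from its phi-psi angles); for
#' every grid pair t, the states observed for each of the candidate
#' dipeptides -- `m1` from the (phi_t, psi_t) plane and `m2` from the
#' (psi_t, phi_t+1) plane. States are 1-11 or `NA` for unclassified
#' (strained) docked poses.
#'
#' @param obs1 integer vector over the alphabet: state of each single
#'   residue docked to grid 1.
#' @param pair_obs list of n-1 elements, each a list with integer matrices
#'   `m1` and `m2` indexed `[i, j]` over the alphabet.
#' @param alphabet residue alphabet (default the 20 canonical amino acids).
#' @return an object of class `observation_set`.
#' @export
observation_set <- function(obs1, pair_obs, alphabet = AA_ALPHABET) {
  alphabet <- check_alphabet(alphabet)
  k <- length(alphabet)
  if (is.null(names(obs1))) {
    if (length(obs1) != k) stop("unnamed 'obs1' must have length ", k)
    names(obs1) <- alphabet
  }
  names(obs1) <- aa_normalize(names(obs1))
  if (!setequal(names(obs1), alphabet)) {
    stop("missing first-grid observation for residue(s): ",
         paste(setdiff(alphabet, names(obs1)), collapse = ", "))
  }
  obs1 <- obs1[alphabet]
  check_states <- function(x, where) {
    bad <- !is.na(x) & !(x %in% 1:11)
    if (any(bad)) stop("invalid torsion state in ", where,
                       " (must be 1-11 or NA)")
    storage.mode(x) <- "integer"
    x
  }
  obs1 <- check_states(obs1, "first-grid observations")
  if (!is.list(pair_obs) || length(pair_obs) < 1L) {
    stop("'pair_obs' must be a nonempty list")
  }
  pair_obs <- lapply(seq_along(pair_obs), function(t) {
    ob <- pair_obs[[t]]
    for (nmx in c("m1", "m2")) {
      M <- ob[[nmx]]
      if (!is.matrix(M) || any(dim(M) != k)) {
        stop(sprintf("observation matrix '%s' for grid pair %d is not %d x %d",
                     nmx, t, k, k))
      }
      if (is.null(dimnames(M))) dimnames(M) <- list(alphabet, alphabet)
      ob[[nmx]] <- check_states(M[alphabet, alphabet, drop = FALSE],
                                sprintf("'%s' of grid pair %d", nmx, t))
    }
    ob[c("m1", "m2")]
  })
  structure(list(obs1 = obs1, pair_obs = pair_obs, alphabet = alphabet,
                 n = length(pair_obs) + 1L),
            class = "observation_set")
}

# log with floor substitution for exact zeros: log(0) stays -Inf only when
# floor is 0
log_floor <- function(p) {
  out <- p
  pos <- p > 0
  out[pos] <- log(p[pos])
  out[!pos] <- -Inf
  out
}

#' Viterbi initialization over the first grid
#'
#' The score of ending at residue i after the first grid combines a uniform
#' prior (all residues admitted equally), the first-grid binding
#' probability and the singlet propensity of the observed torsion state:
#' delta_1(i) = log pi_i + log p1_i + log P(i, m_i), with `floor`
#' substituted when the observation is unclassified.
#'
#' @param p1 first-grid binding probabilities ([first_grid_probs()]).
#' @param obs1 integer vector of first-grid torsion states (1-11 or `NA`).
#' @param singlet a [build_singlet_table()] result.
#' @param floor probability substituted for unclassified observations.
#' @return named vector delta_1 of log scores over the alphabet.
#' @export
viterbi_initialize <- function(p1, obs1, singlet, floor = 1e-4) {
  alphabet <- names(p1)
  if (is.null(alphabet)) stop("'p1' must be named by residue")
  if (is.null(names(obs1))) names(obs1) <- alphabet
  miss <- setdiff(alphabet, names(obs1))
  if (length(miss)) stop("missing first-grid observation for residue(s): ",
                         paste(miss, collapse = ", "))
  obs1 <- obs1[alphabet]
  em <- vapply(seq_along(alphabet), function(a) {
    if (is.na(obs1[a])) floor else singlet$values[alphabet[a], obs1[a]]
  }, numeric(1))
  d <- log(1) + log_floor(p1) + log_floor(em)
  names(d) <- alphabet
  d
}

#' One Viterbi induction step
#'
#' Extends the best-path scores from grid t to grid t+1:
#' delta_t+1(j) = max_i [delta_t(i) + log a(j | i) + log b(i, j)], recording
#' the maximizing predecessor. Ties are broken toward the lowest residue
#' index in the canonical alphabet order.
#'
#' @param delta named vector of log scores at grid t.
#' @param transitions transition matrix for the grid pair: conditional
#'   a(j | i) (rows i, columns j) or, in joint mode, the pair marginal.
#' @param emissions matrix of emission probabilities b(i, j) for the
#'   observed states of each candidate dipeptide (see
#'   [emission_probability()]).
#' @param grid integer label used in diagnostics.
#' @return list with `delta` (log scores at grid t+1) and `backptr`
#'   (integer vector of predecessor indices).
#' @export
viterbi_induct <- function(delta, transitions, emissions, grid = NA_integer_) {
  k <- length(delta)
  cand <- delta + log_floor(transitions) + log_floor(emissions)
  delta_next <- apply(cand, 2L, max)
  backptr <- apply(cand, 2L, which.max)
  if (all(!is.finite(delta_next))) {
    stop(sprintf("degenerate model: no viable path into grid %s",
                 as.character(grid)))
  }
  names(delta_next) <- colnames(transitions)
  list(delta = delta_next, backptr = as.integer(backptr))
}

#' Viterbi backtracking
#'
#' Recovers the maximum-probability residue sequence from the stored score
#' arrays and backpointers: the last residue is the argmax of the final
#' delta array and predecessors are read off the stored pointers.
#'
#' @param deltas list of n delta vectors (log scores per grid).
#' @param backptrs list of n-1 integer backpointer vectors.
#' @param alphabet residue alphabet the indices refer to.
#' @return list with `sequence` (character vector of one-letter codes),
#'   `log_score` (max of the final delta array) and `path` (integer
#'   indices).
#' @export
viterbi_backtrack <- function(deltas, backptrs, alphabet = AA_ALPHABET) {
  n <- length(deltas)
  if (length(backptrs) != n - 1L) {
    stop("'backptrs' must have one fewer element than 'deltas'")
  }
  path <- integer(n)
  path[n] <- which.max(deltas[[n]])
  if (n > 1L) {
    for (t in rev(seq_len(n - 1L))) {
      path[t] <- backptrs[[t]][path[t + 1L]]
    }
  }
  list(sequence = alphabet[path],
       log_score = unname(deltas[[n]][path[n]]),
       path = path)
}

# internal workhorse shared by design_peptide(): builds the model layers
# and runs the full forward pass + backtrack. Returns everything needed for
# reporting. O(n k^2) time, O(n k) retained memory.
decode_engine <- function(tables, observations, singlet, pair,
                          th = thermo(), floor = 1e-4,
                          transition_mode = c("conditional", "joint"),
                          singlet_index = c("i", "j"),
                          fold_first_grid = FALSE) {
  transition_mode <- match.arg(transition_mode)
  singlet_index <- match.arg(singlet_index)
  stopifnot(inherits(tables, "energy_tables"),
            inherits(observations, "observation_set"))
  if (!identical(tables$alphabet, observations$alphabet)) {
    stop("energy tables and observations use different alphabets")
  }
  if (tables$n != observations$n) {
    stop(sprintf("energy tables are for n = %d but observations for n = %d",
                 tables$n, observations$n))
  }
  alphabet <- tables$alphabet
  n <- tables$n
  chain <- build_weights(tables, th)
  marg <- pair_marginals(chain, fold_first_grid = fold_first_grid)
  p1 <- first_grid_probs(chain)
  A <- if (transition_mode == "conditional") marg$transitions else marg$pair_probs
  B <- lapply(seq_len(n - 1L), function(t) {
    emission_matrix(singlet, pair,
                    observations$pair_obs[[t]]$m1,
                    observations$pair_obs[[t]]$m2,
                    floor = floor, singlet_index = singlet_index,
                    alphabet = alphabet)
  })
  deltas <- vector("list", n)
  backptrs <- vector("list", n - 1L)
  deltas[[1]] <- viterbi_initialize(p1, observations$obs1, singlet, floor)
  for (t in seq_len(n - 1L)) {
    step <- viterbi_induct(deltas[[t]], A[[t]], B[[t]], grid = t + 1L)
    deltas[[t + 1L]] <- step$delta
    backptrs[[t]] <- step$backptr
  }
  res <- viterbi_backtrack(deltas, backptrs, alphabet)
  # per-step log contributions along the decoded path
  q <- res$path
  breakdown <- data.frame(
    grid = seq_len(n),
    residue = alphabet[q],
    log_prior = c(log(p1[q[1]]), rep(0, n - 1L)),
    log_transition = c(0, vapply(seq_len(n - 1L), function(t) {
      log(A[[t]][q[t], q[t + 1L]])
    }, numeric(1))),
    log_emission = c(deltas[[1]][q[1]] - log(p1[q[1]]),
                     vapply(seq_len(n - 1L), function(t) {
                       log(B[[t]][q[t], q[t + 1L]])
                     }, numeric(1)))
  )
  list(sequence = res$sequence, log_score = res$log_score, path = q,
       deltas = deltas, backptrs = backptrs, breakdown = breakdown,
       p1 = p1, transitions = A, emissions = B, marginals = marg,
       chain = chain, obs1 = observations$obs1, floor = floor,
       transition_mode = transition_mode, singlet_index = singlet_index,
       fold_first_grid = fold_first_grid, alphabet = alphabet, n = n,
       tie_break = "canonical-alphabet-order")
}

#' Score a fixed sequence under a decoded model
#'
#' Independent single-sequence scorer: walks the given residue sequence
#' through the model layers of a fitted design (first-grid probability,
#' first-grid emission, then per-step transition and emission), summing log
#' contributions. For the decoded sequence this reproduces the Viterbi
#' `log_score`; for any other sequence it can never exceed it.
#'
#' @param object a [design_peptide()] fit.
#' @param sequence character vector of n residue codes.
#' @return the log score (scalar, possibly `-Inf`).
#' @export
sequence_score <- function(object, sequence) {
  eng <- object$engine
  sequence <- aa_normalize(sequence)
  if (length(sequence) != eng$n) {
    stop(sprintf("sequence has length %d but the model has n = %d",
                 length(sequence), eng$n))
  }
  q <- match(sequence, eng$alphabet)
  if (any(is.na(q))) stop("sequence contains residues outside the alphabet")
  # direct recomputation along the sequence, not a lookup into deltas
  m1 <- eng$obs1[q[1]]
  em1 <- if (is.na(m1)) eng$floor else
    object$emission_tables$singlet$values[eng$alphabet[q[1]], m1]
  s <- log_floor(eng$p1[q[1]]) + log_floor(em1)
  if (eng$n > 1L) {
    for (t in seq_len(eng$n - 1L)) {
      s <- s + log_floor(eng$transitions[[t]][q[t], q[t + 1L]]) +
        log_floor(eng$emissions[[t]][q[t], q[t + 1L]])
    }
  }
  unname(s)
}
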