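#' Per-grid binding energy tables
#'
#' Container for the docking energies that drive the chain model: 20 (or,
#' in reduced-alphabet mode, `length(alphabet)`) single-residue binding
#' energies for the first grid box and one square matrix of dipeptide
#' binding energies per consecutive grid pair, all in kcal/mol. The
#' amino-acid index order is frozen to [AA_ALPHABET].
#'
#' @param first_grid numeric vector of binding energies for the first grid,
#'   named by residue code (any order; stored in canonical order).
#' @param pair_grids list of n-1 square numeric matrices; element t holds
#'   the energy of the dipeptide (i at grid t, j at grid t+1) in cell
#'   `[i, j]`, dimnames by residue code.
#' @param alphabet residue alphabet; the 20 canonical amino acids by
#'   default. Reduced alphabets (any subset) are supported throughout so
#'   small instances can be checked by exhaustive enumeration.
#' @return an object of class `energy_tables` with fields `n` (peptide
#'   length), `alphabet`, `first_grid`, `pair_grids`.
#' @export
energy_tables <- function(first_grid, pair_grids, alphabet = AA_ALPHABET) {
  alphabet <- check_alphabet(alphabet)
  k <- length(alphabet)
  if (is.null(names(first_grid))) {
    if (length(first_grid) != k) stop("unnamed 'first_grid' must have length ", k)
    names(first_grid) <- alphabet
  }
  names(first_grid) <- aa_normalize(names(first_grid))
  if (!setequal(names(first_grid), alphabet) || length(first_grid) != k) {
    stop("'first_grid' must hold exactly one energy per alphabet residue")
  }
  first_grid <- first_grid[alphabet]
  if (any(!is.finite(first_grid))) {
    stop("non-finite energy in first grid for residue ",
         alphabet[which(!is.finite(first_grid))[1]])
  }
  if (!is.list(pair_grids) || length(pair_grids) < 1L) {
    stop("'pair_grids' must be a nonempty list of square matrices (peptide length >= 2)")
  }
  pair_grids <- lapply(seq_along(pair_grids), function(t) {
    M <- pair_grids[[t]]
    if (!is.matrix(M) || any(dim(M) != k)) {
      stop(sprintf("pair grid %d is not a %d x %d matrix", t, k, k))
    }
    if (is.null(dimnames(M))) dimnames(M) <- list(alphabet, alphabet)
    rownames(M) <- aa_normalize(rownames(M))
    colnames(M) <- aa_normalize(colnames(M))
    M <- M[alphabet, alphabet, drop = FALSE]
    if (any(!is.finite(M))) {
      bad <- which(!is.finite(M), arr.ind = TRUE)[1, ]
      stop(sprintf("non-finite energy in pair grid %d at (%s, %s)",
                   t, alphabet[bad[1]], alphabet[bad[2]]))
    }
    M
  })
  structure(list(n = length(pair_grids) + 1L, alphabet = alphabet,
                 first_grid = first_grid, pair_grids = pair_grids),
            class = "energy_tables")
}

#' Thermodynamic constants
#'
#' The Boltzmann factor scale used to turn kcal/mol binding energies into
#' statistical weights, exp(-E / (kB * T)).
#'
#' @param temperature_K absolute temperature in kelvin (default 298.15).
#' @param kB Boltzmann constant in kcal/(mol K); the default 0.0019872 is
#'   the molar gas constant, matching per-mole energies.
#' @return list with `temperature_K`, `kB` and `beta = 1 / (kB * T)`.
#' @export
thermo <- function(temperature_K = 298.15, kB = 0.0019872) {
  if (!is.finite(temperature_K) || temperature_K <= 0) {
    stop("'temperature_K' must be a positive number")
  }
  if (!is.finite(kB) || kB <= 0) stop("'kB' must be a positive number")
  list(temperature_K = temperature_K, kB = kB, beta = 1 / (kB * temperature_K))
}

#' Build the statistical weight chain from binding energies
#'
#' Converts energies to rotational-isomeric-state statistical weights
#' u = exp(-E / kT), held in the log domain: with favorable pair energies
#' around -13 kcal/mol and chains of length ~9, linear-domain transfer
#' products overflow double precision.
#'
#' @param tables an [energy_tables()] object.
#' @param th a [thermo()] object.
#' @return an object of class `weight_chain` with fields `n`, `alphabet`,
#'   `logU1` (first-grid log-weights) and `logU` (list of n-1 log-weight
#'   matrices).
#' @export
build_weights <- function(tables, th = thermo()) {
  stopifnot(inherits(tables, "energy_tables"))
  structure(list(n = tables$n, alphabet = tables$alphabet,
                 logU1 = -th$beta * tables$first_grid,
                 logU = lapply(tables$pair_grids, function(M) -th$beta * M)),
            class = "weight_chain")
}

#' Chain partition function
#'
#' The partition function over all sequences, Z = J* U^(1) U^(2) ... J,
#' where J* is a row of ones (every residue is admitted as the first), J a
#' column of ones, and U^(t) the pairwise statistical weight matrices.
#' Evaluated by a log-domain transfer recursion (per-step rescaling), so
#' arbitrarily favorable energies cannot overflow.
#'
#' @param chain a [build_weights()] result.
#' @param fold_first_grid if `TRUE`, the first-grid singlet weights are
#'   folded in as a diagonal prefactor (sensitivity mode); by default the
#'   first-grid energies enter only through [first_grid_probs()] and the
#'   Viterbi initialization.
#' @return log Z (scalar).
#' @export
partition_function <- function(chain, fold_first_grid = FALSE) {
  stopifnot(inherits(chain, "weight_chain"))
  if (chain$n < 2L) stop("unsupported peptide length: n must be >= 2")
  lf <- if (fold_first_grid) chain$logU1 else rep(0, length(chain$alphabet))
  for (t in seq_along(chain$logU)) {
    M <- chain$logU[[t]]
    lf <- apply(M + lf, 2L, logsumexp)
  }
  logsumexp(lf)
}

#' Pairwise marginals, singlet marginals and transition matrices
#'
#' The probability of residue i at grid t together with residue j at grid
#' t+1 is the partition-function ratio obtained by zeroing all elements of
#' U^(t) except the (i, j)th. It is evaluated with prefix/suffix transfer
#' vectors (algebraically identical to the zeroed-matrix definition, one
#' matrix sweep instead of 400). Conditional transitions a^(t)(j | i)
#' renormalize each row of the pair marginal; singlet marginals are row or
#' column sums.
#'
#' @inheritParams partition_function
#' @return an object of class `chain_marginals`: `log_Z`, `pair_probs`
#'   (list of n-1 matrices each summing to 1), `singlet_probs` (list of n
#'   vectors), `transitions` (list of n-1 row-stochastic matrices).
#' @export
pair_marginals <- function(chain, fold_first_grid = FALSE) {
  stopifnot(inherits(chain, "weight_chain"))
  if (chain$n < 2L) stop("unsupported peptide length: n must be >= 2")
  k <- length(chain$alphabet)
  nm <- length(chain$logU)
  # prefix vectors: lf[[t]] is log(J* U^(1) ... U^(t-1)) as a row
  lf <- vector("list", nm + 1L)
  lf[[1]] <- if (fold_first_grid) chain$logU1 else rep(0, k)
  for (t in seq_len(nm)) {
    lf[[t + 1L]] <- apply(chain$logU[[t]] + lf[[t]], 2L, logsumexp)
  }
  log_Z <- logsumexp(lf[[nm + 1L]])
  # suffix vectors: lb[[t]] is log(U^(t) ... U^(n-1) J) as a column
  lb <- vector("list", nm + 1L)
  lb[[nm + 1L]] <- rep(0, k)
  for (t in rev(seq_len(nm))) {
    lb[[t]] <- apply(chain$logU[[t]] + rep(lb[[t + 1L]], each = k), 1L, logsumexp)
  }
  pair_probs <- vector("list", nm)
  transitions <- vector("list", nm)
  for (t in seq_len(nm)) {
    lp <- outer(lf[[t]], lb[[t + 1L]], "+") + chain$logU[[t]] - log_Z
    p <- exp(lp)
    dimnames(p) <- list(chain$alphabet, chain$alphabet)
    pair_probs[[t]] <- p
    rs <- rowSums(p)
    if (any(rs <= 0)) {
      stop(sprintf("internal consistency error: zero row marginal at grid %d", t))
    }
    transitions[[t]] <- p / rs
  }
  singlet_probs <- c(lapply(pair_probs, rowSums),
                     list(colSums(pair_probs[[nm]])))
  structure(list(log_Z = log_Z, pair_probs = pair_probs,
                 singlet_probs = singlet_probs, transitions = transitions,
                 alphabet = chain$alphabet),
            class = "chain_marginals")
}

#' First-grid binding probabilities
#'
#' Boltzmann probabilities of each residue binding the first grid box,
#' p_i = u_i / sum_k u_k (a softmax of -E / kT); these seed the Viterbi
#' initialization.
#'
#' @param chain a [build_weights()] result.
#' @return named probability vector over the alphabet (sums to 1).
#' @export
first_grid_probs <- function(chain) {
  stopifnot(inherits(chain, "weight_chain"))
  lw <- chain$logU1 - logsumexp(chain$logU1)
  p <- exp(lw)
  names(p) <- chain$alphabet
  p
}
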