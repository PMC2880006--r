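#' Design a peptide against a binding path
#'
#' Main entry point: given per-grid binding energies, the torsion-state
#' observations of the docked candidates, and coil-library emission tables,
#' computes the chain statistics (statistical weights, partition function,
#' pairwise marginals, conditional transitions) and decodes the
#' maximum-probability peptide sequence with a log-space Viterbi pass.
#'
#' The decoder runs in O(n k^2) time and keeps O(n k) state (k = alphabet
#' size, n = peptide length). Ties in the induction maximum are broken
#' toward the lowest index in the canonical alphabet order, so runs are
#' reproducible.
#'
#' @param energies an [energy_tables()] object (or a list
#'   `list(first_grid =, pair_grids =)` passed on to the constructor).
#' @param observations an [observation_set()] of docked torsion states.
#' @param emissions list with elements `singlet` ([build_singlet_table()])
#'   and `pair` ([build_pair_table()]).
#' @param temperature_K absolute temperature in kelvin (default 298.15).
#' @param kB Boltzmann constant in kcal/(mol K) (default 0.0019872).
#' @param floor probability substituted for unclassified torsion
#'   observations (default 1e-4); `0` makes an unclassified pose veto its
#'   candidate.
#' @param transition_mode `"conditional"` (default) scores steps with
#'   a(j | i) derived from the pairwise marginals; `"joint"` uses the pair
#'   marginal itself.
#' @param singlet_index whether dipeptide emissions take the singlet factor
#'   from the residue at grid t (`"i"`, default) or grid t+1 (`"j"`).
#' @param fold_first_grid fold first-grid weights into the transfer product
#'   (sensitivity mode; default `FALSE`).
#' @return an object of class `peptide_design` with components `sequence`
#'   (one-letter codes), `log_score`, `breakdown` (per-grid log
#'   contributions), `marginals` (a `chain_marginals`), `config`, and the
#'   full decode state. Methods: [print.peptide_design()],
#'   [summary.peptide_design()], [coef.peptide_design()],
#'   [logLik.peptide_design()], [simulate.peptide_design()],
#'   [plot.peptide_design()].
#' @examples
#' spec <- plant_spec(n = 3, sequence = c("W", "Y", "V"), margin = 2)
#' tab <- synth_energy_tables(spec)
#' obs <- synth_observations(tab, rule = "uniform")
#' lib <- synth_torsion_library(n_records = 500, seed = 1)
#' em <- list(singlet = build_singlet_table(lib$singlet),
#'            pair = build_pair_table(lib$pair))
#' fit <- design_peptide(tab, obs, em)
#' fit$sequence
#' @export
design_peptide <- function(energies, observations, emissions,
                           temperature_K = 298.15, kB = 0.0019872,
                           floor = 1e-4,
                           transition_mode = c("conditional", "joint"),
                           singlet_index = c("i", "j"),
                           fold_first_grid = FALSE) {
  cl <- match.call()
  if (!inherits(energies, "energy_tables")) {
    energies <- do.call(energy_tables, energies)
  }
  if (!is.list(emissions) || is.null(emissions$singlet) || is.null(emissions$pair)) {
    stop("'emissions' must be a list with elements 'singlet' and 'pair'")
  }
  th <- thermo(temperature_K, kB)
  eng <- decode_engine(energies, observations,
                       singlet = emissions$singlet, pair = emissions$pair,
                       th = th, floor = floor,
                       transition_mode = transition_mode,
                       singlet_index = singlet_index,
                       fold_first_grid = fold_first_grid)
  structure(list(
    call = cl,
    sequence = eng$sequence,
    log_score = eng$log_score,
    breakdown = eng$breakdown,
    marginals = eng$marginals,
    energies = energies,
    emission_tables = emissions,
    engine = eng,
    config = list(temperature_K = temperature_K, kB = kB, floor = floor,
                  transition_mode = eng$transition_mode,
                  singlet_index = eng$singlet_index,
                  fold_first_grid = fold_first_grid,
                  tie_break = eng$tie_break,
                  alphabet = eng$alphabet)
  ), class = "peptide_design")
}

#' @describeIn design_peptide one-line view: decoded sequence and score.
#' @param x,object a `peptide_design` fit.
#' @param ... unused.
#' @export
print.peptide_design <- function(x, ...) {
  cat("Peptide design (Viterbi decode over RIS chain statistics)\n")
  cat(sprintf("  length n = %d, alphabet size %d\n",
              x$engine$n, length(x$config$alphabet)))
  cat("  sequence:", paste(x$sequence, collapse = "-"),
      sprintf(" (%s)\n", paste(AA_THREE[match(x$sequence, AA_ALPHABET)],
                               collapse = "-")))
  cat(sprintf("  log score: %.4f   log Z: %.4f\n",
              x$log_score, x$marginals$log_Z))
  invisible(x)
}

#' @describeIn design_peptide per-grid breakdown of the decoded path plus
#'   chain summaries.
#' @export
summary.peptide_design <- function(object, ...) {
  out <- list(sequence = object$sequence,
              log_score = object$log_score,
              log_Z = object$marginals$log_Z,
              breakdown = object$breakdown,
              config = object$config)
  class(out) <- "summary.peptide_design"
  out
}

#' @export
print.summary.peptide_design <- function(x, ...) {
  cat("Decoded peptide:", paste(x$sequence, collapse = "-"), "\n")
  cat(sprintf("log score %.4f (log Z = %.4f)\n", x$log_score, x$log_Z))
  cat("\nPer-grid contributions (log domain):\n")
  print(x$breakdown, row.names = FALSE, digits = 4)
  cat(sprintf("\nT = %.2f K, floor = %g, transitions = %s, singlet index = %s\n",
              x$config$temperature_K, x$config$floor,
              x$config$transition_mode, x$config$singlet_index))
  invisible(x)
}

#' @describeIn design_peptide model parameters: first-grid probabilities and
#'   the per-grid transition matrices.
#' @export
coef.peptide_design <- function(object, ...) {
  list(first_grid = object$engine$p1,
       transitions = object$engine$transitions)
}

#' @describeIn design_peptide the decoded path's log probability.
#' @export
logLik.peptide_design <- function(object, ...) {
  val <- object$log_score
  attr(val, "df") <- NA_integer_
  attr(val, "nobs") <- object$engine$n
  class(val) <- "logLik"
  val
}

#' @describeIn design_peptide draw random sequences from the chain
#'   distribution (first-grid probabilities times conditional transitions),
#'   e.g. to compare the decoded sequence against the bulk of the ensemble.
#' @param nsim number of sequences to draw.
#' @param seed optional integer seed (restores the RNG state on exit).
#' @export
simulate.peptide_design <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  alphabet <- object$config$alphabet
  n <- object$engine$n
  p1 <- object$engine$p1
  A <- object$marginals$transitions
  out <- character(nsim)
  for (s in seq_len(nsim)) {
    q <- integer(n)
    q[1] <- sample.int(length(alphabet), 1L, prob = p1)
    for (t in seq_len(n - 1L)) {
      q[t + 1L] <- sample.int(length(alphabet), 1L, prob = A[[t]][q[t], ])
    }
    out[s] <- paste(alphabet[q], collapse = "")
  }
  out
}

#' @describeIn design_peptide base-graphics view of the Viterbi score
#'   surface: per-grid delta values with the decoded path overlaid.
#' @export
plot.peptide_design <- function(x, ...) {
  eng <- x$engine
  D <- do.call(cbind, eng$deltas)
  D[!is.finite(D)] <- NA
  matplot(t(D), type = "l", lty = 1, col = "grey70",
          xlab = "grid", ylab = expression(delta[t](i) ~ "(log)"),
          main = "Viterbi score trajectories", ...)
  path_scores <- vapply(seq_len(eng$n),
                        function(t) eng$deltas[[t]][eng$path[t]], numeric(1))
  lines(seq_len(eng$n), path_scores, col = "firebrick", lwd = 2)
  points(seq_len(eng$n), path_scores, pch = 19, col = "firebrick")
  text(seq_len(eng$n), path_scores, labels = x$sequence, pos = 3,
       col = "firebrick")
  invisible(x)
}
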