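#' Eleven Ramachandran torsion states
#'
#' Backbone dihedral pairs are classified into eleven labeled regions of the
#' Ramachandran map. States are numbered 1-11: epsilon-prime (mirror image of
#' the extended region), epsilon (extended, phi > 0), alpha_R (right-handed
#' helix), gamma (tight turn), delta_R (bridge between beta strands), delta_L
#' (its mirror image), zeta (pre-proline), gamma-prime (inverse tight turn),
#' alpha_L (left-handed helix), beta_s (beta sheet) and beta_p
#' (polyproline-like). Region geometry is not uniquely fixed by the published
#' maps, so the rectangles live in an editable configuration (see
#' [read_regions()]); `default_regions()` ships a boundary set that
#' reproduces the standard taxonomy, with each region containing its
#' canonical anchor point.
#'
#' A region set is a data frame with one row per axis-aligned rectangle and
#' columns `state` (1-11), `name` (ASCII identifier), `symbol` (the Greek
#' label), `phi_lo`, `phi_hi`, `psi_lo`, `psi_hi` (degrees, half-open
#' `[lo, hi)` intervals, evaluated on the torus so regions may wrap across
#' +/-180). A state may own several rectangles (epsilon does, so that it is
#' contiguous across the psi = +/-180 seam).
#'
#' @return `default_regions()` returns a validated region set.
#' @export
default_regions <- function() {
  df <- data.frame(
    state = c(1L, 2L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L),
    name = c("epsilon_prime", "epsilon", "epsilon", "alpha_R", "gamma",
             "delta_R", "delta_L", "zeta", "gamma_prime", "alpha_L",
             "beta_s", "beta_p"),
    phi_lo = c(-180,   20,   20, -160,   40, -160,  20, -180, -110,  20, -180, -110),
    phi_hi = c( -20,  180,  180,  -20,  110,  -20, 160, -110,  -40, 160, -110,  -40),
    psi_lo = c(-180,  140, -180,  -70, -100,  -10, -60,   60,   60,  10,  100,  100),
    psi_hi = c(-140,  180, -140,  -10,  -60,   60,  10,  100,  100,  70,  180,  180),
    stringsAsFactors = FALSE
  )
  region_set(df)
}

# Greek labels of the standard state notation, keyed by ASCII region name
# (built from \u escapes so the source stays ASCII)
region_symbols <- function() {
  c(epsilon_prime = "\u03b5\u2032", epsilon = "\u03b5",
    alpha_R = "\u03b1_R", gamma = "\u03b3", delta_R = "\u03b4_R",
    delta_L = "\u03b4_L", zeta = "\u03b6", gamma_prime = "\u03b3\u2032",
    alpha_L = "\u03b1_L", beta_s = "\u03b2_s", beta_p = "\u03b2_p")
}

#' Validate a torsion-state region set
#'
#' Checks the structural invariants of a region table: exactly 11 states
#' named by the standard taxonomy, positive-width rectangles, and a
#' consistent state/name mapping. Attaches the Greek `symbol` column.
#'
#' @param df data frame with columns `state`, `name`, `phi_lo`, `phi_hi`,
#'   `psi_lo`, `psi_hi` (degrees; one or more rows per state).
#' @return the validated region set (class `region_set`).
#' @export
region_set <- function(df) {
  req <- c("state", "name", "phi_lo", "phi_hi", "psi_lo", "psi_hi")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("region table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$state <- as.integer(df$state)
  syms <- region_symbols()
  if (!setequal(unique(df$name), names(syms))) {
    stop("region names must be exactly the 11 canonical state names")
  }
  if (!setequal(unique(df$state), 1:11)) {
    stop("region states must cover exactly 1..11")
  }
  if (anyDuplicated(unique(df[, c("state", "name")])$state)) {
    stop("a state index maps to more than one region name")
  }
  num <- c("phi_lo", "phi_hi", "psi_lo", "psi_hi")
  for (v in num) df[[v]] <- as.numeric(df[[v]])
  if (any(!is.finite(as.matrix(df[, num])))) stop("non-finite region bound")
  if (any(df$phi_hi <= df$phi_lo) || any(df$psi_hi <= df$psi_lo)) {
    stop("region rectangles must have hi > lo on both axes")
  }
  df$symbol <- unname(syms[df$name])
  df <- df[order(df$state), c("state", "name", "symbol", num)]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

#' Wrap angles to the canonical interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

# membership of x in the half-open arc [lo, hi) on the 360-degree torus
in_arc <- function(x, lo, hi) ((x - lo) %% 360) < (hi - lo)

#' Classify backbone dihedral pairs into torsion states
#'
#' Assigns each (phi, psi) pair to one of the eleven torsion-angle states,
#' or to `NA` (unclassified) when the point falls outside every region --
#' the strained conformations that the published maps leave uncovered.
#' Membership is evaluated on the torus, so classification is invariant
#' under adding multiples of 360 degrees to either angle.
#'
#' @param phi,psi numeric vectors of dihedral angles in degrees (recycled to
#'   a common length).
#' @param regions a region set, by default [default_regions()].
#' @return integer vector of state indices 1-11, `NA` where unclassified.
#' @export
classify_state <- function(phi, psi, regions = default_regions()) {
  if (any(!is.finite(phi))) stop("non-finite value in 'phi'")
  if (any(!is.finite(psi))) stop("non-finite value in 'psi'")
  n <- max(length(phi), length(psi))
  phi <- rep_len(wrap_angle(phi), n)
  psi <- rep_len(wrap_angle(psi), n)
  hits <- integer(n)
  out <- rep(NA_integer_, n)
  for (r in seq_len(nrow(regions))) {
    inside <- in_arc(phi, regions$phi_lo[r], regions$phi_hi[r]) &
      in_arc(psi, regions$psi_lo[r], regions$psi_hi[r])
    hits[inside] <- hits[inside] + 1L
    out[inside] <- regions$state[r]
  }
  if (any(hits > 1L)) {
    k <- which(hits > 1L)[1L]
    stop(sprintf("regions overlap at (phi = %.3f, psi = %.3f)",
                 phi[k], psi[k]))
  }
  out
}

# shared tally: counts of states 1..11 plus number unclassified
tally_states <- function(states) {
  list(counts = tabulate(states[!is.na(states)], nbins = 11L),
       n_unclassified = sum(is.na(states)))
}

#' Build the singlet torsion-state propensity table
#'
#' From coil-library records of per-residue (phi, psi) observations, builds
#' the 20 x 11 table of probabilities that a residue of type i occupies
#' torsion state m: normalized frequencies with an additive pseudocount per
#' state. Records falling outside all regions are discarded from the counts
#' and tallied in `n_unclassified`.
#'
#' @param records data frame with columns `res` (1- or 3-letter code),
#'   `phi`, `psi` (degrees).
#' @param regions region set used for classification.
#' @param pseudocount nonnegative additive count per (residue, state) cell;
#'   default 0.5 keeps sparse libraries away from zero emissions.
#' @return an object of class `singlet_table`: list with `values`
#'   (20 x 11 row-stochastic matrix, rows named by residue), `pseudocount`,
#'   `n_unclassified`.
#' @export
build_singlet_table <- function(records, regions = default_regions(),
                                pseudocount = 0.5) {
  if (NROW(records) < 1L) stop("'records' is empty")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  res <- aa_normalize(records$res)
  states <- classify_state(records$phi, records$psi, regions)
  keep <- !is.na(states)
  counts <- unclass(table(factor(res[keep], levels = AA_ALPHABET),
                          factor(states[keep], levels = 1:11)))
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(AA_ALPHABET, 1:11)
  tot <- rowSums(counts)
  if (pseudocount == 0) {
    bad <- intersect(unique(res), AA_ALPHABET[tot == 0])
    if (length(bad)) {
      stop("no classified records for residue(s) ",
           paste(bad, collapse = ", "), " and pseudocount is 0")
    }
  }
  # with pseudocount 0, residues absent from the library get NaN rows
  values <- (counts + pseudocount) / (tot + 11 * pseudocount)
  structure(list(values = values, pseudocount = pseudocount,
                 n_unclassified = sum(!keep)),
            class = "singlet_table")
}

#' Build the neighbor-pair torsion-state propensity table
#'
#' From coil-library records of neighboring-residue (psi_t, phi_t+1)
#' observations, builds the 20 x 20 x 11 table of probabilities that residue
#' j occupies state m of the (psi_t, phi_t+1) plane given that the
#' preceding residue is of type i. The same region geometry as the
#' (phi, psi) plane is used.
#'
#' @param records data frame with columns `res_i`, `res_j`, `psi_t`,
#'   `phi_next`.
#' @inheritParams build_singlet_table
#' @return an object of class `pair_table`: list with `values`
#'   (20 x 20 x 11 array, each (i, j) fiber summing to 1), `pseudocount`,
#'   `n_unclassified`.
#' @export
build_pair_table <- function(records, regions = default_regions(),
                             pseudocount = 0.5) {
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  counts <- array(0, dim = c(20L, 20L, 11L),
                  dimnames = list(AA_ALPHABET, AA_ALPHABET, 1:11))
  n_unc <- 0L
  if (NROW(records) > 0L) {
    ri <- aa_normalize(records$res_i)
    rj <- aa_normalize(records$res_j)
    states <- classify_state(records$psi_t, records$phi_next, regions)
    keep <- !is.na(states)
    n_unc <- sum(!keep)
    tab <- unclass(table(factor(ri[keep], levels = AA_ALPHABET),
                         factor(rj[keep], levels = AA_ALPHABET),
                         factor(states[keep], levels = 1:11)))
    counts[, , ] <- as.double(tab)
  }
  tot <- apply(counts, c(1, 2), sum)
  if (pseudocount == 0 && NROW(records) > 0L) {
    seen <- unique(cbind(ri, rj))
    bad <- seen[tot[seen] == 0, , drop = FALSE]
    if (nrow(bad)) {
      stop(sprintf("no classified records for pair (%s, %s) and pseudocount is 0",
                   bad[1, 1], bad[1, 2]))
    }
  }
  # with pseudocount 0, pairs absent from the library get NaN fibers
  values <- sweep(counts + pseudocount, c(1, 2), tot + 11 * pseudocount, "/")
  structure(list(values = values, pseudocount = pseudocount,
                 n_unclassified = n_unc),
            class = "pair_table")
}

#' Emission probability of an observed torsion-state pair
#'
#' The emission probability for a candidate dipeptide (i at grid t, j at
#' grid t+1) whose docked conformation was classified to state `m1` in the
#' (phi_t, psi_t) plane and `m2` in the (psi_t, phi_t+1) plane is the
#' product of the singlet propensity and the conditional neighbor-pair
#' propensity. When an observed state is unclassified (`NA`), the
#' corresponding factor is replaced by `floor`, so a single strained docked
#' pose attenuates rather than vetoes a sequence.
#'
#' @param singlet a [build_singlet_table()] result.
#' @param pair a [build_pair_table()] result.
#' @param i,j one-letter (or 3-letter) residue codes.
#' @param m1 state of the (phi_t, psi_t) observation (1-11 or `NA`).
#' @param m2 state of the (psi_t, phi_t+1) observation (1-11 or `NA`).
#' @param floor nonnegative probability substituted for an unclassified
#'   factor (default 1e-4).
#' @param singlet_index whether the singlet factor is indexed by the residue
#'   at grid t (`"i"`, default) or at grid t+1 (`"j"`).
#' @return the emission probability, a scalar in `[0, 1]`.
#' @export
emission_probability <- function(singlet, pair, i, j, m1, m2,
                                 floor = 1e-4, singlet_index = c("i", "j")) {
  singlet_index <- match.arg(singlet_index)
  if (floor < 0) stop("'floor' must be >= 0")
  i <- aa_normalize(i); j <- aa_normalize(j)
  s_res <- if (singlet_index == "i") i else j
  f1 <- if (is.na(m1)) floor else singlet$values[s_res, m1]
  f2 <- if (is.na(m2)) floor else pair$values[i, j, m2]
  f1 * f2
}

# dense 20x20 emission matrix for one grid pair, given observed state
# matrices m1 (phi_t-psi_t) and m2 (psi_t-phi_t+1); used by the decoder
emission_matrix <- function(singlet, pair, m1, m2, floor = 1e-4,
                            singlet_index = "i", alphabet = AA_ALPHABET) {
  k <- length(alphabet)
  sv <- singlet$values[alphabet, , drop = FALSE]
  pv <- pair$values[alphabet, alphabet, , drop = FALSE]
  B <- matrix(NA_real_, k, k, dimnames = list(alphabet, alphabet))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      s1 <- m1[a, b]; s2 <- m2[a, b]
      f1 <- if (is.na(s1)) floor else {
        if (singlet_index == "i") sv[a, s1] else sv[b, s1]
      }
      f2 <- if (is.na(s2)) floor else pv[a, b, s2]
      B[a, b] <- f1 * f2
    }
  }
  B
}
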