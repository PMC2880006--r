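# Independent oracles and tiny fixture builders shared across tests.

# log with -Inf for nonpositive entries, preserving dims
lf <- function(p) {
  out <- p
  pos <- p > 0
  out[pos] <- log(p[pos])
  out[!pos] <- -Inf
  out
}

# exactly uniform emission tables (the zero-count, pseudocount-only limit)
uniform_singlet <- function() {
  structure(list(values = matrix(1 / 11, 20, 11,
                                 dimnames = list(AA_ALPHABET, 1:11)),
                 pseudocount = 1, n_unclassified = 0L),
            class = "singlet_table")
}
uniform_pair <- function() {
  structure(list(values = array(1 / 11, c(20, 20, 11),
                                dimnames = list(AA_ALPHABET, AA_ALPHABET, 1:11)),
                 pseudocount = 1, n_unclassified = 0L),
            class = "pair_table")
}
uniform_emissions <- function() {
  list(singlet = uniform_singlet(), pair = uniform_pair())
}

# random energy tables, deterministic given seed
rand_tables <- function(n, alphabet = AA_ALPHABET, seed = 1, sd = 1.5,
                        base = -6) {
  withr::with_seed(seed, {
    k <- length(alphabet)
    fg <- stats::setNames(base + rnorm(k, 0, sd), alphabet)
    pg <- lapply(seq_len(n - 1L), function(t) {
      matrix(base + rnorm(k * k, 0, sd), k, k,
             dimnames = list(alphabet, alphabet))
    })
    energy_tables(fg, pg, alphabet)
  })
}

# brute-force chain statistics by exhaustive enumeration of all k^n
# sequences, straight from the energy tables (independent of the
# transfer-matrix code path)
bf_chain <- function(tab, th = thermo()) {
  k <- length(tab$alphabet)
  n <- tab$n
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  logw <- rep(0, nrow(seqs))
  for (t in seq_len(n - 1L)) {
    logw <- logw - th$beta * tab$pair_grids[[t]][cbind(seqs[, t], seqs[, t + 1L])]
  }
  w <- exp(logw - max(logw))
  Z_log <- max(logw) + log(sum(w))
  pw <- w / sum(w)
  pair <- lapply(seq_len(n - 1L), function(t) {
    idx <- (seqs[, t + 1L] - 1L) * k + seqs[, t]
    M <- matrix(0, k, k, dimnames = list(tab$alphabet, tab$alphabet))
    agg <- rowsum(pw, group = idx)
    M[as.integer(rownames(agg))] <- agg
    M
  })
  list(Z_log = Z_log, pair = pair)
}

# score every possible sequence under a fitted design's model layers;
# the maximum is the enumeration oracle for the Viterbi decode
enumerate_scores <- function(fit) {
  eng <- fit$engine
  k <- length(eng$alphabet)
  n <- eng$n
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  em1 <- vapply(seq_len(k), function(a) {
    m <- eng$obs1[a]
    if (is.na(m)) eng$floor
    else fit$emission_tables$singlet$values[eng$alphabet[a], m]
  }, numeric(1))
  sc <- lf(eng$p1)[seqs[, 1]] + lf(em1)[seqs[, 1]]
  for (t in seq_len(n - 1L)) {
    ij <- cbind(seqs[, t], seqs[, t + 1L])
    sc <- sc + lf(eng$transitions[[t]])[ij] + lf(eng$emissions[[t]])[ij]
  }
  list(seqs = seqs, scores = unname(sc))
}

# full design run on a synthetic planted instance with neutral emissions
planted_fit <- function(n, seed, margin = 1, noise_sd = 0.1,
                        alphabet = AA_ALPHABET) {
  spec <- plant_spec(n = n, margin = margin, noise_sd = noise_sd,
                     seed = seed, alphabet = alphabet)
  tab <- synth_energy_tables(spec)
  obs <- synth_observations(tab, rule = "uniform")
  fit <- design_peptide(tab, obs, uniform_emissions())
  list(spec = spec, fit = fit)
}
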