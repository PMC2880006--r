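test_that("initialization combines prior, binding and torsion propensity", {
  em <- uniform_emissions()
  p1 <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  obs1 <- stats::setNames(rep(3L, 20), AA_ALPHABET)
  d1 <- viterbi_initialize(p1, obs1, em$singlet)
  expect_equal(unname(d1), rep(log(1 / 20) + log(1 / 11), 20))
  # concentrated first-grid probabilities dominate the argmax
  eps <- 1e-6
  p1w <- stats::setNames(rep(eps, 20), AA_ALPHABET)
  p1w["W"] <- 1 - 19 * eps
  expect_identical(names(which.max(viterbi_initialize(p1w, obs1, em$singlet))),
                   "W")
  # random instance against a direct per-residue product
  withr::with_seed(2, {
    pr <- runif(20); pr <- stats::setNames(pr / sum(pr), AA_ALPHABET)
    ob <- stats::setNames(sample(c(1:11, NA), 20, replace = TRUE), AA_ALPHABET)
  })
  d <- viterbi_initialize(pr, ob, em$singlet, floor = 1e-4)
  ref <- vapply(AA_ALPHABET, function(a) {
    log(pr[a]) + log(if (is.na(ob[a])) 1e-4 else em$singlet$values[a, ob[a]])
  }, numeric(1))
  expect_equal(d, ref, tolerance = 1e-12)
  expect_error(viterbi_initialize(pr, ob[-1], em$singlet), "missing")
})

test_that("induction takes the exhaustive max with first-index tie-break", {
  k <- 20
  al <- AA_ALPHABET
  withr::with_seed(31, {
    delta <- stats::setNames(rnorm(k), al)
    A <- matrix(runif(k * k), k, k, dimnames = list(al, al))
    A <- A / rowSums(A)
    B <- matrix(runif(k * k), k, k, dimnames = list(al, al))
  })
  step <- viterbi_induct(delta, A, B, grid = 2)
  ref_delta <- numeric(k)
  ref_back <- integer(k)
  for (j in seq_len(k)) {
    cand <- delta + log(A[, j]) + log(B[, j])
    ref_delta[j] <- max(cand)
    ref_back[j] <- which.max(cand)
  }
  expect_equal(unname(step$delta), ref_delta, tolerance = 1e-12)
  expect_identical(step$backptr, ref_back)
  # uniform transitions and emissions: every backpointer is argmax(delta)
  U <- matrix(1 / k, k, k, dimnames = list(al, al))
  stepu <- viterbi_induct(delta, U, U)
  expect_equal(unname(stepu$delta), rep(max(delta) + 2 * log(1 / k), k))
  expect_true(all(stepu$backptr == which.max(delta)))
  # identity-dominant transitions keep each column on its own residue
  I <- diag(k) * 0.9 + 0.1 / k
  dimnames(I) <- list(al, al)
  expect_identical(viterbi_induct(delta, I, U)$backptr, seq_len(k))
  # a column with no viable predecessor anywhere is degenerate
  expect_error(viterbi_induct(rep(-Inf, k), A, B, grid = 4), "grid 4")
})

test_that("backtracking recovers the stored optimal path", {
  # n = 1: the argmax of delta_1
  d1 <- c(A = -1, C = -0.5, D = -2)
  res <- viterbi_backtrack(list(d1), list(), alphabet = c("A", "C", "D"))
  expect_identical(res$sequence, "C")
  expect_equal(res$log_score, -0.5)
  expect_error(viterbi_backtrack(list(d1), list(1:3, 1:3), c("A", "C", "D")),
               "one fewer")
})

test_that("fully uniform model decodes to the tie-break sequence", {
  n <- 4
  al <- AA_ALPHABET
  tab <- energy_tables(stats::setNames(rep(-2, 20), al),
                       rep(list(matrix(-2, 20, 20,
                                       dimnames = list(al, al))), n - 1L), al)
  obs <- synth_observations(tab, rule = "uniform", state = 3L)
  fit <- design_peptide(tab, obs, uniform_emissions())
  expect_identical(fit$sequence, rep("A", n))
  expect_equal(fit$log_score,
               log(1 / 20) + log(1 / 11) +
                 (n - 1) * (log(1 / 20) + log(1 / 121)),
               tolerance = 1e-10)
  # breakdown sums to the score
  expect_equal(sum(fit$breakdown[, c("log_prior", "log_transition",
                                     "log_emission")]),
               fit$log_score, tolerance = 1e-10)
})

test_that("decode matches brute force over all sequences (n = 3 and 4)", {
  for (seed in c(1, 2)) {
    tab <- rand_tables(3, AA_ALPHABET, seed = 40 + seed)
    obs <- synth_observations(tab, rule = "random", seed = seed)
    lib <- synth_torsion_library(60, seed = seed)
    em <- list(singlet = build_singlet_table(lib$singlet),
               pair = build_pair_table(lib$pair))
    fit <- design_peptide(tab, obs, em)
    enum <- enumerate_scores(fit)
    best <- which.max(enum$scores)
    expect_equal(fit$log_score, enum$scores[best], tolerance = 1e-10)
    expect_identical(fit$sequence, AA_ALPHABET[enum$seqs[best, ]])
    expect_true(all(enum$scores <= fit$log_score + 1e-10))
  }
  # one 160,000-sequence tetrapeptide instance
  tab4 <- rand_tables(4, AA_ALPHABET, seed = 99)
  obs4 <- synth_observations(tab4, rule = "random", seed = 99)
  fit4 <- design_peptide(tab4, obs4, uniform_emissions())
  enum4 <- enumerate_scores(fit4)
  expect_equal(fit4$log_score, max(enum4$scores), tolerance = 1e-10)
  expect_identical(fit4$sequence,
                   AA_ALPHABET[enum4$seqs[which.max(enum4$scores), ]])
})

test_that("independent sequence scorer reproduces the decoded score", {
  tab <- rand_tables(5, AA_ALPHABET, seed = 77)
  obs <- synth_observations(tab, rule = "random", seed = 77)
  lib <- synth_torsion_library(40, seed = 77)
  em <- list(singlet = build_singlet_table(lib$singlet),
             pair = build_pair_table(lib$pair))
  fit <- design_peptide(tab, obs, em)
  expect_equal(sequence_score(fit, fit$sequence), fit$log_score,
               tolerance = 1e-10)
  # any perturbed sequence scores no higher
  other <- fit$sequence
  other[2] <- setdiff(AA_ALPHABET, other[2])[1]
  expect_lte(sequence_score(fit, other), fit$log_score)
})

test_that("scaling all emissions shifts the score but not the sequence", {
  tab <- rand_tables(4, AA_ALPHABET, seed = 55)
  obs <- synth_observations(tab, rule = "random", seed = 55)
  em <- uniform_emissions()
  fit <- design_peptide(tab, obs, em)
  c0 <- 0.25
  em2 <- em
  em2$singlet$values <- em$singlet$values * c0
  em2$pair$values <- em$pair$values * c0
  fit2 <- design_peptide(tab, obs, em2)
  expect_identical(fit2$sequence, fit$sequence)
  # singlet factor once at grid 1, singlet+pair at each of n-1 steps
  n <- 4
  expect_equal(fit2$log_score - fit$log_score, (2 * (n - 1) + 1) * log(c0),
               tolerance = 1e-10)
})

test_that("planted sequences are recovered across 50 seeds at 1 kcal/mol margin", {
  hits <- 0L
  for (seed in 1:50) {
    pf <- planted_fit(n = 4, seed = seed, margin = 1, noise_sd = 0.1)
    hits <- hits + identical(pf$fit$sequence, pf$spec$sequence)
  }
  expect_identical(hits, 50L)
})

test_that("adversarial zero-probability observations veto the energy optimum", {
  spec <- plant_spec(n = 3, sequence = c("W", "Y", "V"), margin = 2, seed = 9)
  tab <- synth_energy_tables(spec)
  # library that never visits state 7; pseudocount 0 makes it impossible
  lib <- synth_torsion_library(200, seed = 9,
                               singlet_dist = c(rep(1 / 10, 6), 0, rep(1 / 10, 4)),
                               pair_dist = c(rep(1 / 10, 6), 0, rep(1 / 10, 4)))
  em <- list(singlet = build_singlet_table(lib$singlet, pseudocount = 0),
             pair = build_pair_table(lib$pair, pseudocount = 0))
  obs_ok <- synth_observations(tab, rule = "uniform", state = 3L)
  fit_ok <- design_peptide(tab, obs_ok, em, floor = 0)
  expect_identical(fit_ok$sequence, spec$sequence)
  obs_bad <- synth_observations(tab, rule = "adversarial", state = 3L,
                                planted = spec$sequence, penalized_state = 7L)
  fit_bad <- design_peptide(tab, obs_bad, em, floor = 0)
  expect_false(identical(fit_bad$sequence, spec$sequence))
  expect_true(is.finite(fit_bad$log_score))
})

test_that("joint transition mode scores with the pair marginal itself", {
  tab <- rand_tables(3, c("A", "C", "D"), seed = 13)
  obs <- synth_observations(tab, rule = "uniform")
  em <- uniform_emissions()
  fit_j <- design_peptide(tab, obs, em, transition_mode = "joint")
  enum <- enumerate_scores(fit_j)  # uses the stored (joint) matrices
  expect_equal(fit_j$log_score, max(enum$scores), tolerance = 1e-10)
})
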