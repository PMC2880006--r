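test_that("statistical weights are Boltzmann factors of the energies", {
  al <- c("A", "C")
  th <- thermo()
  zero <- energy_tables(stats::setNames(c(0, 0), al),
                        list(matrix(0, 2, 2, dimnames = list(al, al))), al)
  w <- build_weights(zero, th)
  expect_equal(exp(w$logU1), c(A = 1, C = 1))
  expect_equal(exp(w$logU[[1]]), matrix(1, 2, 2, dimnames = list(al, al)))
  # E = -kT ln 2 gives weight exactly 2
  e2 <- -1 / th$beta * log(2)
  tab <- energy_tables(stats::setNames(c(e2, 0), al),
                       list(matrix(e2, 2, 2, dimnames = list(al, al))), al)
  w2 <- build_weights(tab, th)
  expect_equal(unname(exp(w2$logU1[1])), 2)
  # a favorable tripeptide-scale energy, against a scalar oracle
  tab3 <- energy_tables(stats::setNames(c(-7.66, 0), al),
                        list(matrix(0, 2, 2, dimnames = list(al, al))), al)
  expect_equal(unname(exp(build_weights(tab3, th)$logU1[1])),
               exp(7.66 / (0.0019872 * 298.15)))
  expect_error(energy_tables(stats::setNames(c(NA, 0), al),
                             list(matrix(0, 2, 2)), al),
               "non-finite energy")
})

test_that("partition function matches closed forms and brute force", {
  # all weights 1, n = 3, full alphabet: Z = 20^3
  al20 <- AA_ALPHABET
  ones <- energy_tables(stats::setNames(rep(0, 20), al20),
                        rep(list(matrix(0, 20, 20,
                                        dimnames = list(al20, al20))), 2),
                        al20)
  expect_equal(partition_function(build_weights(ones)), log(20^3),
               tolerance = 1e-12)
  # reduced alphabets, n up to 5, random energies: exhaustive enumeration
  for (k in 2:3) {
    for (n in c(3L, 5L)) {
      tab <- rand_tables(n, AA_ALPHABET[seq_len(k)], seed = 10 * k + n)
      ch <- build_weights(tab)
      bf <- bf_chain(tab)
      expect_equal(partition_function(ch), bf$Z_log, tolerance = 1e-10)
    }
  }
  expect_error(partition_function(structure(list(n = 1L, alphabet = "A",
                                                 logU1 = 0, logU = list()),
                                            class = "weight_chain")),
               "unsupported")
})

test_that("adding a constant to one grid's energies rescales Z predictably", {
  tab <- rand_tables(4, c("A", "C", "D"), seed = 3)
  th <- thermo()
  z0 <- partition_function(build_weights(tab, th))
  shift <- 2.7
  tab$pair_grids[[2]] <- tab$pair_grids[[2]] + shift
  z1 <- partition_function(build_weights(tab, th))
  expect_equal(z1, z0 - th$beta * shift, tolerance = 1e-12)
})

test_that("pair marginals equal the zeroed-matrix brute force", {
  for (k in 2:3) {
    for (n in 3:5) {
      tab <- rand_tables(n, AA_ALPHABET[seq_len(k)], seed = 100 + 10 * k + n)
      marg <- pair_marginals(build_weights(tab))
      bf <- bf_chain(tab)
      for (t in seq_len(n - 1L)) {
        expect_equal(marg$pair_probs[[t]], bf$pair[[t]], tolerance = 1e-10)
      }
    }
  }
})

test_that("marginals normalize, agree across positions and shift-invariantly", {
  tab <- rand_tables(5, AA_ALPHABET, seed = 21)
  marg <- pair_marginals(build_weights(tab))
  for (t in seq_len(4)) {
    expect_equal(sum(marg$pair_probs[[t]]), 1, tolerance = 1e-10)
    expect_equal(unname(rowSums(marg$transitions[[t]])), rep(1, 20),
                 tolerance = 1e-10)
  }
  # adjacent-pair consistency: the singlet marginal of residue j at an
  # interior position is the same whether read from the left or right pair
  for (t in 2:4) {
    expect_equal(colSums(marg$pair_probs[[t - 1L]]),
                 rowSums(marg$pair_probs[[t]]), tolerance = 1e-10)
  }
  # shift invariance of all probabilities
  tab2 <- tab
  tab2$pair_grids[[2]] <- tab2$pair_grids[[2]] + 5
  tab2$first_grid <- tab2$first_grid - 3
  marg2 <- pair_marginals(build_weights(tab2))
  for (t in seq_len(4)) {
    expect_equal(marg$pair_probs[[t]], marg2$pair_probs[[t]],
                 tolerance = 1e-12)
    expect_equal(marg$transitions[[t]], marg2$transitions[[t]],
                 tolerance = 1e-12)
  }
})

test_that("uniform weights give uniform marginals and transitions", {
  al <- AA_ALPHABET
  ones <- energy_tables(stats::setNames(rep(0, 20), al),
                        rep(list(matrix(0, 20, 20, dimnames = list(al, al))), 2),
                        al)
  marg <- pair_marginals(build_weights(ones))
  expect_true(all(abs(marg$pair_probs[[1]] - 1 / 400) < 1e-14))
  expect_true(all(abs(marg$transitions[[2]] - 1 / 20) < 1e-14))
})

test_that("transfer evaluation is associative", {
  tab <- rand_tables(4, c("A", "C", "D", "E"), seed = 8)
  ch <- build_weights(tab)
  left <- partition_function(ch)
  # right-to-left evaluation via the suffix recursion
  k <- 4
  lb <- rep(0, k)
  for (t in rev(seq_along(ch$logU))) {
    M <- ch$logU[[t]]
    lb <- vapply(seq_len(k), function(i) {
      m <- max(M[i, ] + lb)
      m + log(sum(exp(M[i, ] + lb - m)))
    }, numeric(1))
  }
  m <- max(lb)
  right <- m + log(sum(exp(lb - m)))
  expect_equal(left, right, tolerance = 1e-12)
})

test_that("first-grid probabilities are the softmax of -E/kT", {
  th <- thermo()
  al <- AA_ALPHABET
  # equal energies: uniform
  eq <- energy_tables(stats::setNames(rep(-3, 20), al),
                      list(matrix(0, 20, 20, dimnames = list(al, al))), al)
  expect_equal(unname(first_grid_probs(build_weights(eq, th))), rep(1 / 20, 20))
  # one residue lower by kT ln 19 gets probability 1/2
  e <- stats::setNames(rep(0, 20), al)
  e["W"] <- -log(19) / th$beta
  tab <- energy_tables(e, list(matrix(0, 20, 20, dimnames = list(al, al))), al)
  p <- first_grid_probs(build_weights(tab, th))
  expect_equal(unname(p["W"]), 0.5, tolerance = 1e-12)
  # random energies against a direct softmax
  tabr <- rand_tables(2, al, seed = 5)
  pr <- first_grid_probs(build_weights(tabr, th))
  ref <- exp(-th$beta * tabr$first_grid)
  expect_equal(pr, ref / sum(ref), tolerance = 1e-12)
})

test_that("folding first-grid weights in shifts Z by their log-mean", {
  tab <- rand_tables(3, c("A", "C"), seed = 12)
  ch <- build_weights(tab)
  z_plain <- partition_function(ch)
  z_fold <- partition_function(ch, fold_first_grid = TRUE)
  # brute force with the diagonal prefactor
  th <- thermo()
  k <- 2
  seqs <- as.matrix(expand.grid(1:k, 1:k, 1:k))
  w <- exp(-th$beta * (tab$first_grid[seqs[, 1]] +
                         tab$pair_grids[[1]][cbind(seqs[, 1], seqs[, 2])] +
                         tab$pair_grids[[2]][cbind(seqs[, 2], seqs[, 3])]))
  expect_equal(z_fold, log(sum(w)), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(z_plain, z_fold)))
})
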