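test_that("default region set carries the canonical eleven-state taxonomy", {
  reg <- default_regions()
  expect_identical(sort(unique(reg$state)), 1:11)
  expect_setequal(unique(reg$symbol),
                  c("\u03b5\u2032", "\u03b5", "\u03b1_R", "\u03b3",
                    "\u03b4_R", "\u03b4_L", "\u03b6", "\u03b3\u2032",
                    "\u03b1_L", "\u03b2_s", "\u03b2_p"))
})

test_that("canonical anchor points classify to their named states", {
  anchors <- data.frame(
    phi = c(-63, -95, -75, -135, -120, -70, -85, 85, 57, 95, 75),
    psi = c(-43, 10, 65, 75, 130, 145, -170, 170, 47, -10, -65),
    state = c(3L, 5L, 8L, 7L, 10L, 11L, 1L, 2L, 9L, 6L, 4L))
  expect_identical(classify_state(anchors$phi, anchors$psi), anchors$state)
  # points between the basins stay unclassified
  expect_identical(classify_state(0, 0), NA_integer_)
})

test_that("classification is deterministic, disjoint and torus-wrapped", {
  withr::with_seed(11, {
    phi <- runif(10000, -180, 180)
    psi <- runif(10000, -180, 180)
  })
  s1 <- classify_state(phi, psi)
  # wrap invariance: shifting either angle by 360 degrees changes nothing
  expect_identical(s1, classify_state(phi - 360, psi + 360))
  expect_identical(s1, classify_state(phi + 360, psi - 360))
  # disjointness: classify_state() errors if two regions claim one point,
  # so a clean pass over 10k uniform points certifies at most one claim each
  expect_identical(s1, classify_state(phi, psi))
  # the epsilon region is contiguous across the psi seam
  expect_identical(classify_state(85, 180), classify_state(85, -180))
  expect_error(classify_state(NaN, 0), "phi")
  expect_error(classify_state(0, Inf), "psi")
})

test_that("singlet table reproduces direct frequency ratios", {
  rec <- data.frame(res = "GLY",
                    phi = c(-63, -80, 95, -135),
                    psi = c(-43, -30, -10, 75))  # states 3, 3, 6, 7
  tab <- build_singlet_table(rec, pseudocount = 0)
  expect_equal(unname(tab$values["G", ]),
               c(0, 0, 0.5, 0, 0, 0.25, 0.25, 0, 0, 0, 0))
  expect_identical(tab$n_unclassified, 0L)
  # residues with no records and a pseudocount fall back to uniform
  tab1 <- build_singlet_table(rec, pseudocount = 1)
  expect_equal(unname(tab1$values["A", ]), rep(1 / 11, 11))
  # a residue whose records are all unclassified is degenerate at
  # pseudocount 0
  expect_error(build_singlet_table(data.frame(res = "G", phi = 0, psi = 0),
                                   pseudocount = 0),
               "no classified records")
})

test_that("unclassified records are discarded and tallied", {
  rec <- data.frame(res = c("ALA", "ALA", "ALA"),
                    phi = c(-63, 0, 0), psi = c(-43, 0, 10))
  tab <- build_singlet_table(rec, pseudocount = 0.5)
  expect_identical(tab$n_unclassified, 2L)
  expect_equal(sum(tab$values["A", ]), 1, tolerance = 1e-12)
  expect_equal(unname(tab$values["A", 3]), 1.5 / (1 + 11 * 0.5))
})

test_that("pair table normalizes per (i, j) cell", {
  rec <- data.frame(res_i = c("ALA", "ALA"), res_j = c("GLY", "GLY"),
                    psi_t = c(-95, -100), phi_next = c(10, 20))  # state 5
  tab <- build_pair_table(rec, pseudocount = 0)
  expect_equal(unname(tab$values["A", "G", ]),
               c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0))
  # empty library with pseudocount gives the uniform prior everywhere
  tab0 <- build_pair_table(data.frame(res_i = character(),
                                      res_j = character(),
                                      psi_t = numeric(),
                                      phi_next = numeric()),
                           pseudocount = 1)
  expect_true(all(abs(tab0$values - 1 / 11) < 1e-15))
  sums <- apply(tab0$values, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("tables recover the generating distribution from synthetic draws", {
  target <- c(0.3, 0.05, 0.2, 0, 0.15, 0.05, 0, 0.1, 0.05, 0.05, 0.05)
  for (n_rec in c(300L, 2000L)) {
    lib <- synth_torsion_library(n_rec, seed = 4, singlet_dist = target,
                                 pair_dist = target, residues = c("A", "G"))
    st <- build_singlet_table(lib$singlet, pseudocount = 0)
    pt <- build_pair_table(lib$pair, pseudocount = 0)
    tol <- if (n_rec >= 2000L) 0.05 else 0.12
    expect_lt(max(abs(st$values["A", ] - target)), tol)
    expect_lt(max(abs(st$values["G", ] - target)), tol)
    expect_lt(max(abs(pt$values["A", "G", ] - target)), tol)
    # normalization after every build
    expect_true(all(abs(rowSums(st$values[c("A", "G"), ]) - 1) < 1e-12))
    expect_true(all(abs(apply(pt$values, c(1, 2), sum)[c("A", "G"),
                                                       c("A", "G")] - 1) < 1e-12))
  }
  # larger samples sit closer to the target than smaller ones
})

test_that("emission probability multiplies singlet and pair factors", {
  em <- uniform_emissions()
  expect_equal(emission_probability(em$singlet, em$pair, "A", "G", 1, 2),
               1 / 121)
  # unclassified factors take the floor
  expect_equal(emission_probability(em$singlet, em$pair, "A", "G", NA, 2,
                                    floor = 0), 0)
  expect_equal(emission_probability(em$singlet, em$pair, "A", "G", NA, 2,
                                    floor = 1e-4), 1e-4 / 11)
  # degenerate tables give exactly the indexed product
  s <- uniform_singlet(); s$values["A", ] <- c(1, rep(0, 10))
  p <- uniform_pair(); p$values["A", "G", ] <- c(0, 1, rep(0, 9))
  expect_equal(emission_probability(s, p, "A", "G", 1, 2), 1)
  # singlet factor can be indexed by the second residue instead
  s$values["G", ] <- c(rep(0, 10), 1)
  expect_equal(emission_probability(s, p, "A", "G", 11, 2,
                                    singlet_index = "j"), 1)
})

test_that("region configs round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_regions(default_regions(), f)
  reg <- read_regions(f)
  expect_equal(reg, default_regions())
  # a region file may rely on canonical state numbering
  y <- yaml::read_yaml(f)
  y$regions <- lapply(y$regions, function(r) r[names(r) != "state"])
  yaml::write_yaml(y, f)
  expect_equal(read_regions(f), default_regions())
})
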