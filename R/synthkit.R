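# Synthetic fixtures: energy tables with planted optima, torsion libraries
# with known state frequencies, toy structures and docking logs. Every
# generator is a pure function of (spec, seed): a named offset per
# generator keeps the pseudorandom streams independent, so adding one
# generator never perturbs another's output.

SEED_STREAMS <- c(energy = 101L, library = 202L, observations = 303L,
                  structure = 404L, logs = 505L)

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Specification of a planted-optimum energy instance
#'
#' Describes a synthetic energy landscape in which one chosen peptide
#' sequence is strictly dominant: its first-grid cell and every
#' consecutive-pair cell sit `margin` kcal/mol below the background, whose
#' cells get `base_energy` plus Gaussian noise truncated to half the
#' margin (so the planted path stays strictly dominant cell-by-cell).
#' A sufficient condition for Viterbi recovery under neutral emissions is
#' `margin > 4 * noise_sd`.
#'
#' @param n peptide length (>= 2).
#' @param sequence planted sequence (n residue codes); drawn uniformly at
#'   random from the alphabet when `NULL`.
#' @param margin energy gap in kcal/mol (>= 0).
#' @param base_energy background binding energy in kcal/mol.
#' @param noise_sd Gaussian noise SD on background cells, kcal/mol.
#' @param seed integer seed.
#' @param alphabet residue alphabet.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(n, sequence = NULL, margin = 1, base_energy = -5,
                       noise_sd = 0.1, seed = 1L, alphabet = AA_ALPHABET) {
  alphabet <- check_alphabet(alphabet)
  if (n < 2L) stop("'n' must be >= 2")
  if (margin < 0 || noise_sd < 0) stop("'margin' and 'noise_sd' must be >= 0")
  if (is.null(sequence)) {
    sequence <- with_seed(seed + 7L, sample(alphabet, n, replace = TRUE))
  }
  sequence <- aa_normalize(sequence)
  if (length(sequence) != n) stop("'sequence' must have length n")
  if (!all(sequence %in% alphabet)) {
    stop("planted sequence uses residues outside the alphabet")
  }
  structure(list(n = as.integer(n), sequence = sequence, margin = margin,
                 base_energy = base_energy, noise_sd = noise_sd,
                 seed = as.integer(seed), alphabet = alphabet),
            class = "plant_spec")
}

#' Synthesize energy tables with a planted optimal sequence
#'
#' @param spec a [plant_spec()].
#' @return an [energy_tables()] object; deterministic given the spec.
#' @export
synth_energy_tables <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  al <- spec$alphabet
  k <- length(al)
  half <- spec$margin / 2
  trunc_noise <- function(m) {
    e <- matrix(stats::rnorm(length(m), 0, spec$noise_sd), nrow = nrow(m))
    if (spec$margin > 0) e <- pmin(pmax(e, -half), half)
    e
  }
  with_seed(spec$seed + SEED_STREAMS[["energy"]], {
    fg <- spec$base_energy + drop(trunc_noise(matrix(0, 1, k)))
    names(fg) <- al
    fg[spec$sequence[1]] <- spec$base_energy - spec$margin
    pg <- lapply(seq_len(spec$n - 1L), function(t) {
      M <- spec$base_energy + trunc_noise(matrix(0, k, k))
      dimnames(M) <- list(al, al)
      M[spec$sequence[t], spec$sequence[t + 1L]] <- spec$base_energy - spec$margin
      M
    })
    energy_tables(fg, pg, al)
  })
}

# area-weighted uniform draws inside torsion-state regions, one (x, y)
# point per requested state (vectorized per unique state)
sample_states_points <- function(states, regions) {
  pts <- matrix(NA_real_, length(states), 2L, dimnames = list(NULL, c("x", "y")))
  for (s in unique(states)) {
    idx <- which(states == s)
    rects <- regions[regions$state == s, , drop = FALSE]
    w <- (rects$phi_hi - rects$phi_lo) * (rects$psi_hi - rects$psi_lo)
    r <- if (nrow(rects) == 1L) rep(1L, length(idx))
      else sample.int(nrow(rects), length(idx), replace = TRUE, prob = w)
    pts[idx, 1] <- stats::runif(length(idx), rects$phi_lo[r], rects$phi_hi[r])
    pts[idx, 2] <- stats::runif(length(idx), rects$psi_lo[r], rects$psi_hi[r])
  }
  pts
}

sample_in_region <- function(state, regions) {
  drop(sample_states_points(state, regions))
}

#' Synthesize a coil library with known state frequencies
#'
#' Draws, for each residue (and residue pair), `n_records` torsion-state
#' labels from a target categorical distribution and places each record
#' uniformly at random inside the chosen region's rectangle. Built tables
#' therefore converge to the target distribution as `n_records` grows.
#'
#' @param n_records records per residue (singlet) and per residue pair.
#' @param seed integer seed.
#' @param singlet_dist target state distribution: an 11-vector shared by
#'   all residues, or a `length(residues)` x 11 matrix; uniform when
#'   `NULL`.
#' @param pair_dist as `singlet_dist` but for pairs (11-vector or
#'   k x k x 11 array).
#' @param residues residues to generate records for (pairs are all ordered
#'   combinations of these).
#' @param regions region set.
#' @return list with data frames `singlet` (`res`, `phi`, `psi`) and
#'   `pair` (`res_i`, `res_j`, `psi_t`, `phi_next`).
#' @export
synth_torsion_library <- function(n_records, seed = 1L, singlet_dist = NULL,
                                  pair_dist = NULL, residues = AA_ALPHABET,
                                  regions = default_regions()) {
  residues <- check_alphabet(residues)
  k <- length(residues)
  s_dist <- if (is.null(singlet_dist)) matrix(1 / 11, k, 11)
    else if (is.matrix(singlet_dist)) singlet_dist
    else matrix(singlet_dist, k, 11, byrow = TRUE)
  if (any(abs(rowSums(s_dist) - 1) > 1e-8)) {
    stop("'singlet_dist' rows must sum to 1")
  }
  p_dist <- if (is.null(pair_dist)) array(1 / 11, c(k, k, 11))
    else if (is.array(pair_dist) && length(dim(pair_dist)) == 3L) pair_dist
    else array(rep(pair_dist, each = k * k), c(k, k, 11))
  with_seed(seed + SEED_STREAMS[["library"]], {
    singlet <- do.call(rbind, lapply(seq_len(k), function(a) {
      states <- sample.int(11L, n_records, replace = TRUE, prob = s_dist[a, ])
      pts <- sample_states_points(states, regions)
      data.frame(res = residues[a], phi = pts[, 1], psi = pts[, 2])
    }))
    pair <- do.call(rbind, lapply(seq_len(k), function(a) {
      do.call(rbind, lapply(seq_len(k), function(b) {
        states <- sample.int(11L, n_records, replace = TRUE,
                             prob = p_dist[a, b, ])
        pts <- sample_states_points(states, regions)
        data.frame(res_i = residues[a], res_j = residues[b],
                   psi_t = pts[, 1], phi_next = pts[, 2])
      }))
    }))
    list(singlet = singlet, pair = pair)
  })
}

#' Synthesize torsion-state observations for an energy instance
#'
#' Assigns a torsion state to every docked candidate. Rules: `"uniform"`
#' gives every candidate the same `state` (neutralizing emissions, so a
#' decode is driven by energies alone); `"random"` draws i.i.d. states;
#' `"adversarial"` gives the planted path's candidates `penalized_state`
#' and everyone else `state` (with a zero-probability penalized state and
#' `floor = 0`, this demonstrates that emissions can veto the energy
#' optimum).
#'
#' @param tables an [energy_tables()] (defines alphabet and length).
#' @param rule `"uniform"`, `"random"` or `"adversarial"`.
#' @param seed integer seed (used by `"random"`).
#' @param state background state (default 3, the alpha_R basin).
#' @param planted planted sequence for the adversarial rule.
#' @param penalized_state state assigned along the planted path.
#' @return an [observation_set()].
#' @export
synth_observations <- function(tables, rule = c("uniform", "random",
                                                "adversarial"),
                               seed = 1L, state = 3L, planted = NULL,
                               penalized_state = 7L) {
  rule <- match.arg(rule)
  stopifnot(inherits(tables, "energy_tables"))
  al <- tables$alphabet
  k <- length(al)
  nm <- tables$n - 1L
  draw <- function(len) sample.int(11L, len, replace = TRUE)
  build <- function() {
    obs1 <- stats::setNames(rep(as.integer(state), k), al)
    pair_obs <- lapply(seq_len(nm), function(t) {
      m <- matrix(as.integer(state), k, k, dimnames = list(al, al))
      list(m1 = m, m2 = m)
    })
    if (rule == "random") {
      obs1 <- stats::setNames(draw(k), al)
      pair_obs <- lapply(seq_len(nm), function(t) {
        list(m1 = matrix(draw(k * k), k, k, dimnames = list(al, al)),
             m2 = matrix(draw(k * k), k, k, dimnames = list(al, al)))
      })
    } else if (rule == "adversarial") {
      if (is.null(planted)) stop("adversarial rule needs 'planted'")
      planted <- aa_normalize(planted)
      obs1[planted[1]] <- as.integer(penalized_state)
      for (t in seq_len(nm)) {
        pair_obs[[t]]$m1[planted[t], planted[t + 1L]] <- as.integer(penalized_state)
        pair_obs[[t]]$m2[planted[t], planted[t + 1L]] <- as.integer(penalized_state)
      }
    }
    observation_set(obs1, pair_obs, al)
  }
  if (rule == "random") {
    with_seed(seed + SEED_STREAMS[["observations"]], build())
  } else build()
}

# states of the (psi_t, phi_next) plane reachable once psi_t is fixed:
# regions whose phi-axis arc contains psi_t
compatible_states <- function(psi_t, regions) {
  ok <- in_arc(psi_t, regions$phi_lo, regions$phi_hi)
  unique(regions$state[ok])
}

#' Synthesize per-candidate torsion angles
#'
#' Angle-level counterpart of [synth_observations()]: generates actual
#' (phi, psi) values inside the target regions, respecting the geometric
#' coupling that psi_t is shared between the (phi_t, psi_t) and
#' (psi_t, phi_t+1) planes. Where the drawn psi_t is incompatible with
#' every region's phi-axis, phi_t+1 is drawn uniformly (the record may
#' classify as unclassified, as strained docked poses do).
#'
#' @inheritParams synth_observations
#' @param regions region set.
#' @return list of data frames `first` (`aa`, `phi`, `psi`) and `pairs`
#'   (`grid_t`, `aa_i`, `aa_j`, `phi_t`, `psi_t`, `phi_next`), suitable for
#'   [make_observations()] and [write_energy_tables()].
#' @export
synth_observation_angles <- function(tables, rule = c("uniform", "random"),
                                     seed = 1L, state = 3L,
                                     regions = default_regions()) {
  rule <- match.arg(rule)
  stopifnot(inherits(tables, "energy_tables"))
  al <- tables$alphabet
  k <- length(al)
  with_seed(seed + SEED_STREAMS[["observations"]], {
    pick_state <- function() {
      if (rule == "uniform") as.integer(state) else sample.int(11L, 1L)
    }
    first <- do.call(rbind, lapply(al, function(a) {
      pt <- sample_in_region(pick_state(), regions)
      data.frame(aa = a, phi = pt[["x"]], psi = pt[["y"]])
    }))
    pairs <- do.call(rbind, lapply(seq_len(tables$n - 1L), function(t) {
      do.call(rbind, lapply(al, function(a) {
        do.call(rbind, lapply(al, function(b) {
          m1 <- pick_state()
          pt <- sample_in_region(m1, regions)
          phi_t <- pt[["x"]]; psi_t <- pt[["y"]]
          if (rule == "uniform") {
            # keep psi_t inside the state's own phi arc where possible, so
            # the (psi_t, phi_next) plane can realize the same state
            rect <- regions[regions$state == m1, ][1, ]
            lo <- max(rect$psi_lo, rect$phi_lo)
            hi <- min(rect$psi_hi, rect$phi_hi)
            if (lo < hi) psi_t <- stats::runif(1, lo, hi)
          }
          comp <- compatible_states(psi_t, regions)
          target <- if (rule == "uniform" && state %in% comp) as.integer(state)
            else if (length(comp)) comp[sample.int(length(comp), 1L)]
            else NA_integer_
          phi_next <- if (is.na(target)) {
            stats::runif(1, -180, 180)
          } else {
            # draw phi_next from a rectangle of the target region whose
            # phi-arc contains psi_t
            rects <- regions[regions$state == target &
                               in_arc(psi_t, regions$phi_lo, regions$phi_hi), ,
                             drop = FALSE]
            r <- if (nrow(rects) == 1L) 1L else sample.int(nrow(rects), 1L)
            stats::runif(1, rects$psi_lo[r], rects$psi_hi[r])
          }
          data.frame(grid_t = t, aa_i = a, aa_j = b, phi_t = phi_t,
                     psi_t = psi_t, phi_next = phi_next)
        }))
      }))
    }))
    list(first = first, pairs = pairs)
  })
}

#' Write a toy CA-trace structure in PDB format
#'
#' @param file output path.
#' @param coords n x 3 coordinate matrix (angstroms).
#' @param resnos residue numbers (default 1..n); repeats allowed together
#'   with `alt` to emit alternate-location conformers.
#' @param chain chain identifier.
#' @param alt per-row altLoc characters (`""` for none).
#' @param occ per-row occupancies.
#' @param resid residue name for all rows.
#' @return the file path, invisibly.
#' @export
synth_ca_pdb <- function(file, coords, resnos = seq_len(nrow(coords)),
                         chain = "A", alt = rep("", nrow(coords)),
                         occ = rep(1, nrow(coords)), resid = "ALA") {
  coords <- as.matrix(coords)
  lines <- vapply(seq_len(nrow(coords)), function(r) {
    sprintf("ATOM  %5d  CA %1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            r, substr(paste0(alt[r], " "), 1, 1), resid, chain, resnos[r],
            coords[r, 1], coords[r, 2], coords[r, 3], occ[r], 0)
  }, character(1))
  writeLines(c(lines, "END"), file)
  invisible(file)
}

# PDB-style ATOM line for docked-coordinate blocks of synthetic logs
# (standard columns: name 13-16, resName 18-20, chain 22, resSeq 23-26)
format_atom_line <- function(eleno, elety, resid, resno, xyz) {
  name <- if (nchar(elety) < 4L) paste0(" ", elety) else elety
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          eleno, name, resid, resno, xyz[1], xyz[2], xyz[3])
}

#' Write a synthetic docking result log
#'
#' Emits the tolerant run-block grammar [parse_docking_log()] consumes:
#' one block per energy, each with an estimated free energy of binding
#' line and docked coordinates built by forward kinematics from the given
#' torsions.
#'
#' @param file output path.
#' @param energies binding energies, one per run (kcal/mol).
#' @param torsions for `kind = "pair"`, `c(phi_t, psi_t, phi_next)`; for
#'   `kind = "single"`, `c(phi, psi)`. Used for every run's coordinates.
#' @param kind `"pair"` (Ace-capped dipeptide) or `"single"` (Ace-capped
#'   single residue with terminal carboxyl oxygen).
#' @return the file path, invisibly.
#' @export
synth_docking_log <- function(file, energies, torsions, kind = c("pair",
                                                                 "single")) {
  kind <- match.arg(kind)
  coords <- if (kind == "pair") {
    m <- build_dipeptide_geometry(torsions[1], torsions[2], torsions[3])
    rbind(
      format_atom_line(1, "C", "ACE", 1, m["C_ace", ]),
      format_atom_line(2, "N", "GLY", 2, m["N1", ]),
      format_atom_line(3, "CA", "GLY", 2, m["CA1", ]),
      format_atom_line(4, "C", "GLY", 2, m["C1", ]),
      format_atom_line(5, "N", "GLY", 3, m["N2", ]),
      format_atom_line(6, "CA", "GLY", 3, m["CA2", ]),
      format_atom_line(7, "C", "GLY", 3, m["C2", ]))
  } else {
    # single residue: phi from the Ace cap, psi measured to OXT
    m <- build_dipeptide_geometry(torsions[1], torsions[2], 0)
    rbind(
      format_atom_line(1, "C", "ACE", 1, m["C_ace", ]),
      format_atom_line(2, "N", "GLY", 2, m["N1", ]),
      format_atom_line(3, "CA", "GLY", 2, m["CA1", ]),
      format_atom_line(4, "C", "GLY", 2, m["C1", ]),
      format_atom_line(5, "OXT", "GLY", 2, m["N2", ]))
  }
  blocks <- unlist(lapply(seq_along(energies), function(r) {
    c(sprintf("Run: %d", r),
      sprintf("Estimated Free Energy of Binding    =  %+.2f kcal/mol",
              energies[r]),
      paste0("DOCKED: ", coords),
      "")
  }))
  writeLines(blocks, file)
  invisible(file)
}

#' Write a complete docking-log directory for an energy instance
#'
#' Materializes an [energy_tables()] object (plus a uniform torsion rule)
#' as the on-disk layout [backend_from_logs()] reads: `grid1/<AA>.log` and
#' `grid<t>/<AAi><AAj>.log`, single-run logs whose energies are the table
#' cells and whose docked coordinates realize the requested torsion state.
#'
#' @param dir output directory (created).
#' @param tables an [energy_tables()].
#' @param state torsion state realized by every candidate's coordinates.
#' @param regions region set (for the state's representative angles).
#' @return `dir`, invisibly.
#' @export
synth_log_dir <- function(dir, tables, state = 3L,
                          regions = default_regions()) {
  stopifnot(inherits(tables, "energy_tables"))
  rect <- regions[regions$state == state, ][1, ]
  mid_phi <- (rect$phi_lo + rect$phi_hi) / 2
  mid_psi <- (rect$psi_lo + rect$psi_hi) / 2
  al <- tables$alphabet
  dir.create(file.path(dir, "grid1"), recursive = TRUE, showWarnings = FALSE)
  for (a in al) {
    synth_docking_log(file.path(dir, "grid1", paste0(a, ".log")),
                      energies = tables$first_grid[a],
                      torsions = c(mid_phi, mid_psi), kind = "single")
  }
  for (t in seq_len(tables$n - 1L)) {
    gdir <- file.path(dir, paste0("grid", t + 1L))
    dir.create(gdir, showWarnings = FALSE)
    for (a in al) for (b in al) {
      # psi_t doubles as the phi-axis of the pair plane; the alpha_R basin
      # is self-consistent (its psi range lies inside its phi range)
      synth_docking_log(file.path(gdir, paste0(a, b, ".log")),
                        energies = tables$pair_grids[[t]][a, b],
                        torsions = c(mid_phi, mid_psi, mid_psi),
                        kind = "pair")
    }
  }
  invisible(dir)
}
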