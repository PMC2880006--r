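#' Read per-grid binding energy tables from TSV
#'
#' First-grid file: header `aa`, `energy_kcal_mol` (optionally `phi`,
#' `psi`); one row per alphabet residue. Pair file: header `grid_t`,
#' `aa_i`, `aa_j`, `energy_kcal_mol` (optionally `phi_t`, `psi_t`,
#' `phi_next`); grid_t runs 1..n-1 with one row per (i, j) cell.
#' Completeness and duplicates are checked strictly and reported by cell.
#'
#' @param first_grid_file,pair_file TSV paths.
#' @param alphabet residue alphabet (reduced alphabets supported).
#' @return list with `energies` (an [energy_tables()]) and `torsions`
#'   (`NULL` when the files carry no angle columns, else a list `first` /
#'   `pairs` of data frames usable by [make_observations()]).
#' @export
read_energy_tables <- function(first_grid_file, pair_file,
                               alphabet = AA_ALPHABET) {
  alphabet <- check_alphabet(alphabet)
  k <- length(alphabet)
  for (f in c(first_grid_file, pair_file)) {
    if (!file.exists(f)) stop("energy table file not found: ", f)
  }
  fg <- utils::read.delim(first_grid_file, stringsAsFactors = FALSE)
  if (!all(c("aa", "energy_kcal_mol") %in% names(fg))) {
    stop("first-grid file must have columns 'aa' and 'energy_kcal_mol'")
  }
  fg$aa <- aa_normalize(fg$aa)
  if (anyDuplicated(fg$aa)) {
    stop("duplicate first-grid row for residue ",
         fg$aa[duplicated(fg$aa)][1])
  }
  miss <- setdiff(alphabet, fg$aa)
  if (length(miss)) stop("first-grid file missing residue(s): ",
                         paste(miss, collapse = ", "))
  fg <- fg[match(alphabet, fg$aa), ]
  first_grid <- stats::setNames(as.numeric(fg$energy_kcal_mol), alphabet)

  pr <- utils::read.delim(pair_file, stringsAsFactors = FALSE)
  need <- c("grid_t", "aa_i", "aa_j", "energy_kcal_mol")
  if (!all(need %in% names(pr))) {
    stop("pair file must have columns ", paste(need, collapse = ", "))
  }
  pr$aa_i <- aa_normalize(pr$aa_i)
  pr$aa_j <- aa_normalize(pr$aa_j)
  pr$grid_t <- as.integer(pr$grid_t)
  grids <- sort(unique(pr$grid_t))
  if (!identical(grids, seq_along(grids))) {
    stop("pair file grid_t values must be contiguous starting at 1")
  }
  key <- paste(pr$grid_t, pr$aa_i, pr$aa_j)
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1], " ")[[1]]
    stop(sprintf("duplicate pair-energy cell (grid %s, %s, %s)",
                 d[1], d[2], d[3]))
  }
  pair_grids <- lapply(grids, function(t) {
    sub <- pr[pr$grid_t == t, ]
    M <- matrix(NA_real_, k, k, dimnames = list(alphabet, alphabet))
    M[cbind(sub$aa_i, sub$aa_j)] <- as.numeric(sub$energy_kcal_mol)
    if (anyNA(M)) {
      bad <- which(is.na(M), arr.ind = TRUE)[1, ]
      stop(sprintf("pair file missing cell (grid %d, %s, %s)",
                   t, alphabet[bad[1]], alphabet[bad[2]]))
    }
    M
  })
  energies <- energy_tables(first_grid, pair_grids, alphabet)
  torsions <- NULL
  if (all(c("phi", "psi") %in% names(fg)) &&
      all(c("phi_t", "psi_t", "phi_next") %in% names(pr))) {
    torsions <- list(first = fg[, c("aa", "phi", "psi")],
                     pairs = pr[, c("grid_t", "aa_i", "aa_j",
                                    "phi_t", "psi_t", "phi_next")])
  }
  list(energies = energies, torsions = torsions)
}

#' Write energy tables (and optional torsions) as normalized TSV
#'
#' Writes the canonical interchange format read by [read_energy_tables()]:
#' rows in alphabet order, energies printed with full precision, so
#' write-read-write round trips are byte-identical.
#'
#' @param energies an [energy_tables()] object.
#' @param first_grid_file,pair_file output TSV paths.
#' @param torsions optional torsion observations (`first` / `pairs` data
#'   frames, as produced by [synth_observation_angles()]) to embed.
#' @return invisibly, the two paths.
#' @export
write_energy_tables <- function(energies, first_grid_file, pair_file,
                                torsions = NULL) {
  stopifnot(inherits(energies, "energy_tables"))
  al <- energies$alphabet
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  fg <- data.frame(aa = al, energy_kcal_mol = fmt(energies$first_grid))
  pr <- do.call(rbind, lapply(seq_along(energies$pair_grids), function(t) {
    M <- energies$pair_grids[[t]]
    data.frame(grid_t = t,
               aa_i = rep(al, times = length(al)),
               aa_j = rep(al, each = length(al)),
               energy_kcal_mol = fmt(M[cbind(rep(al, times = length(al)),
                                             rep(al, each = length(al)))]))
  }))
  if (!is.null(torsions)) {
    tf <- torsions$first
    fg$phi <- fmt(tf$phi[match(al, aa_normalize(tf$aa))])
    fg$psi <- fmt(tf$psi[match(al, aa_normalize(tf$aa))])
    tp <- torsions$pairs
    kk <- paste(tp$grid_t, aa_normalize(tp$aa_i), aa_normalize(tp$aa_j))
    idx <- match(paste(pr$grid_t, pr$aa_i, pr$aa_j), kk)
    pr$phi_t <- fmt(tp$phi_t[idx])
    pr$psi_t <- fmt(tp$psi_t[idx])
    pr$phi_next <- fmt(tp$phi_next[idx])
  }
  utils::write.table(fg, first_grid_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pr, pair_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(first_grid_file, pair_file))
}

#' Build an observation set from torsion-angle tables
#'
#' Classifies the per-candidate docked torsion angles (as read by
#' [read_energy_tables()] or generated by [synth_observation_angles()])
#' into the eleven states.
#'
#' @param torsions list with data frames `first` (`aa`, `phi`, `psi`) and
#'   `pairs` (`grid_t`, `aa_i`, `aa_j`, `phi_t`, `psi_t`, `phi_next`).
#' @param regions region set for classification.
#' @param alphabet residue alphabet.
#' @return an [observation_set()].
#' @export
make_observations <- function(torsions, regions = default_regions(),
                              alphabet = AA_ALPHABET) {
  alphabet <- check_alphabet(alphabet)
  k <- length(alphabet)
  tf <- torsions$first
  obs1 <- stats::setNames(classify_state(tf$phi, tf$psi, regions),
                          aa_normalize(tf$aa))[alphabet]
  tp <- torsions$pairs
  tp$aa_i <- aa_normalize(tp$aa_i); tp$aa_j <- aa_normalize(tp$aa_j)
  pair_obs <- lapply(sort(unique(tp$grid_t)), function(t) {
    sub <- tp[tp$grid_t == t, ]
    m1 <- m2 <- matrix(NA_integer_, k, k, dimnames = list(alphabet, alphabet))
    m1[cbind(sub$aa_i, sub$aa_j)] <- classify_state(sub$phi_t, sub$psi_t, regions)
    m2[cbind(sub$aa_i, sub$aa_j)] <- classify_state(sub$psi_t, sub$phi_next, regions)
    list(m1 = m1, m2 = m2)
  })
  observation_set(obs1, pair_obs, alphabet)
}

#' Read a coil library from TSV
#'
#' Singlet file: header `res`, `phi`, `psi`. Pair file: header `res_i`,
#' `res_j`, `psi_t`, `phi_next`. Residues as 1- or 3-letter codes.
#'
#' @param singlet_file,pair_file TSV paths (either may be `NULL`).
#' @return list with data frames `singlet` and `pair` (normalized 1-letter
#'   codes).
#' @export
read_coil_library <- function(singlet_file = NULL, pair_file = NULL) {
  out <- list(singlet = NULL, pair = NULL)
  for (f in c(singlet_file, pair_file)) {
    if (!file.exists(f)) stop("coil library file not found: ", f)
  }
  if (!is.null(singlet_file)) {
    s <- utils::read.delim(singlet_file, stringsAsFactors = FALSE)
    if (!all(c("res", "phi", "psi") %in% names(s))) {
      stop("coil singlet file must have columns res, phi, psi")
    }
    s$res <- aa_normalize(s$res)
    out$singlet <- s[, c("res", "phi", "psi")]
  }
  if (!is.null(pair_file)) {
    p <- utils::read.delim(pair_file, stringsAsFactors = FALSE)
    if (!all(c("res_i", "res_j", "psi_t", "phi_next") %in% names(p))) {
      stop("coil pair file must have columns res_i, res_j, psi_t, phi_next")
    }
    p$res_i <- aa_normalize(p$res_i); p$res_j <- aa_normalize(p$res_j)
    out$pair <- p[, c("res_i", "res_j", "psi_t", "phi_next")]
  }
  out
}

#' Read / write a torsion-region configuration
#'
#' YAML with a top-level `regions` list; each entry has `name`, `phi_lo`,
#' `phi_hi`, `psi_lo`, `psi_hi` and optionally `state`. Multiple entries
#' may share a name (wrapped regions). States default to the canonical
#' numbering of the names.
#'
#' @param path YAML file path.
#' @return [read_regions()] returns a validated region set.
#' @export
read_regions <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$regions)) stop("region file has no 'regions' list")
  rows <- lapply(y$regions, function(r) {
    data.frame(state = if (is.null(r$state)) NA_integer_ else as.integer(r$state),
               name = r$name, phi_lo = r$phi_lo, phi_hi = r$phi_hi,
               psi_lo = r$psi_lo, psi_hi = r$psi_hi,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (anyNA(df$state)) {
    canon <- stats::setNames(1:11, unique(default_regions()$name))
    df$state <- unname(canon[df$name])
    if (anyNA(df$state)) stop("unknown region name in ", path)
  }
  region_set(df)
}

#' @rdname read_regions
#' @param regions a region set to serialize.
#' @return [write_regions()] returns the path, invisibly.
#' @export
write_regions <- function(regions, path) {
  entries <- lapply(seq_len(nrow(regions)), function(r) {
    list(name = regions$name[r], state = regions$state[r],
         phi_lo = regions$phi_lo[r], phi_hi = regions$phi_hi[r],
         psi_lo = regions$psi_lo[r], psi_hi = regions$psi_hi[r])
  })
  yaml::write_yaml(list(regions = entries), path)
  invisible(path)
}

#' Parse a docking result log
#'
#' Tolerant line-oriented parser for classic docking logs: runs are
#' announced by a `Run: <k>` line, each carrying an
#' `Estimated Free Energy of Binding = <e> kcal/mol` line and docked
#' coordinate records (`ATOM`/`HETATM`, optionally prefixed `DOCKED:`).
#' Returns the best (lowest-energy) run; ties go to the earliest run.
#'
#' @param path log file path (or a character vector of lines).
#' @return list with `run`, `binding_energy` (kcal/mol) and `atoms` (data
#'   frame: `resid`, `resno`, `elety`, `x`, `y`, `z`).
#' @export
parse_docking_log <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  run_starts <- grep("^\\s*(DOCKED:\\s*)?Run[ :=]+[0-9]+", lines)
  if (!length(run_starts)) stop("parse error: no docking runs found")
  bounds <- c(run_starts, length(lines) + 1L)
  runs <- vector("list", length(run_starts))
  for (b in seq_along(run_starts)) {
    block <- lines[run_starts[b]:(bounds[b + 1L] - 1L)]
    run_id <- as.integer(sub("^\\s*(DOCKED:\\s*)?Run[ :=]+([0-9]+).*$", "\\2",
                             block[1]))
    eline <- grep("Estimated Free Energy of Binding", block)
    if (!length(eline)) {
      stop(sprintf("parse error: run %d has no binding energy line", run_id))
    }
    eg <- regmatches(block[eline[1]],
                     regexpr("[=:]\\s*[-+]?[0-9.]+([eE][-+]?[0-9]+)?",
                             block[eline[1]]))
    energy <- suppressWarnings(as.numeric(sub("^[=:]\\s*", "", eg)))
    if (!length(energy) || is.na(energy)) {
      stop(sprintf("parse error at line %d: unparseable binding energy",
                   run_starts[b] + eline[1] - 1L))
    }
    arec <- grep("^(DOCKED:\\s*)?(ATOM|HETATM)", block, value = TRUE)
    arec <- sub("^DOCKED:\\s*", "", arec)
    atoms <- if (length(arec)) {
      data.frame(
        resid = trimws(substr(arec, 18, 20)),
        resno = as.integer(substr(arec, 23, 26)),
        elety = trimws(substr(arec, 13, 16)),
        x = as.numeric(substr(arec, 31, 38)),
        y = as.numeric(substr(arec, 39, 46)),
        z = as.numeric(substr(arec, 47, 54)),
        stringsAsFactors = FALSE)
    } else {
      data.frame(resid = character(), resno = integer(), elety = character(),
                 x = numeric(), y = numeric(), z = numeric())
    }
    runs[[b]] <- list(run = run_id, binding_energy = energy, atoms = atoms)
  }
  energies <- vapply(runs, `[[`, numeric(1), "binding_energy")
  runs[[which.min(energies)]]  # which.min takes the earliest on ties
}

# torsions of a docked single residue from its log atoms: phi from the Ace
# carbonyl, psi measured to the terminal carboxyl oxygen (OXT, else O)
single_torsions_from_atoms <- function(atoms) {
  ace <- atoms[atoms$resid == "ACE", ]
  res <- atoms[atoms$resid != "ACE", ]
  need <- function(df, what) {
    row <- df[df$elety == what, ]
    if (!nrow(row)) stop("missing backbone atom: ", what)
    as.numeric(row[1, c("x", "y", "z")])
  }
  c_ace <- need(ace, "C")
  nn <- need(res, "N"); ca <- need(res, "CA"); cc <- need(res, "C")
  oterm <- res[res$elety %in% c("OXT", "O"), ]
  if (!nrow(oterm)) stop("missing backbone atom: OXT/O")
  oterm <- oterm[order(match(oterm$elety, c("OXT", "O"))), ]
  ox <- as.numeric(oterm[1, c("x", "y", "z")])
  c(phi = dihedral(c_ace, nn, ca, cc), psi = dihedral(nn, ca, cc, ox))
}

# torsions of a docked Ace-capped dipeptide from its log atoms
pair_torsions_from_atoms <- function(atoms) {
  ace <- atoms[atoms$resid == "ACE", ]
  res <- atoms[atoms$resid != "ACE", ]
  rn <- sort(unique(res$resno))
  if (length(rn) < 2L) stop("docked coordinates do not contain two residues")
  need <- function(df, what) {
    row <- df[df$elety == what, ]
    if (!nrow(row)) stop("missing backbone atom: ", what)
    as.numeric(row[1, c("x", "y", "z")])
  }
  r1 <- res[res$resno == rn[1], ]; r2 <- res[res$resno == rn[2], ]
  m <- rbind(C_ace = need(ace, "C"),
             N1 = need(r1, "N"), CA1 = need(r1, "CA"), C1 = need(r1, "C"),
             N2 = need(r2, "N"), CA2 = need(r2, "CA"), C2 = need(r2, "C"))
  backbone_torsions(m)
}

#' Energy backend from a directory of docking logs
#'
#' Directory layout: `grid1/<AA>.log` for the 20 single-residue docks and
#' `grid<t>/<AAi><AAj>.log` (t = 2..n) for the 400 dipeptide docks of each
#' grid pair. Each candidate's energy is its best run's binding energy and
#' its torsion observation is computed from the best run's docked
#' coordinates.
#'
#' @param dir directory path.
#' @param n peptide length.
#' @param alphabet residue alphabet (reduced alphabets supported, matching
#'   reduced candidate sets on disk).
#' @param regions region set for torsion-state classification.
#' @return list with `energies` ([energy_tables()]) and `observations`
#'   ([observation_set()]).
#' @export
backend_from_logs <- function(dir, n, alphabet = AA_ALPHABET,
                              regions = default_regions()) {
  alphabet <- check_alphabet(alphabet)
  k <- length(alphabet)
  grab <- function(path) {
    if (!file.exists(path)) stop("completeness error: missing candidate log ", path)
    rec <- tryCatch(parse_docking_log(path),
                    error = function(e) stop("error in log ", path, ": ",
                                             conditionMessage(e)))
    rec
  }
  first_grid <- stats::setNames(numeric(k), alphabet)
  phi1 <- psi1 <- stats::setNames(numeric(k), alphabet)
  for (a in alphabet) {
    rec <- grab(file.path(dir, "grid1", paste0(a, ".log")))
    first_grid[a] <- rec$binding_energy
    tors <- single_torsions_from_atoms(rec$atoms)
    phi1[a] <- tors["phi"]; psi1[a] <- tors["psi"]
  }
  pair_grids <- vector("list", n - 1L)
  pair_obs <- vector("list", n - 1L)
  for (t in seq_len(n - 1L)) {
    M <- matrix(NA_real_, k, k, dimnames = list(alphabet, alphabet))
    m1 <- m2 <- matrix(NA_integer_, k, k, dimnames = list(alphabet, alphabet))
    for (a in alphabet) for (b in alphabet) {
      rec <- grab(file.path(dir, paste0("grid", t + 1L), paste0(a, b, ".log")))
      M[a, b] <- rec$binding_energy
      tors <- pair_torsions_from_atoms(rec$atoms)
      m1[a, b] <- classify_state(tors["phi_t"], tors["psi_t"], regions)
      m2[a, b] <- classify_state(tors["psi_t"], tors["phi_next"], regions)
    }
    pair_grids[[t]] <- M
    pair_obs[[t]] <- list(m1 = m1, m2 = m2)
  }
  obs1 <- stats::setNames(classify_state(phi1, psi1, regions), alphabet)
  list(energies = energy_tables(first_grid, pair_grids, alphabet),
       observations = observation_set(obs1, pair_obs, alphabet))
}

#' Write the design report and FASTA output
#'
#' The JSON report carries the decoded sequence, its log score, the
#' per-grid breakdown, the echoed run configuration and the seed; the
#' FASTA file holds the designed peptide in one-letter codes.
#'
#' @param fit a [design_peptide()] result.
#' @param report_file JSON output path (skipped if `NULL`).
#' @param fasta_file FASTA output path (skipped if `NULL`).
#' @param seed seed to echo in the report.
#' @param timestamp whether to include a wall-clock timestamp (excluded
#'   from byte-identity comparisons).
#' @return invisibly, the report list.
#' @export
write_design_report <- function(fit, report_file = NULL, fasta_file = NULL,
                                seed = NULL, timestamp = TRUE) {
  stopifnot(inherits(fit, "peptide_design"))
  rep <- list(
    sequence = paste(fit$sequence, collapse = ""),
    sequence3 = paste(AA_THREE[match(fit$sequence, AA_ALPHABET)],
                      collapse = "-"),
    log_score = fit$log_score,
    log_Z = fit$marginals$log_Z,
    breakdown = fit$breakdown,
    config = fit$config[setdiff(names(fit$config), "alphabet")],
    alphabet = paste(fit$config$alphabet, collapse = ""),
    seed = seed
  )
  if (timestamp) rep$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(report_file)) {
    jsonlite::write_json(rep, report_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  if (!is.null(fasta_file)) {
    writeLines(c(sprintf(">designed_peptide log_score=%.6f", fit$log_score),
                 paste(fit$sequence, collapse = "")), fasta_file)
  }
  invisible(rep)
}

#' Write emission tables as TSV
#'
#' @param singlet a [build_singlet_table()] result.
#' @param pair a [build_pair_table()] result.
#' @param singlet_file,pair_file output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_emission_tables <- function(singlet = NULL, pair = NULL,
                                  singlet_file = NULL, pair_file = NULL) {
  paths <- character()
  if (!is.null(singlet) && !is.null(singlet_file)) {
    df <- data.frame(res = rownames(singlet$values), singlet$values,
                     check.names = FALSE)
    names(df) <- c("res", paste0("state", 1:11))
    utils::write.table(df, singlet_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, singlet_file)
  }
  if (!is.null(pair) && !is.null(pair_file)) {
    grid <- expand.grid(res_i = AA_ALPHABET, res_j = AA_ALPHABET,
                        stringsAsFactors = FALSE)
    vals <- t(vapply(seq_len(nrow(grid)), function(r) {
      pair$values[grid$res_i[r], grid$res_j[r], ]
    }, numeric(11)))
    df <- data.frame(grid, vals)
    names(df) <- c("res_i", "res_j", paste0("state", 1:11))
    utils::write.table(df, pair_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, pair_file)
  }
  invisible(paths)
}
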