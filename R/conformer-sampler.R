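#' Ramachandran basin library
#'
#' Parametric Gaussian basins in (phi, psi) space used for biased backbone
#' sampling, together with the disjoint classification rectangles used to
#' label a conformation as PPII, beta, right- or left-handed alpha. Centers
#' and spreads follow the canonical basin locations for disordered chains;
#' rectangles are pairwise disjoint and each contains its own center.
#'
#' @param spread_scale Multiplier applied to all basin spreads (default 1).
#' @return A tibble with one row per basin (`ppii`, `beta`, `alpha_r`,
#'   `alpha_l`) and columns `basin`, `phi_c`, `psi_c`, `sig_phi`, `sig_psi`,
#'   `phi_min`, `phi_max`, `psi_min`, `psi_max`.
#' @export
basin_library <- function(spread_scale = 1) {
  tibble::tibble(
    basin = c("ppii", "beta", "alpha_r", "alpha_l"),
    phi_c = c(-75, -135, -63, 60),
    psi_c = c(145, 135, -43, 45),
    sig_phi = c(15, 20, 10, 10) * spread_scale,
    sig_psi = c(15, 20, 10, 10) * spread_scale,
    phi_min = c(-115, -180, -140, 20),
    phi_max = c(-40, -115, -40, 110),
    psi_min = c(90, 90, -90, -10),
    psi_max = c(180, 180, 40, 100)
  )
}

beta_rect_vector <- function(basins) {
  b <- basins[basins$basin == "beta", ]
  c(b$phi_min, b$phi_max, b$psi_min, b$psi_max)
}

# default coil-state mixture over basins (ppii, beta, alpha_r, alpha_l);
# calibrated so a 323-residue coil-preset ensemble reproduces the compact
# disordered-chain R_Gyr regime (see the methods vignette)
COIL_MIX_DEFAULT <- c(ppii = 0.55, beta = 0.02, alpha_r = 0.33, alpha_l = 0.10)

basins_to_matrix <- function(basins) {
  # rows: ppii, beta, alpha_r, alpha_l; cols: phi_c, psi_c, sig_phi, sig_psi
  ord <- match(c("ppii", "beta", "alpha_r", "alpha_l"), basins$basin)
  as.matrix(basins[ord, c("phi_c", "psi_c", "sig_phi", "sig_psi")])
}

coil_mix_vector <- function(coil_mix) {
  # order: ppii, beta, alpha_r, alpha_l (matches basin matrix rows)
  if (!is.null(names(coil_mix))) {
    coil_mix <- coil_mix[c("ppii", "beta", "alpha_r", "alpha_l")]
  }
  if (length(coil_mix) != 4 || any(coil_mix < 0)) {
    abort("`coil_mix` must be 4 nonnegative weights (ppii, beta, alpha_r, alpha_l).")
  }
  as.numeric(coil_mix / sum(coil_mix))
}

#' Per-residue secondary-structure sampling weights
#'
#' Builds the per-residue (alpha, beta, coil) weight profile that drives
#' basin selection during sampling. `preset = "coil"` puts all weight on the
#' coil state, `"beta"` on the beta state; `"threestate"` uses the supplied
#' per-residue profile (e.g. a 3-state secondary-structure prediction).
#'
#' @param sequence Sequence string (sets the profile length).
#' @param preset One of `"coil"`, `"beta"`, `"threestate"`.
#' @param profile For `"threestate"`: a data frame with numeric columns
#'   `w_alpha`, `w_beta`, `w_coil` and one row per residue (rows are
#'   renormalized to sum to 1).
#' @return A tibble with columns `residue` (one-letter code), `w_alpha`,
#'   `w_beta`, `w_coil`; rows sum to 1.
#' @export
weight_profile <- function(sequence, preset = c("coil", "beta", "threestate"),
                           profile = NULL) {
  preset <- match.arg(preset)
  chars <- seq_to_chars(sequence)
  L <- length(chars)
  if (preset == "coil") {
    w <- cbind(w_alpha = rep(0, L), w_beta = 0, w_coil = 1)
  } else if (preset == "beta") {
    w <- cbind(w_alpha = rep(0, L), w_beta = 1, w_coil = 0)
  } else {
    if (is.null(profile)) {
      abort("Preset \"threestate\" requires `profile` (see `--profile`/`profile=`).")
    }
    if (!all(c("w_alpha", "w_beta", "w_coil") %in% names(profile))) {
      abort("`profile` must have columns w_alpha, w_beta, w_coil.")
    }
    if (nrow(profile) != L) {
      abort(sprintf("`profile` has %d rows but the sequence has %d residues.",
                    nrow(profile), L))
    }
    w <- as.matrix(profile[, c("w_alpha", "w_beta", "w_coil")])
    if (any(w < 0) || any(rowSums(w) <= 0)) {
      abort("`profile` weights must be nonnegative with positive row sums.")
    }
    w <- w / rowSums(w)
  }
  tibble::tibble(residue = chars, w_alpha = w[, 1], w_beta = w[, 2],
                 w_coil = w[, 3])
}

#' Read a 3-state secondary-structure profile from TSV
#'
#' Expects a header row and numeric columns `w_alpha`, `w_beta`, `w_coil`
#' (extra columns are ignored), one row per residue.
#'
#' @param path File path.
#' @return A tibble usable as the `profile` argument of [weight_profile()].
#' @export
read_threestate_profile <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (!all(c("w_alpha", "w_beta", "w_coil") %in% names(df))) {
    abort("Profile TSV must have columns w_alpha, w_beta, w_coil.")
  }
  tibble::as_tibble(df)
}

#' Sample per-residue backbone dihedrals for one chain
#'
#' For each residue a conformational state is chosen from its
#' (alpha, beta, coil) weights; the alpha state draws from the right-handed
#' alpha basin, beta from the beta basin, and coil from a mixture over
#' PPII, beta, and both alpha basins (`coil_mix`). Phi and psi are drawn from
#' the chosen basin's Gaussian. Proline phi is clamped near -65 degrees
#' (pyrrolidine ring constraint) regardless of basin. Omega is 180 degrees
#' (trans) except that each peptide bond preceding a proline is cis
#' (omega = 0) with probability `cis_prob`; chains exceeding `max_cis`
#' cis-prolines are redrawn.
#'
#' @param sequence Sequence string.
#' @param weights Weight profile from [weight_profile()] (defaults to the
#'   coil preset).
#' @param basins Basin library (default [basin_library()]).
#' @param coil_mix Coil-state mixture over basins, named
#'   (ppii, beta, alpha_r, alpha_l).
#' @param cis_prob Per-proline cis probability (default 0.04).
#' @param max_cis Maximum cis-prolines per chain (default 6).
#' @param seed RNG seed (`NULL` uses the current RNG stream).
#' @return A tibble with columns `residue`, `position`, `phi`, `psi`,
#'   `omega` (degrees); the cis-proline count is attached as attribute
#'   `"cis_count"`.
#' @export
sample_dihedrals <- function(sequence, weights = NULL,
                             basins = basin_library(),
                             coil_mix = COIL_MIX_DEFAULT,
                             cis_prob = 0.04, max_cis = 6, seed = NULL) {
  chars <- seq_to_chars(sequence)
  if (is.null(weights)) weights <- weight_profile(sequence, "coil")
  w <- as.matrix(weights[, c("w_alpha", "w_beta", "w_coil")])
  if (nrow(w) != length(chars)) {
    abort("`weights` length must equal the sequence length.")
  }
  if (any(abs(rowSums(w) - 1) > 1e-8)) {
    abort("`weights` rows must be normalized (sum to 1 per residue).")
  }
  run <- function() {
    cpp_sample_dihedrals(w, basins_to_matrix(basins),
                         coil_mix_vector(coil_mix), beta_rect_vector(basins),
                         chars == "P", -65, 7, cis_prob, as.integer(max_cis))
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  out <- tibble::tibble(
    residue = chars, position = seq_along(chars),
    phi = res$phi, psi = res$psi, omega = res$omega
  )
  attr(out, "cis_count") <- res$cis_count
  out
}

#' Build backbone coordinates from dihedrals
#'
#' Places N, C-alpha, C and O atoms sequentially from per-residue
#' (phi, psi, omega) using fixed ideal bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; N-CA-C 111.2,
#' CA-C-N 116.2, C-N-CA 121.7 degrees; O trans to N). The first residue sits
#' at the origin in a canonical orientation; the construction is
#' deterministic.
#'
#' @param dihedrals A data frame with columns `phi`, `psi`, `omega`
#'   (degrees), e.g. from [sample_dihedrals()], or a conformer tibble.
#' @return A tibble with columns `position`, `atom`
#'   (`N`/`CA`/`C`/`O`), `x`, `y`, `z` (Angstrom).
#' @export
build_backbone <- function(dihedrals) {
  stopifnot(all(c("phi", "psi", "omega") %in% names(dihedrals)))
  L <- nrow(dihedrals)
  m <- cpp_build_backbone(dihedrals$phi, dihedrals$psi, dihedrals$omega)
  tibble::tibble(
    position = rep(seq_len(L), each = 4L),
    atom = rep(c("N", "CA", "C", "O"), L),
    x = m[, 1], y = m[, 2], z = m[, 3]
  )
}

#' Measure backbone dihedrals from coordinates
#'
#' Inverse of [build_backbone()]: recovers phi (undefined for the first
#' residue), psi (recovered for the last residue via the carbonyl oxygen)
#' and omega (undefined for the first residue) from backbone coordinates.
#'
#' @param coordinates Backbone coordinate tibble from [build_backbone()].
#' @return A tibble with columns `position`, `phi`, `psi`, `omega` (degrees;
#'   `NA` where undefined).
#' @export
measure_dihedrals <- function(coordinates) {
  stopifnot(all(c("atom", "x", "y", "z") %in% names(coordinates)))
  m <- as.matrix(coordinates[, c("x", "y", "z")])
  L <- nrow(m) / 4
  N <- m[4 * (seq_len(L) - 1) + 1, , drop = FALSE]
  CA <- m[4 * (seq_len(L) - 1) + 2, , drop = FALSE]
  C <- m[4 * (seq_len(L) - 1) + 3, , drop = FALSE]
  O <- m[4 * (seq_len(L) - 1) + 4, , drop = FALSE]

  dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1
    b2 <- p3 - p2
    b3 <- p4 - p3
    n1 <- pracma_cross(b1, b2)
    n2 <- pracma_cross(b2, b3)
    m1 <- pracma_cross(n1, b2 / sqrt(rowSums(b2^2)))
    atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  }
  phi <- rep(NA_real_, L)
  psi <- rep(NA_real_, L)
  omega <- rep(NA_real_, L)
  if (L >= 2) {
    i <- 2:L
    phi[i] <- dihedral(C[i - 1, , drop = FALSE], N[i, , drop = FALSE],
                       CA[i, , drop = FALSE], C[i, , drop = FALSE])
    psi[1:(L - 1)] <- dihedral(N[1:(L - 1), , drop = FALSE],
                               CA[1:(L - 1), , drop = FALSE],
                               C[1:(L - 1), , drop = FALSE],
                               N[i, , drop = FALSE])
    omega[i] <- dihedral(CA[i - 1, , drop = FALSE], C[i - 1, , drop = FALSE],
                         N[i, , drop = FALSE], CA[i, , drop = FALSE])
  }
  # last psi via the carbonyl oxygen (O is placed trans to N: psi + 180)
  psiO <- dihedral(N[L, , drop = FALSE], CA[L, , drop = FALSE],
                   C[L, , drop = FALSE], O[L, , drop = FALSE])
  psi[L] <- ((psiO - 180) %% 360)
  psi[L] <- ifelse(psi[L] > 180, psi[L] - 360, psi[L])
  tibble::tibble(position = seq_len(L), phi = phi, psi = psi, omega = omega)
}

# row-wise cross product for 3-column matrices
pracma_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Steric clash check on backbone coordinates
#'
#' A chain is rejected iff any pair of C-alpha atoms at least `min_sep`
#' residues apart in sequence lies closer than `min_distance` (default
#' 4.0 Angstrom), the standard C-alpha-level surrogate for atomic
#' self-avoidance.
#'
#' @param coordinates Backbone coordinates from [build_backbone()].
#' @param min_distance Clash threshold in Angstrom (default 4).
#' @param min_sep Minimum sequence separation considered (default 3).
#' @return A list with `accept` (logical) and `pairs` (tibble of offending
#'   `i`, `j`, `distance`).
#' @export
clash_check <- function(coordinates, min_distance = 4, min_sep = 3) {
  ca <- coordinates[coordinates$atom == "CA", c("x", "y", "z")]
  m <- as.matrix(ca)
  L <- nrow(m)
  d <- as.matrix(stats::dist(m))
  sep <- abs(outer(seq_len(L), seq_len(L), `-`))
  bad <- which(d < min_distance & sep >= min_sep & upper.tri(d), arr.ind = TRUE)
  pairs <- tibble::tibble(
    i = as.integer(bad[, 1]), j = as.integer(bad[, 2]),
    distance = d[bad]
  )
  list(accept = nrow(pairs) == 0, pairs = pairs)
}

#' Classify a backbone conformation by Ramachandran rectangle
#'
#' Labels each (phi, psi) pair by membership in the basin classification
#' rectangles; the two alpha basins are merged into a single `"alpha"`
#' label for reporting, and pairs outside all rectangles are `"other"`.
#'
#' @param phi,psi Angles in degrees, vectors of equal length.
#' @param basins Basin library (default [basin_library()]).
#' @return Character vector with values in
#'   `c("PPII", "alpha", "beta", "other")`.
#' @examples
#' classify_conformation(-75, 145) # "PPII"
#' @export
classify_conformation <- function(phi, psi, basins = basin_library()) {
  out <- rep("other", length(phi))
  for (k in seq_len(nrow(basins))) {
    hit <- phi > basins$phi_min[k] & phi <= basins$phi_max[k] &
      psi > basins$psi_min[k] & psi <= basins$psi_max[k]
    lab <- switch(basins$basin[k],
                  ppii = "PPII", beta = "beta",
                  alpha_r = "alpha", alpha_l = "alpha")
    out[hit & out == "other"] <- lab
  }
  out
}

#' Generate an ensemble of non-clashing backbone conformers
#'
#' Draws `n` accepted conformers of the sequence under the chosen
#' secondary-structure bias. Each chain's dihedrals are sampled with
#' [sample_dihedrals()] semantics, its backbone built with ideal geometry,
#' and the whole chain resampled on any C-alpha clash (up to `max_restarts`
#' restarts per conformer). Per-conformer radii of gyration over all
#' backbone atoms are cached. Runs are reproducible given `seed`.
#'
#' @inheritParams sample_dihedrals
#' @param preset Sampling bias: `"coil"`, `"beta"`, or `"threestate"` with a
#'   per-residue `profile`.
#' @param n Number of accepted conformers (>= 1).
#' @param profile Per-residue 3-state profile (see [weight_profile()]).
#' @param min_distance Clash threshold in Angstrom.
#' @param max_restarts Maximum chain restarts per conformer.
#' @param seed RNG seed (default 1).
#' @return An object of class `conformer_ensemble`: a list with `sequence`,
#'   `preset`, `seed`, `n`, matrices `phi`, `psi`, `omega` (conformers x
#'   residues, degrees), `rgyr` (Angstrom), `cis_count`, and
#'   `acceptance_rate` (accepted / attempted chains).
#' @export
generate_ensemble <- function(sequence,
                              preset = c("coil", "beta", "threestate"),
                              n = 3000, seed = 1, profile = NULL,
                              basins = basin_library(),
                              coil_mix = COIL_MIX_DEFAULT,
                              cis_prob = 0.04, max_cis = 6,
                              min_distance = 4, max_restarts = 10000) {
  preset <- match.arg(preset)
  stopifnot(n >= 1)
  chars <- seq_to_chars(sequence)
  wp <- weight_profile(sequence, preset, profile)
  w <- as.matrix(wp[, c("w_alpha", "w_beta", "w_coil")])
  res <- with_seed(seed, cpp_sample_ensemble(
    as.integer(n), w, basins_to_matrix(basins), coil_mix_vector(coil_mix),
    beta_rect_vector(basins), chars == "P", -65, 7, cis_prob,
    as.integer(max_cis), min_distance, 3L, as.integer(max_restarts)
  ))
  acceptance <- n / res$attempts
  if (acceptance < 0.001) {
    abort(sprintf(
      "Acceptance rate %.4f%% is below 0.1%%; loosen the clash threshold or bias.",
      100 * acceptance
    ))
  }
  structure(
    list(
      sequence = sequence, preset = preset, seed = seed, n = n,
      phi = res$phi, psi = res$psi, omega = res$omega,
      rgyr = res$rgyr, cis_count = res$cis_count,
      acceptance_rate = acceptance
    ),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(
    "Conformer ensemble: %d chains of %d residues (%s preset, seed %s)\n",
    x$n, nchar(x$sequence), x$preset, format(x$seed)
  ))
  cat(sprintf("  mean R_Gyr %.1f A, acceptance rate %.1f%%\n",
              mean(x$rgyr), 100 * x$acceptance_rate))
  invisible(x)
}

#' Extract one conformer from an ensemble
#'
#' @param ensemble A `conformer_ensemble`.
#' @param i Conformer index.
#' @return A dihedral tibble (as from [sample_dihedrals()]) for conformer
#'   `i`, with its cis-proline count as attribute `"cis_count"`.
#' @export
conformer <- function(ensemble, i = 1) {
  stopifnot(inherits(ensemble, "conformer_ensemble"), i >= 1, i <= ensemble$n)
  out <- tibble::tibble(
    residue = seq_to_chars(ensemble$sequence),
    position = seq_len(ncol(ensemble$phi)),
    phi = ensemble$phi[i, ], psi = ensemble$psi[i, ],
    omega = ensemble$omega[i, ]
  )
  attr(out, "cis_count") <- ensemble$cis_count[i]
  out
}

#' @rdname generate_ensemble
#' @param x A `conformer_ensemble`.
#' @param ... Unused.
#' @method tidy conformer_ensemble
#' @export
tidy.conformer_ensemble <- function(x, ...) {
  tibble::tibble(
    conformer = seq_len(x$n),
    rgyr = x$rgyr,
    cis_count = x$cis_count
  )
}

#' @rdname generate_ensemble
#' @method glance conformer_ensemble
#' @export
glance.conformer_ensemble <- function(x, ...) {
  s <- ensemble_summary(x$rgyr)
  tibble::tibble(
    preset = x$preset, n = x$n, seed = x$seed,
    mean_rgyr = s$mean, median_rgyr = s$median, peak_rgyr = s$peak,
    sd_rgyr = s$sd, fwhm_rgyr = s$fwhm,
    acceptance_rate = x$acceptance_rate
  )
}

#' Write conformers as a multi-model backbone PDB file
#'
#' Writes backbone atoms (N, CA, C, O) of selected conformers as one MODEL
#' per conformer, chain A, 1-based residue numbers.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param path Output file path.
#' @param models Conformer indices to write (default first 10 or fewer).
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path,
                               models = seq_len(min(10, ensemble$n))) {
  chars <- seq_to_chars(ensemble$sequence)
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  con <- file(path, "w")
  on.exit(close(con))
  elem <- c(N = "N", CA = "C", C = "C", O = "O")
  for (m in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    coords <- build_backbone(conformer(ensemble, models[m]))
    lines <- sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(coords)), coords$atom, aa3[chars[coords$position]],
      coords$position, coords$x, coords$y, coords$z, elem[coords$atom]
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
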