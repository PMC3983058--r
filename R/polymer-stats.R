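#' Radius of gyration of a point set
#'
#' Root-mean-square distance of atoms from their unweighted centroid. For
#' conformers this is computed over backbone atoms (N, C-alpha, C, O) with no
#' mass weighting.
#'
#' @param coordinates Numeric matrix with 3 columns (x, y, z in Angstrom), or
#'   a data frame with columns `x`, `y`, `z`.
#' @return Radius of gyration in Angstrom.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))) # two atoms 2 apart -> 1
#' @export
radius_of_gyration <- function(coordinates) {
  if (is.data.frame(coordinates)) {
    coordinates <- as.matrix(coordinates[, c("x", "y", "z")])
  }
  if (!is.matrix(coordinates) || ncol(coordinates) != 3 || nrow(coordinates) < 1) {
    abort("`coordinates` must be a non-empty matrix with 3 columns.")
  }
  centered <- sweep(coordinates, 2, colMeans(coordinates))
  sqrt(mean(rowSums(centered^2)))
}

#' Distribution summary of an ensemble's radii of gyration
#'
#' Summarizes a vector of per-conformer R_Gyr values the way non-Gaussian
#' ensemble histograms are reported: the peak (center of the modal histogram
#' bin), mean, median, SD, and the full width at half maximum of the binned
#' density (distance between the outermost half-maximum crossings, located by
#' linear interpolation between bin centers).
#'
#' @param rgyr_values Numeric vector of radii (Angstrom), length >= 2, or a
#'   `conformer_ensemble` (its cached radii are used).
#' @param histogram_bin Histogram bin width in Angstrom (default 2).
#' @return A one-row tibble of class `ensemble_summary` with columns `n`,
#'   `peak`, `mean`, `median`, `sd`, `fwhm`.
#' @export
ensemble_summary <- function(rgyr_values, histogram_bin = 2) {
  if (inherits(rgyr_values, "conformer_ensemble")) {
    rgyr_values <- rgyr_values$rgyr
  }
  x <- as.numeric(rgyr_values)
  if (length(x) < 2) abort("Need at least 2 values.")
  if (diff(range(x)) == 0) {
    warn("All values equal: FWHM undefined, reported as 0.")
    return(structure(
      tibble::tibble(n = length(x), peak = x[1], mean = x[1],
                     median = x[1], sd = 0, fwhm = 0),
      class = c("ensemble_summary", class(tibble::tibble()))
    ))
  }
  edges <- seq(floor(min(x) / histogram_bin) * histogram_bin,
               max(x) + histogram_bin, by = histogram_bin)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  centers <- edges[-length(edges)] + histogram_bin / 2
  imax <- which.max(counts)
  half <- counts[imax] / 2

  # outermost crossings of the half maximum, interpolated between centers
  left <- centers[1] - histogram_bin / 2
  for (i in seq_len(imax)) {
    if (counts[i] >= half) {
      left <- if (i == 1) centers[1] - histogram_bin / 2 else
        centers[i - 1] + histogram_bin * (half - counts[i - 1]) /
          (counts[i] - counts[i - 1])
      break
    }
  }
  right <- centers[length(centers)] + histogram_bin / 2
  for (i in rev(seq(imax, length(counts)))) {
    if (counts[i] >= half) {
      right <- if (i == length(counts)) centers[i] + histogram_bin / 2 else
        centers[i] + histogram_bin * (counts[i] - half) /
          (counts[i] - counts[i + 1])
      break
    }
  }
  structure(
    tibble::tibble(
      n = length(x), peak = centers[imax], mean = mean(x),
      median = median(x), sd = sd(x), fwhm = right - left
    ),
    class = c("ensemble_summary", class(tibble::tibble()))
  )
}

#' Secondary-structure content as a function of ensemble size
#'
#' Bins the conformers of an ensemble into windows of radius of gyration
#' (default 5 Angstrom) and reports, per bin, the fraction of residue
#' conformations classified as PPII, alpha (right- plus left-handed) and
#' beta by [classify_conformation()]. Only populated bins appear in the
#' output.
#'
#' @param ensemble A `conformer_ensemble` from [generate_ensemble()].
#' @param bin_width R_Gyr bin width in Angstrom (default 5).
#' @param basins Basin library used for classification (default
#'   [basin_library()]).
#' @return A tibble of class `ss_content_profile` with columns `bin_lo`,
#'   `bin_hi`, `bin_mid`, `n_conformers`, `f_ppii`, `f_alpha`, `f_beta`,
#'   `f_other`.
#' @export
ss_content_by_rgyr <- function(ensemble, bin_width = 5, basins = basin_library()) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  rg <- ensemble$rgyr
  lo <- floor(min(rg) / bin_width) * bin_width
  bin_id <- floor((rg - lo) / bin_width)
  labels <- classify_conformation(as.vector(ensemble$phi),
                                  as.vector(ensemble$psi), basins)
  lab <- matrix(labels, nrow = nrow(ensemble$phi))

  ids <- sort(unique(bin_id))
  rows <- lapply(ids, function(b) {
    sel <- which(bin_id == b)
    l <- as.vector(lab[sel, , drop = FALSE])
    n <- length(l)
    tibble::tibble(
      bin_lo = lo + b * bin_width,
      bin_hi = lo + (b + 1) * bin_width,
      bin_mid = lo + (b + 0.5) * bin_width,
      n_conformers = length(sel),
      f_ppii = sum(l == "PPII") / n,
      f_alpha = sum(l == "alpha") / n,
      f_beta = sum(l == "beta") / n,
      f_other = sum(l == "other") / n
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ss_content_profile", class(out))
  out
}

#' Interconvert radius of gyration and hydrodynamic (Stokes) radius
#'
#' Uses the approximate ratio R_Gyr / R_H = 1.06 established for denatured
#' and disordered chains.
#'
#' @param rgyr,rh Radius in Angstrom (> 0).
#' @param ratio The R_Gyr/R_H conversion constant (default 1.06).
#' @return Radius in Angstrom.
#' @examples
#' rh_from_rgyr(53) # 50
#' @export
rh_from_rgyr <- function(rgyr, ratio = 1.06) {
  if (any(rgyr <= 0)) abort("`rgyr` must be positive.")
  rgyr / ratio
}

#' @rdname rh_from_rgyr
#' @export
rgyr_from_rh <- function(rh, ratio = 1.06) {
  if (any(rh <= 0)) abort("`rh` must be positive.")
  rh * ratio
}

#' Kohn scaling estimate of a denatured chain's radius of gyration
#'
#' Empirical power law for urea-denatured proteins:
#' R_Gyr = 1.927 * N^0.598 Angstrom for a chain of N residues.
#'
#' @param n_residues Chain length(s), >= 1.
#' @return Radius of gyration in Angstrom.
#' @examples
#' kohn_rgyr(323) # ~61.0
#' @export
kohn_rgyr <- function(n_residues) {
  stopifnot(all(n_residues >= 1))
  1.927 * n_residues^0.598
}

#' Minimal radius of an ideal anhydrous protein sphere
#'
#' Erickson's relation R_min(nm) = 0.066 * M^(1/3) with M the molecular
#' weight in Da; returned in Angstrom. This is the smallest hydrodynamic
#' radius a protein of that mass could have, used as the denominator of the
#' friction ratio.
#'
#' @param mw Molecular weight in Da (> 0).
#' @return Minimal sphere radius in Angstrom.
#' @examples
#' erickson_min_radius(34900) # ~21.6
#' @export
erickson_min_radius <- function(mw) {
  if (any(mw <= 0)) abort("`mw` must be positive.")
  10 * 0.066 * mw^(1 / 3)
}

#' Friction ratio and its shape interpretation
#'
#' The friction ratio is the measured hydrodynamic radius divided by the
#' minimal-sphere radius of equal mass. Empirically, nearly globular
#' proteins show ratios around 1.2-1.3, elongated or branched proteins
#' 2.0-3.0.
#'
#' @param rh Hydrodynamic (Stokes) radius, Angstrom.
#' @param rmin Minimal-sphere radius, Angstrom.
#' @return `friction_ratio()`: the dimensionless ratio.
#'   `friction_class()`: a character label among `"nearly globular"`
#'   (1.2-1.3), `"elongated"` (2.0-3.0), `"intermediate"`, `"compact"`
#'   (< 1.2) or `"extended"` (> 3.0).
#' @examples
#' friction_ratio(48.1, 21.6) # ~2.23
#' @export
friction_ratio <- function(rh, rmin) {
  if (any(rh <= 0) || any(rmin <= 0)) abort("Radii must be positive.")
  rh / rmin
}

#' @rdname friction_ratio
#' @param ratio A friction ratio.
#' @export
friction_class <- function(ratio) {
  vapply(ratio, function(r) {
    if (r < 1.2) "compact"
    else if (r <= 1.3) "nearly globular"
    else if (r < 2.0) "intermediate"
    else if (r <= 3.0) "elongated"
    else "extended"
  }, character(1))
}

#' Flory-ratio correction for tag residues added to a disordered chain
#'
#' For ideal-chain scaling, R_Gyr^2 / (N l^2) is approximately constant with
#' bond length l = 3.81 Angstrom (virtual C-alpha-C-alpha bond) and a
#' peak-to-mean constant c in the range 0.407-0.595. The change in R_Gyr from
#' extending a chain of `n_domain` residues to `n_total` is then
#' Delta R_Gyr = l * sqrt(c) * (sqrt(n_total) - sqrt(n_domain)), evaluated at
#' the low, midpoint and high ends of the c range.
#'
#' @param n_total Residue count with tags (> `n_domain`).
#' @param n_domain Residue count of the bare domain (>= 1).
#' @param c_low,c_high Bounds of the Flory ratio constant.
#' @param l Virtual bond length in Angstrom (default 3.81).
#' @return A one-row tibble with columns `low`, `mid`, `high` (Angstrom) and
#'   `half_range`.
#' @examples
#' flory_tag_correction(323, 306) # midpoint ~1.3 Angstrom
#' @export
flory_tag_correction <- function(n_total, n_domain,
                                 c_low = 0.407, c_high = 0.595, l = 3.81) {
  stopifnot(n_domain >= 1, n_total >= n_domain)
  d <- sqrt(n_total) - sqrt(n_domain)
  low <- l * sqrt(c_low) * d
  high <- l * sqrt(c_high) * d
  tibble::tibble(
    low = low, mid = (low + high) / 2, high = high,
    half_range = (high - low) / 2
  )
}

#' Hydrodynamic record for a disordered domain
#'
#' Combines the closed-form conversions into one report: given a measured
#' (or ensemble-derived) hydrodynamic radius and the construct mass, returns
#' the equivalent R_Gyr, the minimal-sphere radius, the friction ratio and
#' its shape class, and the Kohn denatured-state expectation for the chain
#' length.
#'
#' @param rh Hydrodynamic radius in Angstrom.
#' @param mw Molecular weight in Da.
#' @param n_residues Chain length (with tags) for the Kohn estimate.
#' @return A one-row tibble with columns `rh`, `rgyr_equiv`, `mw`, `r_min`,
#'   `friction_ratio`, `shape_class`, `kohn_rgyr`.
#' @export
hydrodynamic_record <- function(rh, mw, n_residues) {
  rmin <- erickson_min_radius(mw)
  fr <- friction_ratio(rh, rmin)
  tibble::tibble(
    rh = rh,
    rgyr_equiv = rgyr_from_rh(rh),
    mw = mw,
    r_min = rmin,
    friction_ratio = fr,
    shape_class = friction_class(fr),
    kohn_rgyr = kohn_rgyr(n_residues)
  )
}
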