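#' Generate a synthetic proline-rich sequence with regularly spaced YxxP motifs
#'
#' Builds a sequence that emulates the composition of the p130Cas substrate
#' domain: a fixed number of evenly spaced, non-overlapping Y-x-x-P motifs and
#' an overall proline fraction hit to within one residue. Motif tyrosines are
#' placed at period `motif_period`; prolines beyond the motif prolines are
#' scattered uniformly over the remaining positions; all other positions draw
#' uniformly from the 18 residues that are neither Y nor P, so no accidental
#' YxxP match can arise and the motif count is exact by construction.
#'
#' @param length Residue count of the sequence.
#' @param proline_fraction Target proline fraction in `[0, 1]` (motif prolines
#'   count toward the total).
#' @param motif_count Number of YxxP motifs.
#' @param motif_period Residues between successive motif tyrosines.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#'
#' @return A single sequence string of exactly `length` residues.
#' @examples
#' s <- gen_proline_rich_sequence(306, 0.199, motif_count = 15,
#'                                motif_period = 20, seed = 1)
#' nrow(find_yxxp(s)) # 15
#' @export
gen_proline_rich_sequence <- function(length, proline_fraction = 0.199,
                                      motif_count = 15, motif_period = 20,
                                      seed = 1) {
  stopifnot(length >= 1, motif_count >= 0, motif_period >= 4)
  if (proline_fraction < 0 || proline_fraction > 1) {
    abort("`proline_fraction` must be in [0, 1].")
  }
  if (length < motif_count * 4) {
    abort("Infeasible spec: `length` must be at least 4 * `motif_count`.")
  }
  span <- if (motif_count > 0) (motif_count - 1) * motif_period + 4 else 0
  if (span > length) {
    abort(sprintf(
      "Infeasible spec: %d motifs at period %d span %d residues but length is %d.",
      motif_count, motif_period, span, length
    ))
  }
  target_pro <- round(proline_fraction * length)
  if (target_pro < motif_count) {
    abort("Infeasible spec: motif prolines alone exceed the proline target.")
  }

  with_seed(seed, {
    chars <- character(length)
    start <- floor((length - span) / 2) + 1L
    tyr <- if (motif_count > 0) start + (seq_len(motif_count) - 1L) * motif_period else integer(0)
    chars[tyr] <- "Y"
    chars[tyr + 3L] <- "P"
    free <- which(chars == "")
    n_extra <- target_pro - motif_count
    if (n_extra > length(free)) {
      abort("Infeasible spec: not enough free positions for the proline target.")
    }
    pro_pos <- if (n_extra > 0) sample(free, n_extra) else integer(0)
    chars[pro_pos] <- "P"
    rest <- which(chars == "")
    background <- setdiff(AA_ALPHABET, c("Y", "P"))
    chars[rest] <- sample(background, length(rest), replace = TRUE)
    paste(chars, collapse = "")
  })
}

#' Generate a gapless synthetic alignment with conserved motifs and
#' variability hotspots
#'
#' Mutates a reference sequence into `n_taxa` aligned rows. The Y and P
#' columns of every YxxP motif are never substituted (the motif spacing is
#' absolutely conserved by construction); the columns at the given offsets
#' before each motif tyrosine mutate at the elevated hotspot rate; every
#' other column mutates at the background rate. Substitutions never introduce
#' a tyrosine, so the motif count is invariant across rows. The first row is
#' the unmutated reference.
#'
#' The default rates are calibrated by simulation so that an 11-row alignment
#' over a 306-residue, 15-motif reference has a mean pairwise identity of
#' about 71%.
#'
#' @param reference Reference sequence string.
#' @param n_taxa Number of rows.
#' @param hotspot_offsets Offsets (in residues) before each motif tyrosine
#'   that mutate at the hotspot rate. Default `2:9`.
#' @param substitution_rate_hotspot,substitution_rate_background Per-column
#'   substitution probabilities, hotspot > background, both in (0, 1) or 0.
#' @param seed RNG seed.
#'
#' @return Character vector of `n_taxa` aligned rows (no gaps), named
#'   `taxon_1` ... `taxon_n`.
#' @export
gen_alignment <- function(reference, n_taxa = 11,
                          hotspot_offsets = 2:9,
                          substitution_rate_hotspot = 0.36,
                          substitution_rate_background = 0.08,
                          seed = 1) {
  chars <- seq_to_chars(reference, "reference")
  n <- length(chars)
  if (substitution_rate_hotspot < substitution_rate_background) {
    abort("Hotspot substitution rate must be >= the background rate.")
  }
  if (any(c(substitution_rate_hotspot, substitution_rate_background) < 0) ||
      any(c(substitution_rate_hotspot, substitution_rate_background) >= 1)) {
    abort("Substitution rates must lie in [0, 1).")
  }
  motifs <- find_yxxp(reference)
  tyr <- motifs$start
  protected <- sort(unique(c(tyr, tyr + 3L)))
  if (length(hotspot_offsets)) {
    if (any(hotspot_offsets < 1)) abort("`hotspot_offsets` must be positive.")
    hot <- unique(as.vector(outer(tyr, hotspot_offsets, `-`)))
    if (length(tyr) > 0 && any(outer(tyr, hotspot_offsets, `-`) < 1)) {
      abort("`hotspot_offsets` reach before the start of the sequence.")
    }
    hot <- setdiff(hot[hot >= 1 & hot <= n], protected)
  } else {
    hot <- integer(0)
  }
  rate <- rep(substitution_rate_background, n)
  rate[hot] <- substitution_rate_hotspot
  rate[protected] <- 0

  sub_alphabet <- setdiff(AA_ALPHABET, "Y")
  with_seed(seed, {
    rows <- vapply(seq_len(n_taxa), function(i) {
      if (i == 1) return(paste(chars, collapse = ""))
      mut <- chars
      hit <- which(runif(n) < rate)
      for (j in hit) {
        mut[j] <- sample(setdiff(sub_alphabet, mut[j]), 1)
      }
      paste(mut, collapse = "")
    }, character(1))
    names(rows) <- paste0("taxon_", seq_len(n_taxa))
    rows
  })
}

#' Generate a synthetic matrix of disorder-predictor scores
#'
#' Emulates the per-residue output of a panel of disorder predictors:
#' residues inside the given disordered segments score high (base 1),
#' residues outside score low (base 0), with optional truncated Gaussian
#' noise per program and residue. Scores are clamped to `[0, 1]`.
#'
#' @param length Number of residues.
#' @param n_programs Number of predictor programs (rows).
#' @param disordered_segments List of `c(start, end)` integer intervals
#'   (1-based, inclusive) within `[1, length]`.
#' @param noise_sd Standard deviation of additive Gaussian noise (default
#'   0.05; 0 gives exact 0/1 scores).
#' @param seed RNG seed.
#'
#' @return Numeric matrix `n_programs` x `length`, rows named
#'   `program_1` ... .
#' @export
gen_predictor_scores <- function(length, n_programs = 10,
                                 disordered_segments = list(),
                                 noise_sd = 0.05, seed = 1) {
  stopifnot(length >= 1, n_programs >= 1, noise_sd >= 0)
  base <- rep(0, length)
  for (seg in disordered_segments) {
    if (length(seg) != 2 || seg[1] < 1 || seg[2] > length || seg[1] > seg[2]) {
      abort("Each disordered segment must be c(start, end) within [1, length].")
    }
    base[seg[1]:seg[2]] <- 1
  }
  with_seed(seed, {
    m <- matrix(rep(base, each = n_programs), nrow = n_programs)
    if (noise_sd > 0) {
      m <- m + matrix(rnorm(n_programs * length, sd = noise_sd),
                      nrow = n_programs)
      m <- pmin(pmax(m, 0), 1)
    }
    rownames(m) <- paste0("program_", seq_len(n_programs))
    m
  })
}

#' Simulate a sawtooth AFM force-extension trace
#'
#' Concatenates Marko-Siggia worm-like-chain segments into the sawtooth trace
#' produced by constant-velocity pulling on a polyprotein: the accessible
#' contour length starts at `tether_contour_length` and grows by one domain's
#' contour-length increment each time the WLC force reaches that domain's
#' scripted unfolding force. Domains unfold weakest-first. After the last
#' unfolding the force rises to `detach_force` and drops to 0 pN
#' (detachment). White Gaussian force noise is added pointwise.
#'
#' @param domain_contour_lengths Contour-length increments Delta-L released
#'   by each domain, nm (e.g. `c(28, 28)` for two titin I27 domains).
#' @param domain_unfold_forces Scripted unfolding force of each domain, pN.
#' @param persistence_length WLC persistence length, nm (default 0.4).
#' @param tether_contour_length Initial accessible contour length (handles,
#'   tags and the folded construct), nm.
#' @param detach_force Force at which the final stretch detaches, pN.
#' @param temperature Temperature in K (default 298).
#' @param noise_sd Gaussian force-noise SD, pN.
#' @param points_per_nm Sampling density of the extension axis.
#' @param seed RNG seed.
#'
#' @return A tibble of class `force_extension_trace` with columns
#'   `extension` (nm, strictly increasing) and `force` (pN); pulling
#'   parameters are attached as attributes.
#' @export
gen_afm_trace <- function(domain_contour_lengths = c(28, 28),
                          domain_unfold_forces = c(150, 160),
                          persistence_length = 0.4,
                          tether_contour_length = 60,
                          detach_force = 250,
                          temperature = 298,
                          noise_sd = 0,
                          points_per_nm = 10,
                          seed = 1) {
  k <- length(domain_contour_lengths)
  if (length(domain_unfold_forces) != k) {
    abort("Contour-length and unfold-force lists must have equal length.")
  }
  if (k > 0 && (any(domain_contour_lengths <= 0) || any(domain_unfold_forces <= 0))) {
    abort("Domain contour lengths and unfold forces must be positive.")
  }
  stopifnot(noise_sd >= 0, persistence_length > 0, tether_contour_length > 0)

  ord <- order(domain_unfold_forces)
  dl <- domain_contour_lengths[ord]
  fu <- domain_unfold_forces[ord]

  # extension at which the WLC on contour L reaches force f
  x_at_force <- function(f, L) {
    uniroot(
      function(x) wlc_force(x, L, persistence_length, temperature) - f,
      interval = c(0, L * (1 - 1e-9)), tol = 1e-10
    )$root
  }

  contours <- tether_contour_length + cumsum(c(0, dl))
  breaks <- numeric(k + 1)
  for (i in seq_len(k)) breaks[i] <- x_at_force(fu[i], contours[i])
  breaks[k + 1] <- x_at_force(detach_force, contours[k + 1])

  x_max <- breaks[k + 1]
  x <- seq(0, x_max, by = 1 / points_per_nm)
  phase <- findInterval(x, breaks, left.open = TRUE) + 1
  force <- vapply(seq_along(x), function(i) {
    wlc_force(min(x[i], contours[phase[i]] * (1 - 1e-9)),
              contours[phase[i]], persistence_length, temperature)
  }, numeric(1))
  # detachment: one final point back at zero force
  x <- c(x, x_max + 1 / points_per_nm)
  force <- c(force, 0)

  if (noise_sd > 0) {
    force <- with_seed(seed, force + rnorm(length(force), sd = noise_sd))
  }
  new_trace(x, force,
            persistence_length = persistence_length,
            temperature = temperature,
            contour_lengths = contours)
}

#' Generate a synthetic 3-state secondary-structure profile
#'
#' Emulates a per-residue 3-state prediction for a disordered, proline-rich
#' domain: almost completely coil with small alpha and beta weights, plus
#' optional Dirichlet-like jitter. Usable as the `profile` of the
#' `"threestate"` ensemble preset.
#'
#' @param length Number of residues.
#' @param w_alpha,w_beta,w_coil Mean state weights (renormalized to sum
#'   to 1).
#' @param jitter SD of multiplicative log-normal jitter per residue and
#'   state (default 0.2; 0 gives a flat profile).
#' @param seed RNG seed.
#' @return A tibble with columns `w_alpha`, `w_beta`, `w_coil`, rows
#'   normalized to 1.
#' @export
gen_threestate_profile <- function(length, w_alpha = 0.04, w_beta = 0.20,
                                   w_coil = 0.76, jitter = 0.2, seed = 1) {
  stopifnot(length >= 1, w_alpha >= 0, w_beta >= 0, w_coil > 0, jitter >= 0)
  with_seed(seed, {
    w <- matrix(rep(c(w_alpha, w_beta, w_coil), each = length), ncol = 3)
    if (jitter > 0) {
      w <- w * matrix(exp(rnorm(3 * length, sd = jitter)), ncol = 3)
    }
    w <- w / rowSums(w)
    tibble::tibble(w_alpha = w[, 1], w_beta = w[, 2], w_coil = w[, 3])
  })
}

new_trace <- function(extension, force, ...) {
  out <- tibble::tibble(extension = extension, force = force)
  class(out) <- c("force_extension_trace", class(out))
  meta <- list(...)
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  out
}
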