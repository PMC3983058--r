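#' Marko-Siggia worm-like-chain force
#'
#' Entropic-elasticity interpolation formula for the force required to hold a
#' worm-like chain of contour length `L` and persistence length `p` at
#' end-to-end extension `x`:
#' F = (kB T / p) * (1 / (4 (1 - x/L)^2) - 1/4 + x/L).
#'
#' @param x Extension in nm, `0 <= x < L` (vectorized).
#' @param L Contour length in nm.
#' @param p Persistence length in nm (> 0).
#' @param temperature Temperature in K; kB T = 4.114 pN nm at the default
#'   298 K.
#' @return Force in pN.
#' @examples
#' wlc_force(0.5 * 100, 100, 0.4) # 1.25 kBT/p ~ 12.9 pN
#' @export
wlc_force <- function(x, L, p, temperature = 298) {
  if (any(p <= 0)) abort("`p` must be positive.")
  if (any(x < 0) || any(x >= L)) {
    abort("`x` must satisfy 0 <= x < L (force diverges at x = L).")
  }
  kbt <- 0.0138064852 * temperature
  t <- x / L
  (kbt / p) * (1 / (4 * (1 - t)^2) - 0.25 + t)
}

#' Detect unfolding peaks in a force-extension trace
#'
#' Finds local force maxima that exceed the detection floor and are followed
#' by a force drop of at least `min_drop` before the next rise. The terminal
#' detachment peak -- the last maximum after which the force never again
#' reaches the detection floor -- is excluded, since it marks loss of the
#' tether rather than a domain unfolding.
#'
#' @param trace A `force_extension_trace` (tibble with `extension`, `force`).
#' @param min_force Minimum peak force in pN (default 15, the AFM detection
#'   limit).
#' @param min_drop Minimum force drop after a peak in pN (default 10). The
#'   effective threshold is raised to 4x the trace's estimated noise SD
#'   (median absolute successive difference) when that is larger, so noise
#'   excursions are not called events.
#' @param smooth Odd window length of an optional running-mean filter applied
#'   before detection (default 1 = no smoothing); peak heights are read from
#'   the raw trace.
#' @return A tibble with one row per peak: `index`, `extension`, `force`.
#' @export
detect_peaks <- function(trace, min_force = 15, min_drop = 10, smooth = 1) {
  stopifnot(all(c("extension", "force") %in% names(trace)))
  f_raw <- trace$force
  n <- length(f_raw)
  sigma_est <- stats::median(abs(diff(f_raw))) / (sqrt(2) * 0.6745)
  min_drop <- max(min_drop, 4 * sigma_est)
  f <- f_raw
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    f <- as.numeric(stats::filter(f_raw, k, sides = 2))
    f[is.na(f)] <- f_raw[is.na(f)]
  }
  if (n < 3) {
    return(tibble::tibble(index = integer(0), extension = numeric(0),
                          force = numeric(0)))
  }
  # candidate local maxima on the (possibly smoothed) signal
  cand <- which(diff(sign(diff(f))) < 0) + 1L
  cand <- cand[f_raw[cand] >= min_force]

  # merge jitter: candidates not separated by a real valley are one peak
  if (length(cand) > 1) {
    merged <- cand[1]
    for (i in seq_along(cand)[-1]) {
      a <- merged[length(merged)]
      b <- cand[i]
      gap_min <- min(f_raw[a:b])
      if (gap_min > min(f_raw[a], f_raw[b]) - min_drop) {
        if (f_raw[b] > f_raw[a]) merged[length(merged)] <- b
      } else {
        merged <- c(merged, b)
      }
    }
    cand <- merged
  }

  # a peak must be followed by a drop >= min_drop before the next peak
  if (length(cand) > 0) {
    nxt <- c(cand[-1], n)
    keep <- vapply(seq_along(cand), function(i) {
      valley <- min(f[cand[i]:nxt[i]])
      (f[cand[i]] - valley) >= min_drop
    }, logical(1))
    cand <- cand[keep]
  }

  # exclude terminal detachment peaks: once the force has fallen min_drop
  # below the peak it never again reaches the detection floor
  while (length(cand) > 0) {
    j <- cand[length(cand)]
    t0 <- if (j < n) {
      off <- which(f_raw[(j + 1):n] <= f_raw[j] - min_drop)
      if (length(off)) off[1] + j else NA_integer_
    } else NA_integer_
    recovery <- if (is.na(t0)) -Inf else max(f_raw[t0:n])
    if (recovery < min_force) cand <- cand[-length(cand)] else break
  }

  tibble::tibble(
    index = cand,
    extension = trace$extension[cand],
    force = f_raw[cand]
  )
}

#' Fit WLC contour lengths to the rising segments of a trace
#'
#' For each detected peak, least-squares fits the Marko-Siggia WLC to the
#' rising segment that precedes it (from the force minimum after the previous
#' peak to the sample immediately before the current peak), yielding contour
#' length `L` and persistence length `p`. The contour-length increment
#' Delta-L of event i is `L[i+1] - L[i]`; for the last event the contour of
#' the final rising segment (before detachment) serves as the reference when
#' it can be fitted, so a trace truncated at its last peak yields `NA`.
#'
#' @param trace A `force_extension_trace`.
#' @param peaks Peak table from [detect_peaks()]; detected at defaults when
#'   omitted.
#' @param p_fixed If non-`NULL`, fix the persistence length at this value
#'   (nm) and fit only `L`; otherwise `p` is fitted freely per event.
#' @param temperature Temperature in K.
#' @param min_points Minimum samples in a segment for a fit (default 8).
#' @return A tibble of class `wlc_events` with one row per peak:
#'   `peak_extension`, `peak_force`, `L`, `p`, `dL`, `converged`.
#' @export
fit_wlc_events <- function(trace, peaks = NULL, p_fixed = NULL,
                           temperature = 298, min_points = 8) {
  if (is.null(peaks)) peaks <- detect_peaks(trace)
  if (nrow(peaks) < 1) abort("No peaks to fit.")
  x <- trace$extension
  f <- trace$force
  n <- length(x)
  idx <- peaks$index

  seg_bounds <- function(i_prev, i_peak) {
    lo <- if (is.na(i_prev)) 1L else {
      between <- f[i_prev:i_peak]
      which.min(between) + i_prev - 1L
    }
    c(lo, i_peak - 1L)
  }

  fit_segment <- function(lo, hi, x_peak) {
    if (hi - lo + 1 < min_points) return(NULL)
    xs <- x[lo:hi]
    fs <- f[lo:hi]
    xs <- xs[fs > 0 | TRUE] # keep all; noise may dip below 0
    start_L <- max(x_peak * 1.1, max(xs) * 1.05)
    out <- tryCatch({
      if (is.null(p_fixed)) {
        fit <- minpack.lm::nlsLM(
          fs ~ wlc_force(xs, L, p, temperature),
          start = list(L = start_L, p = 0.4),
          lower = c(max(xs) * 1.001, 0.01),
          upper = c(max(xs) * 100, 10),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
        c(stats::coef(fit)[["L"]], stats::coef(fit)[["p"]])
      } else {
        fit <- minpack.lm::nlsLM(
          fs ~ wlc_force(xs, L, p_fixed, temperature),
          start = list(L = start_L),
          lower = max(xs) * 1.001, upper = max(xs) * 100,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
        c(stats::coef(fit)[["L"]], p_fixed)
      }
    }, error = function(e) NULL)
    out
  }

  k <- length(idx)
  L <- p <- rep(NA_real_, k)
  conv <- logical(k)
  for (i in seq_len(k)) {
    b <- seg_bounds(if (i == 1) NA else idx[i - 1], idx[i])
    res <- fit_segment(b[1], b[2], x[idx[i]])
    if (!is.null(res)) {
      L[i] <- res[1]
      p[i] <- res[2]
      conv[i] <- TRUE
    }
  }
  # final rising segment after the last peak (pre-detachment reference):
  # from the valley following the last peak up to the detachment top,
  # excluding anything after the detachment drop
  L_final <- NA_real_
  j <- idx[k]
  if (j < n) {
    top <- which.max(f[j:n]) + j - 1L
    if (top > j + 1L && f[top] >= 5) { # a real re-stretch, not baseline noise
      valley <- which.min(f[j:top]) + j - 1L
      res <- fit_segment(valley, top, x[top])
      if (!is.null(res)) L_final <- res[1]
    }
  }
  L_next <- c(L[-1], L_final)
  dL <- ifelse(conv & !is.na(L_next), L_next - L, NA_real_)
  dL[!conv] <- NA_real_

  out <- tibble::tibble(
    peak_extension = x[idx],
    peak_force = f[idx],
    L = L, p = p, dL = dL, converged = conv
  )
  class(out) <- c("wlc_events", class(out))
  attr(out, "L_final") <- L_final
  out
}

#' Classify a trace by its I27 unfolding signature
#'
#' Applies the fingerprint gate used for polyprotein constructs carrying two
#' titin I27 reference domains: an event is an I27 unfolding if its
#' contour-length increment lies in `i27_dl` (default 28 +/- 2 nm) and its
#' peak force exceeds `i27_fmin` (default 100 pN). A trace is `rejected`
#' unless it contains exactly two I27 events; with two I27 events and no
#' other event it is `type1` (the disordered domain stretched without
#' detectable resistance); with additional events it is `type2`.
#' Classification does not depend on the order of the input rows.
#'
#' @param events A `wlc_events` tibble from [fit_wlc_events()].
#' @param i27_dl Length-2 numeric, the accepted Delta-L window in nm
#'   (default `c(26, 30)`).
#' @param i27_fmin Minimum I27 peak force in pN (default 100).
#' @return A list of class `trace_classification` with elements `label`
#'   (`"rejected"`, `"type1"` or `"type2"`), `i27_events` and `other_events`
#'   (tibbles).
#' @export
classify_trace <- function(events, i27_dl = c(26, 30), i27_fmin = 100) {
  stopifnot(is.data.frame(events),
            all(c("peak_force", "dL") %in% names(events)))
  is_i27 <- !is.na(events$dL) &
    events$dL >= i27_dl[1] & events$dL <= i27_dl[2] &
    events$peak_force > i27_fmin
  i27 <- events[is_i27, , drop = FALSE]
  other <- events[!is_i27, , drop = FALSE]
  label <- if (nrow(i27) != 2) "rejected"
           else if (nrow(other) == 0) "type1"
           else "type2"
  structure(
    list(label = label, i27_events = i27, other_events = other),
    class = "trace_classification"
  )
}

#' @export
print.trace_classification <- function(x, ...) {
  cat(sprintf("Trace classification: %s (%d I27 event(s), %d other)\n",
              x$label, nrow(x$i27_events), nrow(x$other_events)))
  invisible(x)
}

#' @rdname classify_trace
#' @param x A `trace_classification`.
#' @param ... Unused.
#' @method glance trace_classification
#' @export
glance.trace_classification <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    n_i27 = nrow(x$i27_events),
    n_other = nrow(x$other_events)
  )
}

#' Correlation and range summary of non-I27 unfolding events
#'
#' For the weak, heterogeneous events attributed to the disordered domain in
#' type-2 traces, reports the Pearson correlation between peak force and
#' contour-length increment together with the observed spans of both. For a
#' structurally random domain these are uncorrelated.
#'
#' @param events Tibble with columns `peak_force` and `dL` (I27 events
#'   already excluded), at least 3 complete rows.
#' @return A one-row tibble: `n`, `r` (Pearson), `force_min`, `force_max`,
#'   `dl_min`, `dl_max`.
#' @export
event_scatter_stats <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("peak_force", "dL") %in% names(events)))
  ok <- stats::complete.cases(events[, c("peak_force", "dL")])
  ev <- events[ok, ]
  if (nrow(ev) < 3) abort("Need at least 3 complete events.")
  tibble::tibble(
    n = nrow(ev),
    r = cor(ev$peak_force, ev$dL),
    force_min = min(ev$peak_force), force_max = max(ev$peak_force),
    dl_min = min(ev$dL), dl_max = max(ev$dL)
  )
}
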