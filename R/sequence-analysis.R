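#' Map YxxP substrate motifs in a protein sequence
#'
#' Scans a sequence left to right for every match of the four-residue pattern
#' Y-x-x-P (tyrosine, any two residues, proline), the Src-family kinase
#' substrate motif that repeats through the p130Cas substrate domain.
#' Overlapping matches are all reported (sliding window).
#'
#' @param sequence A single string of standard one-letter amino-acid codes.
#' @param offset Integer added to reported positions, for domains excised from
#'   a longer protein (e.g. `offset = 114` converts domain-local coordinates
#'   1..306 to full-protein numbering 115..420). Default 0 (domain-local,
#'   1-based).
#'
#' @return A tibble of class `motif_map` with one row per match and columns
#'   `start` (position of the Y), `end` (position of the P),
#'   `motif` (the matched four residues) and `spacing_to_next` (distance from
#'   this motif's tyrosine to the next motif's tyrosine; `NA` for the last).
#'   The tyrosine positions are `start` itself since the pattern is anchored
#'   on Y.
#' @examples
#' find_yxxp("YAAPYAAP")
#' @export
find_yxxp <- function(sequence, offset = 0L) {
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  starts <- integer(0)
  if (n >= 4) {
    idx <- seq_len(n - 3L)
    starts <- idx[chars[idx] == "Y" & chars[idx + 3L] == "P"]
  }
  out <- tibble::tibble(
    start = starts + offset,
    end = starts + 3L + offset,
    motif = vapply(
      starts,
      function(i) paste(chars[i:(i + 3L)], collapse = ""),
      character(1)
    ),
    spacing_to_next = c(diff(starts), NA_integer_)
  )
  class(out) <- c("motif_map", class(out))
  attr(out, "sequence_length") <- n
  attr(out, "offset") <- offset
  out
}

#' Amino-acid composition of a sequence
#'
#' Exact residue counts and fractions for each of the 20 standard amino
#' acids present in the sequence. Fractions sum to 1.
#'
#' @inheritParams find_yxxp
#' @return A tibble with columns `residue`, `count`, `fraction`, one row per
#'   residue type present, sorted by decreasing count.
#' @examples
#' composition("PPPP")
#' @export
composition <- function(sequence) {
  chars <- seq_to_chars(sequence)
  if (length(chars) == 0) abort("`sequence` must be nonempty.")
  tab <- table(factor(chars, levels = AA_ALPHABET))
  tab <- tab[tab > 0]
  out <- tibble::tibble(
    residue = names(tab),
    count = as.integer(tab),
    fraction = as.integer(tab) / length(chars)
  )
  dplyr::arrange(out, dplyr::desc(.data$count), .data$residue)
}

#' Average molecular weight of a peptide
#'
#' Sum of standard average (isotope-abundance-weighted) residue masses plus
#' one water. No post-translational modifications are considered.
#'
#' @inheritParams find_yxxp
#' @return Molecular weight in Da (divide by 1000 for kDa).
#' @examples
#' calc_mw("G") # 75.07 Da, glycine plus water
#' @export
calc_mw <- function(sequence) {
  chars <- seq_to_chars(sequence)
  if (length(chars) == 0) abort("`sequence` must be nonempty.")
  sum(AA_RESIDUE_MASS[chars]) + MASS_WATER
}

#' Consensus of per-residue disorder predictions
#'
#' Combines per-residue scores from several disorder predictors into a crude
#' consensus. Each program's scores are min-max normalized to a 0-9 scale
#' (9 most disordered); a residue is counted as called disordered by a
#' program when its normalized score is at or above that program's threshold;
#' the per-residue vote fraction (programs calling disordered / programs)
#' is banded into four tiers:
#' vote < 0.5 `"less"`, 0.5 <= vote < 0.7 `"intermediate"`,
#' 0.7 <= vote < 0.9 `"disordered"`, vote >= 0.9 `"extensive"`.
#' Programs whose scores are constant cannot be normalized; they are dropped
#' from the vote with a warning.
#'
#' @param score_matrix Numeric matrix, one row per predictor program, one
#'   column per residue. Row names, if present, name the programs.
#' @param thresholds Per-program disorder thresholds on the normalized 0-9
#'   scale; a single value is recycled. Default 4.5 (scale midpoint).
#'
#' @return A tibble of class `disorder_consensus` with columns `position`,
#'   `n_programs` (programs contributing after exclusions), `votes`,
#'   `vote_fraction` and `tier` (ordered factor
#'   less < intermediate < disordered < extensive). The normalized 0-9 score
#'   matrix is attached as attribute `"normalized"`.
#' @export
disorder_consensus <- function(score_matrix, thresholds = 4.5) {
  if (!is.matrix(score_matrix) || !is.numeric(score_matrix)) {
    abort("`score_matrix` must be a numeric matrix (programs x residues).")
  }
  n_prog <- nrow(score_matrix)
  n_res <- ncol(score_matrix)
  if (n_prog < 1 || n_res < 1) abort("`score_matrix` must be non-empty.")
  thresholds <- rep_len(thresholds, n_prog)

  rng <- apply(score_matrix, 1, range)
  degenerate <- rng[1, ] == rng[2, ]
  if (any(degenerate)) {
    nm <- rownames(score_matrix)
    who <- if (is.null(nm)) which(degenerate) else nm[degenerate]
    warn(sprintf(
      "Excluding %d constant-score program(s) from the vote: %s",
      sum(degenerate), paste(who, collapse = ", ")
    ))
  }
  norm <- score_matrix
  for (i in seq_len(n_prog)) {
    if (degenerate[i]) {
      norm[i, ] <- NA_real_
    } else {
      norm[i, ] <- 9 * (score_matrix[i, ] - rng[1, i]) / (rng[2, i] - rng[1, i])
    }
  }
  keep <- which(!degenerate)
  if (length(keep) == 0) abort("All programs have constant scores; no vote possible.")
  calls <- norm[keep, , drop = FALSE] >= thresholds[keep]
  votes <- colSums(calls)
  vote_fraction <- votes / length(keep)

  tier <- cut(
    vote_fraction,
    breaks = c(-Inf, 0.5, 0.7, 0.9, Inf),
    labels = c("less", "intermediate", "disordered", "extensive"),
    right = FALSE, ordered_result = TRUE
  )
  out <- tibble::tibble(
    position = seq_len(n_res),
    n_programs = length(keep),
    votes = as.integer(votes),
    vote_fraction = vote_fraction,
    tier = tier
  )
  class(out) <- c("disorder_consensus", class(out))
  attr(out, "normalized") <- norm
  out
}

#' Conservation statistics of a multiple sequence alignment
#'
#' Computes mean pairwise percent identity over ungapped columns, a
#' per-column variability score, and the offsets of high-variability
#' ("hotspot") columns to the nearest downstream YxxP motif tyrosine.
#'
#' Percent identity for one pair of rows is the number of ungapped columns at
#' which the two residues agree divided by the number of ungapped columns;
#' the reported identity is the mean over all row pairs. Column variability
#' is 1 minus the frequency of the modal residue (gaps excluded from the
#' mode). Hotspot columns are those whose variability exceeds the given
#' quantile of positive-variability columns.
#'
#' @param alignment Character vector of aligned rows (equal lengths; `-` for
#'   gaps), or a list coercible to one.
#' @param motif_map Optional `motif_map` (see [find_yxxp()]) in alignment
#'   column coordinates, used to compute hotspot offsets to the nearest
#'   downstream motif tyrosine. If `NULL`, motifs are taken from the first
#'   (reference) row.
#' @param hotspot_quantile Quantile of positive variability defining a
#'   hotspot column (default 0.75).
#'
#' @return A list of class `alignment_stats` with elements `n_taxa`,
#'   `identity` (mean pairwise percent identity, 0-100), `columns` (tibble of
#'   `position`, `variability`, `is_hotspot`, `offset_to_motif_y`) and
#'   `hotspot_offsets` (offsets of hotspot columns to the nearest downstream
#'   motif tyrosine, positive = upstream of the tyrosine).
#' @export
alignment_stats <- function(alignment, motif_map = NULL,
                            hotspot_quantile = 0.75) {
  rows <- as.character(unlist(alignment, use.names = FALSE))
  if (length(rows) < 2) abort("`alignment` needs at least 2 rows.")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    abort("`alignment` is ragged: rows have unequal lengths.")
  }
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  n_taxa <- nrow(m)
  n_col <- ncol(m)

  pair_ids <- utils::combn(n_taxa, 2)
  identities <- apply(pair_ids, 2, function(p) {
    a <- m[p[1], ]
    b <- m[p[2], ]
    ok <- a != "-" & b != "-"
    if (!any(ok)) return(NA_real_)
    100 * sum(a[ok] == b[ok]) / sum(ok)
  })
  identity <- mean(identities, na.rm = TRUE)

  variability <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(NA_real_)
    1 - max(table(col)) / length(col)
  })

  if (is.null(motif_map)) {
    ref <- paste(m[1, ], collapse = "")
    motif_map <- find_yxxp(gsub("-", "A", ref))
  }
  tyr <- motif_map$start

  pos_var <- variability[!is.na(variability) & variability > 0]
  cutoff <- if (length(pos_var)) stats::quantile(pos_var, hotspot_quantile) else Inf
  is_hotspot <- !is.na(variability) & variability > 0 & variability >= cutoff

  offset_to_y <- vapply(seq_len(n_col), function(j) {
    down <- tyr[tyr >= j]
    if (length(down) == 0) return(NA_integer_)
    as.integer(min(down) - j)
  }, integer(1))

  columns <- tibble::tibble(
    position = seq_len(n_col),
    variability = variability,
    is_hotspot = is_hotspot,
    offset_to_motif_y = offset_to_y
  )
  structure(
    list(
      n_taxa = n_taxa,
      identity = identity,
      columns = columns,
      hotspot_offsets = offset_to_y[is_hotspot]
    ),
    class = "alignment_stats"
  )
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf(
    "Alignment of %d rows: mean pairwise identity %.1f%%, %d hotspot column(s)\n",
    x$n_taxa, x$identity, sum(x$columns$is_hotspot)
  ))
  invisible(x)
}

#' @rdname alignment_stats
#' @param x An `alignment_stats` object.
#' @param ... Unused.
#' @method glance alignment_stats
#' @export
glance.alignment_stats <- function(x, ...) {
  tibble::tibble(
    n_taxa = x$n_taxa,
    identity = x$identity,
    n_hotspots = sum(x$columns$is_hotspot)
  )
}

#' @rdname alignment_stats
#' @method tidy alignment_stats
#' @export
tidy.alignment_stats <- function(x, ...) x$columns
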