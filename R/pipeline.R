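#' Configuration for an end-to-end characterization run
#'
#' Collects and validates everything [run_characterization()] needs. The
#' sequence may be given directly, read from a FASTA file, or generated
#' synthetically from a spec list.
#'
#' @param sequence Sequence string, or `NULL` to use `fasta` / `synthetic`.
#' @param fasta Path to a FASTA file (first record used).
#' @param synthetic Named list of arguments for
#'   [gen_proline_rich_sequence()] (e.g. `list(length = 306)`).
#' @param presets Ensemble presets to run, subset of
#'   `c("coil", "beta", "threestate")`.
#' @param profile Per-residue 3-state profile, required when `"threestate"`
#'   is among `presets`.
#' @param n Conformers per ensemble.
#' @param seed Root seed; every stage derives its stream from it.
#' @param scores Optional predictor score matrix for the disorder consensus.
#' @param score_thresholds Thresholds passed to [disorder_consensus()].
#' @param alignment Optional aligned rows for [alignment_stats()].
#' @param output_dir Optional directory for the JSON report and TSVs.
#' @param force Overwrite existing outputs (default `FALSE`).
#' @return A list of class `run_config`.
#' @export
characterize_config <- function(sequence = NULL, fasta = NULL,
                                synthetic = NULL,
                                presets = c("coil", "beta"),
                                profile = NULL, n = 500, seed = 1,
                                scores = NULL, score_thresholds = 4.5,
                                alignment = NULL,
                                output_dir = NULL, force = FALSE) {
  presets <- match.arg(presets, c("coil", "beta", "threestate"),
                       several.ok = TRUE)
  if ("threestate" %in% presets && is.null(profile)) {
    abort(paste("Preset \"threestate\" requires `profile =` (a per-residue",
                "w_alpha/w_beta/w_coil table)."))
  }
  if (is.null(sequence)) {
    if (!is.null(fasta)) {
      sequence <- read_fasta(fasta)[[1]]
    } else if (!is.null(synthetic)) {
      synthetic$seed <- synthetic$seed %||% seed
      sequence <- do.call(gen_proline_rich_sequence, synthetic)
    } else {
      abort("Provide one of `sequence`, `fasta` or `synthetic`.")
    }
  }
  structure(
    list(sequence = sequence, presets = presets, profile = profile,
         n = n, seed = seed, scores = scores,
         score_thresholds = score_thresholds, alignment = alignment,
         output_dir = output_dir, force = force),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full characterization workflow
#'
#' Composes the pipeline end to end on one sequence: YxxP motif map,
#' composition and molecular weight, optional disorder-prediction consensus
#' and alignment conservation, the requested conformer ensembles with their
#' R_Gyr summaries and secondary-structure content profiles, and the
#' hydrodynamic record derived from the first ensemble's mean R_Gyr. All
#' randomness derives from the root seed (stage `k` of the ensemble stages
#' uses `seed + k`), so stages can be rerun independently and the whole run
#' is deterministic; rerunning an identical config writes a byte-identical
#' JSON report.
#'
#' @param config A `run_config` from [characterize_config()].
#' @return A list of class `characterization_report` with elements `motifs`,
#'   `composition`, `mw_da`, `consensus`, `alignment`, `ensembles` (named
#'   list of `summary` / `ss_content` / `glance` per preset), `hydro`,
#'   `seed` and `package_version`. If `config$output_dir` is set, a
#'   `report.json` plus per-stage TSVs are written there (refusing to
#'   overwrite unless `force`).
#' @export
run_characterization <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seq <- config$sequence

  motifs <- find_yxxp(seq)
  comp <- composition(seq)
  mw <- calc_mw(seq)

  consensus <- NULL
  if (!is.null(config$scores)) {
    consensus <- disorder_consensus(config$scores, config$score_thresholds)
  }
  aln <- NULL
  if (!is.null(config$alignment)) {
    aln <- alignment_stats(config$alignment, motifs)
  }

  ensembles <- list()
  for (k in seq_along(config$presets)) {
    preset <- config$presets[k]
    t0 <- proc.time()[["elapsed"]]
    ens <- generate_ensemble(
      seq, preset = preset, n = config$n, seed = config$seed + k,
      profile = if (preset == "threestate") config$profile else NULL
    )
    g <- glance(ens)
    g$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 2)
    ensembles[[preset]] <- list(
      summary = ensemble_summary(ens$rgyr),
      ss_content = ss_content_by_rgyr(ens),
      glance = g
    )
  }

  hydro <- NULL
  if (length(ensembles) > 0) {
    mean_rg <- ensembles[[1]]$summary$mean
    hydro <- hydrodynamic_record(rh = rh_from_rgyr(mean_rg), mw = mw,
                                 n_residues = nchar(seq))
  }

  report <- structure(
    list(
      sequence_length = nchar(seq),
      motifs = motifs, composition = comp, mw_da = mw,
      consensus = consensus, alignment = aln,
      ensembles = ensembles, hydro = hydro,
      seed = config$seed,
      package_version = as.character(utils::packageVersion("casidp"))
    ),
    class = "characterization_report"
  )
  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir, force = config$force)
  }
  report
}

#' @export
print.characterization_report <- function(x, ...) {
  cat(sprintf("Characterization of a %d-residue sequence (seed %s)\n",
              x$sequence_length, format(x$seed)))
  cat(sprintf("  %d YxxP motif(s); MW %.1f kDa\n",
              nrow(x$motifs), x$mw_da / 1000))
  for (nm in names(x$ensembles)) {
    s <- x$ensembles[[nm]]$summary
    cat(sprintf(
      "  %s ensemble (n=%d): mean R_Gyr %.1f A, peak %.1f A, FWHM %.1f A\n",
      nm, s$n, s$mean, s$peak, s$fwhm
    ))
  }
  if (!is.null(x$hydro)) {
    cat(sprintf("  hydrodynamics: R_H %.1f A, friction ratio %.2f (%s)\n",
                x$hydro$rh, x$hydro$friction_ratio, x$hydro$shape_class))
  }
  invisible(x)
}

write_report <- function(report, dir, force = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  if (file.exists(json_path) && !force) {
    abort(sprintf("Output %s exists; use `force = TRUE` to overwrite.",
                  json_path))
  }
  payload <- list(
    seed = report$seed,
    package_version = report$package_version,
    sequence_length = report$sequence_length,
    mw_da = report$mw_da,
    n_motifs = nrow(report$motifs),
    motifs = as.data.frame(report$motifs),
    composition = as.data.frame(report$composition),
    ensembles = lapply(report$ensembles, function(e) {
      list(summary = as.data.frame(e$summary),
           ss_content = as.data.frame(e$ss_content))
    }),
    hydro = if (!is.null(report$hydro)) as.data.frame(report$hydro)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(json_path)
}

#' Read and write sequences as FASTA
#'
#' Minimal FASTA I/O for protein sequences: `read_fasta()` returns a named
#' character vector of sequences; `write_fasta()` writes one record per
#' element, wrapping lines at 60 characters.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("Not a FASTA file: no '>' header found.")
  id <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  setNames(seqs, names[as.integer(names(seqs))])
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nms <- names(sequences) %||% paste0("seq_", seq_along(sequences))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", nms[i]), con)
    s <- sequences[[i]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Read and write force-extension traces as TSV
#'
#' Two-column TSV (`extension_nm`, `force_pN`) with `#`-prefixed metadata
#' header lines.
#'
#' @param path File path.
#' @return `read_trace_tsv()`: a `force_extension_trace` tibble.
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  stopifnot(all(c("extension_nm", "force_pN") %in% names(df)))
  new_trace(df$extension_nm, df$force_pN)
}

#' @rdname read_trace_tsv
#' @param trace A `force_extension_trace`.
#' @export
write_trace_tsv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# force-extension trace (extension nm, force pN)", con)
  utils::write.table(
    data.frame(extension_nm = trace$extension, force_pN = trace$force),
    con, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
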