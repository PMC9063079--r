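#' Run the four relaxed energy-minimization paths for one sequence
#'
#' Each path relaxes the per-sequence guide differently before the final
#' restricted pseudoknotted minimization:
#' \describe{
#'   \item{P5}{restricted pseudoknotted minimization of the guide as-is.}
#'   \item{P6}{keep only predicted base pairs that cross a guide pair
#'     (plus the `x` marks) as a new guide, letting competing crossing
#'     pairs form.}
#'   \item{P7}{pseudoknot-free restricted fold, keep only relaxed stable
#'     stems, re-minimize; lets competing nested pairs form.}
#'   \item{P8}{open the outermost pair of every disjoint guide
#'     substructure first, then proceed as P7.}
#' }
#' The lowest-energy result is selected (ties go to the earlier path).
#' A path failing on a degenerate input falls back to the empty-guide
#' fold for that path.
#'
#' @param seq RNA sequence string (ungapped).
#' @param guide Per-sequence `guide_structure`.
#' @param params Energy parameters.
#' @param min_stem,max_interruption Relaxed-stem extraction settings for
#'   paths P7/P8.
#' @return A `prediction_record`: list with `sequence`, `guide`, `paths`
#'   (named list of `fold_result`s), `chosen` and `chosen_path`.
#' @export
run_paths <- function(seq, guide = NULL,
                      params = default_energy_parameters(),
                      min_stem = 3L, max_interruption = 2L) {
  gc <- guide_constraints(seq, guide)
  guide <- gc$guide
  n <- nchar(seq)
  x_only <- guide_structure(n, NULL, guide$forbidden)
  safely_path <- function(expr) {
    tryCatch(expr, error = function(e) {
      message("path failed (", conditionMessage(e), "); using empty-guide fold")
      restricted_pk_mfe(seq, x_only, params)
    })
  }
  p5 <- safely_path(restricted_pk_mfe(seq, guide, params))
  p6 <- safely_path({
    pm <- p5$structure$pairs
    gp <- guide$pairs
    crossing <- if (nrow(pm) && nrow(gp)) {
      pm[vapply(seq_len(nrow(pm)), function(r) {
        any((pm[r, 1L] < gp[, 1L] & gp[, 1L] < pm[r, 2L] & pm[r, 2L] < gp[, 2L]) |
              (gp[, 1L] < pm[r, 1L] & pm[r, 1L] < gp[, 2L] & gp[, 2L] < pm[r, 2L]))
      }, logical(1)), , drop = FALSE]
    } else normalize_pairs(NULL)
    if (!nrow(crossing)) {
      p5  # no crossing pairs identified: the path contributes nothing new
    } else {
      g6 <- guide_structure(n, crossing, guide$forbidden)
      restricted_pk_mfe(seq, g6, params)
    }
  })
  p7 <- safely_path({
    nested <- restricted_pkfree_mfe(seq, guide, params)
    stems <- extract_relaxed_stems(nested$structure, min_stem, max_interruption)
    g7 <- guide_structure(n, stems$pairs,
                          setdiff(guide$forbidden, as.vector(stems$pairs)))
    restricted_pk_mfe(seq, g7, params)
  })
  p8 <- safely_path({
    opened <- open_outer_pairs(guide)
    nested <- restricted_pkfree_mfe(seq, opened, params)
    stems <- extract_relaxed_stems(nested$structure, min_stem, max_interruption)
    g8 <- guide_structure(n, stems$pairs,
                          setdiff(guide$forbidden, as.vector(stems$pairs)))
    restricted_pk_mfe(seq, g8, params)
  })
  paths <- list(P5 = p5, P6 = p6, P7 = p7, P8 = p8)
  energies <- vapply(paths, function(p) p$energy, numeric(1))
  chosen_path <- names(paths)[which.min(energies)]
  structure(list(sequence = seq, guide = guide, paths = paths,
                 chosen = paths[[chosen_path]], chosen_path = chosen_path),
            class = "prediction_record")
}

#' @export
print.prediction_record <- function(x, ...) {
  cat("<prediction_record> chose ", x$chosen_path, " (",
      sprintf("%.2f", x$chosen$energy), " kcal/mol)\n", sep = "")
  print(x$chosen)
  invisible(x)
}

#' Predict a structure for every sequence of an alignment
#'
#' The end-to-end pipeline: adjusted mutual information is computed once
#' for the alignment; intermediary base pairs and restricted unpaired
#' columns form an alignment-level guide; the guide is projected onto
#' each row (gaps removed); and each sequence is folded along the four
#' relaxed-minimization paths of [run_paths()], keeping the lowest-energy
#' structure. O(N n^3) time for N sequences of length n.
#'
#' @param aln An `rna_alignment`.
#' @param threshold MIp acceptance threshold (default 0.4).
#' @param min_span Minimal intermediary-pair span (default 4).
#' @param restricted Identify and enforce restricted unpaired columns
#'   (default `TRUE`).
#' @param params Energy parameters.
#' @param min_stem,max_interruption Relaxed-stem settings for P7/P8.
#' @return A tibble with one row per input sequence, in input order:
#'   `id`, `sequence` (ungapped), `guide` (projected guide string),
#'   `structure` (dot-bracket), `energy` (kcal/mol), `method` (winning
#'   path), `pseudoknotted`, and a `paths` list-column of per-path
#'   summaries. The alignment-level guide is attached as attribute
#'   `"alignment_guide"`.
#' @export
predict_alignment <- function(aln, threshold = 0.4, min_span = 4L,
                              restricted = TRUE,
                              params = default_energy_parameters(),
                              min_stem = 3L, max_interruption = 2L) {
  stopifnot(inherits(aln, "rna_alignment"))
  mim <- adjusted_mutual_information(aln)
  sel <- select_intermediary_pairs(mim, threshold = threshold,
                                   min_span = min_span)
  restr <- if (restricted) restricted_unpaired_columns(mim) else integer(0)
  aln_guide <- build_alignment_guide(sel, restr, aln$n_a)
  rows <- purrr::map(seq_len(aln$n), function(r) {
    tryCatch({
      proj <- project_guide(aln_guide, aln$rows[r])
      rec <- run_paths(proj$sequence, proj$guide, params,
                       min_stem = min_stem,
                       max_interruption = max_interruption)
      tibble::tibble(
        id = aln$ids[r],
        sequence = proj$sequence,
        guide = guide_string(proj$guide),
        structure = render_dotbracket(rec$chosen$structure),
        energy = rec$chosen$energy,
        method = rec$chosen_path,
        pseudoknotted = !is_pseudoknot_free(rec$chosen$structure$pairs),
        paths = list(purrr::map_dfr(rec$paths, glance) |>
                       dplyr::mutate(path = names(rec$paths),
                                     .before = 1L))
      )
    }, error = function(e) {
      warning("sequence '", aln$ids[r], "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  })
  failed <- sum(vapply(rows, is.null, logical(1)))
  if (failed > 0L) {
    message(failed, " of ", aln$n, " sequence(s) skipped; see warnings")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "alignment_guide") <- aln_guide
  out
}

#' Arc diagram of a fold result
#'
#' @param object A `fold_result`.
#' @param ... Unused.
#' @return A ggplot object: base pairs as arcs over the sequence, guide
#'   pairs and pseudoknotted pairs distinguished by color.
#' @export
autoplot.fold_result <- function(object, ...) {
  df <- tidy(object)
  kind <- dplyr::case_when(df$pseudoknotted ~ "pseudoknotted",
                           df$guide ~ "guide",
                           TRUE ~ "predicted")
  df$kind <- kind
  ggplot2::ggplot(df) +
    ggplot2::geom_curve(ggplot2::aes(x = .data$i, xend = .data$j,
                                     y = 0, yend = 0, color = .data$kind),
                        curvature = -0.5) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(predicted = "grey40",
                                           guide = "steelblue",
                                           pseudoknotted = "firebrick")) +
    ggplot2::coord_cartesian(ylim = c(-0.1, 1)) +
    ggplot2::labs(x = "sequence position", y = NULL, color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over the package functions; installed as
#' the `inst/cli/covfold` Rscript. Subcommands: `predict` (alignment in,
#' structures out), `covary` (MIp table TSV), `evaluate` (predictions +
#' reference dot-brackets, per-sequence scores TSV), `sweep` (threshold
#' grid report).
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: covfold <predict|covary|evaluate|sweep> [options]",
    "  predict  -i aln.fa -o out.txt [--threshold 0.4] [--params FILE]",
    "           [--min-stem 3] [--no-restricted]",
    "  covary   -i aln.fa -o mip.tsv",
    "  evaluate -i predictions.txt --references ref.dbn -o scores.tsv",
    "           [--adjusted]",
    "  sweep    -i aln.fa --references ref.dbn -o sweep.tsv",
    sep = "\n")
  fail <- function(msg) {
    message(msg, "\n", usage)
    return(invisible(1L))
  }
  if (!length(args)) return(fail("no subcommand"))
  cmd <- args[1L]
  args <- args[-1L]
  opt <- list(threshold = 0.4, min_stem = 3L, params = "default37",
              restricted = TRUE, adjusted = FALSE)
  k <- 1L
  while (k <= length(args)) {
    a <- args[k]
    take <- function() {
      if (k + 1L > length(args)) stop("missing value for ", a, call. = FALSE)
      args[k + 1L]
    }
    consumed <- 2L
    switch(a,
           "-i" = , "--input" = opt$input <- take(),
           "-o" = , "--output" = opt$output <- take(),
           "--threshold" = opt$threshold <- as.numeric(take()),
           "--params" = opt$params <- take(),
           "--min-stem" = opt$min_stem <- as.integer(take()),
           "--references" = opt$references <- take(),
           "--no-restricted" = { opt$restricted <- FALSE; consumed <- 1L },
           "--adjusted" = { opt$adjusted <- TRUE; consumed <- 1L },
           return(fail(paste("unknown option", a))))
    k <- k + consumed
  }
  if (is.null(opt$input)) return(fail("missing -i/--input"))
  if (is.null(opt$output)) return(fail("missing -o/--output"))
  if (!file.exists(opt$input)) return(fail(paste("no such file:", opt$input)))
  status <- tryCatch({
    if (cmd == "predict") {
      aln <- read_alignment(opt$input)
      params <- read_energy_parameters(opt$params)
      pred <- predict_alignment(aln, threshold = opt$threshold,
                                restricted = opt$restricted, params = params,
                                min_stem = opt$min_stem)
      write_predictions(pred, opt$output)
    } else if (cmd == "covary") {
      aln <- read_alignment(opt$input)
      tab <- mip_table(adjusted_mutual_information(aln))
      utils::write.table(tab, opt$output, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else if (cmd == "evaluate") {
      if (is.null(opt$references)) return(fail("missing --references"))
      pred <- read_predictions(opt$input)
      refs <- read_structures(opt$references)
      sc <- evaluate_predictions(pred, refs, adjusted = opt$adjusted)
      utils::write.table(sc, opt$output, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else if (cmd == "sweep") {
      if (is.null(opt$references)) return(fail("missing --references"))
      aln <- read_alignment(opt$input)
      refs <- read_structures(opt$references)
      tab <- guide_threshold_sweep(aln, refs)
      utils::write.table(tab, opt$output, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      return(fail(paste("unknown subcommand", cmd)))
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
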