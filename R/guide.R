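#' Select intermediary base pairs from MIp scores
#'
#' All column pairs with `MIp > threshold` and span `b - a >= min_span`
#' are collected, sorted by decreasing score (ties broken by ascending
#' `(a, b)` for determinism), and accepted greedily: a pair is kept only
#' when both of its columns are still unpaired.
#'
#' @param mim An `mi_matrix` from [adjusted_mutual_information()], or a
#'   plain symmetric score matrix.
#' @param threshold Minimal MIp score, exclusive. Default 0.4.
#' @param min_span Minimal span `b - a` of a candidate pair. Default 4,
#'   consistent with the 3-base minimal hairpin loop.
#' @return Tibble with columns `a`, `b`, `score`, in acceptance order.
#' @export
select_intermediary_pairs <- function(mim, threshold = 0.4, min_span = 4L) {
  scores <- if (inherits(mim, "mi_matrix")) mim$mip else mim
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  n_a <- nrow(scores)
  empty <- tibble::tibble(a = integer(0), b = integer(0), score = numeric(0))
  if (n_a < 2L) return(empty)
  ut <- which(upper.tri(scores), arr.ind = TRUE)
  keep <- scores[ut] > threshold & (ut[, 2L] - ut[, 1L]) >= min_span
  if (!any(keep)) return(empty)
  cand <- tibble::tibble(a = ut[keep, 1L], b = ut[keep, 2L],
                         score = scores[ut][keep])
  cand <- dplyr::arrange(cand, dplyr::desc(.data$score), .data$a, .data$b)
  taken <- logical(n_a)
  acc <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!taken[cand$a[r]] && !taken[cand$b[r]]) {
      acc[r] <- TRUE
      taken[cand$a[r]] <- TRUE
      taken[cand$b[r]] <- TRUE
    }
  }
  cand[acc, ]
}

#' Columns restricted as unpaired
#'
#' Columns whose maximum raw mutual information against any other column
#' falls below the alignment's mean mutual information (`MI_avg`) are
#' considered unlikely to pair and are forced unpaired in the guide.
#'
#' @param mim An `mi_matrix`.
#' @param use_mip Use MIp maxima instead of raw MI maxima (the default
#'   follows the raw-MI reading). The comparison value stays `MI_avg`.
#' @return Integer vector of restricted column indices.
#' @export
restricted_unpaired_columns <- function(mim, use_mip = FALSE) {
  stopifnot(inherits(mim, "mi_matrix"))
  m <- if (use_mip) mim$mip else mim$mi
  if (mim$n_a < 2L) return(integer(0))
  diag(m) <- -Inf
  which(apply(m, 1L, max) < mim$grand_avg)
}

#' Build the alignment-level guide structure
#'
#' Combines accepted intermediary pairs and restricted unpaired columns
#' into a guide over alignment coordinates: `(`/`)` at paired columns,
#' `x` at restricted columns, `_` elsewhere. Crossing conflicts among
#' accepted pairs are resolved by keeping the higher-scoring pair so the
#' guide is pseudoknot-free (a requirement of the restricted folding
#' step); a restricted column that is also a pair endpoint loses its
#' restriction, with a warning.
#'
#' @param pairs Tibble/data frame with columns `a`, `b` and optionally
#'   `score` (used for crossing resolution; defaults to acceptance order).
#' @param restricted Integer vector of restricted column indices.
#' @param n_a Guide length (alignment length).
#' @return Object of class `guide_structure`: list with `length`, `pairs`
#'   (two-column matrix), `forbidden` (integer vector of 'x' positions)
#'   and `scores` (per kept pair).
#' @export
build_alignment_guide <- function(pairs, restricted = integer(0), n_a) {
  n_a <- as.integer(n_a)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pm <- matrix(integer(0), ncol = 2L)
    sc <- numeric(0)
  } else {
    sc <- if ("score" %in% names(pairs)) pairs$score else
      rev(seq_len(nrow(pairs)))
    ord <- order(-sc, pairs$a, pairs$b)
    pm0 <- cbind(pairs$a, pairs$b)[ord, , drop = FALSE]
    sc <- sc[ord]
    keep <- logical(nrow(pm0))
    for (r in seq_len(nrow(pm0))) {
      ok <- TRUE
      for (q in which(keep)) {
        if (pairs_cross(pm0[r, ], pm0[q, ])) { ok <- FALSE; break }
      }
      keep[r] <- ok
    }
    pm <- pm0[keep, , drop = FALSE]
    sc <- sc[keep]
  }
  restricted <- as.integer(restricted)
  clash <- restricted %in% as.vector(pm)
  if (any(clash)) {
    warning("restricted column(s) ", paste(restricted[clash], collapse = ", "),
            " are intermediary pair endpoints; restriction dropped",
            call. = FALSE)
    restricted <- restricted[!clash]
  }
  guide_structure(n_a, pm, restricted, sc)
}

#' Construct a guide structure
#'
#' @param length Guide length.
#' @param pairs Two-column matrix of forced (non-crossing) pairs.
#' @param forbidden Integer positions forced unpaired (`x`).
#' @param scores Optional per-pair scores.
#' @return A `guide_structure`.
#' @export
guide_structure <- function(length, pairs = NULL, forbidden = integer(0),
                            scores = NULL) {
  length <- as.integer(length)
  pairs <- normalize_pairs(pairs)
  forbidden <- sort(unique(as.integer(forbidden)))
  if (nrow(pairs)) {
    if (anyDuplicated(as.vector(pairs))) {
      stop("guide pairs share a column", call. = FALSE)
    }
    if (!is_pseudoknot_free(pairs)) {
      stop("guide pairs must be pseudoknot-free", call. = FALSE)
    }
    if (min(pairs) < 1L || max(pairs) > length) {
      stop("guide pair out of range", call. = FALSE)
    }
  }
  if (length(forbidden) &&
      (any(forbidden < 1L) || any(forbidden > length))) {
    stop("forbidden position out of range", call. = FALSE)
  }
  if (any(forbidden %in% as.vector(pairs))) {
    stop("a position cannot be both paired and forced-unpaired", call. = FALSE)
  }
  structure(list(length = length, pairs = pairs, forbidden = forbidden,
                 scores = scores),
            class = "guide_structure")
}

#' Render a guide structure as a string over `()_x`
#'
#' @param guide A `guide_structure`.
#' @return String of length `guide$length`.
#' @export
guide_string <- function(guide) {
  stopifnot(inherits(guide, "guide_structure"))
  ch <- rep("_", guide$length)
  if (nrow(guide$pairs)) {
    ch[guide$pairs[, 1L]] <- "("
    ch[guide$pairs[, 2L]] <- ")"
  }
  ch[guide$forbidden] <- "x"
  paste(ch, collapse = "")
}

#' Parse a guide string over `()_x`
#'
#' @param s Guide string.
#' @return A `guide_structure`.
#' @export
parse_guide <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), c("(", ")", "_", "x"))
  if (length(bad)) stop("illegal guide character(s): ",
                        paste(bad, collapse = " "), call. = FALSE)
  stack <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (t in seq_along(ch)) {
    if (ch[t] == "(") stack <- c(stack, t)
    else if (ch[t] == ")") {
      if (!length(stack)) stop("unbalanced ')' at ", t, call. = FALSE)
      pi <- c(pi, stack[length(stack)]); pj <- c(pj, t)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced '(' in guide", call. = FALSE)
  guide_structure(length(ch), cbind(pi, pj), which(ch == "x"))
}

#' @export
print.guide_structure <- function(x, ...) {
  cat("<guide_structure> length ", x$length, ", ", nrow(x$pairs),
      " forced pairs, ", length(x$forbidden), " forced-unpaired\n", sep = "")
  cat(guide_string(x), "\n", sep = "")
  invisible(x)
}

#' Project an alignment guide onto one aligned sequence
#'
#' Gap columns of the row are deleted from both the sequence and the
#' guide. A pair that loses an endpoint to a gap is removed entirely (the
#' surviving endpoint becomes free), and pairs whose hairpin loop shrinks
#' below 3 unpaired bases after gap removal are removed iteratively, so
#' the projected guide always satisfies the structure invariants.
#'
#' @param guide Alignment-level `guide_structure`.
#' @param row Aligned sequence (string of length `guide$length`, gaps `-`).
#' @return List with `sequence` (ungapped string) and `guide`
#'   (per-sequence `guide_structure`).
#' @export
project_guide <- function(guide, row) {
  stopifnot(inherits(guide, "guide_structure"))
  ch <- strsplit(row, "", fixed = TRUE)[[1]]
  if (length(ch) != guide$length) {
    stop("row length ", length(ch), " != guide length ", guide$length,
         call. = FALSE)
  }
  keep <- ch != "-"
  new_pos <- cumsum(keep)           # alignment column -> sequence position
  seq_chars <- ch[keep]
  n <- length(seq_chars)
  pm <- guide$pairs
  if (nrow(pm)) {
    both <- keep[pm[, 1L]] & keep[pm[, 2L]]
    pm <- pm[both, , drop = FALSE]
    pm <- cbind(new_pos[pm[, 1L]], new_pos[pm[, 2L]])
    pm <- drop_tight_hairpins(pm)
  }
  forbidden <- new_pos[guide$forbidden[keep[guide$forbidden]]]
  list(sequence = paste(seq_chars, collapse = ""),
       guide = guide_structure(n, pm, forbidden))
}

# Iteratively remove innermost pairs with hairpin loop < 3.
drop_tight_hairpins <- function(pm) {
  pm <- normalize_pairs(pm)
  repeat {
    if (!nrow(pm)) return(pm)
    innermost <- vapply(seq_len(nrow(pm)), function(r) {
      !any(pm[, 1L] > pm[r, 1L] & pm[, 2L] < pm[r, 2L])
    }, logical(1))
    bad <- innermost & (pm[, 2L] - pm[, 1L] - 1L < 3L)
    if (!any(bad)) return(pm)
    pm <- pm[!bad, , drop = FALSE]
  }
}

#' Sweep the MIp acceptance threshold against reference structures
#'
#' Re-selects intermediary pairs over a grid of thresholds and scores the
#' resulting alignment-level guide pairs against per-sequence reference
#' structures (projected through each row), mirroring a grid-search
#' calibration of the score cutoff.
#'
#' @param aln An `rna_alignment`.
#' @param references Named list of [rna_structure()] reference structures,
#'   one per alignment row (ungapped coordinates).
#' @param thresholds Numeric grid; default `seq(-0.2, 1.5, by = 0.1)`.
#' @param min_span Passed to [select_intermediary_pairs()].
#' @return Tibble with columns `threshold`, `n_pairs`, `sensitivity`,
#'   `ppv`, `f_measure` (means over sequences).
#' @export
guide_threshold_sweep <- function(aln, references,
                                  thresholds = seq(-0.2, 1.5, by = 0.1),
                                  min_span = 4L) {
  stopifnot(inherits(aln, "rna_alignment"), length(references) == aln$n)
  mim <- adjusted_mutual_information(aln)
  purrr::map_dfr(thresholds, function(th) {
    sel <- select_intermediary_pairs(mim, threshold = th, min_span = min_span)
    g <- build_alignment_guide(sel, integer(0), aln$n_a)
    sc <- purrr::map_dfr(seq_len(aln$n), function(r) {
      proj <- project_guide(g, aln$rows[r])
      pred <- rna_structure(proj$guide$length, proj$guide$pairs)
      structure_scores(references[[r]], pred)
    })
    tibble::tibble(threshold = th, n_pairs = nrow(sel),
                   sensitivity = mean(sc$sensitivity),
                   ppv = mean(sc$ppv),
                   f_measure = mean(sc$f_measure))
  })
}
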