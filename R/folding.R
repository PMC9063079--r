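seq_codes <- function(seq) {
  # A=65 C=67 G=71 U=85 (upper), a=97 c=99 g=103 u=117
  lut <- integer(128)
  lut[c(65L, 97L)] <- 1L
  lut[c(67L, 99L)] <- 2L
  lut[c(71L, 103L)] <- 3L
  lut[c(85L, 117L)] <- 4L
  raw <- utf8ToInt(seq)
  bad <- raw > 127L
  codes <- integer(length(raw))
  codes[!bad] <- lut[raw[!bad]]
  if (any(codes == 0L)) {
    stop("sequence contains non-ACGU residue at position ",
         which(codes == 0L)[1L], call. = FALSE)
  }
  codes
}

# light-weight constructor for the (hot) unconstrained path
EMPTY_PAIRS <- matrix(integer(0), ncol = 2L,
                      dimnames = list(NULL, c("i", "j")))

empty_guide <- function(n) {
  structure(list(length = as.integer(n), pairs = EMPTY_PAIRS,
                 forbidden = integer(0), scores = NULL),
            class = "guide_structure")
}

fold_result <- function(seq, pairs, energy, guide, method) {
  n <- nchar(seq)
  # lean normalization: DP traceback already emits i < j
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- EMPTY_PAIRS
  } else {
    if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
    storage.mode(pairs) <- "integer"
    swap <- pairs[, 1L] > pairs[, 2L]
    if (any(swap)) pairs[swap, ] <- pairs[swap, c(2L, 1L)]
    if (is.unsorted(pairs[, 1L])) {  # DP traceback output arrives sorted
      pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    }
    dimnames(pairs) <- list(NULL, c("i", "j"))
  }
  st <- structure(list(length = n, pairs = pairs, energy = energy),
                  class = "rna_structure")
  retained <- if (nrow(guide$pairs)) {
    gp <- guide$pairs
    keep <- paste(gp[, 1L], gp[, 2L]) %in% paste(pairs[, 1L], pairs[, 2L])
    gp[keep, , drop = FALSE]
  } else normalize_pairs(NULL)
  structure(list(sequence = seq, structure = st, energy = energy,
                 guide_pairs_retained = retained, method = method),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result> [", x$method, "] ", nrow(x$structure$pairs),
      " pairs, ", sprintf("%.2f", x$energy), " kcal/mol\n", sep = "")
  cat(x$sequence, "\n", render_dotbracket(x$structure), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fold result into a base-pair table
#'
#' @param x A `fold_result`.
#' @param ... Unused.
#' @return Tibble with one row per base pair: `i`, `j`, the paired bases,
#'   whether the pair was part of the guide, and whether it crosses
#'   another pair (pseudoknotted).
#' @export
tidy.fold_result <- function(x, ...) {
  pm <- x$structure$pairs
  bases <- strsplit(x$sequence, "", fixed = TRUE)[[1]]
  crossing <- if (nrow(pm)) rowSums(crossing_matrix(pm)) > 0 else logical(0)
  in_guide <- if (nrow(pm)) {
    paste(pm[, 1L], pm[, 2L]) %in%
      paste(x$guide_pairs_retained[, 1L], x$guide_pairs_retained[, 2L])
  } else logical(0)
  tibble::tibble(i = pm[, 1L], j = pm[, 2L],
                 base_i = bases[pm[, 1L]], base_j = bases[pm[, 2L]],
                 guide = in_guide, pseudoknotted = crossing)
}

#' One-row summary of a fold result
#'
#' @param x A `fold_result`.
#' @param ... Unused.
#' @return Tibble with `method`, `energy`, `n_pairs`, `n_guide_retained`,
#'   `pseudoknotted`.
#' @export
glance.fold_result <- function(x, ...) {
  tibble::tibble(method = x$method, energy = x$energy,
                 n_pairs = nrow(x$structure$pairs),
                 n_guide_retained = nrow(x$guide_pairs_retained),
                 pseudoknotted = !is_pseudoknot_free(x$structure$pairs))
}

# Prepare guide constraints for a sequence: drop guide pairs that are
# non-canonical on this sequence (warn) or too short-spanned.
guide_constraints <- function(seq, guide) {
  n <- nchar(seq)
  if (is.null(guide)) {
    return(list(guide = empty_guide(n), fp = integer(n),
                forbidden = logical(n)))
  }
  stopifnot(inherits(guide, "guide_structure"))
  if (guide$length != n) {
    stop("guide length ", guide$length, " != sequence length ", n,
         call. = FALSE)
  }
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  pm <- guide$pairs
  if (nrow(pm)) {
    ok <- pair_type(bases[pm[, 1L]], bases[pm[, 2L]]) > 0L &
      (pm[, 2L] - pm[, 1L]) >= 4L
    if (any(!ok)) {
      warning(sum(!ok), " guide pair(s) infeasible for this sequence; dropped",
              call. = FALSE)
      pm <- pm[ok, , drop = FALSE]
    }
  }
  fp <- integer(n)
  if (nrow(pm)) {
    fp[pm[, 1L]] <- pm[, 2L]
    fp[pm[, 2L]] <- pm[, 1L]
  }
  forbidden <- logical(n)
  forbidden[guide$forbidden] <- TRUE
  list(guide = guide_structure(n, pm, guide$forbidden),
       fp = fp, forbidden = forbidden)
}

#' Restricted pseudoknot-free minimum free energy folding
#'
#' Finds the minimum-free-energy pseudoknot-free structure that contains
#' every guide pair, pairs no forced-unpaired (`x`) position, uses
#' canonical pairs only and keeps hairpin loops of at least 3 bases.
#' Dynamic programming in O(n^3) time and O(n^2) space. Guide pairs that
#' are non-canonical on the given sequence are dropped with a warning; an
#' otherwise infeasible guide falls back to the empty-guide fold (keeping
#' the `x` constraints), also with a warning.
#'
#' @param seq RNA sequence string.
#' @param guide A `guide_structure` (or `NULL` for unconstrained).
#' @param params Energy parameters.
#' @return A `fold_result`.
#' @export
restricted_pkfree_mfe <- function(seq, guide = NULL,
                                  params = default_energy_parameters()) {
  gc <- guide_constraints(seq, guide)
  codes <- seq_codes(seq)
  res <- fold_restricted_cpp(codes, gc$fp, gc$forbidden, params$stack,
                             params$hairpin, params$bulge, params$internal,
                             params$extrapolation, params$ninio, params$multi)
  if (!res$feasible) {
    warning("guide infeasible; refolding without forced pairs", call. = FALSE)
    res <- fold_restricted_cpp(codes, integer(length(codes)), gc$forbidden,
                               params$stack, params$hairpin, params$bulge,
                               params$internal, params$extrapolation,
                               params$ninio, params$multi)
    gc$guide <- guide_structure(length(codes), NULL, gc$guide$forbidden)
  }
  fold_result(seq, res$pairs, res$energy, gc$guide, "restricted_pkfree")
}

# --- added crossing layer -------------------------------------------------

# Enumerate candidate perfect helices over free positions, each crossing at
# least one base-layer pair. Returns a list of helices; each helix is a
# two-column pair matrix plus a precomputed score.
candidate_crossing_helices <- function(seq, base_pairs, forbidden, params,
                                       min_helix = 2L) {
  n <- nchar(seq)
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  avail <- rep(TRUE, n)
  avail[as.vector(base_pairs)] <- FALSE
  avail[forbidden] <- FALSE
  base_runs <- stack_runs(base_pairs)
  out <- list()
  for (i in seq_len(n)) {
    if (!avail[i]) next
    for (j in seq_len(n)) {
      if (j - i < 4L) next
      if (!avail[j] || pair_type(bases[i], bases[j]) == 0L) next
      # maximal inward extension of a perfect helix starting at (i, j)
      L <- 1L
      while (TRUE) {
        ii <- i + L; jj <- j - L
        if (jj - ii < 4L || !avail[ii] || !avail[jj] ||
            pair_type(bases[ii], bases[jj]) == 0L) break
        L <- L + 1L
      }
      if (L < min_helix) next
      helix <- cbind(i + 0:(L - 1L), j - 0:(L - 1L))
      # must cross the base layer
      ncross_runs <- crossed_run_count(helix, base_runs)
      if (ncross_runs == 0L) next
      out[[length(out) + 1L]] <-
        list(pairs = helix, span = c(i, j),
             score = helix_score(bases, helix, ncross_runs, params))
    }
  }
  out
}

# Maximal stacked runs of a pair set (used as proto-bands of the base layer).
stack_runs <- function(pairs) {
  pairs <- normalize_pairs(pairs)
  if (!nrow(pairs)) return(list())
  key <- paste(pairs[, 1L], pairs[, 2L])
  row_of <- stats::setNames(seq_len(nrow(pairs)), key)
  run_id <- integer(nrow(pairs))
  nr <- 0L
  for (r in order(pairs[, 1L])) {
    prev <- row_of[paste(pairs[r, 1L] - 1L, pairs[r, 2L] + 1L)]
    if (!is.na(prev) && run_id[prev] > 0L) run_id[r] <- run_id[prev]
    else { nr <- nr + 1L; run_id[r] <- nr }
  }
  lapply(seq_len(nr), function(b) pairs[run_id == b, , drop = FALSE])
}

crossed_run_count <- function(helix, base_runs) {
  if (!length(base_runs)) return(0L)
  h <- helix[1L, ]  # outermost pair; helices never split base runs
  sum(vapply(base_runs, function(run) {
    any((run[, 1L] < h[1L] & h[1L] < run[, 2L] & run[, 2L] < h[2L]) |
          (h[1L] < run[, 1L] & run[, 1L] < h[2L] & h[2L] < run[, 2L]))
  }, logical(1)))
}

# Score of adding one crossing helix: its stacking terms in the added
# layer plus its share of the affine pseudoknot penalty (own band +
# newly pseudoknotted base-layer runs + initiation). Band loops carry no
# hairpin/internal initiation (stack-only band scoring).
helix_score <- function(bases, helix, ncross_runs, params) {
  L <- nrow(helix)
  e <- 0
  if (L > 1L) {
    for (t in seq_len(L - 1L)) {
      e <- e + loop_energy(params, "stack",
                           closing = PAIR_TYPES[pair_type(bases[helix[t, 1L]],
                                                          bases[helix[t, 2L]])],
                           inner = PAIR_TYPES[pair_type(bases[helix[t + 1L, 1L]],
                                                        bases[helix[t + 1L, 2L]])])
    }
  }
  e + params$pk[["init"]] +
    params$pk[["band"]] * (1L + ncross_runs)
}

# Select a span-disjoint, energy-lowering subset of candidate helices
# (weighted interval scheduling on the candidate spans).
select_crossing_helices <- function(cands) {
  cands <- Filter(function(h) h$score < 0, cands)
  if (!length(cands)) return(list())
  ends <- vapply(cands, function(h) h$span[2L], numeric(1))
  ord <- order(ends)
  cands <- cands[ord]
  m <- length(cands)
  starts <- vapply(cands, function(h) h$span[1L], numeric(1))
  ends <- ends[ord]
  best <- numeric(m + 1L)   # best (most negative) total up to candidate t
  take <- logical(m)
  prev <- integer(m)
  for (t in seq_len(m)) {
    p <- which(ends < starts[t])
    prev[t] <- if (length(p)) max(p) else 0L
    with_t <- best[prev[t] + 1L] + cands[[t]]$score
    best[t + 1L] <- min(best[t], with_t)
    take[t] <- with_t < best[t]
  }
  sel <- list()
  t <- m
  while (t >= 1L) {
    if (take[t]) {
      sel[[length(sel) + 1L]] <- cands[[t]]
      t <- prev[t]
    } else t <- t - 1L
  }
  rev(sel)
}

add_crossing_layer <- function(seq, base_pairs, forbidden, params) {
  cands <- candidate_crossing_helices(seq, base_pairs, forbidden, params)
  sel <- select_crossing_helices(cands)
  if (!length(sel)) return(normalize_pairs(NULL))
  do.call(rbind, lapply(sel, function(h) h$pairs))
}

#' Restricted pseudoknotted minimum free energy folding
#'
#' Adds a disjoint pseudoknot-free layer to a pseudoknot-free guide so
#' that the union is a density-2 structure of minimal free energy under
#' the affine pseudoknot model. Three relaxations are evaluated and the
#' best kept: (1) the purely nested completion
#' ([restricted_pkfree_mfe()]); (2) an added layer of span-disjoint
#' crossing helices over the guide, followed by a nested re-completion of
#' the remaining free bases; (3) crossing helices added hierarchically on
#' top of the nested completion. Candidates are compared by
#' [structure_energy()] and any candidate failing the density-2 check is
#' discarded.
#'
#' @inheritParams restricted_pkfree_mfe
#' @return A `fold_result`; its energy is never above the pseudoknot-free
#'   restricted optimum for the same input.
#' @export
restricted_pk_mfe <- function(seq, guide = NULL,
                              params = default_energy_parameters()) {
  gc <- guide_constraints(seq, guide)
  guide <- gc$guide
  n <- nchar(seq)
  r1 <- restricted_pkfree_mfe(seq, guide, params)
  cand <- list(list(pairs = r1$structure$pairs, method = "restricted_pkfree"))

  # (2) crossing layer over the guide, then nested re-completion
  l2 <- add_crossing_layer(seq, guide$pairs, guide$forbidden, params)
  if (nrow(l2)) {
    forb2 <- sort(unique(c(guide$forbidden, as.vector(l2))))
    g2 <- guide_structure(n, guide$pairs, setdiff(forb2, as.vector(guide$pairs)))
    n2 <- restricted_pkfree_mfe(seq, g2, params)
    cand[[length(cand) + 1L]] <- list(pairs = rbind(n2$structure$pairs, l2),
                                      method = "restricted_pk_guide_layer")
  }
  # (3) crossing layer on top of the nested completion
  l3 <- add_crossing_layer(seq, r1$structure$pairs, guide$forbidden, params)
  if (nrow(l3)) {
    cand[[length(cand) + 1L]] <- list(pairs = rbind(r1$structure$pairs, l3),
                                      method = "restricted_pk_hierarchical")
  }
  energies <- vapply(cand, function(cc) {
    pm <- normalize_pairs(cc$pairs)
    if (nrow(pm) && !is_density2(pm)) return(Inf)
    suppressWarnings(structure_energy(seq, rna_structure(n, pm), params))
  }, numeric(1))
  best <- which.min(energies)
  method <- if (best == 1L) "restricted_pk" else cand[[best]]$method
  fold_result(seq, cand[[best]]$pairs, energies[best], guide, method)
}

# --- brute force oracle ---------------------------------------------------

#' Exhaustive minimum free energy search (test oracle)
#'
#' Enumerates every structure satisfying the constraints (guide pairs
#' included, `x` positions unpaired, canonical pairs, hairpins >= 3) and
#' returns the global minimum of [structure_energy()]. With
#' `allow_crossing = TRUE` the enumeration runs over all pseudoknot-free
#' added layers disjoint from the guide whose union with the guide is a
#' density-2 structure. Ties are broken lexicographically on the sorted
#' pair list. Exponential: refuses sequences longer than `cap`.
#'
#' @inheritParams restricted_pkfree_mfe
#' @param allow_crossing Permit the added layer to cross the guide.
#' @param cap Maximal sequence length (default 18).
#' @return A `fold_result` with method `"brute_force"`.
#' @export
brute_force_mfe <- function(seq, guide = NULL, allow_crossing = FALSE,
                            params = default_energy_parameters(), cap = 18L) {
  n <- nchar(seq)
  if (n > cap) stop("brute force refuses n > ", cap, call. = FALSE)
  gc <- guide_constraints(seq, guide)
  guide <- gc$guide
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  avail <- rep(TRUE, n)
  avail[as.vector(guide$pairs)] <- FALSE
  avail[guide$forbidden] <- FALSE
  layers <- enumerate_pkfree_layers(bases, avail, 1L, n)
  best_e <- Inf
  best_pairs <- NULL
  for (l2 in layers) {
    pm <- rbind(guide$pairs, l2)
    pm <- normalize_pairs(pm)
    if (!allow_crossing && !is_pseudoknot_free(pm)) next
    if (allow_crossing && nrow(pm) && !is_density2(pm)) next
    e <- tryCatch(
      suppressWarnings(structure_energy(seq, rna_structure(n, pm), params)),
      error = function(err) Inf)
    if (e < best_e - 1e-12 ||
        (abs(e - best_e) <= 1e-12 && lex_less(pm, best_pairs))) {
      best_e <- e
      best_pairs <- pm
    }
  }
  fold_result(seq, best_pairs, best_e, guide, "brute_force")
}

lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  ka <- paste(sprintf("%03d%03d", a[, 1L], a[, 2L]), collapse = " ")
  kb <- paste(sprintf("%03d%03d", b[, 1L], b[, 2L]), collapse = " ")
  ka < kb
}

# All pseudoknot-free pair sets over available positions of window [i, j];
# returns a list of pair matrices (possibly empty matrix).
enumerate_pkfree_layers <- function(bases, avail, i, j) {
  if (i >= j) return(list(normalize_pairs(NULL)))
  # case: i unpaired (or unavailable)
  res <- enumerate_pkfree_layers(bases, avail, i + 1L, j)
  if (avail[i]) {
    for (k in seq.int(i + 4L, length.out = max(0L, j - i - 3L))) {
      if (!avail[k] || pair_type(bases[i], bases[k]) == 0L) next
      inner <- enumerate_pkfree_layers(bases, avail, i + 1L, k - 1L)
      outer <- enumerate_pkfree_layers(bases, avail, k + 1L, j)
      for (a in inner) for (b in outer) {
        res[[length(res) + 1L]] <- rbind(c(i, k), a, b)
      }
    }
  }
  res
}

#' Extract relaxed stable stems from a structure
#'
#' Keeps only pairs belonging to helices of at least `min_len` stacked
#' pairs, where consecutive pairs of a helix may be separated by up to
#' `max_interruption` unpaired bases on each side (small bulges or
#' internal loops). Everything else becomes free.
#'
#' @param st A pseudoknot-free [rna_structure()].
#' @param min_len Minimal number of pairs per kept helix (default 3).
#' @param max_interruption Maximal unpaired bases per side between
#'   consecutive helix pairs (default 2).
#' @return A `guide_structure` containing the kept pairs.
#' @export
extract_relaxed_stems <- function(st, min_len = 3L, max_interruption = 2L) {
  if (is.character(st)) st <- parse_dotbracket(st)
  pm <- st$pairs
  if (!is_pseudoknot_free(pm)) {
    stop("relaxed stems are defined on pseudoknot-free structures",
         call. = FALSE)
  }
  if (!nrow(pm)) return(guide_structure(st$length))
  ord <- order(pm[, 1L])
  pm <- pm[ord, , drop = FALSE]
  m <- nrow(pm)
  nxt <- rep(NA_integer_, m)
  for (r in seq_len(m)) {
    inside <- which(pm[, 1L] > pm[r, 1L] & pm[, 2L] < pm[r, 2L])
    if (!length(inside)) next
    q <- inside[which.min(pm[inside, 1L])]  # direct successor by 5' side
    if (pm[q, 1L] - pm[r, 1L] - 1L <= max_interruption &&
        pm[r, 2L] - pm[q, 2L] - 1L <= max_interruption &&
        # no other pair between r and q
        !any(pm[, 1L] > pm[r, 1L] & pm[, 1L] < pm[q, 1L]) ) {
      nxt[r] <- q
    }
  }
  has_prev <- logical(m)
  has_prev[nxt[!is.na(nxt)]] <- TRUE
  keep <- logical(m)
  for (r in which(!has_prev)) {
    chain <- r
    while (!is.na(nxt[chain[length(chain)]])) {
      chain <- c(chain, nxt[chain[length(chain)]])
    }
    if (length(chain) >= min_len) keep[chain] <- TRUE
  }
  guide_structure(st$length, pm[keep, , drop = FALSE])
}

#' Open the outermost pair of each disjoint substructure
#'
#' For each outermost-level pair of the guide (a pair nested in no other
#' guide pair) the pair is removed and its endpoints become free;
#' forced-unpaired positions are unchanged. Used to let competing nested
#' base pairs form during relaxation.
#'
#' @param guide A pseudoknot-free `guide_structure`.
#' @return A `guide_structure`.
#' @export
open_outer_pairs <- function(guide) {
  stopifnot(inherits(guide, "guide_structure"))
  pm <- guide$pairs
  if (!nrow(pm)) return(guide)
  outer <- vapply(seq_len(nrow(pm)), function(r) {
    !any(pm[, 1L] < pm[r, 1L] & pm[, 2L] > pm[r, 2L])
  }, logical(1))
  guide_structure(guide$length, pm[!outer, , drop = FALSE], guide$forbidden)
}
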