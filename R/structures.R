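#' RNA secondary structures
#'
#' A secondary structure over an (ungapped) sequence of length `length` is a
#' set of base pairs `(i, j)` with `1 <= i < j <= length`, each base paired at
#' most once, and every pair spanning at least three unpaired bases
#' (`j - i >= 4`, the minimal hairpin loop). Pairs may cross, in which case
#' the structure is pseudoknotted.
#'
#' @param length Sequence length (non-negative integer).
#' @param pairs Two-column integer matrix (or data frame) of pairs; may be
#'   empty. Rows are normalized so that `i < j` and sorted by `i`.
#' @param energy Optional free energy in kcal/mol.
#'
#' @return An object of class `rna_structure`: a list with fields `length`,
#'   `pairs` (sorted two-column integer matrix) and `energy`.
#' @export
rna_structure <- function(length, pairs = NULL, energy = NULL) {
  length <- as.integer(length)
  stopifnot(length >= 0L)
  pairs <- normalize_pairs(pairs)
  if (nrow(pairs) > 0L) {
    if (min(pairs) < 1L || max(pairs) > length) {
      stop("pair index out of range 1..", length, call. = FALSE)
    }
    idx <- as.vector(pairs)
    if (anyDuplicated(idx)) {
      stop("a base may pair with at most one other base", call. = FALSE)
    }
    if (any(pairs[, 2L] - pairs[, 1L] < 4L)) {
      stop("hairpin loops must contain at least 3 unpaired bases (j - i >= 4)",
           call. = FALSE)
    }
  }
  structure(list(length = length, pairs = pairs, energy = energy),
            class = "rna_structure")
}

normalize_pairs <- function(pairs) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) ||
      (is.data.frame(pairs) && nrow(pairs) == 0L)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2L) stop("pairs must have two columns", call. = FALSE)
  swap <- pairs[, 1L] > pairs[, 2L]
  if (any(swap)) pairs[swap, ] <- pairs[swap, c(2L, 1L)]
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> length ", x$length, ", ", nrow(x$pairs), " pairs",
      if (!is.null(x$energy)) sprintf(", %.2f kcal/mol", x$energy), "\n",
      sep = "")
  cat(render_dotbracket(x), "\n", sep = "")
  invisible(x)
}

#' Partner vector of a structure
#'
#' @param st An `rna_structure`.
#' @return Integer vector `p` of length `st$length` with `p[i] = j` if
#'   `(i, j)` or `(j, i)` is a pair and `NA` otherwise.
#' @keywords internal
pair_partner <- function(st) {
  p <- rep(NA_integer_, st$length)
  if (nrow(st$pairs)) {
    p[st$pairs[, 1L]] <- st$pairs[, 2L]
    p[st$pairs[, 2L]] <- st$pairs[, 1L]
  }
  p
}

# TRUE where pair p and q cross: p1 < q1 < p2 < q2 (either order).
pairs_cross <- function(p, q) {
  (p[1L] < q[1L] & q[1L] < p[2L] & p[2L] < q[2L]) ||
    (q[1L] < p[1L] & p[1L] < q[2L] & q[2L] < p[2L])
}

# Logical matrix of pairwise crossings for an m x 2 pair matrix.
crossing_matrix <- function(pairs) {
  m <- nrow(pairs)
  if (m == 0L) return(matrix(logical(0), 0L, 0L))
  i <- pairs[, 1L]; j <- pairs[, 2L]
  ii <- matrix(i, m, m); jj <- matrix(j, m, m)
  ti <- t(ii); tj <- t(jj)
  (ii < ti & ti < jj & jj < tj) | (ti < ii & ii < tj & tj < jj)
}

is_pseudoknot_free <- function(pairs) {
  !any(crossing_matrix(normalize_pairs(pairs)))
}

#' Parse a dot-bracket string
#'
#' Supports up to four bracket layers `()`, `[]`, `{}`, `<>` for crossing
#' (pseudoknotted) pairs; `.` marks unpaired bases.
#'
#' @param s A dot-bracket string.
#' @return An [rna_structure()].
#' @examples
#' parse_dotbracket("(((...)))")
#' parse_dotbracket("((..[[..))..]]")  # crossing layers
#' @export
parse_dotbracket <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  openers <- c("(" = 1L, "[" = 2L, "{" = 3L, "<" = 4L)
  closers <- c(")" = 1L, "]" = 2L, "}" = 3L, ">" = 4L)
  bad <- setdiff(unique(chars), c(names(openers), names(closers), "."))
  if (length(bad)) {
    stop("illegal dot-bracket character(s): ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  stacks <- list(integer(0), integer(0), integer(0), integer(0))
  out_i <- integer(0); out_j <- integer(0)
  for (t in seq_len(n)) {
    ch <- chars[t]
    if (ch %in% names(openers)) {
      k <- openers[[ch]]
      stacks[[k]] <- c(stacks[[k]], t)
    } else if (ch %in% names(closers)) {
      k <- closers[[ch]]
      if (!length(stacks[[k]])) {
        stop("unbalanced '", ch, "' at position ", t, call. = FALSE)
      }
      top <- stacks[[k]][length(stacks[[k]])]
      stacks[[k]] <- stacks[[k]][-length(stacks[[k]])]
      out_i <- c(out_i, top); out_j <- c(out_j, t)
    }
  }
  open_left <- vapply(stacks, length, integer(1))
  if (any(open_left > 0L)) {
    stop("unbalanced opening bracket(s) in layer(s): ",
         paste(c("()", "[]", "{}", "<>")[open_left > 0L], collapse = " "),
         call. = FALSE)
  }
  rna_structure(n, cbind(out_i, out_j))
}

#' Render a structure as a dot-bracket string
#'
#' Pairs are assigned greedily (sorted by opening position) to the first
#' bracket layer in which they cross no previously assigned pair, so
#' pseudoknot-free structures always use a single `()` layer and crossing
#' pairs spill into `[]`, `{}`, `<>`. `parse_dotbracket(render_dotbracket(x))`
#' recovers `x`.
#'
#' @param st An [rna_structure()].
#' @return A dot-bracket string of length `st$length`.
#' @export
render_dotbracket <- function(st) {
  stopifnot(inherits(st, "rna_structure"))
  chars <- rep(".", st$length)
  pairs <- st$pairs
  if (nrow(pairs) == 0L) return(paste(chars, collapse = ""))
  open_sym <- c("(", "[", "{", "<")
  close_sym <- c(")", "]", "}", ">")
  layers <- vector("list", 4L)
  for (r in seq_len(nrow(pairs))) {
    p <- pairs[r, ]
    placed <- FALSE
    for (k in 1:4) {
      conflict <- FALSE
      lay <- layers[[k]]
      if (!is.null(lay)) {
        for (q in seq_len(nrow(lay))) {
          if (pairs_cross(p, lay[q, ])) { conflict <- TRUE; break }
        }
      }
      if (!conflict) {
        layers[[k]] <- rbind(lay, p)
        chars[p[1L]] <- open_sym[k]
        chars[p[2L]] <- close_sym[k]
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("structure needs more than 4 bracket layers", call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' First-fit bipartition of a pair set into two pseudoknot-free layers
#'
#' Pairs sorted by `(i, j)` are placed in layer 1 unless they cross a pair
#' already there, else layer 2. For a bisecondary structure built as a
#' pseudoknot-free base layer plus an added layer whose every pair crosses
#' the base layer, this recovers exactly that split.
#'
#' @param pairs Two-column pair matrix.
#' @return List with integer row indices `layer1`, `layer2`; errors if the
#'   remainder still crosses (structure not representable in two layers).
#' @keywords internal
split_layers <- function(pairs) {
  pairs <- normalize_pairs(pairs)
  m <- nrow(pairs)
  if (m == 0L) return(list(layer1 = integer(0), layer2 = integer(0)))
  cm <- crossing_matrix(pairs)
  l1 <- integer(0)
  l2 <- integer(0)
  for (r in seq_len(m)) {
    if (!length(l1) || !any(cm[r, l1])) l1 <- c(l1, r) else l2 <- c(l2, r)
  }
  if (length(l2) > 1L && any(cm[l2, l2])) {
    stop("structure is not bisecondary (added layer crosses itself)",
         call. = FALSE)
  }
  list(layer1 = l1, layer2 = l2)
}

#' Bands of a pseudoknotted structure
#'
#' A band is a maximal run of consecutively stacked pseudoknotted base pairs
#' (pairs that cross at least one other pair) lying in the same layer.
#'
#' @param pairs Two-column pair matrix.
#' @return A list of two-column matrices, one per band; empty list when the
#'   structure is pseudoknot-free.
#' @keywords internal
structure_bands <- function(pairs) {
  pairs <- normalize_pairs(pairs)
  m <- nrow(pairs)
  if (m == 0L) return(list())
  cm <- crossing_matrix(pairs)
  pk <- rowSums(cm) > 0
  if (!any(pk)) return(list())
  lay <- split_layers(pairs)
  layer_of <- integer(m)
  layer_of[lay$layer1] <- 1L
  layer_of[lay$layer2] <- 2L
  idx <- which(pk)
  # group: (i, j) and (i + 1, j - 1), same layer, both pseudoknotted
  key <- paste(pairs[, 1L], pairs[, 2L])
  row_of <- stats::setNames(seq_len(m), key)
  band_id <- rep(NA_integer_, m)
  nb <- 0L
  for (r in idx[order(pairs[idx, 1L])]) {
    prev <- row_of[paste(pairs[r, 1L] - 1L, pairs[r, 2L] + 1L)]
    if (!is.na(prev) && !is.na(band_id[prev]) &&
        layer_of[prev] == layer_of[r] && pk[prev]) {
      band_id[r] <- band_id[prev]
    } else {
      nb <- nb + 1L
      band_id[r] <- nb
    }
  }
  lapply(seq_len(nb), function(b) {
    pairs[which(!is.na(band_id) & band_id == b), , drop = FALSE]
  })
}

#' Check the density-2 property
#'
#' A structure is density-2 when no sequence index is spanned by more than
#' two bands (maximal stacked runs of pseudoknotted pairs). Pseudoknot-free
#' structures are vacuously density-2.
#'
#' @param st An [rna_structure()] or a two-column pair matrix.
#' @return `TRUE`/`FALSE`.
#' @export
is_density2 <- function(st) {
  pairs <- if (inherits(st, "rna_structure")) st$pairs else normalize_pairs(st)
  bands <- tryCatch(structure_bands(pairs), error = function(e) NULL)
  if (is.null(bands)) return(FALSE)
  if (!length(bands)) return(TRUE)
  n <- max(pairs)
  cover <- integer(n)
  for (b in bands) {
    lo <- min(b[, 1L]); hi <- max(b[, 2L])
    cover[lo:hi] <- cover[lo:hi] + 1L
  }
  all(cover <= 2L)
}
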