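#' Canonical-pair joint and marginal frequencies for two columns
#'
#' For alignment columns `a` and `b`, rows where either column is a gap
#' are excluded. Joint counts accumulate only over rows whose residue
#' combination is one of the six canonical base pairs (A·U, U·A, G·C,
#' C·G, G·U, U·G) and are normalized by the number of non-gap rows (so
#' their sum is the canonical fraction, at most 1); the marginals are the
#' ordinary base frequencies at each column over the same non-gap rows.
#' Normalizing the joint by the canonical-retained rows alone would make
#' two independent uniformly-varying columns indistinguishable from a
#' perfectly covarying pair (both condition to the uniform distribution
#' over the six canonical combinations), so the marginals are deliberately
#' unconditional.
#'
#' @param aln An `rna_alignment` (or its character matrix).
#' @param a,b Column indices (1-based).
#' @return List with `joint` (4x4 matrix over A,C,G,U; nonzero only at
#'   canonical combinations), `fa`, `fb` (length-4 marginals),
#'   `n_ungapped` (non-gap rows) and `retained` (canonical rows).
#' @export
pair_frequencies <- function(aln, a, b) {
  M <- if (inherits(aln, "rna_alignment")) alignment_codes(aln) else
    code_matrix(aln)
  stopifnot(a >= 1L, b >= 1L, a <= ncol(M), b <= ncol(M))
  x <- M[, a]; y <- M[, b]
  ungapped <- !is.na(x) & !is.na(y)
  x <- x[ungapped]; y <- y[ungapped]
  can <- canonical_code(x, y)
  joint <- matrix(0, 4L, 4L, dimnames = list(BASES, BASES))
  fa <- stats::setNames(numeric(4L), BASES)
  fb <- stats::setNames(numeric(4L), BASES)
  if (length(x)) {
    tab <- tabulate((x[can] - 1L) * 4L + y[can], nbins = 16L)
    joint[] <- matrix(tab, 4L, 4L, byrow = TRUE) / length(x)
    fa[] <- tabulate(x, nbins = 4L) / length(x)
    fb[] <- tabulate(y, nbins = 4L) / length(y)
  }
  list(joint = joint, fa = fa, fb = fb, n_ungapped = length(x),
       retained = sum(can))
}

BASES <- c("A", "C", "G", "U")

# Integer codes: A=1, C=2, G=3, U=4, gap=NA.
code_matrix <- function(chars) {
  M <- matrix(match(chars, BASES), nrow(chars), ncol(chars))
  M
}

alignment_codes <- function(aln) {
  code_matrix(alignment_matrix(aln))
}

# Canonical pairing indicator on code vectors (NA-safe).
canonical_code <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  ok[ok] <- (x[ok] + y[ok] == 5L) |            # A.U, U.A, C.G, G.C
    (x[ok] == 3L & y[ok] == 4L) |              # G.U
    (x[ok] == 4L & y[ok] == 3L)                # U.G
  ok
}

#' Mutual information between alignment columns
#'
#' \deqn{MI(a,b) = \sum_{x,y} f_{a,b}(x,y)\,\log_2 \frac{f_{a,b}(x,y)}
#'   {f_a(x) f_b(y)}}
#' with the summation restricted to the six canonical base pairs and
#' frequencies from [pair_frequencies()]; `0 log 0 := 0`, and the value
#' is clipped to the score's documented range `[0, 2]` (the truncated
#' sum can otherwise dip marginally below 0). Values are in bits.
#' `MI(a, a)` is reported as 0, and perfectly conserved columns carry no
#' information even when they always form a canonical pair.
#'
#' @param aln An `rna_alignment` with at least two sequences.
#' @return Symmetric `n_a x n_a` matrix of MI values (bits).
#' @export
mutual_information <- function(aln) {
  stopifnot(inherits(aln, "rna_alignment"))
  if (aln$n < 2L) stop("covariation needs at least 2 sequences", call. = FALSE)
  M <- alignment_codes(aln)
  n_a <- ncol(M)
  mi <- matrix(0, n_a, n_a)
  if (n_a < 2L) return(mi)
  for (a in seq_len(n_a - 1L)) {
    xa <- M[, a]
    for (b in (a + 1L):n_a) {
      mi[a, b] <- mi[b, a] <- mi_two_columns(xa, M[, b])
    }
  }
  mi
}

mi_two_columns <- function(x, y) {
  ungapped <- !is.na(x) & !is.na(y)
  if (!any(ungapped)) return(0)
  x <- x[ungapped]; y <- y[ungapped]
  nr <- length(x)
  can <- canonical_code(x, y)
  if (!any(can)) return(0)
  tab <- tabulate((x[can] - 1L) * 4L + y[can], nbins = 16L)
  fxy <- tab / nr
  fa <- tabulate(x, nbins = 4L) / nr
  fb <- tabulate(y, nbins = 4L) / nr
  nz <- which(tab > 0L)
  xi <- ((nz - 1L) %/% 4L) + 1L
  yi <- ((nz - 1L) %% 4L) + 1L
  val <- sum(fxy[nz] * log2(fxy[nz] / (fa[xi] * fb[yi])))
  # the truncated (canonical-only) sum can dip below 0; the score's
  # documented range is [0, 2]
  min(max(val, 0), 2)
}

#' Average product correction of an MI matrix
#'
#' Column averages exclude near-diagonal terms:
#' \deqn{MI(a,\bar z) = \frac{1}{n_a - 1} \sum_z [\,|a - z| > 3\,]\,MI(a,z)}
#' \deqn{MI_{avg} = \frac{2}{n_a (n_a - 1)} \sum_{w < z}
#'   [\,|w - z| > 3\,]\,MI(w,z)}
#' \deqn{APC(a,b) = MI(a,\bar z)\, MI(b,\bar z) / MI_{avg}}
#' Zero-substituted near-diagonal terms stay inside the sums and their
#' denominators; the grand average is the mean over unordered column
#' pairs, the convention under which a flat MI matrix gives `APC = MI`
#' and hence `MIp ~ 0`. When `MI_avg` is 0 the APC is defined as 0
#' everywhere and a message is emitted.
#'
#' @param mi Square symmetric MI matrix.
#' @return List with `col_avg` (vector \eqn{MI(a,\bar z)}), `grand_avg`
#'   (scalar \eqn{MI_{avg}}) and `apc` (matrix).
#' @export
average_product_correction <- function(mi) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  n_a <- nrow(mi)
  idx <- seq_len(n_a)
  far <- abs(outer(idx, idx, "-")) > 3L
  masked <- mi * far
  col_avg <- rowSums(masked) / max(n_a - 1L, 1L)
  # 2/(n_a (n_a - 1)) times the sum over unordered pairs w < z; the
  # symmetric matrix supplies each pair twice, hence the plain mean here
  grand_avg <- sum(masked) / max(n_a * (n_a - 1L), 1L)
  if (grand_avg == 0) {
    message("MI grand average is 0; APC set to 0 everywhere")
    apc <- matrix(0, n_a, n_a)
  } else {
    apc <- outer(col_avg, col_avg) / grand_avg
  }
  list(col_avg = col_avg, grand_avg = grand_avg, apc = apc)
}

#' Adjusted mutual information (MIp) of an alignment
#'
#' Computes the full covariation summary: raw MI, average product
#' correction and their difference `MIp = MI - APC` (which may be
#' negative). MIp suppresses background covariation shared across many
#' columns (random and phylogenetic noise) and is the score from which
#' intermediary base pairs are selected.
#'
#' @param aln An `rna_alignment`.
#' @return Object of class `mi_matrix`: list with `n_a`, symmetric matrices
#'   `mi`, `apc`, `mip`, vector `col_avg` and scalar `grand_avg`.
#' @seealso [select_intermediary_pairs()], [restricted_unpaired_columns()]
#' @export
adjusted_mutual_information <- function(aln) {
  mi <- mutual_information(aln)
  ap <- average_product_correction(mi)
  structure(list(n_a = nrow(mi), mi = mi, apc = ap$apc,
                 mip = mi - ap$apc, col_avg = ap$col_avg,
                 grand_avg = ap$grand_avg),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat("<mi_matrix> ", x$n_a, " columns; MI grand average ",
      format(x$grand_avg, digits = 4), "\n", sep = "")
  top <- mip_table(x)
  print(utils::head(top, 5L))
  invisible(x)
}

#' Long-format covariation table
#'
#' @param mim An `mi_matrix`.
#' @return Tibble with one row per unordered column pair `a < b` and
#'   columns `a`, `b`, `mi`, `apc`, `mip`, sorted by decreasing `mip`
#'   (suitable for TSV export with [utils::write.table()]).
#' @export
mip_table <- function(mim) {
  stopifnot(inherits(mim, "mi_matrix"))
  n_a <- mim$n_a
  if (n_a < 2L) {
    return(tibble::tibble(a = integer(0), b = integer(0), mi = numeric(0),
                          apc = numeric(0), mip = numeric(0)))
  }
  ut <- which(upper.tri(mim$mi), arr.ind = TRUE)
  out <- tibble::tibble(a = ut[, 1L], b = ut[, 2L],
                        mi = mim$mi[ut], apc = mim$apc[ut], mip = mim$mip[ut])
  dplyr::arrange(out, dplyr::desc(.data$mip), .data$a, .data$b)
}

#' Heatmap of adjusted mutual information
#'
#' @param object An `mi_matrix`.
#' @param ... Unused.
#' @return A ggplot object: upper-triangle tile map of MIp.
#' @export
autoplot.mi_matrix <- function(object, ...) {
  df <- mip_table(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$mip)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "alignment column a", y = "alignment column b",
                  fill = "MIp (bits)") +
    ggplot2::theme_minimal()
}
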