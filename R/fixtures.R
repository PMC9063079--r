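#' Generate a synthetic alignment with a planted consensus structure
#'
#' Emulates the covariation signal left by compensatory mutations: a
#' random root sequence consistent with the planted pairs is evolved into
#' `n_sequences` rows. At each planted pair, with probability
#' `compensatory` the two bases are replaced *jointly* by a canonical
#' pair drawn uniformly from the six types (preserving pairing ability,
#' hence maximal covariation when saturated); otherwise each endpoint
#' mutates independently at the background rate. Unpaired columns mutate
#' independently at the background rate. Gaps are single-cell deletions
#' inserted at `gap_rate`; each row's truth structure is the planted
#' structure projected through its gaps (orphaned pairs and hairpins
#' shrunk below 3 removed).
#'
#' @param consensus Planted consensus structure: dot-bracket string
#'   (bracket layers allowed for a crossing layer) or [rna_structure()].
#' @param n_sequences Number of rows (default 50).
#' @param compensatory Per-pair joint substitution probability
#'   (default 1.0: saturated covariation).
#' @param background Per-base independent substitution probability for
#'   unpaired columns and non-compensatory events (default 0.05).
#' @param gap_rate Per-cell deletion probability (default 0).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return List with `alignment` (`rna_alignment`), `structures` (list of
#'   per-row truth [rna_structure()]s on ungapped coordinates),
#'   `sequences` (ungapped row strings) and `consensus`.
#' @export
synthesize_alignment <- function(consensus, n_sequences = 50L,
                                 compensatory = 1.0, background = 0.05,
                                 gap_rate = 0, seed = NULL) {
  if (is.character(consensus)) consensus <- parse_dotbracket(consensus)
  stopifnot(inherits(consensus, "rna_structure"), n_sequences >= 2L)
  if (!is_density2(consensus)) {
    stop("planted structure must be density-2", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n_a <- consensus$length
  pm <- consensus$pairs
  partner <- pair_partner(consensus)
  canonical <- matrix(c("A", "U", "U", "A", "C", "G", "G", "C", "G", "U",
                        "U", "G"), ncol = 2L, byrow = TRUE)
  root <- character(n_a)
  unpaired_cols <- which(is.na(partner))
  root[unpaired_cols] <- sample(BASES, length(unpaired_cols), replace = TRUE)
  if (nrow(pm)) {
    draw <- sample.int(6L, nrow(pm), replace = TRUE)
    root[pm[, 1L]] <- canonical[draw, 1L]
    root[pm[, 2L]] <- canonical[draw, 2L]
  }
  rows <- character(n_sequences)
  structures <- vector("list", n_sequences)
  sequences <- character(n_sequences)
  for (s in seq_len(n_sequences)) {
    ch <- root
    if (nrow(pm)) {
      comp <- stats::runif(nrow(pm)) < compensatory
      if (any(comp)) {
        draw <- sample.int(6L, sum(comp), replace = TRUE)
        ch[pm[comp, 1L]] <- canonical[draw, 1L]
        ch[pm[comp, 2L]] <- canonical[draw, 2L]
      }
      loose <- as.vector(pm[!comp, , drop = FALSE])
    } else loose <- integer(0)
    mutable <- c(unpaired_cols, loose)
    mut <- mutable[stats::runif(length(mutable)) < background]
    if (length(mut)) {
      ch[mut] <- vapply(ch[mut], function(b) {
        sample(setdiff(BASES, b), 1L)
      }, character(1))
    }
    if (gap_rate > 0) {
      gap <- stats::runif(n_a) < gap_rate
      ch[gap] <- "-"
    }
    rows[s] <- paste(ch, collapse = "")
    keep <- ch != "-"
    new_pos <- cumsum(keep)
    st_pairs <- pm
    if (nrow(st_pairs)) {
      both <- keep[st_pairs[, 1L]] & keep[st_pairs[, 2L]]
      st_pairs <- st_pairs[both, , drop = FALSE]
      st_pairs <- cbind(new_pos[st_pairs[, 1L]], new_pos[st_pairs[, 2L]])
      st_pairs <- drop_tight_hairpins(st_pairs)
    }
    sequences[s] <- paste(ch[keep], collapse = "")
    structures[[s]] <- rna_structure(sum(keep), st_pairs)
  }
  aln <- rna_alignment(sprintf("seq_%03d", seq_len(n_sequences)), rows)
  list(alignment = aln, structures = structures, sequences = sequences,
       consensus = consensus)
}

#' Bundled tRNA-like synthetic fixture
#'
#' A 76-column alignment with a planted 4-stem cloverleaf (acceptor, D,
#' anticodon and T stems), saturated compensatory mutation and light
#' background noise; used in end-to-end tests. Deterministic.
#'
#' @param n_sequences Number of rows (default 20).
#' @param seed Seed (default 42).
#' @param gap_rate Per-cell deletion probability (default 0).
#' @return As [synthesize_alignment()], plus `stems`: a list of the four
#'   planted stems (pair matrices in alignment coordinates).
#' @export
trna_like_fixture <- function(n_sequences = 20L, seed = 42L, gap_rate = 0) {
  stems <- list(
    acceptor = cbind(1:7, 72:66),
    d_arm = cbind(10:13, 25:22),
    anticodon = cbind(27:31, 43:39),
    t_arm = cbind(49:53, 65:61)
  )
  consensus <- rna_structure(76L, do.call(rbind, stems))
  out <- synthesize_alignment(consensus, n_sequences = n_sequences,
                              compensatory = 1.0, background = 0.02,
                              gap_rate = gap_rate, seed = seed)
  out$stems <- stems
  out
}
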