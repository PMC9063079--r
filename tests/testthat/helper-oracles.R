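# Independent oracles and random-case generators shared across the suite.
# The oracles re-derive quantities from their definitions with plain loops
# and never call the code paths they check.

CANONICAL <- c("AU", "UA", "CG", "GC", "GU", "UG")

# length-safe sample: pick one element of v
pick <- function(v) v[sample.int(length(v), 1L)]

rand_rna <- function(n, gc_rich = FALSE) {
  prob <- if (gc_rich) c(.15, .35, .35, .15) else rep(.25, 4)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# naive per-definition mutual information between all column pairs:
# joint over canonical combinations normalized by non-gap rows, marginals
# over non-gap rows, clipped to [0, 2]
oracle_mi <- function(M) {
  n_a <- ncol(M)
  mi <- matrix(0, n_a, n_a)
  if (n_a < 2L) return(mi)
  for (a in 1:(n_a - 1L)) for (b in (a + 1L):n_a) {
    rows <- which(M[, a] != "-" & M[, b] != "-")
    if (!length(rows)) next
    v <- 0
    for (x in c("A", "C", "G", "U")) for (y in c("A", "C", "G", "U")) {
      if (!paste0(x, y) %in% CANONICAL) next
      fxy <- sum(M[rows, a] == x & M[rows, b] == y) / length(rows)
      if (fxy > 0) {
        fa <- sum(M[rows, a] == x) / length(rows)
        fb <- sum(M[rows, b] == y) / length(rows)
        v <- v + fxy * log2(fxy / (fa * fb))
      }
    }
    mi[a, b] <- mi[b, a] <- min(max(v, 0), 2)
  }
  mi
}

# naive average product correction, literal normalizations
oracle_apc <- function(mi) {
  n_a <- nrow(mi)
  col_avg <- numeric(n_a)
  for (a in 1:n_a) {
    s <- 0
    for (z in 1:n_a) if (abs(a - z) > 3) s <- s + mi[a, z]
    col_avg[a] <- s / (n_a - 1L)
  }
  g <- 0
  for (w in 1:(n_a - 1L)) for (z in (w + 1L):n_a) {
    if (abs(w - z) > 3) g <- g + mi[w, z]
  }
  g <- 2 * g / (n_a * (n_a - 1L))
  apc <- if (g == 0) matrix(0, n_a, n_a) else outer(col_avg, col_avg) / g
  list(col_avg = col_avg, grand_avg = g, apc = apc)
}

rand_alignment <- function(n = NULL, n_a = NULL, gap_prob = 0.1) {
  if (is.null(n)) n <- pick(3:10)
  if (is.null(n_a)) n_a <- pick(6:15)
  rows <- replicate(n, paste(
    sample(c("A", "C", "G", "U", "-"), n_a, replace = TRUE,
           prob = c(rep((1 - gap_prob) / 4, 4), gap_prob)),
    collapse = ""))
  rna_alignment(paste0("s", seq_len(n)), rows)
}

can_pair <- function(bases, i, j) paste0(bases[i], bases[j]) %in% CANONICAL

# random pseudoknot-free guide: up to `npairs` forced pairs + `nx` x marks
rand_guide_for <- function(s, npairs = 2L, nx = 1L) {
  n <- nchar(s)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  pairs <- NULL
  used <- logical(n)
  cand <- which(outer(1:n, 1:n, function(i, j) j - i >= 4), arr.ind = TRUE)
  cand <- cand[sample(nrow(cand)), , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (!can_pair(bases, i, j) || used[i] || used[j]) next
    ok <- TRUE
    if (!is.null(pairs)) {
      for (q in seq_len(nrow(pairs))) {
        a <- pairs[q, 1L]; b <- pairs[q, 2L]
        if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
          ok <- FALSE
          break
        }
      }
    }
    if (!ok) next
    pairs <- rbind(pairs, c(i, j))
    used[i] <- used[j] <- TRUE
    if (nrow(pairs) >= npairs) break
  }
  avail <- setdiff(seq_len(n), which(used))
  xs <- if (nx > 0L && length(avail)) {
    avail[sample.int(length(avail), min(nx, length(avail)))]
  } else integer(0)
  guide_structure(n, pairs, xs)
}

# random forced stem guide (two stacked pairs), for pseudoknot tests
rand_stem_guide_for <- function(s) {
  n <- nchar(s)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  for (tries in 1:200) {
    i <- pick(1:(n - 9L)); j <- pick((i + 9L):n)
    if (can_pair(bases, i, j) && can_pair(bases, i + 1L, j - 1L)) {
      return(guide_structure(n, cbind(c(i, i + 1L), c(j, j - 1L))))
    }
  }
  guide_structure(n)
}

# random valid structure for round-trip tests; `crossing = TRUE` overlays
# a second pseudoknot-free layer so the result is bisecondary
rand_structure <- function(n, crossing = FALSE) {
  draw_layer <- function(used, tries) {
    pairs <- NULL
    for (t in seq_len(tries)) {
      i <- pick(1:max(1, n - 4L)); j <- i + 3L + pick(1:max(1, n - i - 3L))
      if (j > n || used[i] || used[j]) next
      ok <- TRUE
      if (!is.null(pairs)) {
        for (q in seq_len(nrow(pairs))) {
          a <- pairs[q, 1L]; b <- pairs[q, 2L]
          if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      pairs <- rbind(pairs, c(i, j))
      used[i] <- used[j] <- TRUE
    }
    list(pairs = pairs, used = used)
  }
  l1 <- draw_layer(logical(n), 2L * n)
  pairs <- l1$pairs
  if (crossing) {
    l2 <- draw_layer(l1$used, max(2L, n %/% 4L))
    pairs <- rbind(pairs, l2$pairs)
  }
  rna_structure(n, pairs)
}

same_pairs <- function(a, b) {
  setequal(paste(a[, 1L], a[, 2L]), paste(b[, 1L], b[, 2L]))
}

# 3-stem planted consensus used by the end-to-end tests (length 77)
THREE_STEM_CONSENSUS <- paste0(
  "..((((((....))))))....",
  "(((((((........)))))))",
  "....((((((......))))))...........")
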