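score_matrix <- function(n_a, entries) {
  m <- matrix(0, n_a, n_a)
  for (e in entries) {
    m[e[[1L]], e[[2L]]] <- m[e[[2L]], e[[1L]]] <- e[[3L]]
  }
  m
}

test_that("intermediary pairs: threshold, sorting and greedy acceptance", {
  m <- score_matrix(14L, list(list(2L, 10L, 1.2), list(2L, 12L, 0.9),
                              list(5L, 12L, 0.8)))
  sel <- select_intermediary_pairs(m, threshold = 0.4)
  # (2,12) is rejected: column 2 already taken by the higher-scoring (2,10)
  expect_equal(sel$a, c(2L, 5L))
  expect_equal(sel$b, c(10L, 12L))

  expect_equal(nrow(select_intermediary_pairs(m, threshold = 1.5)), 0L)
  # threshold is strict: a score exactly at the threshold is excluded
  m2 <- score_matrix(10L, list(list(1L, 8L, 0.4)))
  expect_equal(nrow(select_intermediary_pairs(m2, threshold = 0.4)), 0L)
  # minimal span: b - a >= 4
  m3 <- score_matrix(10L, list(list(3L, 6L, 2.0)))
  expect_equal(nrow(select_intermediary_pairs(m3)), 0L)
  # determinism under rerun
  set.seed(11)
  r <- matrix(runif(400), 20L)
  r <- (r + t(r)) / 2
  expect_identical(select_intermediary_pairs(r),
                   select_intermediary_pairs(r))
})

test_that("raising the threshold never adds intermediary pairs", {
  set.seed(12)
  for (t in 1:10) {
    r <- matrix(runif(15L^2, -0.5, 1.5), 15L)
    r <- (r + t(r)) / 2
    prev <- select_intermediary_pairs(r, threshold = -0.2)
    for (th in seq(0, 1.5, by = 0.25)) {
      cur <- select_intermediary_pairs(r, threshold = th)
      expect_true(all(paste(cur$a, cur$b) %in% paste(prev$a, prev$b)))
      prev <- cur
    }
  }
})

test_that("restricted unpaired columns are those below the mean MI", {
  aln <- trna_like_fixture(n_sequences = 12L, seed = 3L)$alignment
  mim <- adjusted_mutual_information(aln)
  restr <- restricted_unpaired_columns(mim)
  # naive recomputation
  m <- mim$mi
  diag(m) <- -Inf
  expect_identical(restr, which(apply(m, 1L, max) < mim$grand_avg))
  # a column reaching the maximal MI of 2 can never be restricted
  m2 <- mim
  m2$mi[1L, 10L] <- m2$mi[10L, 1L] <- 2
  expect_false(1L %in% restricted_unpaired_columns(m2))
})

test_that("alignment guides combine pairs and restrictions", {
  g <- build_alignment_guide(tibble::tibble(a = 1L, b = 10L, score = 1),
                             restricted = 5L, n_a = 10L)
  expect_equal(guide_string(g), "(___x____)")
  g0 <- build_alignment_guide(NULL, integer(0), 8L)
  expect_equal(guide_string(g0), "________")
  # crossing conflict: the lower-scoring pair is dropped
  gx <- build_alignment_guide(
    tibble::tibble(a = c(1L, 4L), b = c(8L, 12L), score = c(2, 1)),
    integer(0), 12L)
  expect_equal(nrow(gx$pairs), 1L)
  expect_equal(unname(gx$pairs[1L, ]), c(1L, 8L))
  # restriction on a pair endpoint is dropped with a warning
  expect_warning(
    gw <- build_alignment_guide(tibble::tibble(a = 1L, b = 10L, score = 1),
                                restricted = c(1L, 5L), n_a = 10L),
    "restriction dropped")
  expect_equal(gw$forbidden, 5L)
})

test_that("guide strings parse back and invariants hold", {
  g <- parse_guide("((_x_))__x")
  expect_equal(nrow(g$pairs), 2L)
  expect_equal(g$forbidden, c(4L, 10L))
  expect_equal(guide_string(g), "((_x_))__x")
  expect_error(parse_guide("(()"), "unbalanced")
  expect_error(guide_structure(10L, cbind(1L, 8L), forbidden = 1L),
               "both paired and forced-unpaired")
  expect_error(guide_structure(12L, rbind(c(1L, 8L), c(4L, 12L))),
               "pseudoknot-free")
})

test_that("projection removes gaps, orphans and tight hairpins", {
  # "(___)" over "AC-GU": loop shrinks to 2 < 3, pair removed
  g <- parse_guide("(___)")
  pr <- project_guide(g, "AC-GU")
  expect_equal(pr$sequence, "ACGU")
  expect_equal(nrow(pr$guide$pairs), 0L)

  # loop still >= 3 on a gapless row: pair and x kept
  g2 <- parse_guide("(___x___)")
  pr2 <- project_guide(g2, "ACGUACGUA")
  expect_equal(nrow(pr2$guide$pairs), 1L)
  expect_equal(pr2$guide$forbidden, 5L)

  # gap at a paired column: both endpoints become unpaired
  pr3 <- project_guide(parse_guide("((___))"), "A-CGUAC")
  expect_equal(nrow(pr3$guide$pairs), 1L)
  expect_equal(unname(pr3$guide$pairs[1L, ]), c(1L, 6L))

  expect_error(project_guide(g, "ACGU"), "row length")
})

test_that("projected guides always satisfy the structure invariants", {
  set.seed(13)
  for (t in 1:25) {
    n_a <- pick(12:30)
    row <- paste(sample(c("A", "C", "G", "U", "-"), n_a, TRUE,
                        prob = c(.2, .2, .2, .2, .2)), collapse = "")
    g <- rand_guide_for(gsub("-", "A", row), npairs = 3L, nx = 2L)
    pr <- project_guide(g, row)
    pm <- pr$guide$pairs
    if (nrow(pm)) {
      expect_true(covfold:::is_pseudoknot_free(pm))
      inner <- vapply(seq_len(nrow(pm)), function(r) {
        !any(pm[, 1L] > pm[r, 1L] & pm[, 2L] < pm[r, 2L])
      }, logical(1))
      expect_true(all(pm[inner, 2L] - pm[inner, 1L] - 1L >= 3L))
    }
    # no projected position may exceed the ungapped length
    expect_true(all(c(pm, pr$guide$forbidden) <= nchar(pr$sequence)))
  }
})

test_that("threshold sweep reports the guide accuracy grid", {
  fx <- trna_like_fixture(n_sequences = 10L, seed = 21L)
  sw <- guide_threshold_sweep(fx$alignment, fx$structures,
                              thresholds = c(0.2, 0.8, 1.4))
  expect_equal(nrow(sw), 3L)
  expect_true(all(sw$n_pairs == cummin(sw$n_pairs)))  # monotone in threshold
  expect_true(all(sw$f_measure >= 0 & sw$f_measure <= 1))
})
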