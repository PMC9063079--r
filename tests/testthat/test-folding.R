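test_that("restricted pseudoknot-free DP equals brute force on random instances", {
  set.seed(51)
  for (t in 1:60) {
    n <- pick(9:13)
    s <- rand_rna(n)
    g <- if (t %% 3 == 0) NULL else rand_guide_for(s, npairs = pick(0:2),
                                                   nx = pick(0:2))
    dp <- suppressWarnings(restricted_pkfree_mfe(s, g))
    bf <- suppressWarnings(brute_force_mfe(s, g))
    expect_equal(dp$energy, bf$energy, tolerance = 1e-9)
    # reported energy always equals the recomputed decomposition energy
    expect_equal(structure_energy(s, dp$structure), dp$energy,
                 tolerance = 1e-6)
    # constraints honored
    if (!is.null(g)) {
      expect_false(any(g$forbidden %in% as.vector(dp$structure$pairs)))
    }
  }
})

test_that("forced guide pairs appear in the fold; infeasible ones are dropped", {
  s <- "GGGAAACCCAAAGGGAAACCC"
  g <- guide_structure(21L, cbind(c(1L, 2L), c(9L, 8L)))
  r <- restricted_pkfree_mfe(s, g)
  expect_true(all(paste(g$pairs[, 1L], g$pairs[, 2L]) %in%
                    paste(r$structure$pairs[, 1L], r$structure$pairs[, 2L])))
  expect_equal(nrow(r$guide_pairs_retained), 2L)
  # non-canonical guide pair for this sequence is dropped with a warning
  g2 <- guide_structure(21L, cbind(4L, 12L))  # A.A
  expect_warning(r2 <- restricted_pkfree_mfe(s, g2), "infeasible")
  expect_s3_class(r2, "fold_result")
})

test_that("adding constraints never lowers the optimal energy", {
  set.seed(52)
  for (t in 1:15) {
    n <- pick(20:35)
    s <- rand_rna(n, gc_rich = TRUE)
    base <- restricted_pkfree_mfe(s)
    # extra x on a previously paired position
    pm <- base$structure$pairs
    if (nrow(pm)) {
      xg <- guide_structure(n, NULL, pm[1L, 1L])
      expect_gte(restricted_pkfree_mfe(s, xg)$energy, base$energy - 1e-9)
    }
    # random forced stem
    g <- rand_stem_guide_for(s)
    if (nrow(g$pairs)) {
      con <- suppressWarnings(restricted_pkfree_mfe(s, g))
      expect_gte(con$energy, base$energy - 1e-9)
    }
  }
})

test_that("pseudoknotted folding forms crossing pairs on an H-type fixture", {
  s <- "AAAGGGGGUUACCCCC"
  g <- guide_structure(16L, cbind(c(1L, 2L), c(10L, 9L)))
  pkfree <- restricted_pkfree_mfe(s, g)
  pk <- restricted_pk_mfe(s, g)
  expect_lt(pk$energy, pkfree$energy)
  expect_false(covfold:::is_pseudoknot_free(pk$structure$pairs))
  expect_true(is_density2(pk$structure))
  # guide pairs retained
  expect_equal(nrow(pk$guide_pairs_retained), 2L)
  # matches the exhaustive search over disjoint pseudoknot-free added layers
  bf <- brute_force_mfe(s, g, allow_crossing = TRUE)
  expect_equal(pk$energy, bf$energy, tolerance = 1e-9)
})

test_that("pseudoknotted folding stays density-2 and beats no candidate", {
  set.seed(53)
  for (t in 1:25) {
    n <- pick(12:16)
    s <- rand_rna(n, gc_rich = TRUE)
    g <- rand_stem_guide_for(s)
    pk <- suppressWarnings(restricted_pk_mfe(s, g))
    expect_true(is_density2(pk$structure))
    pkfree <- suppressWarnings(restricted_pkfree_mfe(s, g))
    expect_lte(pk$energy, pkfree$energy + 1e-9)
    expect_equal(structure_energy(s, pk$structure), pk$energy,
                 tolerance = 1e-6)
  }
})

test_that("brute force refuses long sequences and handles trivial ones", {
  expect_error(brute_force_mfe(rand_rna(25L)), "refuses")
  r <- brute_force_mfe("ACGU")
  expect_equal(r$energy, 0)
  expect_equal(nrow(r$structure$pairs), 0L)
})

test_that("relaxed stems keep interrupted helices and drop lone pairs", {
  # lone pair: removed at the default minimum stem length
  lone <- parse_dotbracket("..(....)....")
  expect_equal(nrow(extract_relaxed_stems(lone)$pairs), 0L)
  # 5-stack helix with a 1-base bulge on the 5' side: retained whole
  bulged <- rna_structure(18L, rbind(c(1L, 16L), c(2L, 15L), c(4L, 14L),
                                     c(5L, 13L), c(6L, 12L)))
  stems <- extract_relaxed_stems(bulged)
  expect_equal(nrow(stems$pairs), 5L)
  # with no interruption allowed the helix splits; only the 3-stack half
  # survives the minimum stem length
  expect_equal(nrow(extract_relaxed_stems(bulged, max_interruption = 0L)$pairs),
               3L)
  # empty structure
  expect_equal(nrow(extract_relaxed_stems(rna_structure(10L))$pairs), 0L)
  expect_error(extract_relaxed_stems(rna_structure(12L,
                                                   rbind(c(1L, 8L), c(4L, 12L)))),
               "pseudoknot-free")
})

test_that("opening outer pairs removes one pair per disjoint substructure", {
  g <- parse_guide("((___))")
  expect_equal(guide_string(open_outer_pairs(g)), "_(___)_")
  # two disjoint stems: one pair removed from each
  g2 <- parse_guide("((___))x((___))")
  opened <- open_outer_pairs(g2)
  expect_equal(guide_string(opened), "_(___)_x_(___)_")
  expect_equal(opened$forbidden, 8L)
  # empty guide unchanged
  g3 <- parse_guide("______")
  expect_identical(guide_string(open_outer_pairs(g3)), "______")
})

test_that("fold results tidy and glance into well-formed tibbles", {
  s <- "AAAGGGGGUUACCCCC"
  g <- guide_structure(16L, cbind(c(1L, 2L), c(10L, 9L)))
  pk <- restricted_pk_mfe(s, g)
  td <- tidy(pk)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(pk$structure$pairs))
  expect_true(any(td$pseudoknotted))
  expect_true(sum(td$guide) == 2L)
  gl <- glance(pk)
  expect_equal(gl$energy, pk$energy)
  expect_true(gl$pseudoknotted)
})
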