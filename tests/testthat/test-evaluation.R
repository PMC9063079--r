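test_that("confusion counts follow the exact-pair and compatibility rules", {
  expect_equal(confusion_counts("(((...)))", "(((...)))"),
               c(tp = 3L, fp = 0L, fn = 0L))
  expect_equal(confusion_counts("(((...)))", "((.....))"),
               c(tp = 2L, fp = 0L, fn = 1L))
  # an extra pair with both endpoints unpaired in the reference is a
  # compatible pair: counted as FP unadjusted, excluded when adjusted
  ref <- "(((...)))....."
  prd <- "(((...)))(...)"
  expect_equal(confusion_counts(ref, prd)[["fp"]], 1L)
  expect_equal(confusion_counts(ref, prd, adjusted = TRUE)[["fp"]], 0L)
  expect_error(confusion_counts("((...))", "((....))"), "length")
})

test_that("inconsistent pairs are penalized even in adjusted mode", {
  ref <- parse_dotbracket("((((...))))......")
  # prediction pairs position 1 with 17 (1 is paired with 11 in ref)
  prd <- rna_structure(17L, rbind(c(1L, 17L)))
  cc <- confusion_counts(ref, prd, adjusted = TRUE)
  expect_equal(cc[["fp"]], 1L)
})

test_that("scores implement the three formulas and their conventions", {
  sc <- structure_scores("(((...)))", "((.....))")
  expect_equal(sc$sensitivity, 2 / 3)
  expect_equal(sc$ppv, 1)
  expect_equal(sc$f_measure, 0.8)
  # no predicted and no reference pairs: vacuously perfect
  sc2 <- structure_scores(".....", ".....")
  expect_equal(sc2$f_measure, 1)
  # PPV = 0 forces F = 0
  sc3 <- structure_scores("(((...)))", ".........")
  expect_equal(sc3$ppv, 1)  # vacuous: nothing predicted
  expect_equal(sc3$f_measure, 0)  # sensitivity 0
  sc4 <- structure_scores(".........(...).", "(((...)))......")
  expect_equal(sc4$ppv, 0)
  expect_equal(sc4$f_measure, 0)
})

test_that("self-comparison scores 1 and adjusted-F dominates unadjusted-F", {
  set.seed(71)
  for (t in 1:20) {
    n <- pick(10:30)
    st <- rand_structure(n, crossing = (t %% 4 == 0))
    self <- structure_scores(st, st)
    expect_equal(self$sensitivity, 1)
    expect_equal(self$ppv, 1)
    expect_equal(self$f_measure, 1)
    other <- rand_structure(n)
    plain <- structure_scores(st, other)
    adj <- structure_scores(st, other, adjusted = TRUE)
    expect_lte(adj$fp, plain$fp)
    expect_gte(adj$f_measure, plain$f_measure)
  }
})

test_that("reference filtering drops non-canonical pairs and tight loops", {
  # pair 1.9 is A.A on this sequence: dropped before scoring
  seq <- "AGGAAACCA"
  ref <- parse_dotbracket("(((...)))")
  sc <- structure_scores(ref, "(((...)))", seq = seq)
  expect_equal(sc$tp, 2L)
  expect_equal(sc$fp, 1L)
  expect_equal(sc$fn, 0L)
})

test_that("the literal resampling test behaves as printed", {
  set.seed(72)
  f <- runif(40, 0.3, 0.9)
  # identical vectors: t_s = 0, roughly half the resampled t' exceed it
  res <- permutation_test(f, f, reps = 2000L, seed = 1L)
  expect_gt(res$p_value, 0.05)
  expect_false(res$significant)
  # degenerate constant vectors: every t' equals t_s, p = 1
  res2 <- permutation_test(rep(0.9, 10L), rep(0.2, 10L), reps = 500L,
                           seed = 2L)
  expect_equal(res2$p_value, 1)
  # seed reproducibility at full depth
  a <- permutation_test(f, f + 0.02, reps = 10000L, seed = 99L)
  b <- permutation_test(f, f + 0.02, reps = 10000L, seed = 99L)
  expect_identical(a$p_value, b$p_value)
  expect_true(a$p_value >= 0 && a$p_value <= 1)
  # conventional label-permutation alternative is two-sided
  perm <- permutation_test(f + 0.3, f, reps = 2000L, seed = 3L,
                           method = "permutation")
  expect_lt(perm$p_value, 0.05)
  expect_error(permutation_test(numeric(0), f), "empty")
})

test_that("prediction tables are scored row-wise against references", {
  fx <- trna_like_fixture(n_sequences = 5L, seed = 17L)
  pred <- suppressWarnings(predict_alignment(fx$alignment))
  refs <- fx$structures
  names(refs) <- fx$alignment$ids
  sc <- evaluate_predictions(pred, refs)
  expect_equal(nrow(sc), 5L)
  expect_true(all(c("sensitivity", "ppv", "f_measure") %in% names(sc)))
  expect_true(all(sc$f_measure >= 0 & sc$f_measure <= 1))
})
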