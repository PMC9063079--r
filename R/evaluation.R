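#' Base-pair confusion counts
#'
#' A true positive is a predicted pair identical to a reference pair;
#' a false negative is a reference pair missing from the prediction; a
#' false positive is a predicted pair absent from the reference. In
#' adjusted mode, a predicted pair `i.j` is *inconsistent* when the
#' reference pairs `i` or `j` with some other partner; predicted pairs
#' that are neither in the reference nor inconsistent are *compatible*
#' and are excluded from the false positives.
#'
#' @param ref,pred [rna_structure()] objects (or dot-bracket strings) of
#'   equal length.
#' @param adjusted Exclude compatible pairs from FP (default `FALSE`).
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
confusion_counts <- function(ref, pred, adjusted = FALSE) {
  if (is.character(ref)) ref <- parse_dotbracket(ref)
  if (is.character(pred)) pred <- parse_dotbracket(pred)
  if (ref$length != pred$length) {
    stop("reference length ", ref$length, " != prediction length ",
         pred$length, call. = FALSE)
  }
  rk <- paste(ref$pairs[, 1L], ref$pairs[, 2L])
  pk <- paste(pred$pairs[, 1L], pred$pairs[, 2L])
  tp <- sum(pk %in% rk)
  fn <- sum(!rk %in% pk)
  extra <- which(!pk %in% rk)
  if (!adjusted) {
    fp <- length(extra)
  } else {
    rp <- pair_partner(ref)
    inconsistent <- vapply(extra, function(r) {
      i <- pred$pairs[r, 1L]; j <- pred$pairs[r, 2L]
      (!is.na(rp[i]) && rp[i] != j) || (!is.na(rp[j]) && rp[j] != i)
    }, logical(1))
    fp <- sum(inconsistent)
  }
  c(tp = tp, fp = fp, fn = fn)
}

#' Sensitivity, PPV and F-measure of a predicted structure
#'
#' \deqn{Sen = TP/(TP+FN), \quad PPV = TP/(TP+FP), \quad
#'   F = 2\,PPV\,Sen/(PPV+Sen)}
#' `F` is 0 when PPV or sensitivity is 0. An empty prediction against an
#' empty reference is vacuously perfect (all 1). When a sequence is
#' supplied, non-canonical reference pairs and reference hairpin loops
#' shorter than 3 are dropped before counting.
#'
#' @inheritParams confusion_counts
#' @param seq Optional sequence used to filter the reference.
#' @return One-row tibble: `tp`, `fp`, `fn`, `sensitivity`, `ppv`,
#'   `f_measure`, `adjusted`.
#' @export
structure_scores <- function(ref, pred, adjusted = FALSE, seq = NULL) {
  if (is.character(ref)) ref <- parse_dotbracket(ref)
  if (is.character(pred)) pred <- parse_dotbracket(pred)
  if (!is.null(seq)) ref <- filter_reference(ref, seq)
  cc <- confusion_counts(ref, pred, adjusted = adjusted)
  sen <- if (cc[["tp"]] + cc[["fn"]] > 0L) {
    cc[["tp"]] / (cc[["tp"]] + cc[["fn"]])
  } else 1
  ppv <- if (cc[["tp"]] + cc[["fp"]] > 0L) {
    cc[["tp"]] / (cc[["tp"]] + cc[["fp"]])
  } else 1
  f <- if (sen > 0 && ppv > 0) 2 * ppv * sen / (ppv + sen) else 0
  tibble::tibble(tp = cc[["tp"]], fp = cc[["fp"]], fn = cc[["fn"]],
                 sensitivity = sen, ppv = ppv, f_measure = f,
                 adjusted = adjusted)
}

# Drop non-canonical reference pairs and (iteratively) hairpins < 3.
filter_reference <- function(ref, seq) {
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  pm <- ref$pairs
  if (nrow(pm)) {
    ok <- pair_type(bases[pm[, 1L]], bases[pm[, 2L]]) > 0L
    pm <- drop_tight_hairpins(pm[ok, , drop = FALSE])
  }
  rna_structure(ref$length, pm)
}

#' Score a prediction table against reference structures
#'
#' @param predictions Tibble from [predict_alignment()] or
#'   [read_predictions()].
#' @param references Named list of reference structures (names matched to
#'   `predictions$id`; unnamed lists are matched by position).
#' @param adjusted Exclude compatible pairs from FP.
#' @return `predictions` with score columns appended (one row per
#'   sequence).
#' @export
evaluate_predictions <- function(predictions, references, adjusted = FALSE) {
  stopifnot(nrow(predictions) >= 1L)
  get_ref <- function(r) {
    if (!is.null(names(references)) &&
        predictions$id[r] %in% names(references)) {
      references[[predictions$id[r]]]
    } else references[[r]]
  }
  sc <- purrr::map_dfr(seq_len(nrow(predictions)), function(r) {
    structure_scores(get_ref(r), parse_dotbracket(predictions$structure[r]),
                     adjusted = adjusted, seq = predictions$sequence[r])
  })
  dplyr::bind_cols(predictions[c("id", "sequence", "structure", "energy")], sc)
}

#' Resampling significance test on two F-measure vectors
#'
#' The test statistic is `t_s = mean(f1) - mean(f2)`. Each repetition
#' draws, with replacement, a resample of `f1` and of `f2` (each to its
#' own size), recomputes the difference of means `t'_s`, and the p-value
#' is the proportion of repetitions with `t'_s >= t_s`. This literal
#' bootstrap procedure degenerates to p = 1 on constant vectors (each
#' `t'_s` equals `t_s`); a conventional label-permutation two-sided test
#' is available via `method = "permutation"`, which pools the values,
#' permutes group labels and counts `|t'_s| >= |t_s|`.
#'
#' @param f1,f2 Non-empty numeric vectors of per-sequence F-measures.
#' @param reps Number of repetitions (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param method `"bootstrap"` (the literal resampling procedure, default)
#'   or `"permutation"`.
#' @return One-row tibble: `p_value`, `t_s`, `reps`, `method`,
#'   `significant` (at 0.05).
#' @export
permutation_test <- function(f1, f2, reps = 10000L, seed = NULL,
                             method = c("bootstrap", "permutation")) {
  method <- match.arg(method)
  if (!length(f1) || !length(f2)) stop("empty score vector", call. = FALSE)
  stopifnot(reps >= 1L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  t_s <- mean(f1) - mean(f2)
  if (method == "bootstrap") {
    n1 <- length(f1); n2 <- length(f2)
    tprime <- vapply(seq_len(reps), function(r) {
      mean(f1[sample.int(n1, n1, replace = TRUE)]) -
        mean(f2[sample.int(n2, n2, replace = TRUE)])
    }, numeric(1))
    p <- sum(tprime >= t_s) / reps
  } else {
    pool <- c(f1, f2)
    n1 <- length(f1)
    tprime <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(length(pool), n1)
      mean(pool[idx]) - mean(pool[-idx])
    }, numeric(1))
    p <- sum(abs(tprime) >= abs(t_s)) / reps
  }
  tibble::tibble(p_value = p, t_s = t_s, reps = as.integer(reps),
                 method = method, significant = p < 0.05)
}
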