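test_that("aligned FASTA is read, normalized and validated", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC-GU", ">b", "acagt"), path)
  aln <- read_alignment(path)
  expect_s3_class(aln, "rna_alignment")
  expect_equal(aln$n, 2L)
  expect_equal(aln$n_a, 5L)
  expect_equal(aln$rows, c("AC-GU", "ACAGU"))  # uppercase, T -> U

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGU", ">b", "ACG"), bad)
  expect_error(read_alignment(bad), "unequal")

  amb <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACNU", ">b", "ACGU"), amb)
  expect_error(read_alignment(amb), "illegal residue 'N' in record 'a' at column 3")

  expect_error(read_alignment(file.path(tempdir(), "nope.fa")), "no such file")
  # '.' and '_' both read as gaps
  dots <- rna_alignment(c("a", "b"), c("AC.GU", "AC_GU"))
  expect_equal(dots$rows, c("AC-GU", "AC-GU"))
})

test_that("dot-bracket parsing handles layers and rejects imbalance", {
  st <- parse_dotbracket("(((...)))")
  expect_equal(st$pairs, rbind(c(1L, 9L), c(2L, 8L), c(3L, 7L)),
               ignore_attr = TRUE)
  st2 <- parse_dotbracket("((..[[..))..]]")
  expect_true(any(covfold:::crossing_matrix(st2$pairs)))
  expect_error(parse_dotbracket("((."), "unbalanced")
  expect_error(parse_dotbracket("(])"), "unbalanced")
  expect_error(parse_dotbracket("(x)"), "illegal")
})

test_that("rendering uses minimal layers and round-trips", {
  expect_equal(render_dotbracket(rna_structure(5L)), ".....")
  # pseudoknot-free -> single () layer
  s <- render_dotbracket(parse_dotbracket("((((...)))).."))
  expect_false(grepl("\\[", s))
  # crossing pairs force a second layer
  htype <- rna_structure(12L, rbind(c(1L, 8L), c(4L, 12L)))
  r <- render_dotbracket(htype)
  expect_true(grepl("\\[", r))
  expect_equal(parse_dotbracket(r)$pairs, htype$pairs, ignore_attr = TRUE)
})

test_that("parse/render round-trip is the identity on random structures", {
  set.seed(401)
  for (t in 1:40) {
    st <- rand_structure(pick(8:40), crossing = (t %% 2 == 0))
    rendered <- render_dotbracket(st)
    expect_equal(parse_dotbracket(rendered)$pairs, st$pairs,
                 ignore_attr = TRUE)
    # pairs assigned to the same bracket layer never cross
    ch <- strsplit(rendered, "", fixed = TRUE)[[1]]
    if (nrow(st$pairs)) {
      layer_of <- match(ch[st$pairs[, 1L]], c("(", "[", "{", "<"))
      for (lay in unique(layer_of)) {
        grp <- st$pairs[layer_of == lay, , drop = FALSE]
        expect_true(covfold:::is_pseudoknot_free(grp))
      }
    }
  }
})

test_that("secondary-structure invariants are enforced", {
  expect_error(rna_structure(10L, rbind(c(1L, 5L), c(5L, 10L))),
               "at most one other base")
  expect_error(rna_structure(10L, cbind(2L, 5L)), "hairpin")
  expect_error(rna_structure(4L, cbind(1L, 9L)), "out of range")
  # i > j input is normalized
  st <- rna_structure(10L, cbind(9L, 1L))
  expect_equal(st$pairs[1L, ], c(i = 1L, j = 9L))
})

test_that("prediction files round-trip and preserve order", {
  preds <- tibble::tibble(
    id = c("z_second", "a_first"),
    sequence = c("GGGAAACCC", "ACGUACGUA"),
    structure = c("(((...)))", "........."),
    energy = c(-1.2, 0))
  path <- withr::local_tempfile(fileext = ".txt")
  write_predictions(preds, path)
  back <- read_predictions(path)
  expect_equal(back$id, preds$id)  # input order kept, not sorted
  expect_equal(back$structure, preds$structure)
  expect_equal(back$energy, preds$energy, tolerance = 1e-4)

  empty <- preds[0, ]
  write_predictions(empty, path)
  expect_equal(nrow(read_predictions(path)), 0L)
})

test_that("reference structure files are read with and without headers", {
  path <- withr::local_tempfile(fileext = ".dbn")
  writeLines(c(">r1", "(((...)))", ">r2", "..[[..((..]]..))"), path)
  refs <- read_structures(path)
  expect_named(refs, c("r1", "r2"))
  expect_equal(nrow(refs$r2$pairs), 4L)
  writeLines(c("(((...)))"), path)
  expect_length(read_structures(path), 1L)
})
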