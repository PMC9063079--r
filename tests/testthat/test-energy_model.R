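test_that("builtin parameters load, validate and round-trip through files", {
  p <- read_energy_parameters("default37")
  expect_s3_class(p, "energy_parameters")
  expect_equal(p$temperature, 37)
  expect_true(all(is.finite(p$stack)))

  path <- withr::local_tempfile(fileext = ".par")
  write_energy_parameters(p, path)
  p2 <- read_energy_parameters(path)
  for (f in c("temperature", "hairpin", "bulge", "internal")) {
    expect_equal(p2[[f]], p[[f]], tolerance = 1e-6)
  }
  expect_equal(p2$stack, p$stack, tolerance = 1e-6)
  expect_equal(p2$pk, p$pk, tolerance = 1e-6)
})

test_that("incomplete parameter files fail loudly, naming the entry", {
  p <- default_energy_parameters()
  path <- withr::local_tempfile(fileext = ".par")
  write_energy_parameters(p, path)
  lines <- readLines(path)
  # drop the GU-on-CG stack entry
  writeLines(lines[!grepl("^GU CG ", lines)], path)
  expect_error(read_energy_parameters(path), "missing STACK entry for GU on CG")
  # garbage in a table section names the line
  writeLines(c("STACK", "AU XX -1.0"), path)
  expect_error(read_energy_parameters(path), "line 2")
  expect_error(read_energy_parameters(file.path(tempdir(), "none.par")),
               "no such parameter file")
})

test_that("loop energies follow the documented formulas", {
  p <- default_energy_parameters()
  expect_identical(loop_energy(p, "hairpin", size = 2L), Inf)
  expect_equal(loop_energy(p, "hairpin", size = 4L), p$hairpin[4L])
  # beyond the table: logarithmic extrapolation
  expect_equal(loop_energy(p, "hairpin", size = 40L),
               p$hairpin[30L] + p$extrapolation * log(40 / 30))
  expect_equal(loop_energy(p, "stack", closing = "GC", inner = "CG"),
               p$stack["GC", "CG"])
  expect_identical(loop_energy(p, "stack", closing = "GC", inner = "AA"), Inf)
  # internal loop: table(total unpaired) + capped asymmetry
  expect_equal(loop_energy(p, "internal", closing = "AU", inner = "GC",
                           l1 = 2L, l2 = 5L),
               p$internal[7L] + min(p$ninio[["max"]], p$ninio[["slope"]] * 3))
  expect_equal(loop_energy(p, "multiloop", branches = 3L, unpaired = 4L),
               p$multi[["closing"]] + 3 * p$multi[["branch"]] +
                 4 * p$multi[["unpaired"]])
})

test_that("structure energy is the sum of its loop decomposition", {
  p <- default_energy_parameters()
  expect_equal(structure_energy("GGGAAACCC", rna_structure(9L)), 0)
  # two stacks + one hairpin, checked against individual loop_energy calls
  e <- structure_energy("GGGAAACCC", "(((...)))")
  manual <- loop_energy(p, "stack", closing = "GC", inner = "GC") +
    loop_energy(p, "stack", closing = "GC", inner = "GC") +
    loop_energy(p, "hairpin", size = 3L)
  expect_equal(e, manual, tolerance = 1e-12)
  # non-canonical pair: Inf sentinel with diagnostic
  expect_warning(e2 <- structure_energy("GGGAAAGGG", "(((...)))"),
                 "non-canonical")
  expect_identical(e2, Inf)
})

test_that("H-type decomposition carries 1 initiation and 2 band terms", {
  p <- default_energy_parameters()
  s <- "AAAGGGGGUUACCCCC"
  st <- rna_structure(16L, rbind(c(1L, 10L), c(2L, 9L),
                                 c(4L, 16L), c(5L, 15L), c(6L, 14L),
                                 c(7L, 13L), c(8L, 12L)))
  e0 <- structure_energy(s, st, p)
  # bump the initiation by 1: energy moves by exactly 1 (one component)
  p_init <- p; p_init$pk[["init"]] <- p$pk[["init"]] + 1
  expect_equal(structure_energy(s, st, p_init) - e0, 1)
  # bump the band penalty by 1: energy moves by exactly 2 (two bands)
  p_band <- p; p_band$pk[["band"]] <- p$pk[["band"]] + 1
  expect_equal(structure_energy(s, st, p_band) - e0, 2)
})

test_that("structure energy ignores pair ordering and respects additivity", {
  p <- default_energy_parameters()
  set.seed(31)
  for (t in 1:10) {
    n <- pick(15:25)
    st <- rand_structure(n)
    # paint canonical letters onto the paired positions
    bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    if (nrow(st$pairs)) {
      pt <- CANONICAL[sample.int(6L, nrow(st$pairs), TRUE)]
      bases[st$pairs[, 1L]] <- substr(pt, 1L, 1L)
      bases[st$pairs[, 2L]] <- substr(pt, 2L, 2L)
    }
    s <- paste(bases, collapse = "")
    e1 <- structure_energy(s, st, p)
    shuf <- st
    shuf$pairs <- st$pairs[sample(nrow(st$pairs)), , drop = FALSE]
    shuf$pairs <- covfold:::normalize_pairs(shuf$pairs)
    expect_equal(structure_energy(s, shuf, p), e1, tolerance = 1e-12)
  }
})

test_that("density-2 checking accepts the target class and rejects overlaps", {
  # H-type: two bands, density-2
  expect_true(is_density2(rbind(c(1L, 10L), c(2L, 9L), c(5L, 15L), c(6L, 14L))))
  # pseudoknot-free: vacuously density-2
  expect_true(is_density2(parse_dotbracket("((((...))))")))
  # bisecondary but not density-2: index 15 sits under three band spans
  triple <- rbind(c(1L, 30L), c(5L, 20L), c(10L, 40L), c(35L, 45L))
  expect_false(is_density2(triple))
  # more than two layers needed: not even bisecondary
  expect_false(is_density2(rbind(c(1L, 30L), c(10L, 40L), c(15L, 50L))))
})
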