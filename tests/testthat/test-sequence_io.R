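test_that("the alphabet is a 21-token bijection with pad at 0", {
  expect_length(aminoAcids(), 20L)
  expect_identical(tokenIndex(padSymbol()), 0L)
  idx <- tokenIndex(aminoAcids())
  expect_identical(sort(idx), 1:20)
  expect_identical(tokenFromIndex(tokenIndex(c("A", "W", "-"))),
                   c("A", "W", "-"))
  expect_error(tokenIndex("B"), "outside the amino-acid alphabet")
  expect_error(tokenFromIndex(21L), "outside 0..20")
})

test_that("IC50 transform matches its closed form and inverts", {
  expect_equal(ic50ToScore(50000), 0)
  expect_equal(ic50ToScore(1), 1)
  expect_equal(ic50ToScore(500), 1 - log(500) / log(50000), tolerance = 1e-12)
  expect_equal(ic50ToScore(500), 0.42562, tolerance = 1e-4)
  s <- seq(0.01, 0.99, by = 0.014)
  expect_equal(ic50ToScore(scoreToIc50(s)), s, tolerance = 1e-12)
  expect_true(all(diff(ic50ToScore(c(1, 10, 100, 1000, 10000))) < 0))
  expect_error(ic50ToScore(0), "> 0")
  expect_error(ic50ToScore(-5), "> 0")
})

test_that("padPeptide splits pads evenly, extra pad to the right", {
  p <- padPeptide(strrep("A", 9), 13)
  expect_identical(leftPad(p), 2L)
  expect_identical(length(peptideIndices(p)) - leftPad(p) - trueLength(p), 2L)
  p2 <- padPeptide(strrep("A", 10), 13)
  expect_identical(leftPad(p2), 1L)
  p3 <- padPeptide(strrep("A", 13), 13)
  expect_identical(leftPad(p3), 0L)
  expect_error(padPeptide(strrep("A", 14), 13), "exceeds the frame")
  expect_error(padPeptide("AAAA", 13), "shorter than 9")
})

test_that("padding round-trips and is length-preserving for all lengths", {
  for (n in 9:22) {
    pep <- withSeed(n, paste(sample(aminoAcids(), n, TRUE), collapse = ""))
    p <- padPeptide(pep, 26)
    expect_identical(length(peptideIndices(p)), 26L)
    body <- peptideIndices(p)[(leftPad(p) + 1):(leftPad(p) + trueLength(p))]
    expect_identical(paste(tokenFromIndex(body), collapse = ""), pep)
    expect_true(all(peptideIndices(p)[seq_len(leftPad(p))] == 0L))
  }
})

test_that("pseudo-sequence parser accepts valid tables and rejects bad ones", {
  one <- parsePseudoSequences(paste("A1", strrep("A", 34)))
  expect_identical(unname(one["A1"]), strrep("A", 34))
  expect_length(one, 1L)
  two <- parsePseudoSequences(c(paste("A1", strrep("A", 34)),
                                paste("B1", strrep("C", 34))))
  expect_identical(sort(names(two)), c("A1", "B1"))
  # idempotent duplicate, conflicting duplicate
  expect_length(parsePseudoSequences(rep(paste("A1", strrep("A", 34)), 2)), 1L)
  expect_error(parsePseudoSequences(c(paste("A1", strrep("A", 34)),
                                      paste("A1", strrep("C", 34)))),
               "conflicting")
  expect_error(parsePseudoSequences(paste("A1", strrep("A", 33))),
               "length 33")
  expect_error(parsePseudoSequences(paste("A1", paste0(strrep("A", 33), "Z"))),
               "non-standard")
})

test_that("binding-table parser validates records and applies the IC50 flag", {
  ps <- c(A1 = strrep("A", 34))
  r <- parseBindingData("AAAAAAAAA 0.5 A1", ps)
  expect_identical(nrow(r), 1L)
  expect_equal(r$affinity, 0.5)
  expect_error(parseBindingData("AAAAAAAA 0.5 A1", ps), "9-22")
  expect_error(parseBindingData(paste(strrep("A", 23), "0.5 A1"), ps), "9-22")
  expect_error(parseBindingData("AAAAAAAAA 0.5 Zz", ps), "absent")
  expect_warning(
    r2 <- parseBindingData(c("AAAAAAAAA 0.5 A1", "AAAAAAAAA 0.5 Zz"),
                           ps, lenient = TRUE), "skipping")
  expect_identical(nrow(r2), 1L)
  expect_error(parseBindingData("AAAAAAAAA 1.5 A1", ps), "outside")
  r3 <- parseBindingData("AAAAAAAAA 500 A1", ps, ic50 = TRUE)
  expect_equal(r3$affinity, 1 - log(500) / log(50000), tolerance = 1e-12)
  r4 <- parseBindingData("AAAAAAAAA 0.5 A1 grp7", ps)
  expect_identical(r4$group, "grp7")
})

test_that("parsers accept a fuzzed corpus of valid lines", {
  ps <- tinyPseudo(3)
  lines <- withSeed(7, {
    n <- 40L
    sprintf("%s %.4f %s g%d", samplePeptide(n, c(9, 22)), runif(n),
            sample(names(ps), n, TRUE), sample.int(8, n, TRUE))
  })
  r <- parseBindingData(lines, ps)
  expect_identical(nrow(r), 40L)
  expect_true(all(r$affinity >= 0 & r$affinity <= 1))
  psLines <- sprintf("%s %s", names(ps), ps)
  expect_identical(parsePseudoSequences(psLines), ps)
})

test_that("core benchmark parser validates offsets", {
  ps <- c(A1 = strrep("A", 34))
  b <- parseCoreBenchmark("AAAAAAAAAAAA A1 3", ps)
  expect_identical(b$coreStart, 3L)
  expect_error(parseCoreBenchmark("AAAAAAAAAAAA A1 4", ps), "past the")
  expect_error(parseCoreBenchmark("AAAAAAAAAAAA Zz 0", ps), "unknown allele")
})

test_that("prediction writer round-trips its own output", {
  recs <- data.frame(peptide = c("ACDEFGHIKLM", "WYVRNDCEQGH"),
                     allele = c("A1", "B1"), stringsAsFactors = FALSE)
  lines <- writePredictions(recs, c(0.25, 0.75), c(0L, 2L))
  expect_length(lines, 3L)
  expect_match(lines[1], "^peptide\t")
  parts <- strsplit(lines[-1], "\t")
  expect_identical(vapply(parts, `[[`, "", 5),
                   c(substr(recs$peptide[1], 1, 9),
                     substr(recs$peptide[2], 3, 11)))
  expect_identical(vapply(parts, `[[`, "", 1), recs$peptide)
  expect_identical(writePredictions(recs[0, , drop = FALSE],
                                    numeric(0), integer(0)),
                   lines[1])
  expect_error(writePredictions(recs, 0.5, c(0L, 1L)), "equal length")
})
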