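blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

test_that("smithWaterman matches the brute-force DP oracle", {
  set.seed(101)
  for (r in 1:60) {
    a <- randomPeptide(8)
    b <- randomPeptide(120)
    expect_equal(smithWaterman(a, b)$score,
                 oracleSmithWaterman(a, b, blosum62))
  }
})

test_that("self-alignment score is the BLOSUM62 diagonal sum", {
  p <- "QVQLVESGGGLVK"
  ch <- strsplit(p, "")[[1]]
  expect_equal(smithWaterman(p, p)$score,
               sum(blosum62[cbind(ch, ch)]))
})

test_that("hopeless alignments floor at zero", {
  r <- smithWaterman("AAAA", "CCCCCCCC")
  expect_equal(r$score, 0)
  expect_equal(r$nAligned, 0L)
  expect_true(is.na(r$subjectStart))
})

test_that("aligned subject positions track gaps correctly", {
  # peptide equals subject residues 3..8 exactly
  r <- smithWaterman("DEFGHI", "WWDEFGHIWW")
  expect_equal(r$subjectStart, 3L)
  expect_equal(r$subjectEnd, 8L)
  expect_equal(r$alignedSubjectPos, 3:8)
  # a deletion in the peptide skips the deleted subject residue
  r2 <- smithWaterman("MNDEFGHIKRMW", "MNDEFWWWGHIKRMW")
  expect_true(all(r2$alignedSubjectPos %in% r2$subjectStart:r2$subjectEnd))
  expect_lte(r2$nAligned, nchar("MNDEFGHIKRMW"))
})

test_that("empty sequences are rejected", {
  expect_error(smithWaterman("", "ACDE"), "empty")
  expect_error(smithWaterman("ACDE", ""), "empty")
})

test_that("Karlin-Altschul E-value matches the closed form", {
  expect_equal(karlinAltschulEvalue(35, 12, 3000),
               0.041 * 12 * 3000 * exp(-0.267 * 35))
  # monotone decreasing in score, linear in database size
  e <- karlinAltschulEvalue(c(10, 20, 30), 10, 1000)
  expect_true(all(diff(e) < 0))
  expect_equal(karlinAltschulEvalue(20, 10, 2000),
               2 * karlinAltschulEvalue(20, 10, 1000))
  expect_error(karlinAltschulEvalue(10, 0, 100), "validation")
})

gl <- loadGermlineSet()

test_that("constant-region matching respects isotype-group uniqueness", {
  isC <- segmentType(gl) == "constant"
  seqs <- as.character(germlineSequences(gl))[isC]
  grp <- isotypeGroup(gl)[isC]
  # build a peptide unique to one group and check it resolves there
  for (g in unique(grp)) {
    cand <- digestSequence(seqs[grp == g][1], minLength = 6)
    other <- seqs[grp != g]
    uniq <- cand[!vapply(cand, function(p)
      any(grepl(p, other, fixed = TRUE)), logical(1))]
    if (!length(uniq)) next
    m <- matchConstantRegion(uniq[1], gl)
    expect_true(m$matched)
    expect_true(m$unique_to_isotype)
    expect_equal(m$isotype_group, g)
  }
})

test_that("duplicate accessions of one group still count as unique", {
  # IgG1 has two accessions; a peptide present in both is unique to IgG1
  isG1 <- segmentType(gl) == "constant" & isotypeGroup(gl) == "IgG1"
  seqs <- as.character(germlineSequences(gl))
  g1 <- seqs[isG1]
  shared <- digestSequence(g1[1], minLength = 6)
  shared <- shared[vapply(shared, function(p)
    all(grepl(p, g1, fixed = TRUE)), logical(1))]
  shared <- shared[!vapply(shared, function(p)
    any(grepl(p, seqs[segmentType(gl) == "constant" &
                      isotypeGroup(gl) != "IgG1"], fixed = TRUE)),
    logical(1))]
  expect_gt(length(shared), 0)
  m <- matchConstantRegion(shared[1], gl)
  expect_true(m$unique_to_isotype)
  expect_equal(m$isotype_group, "IgG1")
})

test_that("a peptide shared across isotype groups is non-unique", {
  isC <- segmentType(gl) == "constant"
  seqs <- as.character(germlineSequences(gl))[isC]
  grp <- isotypeGroup(gl)[isC]
  found <- FALSE
  for (p in digestSequence(seqs[1], minLength = 4)) {
    hits <- unique(grp[vapply(seqs, function(s)
      grepl(p, s, fixed = TRUE), logical(1))])
    if (length(hits) > 1) {
      m <- matchConstantRegion(p, gl)
      expect_true(m$matched)
      expect_false(m$unique_to_isotype)
      expect_true(is.na(m$isotype_group))
      found <- TRUE
      break
    }
  }
  # the synthetic IgG subclasses are point variants of one scaffold, so a
  # cross-group peptide must exist
  expect_true(found)
})

test_that("variable-region assignment accepts germline-true peptides", {
  # a peptide cut straight out of a V germline must be accepted
  vseq <- as.character(germlineSequences(gl))[segmentType(gl) == "V"][1]
  pep <- digestSequence(vseq, minLength = 8)[1]
  a <- assignVariableRegion(pep, gl)
  expect_equal(a$category, "variable")
  expect_lte(a$e_value, 1)
  expect_false(is.na(a$germline_gene))
})

test_that("alignments with fewer than 3 CDR residues are labelled FR", {
  # residues at IMGT positions 19-28 of a kappa V gene: 8 FR1 + 2 CDR1
  i <- which(segmentType(gl) == "V" & chainType(gl) == "kappa")[1]
  pos <- imgtPositions(gl)[[i]]
  s <- as.character(germlineSequences(gl))[[i]]
  idx <- which(pos >= 17 & pos <= 28)
  pep <- substr(s, min(idx), max(idx))
  expected_cdr <- sum(pos[idx] >= 27)
  expect_lte(expected_cdr, 2L)   # at most positions 27 and 28
  a <- assignVariableRegion(pep, gl)
  expect_equal(a$category, "variable")
  expect_equal(a$n_cdr_residues, expected_cdr)
  expect_equal(a$region_label, "FR")
})

test_that("alignments with >= 3 CDR residues gain a CDR label", {
  i <- which(segmentType(gl) == "V" & chainType(gl) == "kappa")[1]
  pos <- imgtPositions(gl)[[i]]
  s <- as.character(germlineSequences(gl))[[i]]
  idx <- which(pos >= 18 & pos <= 38)   # FR1 tail + full CDR1
  pep <- substr(s, min(idx), max(idx))
  expect_gte(sum(pos[idx] >= 27), 3L)
  a <- assignVariableRegion(pep, gl)
  expect_equal(a$category, "variable")
  expect_gte(a$n_cdr_residues, 3L)
  expect_equal(a$region_label, "FR+CDR")
})

test_that("random peptides are non_ig", {
  set.seed(7)
  hits <- vapply(1:20, function(i)
    assignVariableRegion(randomPeptide(8), gl)$category, character(1))
  expect_true(mean(hits == "non_ig") > 0.9)
})

test_that("assignment is invariant to germline record order", {
  pep <- "SLSPGERATL"
  a1 <- assignVariableRegion(pep, gl)
  set.seed(3)
  glr <- gl[sample(length(gl))]
  a2 <- assignVariableRegion(pep, glr)
  expect_equal(a1$germline_gene, a2$germline_gene)
  expect_equal(a1$sw_score, a2$sw_score)
  expect_equal(a1$region_label, a2$region_label)
})

test_that("I/L folding unifies isobaric de novo sequences", {
  pep <- "SLSPGERATL"
  folded <- gsub("L", "I", pep)
  strict <- assignVariableRegion(folded, gl, ilEquivalent = FALSE)
  loose <- assignVariableRegion(folded, gl, ilEquivalent = TRUE)
  exact <- assignVariableRegion(pep, gl, ilEquivalent = TRUE)
  expect_equal(loose$sw_score, exact$sw_score)
  expect_lte(strict$sw_score, loose$sw_score)
})

test_that("annotatePeptides assigns exactly one category per peptide", {
  isC <- segmentType(gl) == "constant"
  cpep <- digestSequence(as.character(germlineSequences(gl))[isC][1],
                         minLength = 6)[1]
  vseq <- as.character(germlineSequences(gl))[segmentType(gl) == "V"][2]
  vpep <- digestSequence(vseq, minLength = 8)[1]
  set.seed(11)
  rnd <- randomPeptide(9)
  ann <- annotatePeptides(c(cpep, vpep, rnd, cpep), gl)
  expect_equal(nrow(ann), 4L)
  expect_equal(ann$category, c("constant", "variable", "non_ig",
                               "constant"))
  # constant precedence: never scored against V genes
  expect_true(is.na(ann$sw_score[1]))
  expect_true(ann$ig_related[1] && ann$ig_related[2] && !ann$ig_related[3])
  # duplicated input rows give identical annotation rows
  expect_equal(ann$isotype_group[1], ann$isotype_group[4])
})
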