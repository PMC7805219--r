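test_that("identical ungapped rows give a clean match-dominated model", {
  aln <- SeedAlignment(rep("ACGT", 4))
  hmm <- buildHMM(aln)
  expect_equal(modelLength(hmm), 4L)
  expect_equal(unname(apply(hmm@matchEmissions, 1, which.max)),
               c(1L, 2L, 3L, 4L))  # A, C, G, T
  expect_true(all(apply(hmm@matchTransitions[2:4, ], 1, which.max) == 1))
  # probability conservation (also enforced by the validity method)
  expect_true(validObject(hmm))
  # stated pseudocount closed form: (counts + 0.25) / (n + 1)
  aln3 <- SeedAlignment(c("AC", "AG", "AT"))
  h3 <- buildHMM(aln3, pseudocount = 1)
  expect_equal(unname(h3@matchEmissions[1, ]),
               c(3.25 / 4, 0.25 / 4, 0.25 / 4, 0.25 / 4))
  expect_equal(unname(h3@matchEmissions[2, ]),
               c(0.25 / 4, 1.25 / 4, 1.25 / 4, 1.25 / 4))
})

test_that("symfrac boundary is inclusive: 50% occupancy is a match state", {
  aln <- SeedAlignment(c("AC", "A-", "AC", "A-"))
  hmm <- buildHMM(aln, symfrac = 0.5)
  expect_equal(modelLength(hmm), 2L)
  expect_error(buildHMM(SeedAlignment(c("A-", "-C")), symfrac = 0.9),
               "zero match columns")
})

test_that("consensus map is a bijection onto consensus positions", {
  set.seed(9)
  sim <- oneFamilySim(seed = 44, n = 12, len = 150)
  aln <- sim$truth$seedAlignments$fam
  hmm <- buildHMM(aln)
  cm <- consensusMap(hmm)
  expect_equal(length(cm), modelLength(hmm))
  expect_false(anyDuplicated(cm) > 0)
  # composing with its inverse is the identity on match states
  inv <- match(cm, cm)
  expect_equal(inv, seq_along(cm))
})

test_that("the model's own consensus aligns as an all-match path", {
  aln <- SeedAlignment(rep("ACGTACGT", 5))
  hmm <- buildHMM(aln)
  cons <- "ACGTACGT"
  ma <- viterbiAlign(hmm, cons)
  expect_true(all(ma@path$kind == "M"))
  expect_equal(ma@seqStart, 1L)
  expect_equal(ma@seqEnd, 8L)
})

test_that("Viterbi equals exhaustive path enumeration on random instances", {
  set.seed(42)
  for (t in 1:200) {
    L <- sample(1:4, 1)
    n <- sample(1:5, 1)
    hmm <- randomProfileHMM(L)
    seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    expect_equal(viterbiAlign(hmm, seq)@score, oracleViterbi(hmm, seq),
                 tolerance = 1e-9)
  }
})

test_that("consensus outscores shuffles of itself", {
  set.seed(17)
  sim <- oneFamilySim(seed = 55, n = 15, len = 120)
  aln <- sim$truth$seedAlignments$fam
  hmm <- buildHMM(aln)
  cons <- consensusSequence(callConsensus(aln,
                                          neutralSubstitutionMatrix(0.2)))
  sc <- viterbiAlign(hmm, cons)@score
  shuf <- vapply(1:100, function(i)
    viterbiAlign(hmm, pasteChars(sample(strsplit(cons, "")[[1]])))@score,
    numeric(1))
  expect_gt(sc, mean(shuf))
})

test_that("bit score is invariant under background flanks", {
  set.seed(23)
  aln <- SeedAlignment(rep("ACGTACGTACGTACGT", 6))
  hmm <- buildHMM(aln)
  core <- "ACGTACGTACGTACGT"
  s0 <- viterbiAlign(hmm, core)@score
  for (i in 1:5) {
    flankL <- pasteChars(sample(c("A", "C", "G", "T"), 30, TRUE))
    flankR <- pasteChars(sample(c("A", "C", "G", "T"), 30, TRUE))
    s1 <- viterbiAlign(hmm, paste0(flankL, core, flankR))@score
    expect_gte(s1 + 1e-9, s0)  # flanks are free; can only help
  }
})

test_that("N residues score zero bits and do not crash decoding", {
  aln <- SeedAlignment(rep("ACGTACGT", 5))
  hmm <- buildHMM(aln)
  expect_silent(ma <- viterbiAlign(hmm, "ACNTACGT"))
  expect_true(is.finite(ma@score))
})

test_that("projection maps match, insert and delete states correctly", {
  aln <- SeedAlignment(rep("ACGT", 5))
  hmm <- buildHMM(aln)
  ma <- viterbiAlign(hmm, "ACGT")
  pr <- projectAlignment(hmm, ma)
  expect_equal(pr$consensusPos, 1:4)
  expect_equal(pr$seqPos, 1:4)
  # a deletion pairs a consensus position with no sequence position
  ma2 <- viterbiAlign(hmm, "AGT")
  pr2 <- projectAlignment(hmm, ma2)
  expect_true(any(is.na(pr2$seqPos) & !is.na(pr2$consensusPos)))
  # foreign alignments are rejected
  other <- buildHMM(SeedAlignment(rep("TTTT", 4)), name = "other")
  expect_error(projectAlignment(other, ma), "different model")
})

test_that("projected pairs recover the generative alignment", {
  set.seed(77)
  sim <- oneFamilySim(seed = 61, n = 25, len = 300, div = 0.15)
  aln <- sim$truth$seedAlignments$fam
  hmm <- buildHMM(aln)
  cm <- consensusMap(hmm)
  m <- alignmentMatrix(aln)
  matchCols <- which(colSums(m != "-") / nrow(m) >= 0.5)
  agree <- total <- 0
  for (r in 1:10) {
    seqr <- gsub("-", "", aln@sequences[r])
    ma <- viterbiAlign(hmm, seqr)
    pr <- projectAlignment(hmm, ma)
    pr <- pr[!is.na(pr$consensusPos) & !is.na(pr$seqPos), ]
    # ground truth: sequence position of row r at each match column
    chars <- strsplit(aln@sequences[r], "")[[1]]
    seqpos <- cumsum(chars != "-")
    trueAt <- ifelse(chars[matchCols] != "-", seqpos[matchCols], NA)
    names(trueAt) <- as.character(seq_along(matchCols))
    mstate <- match(pr$consensusPos, consensusMap(hmm))
    ok <- !is.na(mstate)
    agree <- agree + sum(pr$seqPos[ok] == trueAt[mstate[ok]], na.rm = TRUE)
    total <- total + sum(ok)
  }
  expect_gte(agree / total, 0.95)
})

test_that("models build from indel-rich alignments of every family kind", {
  sim <- simulateTE(simConfig(seed = 3))
  for (fn in names(sim$truth$seedAlignments)) {
    hmm <- buildHMM(sim$truth$seedAlignments[[fn]], name = fn)
    expect_true(validObject(hmm))
    expect_gt(modelLength(hmm), 100)
  }
})

test_that("HMM text round trip preserves parameters to full precision", {
  set.seed(5)
  sim <- oneFamilySim(seed = 71, n = 10, len = 80)
  hmm <- buildHMM(sim$truth$seedAlignments$fam)
  f <- withr::local_tempfile(fileext = ".hmm")
  writeProfileHMM(hmm, f)
  back <- readProfileHMM(f)
  expect_equal(back@matchEmissions, hmm@matchEmissions, tolerance = 1e-12)
  expect_equal(back@insertEmissions, hmm@insertEmissions,
               tolerance = 1e-12)
  expect_equal(back@matchTransitions, hmm@matchTransitions,
               tolerance = 1e-12)
  expect_equal(back@consensusMap, hmm@consensusMap)
})
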