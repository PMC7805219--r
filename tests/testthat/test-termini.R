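test_that("terminus extraction anchors and N-pads at the boundaries", {
  s <- pasteChars(rep(c("A", "C", "G", "T"), 25))  # 100 bp
  t <- extractTermini(s, 60)
  expect_equal(t$five, substr(s, 1, 60))
  expect_equal(t$three, substr(s, 41, 100))
  short <- substr(s, 1, 40)
  t2 <- extractTermini(short, 60)
  expect_equal(t2$five, paste0(short, strrep("N", 20)))
  expect_equal(t2$three, paste0(strrep("N", 20), short))
  expect_error(extractTermini(""), "empty")
})

test_that("simulated TIR elements have inverted terminal repeats", {
  set.seed(3)
  sim <- oneFamilySim(seed = 12, n = 5, len = 300, div = 0.05)
  anc <- sim$truth$ancestralSequences[["fam"]]
  t <- extractTermini(anc, 60)
  rc3 <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(t$three))),
    "")[[1]]
  five <- strsplit(t$five, "")[[1]]
  expect_gte(mean(rc3[1:15] == five[1:15]), 0.8)
})

test_that("signature profiles conserve probability and bound IC", {
  set.seed(4)
  lib <- simulateTerminiLibrary(2, 10)
  fams <- lib$families[lib$families$category == lib$categories[1], ]
  term <- lapply(fams$consensus, extractTermini)
  p5 <- buildTerminusPileup(vapply(term, `[[`, "", "five"),
                            lib$categories[1], "five_prime")
  p3 <- buildTerminusPileup(vapply(term, `[[`, "", "three"),
                            lib$categories[1], "three_prime")
  sig <- terminiSignature(p5, p3, makeCombined = TRUE)
  for (end in names(sig@profiles)) {
    expect_equal(rowSums(sig@profiles[[end]]), rep(1, 60),
                 tolerance = 1e-9)
    ic <- sig@informationContent[[end]]
    expect_true(all(ic >= 0 & ic <= 2))
  }
  expect_warning(
    terminiSignature(buildTerminusPileup("ACGT", "c", "five_prime"),
                     buildTerminusPileup("ACGT", "c", "three_prime")),
    "singleton")
})

test_that("IC approaches 2 bits for conserved columns, 0 for uniform", {
  rows <- rep(paste0("TA", strrep("N", 58)), 4)
  p5 <- buildTerminusPileup(rows, "c", "five_prime", maxShift = 0)
  p3 <- buildTerminusPileup(rows, "c", "three_prime", maxShift = 0)
  sig <- terminiSignature(p5, p3, pseudocount = 1e-6)
  expect_gt(sig@informationContent$five_prime[1], 1.99)
  # uniform random rows: mean IC near zero
  set.seed(6)
  rnd <- vapply(1:100, function(i) pasteChars(
    sample(c("A", "C", "G", "T"), 60, TRUE)), character(1))
  sigR <- terminiSignature(
    buildTerminusPileup(rnd, "r", "five_prime", maxShift = 0),
    buildTerminusPileup(rnd, "r", "three_prime", maxShift = 0))
  expect_lt(mean(sigR@informationContent$five_prime), 0.1)
})

test_that("combined profile of a TIR category beats either end alone", {
  set.seed(8)
  # construct termini whose 5' agrees with revcomp(3') everywhere
  five <- randomDNA(60)
  three <- revComp(five)
  mut <- function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(60, 6)
    ch[i] <- vapply(i, function(k)
      sample(setdiff(c("A", "C", "G", "T"), ch[k]), 1), character(1))
    pasteChars(ch)
  }
  f5 <- vapply(1:8, function(i) mut(five), character(1))
  f3 <- vapply(1:8, function(i) mut(three), character(1))
  sig <- terminiSignature(
    buildTerminusPileup(f5, "c", "five_prime", maxShift = 0),
    buildTerminusPileup(f3, "c", "three_prime", maxShift = 0),
    makeCombined = TRUE)
  expect_gt(sum(sig@informationContent$combined),
            max(sum(sig@informationContent$five_prime),
                sum(sig@informationContent$three_prime)) - 1e-9)
})

test_that("held-out termini classification is accurate and orientation-safe", {
  set.seed(5)
  lib <- simulateTerminiLibrary(5, 20, terminusDivergence = 0.10)
  sigs <- list(); test <- list()
  for (cat_ in lib$categories) {
    rows <- lib$families[lib$families$category == cat_, ]
    ntr <- floor(0.8 * nrow(rows))
    tr <- rows[1:ntr, ]
    term <- lapply(tr$consensus, extractTermini)
    sigs[[cat_]] <- terminiSignature(
      buildTerminusPileup(vapply(term, `[[`, "", "five"), cat_,
                          "five_prime", tr$family),
      buildTerminusPileup(vapply(term, `[[`, "", "three"), cat_,
                          "three_prime", tr$family),
      makeCombined = TRUE)
    test[[cat_]] <- rows[(ntr + 1):nrow(rows), ]
  }
  correct <- tot <- swapRejected <- 0
  for (cat_ in lib$categories) for (i in seq_len(nrow(test[[cat_]]))) {
    q <- test[[cat_]]$consensus[i]
    hits <- classifyByTermini(q, sigs)
    tot <- tot + 1
    if (nrow(hits) && hits$category[1] == cat_) correct <- correct + 1
    n <- nchar(q)
    swapped <- paste0(substr(q, n - 59, n), substr(q, 61, n - 60),
                      substr(q, 1, 60))
    if (nrow(classifyByTermini(swapped, sigs)) == 0)
      swapRejected <- swapRejected + 1
  }
  expect_gte(correct / tot, 0.90)
  expect_equal(swapRejected / tot, 1)
  # self-consistency: training consensi classify to their own category
  for (cat_ in lib$categories) {
    h <- classifyByTermini(
      lib$families$consensus[lib$families$category == cat_][1], sigs)
    expect_equal(h$category[1], cat_)
  }
})

test_that("reverse-complementing a query preserves the best score", {
  set.seed(14)
  lib <- simulateTerminiLibrary(3, 10)
  sigs <- list()
  for (cat_ in lib$categories) {
    rows <- lib$families[lib$families$category == cat_, ]
    term <- lapply(rows$consensus, extractTermini)
    sigs[[cat_]] <- terminiSignature(
      buildTerminusPileup(vapply(term, `[[`, "", "five"), cat_,
                          "five_prime"),
      buildTerminusPileup(vapply(term, `[[`, "", "three"), cat_,
                          "three_prime"))
  }
  q <- lib$families$consensus[1]
  h1 <- classifyByTermini(q, sigs)
  h2 <- classifyByTermini(revComp(q), sigs)
  expect_equal(h1$score[1], h2$score[1], tolerance = 1e-9)
  expect_equal(h1$category[1], h2$category[1])
  # strand flip swaps the reported orientation of the top hit
  expect_false(h1$orientation[1] == h2$orientation[1])
})

test_that("TSD detection follows the mismatch rule and resists chance", {
  left <- paste0(strrep("G", 20), "ACGTT")
  right <- paste0("ACGTT", strrep("G", 20))
  t <- detectTSD(left, right)
  expect_equal(t$length, 5L)
  expect_equal(t$motif, "ACGTT")
  # one mismatch tolerated only for k >= 8
  l8 <- paste0(strrep("G", 15), "ACGTACGA")
  r8 <- paste0("ACGTACGT", strrep("G", 15))
  expect_equal(detectTSD(l8, r8)$length, 8L)
  expect_error(detectTSD("ACGT", "ACGT"), "20 bp")
  set.seed(10)
  fp <- sum(vapply(1:1000, function(i) {
    t <- detectTSD(randomDNA(20), randomDNA(20))
    !is.null(t) && t$length >= 4
  }, logical(1)))
  expect_lte(fp / 1000, 0.05)
})

test_that("simulated 8 bp TSDs are recovered from insertion flanks", {
  set.seed(2)
  sim <- oneFamilySim(seed = 88, n = 40, len = 400, div = 0.15, tsd = 8L)
  ins <- sim$truth$insertions
  g <- sim$genome
  rec <- vapply(seq_len(nrow(ins)), function(k) {
    t <- detectTSD(substr(g, ins$start[k] - 20, ins$start[k] - 1),
                   substr(g, ins$end[k] + 1, ins$end[k] + 20))
    !is.null(t) && t$length == 8L
  }, logical(1))
  expect_gte(mean(rec), 0.95)
})

test_that("solo-LTR heuristic separates solo LTRs from TIR elements", {
  set.seed(19)
  simL <- oneFamilySim(seed = 31, n = 8, len = 350, div = 0.05,
                       kind = "solo_ltr", tsd = 5L)
  simT <- oneFamilySim(seed = 32, n = 8, len = 350, div = 0.05,
                       kind = "class2_tir", tsd = 8L)
  expect_true(isSoloLTRCandidate(simL$truth$ancestralSequences[["fam"]]))
  expect_false(isSoloLTRCandidate(simT$truth$ancestralSequences[["fam"]]))
  # with flanks: the 4-6 bp TSD requirement must also hold
  ins <- simL$truth$insertions[1, ]
  g <- simL$genome
  cons <- simL$truth$ancestralSequences[["fam"]]
  expect_true(isSoloLTRCandidate(
    cons, substr(g, ins$start - 20, ins$start - 1),
    substr(g, ins$end + 1, ins$end + 20)))
})

test_that("sequence logos render stacks proportional to information", {
  rows <- rep(paste0("TTTT", strrep("A", 56)), 6)
  sig <- terminiSignature(
    buildTerminusPileup(rows, "c", "five_prime", maxShift = 0),
    buildTerminusPileup(rows, "c", "three_prime", maxShift = 0),
    pseudocount = 0.01)
  f <- withr::local_tempfile(fileext = ".svg")
  renderLogo(sig, "five_prime", f)
  svg <- readLines(f)
  expect_true(grepl("^<svg", svg[1]))
  expect_equal(sum(grepl("<text", svg)), 60)  # one tall letter per column
  expect_error(renderLogo(sig, "combined", f), "no 'combined'")
})
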