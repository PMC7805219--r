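test_that("identical seeds reproduce byte-identical simulations", {
  s1 <- oneFamilySim(seed = 123, n = 8, len = 200)
  s2 <- oneFamilySim(seed = 123, n = 8, len = 200)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth$seedAlignments$fam@sequences,
                   s2$truth$seedAlignments$fam@sequences)
  expect_identical(s1$truth$insertions, s2$truth$insertions)
  s3 <- oneFamilySim(seed = 124, n = 8, len = 200)
  expect_false(identical(s1$genome, s3$genome))
})

test_that("zero divergence yields copies identical to the ancestor", {
  sim <- oneFamilySim(seed = 9, n = 6, len = 150, div = 0)
  aln <- sim$truth$seedAlignments$fam
  anc <- sim$truth$ancestralSequences[["fam"]]
  expect_true(all(gsub("-", "", aln@sequences) == anc))
  cq <- coverageQuality(aln, anc)
  expect_true(all(cq$perWindowQuality == 1, na.rm = TRUE))
})

test_that("realized divergence tracks the configured rate", {
  sim <- oneFamilySim(seed = 10, n = 50, len = 1000, div = 0.15,
                      cpgMult = 1)
  aln <- sim$truth$seedAlignments$fam
  anc <- sim$truth$ancestralSequences[["fam"]]
  rf <- strsplit(aln@referenceAnnotation, "")[[1]]
  ancCols <- which(rf == "x")
  m <- alignmentMatrix(aln)[, ancCols]
  a <- strsplit(anc, "")[[1]]
  ng <- m != "-"
  div <- 1 - sum(m == matrix(a, nrow(m), length(a), byrow = TRUE)) / sum(ng)
  expect_lt(abs(div - 0.15) / 0.15, 0.10)  # within 10% relative
})

test_that("genome extraction reproduces the inserted copies exactly", {
  sim <- oneFamilySim(seed = 15, n = 10, len = 250)
  ins <- sim$truth$insertions
  aln <- sim$truth$seedAlignments$fam
  for (k in seq_len(nrow(ins))) {
    got <- substr(sim$genome, ins$start[k], ins$end[k])
    if (ins$strand[k] == "-") got <- revComp(got)
    want <- gsub("-", "", aln@sequences[ins$copy[k]])
    expect_identical(got, want)
  }
  # TSD text flanks both sides of every insertion
  for (k in seq_len(nrow(ins))) {
    tsd <- ins$tsd[k]
    expect_identical(substr(sim$genome, ins$start[k] - nchar(tsd),
                            ins$start[k] - 1), tsd)
    expect_identical(substr(sim$genome, ins$end[k] + 1,
                            ins$end[k] + nchar(tsd)), tsd)
  }
})

test_that("class II copies are star-shaped: derived mutations not shared", {
  sim <- oneFamilySim(seed = 16, n = 30, len = 800, div = 0.05,
                      cpgMult = 1)
  aln <- sim$truth$seedAlignments$fam
  anc <- sim$truth$ancestralSequences[["fam"]]
  rf <- strsplit(aln@referenceAnnotation, "")[[1]]
  m <- alignmentMatrix(aln)[, rf == "x"]
  a <- strsplit(anc, "")[[1]]
  # with 30 copies at 5% divergence, derived bases co-occur only by
  # independent chance: no derived base forms a clonal block of more
  # than half the copies
  for (j in seq_along(a)) {
    der <- m[, j] != "-" & m[, j] != a[j]
    if (any(der)) {
      tab <- table(m[der, j])
      expect_lt(max(tab), nrow(m) / 2)
    }
  }
})

test_that("class I subfamilies carry co-segregating diagnostic columns", {
  sim <- oneFamilySim(seed = 17, n = 20, len = 600, div = 0.10,
                      kind = "class1_line", tsd = NA,
                      subfamilyCount = 2L)
  aln <- sim$truth$seedAlignments$fam
  sub <- sim$truth$subfamilyOf$fam
  diag <- sim$truth$diagnosticSites$fam
  expect_gte(length(diag), 3L)
  rf <- strsplit(aln@referenceAnnotation, "")[[1]]
  m <- alignmentMatrix(aln)[, rf == "x"]
  perfect <- 0
  for (j in diag) {
    col <- m[, j]
    ok <- col != "-"
    if (length(unique(sub[ok])) < 2) next
    groups <- split(col[ok], sub[ok])
    vals <- vapply(groups, function(g) length(unique(g)) == 1, logical(1))
    if (all(vals) &&
        length(unique(vapply(groups, `[`, "", 1))) == length(groups))
      perfect <- perfect + 1
  }
  expect_gte(perfect, 3L)
})

test_that("LINE copies are 5'-truncated and end in poly-A", {
  sim <- oneFamilySim(seed = 18, n = 25, len = 800, div = 0.05,
                      kind = "class1_line", tsd = NA,
                      truncation = "five_prime_geometric",
                      truncationP = 0.01)
  anc <- sim$truth$ancestralSequences[["fam"]]
  expect_true(grepl("AAAAAA", substr(anc, nchar(anc) - 15, nchar(anc))))
  rng <- instanceRanges(sim$truth$seedAlignments$fam)
  expect_gt(mean(rng$startCol > 1), 0.3)  # many copies start late
})

test_that("solo LTR ancestors carry the expected structural signals", {
  sim <- oneFamilySim(seed = 19, n = 5, len = 300, div = 0.05,
                      kind = "solo_ltr", tsd = NA)
  anc <- sim$truth$ancestralSequences[["fam"]]
  expect_true(startsWith(anc, "TG"))
  expect_true(endsWith(anc, "CA"))
  expect_true(grepl("AATAAA", anc))
  expect_true(all(sim$truth$insertions$tsdLength %in% 4:6))
})

test_that("CpG sites decay to TG/CA at the configured elevated rate", {
  sim <- oneFamilySim(seed = 20, n = 60, len = 2000, div = 0.10,
                      cpgMult = 10)
  anc <- sim$truth$ancestralSequences[["fam"]]
  aln <- sim$truth$seedAlignments$fam
  rf <- strsplit(aln@referenceAnnotation, "")[[1]]
  m <- alignmentMatrix(aln)[, rf == "x"]
  a <- strsplit(anc, "")[[1]]
  cpg <- cpgPositions(anc)
  nonCpGc <- setdiff(which(a == "C"), c(cpg, cpg + 1))
  rate <- function(cols, from, to) {
    sub <- m[, cols, drop = FALSE]
    mean(sub[sub != "-"] == to)
  }
  rCpG <- rate(cpg, "C", "T")
  rBg <- rate(nonCpGc, "C", "T")
  expect_gt(rCpG / rBg, 3)  # strongly elevated over background C->T
})

test_that("fixture files are consistent and reload through the readers", {
  sim <- oneFamilySim(seed = 22, n = 6, len = 150)
  d <- withr::local_tempdir()
  paths <- emitFixtures(sim, d)
  g <- Biostrings::readDNAStringSet(paths$genome)
  expect_equal(nchar(as.character(g[[1]])), nchar(sim$genome))
  bed <- utils::read.delim(paths$bed, header = FALSE)
  ins <- sim$truth$insertions
  # BED is 0-based half-open: re-extraction reproduces the instances
  for (k in seq_len(nrow(bed))) {
    s <- substr(as.character(g[[1]]), bed$V2[k] + 1, bed$V3[k])
    if (bed$V6[k] == "-") s <- revComp(s)
    want <- gsub("-", "",
                 sim$truth$seedAlignments$fam@sequences[ins$copy[k]])
    expect_identical(s, want)
  }
  aln <- readStockholm(paths$seed_fam)
  expect_equal(aln@sequences,
               toupper(sim$truth$seedAlignments$fam@sequences))
})
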