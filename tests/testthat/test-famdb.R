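toyStore <- function(nTaxa = 30, path = tempfile(fileext = ".h5")) {
  famdbCreate(path, makeToyTaxonomy(nTaxa))
}

test_that("store creation validates the taxonomy", {
  set.seed(1)
  st <- toyStore(3)
  expect_s4_class(st, "FamDB")
  expect_true(file.exists(st@path))
  fid <- rhdf5::H5Fopen(st@path)
  attrs <- rhdf5::h5readAttributes(fid, "/")
  rhdf5::H5Fclose(fid)
  expect_true(grepl("famdb", attrs$famdb_layout))
  expect_error(
    famdbCreate(tempfile(), data.frame(tax_id = 1:3,
                                       parent_id = c(NA, 3, 2),
                                       name = c("r", "a", "b"))),
    "cycle")
  expect_error(
    famdbCreate(tempfile(), data.frame(tax_id = 1:2,
                                       parent_id = c(NA, NA),
                                       name = c("r", "r2"))),
    "one root")
})

test_that("families round-trip through HDF5 with all fields", {
  set.seed(2)
  st <- toyStore(20)
  aln <- SeedAlignment(rep("ACGTACGTACGT", 5))
  hmm <- buildHMM(aln, name = "rt")
  fam <- TEFamily(consensus = "ACGTACGTACGT", name = "rt",
                  classification = "Interspersed_Repeat;Unknown",
                  cladeTaxa = c(3L, 7L), curated = FALSE,
                  metadata = list(description = "round trip",
                                  citations = "none"))
  fam@hmm <- hmm
  acc <- famdbAddFamily(st, fam)
  famdbFlush(st)
  st2 <- famdbOpen(st@path)
  g <- famdbGetFamily(st2, acc)
  expect_identical(g@consensus, fam@consensus)
  expect_identical(g@name, fam@name)
  expect_identical(g@classification, fam@classification)
  expect_identical(sort(g@cladeTaxa), sort(fam@cladeTaxa))
  expect_identical(g@metadata$description, "round trip")
  expect_equal(g@hmm@matchEmissions, hmm@matchEmissions,
               tolerance = 1e-12)
  expect_equal(g@hmm@matchTransitions, hmm@matchTransitions,
               tolerance = 1e-12)
})

test_that("accession auto-assignment is strictly increasing and guarded", {
  set.seed(3)
  st <- toyStore(5)
  a1 <- famdbAddFamily(st, TEFamily("ACGT", name = "a"))
  a2 <- famdbAddFamily(st, TEFamily("ACGT", name = "b"))
  expect_equal(a1, "DR0000001.1")
  expect_equal(a2, "DR0000002.1")
  expect_error(
    famdbAddFamily(st, TEFamily("ACGT", accession = a1)), "duplicate")
  expect_error(
    famdbAddFamily(st, TEFamily("ACGT", accession = "XX1.1")),
    "accession")
  expect_error(
    famdbAddFamily(st, TEFamily("ACGT", cladeTaxa = 99L)), "absent")
  # accession grammar: DF prefix requires the curated flag
  expect_error(TEFamily("ACGT", accession = "DF0000001.1",
                        curated = FALSE), "prefix")
})

test_that("taxon queries respect ancestor and descendant flags", {
  tx <- data.frame(tax_id = 1:5, parent_id = c(NA, 1, 2, 2, 1),
                   name = c("root", "mid", "leafA", "leafB", "other"))
  st <- famdbCreate(tempfile(fileext = ".h5"), tx)
  acc <- famdbAddFamily(st, TEFamily("ACGT", name = "onMid",
                                     cladeTaxa = 2L))
  getAccs <- function(...) names(familiesForTaxon(st, ...))
  expect_equal(getAccs(2L), acc)
  expect_equal(getAccs(3L), character())
  expect_equal(getAccs(3L, includeAncestors = TRUE), acc)
  expect_equal(getAccs(5L, includeAncestors = TRUE), character())
  expect_equal(getAccs(1L, includeDescendants = TRUE), acc)
  expect_error(familiesForTaxon(st, 42L), "unknown tax_id")
})

test_that("indexed queries equal a brute-force scan after random adds", {
  set.seed(4)
  st <- toyStore(40)
  for (i in 1:300)
    famdbAddFamily(st, TEFamily(randomDNA(30), name = paste0("f", i),
                                cladeTaxa = sample(1:40, sample(1:3, 1))))
  e <- st@env
  bruteForce <- function(tid, anc, des) {
    nodes <- tid
    if (anc) nodes <- c(nodes, get(as.character(tid), e$ancestors))
    if (des) for (t in e$taxonomy$tax_id)
      if (tid %in% get(as.character(t), e$ancestors))
        nodes <- c(nodes, t)
    accs <- character()
    for (a in ls(e$families)) {
      f <- get(a, e$families)
      if (length(intersect(f@cladeTaxa, nodes))) accs <- c(accs, a)
    }
    sort(unique(accs))
  }
  for (q in 1:100) {
    tid <- sample(1:40, 1)
    anc <- runif(1) < 0.5
    des <- runif(1) < 0.5
    expect_identical(names(familiesForTaxon(st, tid, anc, des)),
                     bruteForce(tid, anc, des))
  }
})

test_that("exports round-trip and honor the selection", {
  set.seed(5)
  st <- toyStore(10)
  cons <- randomDNA(130)
  hmm <- buildHMM(SeedAlignment(rep("ACGTACGT", 4)), name = "withHmm")
  f1 <- TEFamily(cons, name = "withHmm", cladeTaxa = 2L)
  f1@hmm <- hmm
  a1 <- famdbAddFamily(st, f1)
  a2 <- famdbAddFamily(st, TEFamily("ACGTTTGGCC", name = "noHmm",
                                    cladeTaxa = 2L))
  fa <- tempfile(fileext = ".fa")
  famdbExport(st, c(a1, a2), "fasta", fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(back), 2L)
  expect_equal(as.character(back[[1]]), cons)
  # EMBL sequence round trip
  em <- tempfile(fileext = ".embl")
  famdbExport(st, a1, "embl", em)
  lines <- readLines(em)
  expect_true(any(grepl("^ID   DR", lines)))
  sq <- grep("^SQ", lines)
  seqLines <- lines[(sq + 1):(grep("^//", lines)[1] - 1)]
  seqBack <- toupper(gsub("[^acgtn]", "", paste(seqLines, collapse = "")))
  expect_equal(seqBack, cons)
  # HMM export skips families without a model, with a warning
  hm <- tempfile(fileext = ".hmm")
  expect_warning(famdbExport(st, c(a1, a2), "hmm", hm), "no HMM")
  expect_equal(readProfileHMM(hm)@modelLength, hmm@modelLength)
  # clade export matches the taxon query exactly
  sel <- familiesForTaxon(st, 2L)
  fa2 <- tempfile(fileext = ".fa")
  famdbExport(st, sel, "fasta", fa2)
  expect_equal(length(Biostrings::readDNAStringSet(fa2)), length(sel))
})

test_that("name-token lookups find taxa case-insensitively", {
  set.seed(6)
  tx <- data.frame(tax_id = 1:3, parent_id = c(NA, 1, 1),
                   name = c("root", "Homo sapiens", "Mus musculus"))
  st <- famdbCreate(tempfile(fileext = ".h5"), tx)
  expect_equal(taxaByName(st, "homo"), 2L)
  expect_equal(taxaByName(st, "SAPIENS"), 2L)
  expect_equal(taxaByName(st, "nothing"), integer())
})
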