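# Shared small simulation fixtures (built fresh per use; seeded by the
# caller) and local string utilities.

pasteChars <- function(ch) paste(ch, collapse = "")

randomDNA <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revComp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

oneFamilySim <- function(seed, n = 20, len = 400, div = 0.15,
                         cpgMult = 10, kind = "class2_tir", tsd = 8L,
                         genome = NULL, ...) {
  if (is.null(genome)) genome <- as.integer(2.2 * n * len + 10000)
  simulateTE(simConfig(
    seed = seed, genomeLength = genome,
    families = list(familySpec("fam", kind, ancestralLength = len,
                               copyNumber = n, meanDivergence = div,
                               cpgMultiplier = cpgMult, tsdLength = tsd,
                               ...))))
}

randomColumnProfile <- function() {
  cnt <- stats::rpois(4, lambda = sample(1:8, 1))
  names(cnt) <- c("A", "C", "G", "T")
  if (sum(cnt) == 0) cnt["A"] <- 1
  cnt
}
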