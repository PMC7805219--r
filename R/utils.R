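# Internal string helpers shared across modules.

# reverse complement of a plain character string (delegates to Biostrings)
revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

splitChars <- function(s) strsplit(s, "", fixed = FALSE)[[1L]]

pasteChars <- function(ch) paste(ch, collapse = "")

# i.i.d. uniform random DNA string (uses the current RNG stream)
randomDNA <- function(n) {
  pasteChars(sample(DNA_BASES, n, replace = TRUE))
}

# base -> integer 1..4 (A,C,G,T); N and '-' map to NA
baseIndex <- function(ch) {
  match(ch, DNA_BASES)
}

stopifnot2 <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
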