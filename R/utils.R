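# Internal sequence helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# random DNA of length n from the current RNG stream
random_dna <- function(n, prob = c(0.295, 0.205, 0.205, 0.295)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# coerce a reference argument (path, DNAStringSet, or named character
# vector) to a named character vector of chromosome sequences
as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- sub("\\s.*$", "", names(reference))
    return(out)
  }
  if (is.character(reference)) {
    if (is.null(names(reference))) stop("reference sequences must be named")
    return(reference)
  }
  stop("unsupported reference representation")
}

# substring that errors instead of silently clipping
substr_strict <- function(x, start, end) {
  if (start < 1L || end > nchar(x)) stop("substring out of bounds")
  substr(x, start, end)
}

# write a named character vector of sequences as FASTA
write_fasta <- function(seqs, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, filepath = path, width = width)
  invisible(path)
}
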