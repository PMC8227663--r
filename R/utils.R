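# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement of a plain character string (A,C,G,T,N).
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

# Validate a nucleotide string over the 5-letter alphabet (A,C,G,T,N).
check_dna_alphabet <- function(seq, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTNacgtn]*$" else "^[ACGTacgt]*$"
  bad <- !grepl(pat, seq)
  if (any(bad))
    stop(sprintf("%s contains characters outside the %s alphabet",
                 what, if (allow_n) "A/C/G/T/N" else "A/C/G/T"),
         call. = FALSE)
  invisible(TRUE)
}

# Bacterial-table translation of a nucleotide string; trailing stop removed,
# ambiguous codons rendered as X.
translate_cds <- function(nt) {
  if (nchar(nt) < 3L) return("")
  nt <- substr(nt, 1L, 3L * (nchar(nt) %/% 3L))
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X")))
  sub("\\*$", "", aa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
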