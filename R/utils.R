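# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
CODE4 <- NULL  # filled at load time (Biostrings genetic code 4)

.onLoad <- function(libname, pkgname) {
  CODE4 <<- Biostrings::getGeneticCode("4")
}

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper; `N` is its own complement.
#'
#' @param seq character scalar over A,C,G,T,N
#' @return character scalar
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# split a DNA string into single characters
.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# split a CDS string into codon triplets (length must be divisible by 3)
.codons <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), pmin(seq(3L, n + 2L, 3L), n))
}

#' Translate DNA under the mold mitochondrial genetic code (table 4)
#'
#' TGA encodes tryptophan; TAA and TAG are the only stops.
#'
#' @param nt DNA string, length divisible by 3
#' @param genetic_code named character vector mapping codons to amino
#'   acids; defaults to NCBI translation table 4
#' @return amino-acid string (stops as `*`)
#' @export
translate_cds <- function(nt, genetic_code = CODE4) {
  if (nchar(nt) == 0L) return("")
  stopifnot(nchar(nt) %% 3L == 0L)
  cod <- .codons(nt)
  aa <- genetic_code[cod]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

# run code with a local, restored RNG state seeded from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a stream of child seeds from one parent seed (all < 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# validate a DNA sequence: uppercase A,C,G,T,N only
check_dna <- function(seq, what = "sequence") {
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0L)
    stop(sprintf("%s contains characters other than A,C,G,T,N: '%s'",
                 what, substr(bad, 1L, 10L)), call. = FALSE)
  invisible(seq)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
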