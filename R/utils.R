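# Shared constants and small helpers used across modules.

# The 20 standard amino acids in Biostrings/BLOSUM ordering.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# BLOSUM62 marginal amino-acid background frequencies (Henikoff & Henikoff
# target marginals, as used by BLAST); renormalized to sum to 1.
BLOSUM62_BACKGROUND <- local({
  p <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
         Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
         L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
         S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
  p / sum(p)
})

#' BLOSUM62 substitution matrix restricted to the 20 standard residues
#'
#' Convenience accessor for the BLOSUM62 matrix shipped with Biostrings,
#' subset to the 20 standard amino acids in a fixed order.
#'
#' @return A 20 x 20 integer matrix with dimnames over the amino-acid
#'   one-letter codes.
#' @export
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA20, AA20]
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Structured progress logging to stderr, gated by option(exonweaver.verbose).
ew_log <- function(stage, ...) {
  if (isTRUE(getOption("exonweaver.verbose", FALSE))) {
    message(sprintf("[exonweaver:%s] %s", stage, paste0(...)))
  }
  invisible(NULL)
}

# Reverse complement of a plain character DNA string (keeps N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a plain character DNA string; ambiguous codons become X,
# stops '*'. Trailing partial codon is dropped.
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1L, n)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
}

# Sample a random codon for a residue (uniform over its codons).
codon_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  cods <- names(gc)[gc == aa]
  cods[sample.int(length(cods), 1L)]
}

# Round half up to given digits (3.5 -> 4), used for printed percentages.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
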