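#' Derive a child seed from a global seed and a label
#'
#' All stochastic operations in the package draw their seed from one global
#' seed plus a short text label, so that modules can be run (and tested) in
#' isolation while a pipeline run stays reproducible end to end. The
#' derivation is a 32-bit FNV-1a hash of the label folded into the seed,
#' reduced modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the consumer (e.g. "tcr", "npx").
#' @return an integer seed in [0, 2^31 - 2].
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- fnv1a32(label)
  as.integer((as.double(seed) * 69069 + h) %% 2147483647)
}

#' 32-bit FNV-1a hash of a character vector
#'
#' Used for stable, content-derived clone identifiers and child-seed
#' derivation. Returns the hash as a double (R has no unsigned 32-bit type).
#'
#' @param x character vector.
#' @return numeric vector of hashes in [0, 2^32).
#' @export
fnv1a32 <- function(x) {
  prime <- 16777619
  vapply(x, function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
      # XOR with a byte touches only the low 8 bits
      lo <- h %% 256
      h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
      # 32-bit modular multiply, split to stay within double precision
      h1 <- h %/% 65536; h0 <- h %% 65536
      h <- (h0 * prime + ((h1 * prime) %% 65536) * 65536) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Run code with a temporary RNG state seeded from `seed`; restores the caller's
# .Random.seed afterwards so library code never disturbs user RNG streams.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Standard genetic code over the 61 sense codons plus stop codons ("*").
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L",
  CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M", GTT = "V", GTC = "V",
  GTA = "V", GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S", CCT = "P",
  CCC = "P", CCA = "P", CCG = "P", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
  TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E", TGT = "C",
  TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R", GGT = "G", GGC = "G", GGA = "G",
  GGG = "G")

#' Translate nucleotide sequences to amino acids (standard code)
#'
#' @param nt character vector of nucleotide sequences; lengths must be
#'   multiples of 3.
#' @return character vector of amino-acid sequences ("*" marks a stop codon).
#' @export
translate_nt <- function(nt) {
  vapply(nt, function(s) {
    n <- nchar(s)
    if (n %% 3 != 0) stop("sequence length not a multiple of 3: ", s)
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    aa <- GENETIC_CODE_TABLE[codons]
    if (anyNA(aa)) stop("malformed codon in sequence: ", s)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Sample SD (n-1 denominator) mean +/- k*SD gate used by several QC rules.
exceeds_mean_plus_ksd <- function(x, k = 2) {
  m <- mean(x); s <- stats::sd(x)
  if (is.na(s)) rep(FALSE, length(x)) else x > m + k * s
}
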