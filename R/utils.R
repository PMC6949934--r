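# Shared alphabet, background composition and mutation helpers.

# 20-letter amino-acid alphabet, fixed ordering used by all encoders.
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# Robinson & Robinson amino-acid background frequencies (renormalised).
AA_BACKGROUND <- local({
  f <- c(A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
         G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
         M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
         S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)
  f / sum(f)
})

DNA4 <- c("A", "C", "G", "T")

.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix restricted to the 20 standard residues
#' @return 20 x 20 integer matrix in \code{AA20} order.
#' @keywords internal
blosum62 <- function() {
  if (is.null(.pkg_cache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$B62 <- e$BLOSUM62[AA20, AA20]
  }
  .pkg_cache$B62
}

# BLOSUM62-conditional residue exchange probabilities: P(b | a), b != a,
# proportional to 2^(S(a,b)/2). Keeps mutated sequences alignable.
.exchange_matrix <- function() {
  if (is.null(.pkg_cache$EXCH)) {
    B <- blosum62()
    W <- 2^(B / 2)
    diag(W) <- 0
    .pkg_cache$EXCH <- W / rowSums(W)
  }
  .pkg_cache$EXCH
}

#' Encode a protein string as 1-based indices into the AA20 alphabet
#' @param protein amino-acid string
#' @return integer vector; non-standard letters become NA
#' @keywords internal
encodeProtein <- function(protein) {
  match(strsplit(toupper(protein), "", fixed = TRUE)[[1]], AA20)
}

decodeProtein <- function(idx) paste(AA20[idx], collapse = "")

#' Random protein drawn from the background composition
#' @param n length in residues
#' @return amino-acid string
#' @keywords internal
randomProtein <- function(n) {
  paste(sample(AA20, n, replace = TRUE, prob = AA_BACKGROUND), collapse = "")
}

#' Mutate a protein at a given per-site substitution rate
#'
#' Substitutions are drawn from BLOSUM62-conditional exchange probabilities so
#' diverged copies remain alignable. Positions in `fixed` are never touched.
#'
#' @param protein amino-acid string
#' @param rate expected substitutions per site
#' @param fixed 1-based positions held invariant
#' @return mutated amino-acid string
#' @export
mutateProtein <- function(protein, rate, fixed = integer(0)) {
  if (rate <= 0) return(protein)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA20)
  hit <- which(stats::runif(length(chars)) < rate & !is.na(idx))
  hit <- setdiff(hit, fixed)
  if (length(hit)) {
    EX <- .exchange_matrix()
    for (p in hit) chars[p] <- sample(AA20, 1L, prob = EX[idx[p], ])
  }
  paste(chars, collapse = "")
}

#' Reverse complement of a DNA string
#' @param dna DNA string over A,C,G,T,N
#' @return reverse-complemented string
#' @export
revComp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# Restore the caller's RNG stream after seeded internal randomness.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
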