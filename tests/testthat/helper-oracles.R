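# Independent oracles used across test files. These deliberately re-derive
# quantities by enumeration or direct formula, never by calling the package
# path they check.

# Brute-force enumeration of all local Viterbi paths through a profile:
# entry into any match state (log2(1/L)), free exit after any match emission.
# Mirrors the state space: M emits, I emits (background, log-odds 0), D silent.
bruteForceViterbi <- function(profile, protein) {
  lod <- log2(sweep(profile@matchEmissions, 2L, profile@background, "/"))
  L <- nrow(lod)
  ltr <- if (L > 1L) log2(profile@transitions) else matrix(0, 0, 7)
  x <- baconscope:::encodeProtein(protein)
  n <- length(x)
  entry <- log2(1 / L)
  best <- -Inf
  # state: 1=M, 2=I, 3=D; score so far; recursion over successor moves
  recurse <- function(i, k, state, sc) {
    if (state == 1L) best <<- max(best, sc)   # may exit after any match
    if (state == 1L || state == 2L) {
      if (k < L && i < n) {
        tr <- ltr[k, ]
        if (state == 1L) {
          recurse(i + 1L, k + 1L, 1L, sc + tr[["MM"]] + lod[k + 1L, x[i + 1L]])
          recurse(i + 1L, k, 2L, sc + tr[["MI"]])
          recurse(i, k + 1L, 3L, sc + tr[["MD"]])
        } else {
          recurse(i + 1L, k + 1L, 1L, sc + tr[["IM"]] + lod[k + 1L, x[i + 1L]])
          recurse(i + 1L, k, 2L, sc + tr[["II"]])
        }
      } else if (k < L && state == 1L) {
        recurse(i, k + 1L, 3L, sc + ltr[k, "MD"])
      }
    } else {  # delete
      if (k < L) {
        tr <- ltr[k, ]
        if (i < n)
          recurse(i + 1L, k + 1L, 1L, sc + tr[["DM"]] + lod[k + 1L, x[i + 1L]])
        recurse(i, k + 1L, 3L, sc + tr[["DD"]])
      }
    }
  }
  for (i in seq_len(n))
    for (k in seq_len(L))
      recurse(i, k, 1L, entry + lod[k, x[i]])
  best
}

# random profile over a reduced-support alphabet: emissions concentrated on
# the first nres residues, transitions Dirichlet-ish
randomSmallProfile <- function(L, nres = 4L) {
  mE <- t(vapply(seq_len(L), function(k) {
    w <- rep(1e-4, 20)
    w[seq_len(nres)] <- stats::runif(nres) + 0.1
    w / sum(w)
  }, numeric(20)))
  tr <- if (L > 1L) t(vapply(seq_len(L - 1L), function(k) {
    m <- stats::runif(3) + 0.2; i <- stats::runif(2) + 0.2; d <- stats::runif(2) + 0.2
    c(m / sum(m), i / sum(i), d / sum(d))
  }, numeric(7))) else matrix(0, 0, 7)
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  new("ProfileHMM", matchEmissions = mE,
      insertEmissions = matrix(rep(baconscope:::AA_BACKGROUND, each = L), L, 20),
      transitions = tr, background = baconscope:::AA_BACKGROUND,
      occupancy = rep(1, L),
      consensus = baconscope:::AA20[apply(mE, 1, which.max)])
}

# exhaustive hypergeometric upper tail by enumerating draw overlaps
enumHyper <- function(N, ni, nj, k) {
  sum(vapply(k:min(ni, nj), function(x)
    choose(ni, x) * choose(N - ni, nj - x), numeric(1))) / choose(N, nj)
}

# Ward.D2 Lance-Williams dissimilarity update, applied by hand
wardD2Manual <- function(D) {
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  merges <- list()
  D <- as.matrix(D)
  repeat {
    if (length(active) < 2) break
    pairs <- t(combn(active, 2))
    vals <- D[pairs]
    best <- which.min(vals)
    i <- pairs[best, 1]; j <- pairs[best, 2]
    h <- D[i, j]
    heights <- c(heights, h)
    merges[[length(merges) + 1]] <- sort(c(i, j))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      D[i, k] <- D[k, i] <- sqrt(((ni + nk) * D[i, k]^2 + (nj + nk) * D[j, k]^2 -
                                    nk * h^2) / (ni + nj + nk))
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

# additive distance matrix from a tree given as ape phylo
additiveMatrix <- function(tree) ape::cophenetic.phylo(tree)

# simple global NW with affine gaps over single sequences, hand DP, for
# cross-checking the profile-profile aligner in the pairwise case
nwScoreManual <- function(a, b, sub, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e30
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - ext * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub[av[i], bv[j]]
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# score of a gapped pairwise alignment (two equal-length rows with '-')
alignmentScoreManual <- function(ra, rb, sub, open, ext) {
  ca <- strsplit(ra, "")[[1]]; cb <- strsplit(rb, "")[[1]]
  sc <- 0; inA <- FALSE; inB <- FALSE
  for (p in seq_along(ca)) {
    if (ca[p] != "-" && cb[p] != "-") {
      sc <- sc + sub[ca[p], cb[p]]; inA <- inB <- FALSE
    } else if (ca[p] == "-") {
      sc <- sc - ext - (!inA) * open; inA <- TRUE; inB <- FALSE
    } else {
      sc <- sc - ext - (!inB) * open; inB <- TRUE; inA <- FALSE
    }
  }
  sc
}
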