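# Progressive alignment, gap-column trimming, Kimura-corrected distances,
# bootstrapped neighbor-joining trees, position-in-array clade analysis and
# duplication-mode inference.

#' Progressive multiple alignment of proteins
#'
#' Guide tree from Euclidean distances between normalised 3-mer count
#' profiles (UPGMA); profile-profile Needleman-Wunsch with BLOSUM62 and
#' affine gaps at each merge. Input ids are sorted lexicographically first so
#' the result is independent of input order.
#'
#' @param seqs named character vector of proteins (>= 1)
#' @param gapOpen,gapExtend affine gap costs on the BLOSUM62 scale
#' @return an [Msa]
#' @export
alignProteins <- function(seqs, gapOpen = 10, gapExtend = 1) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  if (n == 1L) return(msa(seqs))
  sub <- blosum62() + 0.0
  prof <- function(rows) {
    m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    vapply(seq_len(ncol(m)), function(j) {
      cnt <- table(factor(m[, j], levels = AA20))
      as.numeric(cnt) / nrow(m)
    }, numeric(20))
  }
  applyMoves <- function(rowsA, rowsB, moves) {
    gapA <- moves != 3L  # consume a column of A unless 'left'
    gapB <- moves != 2L
    expand <- function(rows, use) {
      chars <- strsplit(rows, "", fixed = TRUE)
      vapply(chars, function(ch) {
        out <- rep("-", length(use))
        out[use] <- ch
        paste(out, collapse = "")
      }, character(1))
    }
    c(expand(rowsA, gapA), expand(rowsB, gapB))
  }
  if (n == 2L) {
    mv <- nw_profile(prof(seqs[1L]), prof(seqs[2L]), sub, gapOpen, gapExtend)
    rows <- applyMoves(seqs[1L], seqs[2L], mv)
    names(rows) <- names(seqs)
    return(msa(rows[order(names(rows))]))
  }
  km <- .kmer_profile(seqs, k = 3L)
  gd <- stats::dist(km)
  hc <- stats::hclust(gd, method = "average")  # UPGMA guide tree
  nodes <- vector("list", nrow(hc$merge))
  leaf <- function(i) stats::setNames(seqs[i], names(seqs)[i])
  for (s in seq_len(nrow(hc$merge))) {
    a <- hc$merge[s, 1L]; b <- hc$merge[s, 2L]
    rowsA <- if (a < 0) leaf(-a) else nodes[[a]]
    rowsB <- if (b < 0) leaf(-b) else nodes[[b]]
    mv <- nw_profile(prof(rowsA), prof(rowsB), sub, gapOpen, gapExtend)
    nodes[[s]] <- applyMoves(rowsA, rowsB, mv)
  }
  rows <- nodes[[nrow(hc$merge)]]
  msa(rows[order(names(rows))])
}

.kmer_profile <- function(seqs, k = 3L) {
  vocab <- new.env(parent = emptyenv())
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  })
  kms <- sort(unique(unlist(counts)))
  m <- vapply(counts, function(x) {
    tb <- table(factor(x, levels = kms))
    v <- as.numeric(tb)
    tot <- sum(v)
    if (tot > 0) v / tot else v
  }, numeric(length(kms)))
  t(m)
}

#' Trim gappy alignment columns
#'
#' Retains a column iff its non-gap fraction is at least `gt` (trimal's
#' gap-threshold convention: `gt = 0.05` removes columns with more than 95%
#' gaps).
#'
#' @param x an [Msa]
#' @param gt minimum non-gap fraction in `[0, 1]`
#' @return trimmed [Msa] with attribute `removed` (dropped column indices)
#' @export
trimAlignment <- function(x, gt) {
  stopifnot(gt >= 0, gt <= 1)
  m <- as.matrix(x)
  keep <- colMeans(m != "-") >= gt
  if (!any(keep)) stop("all columns removed at this gap threshold")
  rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  out <- msa(stats::setNames(rows, names(msaSeqs(x))))
  attr(out, "removed") <- which(!keep)
  out
}

#' Concatenate alignments over a shared id universe
#'
#' Rows missing from a block are padded with gaps. The blocks must be
#' linkable through shared ids; fully disjoint id sets are an error.
#'
#' @param msas list of [Msa] objects
#' @return concatenated [Msa] with attribute `provenance` (source block per
#'   column)
#' @export
concatAlignments <- function(msas) {
  stopifnot(length(msas) >= 1L)
  idSets <- lapply(msas, function(x) names(msaSeqs(x)))
  if (length(msas) > 1L) {
    linked <- vapply(seq_along(idSets), function(i)
      length(intersect(idSets[[i]], unlist(idSets[-i]))) > 0L, logical(1))
    if (!all(linked)) stop("disjoint id sets: alignments share no sequences")
  }
  ids <- sort(unique(unlist(idSets)))
  widths <- vapply(msas, msaWidth, numeric(1))
  rows <- vapply(ids, function(id) {
    paste(vapply(seq_along(msas), function(b) {
      s <- msaSeqs(msas[[b]])
      if (id %in% names(s)) s[[id]] else strrep("-", widths[[b]])
    }, character(1)), collapse = "")
  }, character(1))
  out <- msa(rows)
  attr(out, "provenance") <- rep(seq_along(msas), widths)
  out
}

#' Kimura-corrected pairwise protein distances
#'
#' Pairwise-deletion p-distance over columns where both rows have residues,
#' corrected as d = -ln(1 - p - 0.2 p^2). Saturated pairs are capped at 10
#' and flagged, as are pairs with fewer than 10 shared columns.
#'
#' @param x an [Msa] with >= 3 rows
#' @return distance matrix with attribute `flagged` (logical matrix)
#' @export
proteinDistances <- function(x) {
  m <- as.matrix(x)
  n <- nrow(m)
  stopifnot(n >= 3L)
  isRes <- m != "-"
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  FL <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- isRes[i, ] & isRes[j, ]
      ns <- sum(shared)
      if (ns < 10L) FL[i, j] <- FL[j, i] <- TRUE
      p <- if (ns > 0L) mean(m[i, shared] != m[j, shared]) else 1
      arg <- 1 - p - 0.2 * p^2
      d <- if (arg > 0) -log(arg) else { FL[i, j] <- FL[j, i] <- TRUE; 10 }
      d <- min(d, 10)
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "flagged") <- FL
  D
}

#' Neighbor-joining tree
#' @param d distance matrix or dist object
#' @return an unrooted `ape::phylo` tree
#' @export
njTree <- function(d) {
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) stop("non-finite distances")
  ape::nj(stats::as.dist(dm))
}

#' Bootstrapped neighbor-joining tree from an alignment
#'
#' Columns are resampled with replacement `B` times; internal-node labels of
#' the returned tree carry the percentage of replicates containing each
#' split.
#'
#' @param x an [Msa]
#' @param B bootstrap replicates (default 100)
#' @param seed RNG seed (caller's RNG restored)
#' @return `ape::phylo` with node labels = bootstrap support in `[0, 100]`
#' @export
bootstrapNj <- function(x, B = 100L, seed = NULL) {
  stopifnot(B >= 1L)
  tree <- njTree(proteinDistances(x))
  m <- as.matrix(x)
  reps <- .with_seed(seed, lapply(seq_len(B), function(b) {
    cols <- sample.int(ncol(m), replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    rows <- stats::setNames(apply(mb, 1L, paste, collapse = ""), rownames(m))
    njTree(proteinDistances(msa(rows)))
  }))
  cnt <- ape::prop.clades(tree, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  tree$node.label <- round(100 * cnt / B)
  tree
}

#' Monophyly of position-in-array classes on a domain tree
#'
#' For each array position class, tests whether its leaves are monophyletic
#' after pruning unlabelled (e.g. bacterial) leaves, and reports the maximum
#' Jaccard overlap between the class and any clade. Unlabelled leaves vote
#' for the position of their nearest labelled leaf (cophenetic distance);
#' the position attracting most votes is the candidate ancestral domain.
#'
#' @param tree `ape::phylo`
#' @param positionLabels named vector leaf -> array position (NA or missing
#'   = unlabelled)
#' @return list: perClass data.frame(position, n, monophyletic, purity),
#'   bacterialVotes, candidateAncestral
#' @export
positionClades <- function(tree, positionLabels) {
  tips <- tree$tip.label
  lab <- positionLabels[tips]
  names(lab) <- tips
  labelled <- tips[!is.na(lab)]
  if (!length(labelled)) stop("no labelled leaves")
  sub <- if (length(labelled) < length(tips))
    ape::keep.tip(tree, labelled) else tree
  classes <- sort(unique(lab[labelled]))
  perClass <- do.call(rbind, lapply(classes, function(cl) {
    members <- labelled[lab[labelled] == cl]
    out <- setdiff(labelled, members)
    if (length(members) < 2L || !length(out)) {
      # singleton classes (or a single-class tree) are trivially monophyletic
      return(data.frame(position = cl, n = length(members),
                        monophyletic = TRUE, purity = 1,
                        stringsAsFactors = FALSE))
    }
    # monophyly on the unrooted tree = the class forms a split; test it by
    # rooting at a tip outside the class so the split becomes a clade
    tr2 <- ape::root(sub, outgroup = out[[1L]], resolve.root = TRUE)
    mono <- ape::is.monophyletic(tr2, members)
    cladeSets <- lapply(ape::prop.part(tr2), function(p) tr2$tip.label[p])
    jac <- vapply(cladeSets, function(s)
      length(intersect(s, members)) / length(union(s, members)), numeric(1))
    data.frame(position = cl, n = length(members), monophyletic = mono,
               purity = max(jac, 1 / length(members)), stringsAsFactors = FALSE)
  }))
  rownames(perClass) <- NULL
  votes <- NULL
  candidate <- NA
  unlab <- setdiff(tips, labelled)
  if (length(unlab)) {
    co <- ape::cophenetic.phylo(tree)
    vote <- vapply(unlab, function(u) {
      nearest <- labelled[which.min(co[u, labelled])]
      as.character(lab[[nearest]])
    }, character(1))
    votes <- table(vote)
    candidate <- names(votes)[which.max(votes)]
  }
  list(perClass = perClass, bacterialVotes = votes,
       candidateAncestral = candidate)
}

#' Duplication-mode inference from within-array domain similarity
#'
#' Computes the all-vs-all Smith-Waterman bit-score matrix of the domains of
#' one array (in array order) and its offset profile s(d) = mean bit score
#' over pairs at position offset d. The array is classified as "block"
#' duplication of size b when s(b) for some candidate b in 2..m/2 exceeds a
#' robust baseline by more than `madMultiplier` MAD and s(b) > s(1);
#' otherwise "single" domain duplications. Because block duplication makes
#' every multiple of b similar (periodicity), the baseline median/MAD for
#' candidate b is computed over offsets that are not multiples of b. Also
#' reports the nearest-neighbour vs distant similarity contrast
#' s(1) - mean(s(d >= 2)) used to argue internal duplication.
#'
#' @param domains character vector of domain sequences in array order (m >= 3)
#' @param scheme a [scoringScheme()]
#' @param madMultiplier robust z threshold for the block signal (default 2)
#' @return list: matrix (m x m bits), offsetProfile, mode ("single"/"block"),
#'   blockSize (NA for single), contrast
#' @export
duplicationMode <- function(domains, scheme = scoringScheme(),
                            madMultiplier = 2) {
  m <- length(domains)
  if (m < 3L) stop("duplication mode is undecidable for fewer than 3 domains")
  enc <- lapply(domains, function(p) { e <- encodeProtein(p); e[!is.na(e)] })
  sub <- blosum62() + 0.0
  raw <- sw_all(enc, sub, scheme$gapOpen, scheme$gapExtend)
  for (i in seq_len(m))
    raw[i, i] <- sw_score(enc[[i]], enc[[i]], sub, scheme$gapOpen,
                          scheme$gapExtend)
  bits <- bitsFromRaw(raw, scheme)
  dimnames(bits) <- list(seq_len(m), seq_len(m))
  offs <- seq_len(m - 1L)
  s <- vapply(offs, function(d) {
    i <- seq_len(m - d)
    mean(bits[cbind(i, i + d)])
  }, numeric(1))
  names(s) <- offs
  cands <- offs[offs >= 2L & offs <= m %/% 2L]
  hit <- vapply(cands, function(b) {
    base <- s[offs %% b != 0L]
    s[[b]] > stats::median(base) + madMultiplier * stats::mad(base) &&
      s[[b]] > s[[1L]]
  }, logical(1))
  if (any(hit)) {
    b <- cands[hit][[which.max(s[cands[hit]])]]
    mode <- "block"
  } else {
    b <- NA_integer_
    mode <- "single"
  }
  contrast <- if (m > 2L) s[[1L]] - mean(s[-1L]) else NA_real_
  list(matrix = bits, offsetProfile = s, mode = mode, blockSize = b,
       contrast = contrast)
}
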