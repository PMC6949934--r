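# Gene-sharing contig classification: homology graph -> MCL families ->
# hypergeometric shared-content p-values -> Ward.D2 -> silhouette-chosen k.

#' Local-alignment scoring scheme with Karlin-Altschul bit conversion
#'
#' @param gapOpen,gapExtend positive affine gap costs (BLAST defaults 11/1)
#' @param lambda Karlin-Altschul lambda in nats per raw unit (gapped BLOSUM62
#'   default 0.267)
#' @param K Karlin-Altschul K (default 0.041)
#' @param bitThreshold minimum retained edge bit score (default 50)
#' @return a ScoringScheme list
#' @export
scoringScheme <- function(gapOpen = 11, gapExtend = 1, lambda = 0.267,
                          K = 0.041, bitThreshold = 50) {
  stopifnot(lambda > 0, K > 0, gapOpen > 0, gapExtend > 0)
  structure(list(gapOpen = gapOpen, gapExtend = gapExtend, lambda = lambda,
                 K = K, bitThreshold = bitThreshold),
            class = "ScoringScheme")
}

#' Convert a raw local-alignment score to bits
#' @param raw raw Smith-Waterman score
#' @param scheme a [scoringScheme()]
#' @return bit score (lambda * raw - ln K) / ln 2
#' @export
bitsFromRaw <- function(raw, scheme = scoringScheme()) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

#' Drop contigs with too few ORFs
#'
#' Retains contigs whose ORF count is strictly greater than `minOrfs`
#' (default 10, the clustering reliability gate).
#'
#' @param dataset list with `contigs` (named DNA vector) and `orfs`
#'   (ORF table with contig_id)
#' @param minOrfs strict lower bound on ORF count
#' @return the filtered dataset
#' @export
filterContigs <- function(dataset, minOrfs = 10L) {
  stopifnot(minOrfs >= 0L)
  counts <- table(dataset$orfs$contig_id)
  keep <- names(counts)[counts > minOrfs]
  list(contigs = dataset$contigs[names(dataset$contigs) %in% keep],
       orfs = dataset$orfs[dataset$orfs$contig_id %in% keep, , drop = FALSE])
}

#' All-vs-all Smith-Waterman protein scores as a bit-score edge list
#'
#' Raw local-alignment scores under BLOSUM62 with affine gaps, converted to
#' bits with the Karlin-Altschul formula; edges at or below
#' `scheme$bitThreshold` are dropped, as are self comparisons.
#'
#' Pairs are pre-screened with a shared-word filter (as seeded aligners such
#' as BLAST do): only pairs sharing at least one exact `prefilterK`-mer are
#' aligned. Set `prefilterK = 0` to align every pair.
#'
#' @param proteins named character vector (>= 2)
#' @param scheme a [scoringScheme()]
#' @param prefilterK word size of the shared-word prescreen (default 5;
#'   0 disables)
#' @return data.frame: query, target, raw, bits (undirected, query < target)
#' @export
pairwiseScores <- function(proteins, scheme = scoringScheme(),
                           prefilterK = 5L) {
  stopifnot(length(proteins) >= 2L, !is.null(names(proteins)))
  enc <- lapply(proteins, function(p) {
    e <- encodeProtein(p)
    e[!is.na(e)]
  })
  ids <- names(proteins)
  n <- length(ids)
  sub <- blosum62() + 0.0
  cand <- if (prefilterK > 0L) {
    .shared_word_pairs(proteins, prefilterK)
  } else {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    cbind(ut[, 1L], ut[, 2L])
  }
  if (!nrow(cand))
    return(data.frame(query = character(0), target = character(0),
                      raw = numeric(0), bits = numeric(0),
                      stringsAsFactors = FALSE))
  raw <- vapply(seq_len(nrow(cand)), function(r)
    sw_score(enc[[cand[r, 1L]]], enc[[cand[r, 2L]]], sub,
             scheme$gapOpen, scheme$gapExtend), numeric(1))
  bits <- bitsFromRaw(raw, scheme)
  keep <- bits > scheme$bitThreshold
  data.frame(query = ids[cand[keep, 1L]], target = ids[cand[keep, 2L]],
             raw = raw[keep], bits = bits[keep], stringsAsFactors = FALSE)
}

# candidate pairs sharing at least one exact k-mer (inverted word index)
.shared_word_pairs <- function(proteins, k) {
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(proteins)) {
    s <- proteins[[i]]
    n <- nchar(s)
    if (n < k) next
    for (w in unique(substring(s, 1:(n - k + 1L), k:n)))
      assign(w, c(get0(w, idx), i), envir = idx)
  }
  seen <- new.env(parent = emptyenv())
  for (w in ls(idx)) {
    mem <- get(w, idx)
    if (length(mem) < 2L) next
    for (a in seq_len(length(mem) - 1L))
      for (b in (a + 1L):length(mem)) {
        key <- paste0(mem[[a]], "_", mem[[b]])
        if (is.null(get0(key, seen))) assign(key, TRUE, envir = seen)
      }
  }
  keys <- ls(seen)
  if (!length(keys)) return(matrix(integer(0), 0L, 2L))
  m <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  cbind(as.integer(m[, 1L]), as.integer(m[, 2L]))
}

#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Column-stochastic iteration: expansion (matrix squaring), inflation
#' (entrywise power then renormalisation), pruning of entries below 1e-6,
#' until the maximum entry change falls below 1e-9. Self-loops are added with
#' each node's maximum incident edge weight before normalisation. Families
#' are the connected components of the limit matrix support; singletons are
#' allowed.
#'
#' @param edges data.frame(query, target, bits) undirected edge list
#' @param nodes optional full node set (isolated nodes become singletons)
#' @param inflation inflation exponent (> 1; default 2)
#' @param maxIter iteration cap (default 10000)
#' @return named character vector: node -> family id
#' @export
mclCluster <- function(edges, nodes = NULL, inflation = 2, maxIter = 10000L) {
  stopifnot(inflation > 1)
  edges$query <- as.character(edges$query)
  edges$target <- as.character(edges$target)
  nodes <- sort(unique(c(as.character(nodes), edges$query, edges$target)))
  n <- length(nodes)
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    qi <- match(edges$query, nodes); ti <- match(edges$target, nodes)
    w <- if ("bits" %in% names(edges)) edges$bits else rep(1, nrow(edges))
    A[cbind(qi, ti)] <- w
    A[cbind(ti, qi)] <- w
  }
  mx <- apply(A, 1L, max)
  diag(A) <- ifelse(mx > 0, mx, 1)
  M <- sweep(A, 2L, colSums(A), "/")
  for (iter in seq_len(maxIter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < 1e-6] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-9) {
      S <- (M > 1e-6) | t(M > 1e-6)
      comp <- .components(S)
      return(stats::setNames(sprintf("fam%04d", comp), nodes))
    }
  }
  stop("MCL did not converge within the iteration cap")
}

# connected components of a logical adjacency matrix (BFS)
.components <- function(S) {
  n <- nrow(S)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(S[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Hypergeometric shared-gene-content matrix
#'
#' For each contig pair, the upper-tail probability of sharing at least the
#' observed number of gene families, given the family counts of both contigs
#' and the total family universe: P(X >= k), X ~ Hypergeom(N, n_i, n_j).
#' Family sets per contig are deduplicated. The contig distance matrix is the
#' Euclidean distance between rows of the p-value matrix (diagonal set to 0).
#'
#' @param contigFamilies named list: contig -> character vector of family ids
#' @return list: p (p-value matrix), k (shared counts), n (families per
#'   contig), N (total families), dist (Euclidean distance object)
#' @export
sharedContent <- function(contigFamilies) {
  fams <- lapply(contigFamilies, unique)
  allFams <- sort(unique(unlist(fams)))
  N <- length(allFams)
  if (N == 0L) stop("no gene families in the dataset")
  cn <- names(fams)
  inc <- vapply(fams, function(f) allFams %in% f, logical(N))
  inc <- t(inc)  # contigs x families
  K <- inc %*% t(inc)
  nVec <- diag(K)
  P <- matrix(1, length(cn), length(cn), dimnames = list(cn, cn))
  for (i in seq_along(cn))
    for (j in seq_along(cn))
      if (i != j)
        P[i, j] <- stats::phyper(K[i, j] - 1L, nVec[[i]], N - nVec[[i]],
                                 nVec[[j]], lower.tail = FALSE)
  diag(P) <- 0
  list(p = P, k = K, n = nVec, N = N, dist = stats::dist(P))
}

#' Ward.D2 contig clustering with silhouette-based choice of k
#'
#' Agglomerative Ward.D2 clustering of the contig distance matrix; the number
#' of clusters is chosen to maximise the mean silhouette width over
#' `kRange`; per-contig silhouettes for the chosen k are reported.
#'
#' @param d a dist object or symmetric distance matrix
#' @param kRange candidate cluster numbers (clipped to `[2, n-1]`)
#' @return list: assignment (named integer), chosenK, silhouette (per-contig
#'   widths), meanSilhouette (named by k), hclust, dendrogram (ape phylo),
#'   degenerate flag
#' @export
wardCluster <- function(d, kRange = 2:15) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  stopifnot(n >= 3L)
  labs <- attr(d, "Labels") %||% as.character(seq_len(n))
  if (max(d) == 0) {
    warning("all distances are zero; returning a single cluster")
    return(list(assignment = stats::setNames(rep(1L, n), labs),
                chosenK = 1L, silhouette = rep(NA_real_, n),
                meanSilhouette = stats::setNames(numeric(0), character(0)),
                hclust = NULL, dendrogram = NULL, degenerate = TRUE))
  }
  hc <- stats::hclust(d, method = "ward.D2")
  kRange <- kRange[kRange >= 2L & kRange <= n - 1L]
  stopifnot(length(kRange) > 0L)
  msil <- vapply(kRange, function(k) {
    cl <- stats::cutree(hc, k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  names(msil) <- kRange
  chosenK <- kRange[[which.max(msil)]]
  cl <- stats::cutree(hc, chosenK)
  sil <- cluster::silhouette(cl, d)[, "sil_width"]
  list(assignment = stats::setNames(as.integer(cl), labs),
       chosenK = chosenK,
       silhouette = stats::setNames(sil, labs),
       meanSilhouette = msil,
       hclust = hc,
       dendrogram = ape::as.phylo(hc),
       degenerate = FALSE)
}
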