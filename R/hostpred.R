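# k-mer Markov phage-host prediction and representative-genome selection.

#' Select one representative genome per genus
#'
#' Per genus, the genome maximising completeness minus five times
#' contamination (C - 5M); ties broken by the highest coarse-consistency
#' score, then lexicographic genome id.
#'
#' @param records data.frame: genus, genome_id, completeness, contamination,
#'   coarse
#' @return data.frame of selected records with a `score` column
#' @export
selectRepresentatives <- function(records) {
  stopifnot(all(c("genus", "genome_id", "completeness", "contamination",
                  "coarse") %in% names(records)))
  records$score <- records$completeness - 5 * records$contamination
  picked <- lapply(split(records, records$genus), function(g) {
    g[order(-g$score, -g$coarse, g$genome_id), ][1L, ]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Train an order-k Markov model on a bacterial genome
#'
#' Transition counts P(next base | preceding k-mer) are accumulated over both
#' strands with add-one smoothing, so the model is strand-symmetric by
#' construction.
#'
#' @param genome DNA string (length must exceed 4^k)
#' @param k model order (default 3)
#' @param id genome identifier
#' @return a MarkovModel list: k, logp (4^k x 4 log-probabilities), id
#' @export
trainHostModel <- function(genome, k = 3L, id = "genome") {
  if (k < 1L) stop("model order k must be at least 1")
  genome <- toupper(genome)
  if (nchar(genome) <= 4^k)
    stop("genome shorter than 4^k; too little data for an order-k model")
  counts <- matrix(0, 4^k, 4L)
  for (s in c(genome, revComp(genome)))
    counts <- counts + .kmer_transition_counts(s, k)
  counts <- counts + 1  # add-one smoothing
  logp <- log(counts / rowSums(counts))
  structure(list(k = k, logp = logp, id = id), class = "MarkovModel")
}

.kmer_transition_counts <- function(seq, k) {
  v <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA4) - 1L
  n <- length(v)
  counts <- matrix(0, 4^k, 4L)
  if (n < k + 1L) return(counts)
  # rolling k-mer codes; positions touching non-ACGT are dropped
  code <- numeric(n - k + 1L)
  ok <- !is.na(v)
  valid <- rep(TRUE, n - k + 1L)
  for (j in 0:(k - 1L)) {
    idx <- (1L + j):(n - k + 1L + j)
    vv <- v[idx]
    vv[is.na(vv)] <- 0L
    code <- code + vv * 4^(k - 1L - j)
    valid <- valid & ok[idx]
  }
  from <- code[seq_len(n - k)]
  nxt <- v[(k + 1L):n]
  use <- valid[seq_len(n - k)] & !is.na(nxt)
  if (any(use)) {
    tb <- table(factor(from[use] + 1L, levels = seq_len(4^k)),
                factor(nxt[use] + 1L, levels = 1:4))
    counts <- counts + unclass(tb)
  }
  counts
}

#' Score a contig against trained host models
#'
#' Per model, the mean log-likelihood per scored transition of the contig
#' under the order-k Markov chain; hosts are ranked in decreasing order and
#' the margin between the top two is reported.
#'
#' @param models list of MarkovModel objects (from [trainHostModel()])
#' @param contig DNA string of length >= k + 1
#' @return list: ranking data.frame(host, mean_ll, rank), margin
#' @export
predictHost <- function(models, contig) {
  stopifnot(length(models) >= 1L)
  ll <- vapply(models, function(mdl) {
    k <- mdl$k
    if (nchar(contig) < k + 1L)
      stop("contig shorter than k + 1; nothing to score")
    v <- match(strsplit(toupper(contig), "", fixed = TRUE)[[1L]], DNA4) - 1L
    n <- length(v)
    code <- numeric(n - k + 1L)
    ok <- !is.na(v)
    valid <- rep(TRUE, n - k + 1L)
    for (j in 0:(k - 1L)) {
      idx <- (1L + j):(n - k + 1L + j)
      vv <- v[idx]
      vv[is.na(vv)] <- 0L
      code <- code + vv * 4^(k - 1L - j)
      valid <- valid & ok[idx]
    }
    from <- code[seq_len(n - k)]
    nxt <- v[(k + 1L):n]
    use <- valid[seq_len(n - k)] & !is.na(nxt)
    if (!any(use)) return(NA_real_)
    mean(mdl$logp[cbind(from[use] + 1L, nxt[use] + 1L)])
  }, numeric(1))
  ids <- vapply(models, `[[`, character(1), "id")
  o <- order(-ll)
  ranking <- data.frame(host = ids[o], mean_ll = ll[o],
                        rank = seq_along(o), stringsAsFactors = FALSE)
  margin <- if (length(ll) >= 2L) ranking$mean_ll[[1L]] - ranking$mean_ll[[2L]]
            else NA_real_
  list(ranking = ranking, margin = margin)
}
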