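# Domain architecture per ORF/contig, tandem-array detection, +/- w ORF
# genomic neighbourhoods, and the tail-association permutation test.

TAIL_KEYWORDS <- c("tail", "tail fibre", "tail fiber", "tail spike", "baseplate")

#' Histograms of domains per ORF and domain-ORFs per contig
#'
#' @param hits domain-hit table with orf_id
#' @param orfs ORF table with orf_id and contig_id
#' @param clusters optional named vector contig -> cluster label for
#'   stratification
#' @return list of data.frames `perOrf` (n_domains, count) and `perContig`
#'   (n_domain_orfs, count), each with a cluster column when labels are given
#' @export
architectureSummary <- function(hits, orfs, clusters = NULL) {
  perOrfCounts <- table(hits$orf_id)
  contigOf <- stats::setNames(orfs$contig_id, orfs$orf_id)
  oc <- contigOf[names(perOrfCounts)]
  if (anyNA(oc)) stop("hit refers to an ORF absent from the ORF table")
  clusterOf <- function(contig) {
    if (is.null(clusters)) rep("all", length(contig))
    else as.character(clusters[contig])
  }
  perOrf <- as.data.frame(table(
    cluster = clusterOf(oc), n_domains = as.integer(perOrfCounts)),
    responseName = "count")
  perOrf$n_domains <- as.integer(as.character(perOrf$n_domains))
  perOrf <- perOrf[perOrf$count > 0, c("n_domains", "count", "cluster")]
  domOrfsPerContig <- table(oc)
  perContig <- as.data.frame(table(
    cluster = clusterOf(names(domOrfsPerContig)),
    n_domain_orfs = as.integer(domOrfsPerContig)), responseName = "count")
  perContig$n_domain_orfs <- as.integer(as.character(perContig$n_domain_orfs))
  perContig <- perContig[perContig$count > 0,
                         c("n_domain_orfs", "count", "cluster")]
  rownames(perOrf) <- rownames(perContig) <- NULL
  list(perOrf = perOrf, perContig = perContig)
}

#' Detect a tandem array among the domain hits of one ORF
#'
#' An ORF carries a tandem array when it has at least two hits and every
#' inter-envelope gap is at most `maxGap` residues. Array positions are
#' numbered 1..m from the N-terminus.
#'
#' @param orfHits hit table for a single ORF (env_start, env_end, bit_score),
#'   non-overlapping
#' @param maxGap maximum inter-envelope gap in residues (default 30)
#' @return list: hits (with array_position), is_tandem, gaps
#' @export
detectTandem <- function(orfHits, maxGap = 30L) {
  h <- orfHits[order(orfHits$env_start), , drop = FALSE]
  m <- nrow(h)
  if (m > 1L && any(h$env_start[-1L] < h$env_end[-m]))
    stop("overlapping domain hits within one ORF")
  h$array_position <- seq_len(m)
  gaps <- if (m > 1L) h$env_start[-1L] - h$env_end[-m] else numeric(0)
  list(hits = h, is_tandem = m >= 2L && all(gaps <= maxGap), gaps = gaps)
}

#' Annotate all hits with array positions and per-ORF tandem status
#' @param hits combined hit table with orf_id
#' @param maxGap maximum inter-envelope gap (default 30)
#' @return list: hits (with array_position), arrays data.frame(orf_id,
#'   n_domains, is_tandem)
#' @export
annotateArrays <- function(hits, maxGap = 30L) {
  pieces <- lapply(split(hits, hits$orf_id), detectTandem, maxGap = maxGap)
  out <- do.call(rbind, lapply(pieces, `[[`, "hits"))
  rownames(out) <- NULL
  arrays <- data.frame(
    orf_id = names(pieces),
    n_domains = vapply(pieces, function(p) nrow(p$hits), integer(1)),
    is_tandem = vapply(pieces, `[[`, logical(1), "is_tandem"),
    stringsAsFactors = FALSE)
  rownames(arrays) <- NULL
  list(hits = out, arrays = arrays)
}

#' Genomic neighbourhoods of focal ORFs
#'
#' Collects the `w` ORFs up- and downstream of each focal ORF on its contig
#' (windows truncate at contig ends). A neighbourhood is informative when at
#' least one neighbour label differs from "hypothetical protein";
#' uninformative neighbourhoods are excluded from association statistics.
#'
#' @param focalOrfIds character vector of focal ORF ids
#' @param orfs ORF table (orf_id, contig_id, index_on_contig)
#' @param labels named character vector orf_id -> functional label
#' @param w window half-width in ORFs (default 5)
#' @param tailKeywords case-insensitive substrings flagging tail genes
#' @return list: neighbours (long data.frame focal, orf_id, offset, label,
#'   tail_flag), summary (focal, n_neighbours, informative, has_tail)
#' @export
neighbourhoods <- function(focalOrfIds, orfs, labels, w = 5L,
                           tailKeywords = TAIL_KEYWORDS) {
  if (!all(focalOrfIds %in% orfs$orf_id))
    stop("focal ORF absent from the ORF table")
  pat <- paste(tailKeywords, collapse = "|")
  long <- list()
  for (f in focalOrfIds) {
    row <- orfs[orfs$orf_id == f, ]
    same <- orfs[orfs$contig_id == row$contig_id, ]
    off <- same$index_on_contig - row$index_on_contig
    nb <- same[off != 0L & abs(off) <= w, , drop = FALSE]
    off <- nb$index_on_contig - row$index_on_contig
    o <- order(off)
    lab <- as.character(labels[nb$orf_id[o]])
    lab[is.na(lab)] <- "hypothetical protein"
    long[[f]] <- data.frame(
      focal = f, orf_id = nb$orf_id[o], offset = off[o], label = lab,
      tail_flag = grepl(pat, lab, ignore.case = TRUE),
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, long)
  rownames(long) <- NULL
  summ <- do.call(rbind, lapply(split(long, long$focal), function(g)
    data.frame(focal = g$focal[[1L]], n_neighbours = nrow(g),
               informative = any(g$label != "hypothetical protein"),
               has_tail = any(g$tail_flag), stringsAsFactors = FALSE)))
  summ <- summ[match(focalOrfIds, summ$focal), , drop = FALSE]
  rownames(summ) <- NULL
  list(neighbours = long, summary = summ)
}

#' Permutation test for tail-gene association of tandem arrays
#'
#' Statistic: fraction of tandem-array ORFs with at least one tail-annotated
#' neighbour minus the same fraction among single-domain ORFs, over
#' informative neighbourhoods only. The p-value permutes the tandem/single
#' labels with an add-one correction, one-sided for a positive association.
#'
#' @param arrays array table from [annotateArrays()] (orf_id, is_tandem)
#' @param neighbourhoodSummary summary table from [neighbourhoods()]
#' @param nPermutations number of label permutations (default 999)
#' @param seed RNG seed for the permutations (caller's RNG is restored)
#' @return list: statistic, p_value, n_tandem, n_single, permuted (null stats)
#' @export
tailAssociation <- function(arrays, neighbourhoodSummary,
                            nPermutations = 999L, seed = NULL) {
  tab <- merge(arrays, neighbourhoodSummary, by.x = "orf_id", by.y = "focal")
  tab <- tab[tab$informative, , drop = FALSE]
  if (!nrow(tab)) stop("no informative neighbourhoods")
  if (!any(tab$is_tandem) || !any(!tab$is_tandem))
    stop("need both tandem and single-domain ORFs for the contrast")
  stat <- function(isTandem)
    mean(tab$has_tail[isTandem]) - mean(tab$has_tail[!isTandem])
  obs <- stat(tab$is_tandem)
  perm <- .with_seed(seed, vapply(seq_len(nPermutations), function(i)
    stat(sample(tab$is_tandem)), numeric(1)))
  p <- (1 + sum(perm >= obs)) / (nPermutations + 1)
  list(statistic = obs, p_value = p,
       n_tandem = sum(tab$is_tandem), n_single = sum(!tab$is_tandem),
       permuted = perm)
}
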