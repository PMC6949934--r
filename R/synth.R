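# Synthetic phage-genome generator with full ground truth: lineage-structured
# gene content, planted domain arrays with explicit duplication histories,
# horizontal transfer of domain-bearing ORFs, and neighbourhood labels.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the study conditions the pipeline targets: seven phage
#' lineages with cluster-structured shared gene families; one domain-bearing
#' ORF per contig; ~45-residue domains with four strongly conserved residues
#' (W, N, R, Q); tandem arrays grown by single-domain or multi-domain block
#' duplication; occasional horizontal transfer of a domain ORF between
#' lineages; tail labels on ORFs flanking tandem arrays.
#'
#' @param seed integer RNG seed
#' @param nLineages number of phage lineages (default 7)
#' @param contigsPerLineage contigs per lineage (default 4)
#' @param genesPerContig length-2 integer range of genes per contig
#' @param familiesPerLineage size of each lineage-private family pool
#' @param coreGenes number of lineage "core genome" families present in
#'   every contig of the lineage (the rest of the pool is accessory)
#' @param nSharedFamilies size of the cross-lineage shared pool
#' @param betweenLineageSharing probability a gene slot draws from the shared
#'   pool instead of the lineage pool
#' @param familyDivergence substitutions/site between family members
#' @param domainLength domain length in residues (default 45)
#' @param conservedPositions 1-based positions held invariant
#' @param conservedResidues residues planted at those positions
#' @param arraySizes tandem-array size per lineage (recycled; 1 = single
#'   domain). Default c(8, 5, 3, 1, 1, 1, 1): three tandem lineages, the
#'   first carrying the prototypical eight-domain repeat
#' @param duplicationMode "single" or list(mode = "block", blockSize = b)
#' @param divergence substitutions/site applied to all domains after each
#'   duplication event
#' @param copyDivergence substitutions/site between a contig's array instance
#'   and its lineage array
#' @param lineageDomainDivergence substitutions/site between each lineage's
#'   founder domain and the common ancestral domain
#' @param hgtRate per-lineage probability of receiving a transferred domain
#'   ORF from another lineage
#' @param nTermDeletionProb per-domain-instance probability of deleting the
#'   flexible 10-residue N-terminal segment
#' @param tailLabelPolicy "tandem_only" (tail genes only beside tandem
#'   arrays), "all", or "none"
#' @param ancestorDomain optional fixed ancestral domain sequence (length
#'   `domainLength`, conserved residues already in place); random if NULL
#' @return a validated SynthConfig list
#' @export
synthConfig <- function(seed = 1L, nLineages = 7L, contigsPerLineage = 4L,
                        genesPerContig = c(12L, 20L),
                        familiesPerLineage = 22L, coreGenes = 10L,
                        nSharedFamilies = 10L,
                        betweenLineageSharing = 0.15,
                        familyDivergence = 0.05, domainLength = 45L,
                        conservedPositions = c(5L, 20L, 26L, 40L),
                        conservedResidues = c("W", "N", "R", "Q"),
                        arraySizes = c(8L, 5L, 3L, 1L, 1L, 1L, 1L),
                        duplicationMode = "single", divergence = 0.05,
                        copyDivergence = 0.02,
                        lineageDomainDivergence = 0.08, hgtRate = 0.1,
                        nTermDeletionProb = 0.1,
                        tailLabelPolicy = c("tandem_only", "all", "none"),
                        ancestorDomain = NULL) {
  tailLabelPolicy <- match.arg(tailLabelPolicy)
  if (!is.null(ancestorDomain))
    stopifnot(nchar(ancestorDomain) == domainLength)
  stopifnot(nLineages >= 1L, contigsPerLineage >= 1L,
            length(genesPerContig) == 2L,
            genesPerContig[[1L]] <= genesPerContig[[2L]],
            betweenLineageSharing >= 0, betweenLineageSharing <= 1,
            hgtRate >= 0, hgtRate <= 1,
            nTermDeletionProb >= 0, nTermDeletionProb <= 1,
            all(arraySizes >= 1L),
            length(conservedPositions) == length(conservedResidues),
            all(conservedPositions >= 1L),
            all(conservedPositions <= domainLength),
            familiesPerLineage >= genesPerContig[[2L]],
            coreGenes >= 0L, coreGenes <= familiesPerLineage)
  if (genesPerContig[[1L]] < 5L)
    stop("inconsistent config: contigs need at least 5 genes to host an array")
  if (genesPerContig[[1L]] < coreGenes + 2L)
    stop("inconsistent config: genesPerContig too small for the core genome")
  structure(list(
    seed = seed, nLineages = nLineages, contigsPerLineage = contigsPerLineage,
    genesPerContig = genesPerContig, familiesPerLineage = familiesPerLineage,
    coreGenes = coreGenes, nSharedFamilies = nSharedFamilies,
    betweenLineageSharing = betweenLineageSharing,
    familyDivergence = familyDivergence, domainLength = domainLength,
    conservedPositions = conservedPositions,
    conservedResidues = conservedResidues,
    arraySizes = rep_len(arraySizes, nLineages),
    duplicationMode = duplicationMode, divergence = divergence,
    copyDivergence = copyDivergence,
    lineageDomainDivergence = lineageDomainDivergence,
    hgtRate = hgtRate, nTermDeletionProb = nTermDeletionProb,
    tailLabelPolicy = tailLabelPolicy, ancestorDomain = ancestorDomain),
    class = "SynthConfig")
}

#' Replay a duplication event history on an ancestral domain
#'
#' Each event copies a contiguous block of `size` domains starting at
#' `position` and inserts the copy immediately after the block; all domains
#' then diverge at `divergence` substitutions/site with the conserved
#' positions held fixed. The per-domain lineage trace records which original
#' domain each final domain descends from.
#'
#' @param ancestor ancestral domain sequence (or a starting array)
#' @param events data.frame with columns position, size
#' @param divergence substitutions/site applied per event
#' @param conservedPositions 1-based invariant positions
#' @param seed optional RNG seed (caller's RNG restored)
#' @return list: domains, trace, events
#' @export
replayHistory <- function(ancestor, events, divergence,
                          conservedPositions = integer(0), seed = NULL) {
  .with_seed(seed, {
    domains <- ancestor
    trace <- seq_along(domains)
    if (!is.null(events) && nrow(events)) {
      for (e in seq_len(nrow(events))) {
        pos <- events$position[[e]]
        size <- events$size[[e]]
        if (pos < 1L || size < 1L || pos + size - 1L > length(domains))
          stop(sprintf("duplication event %d out of array bounds", e))
        blk <- pos:(pos + size - 1L)
        at <- pos + size - 1L
        domains <- append(domains, domains[blk], after = at)
        trace <- append(trace, trace[blk], after = at)
        domains <- vapply(domains, mutateProtein, character(1),
                          rate = divergence, fixed = conservedPositions)
      }
    }
    list(domains = unname(domains), trace = trace, events = events)
  })
}

# sample a duplication history that grows an array from 1 to targetSize
.sample_events <- function(targetSize, mode) {
  if (targetSize <= 1L)
    return(data.frame(position = integer(0), size = integer(0)))
  blockSize <- 1L
  if (is.list(mode)) {
    stopifnot(identical(mode$mode, "block"), mode$blockSize >= 2L)
    blockSize <- mode$blockSize
  } else stopifnot(identical(mode, "single"))
  len <- 1L
  pos <- integer(0); size <- integer(0)
  while (len < blockSize && len < targetSize) {   # bootstrap the first block
    pos <- c(pos, sample.int(len, 1L)); size <- c(size, 1L)
    len <- len + 1L
  }
  while (len + blockSize <= targetSize && blockSize > 1L) {
    pos <- c(pos, sample.int(len - blockSize + 1L, 1L))
    size <- c(size, blockSize)
    len <- len + blockSize
  }
  while (len < targetSize) {                       # fill any remainder
    pos <- c(pos, sample.int(len, 1L)); size <- c(size, 1L)
    len <- len + 1L
  }
  data.frame(position = pos, size = size)
}

# one codon per amino acid (table 11); "M" maps to the start codon ATG.
# Codons whose reverse complement is a stop are preferred so the reverse
# strand of coding regions stays stop-rich and yields few spurious ORFs.
.codon_table <- function() {
  if (is.null(.pkg_cache$CODONS)) {
    gc <- .genetic_code_11()
    aa <- gc[gc != "*"]
    .pkg_cache$CODONS <- vapply(AA20, function(a) {
      cands <- names(aa)[aa == a]
      revStop <- vapply(cands, function(cd)
        gc[[revComp(cd)]] == "*", logical(1))
      if (any(revStop)) cands[revStop][[1L]] else cands[[1L]]
    }, character(1))
  }
  .pkg_cache$CODONS
}

.reverse_translate <- function(protein) {
  cod <- .codon_table()
  paste0(paste(cod[strsplit(protein, "", fixed = TRUE)[[1L]]], collapse = ""),
         "TAA")
}

# spacer of whole codons ending with an in-frame stop, so the maximal-ORF
# caller recovers every planted ORF exactly in frame 0
.spacer <- function() {
  paste0(paste(sample(DNA4, 3L * sample(3:6, 1L), replace = TRUE),
               collapse = ""), "TAA")
}

#' Simulate a phage contig dataset with known truth
#'
#' Deterministic given `config$seed`. Contigs carry head-to-tail ORFs
#' separated by stop-terminated spacers; each lineage draws gene families
#' from a private pool plus a shared pool; one ORF per contig carries the
#' lineage's domain array, built by replaying a sampled duplication history
#' from a common ancestral domain (conserved positions held fixed).
#' Domain-bearing ORFs are occasionally copied between lineages (horizontal
#' transfer), and functional labels are placed around domain ORFs according
#' to the tail-label policy.
#'
#' @param config a [synthConfig()]
#' @return list: contigs (named DNA vector), truth (lineages, orfs, domains,
#'   events, transfers, ancestorDomain, lineageDomains, lineageArrays),
#'   config
#' @export
simulateDataset <- function(config = synthConfig()) {
  stopifnot(inherits(config, "SynthConfig"))
  .with_seed(config$seed, .simulate_dataset(config))
}

.simulate_dataset <- function(cfg) {
  ancestor <- cfg$ancestorDomain %||% {
    x <- randomProtein(cfg$domainLength)
    a <- strsplit(x, "", fixed = TRUE)[[1L]]
    a[cfg$conservedPositions] <- cfg$conservedResidues
    paste(a, collapse = "")
  }

  sharedPool <- sprintf("famS%02d", seq_len(cfg$nSharedFamilies))
  lineagePools <- lapply(seq_len(cfg$nLineages), function(l)
    sprintf("famL%d_%02d", l, seq_len(cfg$familiesPerLineage)))
  allFams <- c(sharedPool, unlist(lineagePools))
  famRef <- stats::setNames(vapply(allFams, function(f)
    paste0("M", randomProtein(sample(59:119, 1L))), character(1)), allFams)

  lineageDomains <- character(cfg$nLineages)
  lineageArrays <- vector("list", cfg$nLineages)
  eventsByLineage <- vector("list", cfg$nLineages)
  for (l in seq_len(cfg$nLineages)) {
    lineageDomains[[l]] <- mutateProtein(ancestor, cfg$lineageDomainDivergence,
                                         fixed = cfg$conservedPositions)
    ev <- .sample_events(cfg$arraySizes[[l]], cfg$duplicationMode)
    rh <- replayHistory(lineageDomains[[l]], ev, cfg$divergence,
                        cfg$conservedPositions)
    lineageArrays[[l]] <- rh
    eventsByLineage[[l]] <- ev
  }

  contigs <- character(0)
  orfRows <- list()
  domRows <- list()
  transferRows <- list()
  informativePool <- c("portal protein", "major capsid protein",
                       "terminase large subunit", "primase")

  mkDomainOrf <- function(l, transferred) {
    base <- lineageArrays[[l]]$domains
    m <- length(base)
    inst <- vapply(base, mutateProtein, character(1),
                   rate = cfg$copyDivergence, fixed = cfg$conservedPositions)
    del <- stats::runif(m) < cfg$nTermDeletionProb & nchar(inst) > 20L
    inst[del] <- substring(inst[del], 11L)
    flankN <- paste0("M", randomProtein(sample(9:19, 1L)))
    linkers <- vapply(seq_len(max(m - 1L, 0L)), function(i)
      randomProtein(sample(2:8, 1L)), character(1))
    flankC <- randomProtein(sample(10:20, 1L))
    prot <- flankN
    envs <- data.frame(array_position = integer(0), env_start = integer(0),
                       env_end = integer(0), sequence = character(0))
    for (i in seq_len(m)) {
      s0 <- nchar(prot)
      prot <- paste0(prot, inst[[i]])
      envs <- rbind(envs, data.frame(
        array_position = i, env_start = s0, env_end = nchar(prot),
        sequence = inst[[i]], stringsAsFactors = FALSE))
      if (i < m) prot <- paste0(prot, linkers[[i]])
    }
    prot <- paste0(prot, flankC)
    list(protein = prot, envs = envs, family = sprintf("famDomL%d", l),
         n = m, transferred = transferred, source_lineage = l)
  }

  for (l in seq_len(cfg$nLineages)) {
    for (cc in seq_len(cfg$contigsPerLineage)) {
      cid <- sprintf("L%dC%d", l, cc)
      geneCount <- sample(cfg$genesPerContig[[1L]]:cfg$genesPerContig[[2L]], 1L)
      core <- lineagePools[[l]][seq_len(cfg$coreGenes)]
      accessory <- setdiff(lineagePools[[l]], core)
      nAcc <- geneCount - cfg$coreGenes
      nShared <- min(stats::rbinom(1L, nAcc, cfg$betweenLineageSharing),
                     cfg$nSharedFamilies)
      fams <- c(core, sample(sharedPool, nShared),
                sample(accessory, nAcc - nShared))
      genes <- lapply(fams, function(f) list(
        protein = mutateProtein(famRef[[f]], cfg$familyDivergence,
                                fixed = 1L),
        family = f, domain = NULL))
      dom <- mkDomainOrf(l, transferred = FALSE)
      at <- sample(2:(geneCount - 1L), 1L)  # keep neighbours on both sides
      genes <- append(genes, list(list(protein = dom$protein,
                                       family = dom$family, domain = dom)),
                      after = at)
      # labels
      labels <- rep("hypothetical protein", length(genes))
      domIdx <- at + 1L
      nbs <- intersect(c(domIdx - 2L, domIdx - 1L, domIdx + 1L, domIdx + 2L),
                       seq_along(genes))
      isTandemLineage <- dom$n >= 2L
      lab <- switch(cfg$tailLabelPolicy,
        tandem_only = if (isTandemLineage) "tail fiber protein"
                      else sample(informativePool, 1L),
        all = "tail fiber protein",
        none = sample(informativePool, 1L))
      labels[nbs] <- lab
      extra <- sample(setdiff(seq_along(genes), c(domIdx, nbs)),
                      min(2L, max(0L, length(genes) - length(nbs) - 1L)))
      labels[extra] <- sample(informativePool, length(extra), replace = TRUE)
      orfRows[[cid]] <- list(contig = cid, lineage = l, genes = genes,
                             labels = labels, domIdx = domIdx)
    }
  }

  # horizontal transfer of domain ORFs between lineages
  if (cfg$nLineages >= 2L) {
    for (l in seq_len(cfg$nLineages)) {
      if (stats::runif(1L) >= cfg$hgtRate) next
      donor <- sample(setdiff(seq_len(cfg$nLineages), l), 1L)
      cid <- sprintf("L%dC%d", l, sample.int(cfg$contigsPerLineage, 1L))
      dom <- mkDomainOrf(donor, transferred = TRUE)
      entry <- orfRows[[cid]]
      at <- sample(seq_along(entry$genes), 1L)
      entry$genes <- append(entry$genes,
                            list(list(protein = dom$protein,
                                      family = dom$family, domain = dom)),
                            after = at)
      entry$labels <- append(entry$labels, "hypothetical protein", after = at)
      if (entry$domIdx > at) entry$domIdx <- entry$domIdx + 1L
      orfRows[[cid]] <- entry
      transferRows[[length(transferRows) + 1L]] <- data.frame(
        donor_lineage = donor, recipient_lineage = l, contig = cid,
        orf_index = at + 1L, stringsAsFactors = FALSE)
    }
  }

  # assemble DNA and the truth tables
  orfTab <- list()
  for (cid in names(orfRows)) {
    entry <- orfRows[[cid]]
    dna <- .spacer()
    for (gi in seq_along(entry$genes)) {
      g <- entry$genes[[gi]]
      oid <- sprintf("%s_g%02d", cid, gi)
      gdna <- .reverse_translate(g$protein)
      start <- nchar(dna)
      dna <- paste0(dna, gdna, .spacer())
      orfTab[[oid]] <- data.frame(
        orf_id = oid, contig_id = cid, lineage = entry$lineage,
        index_on_contig = gi - 1L, start = start,
        end = start + nchar(gdna), strand = "+",
        family = g$family, label = entry$labels[[gi]],
        protein = g$protein,
        is_domain_orf = !is.null(g$domain),
        n_domains = if (is.null(g$domain)) 0L else g$domain$n,
        stringsAsFactors = FALSE)
      if (!is.null(g$domain)) {
        e <- g$domain$envs
        e$orf_id <- oid
        e$lineage <- g$domain$source_lineage
        e$transferred <- g$domain$transferred
        domRows[[length(domRows) + 1L]] <- e
      }
    }
    contigs[[cid]] <- dna
  }
  orfs <- do.call(rbind, orfTab)
  rownames(orfs) <- NULL
  domains <- do.call(rbind, domRows)
  rownames(domains) <- NULL
  transfers <- if (length(transferRows)) do.call(rbind, transferRows) else
    data.frame(donor_lineage = integer(0), recipient_lineage = integer(0),
               contig = character(0), orf_index = integer(0))
  lineages <- stats::setNames(
    rep(seq_len(cfg$nLineages), each = cfg$contigsPerLineage),
    names(orfRows))
  list(contigs = contigs,
       truth = list(lineages = lineages, orfs = orfs, domains = domains,
                    events = eventsByLineage, transfers = transfers,
                    ancestorDomain = ancestor,
                    lineageDomains = lineageDomains,
                    lineageArrays = lapply(lineageArrays, `[[`, "domains")),
       config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Contigs as FASTA, truth as JSON, per-ORF labels as TSV, and the lineage
#' founder domains as a (trivially ungapped) Stockholm alignment.
#'
#' @param sim result of [simulateDataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeSynth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "contigs.fasta"),
    truth = file.path(dir, "truth.json"),
    labels = file.path(dir, "labels.tsv"),
    seed = file.path(dir, "lineage_domains.sto"))
  writeFasta(sim$contigs, paths[["fasta"]])
  truth <- sim$truth
  truth$events <- lapply(truth$events, as.list)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  utils::write.table(sim$truth$orfs[, c("orf_id", "label")],
                     paths[["labels"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeStockholm(msa(stats::setNames(
    sim$truth$lineageDomains,
    sprintf("lineage%d", seq_along(sim$truth$lineageDomains)))),
    paths[["seed"]])
  invisible(paths)
}

#' Carry truth functional labels over to predicted ORFs
#'
#' Matches predicted ORFs to the generator's planted ORFs by exact
#' (contig, start, end) coordinates and returns their functional labels
#' named by predicted orf_id; unmatched (e.g. spurious reverse-strand) ORFs
#' are labelled "hypothetical protein".
#'
#' @param orfs ORF table from [predictOrfs()]
#' @param truth the `truth` element of a [simulateDataset()] result
#' @return named character vector orf_id -> label
#' @export
truthLabelsFor <- function(orfs, truth) {
  key <- paste(orfs$contig_id, orfs$start, orfs$end)
  tkey <- paste(truth$orfs$contig_id, truth$orfs$start, truth$orfs$end)
  lab <- truth$orfs$label[match(key, tkey)]
  lab[is.na(lab)] <- "hypothetical protein"
  stats::setNames(lab, orfs$orf_id)
}

#' Seed profile built from planted domain instances
#'
#' Convenience constructor for a search seed: a profile HMM built from an
#' ungapped alignment of equal-length domain sequences.
#'
#' @param domains character vector of equal-length domain sequences
#' @param params a [profileParams()]
#' @return a [ProfileHMM]
#' @export
domainSeedProfile <- function(domains, params = profileParams()) {
  stopifnot(length(domains) >= 2L, length(unique(nchar(domains))) == 1L)
  buildProfile(msa(stats::setNames(domains,
                                   sprintf("d%03d", seq_along(domains)))),
               params)
}
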