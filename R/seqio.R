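# Sequence/annotation I/O, ORF prediction and table-11 translation.

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS  <- c("TAA", "TAG", "TGA")

.genetic_code_11 <- function() {
  if (is.null(.pkg_cache$GC11))
    .pkg_cache$GC11 <- Biostrings::getGeneticCode("11")
  .pkg_cache$GC11
}

#' Read a FASTA file as a named character vector
#' @param path file path
#' @return named character vector of sequences
#' @export
readFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector
#' @param path file path
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a Stockholm alignment
#'
#' Markup lines (`#=..`) are ignored; wrapped records are concatenated; gap
#' characters `.` and `-` are both normalised to `-`.
#'
#' @param path file path
#' @return an [Msa]
#' @export
readStockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[[1L]]))
    stop("not a Stockholm file: missing '# STOCKHOLM' header at line 1")
  acc <- list()
  for (i in seq_along(lines)[-1L]) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    if (startsWith(ln, "//")) break
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(tok) != 2L)
      stop(sprintf("malformed Stockholm sequence record at line %d", i))
    acc[[tok[[1L]]]] <- paste0(acc[[tok[[1L]]]] %||% "", tok[[2L]])
  }
  if (!length(acc)) stop("Stockholm file contains no sequence records")
  msa(unlist(acc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an alignment in Stockholm format
#' @param x an [Msa]
#' @param path file path
#' @export
writeStockholm <- function(x, path) {
  ids <- names(msaSeqs(x))
  w <- max(nchar(ids)) + 2L
  writeLines(c("# STOCKHOLM 1.0", "",
               sprintf("%-*s%s", w, ids, msaSeqs(x)), "//"), path)
  invisible(path)
}

#' Read a HMMER3 ASCII profile
#'
#' Parses match/insert emissions and state transitions of a HMMER3 text
#' profile (e.g. a Pfam seed profile) into a [ProfileHMM]. Per-node occupancy
#' is derived from the transition structure by the forward recurrence
#' occ\[k+1\] = occ\[k\](tMM+tMI) + (1-occ\[k\]) tDM.
#'
#' @param path file path
#' @return a [ProfileHMM]
#' @export
readHmmer <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^HMMER3", lines[[1L]]))
    stop("not a HMMER3 ASCII profile: bad magic at line 1")
  num <- function(tok) ifelse(tok == "*", Inf, suppressWarnings(as.numeric(tok)))
  leng <- as.integer(strsplit(trimws(grep("^LENG", lines, value = TRUE)[1L]),
                              "[[:space:]]+")[[1L]][2L])
  alph <- strsplit(trimws(grep("^ALPH", lines, value = TRUE)[1L]),
                   "[[:space:]]+")[[1L]][2L]
  if (tolower(alph) != "amino") stop("only amino-acid profiles are supported")
  hmmAt <- grep("^HMM\\s", lines)[1L]
  resOrder <- strsplit(trimws(lines[[hmmAt]]), "[[:space:]]+")[[1L]][-1L]
  if (!identical(resOrder, AA20))
    stop("unexpected residue ordering in HMM emission header")
  i <- hmmAt + 2L  # skip transition header line
  bg <- AA_BACKGROUND
  tok <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
  if (identical(tok[[1L]], "COMPO")) {
    bg <- exp(-num(tok[-1L]))
    bg <- bg / sum(bg)
    i <- i + 1L
  }
  i <- i + 1L  # node-0 insert emissions (background inserts, not used)
  t0 <- num(strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]])[1:3]
  i <- i + 1L
  mE <- matrix(0, leng, 20L)
  iE <- matrix(0, leng, 20L)
  tr <- matrix(0, leng, 7L)
  for (k in seq_len(leng)) {
    mt <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
    if (as.integer(mt[[1L]]) != k)
      stop(sprintf("HMMER3 parse error: expected node %d at line %d", k, i))
    mE[k, ] <- exp(-num(mt[2:21]))
    it <- strsplit(trimws(lines[[i + 1L]]), "[[:space:]]+")[[1L]]
    iE[k, ] <- exp(-num(it[1:20]))
    tt <- num(strsplit(trimws(lines[[i + 2L]]), "[[:space:]]+")[[1L]])[1:7]
    tr[k, ] <- exp(-tt)
    i <- i + 3L
  }
  mE <- mE / rowSums(mE)
  iE <- iE / rowSums(iE)
  # renormalise transition bundles; node L's M->E exit is dropped
  normBundle <- function(x) if (sum(x) > 0) x / sum(x) else rep(1 / length(x), length(x))
  if (leng > 1L) {
    tr <- tr[-leng, , drop = FALSE]
    for (r in seq_len(nrow(tr))) {
      tr[r, 1:3] <- normBundle(tr[r, 1:3])
      tr[r, 4:5] <- normBundle(tr[r, 4:5])
      tr[r, 6:7] <- normBundle(tr[r, 6:7])
    }
  } else tr <- matrix(0, 0L, 7L)
  pBM <- exp(-t0[[1L]]); pBD <- exp(-t0[[3L]])
  occ <- numeric(leng)
  occ[1L] <- pBM / (pBM + pBD)
  if (leng > 1L)
    for (k in seq_len(leng - 1L))
      occ[k + 1L] <- occ[k] * (tr[k, 1L] + tr[k, 2L]) + (1 - occ[k]) * tr[k, 6L]
  occ <- pmin(pmax(occ, 0), 1)
  new("ProfileHMM", matchEmissions = mE, insertEmissions = iE,
      transitions = tr, background = bg / sum(bg), occupancy = occ,
      consensus = AA20[apply(mE, 1L, which.max)])
}

#' Write ORFs (and optional domain hits) as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 output is 1-based
#' inclusive. Domain hits are written as `protein_match` children of their
#' ORF with residue envelopes mapped to nucleotide coordinates.
#'
#' @param orfs ORF table from [predictOrfs()]
#' @param path file path
#' @param hits optional domain-hit table (orf_id, env_start, env_end, bit_score)
#' @export
writeGff3 <- function(orfs, path, hits = NULL) {
  att <- function(...) paste(..., sep = ";")
  rows <- sprintf("%s\tbaconscope\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                  orfs$contig_id, orfs$start + 1L, orfs$end, orfs$strand,
                  orfs$orf_id)
  if (!is.null(hits) && nrow(hits)) {
    m <- match(hits$orf_id, orfs$orf_id)
    if (anyNA(m)) stop("hit refers to unknown orf_id")
    plus <- orfs$strand[m] == "+"
    nts <- ifelse(plus, orfs$start[m] + 3L * hits$env_start,
                  orfs$end[m] - 3L * hits$env_end)
    nte <- ifelse(plus, orfs$start[m] + 3L * hits$env_end,
                  orfs$end[m] - 3L * hits$env_start)
    rows <- c(rows, sprintf(
      "%s\tbaconscope\tprotein_match\t%d\t%d\t%.1f\t%s\t.\t%s",
      orfs$contig_id[m], nts + 1L, nte, hits$bit_score, orfs$strand[m],
      att(sprintf("ID=%s.d%d", hits$orf_id, seq_len(nrow(hits))),
          sprintf("Parent=%s", hits$orf_id))))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read a GFF3 file into a feature table
#' @param path file path
#' @return data.frame with contig_id, type, start (0-based), end, strand, id
#' @export
readGff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    return(data.frame(contig_id = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), id = character(0)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad))
    stop(sprintf("malformed GFF3 record at line %d (expected 9 columns)",
                 which(lines == body[bad[1L]])[1L]))
  m <- do.call(rbind, parts)
  id <- sub("^ID=([^;]+).*$", "\\1", m[, 9L])
  data.frame(contig_id = m[, 1L], type = m[, 3L],
             start = as.integer(m[, 4L]) - 1L, end = as.integer(m[, 5L]),
             strand = m[, 7L], id = id, stringsAsFactors = FALSE)
}

#' Read or write records in one of the pipeline's interchange formats
#'
#' Supported formats: `FASTA`, `Stockholm`, `GFF3`, `Newick`,
#' `HMMER3-ASCII` (read only) and `TSV`.
#'
#' @param path file path
#' @param format one of the supported format names
#' @return format-specific records
#' @export
readRecords <- function(path, format) {
  switch(format,
    "FASTA" = readFasta(path),
    "Stockholm" = readStockholm(path),
    "GFF3" = readGff3(path),
    "Newick" = ape::read.tree(path),
    "HMMER3-ASCII" = readHmmer(path),
    "TSV" = utils::read.delim(path, stringsAsFactors = FALSE),
    stop(sprintf("unknown format '%s'", format)))
}

#' @rdname readRecords
#' @param x records to write (type must match the format)
#' @export
writeRecords <- function(x, path, format) {
  switch(format,
    "FASTA" = writeFasta(x, path),
    "Stockholm" = writeStockholm(x, path),
    "GFF3" = writeGff3(x, path),
    "Newick" = { ape::write.tree(x, path); invisible(path) },
    "TSV" = { utils::write.table(x, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE); invisible(path) },
    "HMMER3-ASCII" = stop("HMMER3-ASCII profiles are read-only"),
    stop(sprintf("unknown format '%s'", format)))
}

#' Translate DNA under translation table 11
#'
#' Codons containing ambiguity codes are skipped (no `X` emitted) so the
#' resulting protein is scoreable. A terminal stop codon is consumed; an
#' internal stop is an error.
#'
#' @param dna DNA string, length divisible by 3
#' @return amino-acid string
#' @export
translateDna <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("DNA length must be divisible by 3")
  if (n == 0L) return("")
  gc <- .genetic_code_11()
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- gc[codons]
  last <- length(codons)
  stops <- which(!is.na(aa) & aa == "*")
  if (length(stops)) {
    if (any(stops < last))
      stop(sprintf("internal stop codon at codon position %d", stops[1L]))
    aa <- aa[-last]
  }
  paste(aa[!is.na(aa)], collapse = "")
}

#' Predict maximal ORFs on both strands under translation table 11
#'
#' A maximal ORF runs from the first start codon (ATG/GTG/TTG) after the
#' previous in-frame stop through its own stop codon (TAA/TAG/TGA), on either
#' strand. Coordinates are 0-based half-open on the forward strand.
#'
#' @param contigs named character vector of DNA contigs (or one unnamed string)
#' @param minAaLength minimum translated length in residues (default 30)
#' @return data.frame: orf_id, contig_id, start, end, strand, protein,
#'   index_on_contig (rank by start within contig)
#' @export
predictOrfs <- function(contigs, minAaLength = 30L) {
  stopifnot(minAaLength >= 1L)
  if (is.null(names(contigs)))
    names(contigs) <- if (length(contigs) == 1L) "contig" else
      paste0("contig", seq_along(contigs))
  out <- lapply(names(contigs), function(cid)
    .predict_orfs_one(toupper(contigs[[cid]]), cid, minAaLength))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.predict_orfs_one <- function(dna, contigId, minAaLength) {
  empty <- data.frame(orf_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0),
                      index_on_contig = integer(0), stringsAsFactors = FALSE)
  n <- nchar(dna)
  if (n < 3L) return(empty)
  found <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revComp(dna)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 2L) next
      codons <- substring(s, f + 1L + 3L * (0:(ncod - 1L)),
                          f + 3L + 3L * (0:(ncod - 1L)))
      isStop <- codons %in% STOP_CODONS
      isStart <- codons %in% START_CODONS
      seg <- 1L
      for (st in which(isStop)) {
        cand <- which(isStart[seg:(st - 1L)])
        if (st > seg && length(cand)) {
          a <- seg + cand[[1L]] - 1L
          if (st - a >= minAaLength) {
            s0 <- f + 3L * (a - 1L)       # 0-based on strand s
            e0 <- f + 3L * st
            prot <- translateDna(substr(s, s0 + 1L, e0))
            if (nchar(prot) >= minAaLength) {
              fs <- if (strand == "+") s0 else n - e0
              fe <- if (strand == "+") e0 else n - s0
              found[[length(found) + 1L]] <-
                list(start = fs, end = fe, strand = strand, protein = prot)
            }
          }
        }
        seg <- st + 1L
      }
    }
  }
  if (!length(found)) return(empty)
  df <- data.frame(
    contig_id = contigId,
    start = vapply(found, `[[`, integer(1), "start"),
    end = vapply(found, `[[`, integer(1), "end"),
    strand = vapply(found, `[[`, character(1), "strand"),
    protein = vapply(found, `[[`, character(1), "protein"),
    stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  df$index_on_contig <- seq_len(nrow(df)) - 1L
  df$orf_id <- sprintf("%s_orf%03d", contigId, df$index_on_contig + 1L)
  df[, c("orf_id", "contig_id", "start", "end", "strand", "protein",
         "index_on_contig")]
}
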