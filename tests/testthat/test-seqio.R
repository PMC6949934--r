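# Format round-trips, ORF prediction and table-11 translation.

# independent six-frame ORF enumeration used as oracle for predictOrfs
bruteOrfs <- function(dna, minAa) {
  gc <- Biostrings::getGeneticCode("11")
  out <- list()
  n <- nchar(dna)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revComp(dna)
    for (f in 0:2) {
      i <- f + 1L
      while (i + 2L <= n) {  # candidate start positions in this frame
        cod <- substr(s, i, i + 2L)
        if (cod %in% c("ATG", "GTG", "TTG")) {
          # preceded by an in-frame stop or frame start?
          j <- i - 3L
          open <- TRUE
          while (j >= 1L) {
            cj <- substr(s, j, j + 2L)
            if (cj %in% c("TAA", "TAG", "TGA")) break
            if (cj %in% c("ATG", "GTG", "TTG")) { open <- FALSE; break }
            j <- j - 3L
          }
          if (open) {
            k <- i + 3L
            while (k + 2L <= n &&
                   !(substr(s, k, k + 2L) %in% c("TAA", "TAG", "TGA")))
              k <- k + 3L
            if (k + 2L <= n && (k - i) / 3L >= minAa) {
              s0 <- i - 1L; e0 <- k + 2L
              fs <- if (strand == "+") s0 else n - e0
              fe <- if (strand == "+") e0 else n - s0
              out[[length(out) + 1L]] <- c(fs, fe)
            }
          }
        }
        i <- i + 3L
      }
    }
  }
  unique(out)
}

test_that("FASTA and Stockholm round-trips preserve content", {
  tmp <- tempfile(fileext = ".fa")
  seqs <- c(ctgA = "ACGTACGTAA", ctgB = "TTTTGGGGCCCC")
  writeFasta(seqs, tmp)
  expect_identical(readFasta(tmp), seqs)

  al <- msa(c(s1 = "MK-W", s2 = "MKAW", s3 = "M--W"))
  sto <- tempfile(fileext = ".sto")
  writeStockholm(al, sto)
  expect_identical(msaSeqs(readStockholm(sto)), msaSeqs(al))
})

test_that("Stockholm parsing normalises '.' gaps and flags malformed lines", {
  f <- tempfile()
  writeLines(c("# STOCKHOLM 1.0", "", "seq1  MK.W-", "seq2  MKAWA",
               "#=GC RF  xxxxx", "//"), f)
  al <- readStockholm(f)
  expect_identical(msaSeqs(al)[["seq1"]], "MK-W-")
  expect_equal(nrow(al), 2L)

  bad <- tempfile()
  writeLines(c("# STOCKHOLM 1.0", "seq1"), bad)
  expect_error(readStockholm(bad), "line 2")
  nohdr <- tempfile()
  writeLines("seq1 MKW", nohdr)
  expect_error(readStockholm(nohdr), "line 1")
})

test_that("HMMER3 ASCII seed profile parses with 45 match states and landmarks", {
  hmmPath <- system.file("extdata", "synthetic_bacon_seed.hmm",
                         package = "baconscope")
  p <- readHmmer(hmmPath)
  expect_s4_class(p, "ProfileHMM")
  expect_identical(profileLength(p), 45L)
  cons <- strsplit(profileConsensus(p), "")[[1]]
  # the four strongly conserved residues of the seed family
  expect_identical(cons[c(5, 20, 26, 40)], c("W", "N", "R", "Q"))
  expect_true(all(abs(rowSums(p@matchEmissions) - 1) < 1e-9))
  # LENG in the file itself agrees with the parse
  leng <- as.integer(strsplit(trimws(grep("^LENG",
    readLines(hmmPath), value = TRUE)[1]), "\\s+")[[1]][2])
  expect_identical(leng, profileLength(p))
})

test_that("GFF3 output is 1-based inclusive and round-trips coordinates", {
  orfs <- data.frame(orf_id = c("c1_orf001", "c1_orf002"),
                     contig_id = "c1", start = c(0L, 30L), end = c(9L, 120L),
                     strand = c("+", "-"),
                     protein = c("MK", strrep("A", 29)),
                     index_on_contig = 0:1, stringsAsFactors = FALSE)
  hits <- data.frame(orf_id = "c1_orf002", env_start = 2L, env_end = 10L,
                     bit_score = 33.3, stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".gff3")
  writeGff3(orfs, f, hits = hits)
  back <- readGff3(f)
  cds <- back[back$type == "CDS", ]
  expect_equal(cds$start, orfs$start)
  expect_equal(cds$end, orfs$end)
  expect_equal(cds$id, orfs$orf_id)
  # 1-based inclusive on disk
  raw <- readLines(f)
  expect_true(any(grepl("\tCDS\t1\t9\t", raw)))
  # rtracklayer reads the same coordinates (independent GFF3 implementation)
  gr <- rtracklayer::import(f)
  expect_equal(sort(BiocGenerics::start(gr)[gr$type == "CDS"]),
               sort(orfs$start + 1L))
  expect_equal(sort(BiocGenerics::end(gr)[gr$type == "CDS"]),
               sort(orfs$end))
})

test_that("Newick and TSV dispatch through the format gateway", {
  tr <- ape::rtree(5)
  f <- tempfile(fileext = ".nwk")
  writeRecords(tr, f, "Newick")
  back <- readRecords(f, "Newick")
  expect_true(ape::dist.topo(ape::unroot(tr), ape::unroot(back)) == 0)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-8)
  expect_error(readRecords(f, "nonsense"), "unknown format")
  expect_error(writeRecords(NULL, f, "HMMER3-ASCII"), "read-only")
})

test_that("translation table 11 handles stops and ambiguity codes", {
  expect_identical(translateDna("ATGGTG"), "MV")
  expect_identical(translateDna("TGA"), "")            # terminal stop consumed
  expect_identical(translateDna("ATGNNNAAA"), "MK")    # N codon skipped
  expect_error(translateDna("ATGTAAAAA"), "codon position 2")
  expect_error(translateDna("ATGA"), "divisible by 3")
  # random 30-codon fixture equals direct codon-table lookup
  set.seed(404)
  gc <- Biostrings::getGeneticCode("11")
  sense <- names(gc)[gc != "*"]
  codons <- sample(sense, 30, replace = TRUE)
  expect_identical(translateDna(paste(codons, collapse = "")),
                   paste(gc[codons], collapse = ""))
})

test_that("predictOrfs finds maximal ORFs on both strands", {
  o <- predictOrfs(c(x = "ATGAAATAA"), minAaLength = 2)
  expect_equal(nrow(o), 1L)
  expect_identical(o$protein, "MK")
  expect_equal(c(o$start, o$end), c(0L, 9L))

  expect_equal(nrow(predictOrfs(c(x = strrep("N", 120)), minAaLength = 2)), 0L)

  # reverse-strand ORF and oracle agreement on random fixtures
  set.seed(77)
  for (rep in 1:5) {
    dna <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    got <- predictOrfs(c(z = dna), minAaLength = 10)
    want <- bruteOrfs(dna, 10)
    expect_setequal(sprintf("%d-%d", got$start, got$end),
                    vapply(want, function(w) sprintf("%d-%d", w[1], w[2]),
                           character(1)))
  }
})

test_that("ORF coordinates map back to their protein on either strand", {
  set.seed(11)
  sim <- simulateDataset(synthConfig(seed = 303L, nLineages = 2L,
                                     contigsPerLineage = 1L))
  orfs <- predictOrfs(sim$contigs)
  for (r in sample(nrow(orfs), 20)) {
    dna <- substr(sim$contigs[[orfs$contig_id[r]]],
                  orfs$start[r] + 1L, orfs$end[r])
    if (orfs$strand[r] == "-") dna <- revComp(dna)
    expect_identical(translateDna(dna), orfs$protein[r])
  }
  # deterministic and invariant to contig id
  a <- predictOrfs(c(foo = sim$contigs[[1]]))
  b <- predictOrfs(c(bar = sim$contigs[[1]]))
  expect_equal(a[, c("start", "end", "strand", "protein")],
               b[, c("start", "end", "strand", "protein")])
})
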