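# Alignment, trimming, distances, NJ trees, clades, duplication mode.

test_that("progressive alignment matches hand-computed pairwise DP", {
  al <- alignProteins(c(a = "MKW", b = "MW"))
  sub <- baconscope:::blosum62()
  rows <- msaSeqs(al)
  expect_equal(msaWidth(al), 3)
  # realised alignment score equals the NW optimum from a hand DP table
  sc <- alignmentScoreManual(rows[["a"]], rows[["b"]], sub, 10, 1)
  expect_equal(sc, nwScoreManual("MKW", "MW", sub, 10, 1))

  ident <- alignProteins(c(x = "MKWNR", y = "MKWNR"))
  expect_identical(unname(msaSeqs(ident)), c("MKWNR", "MKWNR"))

  single <- alignProteins(c(only = "MKW"))
  expect_identical(msaSeqs(single), c(only = "MKW"))

  # order invariance via the lexicographic tie rule
  set.seed(50)
  seqs <- stats::setNames(vapply(1:6, function(i)
    mutateProtein("MKWNRQAYLTCDEFGHIKLMW", 0.15), character(1)),
    sprintf("s%d", 1:6))
  a1 <- alignProteins(seqs)
  a2 <- alignProteins(rev(seqs))
  expect_identical(msaSeqs(a1), msaSeqs(a2))
})

test_that("planted conserved residues align into single columns", {
  set.seed(73)
  anc <- baconscope:::randomProtein(45)
  a <- strsplit(anc, "")[[1]]; a[c(5, 20, 26, 40)] <- c("W", "N", "R", "Q")
  anc <- paste(a, collapse = "")
  doms <- stats::setNames(vapply(1:8, function(i)
    mutateProtein(anc, 0.2, fixed = c(5, 20, 26, 40)), character(1)),
    sprintf("d%d", 1:8))
  al <- alignProteins(doms)
  m <- as.matrix(al)
  for (res in c("W", "N", "R", "Q")) {
    hom <- which(apply(m, 2, function(col) all(col == res)))
    expect_gte(length(hom), 1)
  }
  # and they survive trimming at gt = 0.4
  tm <- as.matrix(trimAlignment(al, 0.4))
  for (res in c("W", "N", "R", "Q"))
    expect_gte(sum(apply(tm, 2, function(col) all(col == res))), 1)
})

test_that("gap-threshold trimming follows the non-gap fraction rule", {
  rows <- c(sprintf("r%02d", 1:25))
  seqs <- stats::setNames(rep("AC-D", 25), rows)
  seqs[1] <- "ACWD"  # column 3: 4% occupied; removed at gt = 0.05
  al <- msa(seqs)
  tr <- trimAlignment(al, 0.05)
  expect_equal(msaWidth(tr), 3)
  expect_equal(attr(tr, "removed"), 3L)
  # gap-free columns survive any threshold
  expect_equal(msaWidth(trimAlignment(al, 1)), 3)
  # gt = 0 is the identity, and trimming is idempotent
  expect_identical(msaSeqs(trimAlignment(al, 0)), msaSeqs(al))
  expect_identical(msaSeqs(trimAlignment(tr, 0.05)), msaSeqs(tr))
  # 10-column toy alignment against direct per-column gap counts
  set.seed(12)
  toy <- msa(c(a = "AC-DE--FGH", b = "ACWDE--F-H", c = "-C-DE-WFGH"))
  keepWant <- which(colMeans(as.matrix(toy) != "-") >= 0.4)
  tt <- trimAlignment(toy, 0.4)
  expect_equal(setdiff(1:10, attr(tt, "removed")), keepWant)
  expect_error(trimAlignment(msa(c(a = "--", b = "--")), 0.5), "all columns")
})

test_that("concatenation pads missing rows and rejects disjoint blocks", {
  m1 <- msa(c(a = "MKWNR", b = "MKWNR"))
  m2 <- msa(c(a = "QAYLT", b = "QAYLT"))
  cc <- concatAlignments(list(m1, m2))
  expect_equal(msaWidth(cc), 10)
  expect_equal(attr(cc, "provenance"), rep(1:2, each = 5))
  m3 <- msa(c(a = "DDD", c = "EEE"))
  cc2 <- concatAlignments(list(m1, m3))
  expect_identical(msaSeqs(cc2)[["c"]], "-----EEE")
  expect_identical(msaSeqs(cc2)[["b"]], "MKWNR---")
  expect_error(concatAlignments(list(m1, msa(c(z = "FFF")))), "disjoint")
})

test_that("Kimura-corrected distances follow the closed form and saturate safely", {
  al <- msa(c(a = strrep("A", 20), b = strrep("A", 20), c = strrep("C", 20)))
  D <- proteinDistances(al)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 10)  # saturated, capped and flagged
  expect_true(attr(D, "flagged")["a", "c"])
  # p = 0.1 example: 2 mismatches in 20 shared columns
  al2 <- msa(c(a = "AAAAAAAAAAAAAAAAAAAA", b = "CCAAAAAAAAAAAAAAAAAA",
               c = strrep("A", 20)))
  D2 <- proteinDistances(al2)
  expect_equal(D2["a", "b"], -log(1 - 0.1 - 0.2 * 0.01), tolerance = 1e-12)
  expect_equal(round(D2[["a", "b"]], 4), 0.1076)
  # short overlap is flagged
  al3 <- msa(c(a = "MK------", b = "--WN----", c = "MKWN----"))
  expect_true(attr(proteinDistances(al3), "flagged")["a", "b"])
})

test_that("NJ is exact on additive matrices and gives closed-form 3-taxon stars", {
  set.seed(8)
  for (nt in 4:12) {
    tree <- ape::rtree(nt, br = function(n) stats::runif(n, 0.2, 1))
    D <- additiveMatrix(tree)
    est <- njTree(D)
    expect_true(ape::dist.topo(ape::unroot(tree), est) == 0)
    expect_equal(max(abs(additiveMatrix(est)[rownames(D), colnames(D)] - D)),
                 0, tolerance = 1e-8)
  }
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- njTree(D3)
  bl <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)
  expect_error(njTree(matrix(c(0, Inf, Inf, 0), 2)), "non-finite")
})

test_that("bootstrap supports clean separable clades above 90", {
  set.seed(55)
  a1 <- baconscope:::randomProtein(60)
  a2 <- baconscope:::randomProtein(60)
  seqs <- c(
    stats::setNames(vapply(1:4, function(i) mutateProtein(a1, 0.05),
                           character(1)), sprintf("g1_%d", 1:4)),
    stats::setNames(vapply(1:4, function(i) mutateProtein(a2, 0.05),
                           character(1)), sprintf("g2_%d", 1:4)))
  al <- alignProteins(seqs)
  tr <- bootstrapNj(al, B = 100, seed = 6)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 100))
  expect_true(ape::is.monophyletic(tr, sprintf("g1_%d", 1:4)))
  # the split separating the two families is near-unanimous
  mrca <- ape::getMRCA(tr, sprintf("g1_%d", 1:4))
  expect_gt(tr$node.label[mrca - ape::Ntip(tr)], 90)
})

test_that("position classes on a perfectly partitioned tree are pure clades", {
  nwk <- "(((p1a:1,p1b:1):2,(p2a:1,p2b:1):2):1,((p3a:1,p3b:1):2,bact:3):1);"
  tree <- ape::read.tree(text = nwk)
  labs <- c(p1a = 1, p1b = 1, p2a = 2, p2b = 2, p3a = 3, p3b = 3)
  pc <- positionClades(tree, labs)
  expect_true(all(pc$perClass$monophyletic))
  expect_equal(pc$perClass$purity, rep(1, 3))
  # the bacterial leaf votes for its nearest position class
  expect_identical(pc$candidateAncestral, "3")
  # star tree: no class of size >= 2 is monophyletic
  star <- ape::read.tree(text = "(p1a:1,p1b:1,p2a:1,p2b:1);")
  pcs <- positionClades(star, labs[1:4])
  expect_false(any(pcs$perClass$monophyletic))
  expect_error(positionClades(tree, labs[0]), "no labelled")
})

test_that("duplication mode separates single-domain from block histories", {
  set.seed(5)
  anc <- baconscope:::randomProtein(45)
  # identical domains: flat profile, no block signal
  flat <- duplicationMode(rep(anc, 5))
  expect_identical(flat$mode, "single")
  expect_error(duplicationMode(rep(anc, 2)), "fewer than 3")

  one <- function(mode) {
    ev <- baconscope:::.sample_events(8L, mode)
    duplicationMode(replayHistory(anc, ev, 0.08)$domains)
  }
  singles <- replicate(25, one("single")$mode)
  blocks <- vapply(1:25, function(i) {
    r <- one(list(mode = "block", blockSize = 2L))
    paste(r$mode, r$blockSize)
  }, character(1))
  expect_gte(mean(singles == "single"), 0.9)
  expect_gte(mean(blocks == "block 2"), 0.9)
})

test_that("distances increase monotonically with simulated divergence", {
  set.seed(31)
  anc <- baconscope:::randomProtein(45)
  levels <- c(0.02, 0.08, 0.15, 0.25, 0.4)
  meanD <- vapply(levels, function(dv) {
    seqs <- stats::setNames(vapply(1:6, function(i)
      mutateProtein(anc, dv), character(1)), sprintf("s%d", 1:6))
    D <- proteinDistances(alignProteins(seqs))
    mean(D[upper.tri(D)])
  }, numeric(1))
  expect_true(all(diff(meanD) > 0))
})
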