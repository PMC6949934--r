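# Profile construction, Viterbi search, iterative refinement, column stats.

test_that("buildProfile concentrates emissions on the consensus", {
  al <- msa(c(a = "MKWNR", b = "MKWNR", c = "MKWNR", d = "MKWNR"))
  p <- buildProfile(al)
  expect_equal(profileLength(p), 5L)
  expect_identical(profileConsensus(p), "MKWNR")
  idx <- match(c("M", "K", "W", "N", "R"), baconscope:::AA20)
  for (k in 1:5)
    expect_identical(which.max(p@matchEmissions[k, ]), idx[k])
  expect_equal(profileOccupancy(p), rep(1, 5))
})

test_that("gappy columns become inserts, never match states", {
  rows <- c(sprintf("s%02d", 1:25))
  seqs <- stats::setNames(rep("MK-W", 25), rows)
  seqs[1] <- "MKAW"  # 4% occupancy in column 3
  p <- buildProfile(msa(seqs))
  expect_equal(profileLength(p), 3L)
  cs <- columnStats(msa(seqs))
  expect_false(cs$is_match[3])
  expect_true(all(cs$is_match[c(1, 2, 4)]))
  expect_error(buildProfile(msa(c(a = "--", b = "--", c = "M-")),
                            profileParams(matchColumnThreshold = 0.5)),
               "zero match columns")
})

test_that("emission rows, transition bundles and occupancy satisfy the model contract", {
  set.seed(52)
  rows <- vapply(1:12, function(i) mutateProtein("MKWNRQAYLT", 0.2),
                 character(1))
  gap <- seq(4, 12, by = 4)
  rows[gap] <- paste0(substr(rows[gap], 1, 2), "-", substr(rows[gap], 4, 10))
  p <- buildProfile(msa(stats::setNames(rows, sprintf("r%02d", 1:12))))
  expect_true(all(abs(rowSums(p@matchEmissions) - 1) < 1e-9))
  tr <- p@transitions
  expect_true(all(abs(rowSums(tr[, 1:3, drop = FALSE]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(tr[, 4:5, drop = FALSE]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(tr[, 6:7, drop = FALSE]) - 1) < 1e-9))
  expect_true(all(p@occupancy >= 0 & p@occupancy <= 1))
})

test_that("profile rebuilt from its own repeated consensus is emission-idempotent as alpha -> 0", {
  cons <- "MKWNRQAYLT"
  al <- msa(stats::setNames(rep(cons, 20), sprintf("c%02d", 1:20)))
  p <- buildProfile(al, profileParams(pseudocountWeight = 1e-8))
  idx <- encodeProtein(cons)
  for (k in seq_along(idx))
    expect_equal(p@matchEmissions[k, idx[k]], 1, tolerance = 1e-6)
})

test_that("Viterbi search equals brute-force path enumeration on small profiles", {
  set.seed(21)
  for (L in 1:5) {
    for (rep in 1:3) {
      prof <- randomSmallProfile(L)
      for (n in 1:6) {
        prot <- paste(sample(baconscope:::AA20[1:4], n, replace = TRUE),
                      collapse = "")
        bf <- bruteForceViterbi(prof, prot)
        h <- searchProfile(prof, prot, profileParams(scoreThresholdBits = -1e6))
        vit <- if (nrow(h)) max(h$bit_score) else -Inf
        expect_equal(vit, bf, tolerance = 1e-8)
      }
    }
  }
})

test_that("a consensus protein is the top-scoring sequence of its length", {
  set.seed(33)
  doms <- vapply(1:20, function(i) mutateProtein("MKWNRQAYLTCDEFGHIKLM", 0.1),
                 character(1))
  p <- domainSeedProfile(doms)
  cons <- profileConsensus(p)
  hc <- searchProfile(p, cons, profileParams(scoreThresholdBits = -1e6))
  expect_equal(nrow(hc), 1L)
  expect_equal(c(hc$env_start, hc$env_end), c(0L, nchar(cons)))
  for (i in 1:50) {
    rnd <- baconscope:::randomProtein(nchar(cons))
    hr <- searchProfile(p, rnd, profileParams(scoreThresholdBits = -1e6))
    sc <- if (nrow(hr)) max(hr$bit_score) else -Inf
    expect_lte(sc, hc$bit_score)
  }
})

test_that("two domain copies give two non-overlapping hits scoring like each half", {
  set.seed(9)
  dom <- baconscope:::randomProtein(30)
  p <- domainSeedProfile(rep(dom, 5))
  spacer <- baconscope:::randomProtein(20)
  prot <- paste0(dom, spacer, dom)
  h <- searchProfile(p, prot)
  expect_equal(nrow(h), 2L)
  expect_true(h$env_end[1] <= h$env_start[2])
  # oracle: score each half independently
  h1 <- searchProfile(p, dom)
  expect_equal(h$bit_score, rep(h1$bit_score, 2), tolerance = 1e-6)
})

test_that("iterative search is a fixed point on perfectly matching proteins", {
  set.seed(14)
  dom <- baconscope:::randomProtein(40)
  seed <- domainSeedProfile(rep(dom, 4))
  prots <- stats::setNames(
    vapply(1:10, function(i)
      paste0(baconscope:::randomProtein(15), dom,
             baconscope:::randomProtein(15)), character(1)),
    sprintf("p%02d", 1:10))
  res <- iterativeSearch(seed, prots)
  expect_true(res$converged)
  expect_equal(res$iterations, 2L)  # second pass reproduces the first
  expect_equal(nrow(res$hits), 10L)
  # every reported hit scores >= threshold under the final profile
  for (r in seq_len(nrow(res$hits))) {
    hh <- searchProfile(res$profile, prots[[res$hits$orf_id[r]]])
    expect_true(any(hh$env_start == res$hits$env_start[r] &
                      hh$bit_score >= profileParams()$scoreThresholdBits))
  }
})

test_that("iterative refinement recovers diverged domains the seed misses", {
  set.seed(88)
  anc <- baconscope:::randomProtein(45)
  seedDoms <- vapply(1:15, function(i) mutateProtein(anc, 0.05), character(1))
  seed <- domainSeedProfile(seedDoms)
  mk <- function(rate) paste0(baconscope:::randomProtein(20),
                              mutateProtein(anc, rate),
                              baconscope:::randomProtein(20))
  near <- vapply(1:10, function(i) mk(0.15), character(1))
  far <- vapply(1:10, function(i) mk(0.45), character(1))
  prots <- stats::setNames(c(near, far), sprintf("p%02d", 1:20))
  first <- searchProteins(seed, prots)
  res <- iterativeSearch(seed, prots)
  expect_gte(nrow(res$hits), nrow(first))
  expect_gte(res$iterations, 2L)
  # zero hits on an unrelated protein set returns the seed with a warning
  junk <- stats::setNames(vapply(1:5, function(i)
    baconscope:::randomProtein(60), character(1)), sprintf("j%d", 1:5))
  expect_warning(res0 <- iterativeSearch(seed, junk), "no hits")
  expect_identical(res0$status, "no_hits")
  expect_equal(nrow(res0$hits), 0L)
})

test_that("column statistics match the entropy formula", {
  al <- msa(c(a = "WAC", b = "WCC", c = "WDG", d = "WE-"))
  cs <- columnStats(al)
  expect_equal(cs$information_bits[1], log2(20), tolerance = 1e-9)
  expect_equal(cs$conservation[1], 1)
  # column 2: four distinct residues, uniform -> IC = log2(20) - 2
  expect_equal(cs$information_bits[2], log2(20) - 2, tolerance = 1e-9)
  # column 3: C,C,G over 3 residues (one gap)
  h3 <- -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3)
  expect_equal(cs$information_bits[3], log2(20) - h3, tolerance = 1e-9)
  expect_equal(cs$occupancy[3], 3 / 4)
  # all-gap column reports zero information, zero occupancy
  cs2 <- columnStats(msa(c(a = "M-", b = "M-")))
  expect_equal(cs2$information_bits[2], 0)
  expect_equal(cs2$occupancy[2], 0)
})
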