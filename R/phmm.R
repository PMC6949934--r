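# Profile HMM construction, local Viterbi domain search, iterative
# search-to-convergence refinement, and per-column alignment statistics.

#' Parameters for profile construction and search
#'
#' @param matchColumnThreshold minimum non-gap fraction for a column to become
#'   a match state (default 0.5)
#' @param pseudocountWeight Dirichlet pseudocount weight alpha added as
#'   alpha * background to emission counts (default 1)
#' @param scoreThresholdBits minimum reported hit score in bits (default 22,
#'   calibrated so that length-matched shuffled decoys score below threshold
#'   with a multi-bit margin; see the methods vignette)
#' @return a ProfileParams list
#' @export
profileParams <- function(matchColumnThreshold = 0.5, pseudocountWeight = 1,
                          scoreThresholdBits = 22) {
  stopifnot(matchColumnThreshold >= 0, matchColumnThreshold <= 1,
            pseudocountWeight > 0)
  structure(list(matchColumnThreshold = matchColumnThreshold,
                 pseudocountWeight = pseudocountWeight,
                 scoreThresholdBits = scoreThresholdBits),
            class = "ProfileParams")
}

#' Build a profile HMM from a multiple alignment
#'
#' Columns whose non-gap fraction reaches `matchColumnThreshold` become match
#' states; other columns feed insert-state transition counts. Emissions are
#' (counts + alpha * background) / (total + alpha); transitions get a uniform
#' Laplace pseudocount. Occupancy of node k is the non-gap fraction of its
#' source column.
#'
#' @param x an [Msa]
#' @param params a [profileParams()] list
#' @return a [ProfileHMM]
#' @export
buildProfile <- function(x, params = profileParams()) {
  m <- as.matrix(x)
  if (nrow(m) < 2L) stop("alignment must have at least 2 rows")
  isRes <- matrix(m %in% AA20, nrow(m), ncol(m))
  nonGapFrac <- colMeans(isRes)
  isMatch <- nonGapFrac >= params$matchColumnThreshold
  L <- sum(isMatch)
  if (L == 0L) stop("alignment has zero match columns at this threshold")
  alpha <- params$pseudocountWeight
  bg <- AA_BACKGROUND
  matchCols <- which(isMatch)
  mE <- matrix(0, L, 20L)
  for (k in seq_len(L)) {
    col <- m[, matchCols[[k]]]
    cnt <- table(factor(col[col %in% AA20], levels = AA20))
    mE[k, ] <- (as.numeric(cnt) + alpha * bg) / (sum(cnt) + alpha)
  }
  occ <- nonGapFrac[matchCols]
  # transition counts from per-sequence state paths over the match columns
  cn <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  tc <- matrix(0, max(L - 1L, 0L), 7L, dimnames = list(NULL, cn))
  if (L > 1L) {
    nodeOf <- cumsum(isMatch)             # node index per column (0 before node 1)
    for (r in seq_len(nrow(m))) {
      res <- isRes[r, ]
      for (k in seq_len(L - 1L)) {
        c1 <- matchCols[[k]]; c2 <- matchCols[[k + 1L]]
        s1 <- if (res[[c1]]) "M" else "D"
        s2 <- if (res[[c2]]) "M" else "D"
        nIns <- if (c2 > c1 + 1L) sum(res[(c1 + 1L):(c2 - 1L)]) else 0L
        if (nIns == 0L) {
          tc[k, paste0(s1, s2)] <- tc[k, paste0(s1, s2)] + 1
        } else {
          # Plan7 has no D->I / I->D: attribute insert runs to M-anchored moves
          tc[k, "MI"] <- tc[k, "MI"] + 1
          tc[k, "II"] <- tc[k, "II"] + (nIns - 1L)
          tc[k, "IM"] <- tc[k, "IM"] + 1
        }
      }
    }
    tr <- matrix(0, L - 1L, 7L, dimnames = list(NULL, cn))
    for (k in seq_len(L - 1L)) {
      mrow <- tc[k, 1:3] + alpha / 3
      irow <- tc[k, 4:5] + alpha / 2
      drow <- tc[k, 6:7] + alpha / 2
      tr[k, 1:3] <- mrow / sum(mrow)
      tr[k, 4:5] <- irow / sum(irow)
      tr[k, 6:7] <- drow / sum(drow)
    }
  } else tr <- matrix(0, 0L, 7L, dimnames = list(NULL, cn))
  new("ProfileHMM",
      matchEmissions = mE,
      insertEmissions = matrix(rep(bg, each = L), L, 20L),
      transitions = tr,
      background = bg,
      occupancy = as.numeric(occ),
      consensus = AA20[apply(mE, 1L, which.max)])
}

.profile_lod <- function(profile) {
  log2(sweep(profile@matchEmissions, 2L, profile@background, "/"))
}

#' Scan one protein for non-overlapping domain hits
#'
#' Iterated best local Viterbi alignment: the top-scoring local alignment is
#' reported if it reaches `scoreThresholdBits`, its envelope residues are
#' masked, and the scan repeats. Bit scores are log2-odds of the Viterbi path
#' against the background model, with uniform local entry over match states
#' and free exit.
#'
#' @param profile a [ProfileHMM]
#' @param protein amino-acid string
#' @param params a [profileParams()] list
#' @return data.frame of hits: env_start, env_end (0-based half-open residue
#'   coordinates), bit_score, aligned (the hit projected onto the L match
#'   columns, `-` for deletions), sorted by env_start
#' @export
searchProfile <- function(profile, protein, params = profileParams()) {
  stopifnot(nchar(protein) > 0L)
  enc <- encodeProtein(protein)
  enc[is.na(enc)] <- -1L
  L <- profileLength(profile)
  lod <- .profile_lod(profile)
  ltr <- if (L > 1L) log2(profile@transitions) else matrix(0, 0L, 7L)
  entry <- log2(1 / L)
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  hits <- list()
  cur <- enc
  repeat {
    v <- viterbi_local(cur, lod, ltr, entry)
    if (!is.finite(v$score) || v$score < params$scoreThresholdBits) break
    ali <- vapply(v$match_pos, function(p) {
      if (is.na(p)) "-" else if (p == 0L) "-" else chars[[p]]
    }, character(1))
    hits[[length(hits) + 1L]] <- data.frame(
      env_start = v$env_start - 1L, env_end = v$env_end,
      bit_score = v$score, aligned = paste(ali, collapse = ""),
      stringsAsFactors = FALSE)
    cur[v$env_start:v$env_end] <- -1L
  }
  if (!length(hits))
    return(data.frame(env_start = integer(0), env_end = integer(0),
                      bit_score = numeric(0), aligned = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$env_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of proteins for domain hits
#' @param profile a [ProfileHMM]
#' @param proteins named character vector of proteins
#' @param params a [profileParams()] list
#' @return data.frame with orf_id plus the [searchProfile()] columns
#' @export
searchProteins <- function(profile, proteins, params = profileParams()) {
  stopifnot(!is.null(names(proteins)))
  res <- lapply(names(proteins), function(id) {
    h <- searchProfile(profile, proteins[[id]], params)
    if (nrow(h)) cbind(orf_id = id, h, stringsAsFactors = FALSE) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(orf_id = character(0), env_start = integer(0),
                      env_end = integer(0), bit_score = numeric(0),
                      aligned = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Iterative profile refinement to hit-set convergence
#'
#' Searches all proteins, realigns the hit envelopes on the Viterbi-implied
#' match columns, rebuilds the profile from that alignment, and repeats until
#' the set of (orf_id, envelope) hits is identical between successive
#' iterations or `maxIter` is reached.
#'
#' @param seed a [ProfileHMM] seed profile
#' @param proteins named character vector
#' @param params a [profileParams()] list
#' @param maxIter maximum iterations (>= 1; default 8)
#' @return list: profile, hits, iterations, converged, status
#' @export
iterativeSearch <- function(seed, proteins, params = profileParams(),
                            maxIter = 8L) {
  stopifnot(maxIter >= 1L)
  profile <- seed
  prevKey <- NULL
  hits <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    hits <- searchProteins(profile, proteins, params)
    if (it == 1L && nrow(hits) == 0L) {
      warning("no hits at iteration 1; returning the seed profile")
      return(list(profile = seed, hits = hits, iterations = 1L,
                  converged = FALSE, status = "no_hits"))
    }
    key <- sort(sprintf("%s:%d-%d", hits$orf_id, hits$env_start, hits$env_end))
    if (!is.null(prevKey) && identical(key, prevKey)) {
      converged <- TRUE
      break
    }
    prevKey <- key
    if (nrow(hits) >= 2L) {
      rows <- stats::setNames(hits$aligned,
                              sprintf("%s/%d-%d", hits$orf_id,
                                      hits$env_start, hits$env_end))
      profile <- buildProfile(msa(rows), params)
    }
  }
  list(profile = profile, hits = hits, iterations = it,
       converged = converged, status = if (converged) "converged" else "max_iter")
}

#' Per-column statistics of an alignment
#'
#' Occupancy (non-gap fraction), conservation (modal residue frequency),
#' information content `log2(20) - H` of the gap-excluded residue
#' distribution, match/insert classification at a threshold, and for match
#' columns the probability of an insertion immediately after the column.
#'
#' @param x an [Msa]
#' @param matchColumnThreshold match classification threshold (default 0.5)
#' @return data.frame, one row per column: occupancy, conservation,
#'   information_bits, is_match, insert_prob
#' @export
columnStats <- function(x, matchColumnThreshold = 0.5) {
  m <- as.matrix(x)
  nc <- ncol(m)
  isRes <- matrix(m %in% AA20, nrow(m), nc)
  occ <- colMeans(isRes)
  ic <- cons <- numeric(nc)
  for (j in seq_len(nc)) {
    col <- m[isRes[, j], j]
    if (!length(col)) { ic[j] <- 0; cons[j] <- 0; next }
    p <- table(col) / length(col)
    ic[j] <- max(0, log2(20) + sum(p * log2(p)))
    cons[j] <- max(p)
  }
  isMatch <- occ >= matchColumnThreshold
  insProb <- rep(NA_real_, nc)
  mc <- which(isMatch)
  for (idx in seq_along(mc)) {
    j <- mc[[idx]]
    nxt <- if (idx < length(mc)) mc[[idx + 1L]] else nc + 1L
    insProb[j] <- if (nxt > j + 1L)
      mean(rowSums(isRes[, (j + 1L):(nxt - 1L), drop = FALSE]) > 0) else 0
  }
  data.frame(column = seq_len(nc), occupancy = occ, conservation = cons,
             information_bits = ic, is_match = isMatch, insert_prob = insProb)
}
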