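# Core S4 containers: multiple alignments and profile HMMs.

#' Msa: a protein multiple sequence alignment
#'
#' Rows are equal-length aligned strings over residues and `-`. The gap
#' character `.` is accepted on input and normalised to `-`.
#'
#' @slot seqs named character vector of aligned rows
#' @exportClass Msa
setClass("Msa", representation(seqs = "character"))

setValidity("Msa", function(object) {
  s <- object@seqs
  if (length(s) < 1L) return("alignment needs at least one row")
  ids <- names(s)
  if (is.null(ids) || any(!nzchar(ids))) return("rows must be named")
  if (anyDuplicated(ids)) return("row ids must be unique")
  if (length(unique(nchar(s))) != 1L) return("rows must have equal length")
  TRUE
})

#' Construct an Msa from named aligned strings
#' @param seqs named character vector; `.` gaps are normalised to `-`
#' @return an [Msa] object
#' @export
msa <- function(seqs) {
  seqs[] <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  new("Msa", seqs = seqs)
}

#' @describeIn msa number of aligned columns
#' @param x an Msa
#' @export
msaWidth <- function(x) nchar(x@seqs[[1L]])

#' @describeIn msa row sequences as a named character vector
#' @export
msaSeqs <- function(x) x@seqs

#' @export
setMethod("nrow", "Msa", function(x) length(x@seqs))

#' Character matrix view of an alignment (rows = sequences)
#' @param x an Msa
#' @param ... ignored
#' @export
setMethod("as.matrix", "Msa", function(x, ...) {
  m <- do.call(rbind, strsplit(x@seqs, "", fixed = TRUE))
  rownames(m) <- names(x@seqs)
  m
})

setMethod("show", "Msa", function(object) {
  cat(sprintf("Msa: %d sequences x %d columns\n",
              length(object@seqs), msaWidth(object)))
})

#' ProfileHMM: positional model of a protein domain family
#'
#' Plan7-style match/insert/delete architecture with local (uniform) entry
#' over match states and free exit. Insert states emit the background.
#'
#' @slot matchEmissions L x 20 match emission probabilities (rows sum to 1)
#' @slot insertEmissions L x 20 insert emission probabilities
#' @slot transitions (L-1) x 7 probabilities, columns MM, MI, MD, IM, II, DM,
#'   DD, for transitions out of node k
#' @slot background length-20 background composition
#' @slot occupancy per-node probability that a sequence occupies the match
#'   state (fraction of non-gap residues in the source column)
#' @slot consensus consensus residue string, length L
#' @exportClass ProfileHMM
setClass("ProfileHMM", representation(
  matchEmissions = "matrix", insertEmissions = "matrix",
  transitions = "matrix", background = "numeric",
  occupancy = "numeric", consensus = "character"))

setValidity("ProfileHMM", function(object) {
  L <- nrow(object@matchEmissions)
  if (L < 1L) return("profile needs at least one match state")
  if (ncol(object@matchEmissions) != 20L) return("emissions must have 20 columns")
  if (any(abs(rowSums(object@matchEmissions) - 1) > 1e-9))
    return("match emission rows must sum to 1")
  if (any(abs(rowSums(object@insertEmissions) - 1) > 1e-9))
    return("insert emission rows must sum to 1")
  if (abs(sum(object@background) - 1) > 1e-9)
    return("background must sum to 1")
  if (length(object@occupancy) != L || any(object@occupancy < -1e-12) ||
      any(object@occupancy > 1 + 1e-12))
    return("occupancy must be L values in [0,1]")
  if (L > 1L) {
    tr <- object@transitions
    if (nrow(tr) != L - 1L || ncol(tr) != 7L)
      return("transitions must be (L-1) x 7")
    m <- rowSums(tr[, 1:3, drop = FALSE])
    i <- rowSums(tr[, 4:5, drop = FALSE])
    d <- rowSums(tr[, 6:7, drop = FALSE])
    if (any(abs(c(m, i, d) - 1) > 1e-9))
      return("each transition bundle (M->, I->, D->) must sum to 1")
  }
  TRUE
})

#' @describeIn buildProfile number of match states
#' @param profile a ProfileHMM
#' @export
profileLength <- function(profile) nrow(profile@matchEmissions)

#' @describeIn buildProfile per-node match-state occupancy
#' @export
profileOccupancy <- function(profile) profile@occupancy

#' @describeIn buildProfile consensus sequence (modal residue per node)
#' @export
profileConsensus <- function(profile) paste(profile@consensus, collapse = "")

setMethod("show", "ProfileHMM", function(object) {
  cat(sprintf("ProfileHMM with %d match states\nconsensus: %s\n",
              profileLength(object), profileConsensus(object)))
})
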