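# Homology transfer of rRNA modification sites onto a target rRNA.
#
# Known 2'-O-methylation (Nm) and pseudouridylation (psi) positions from
# model-organism rRNAs are lifted onto the target rRNA through a global
# pairwise alignment; transferred sites must land on a consistent
# nucleotide inside a conserved context window.

#' Global pairwise alignment of two rRNA sequences
#'
#' Needleman--Wunsch alignment with affine gaps via
#' [Biostrings::pairwiseAlignment].  A gap run of length `L` costs
#' `gapOpen + L * gapExtend`.  Defaults (+1/-1, open 4, extend 1) suit
#' rRNA-scale homology; all are overridable.
#'
#' @param reference,target RNA strings or `RNAString(Set)` elements.
#' @param match,mismatch,gapOpen,gapExtend scoring parameters; gap costs are
#'   given as positive penalties.
#' @param referenceId,targetId ids carried into the result.
#' @return list with elements `reference_id`, `target_id`, `ref_aln`,
#'   `tgt_aln` (gapped strings over `A,C,G,U,-`) and `score`.
#' @export
globalAlign <- function(reference, target, match = 1, mismatch = -1,
                        gapOpen = 4, gapExtend = 1,
                        referenceId = "reference", targetId = "target") {
  ref <- .asRna(as.character(reference))
  tgt <- .asRna(as.character(target))
  if (nchar(ref) < 1L || nchar(tgt) < 1L) stop("empty sequence")
  .checkResidues(ref, referenceId); .checkResidues(tgt, targetId)
  # align in DNA space (substitution matrices are ACGT-lettered); gaps are
  # alphabet-independent so coordinates are unaffected
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(chartr("U", "T", ref)),
    Biostrings::DNAString(chartr("U", "T", tgt)),
    substitutionMatrix = sm, gapOpening = gapOpen, gapExtension = gapExtend,
    type = "global")
  list(reference_id = referenceId, target_id = targetId,
       ref_aln = chartr("T", "U", as.character(Biostrings::alignedPattern(aln))),
       tgt_aln = chartr("T", "U", as.character(Biostrings::alignedSubject(aln))),
       score = BiocGenerics::score(aln))
}

#' Map a reference position through an alignment
#'
#' @param alignment result of [globalAlign()].
#' @param referencePosition 1-based position on the ungapped reference.
#' @return 1-based target position, or `NA` if the reference residue is
#'   aligned to a target gap (deletion covers the site).
#' @export
mapPosition <- function(alignment, referencePosition) {
  ra <- .chars(alignment$ref_aln)
  ta <- .chars(alignment$tgt_aln)
  refLen <- sum(ra != "-")
  if (referencePosition < 1L || referencePosition > refLen)
    stop("reference position ", referencePosition, " out of range (1..",
         refLen, ")")
  col <- which(cumsum(ra != "-") == referencePosition & ra != "-")[1L]
  if (ta[col] == "-") return(NA_integer_)
  sum(ta[seq_len(col)] != "-")
}

#' Transfer modification sites through an alignment
#'
#' Each reference site is mapped with [mapPosition()]; a transferred site is
#' kept only if (i) the mapped column is not a target gap, (ii) the target
#' nucleotide matches the site nucleotide (psi additionally requires `U`),
#' and (iii) at least `minContextIdentity` of the alignment columns within
#' `contextWindow` of the site column are identical.  Dropped sites are
#' reported with a reason code in the `dropped` attribute.
#'
#' @param alignment result of [globalAlign()].
#' @param referenceSites `GRanges` of sites on the alignment's reference
#'   (mcols `nucleotide`, `mtype`).
#' @param contextWindow window half-width in alignment columns (default 5).
#' @param minContextIdentity minimum fraction of identical columns (default
#'   0.8).
#' @return `GRanges` of sites on the target with `provenance =
#'   "transferred"`; attribute `dropped` is a data.frame of rejected sites
#'   with reason codes (`target_gap`, `nucleotide_mismatch`, `low_context`).
#' @export
transferSites <- function(alignment, referenceSites, contextWindow = 5L,
                          minContextIdentity = 0.8) {
  refIds <- unique(as.character(GenomicRanges::seqnames(referenceSites)))
  if (length(referenceSites) > 0L &&
      !all(refIds == alignment$reference_id))
    stop("sites reference rRNA '", paste(refIds, collapse = ","),
         "' but alignment reference is '", alignment$reference_id, "'")
  ra <- .chars(alignment$ref_aln)
  ta <- .chars(alignment$tgt_aln)
  ident <- ra == ta & ra != "-"
  refColOf <- which(ra != "-")            # reference pos -> column
  tgtPosAt <- cumsum(ta != "-")           # column -> target pos (if not gap)

  keepPos <- integer(0); keepNt <- character(0); keepTy <- character(0)
  dropPos <- integer(0); dropReason <- character(0)
  mc <- S4Vectors::mcols(referenceSites)
  for (i in seq_along(referenceSites)) {
    p <- GenomicRanges::start(referenceSites)[i]
    col <- refColOf[p]
    reason <- NULL
    if (ta[col] == "-") {
      reason <- "target_gap"
    } else {
      tp <- tgtPosAt[col]
      tnt <- ta[col]
      if (tnt != mc$nucleotide[i] || (mc$mtype[i] == "psi" && tnt != "U")) {
        reason <- "nucleotide_mismatch"
      } else {
        win <- max(1L, col - contextWindow):min(length(ra), col + contextWindow)
        if (mean(ident[win]) < minContextIdentity) reason <- "low_context"
      }
    }
    if (is.null(reason)) {
      keepPos <- c(keepPos, tgtPosAt[col])
      keepNt <- c(keepNt, ta[col])
      keepTy <- c(keepTy, mc$mtype[i])
    } else {
      dropPos <- c(dropPos, p)
      dropReason <- c(dropReason, reason)
    }
  }
  out <- GenomicRanges::GRanges(
    rep(alignment$target_id, length(keepPos)),
    IRanges::IRanges(keepPos, width = 1L),
    nucleotide = keepNt, mtype = keepTy,
    provenance = rep("transferred", length(keepPos)))
  attr(out, "dropped") <- data.frame(reference_position = dropPos,
                                     reason = dropReason,
                                     stringsAsFactors = FALSE)
  out
}
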