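#' Candidate snoRNAs located on a transcript repertoire
#'
#' Container for the output of [scanCD()] and [scanHACA()].  Candidates are
#' held as a [GenomicRanges::GRanges] on transcript coordinates (1-based,
#' inclusive) with one metadata row per candidate; box motifs and structural
#' elements (stems, pseudouridylation pockets) live in a second `GRanges`
#' keyed by `candidate_id`.
#'
#' Candidate metadata columns: `candidate_id`, `subfamily` (`"CD"` or
#' `"HACA"`), `n_box_mm` (total box mismatches), `stem_pairs`, `score`,
#' `cls` (`"guide"`, `"orphan"` or `"unclassified"`), `exon_overlap`.
#' Box metadata columns: `candidate_id`, `kind` (`C`, `D`, `Cprime`,
#' `Dprime`, `H`, `ACA`, `stem5`, `stem3`, `pocket5`, `pocket3`),
#' `hairpin` (1/2 for H/ACA elements, `NA` otherwise), `mismatches`.
#'
#' @slot candidates `GRanges` of candidate spans on transcripts.
#' @slot boxes `GRanges` of box/structure elements on transcripts.
#' @slot transcripts `RNAStringSet` the candidates were scanned from (may be
#'   empty, e.g. after re-reading from GFF3).
#' @export
setClass("SnoCandidateSet",
  representation(
    candidates  = "GRanges",
    boxes       = "GRanges",
    transcripts = "RNAStringSet"
  )
)

setValidity("SnoCandidateSet", function(object) {
  cand <- object@candidates
  need <- c("candidate_id", "subfamily", "n_box_mm", "score", "cls",
            "exon_overlap")
  missing <- setdiff(need, colnames(S4Vectors::mcols(cand)))
  if (length(missing) > 0L)
    return(paste("missing candidate columns:", paste(missing, collapse = ", ")))
  ids <- S4Vectors::mcols(cand)$candidate_id
  if (anyDuplicated(ids)) return("duplicate candidate_id")
  if (!all(S4Vectors::mcols(cand)$subfamily %in% c("CD", "HACA")))
    return("subfamily must be 'CD' or 'HACA'")
  if (!all(S4Vectors::mcols(cand)$cls %in% c("guide", "orphan", "unclassified")))
    return("cls must be guide/orphan/unclassified")
  if (length(object@boxes) > 0L) {
    bid <- S4Vectors::mcols(object@boxes)$candidate_id
    if (is.null(bid) || !all(bid %in% ids))
      return("boxes reference unknown candidate_id")
  }
  if (length(object@transcripts) > 0L && length(cand) > 0L) {
    tl <- setNames(Biostrings::width(object@transcripts),
                   names(object@transcripts))
    sq <- as.character(GenomicRanges::seqnames(cand))
    known <- sq %in% names(tl)
    if (!all(known)) return("candidate on unknown transcript")
    if (any(GenomicRanges::start(cand) < 1L) ||
        any(GenomicRanges::end(cand) > tl[sq]))
      return("candidate coordinates outside transcript")
  }
  TRUE
})

#' @rdname SnoCandidateSet-class
#' @param candidates,boxes,transcripts see slots.
#' @return `SnoCandidateSet`
#' @export
SnoCandidateSet <- function(candidates = GenomicRanges::GRanges(),
                            boxes = GenomicRanges::GRanges(),
                            transcripts = Biostrings::RNAStringSet()) {
  if (length(candidates) > 0L) {
    mc <- S4Vectors::mcols(candidates)
    if (is.null(mc$score)) mc$score <- NA_real_
    if (is.null(mc$cls)) mc$cls <- "unclassified"
    if (is.null(mc$exon_overlap)) mc$exon_overlap <- FALSE
    if (is.null(mc$n_box_mm)) mc$n_box_mm <- 0L
    if (is.null(mc$stem_pairs)) mc$stem_pairs <- NA_integer_
    S4Vectors::mcols(candidates) <- mc
  } else {
    S4Vectors::mcols(candidates) <- S4Vectors::DataFrame(
      candidate_id = character(0), subfamily = character(0),
      n_box_mm = integer(0), stem_pairs = integer(0),
      score = numeric(0), cls = character(0), exon_overlap = logical(0))
  }
  methods::new("SnoCandidateSet", candidates = candidates, boxes = boxes,
               transcripts = transcripts)
}

#' @describeIn SnoCandidateSet-class candidate spans as `GRanges`.
#' @param x a `SnoCandidateSet`.
#' @export
candidateRanges <- function(x) x@candidates

#' @describeIn SnoCandidateSet-class box/structure elements as `GRanges`.
#' @export
candidateBoxes <- function(x) x@boxes

#' @describeIn SnoCandidateSet-class scanned transcripts.
#' @export
candidateTranscripts <- function(x) x@transcripts

#' @describeIn SnoCandidateSet-class candidate identifiers.
#' @export
candidateIds <- function(x) S4Vectors::mcols(x@candidates)$candidate_id

#' @describeIn SnoCandidateSet-class guide/orphan/unclassified calls.
#' @export
candidateClasses <- function(x) {
  setNames(S4Vectors::mcols(x@candidates)$cls, candidateIds(x))
}

#' @describeIn SnoCandidateSet-class best duplex score per candidate.
#' @export
candidateScores <- function(x) {
  setNames(S4Vectors::mcols(x@candidates)$score, candidateIds(x))
}

#' @describeIn SnoCandidateSet-class candidate sequences (requires the
#'   `transcripts` slot).
#' @export
candidateSeqs <- function(x) {
  if (length(x@transcripts) == 0L)
    stop("no transcripts stored in this SnoCandidateSet")
  cand <- x@candidates
  seqs <- vapply(seq_along(cand), function(i) {
    tx <- as.character(x@transcripts[[as.character(
      GenomicRanges::seqnames(cand)[i])]])
    substr(tx, GenomicRanges::start(cand)[i], GenomicRanges::end(cand)[i])
  }, character(1))
  Biostrings::RNAStringSet(setNames(seqs, candidateIds(x)))
}

setMethod("length", "SnoCandidateSet", function(x) length(x@candidates))

setMethod("show", "SnoCandidateSet", function(object) {
  mc <- S4Vectors::mcols(object@candidates)
  cat("SnoCandidateSet with", length(object@candidates), "candidates (",
      sum(mc$subfamily == "CD"), "C/D,", sum(mc$subfamily == "HACA"),
      "H/ACA ) on", length(unique(as.character(
        GenomicRanges::seqnames(object@candidates)))), "transcripts\n")
  cls <- table(factor(mc$cls, c("guide", "orphan", "unclassified")))
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
})

#' Synthetic study bundle with planted ground truth
#'
#' Everything the pipeline consumes, generated by [simulateBundle()]:
#' synthetic rRNAs and a pre-rRNA with an ITS1 spacer, a reference
#' modification-site catalogue, transcripts carrying planted snoRNAs, a
#' leaf/latex count table, an F1 population expression/yield table and
#' continuous-tapping time courses.  The `truth` table records every planted
#' candidate (coordinates, boxes, intended target site, intended class).
#'
#' @slot rrnas `RNAStringSet` of mature rRNA analogues (SSU/LSU/5.8S).
#' @slot prerrna `RNAStringSet` of length 1, the pre-rRNA reference.
#' @slot sites `GRanges` of reference modification sites.
#' @slot transcripts `RNAStringSet` transcript repertoire.
#' @slot truth `data.frame` planted ground truth.
#' @slot counts integer matrix, features x samples (includes pre-rRNA row).
#' @slot design list with `latex` and `leaf` sample names.
#' @slot population `data.frame` per-tree expression and TSC/C.
#' @slot timecourse `data.frame` tapping series (tree_id, time_min, tsc).
#' @slot params list of generator settings.
#' @slot seed master seed.
#' @export
setClass("SyntheticBundle",
  representation(
    rrnas = "RNAStringSet", prerrna = "RNAStringSet", sites = "GRanges",
    transcripts = "RNAStringSet", truth = "data.frame", counts = "matrix",
    design = "list", population = "data.frame", timecourse = "data.frame",
    params = "list", seed = "numeric"
  )
)

setValidity("SyntheticBundle", function(object) {
  if (length(object@prerrna) != 1L) return("prerrna must hold one sequence")
  if (nrow(object@counts) > 0L) {
    if (!"pre-rRNA" %in% rownames(object@counts))
      return("counts must include a 'pre-rRNA' row")
    if (any(object@counts < 0)) return("negative counts")
  }
  TRUE
})

setMethod("show", "SyntheticBundle", function(object) {
  cat("SyntheticBundle (seed ", object@seed, ")\n", sep = "")
  cat("  rRNAs: ", paste(names(object@rrnas), collapse = ", "),
      " + pre-rRNA\n", sep = "")
  cat("  reference sites:", length(object@sites), "\n")
  cat("  transcripts:", length(object@transcripts),
      "| planted snoRNAs:", nrow(object@truth), "\n")
  cat("  counts:", nrow(object@counts), "x", ncol(object@counts),
      "| population trees:", nrow(object@population), "\n")
})

#' @describeIn SyntheticBundle-class planted ground-truth table.
#' @param x a `SyntheticBundle`.
#' @export
bundleTruth <- function(x) x@truth

#' @describeIn SyntheticBundle-class transcripts.
#' @export
bundleTranscripts <- function(x) x@transcripts

#' @describeIn SyntheticBundle-class mature rRNA analogues.
#' @export
bundleRRNAs <- function(x) x@rrnas

#' @describeIn SyntheticBundle-class count matrix (features x samples).
#' @export
bundleCounts <- function(x) x@counts

#' @describeIn SyntheticBundle-class reference modification sites.
#' @export
bundleSites <- function(x) x@sites
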