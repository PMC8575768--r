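# Guide-target duplex prediction and guide/orphan classification.
#
# C/D guides: the antisense element immediately upstream of (and including
# the first nucleotide of) the D or D' box pairs antiparallel with the rRNA;
# the rRNA nucleotide paired with the guide position five nucleotides
# upstream of the D-box first nucleotide receives the 2'-O-methyl (D+5
# rule).  H/ACA guides: the two pocket strands of a hairpin's internal loop
# bracket the target U.  Duplex constraints: at most one mismatch, at most
# two GU wobble pairs, no bulges.

#' Default duplex scoring weights
#'
#' Watson--Crick pair +2, GU wobble +0.5, mismatch -6.  Chosen so that (i) a
#' canonical 9--12 nt perfect C/D duplex clears the C/D guide threshold
#' (14) and a two-pocket H/ACA guide with designed stems clears the H/ACA
#' threshold (40), while (ii) the best duplex of a random antisense element
#' against rRNA-scale sequence stays below the thresholds with high
#' probability -- mild GU/mismatch weights would let almost every random
#' element clear 14 somewhere in several kilobases of rRNA, erasing the
#' guide/orphan distinction.  Weights are reported in output metadata so
#' scores are never misread as the original screening tools' bit-scores.
#'
#' @return named list with `wc`, `gu`, `mismatch`.
#' @export
duplexWeights <- function() list(wc = 2, gu = 0.5, mismatch = -6)

#' Guide-classification score thresholds
#'
#' Guide calls require a best duplex score strictly greater than 14 (C/D)
#' or 40 (H/ACA); candidates overlapping an annotated exon use the higher
#' thresholds 20 and 45 with greater-or-equal comparison, as printed.
#'
#' @return named list with `cd`, `haca`, `cdExon`, `hacaExon`.
#' @export
scoreThresholds <- function() list(cd = 14, haca = 40, cdExon = 20, hacaExon = 45)

#' Extract antisense guide elements from candidates
#'
#' For C/D candidates, one element per D and D' box: the window ending at
#' (and including) the box's first nucleotide, up to `maxGuide` nt long,
#' clipped to the candidate span; elements shorter than `minGuide` are
#' dropped.  For H/ACA candidates, the two pocket strands of each hairpin
#' (kinds `pocket5`/`pocket3`).
#'
#' @param x `SnoCandidateSet` with stored transcripts.
#' @param minGuide,maxGuide admissible C/D guide length (default 9--21).
#' @return `data.frame` with columns `candidate_id`, `box_kind`, `hairpin`,
#'   `start`, `end` (transcript coordinates, 1-based inclusive), `residues`.
#' @export
extractGuides <- function(x, minGuide = 9L, maxGuide = 21L) {
  stopifnot(methods::is(x, "SnoCandidateSet"))
  cand <- x@candidates
  boxes <- x@boxes
  mb <- S4Vectors::mcols(boxes)
  out <- list()
  for (i in seq_along(cand)) {
    id <- S4Vectors::mcols(cand)$candidate_id[i]
    tx <- as.character(GenomicRanges::seqnames(cand))[i]
    seqTx <- as.character(x@transcripts[[tx]])
    myBoxes <- boxes[mb$candidate_id == id]
    mbi <- S4Vectors::mcols(myBoxes)
    if (S4Vectors::mcols(cand)$subfamily[i] == "CD") {
      for (k in c("D", "Dprime")) {
        hit <- which(mbi$kind == k)
        if (length(hit) == 0L) next
        ds <- GenomicRanges::start(myBoxes)[hit[1L]]
        gStart <- max(GenomicRanges::start(cand)[i], ds - maxGuide + 1L)
        gEnd <- ds                       # D-box first nucleotide included
        if (gEnd - gStart + 1L < minGuide) next
        out[[length(out) + 1L]] <- data.frame(
          candidate_id = id, box_kind = k, hairpin = NA_integer_,
          start = gStart, end = gEnd,
          residues = substr(seqTx, gStart, gEnd), stringsAsFactors = FALSE)
      }
    } else {
      for (hp in c(1L, 2L)) {
        for (k in c("pocket5", "pocket3")) {
          hit <- which(mbi$kind == k & mbi$hairpin == hp)
          if (length(hit) == 0L) next
          a <- GenomicRanges::start(myBoxes)[hit[1L]]
          b <- GenomicRanges::end(myBoxes)[hit[1L]]
          out[[length(out) + 1L]] <- data.frame(
            candidate_id = id, box_kind = k, hairpin = hp,
            start = a, end = b, residues = substr(seqTx, a, b),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(candidate_id = character(0), box_kind = character(0),
                      hairpin = integer(0), start = integer(0),
                      end = integer(0), residues = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Enumerate admissible guide-rRNA duplexes
#'
#' Considers every 3'-anchored guide sub-length `L` in
#' `[minLen, min(maxLen, guide length)]` (the guide 3' end is fixed at the
#' D-box first nucleotide) and every rRNA window of length `L`, pairing the
#' guide antiparallel and contiguously against the window (no bulges).
#' Windows with at most `maxMismatch` mismatches and at most `maxGU` GU
#' pairs are reported with exact pair counts and score.
#'
#' @param guide guide residue string (5' to 3').
#' @param rrna rRNA string or `RNAString`.
#' @param rrnaId id carried into the result.
#' @param minLen,maxLen guide sub-length bounds (default 9--21).
#' @param maxMismatch,maxGU duplex constraint caps (default 1 and 2).
#' @param weights scoring weights, see [duplexWeights()].
#' @return `data.frame` with columns `rrna_id`, `guide_len`, `target_start`,
#'   `target_end`, `wc`, `gu`, `mm`, `score`, ordered by `guide_len` then
#'   `target_start`.
#' @export
enumerateDuplexes <- function(guide, rrna, rrnaId = "rRNA",
                              minLen = 9L, maxLen = 21L,
                              maxMismatch = 1L, maxGU = 2L,
                              weights = duplexWeights()) {
  g <- .chars(.asRna(as.character(guide)))
  r <- .chars(.asRna(as.character(rrna)))
  n <- length(r); Lg <- length(g)
  res <- list()
  for (L in seq(minLen, min(maxLen, Lg))) {
    if (L > Lg) break
    gs <- g[(Lg - L + 1L):Lg]
    nw <- n - L + 1L
    if (nw < 1L) next
    wc <- integer(nw); gu <- integer(nw); mm <- integer(nw)
    for (k in seq_len(L)) {
      # guide sub-position k pairs rRNA position w + L - k (antiparallel)
      cls <- .pairClass(rep(gs[k], nw), r[(1L:nw) + L - k])
      wc <- wc + (cls == 2L); gu <- gu + (cls == 1L); mm <- mm + (cls == 0L)
    }
    ok <- which(mm <= maxMismatch & gu <= maxGU)
    if (length(ok) == 0L) next
    res[[length(res) + 1L]] <- data.frame(
      rrna_id = rrnaId, guide_len = L, target_start = ok,
      target_end = ok + L - 1L, wc = wc[ok], gu = gu[ok], mm = mm[ok],
      score = weights$wc * wc[ok] + weights$gu * gu[ok] +
        weights$mismatch * mm[ok],
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(rrna_id = character(0), guide_len = integer(0),
                      target_start = integer(0), target_end = integer(0),
                      wc = integer(0), gu = integer(0), mm = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$guide_len, out$target_start), , drop = FALSE]
}

#' Score a duplex from its pair counts
#'
#' `score = wc_weight * wc + gu_weight * gu + mismatch_weight * mm`.
#'
#' @param wc,gu,mm pair counts (vectorised).
#' @param weights see [duplexWeights()].
#' @return numeric score(s).
#' @examples
#' scoreDuplex(12, 0, 0)  # 24
#' scoreDuplex(9, 2, 1)   # 13
#' @export
scoreDuplex <- function(wc, gu, mm, weights = duplexWeights()) {
  weights$wc * wc + weights$gu * gu + weights$mismatch * mm
}

#' Call the 2'-O-methylation site of a C/D duplex (D+5 rule)
#'
#' The methylated rRNA nucleotide is the one paired with the guide
#' nucleotide `dOffset` positions upstream of the D-box first nucleotide
#' (which is the guide 3' terminus).  Under antiparallel contiguous pairing
#' that is rRNA position `target_start + dOffset`; the duplex must cover at
#' least `dOffset + 1` guide positions.
#'
#' @param duplex one row of [enumerateDuplexes()] output.
#' @param rrna the target rRNA string.
#' @param dOffset counting convention for the D+5 rule (default 5).
#' @return one-row data.frame (`rrna_id`, `position`, `nucleotide`,
#'   `mtype = "Nm"`, `provenance = "predicted"`), or `NULL` with a message
#'   when the duplex is too short for the rule.
#' @export
callMethylationSite <- function(duplex, rrna, dOffset = 5L) {
  if (duplex$guide_len < dOffset + 1L) {
    .msg("duplex too short for the D+", dOffset, " rule on ",
         duplex$rrna_id, ":", duplex$target_start)
    return(NULL)
  }
  p <- duplex$target_start + dOffset
  data.frame(rrna_id = duplex$rrna_id, position = p,
             nucleotide = substr(.asRna(as.character(rrna)), p, p),
             mtype = "Nm", provenance = "predicted",
             stringsAsFactors = FALSE)
}

#' Call pseudouridylation sites for one H/ACA pocket pair
#'
#' The target U is bracketed by two pocket duplexes: the 3' pocket strand
#' pairs the rRNA 5' flank (`pocket3[i]` with `rRNA[p - i]`) and the 5'
#' pocket strand pairs the rRNA 3' flank beyond the unpaired U-N
#' dinucleotide (`pocket5[j]` with `rRNA[p + 2 + len5 - j]`).  Each pocket
#' duplex must satisfy the mismatch/GU caps.
#'
#' The pairing register is anchored at the U: prefixes of the 3' pocket
#' strand (from `minPocketPair` nt up to its full length) and suffixes of
#' the 5' pocket strand are enumerated, and each side independently takes
#' its best admissible duplex, so unpaired overhang at the lower-stem side
#' of either pocket strand does not disturb the call.
#'
#' @param pocket5,pocket3 pocket strand residue strings (5' to 3').
#' @param rrna rRNA string.
#' @param rrnaId id carried into the result.
#' @param maxMismatch,maxGU per-duplex caps (default 1 and 2).
#' @param minPocketPair minimum paired length per pocket duplex (default 5).
#' @param weights scoring weights.
#' @return `data.frame` with columns `rrna_id`, `position`, `nucleotide`,
#'   `mtype = "psi"`, `wc`, `gu`, `mm`, `score` (sum of both pocket
#'   duplexes), ordered by position.
#' @export
callPseudouridylationSite <- function(pocket5, pocket3, rrna,
                                      rrnaId = "rRNA", maxMismatch = 1L,
                                      maxGU = 2L, minPocketPair = 5L,
                                      weights = duplexWeights()) {
  p5 <- .chars(.asRna(as.character(pocket5)))
  p3 <- .chars(.asRna(as.character(pocket3)))
  r <- .chars(.asRna(as.character(rrna)))
  n <- length(r)
  L5 <- length(p5); L3 <- length(p3)
  empty <- data.frame(rrna_id = character(0), position = integer(0),
                      nucleotide = character(0), mtype = character(0),
                      wc = integer(0), gu = integer(0), mm = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (L5 < minPocketPair || L3 < minPocketPair) return(empty)
  lo <- L3 + 1L; hi <- n - L5 - 1L
  if (hi < lo) return(empty)
  p <- lo:hi
  np <- length(p)
  sideBest <- function(chars, rposOf) {
    # cumulative pair counts while growing the duplex from the U-anchored
    # end; each admissible length competes for the best per-position score
    wc <- gu <- mm <- integer(np)
    bsc <- rep(-Inf, np)
    bwc <- bgu <- bmm <- integer(np)
    for (k in seq_along(chars)) {
      cls <- .pairClass(rep(chars[k], np), r[rposOf(k)])
      wc <- wc + (cls == 2L); gu <- gu + (cls == 1L); mm <- mm + (cls == 0L)
      if (k < minPocketPair) next
      adm <- mm <= maxMismatch & gu <= maxGU
      sc <- weights$wc * wc + weights$gu * gu + weights$mismatch * mm
      upd <- adm & sc > bsc
      bsc[upd] <- sc[upd]; bwc[upd] <- wc[upd]
      bgu[upd] <- gu[upd]; bmm[upd] <- mm[upd]
    }
    list(sc = bsc, wc = bwc, gu = bgu, mm = bmm)
  }
  # pocket3 grows as prefixes (p3[i] pairs r[p - i]); pocket5 grows as
  # suffixes from its 3' end (p5[L5 + 1 - k] pairs r[p + 1 + k])
  s3 <- sideBest(p3, function(k) p - k)
  s5 <- sideBest(rev(p5), function(k) p + 1L + k)
  ok <- which(r[p] == "U" & is.finite(s3$sc) & is.finite(s5$sc))
  if (length(ok) == 0L) return(empty)
  pos <- p[ok]
  data.frame(rrna_id = rep(rrnaId, length(ok)), position = pos,
             nucleotide = rep("U", length(ok)),
             mtype = rep("psi", length(ok)),
             wc = s3$wc[ok] + s5$wc[ok], gu = s3$gu[ok] + s5$gu[ok],
             mm = s3$mm[ok] + s5$mm[ok],
             score = s3$sc[ok] + s5$sc[ok],
             stringsAsFactors = FALSE)
}

#' Classify a candidate as guide or orphan
#'
#' Guide iff the best duplex score exceeds the subfamily threshold:
#' strictly greater for the plain thresholds, greater-or-equal for the
#' higher exon thresholds (both as printed).
#'
#' @param subfamily `"CD"` or `"HACA"`.
#' @param bestScore best duplex score (`NA`/`-Inf` if no admissible duplex).
#' @param exonOverlap does the candidate overlap an annotated exon?
#' @param thresholds see [scoreThresholds()].
#' @return `"guide"` or `"orphan"`.
#' @examples
#' classifyGuide("CD", 15, FALSE)  # guide  (15 > 14)
#' classifyGuide("CD", 15, TRUE)   # orphan (15 < 20)
#' @export
classifyGuide <- function(subfamily, bestScore, exonOverlap = FALSE,
                          thresholds = scoreThresholds()) {
  stopifnot(subfamily %in% c("CD", "HACA"))
  if (is.na(bestScore) || !is.finite(bestScore)) return("orphan")
  if (subfamily == "CD") {
    if (exonOverlap) {
      if (bestScore >= thresholds$cdExon) "guide" else "orphan"
    } else if (bestScore > thresholds$cd) "guide" else "orphan"
  } else {
    if (exonOverlap) {
      if (bestScore >= thresholds$hacaExon) "guide" else "orphan"
    } else if (bestScore > thresholds$haca) "guide" else "orphan"
  }
}

#' Predict target sites and classify all candidates
#'
#' For each C/D candidate, enumerates duplexes for every D/D' guide against
#' every rRNA and calls methylation sites by the D+5 rule; for each H/ACA
#' candidate, calls pseudouridylation sites from each hairpin's pocket pair
#' (score = pocket duplex sum plus a structure bonus of one point per stem
#' pair beyond `2 * minStemPairs`, capped at `stemBonusCap`).  Candidates
#' are classified with [classifyGuide()] on their best assignment score.
#' When assignments tie on the best score, all are kept and the
#' lexicographically first (rrna_id, position) is flagged `primary`.
#'
#' @param x `SnoCandidateSet` with transcripts.
#' @param rrnas `RNAStringSet` of mature rRNAs.
#' @param thresholds see [scoreThresholds()].
#' @param weights see [duplexWeights()].
#' @param minGuide,maxGuide C/D guide sub-length bounds.
#' @param dOffset D+5 counting convention.
#' @param maxMismatch,maxGU duplex caps.
#' @param minStemPairs,stemBonusCap H/ACA structure-bonus parameters.
#' @return list with `candidates` (the input set with `score` and `cls`
#'   filled) and `assignments` (data.frame: candidate_id, subfamily,
#'   box_kind, hairpin, rrna_id, position, nucleotide, mtype,
#'   target_start, target_end, wc, gu, mm, score, primary).
#' @export
predictTargets <- function(x, rrnas, thresholds = scoreThresholds(),
                           weights = duplexWeights(),
                           minGuide = 9L, maxGuide = 21L, dOffset = 5L,
                           maxMismatch = 1L, maxGU = 2L,
                           minStemPairs = 4L, stemBonusCap = 10L) {
  stopifnot(methods::is(x, "SnoCandidateSet"))
  if (is.character(rrnas)) rrnas <- Biostrings::RNAStringSet(rrnas)
  cand <- x@candidates
  mc <- S4Vectors::mcols(cand)
  guides <- extractGuides(x, minGuide, maxGuide)
  asn <- list()
  scores <- rep(NA_real_, length(cand))
  cls <- character(length(cand))
  rrnaChars <- lapply(as.character(rrnas), identity)
  for (i in seq_along(cand)) {
    id <- mc$candidate_id[i]
    sub <- mc$subfamily[i]
    g <- guides[guides$candidate_id == id, , drop = FALSE]
    rows <- list()
    if (sub == "CD") {
      for (gi in seq_len(nrow(g))) {
        for (rid in names(rrnas)) {
          d <- enumerateDuplexes(g$residues[gi], rrnaChars[[rid]], rid,
                                 minGuide, maxGuide, maxMismatch, maxGU,
                                 weights)
          if (nrow(d) == 0L) next
          for (k in seq_len(nrow(d))) {
            site <- callMethylationSite(d[k, ], rrnaChars[[rid]], dOffset)
            if (is.null(site)) next
            rows[[length(rows) + 1L]] <- data.frame(
              candidate_id = id, subfamily = sub,
              box_kind = g$box_kind[gi], hairpin = NA_integer_,
              rrna_id = rid, position = site$position,
              nucleotide = site$nucleotide, mtype = "Nm",
              target_start = d$target_start[k], target_end = d$target_end[k],
              wc = d$wc[k], gu = d$gu[k], mm = d$mm[k], score = d$score[k],
              stringsAsFactors = FALSE)
          }
        }
      }
    } else {
      bonus <- unname(min(stemBonusCap,
                          max(0L, mc$stem_pairs[i] - 2L * minStemPairs)))
      for (hp in unique(g$hairpin[!is.na(g$hairpin)])) {
        p5 <- g$residues[g$box_kind == "pocket5" & g$hairpin == hp]
        p3 <- g$residues[g$box_kind == "pocket3" & g$hairpin == hp]
        if (length(p5) != 1L || length(p3) != 1L) next
        for (rid in names(rrnas)) {
          d <- callPseudouridylationSite(p5, p3, rrnaChars[[rid]], rid,
                                         maxMismatch, maxGU,
                                         weights = weights)
          if (nrow(d) == 0L) next
          rownames(d) <- NULL
          rows[[length(rows) + 1L]] <- data.frame(
            candidate_id = id, subfamily = sub,
            box_kind = paste0("pocket_hp", hp), hairpin = hp,
            rrna_id = d$rrna_id, position = d$position,
            nucleotide = d$nucleotide, mtype = "psi",
            target_start = d$position - nchar(p3),
            target_end = d$position + 1L + nchar(p5),
            wc = d$wc, gu = d$gu, mm = d$mm, score = d$score + bonus,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) > 0L) {
      ri <- do.call(rbind, rows)
      best <- max(ri$score)
      scores[i] <- best
      top <- which(ri$score == best)
      primIdx <- top[order(ri$rrna_id[top], ri$position[top])[1L]]
      ri$primary <- seq_len(nrow(ri)) == primIdx
      asn[[length(asn) + 1L]] <- ri
    }
    cls[i] <- classifyGuide(sub, scores[i], mc$exon_overlap[i], thresholds)
  }
  mc$score <- scores
  mc$cls <- cls
  S4Vectors::mcols(cand) <- mc
  assignments <- if (length(asn) > 0L) do.call(rbind, asn) else
    data.frame(candidate_id = character(0), subfamily = character(0),
               box_kind = character(0), hairpin = integer(0),
               rrna_id = character(0), position = integer(0),
               nucleotide = character(0), mtype = character(0),
               target_start = integer(0), target_end = integer(0),
               wc = integer(0), gu = integer(0), mm = integer(0),
               score = numeric(0), primary = logical(0),
               stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  list(candidates = SnoCandidateSet(cand, x@boxes, x@transcripts),
       assignments = assignments)
}
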