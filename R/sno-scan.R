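# C/D and H/ACA box snoRNA scanning.
#
# C/D box snoRNAs: 5' C box (RUGAUGA) and 3' D box (CUGA), often with less
# conserved internal C'/D' copies; 50-300 nt.  H/ACA box snoRNAs: two
# hairpins joined by a hinge carrying the H box (ANANNA), a 3' ACA motif a
# fixed tail offset before the 3' end, and a pseudouridylation pocket
# (internal loop) in each hairpin.

.BOX_CONSENSUS <- list(
  C = "RUGAUGA", Cprime = "RUGAUGA",
  D = "CUGA", Dprime = "CUGA",
  H = "ANANNA", ACA = "ACA"
)

#' Locate box motifs on a sequence
#'
#' Slides the subfamily consensus (C/C' `RUGAUGA`, D/D' `CUGA`, H `ANANNA`,
#' ACA `ACA`) along the sequence and reports every window whose degenerate
#' mismatch count (see [matchDegenerate()]) is at most `maxMismatch`.
#'
#' @param seq RNA string (or `RNAString`).
#' @param kind one of `"C"`, `"D"`, `"Cprime"`, `"Dprime"`, `"H"`, `"ACA"`.
#' @param maxMismatch 0 or 1.
#' @return data.frame with columns `kind`, `start`, `end` (1-based
#'   inclusive), `seq`, `mismatches`, sorted by position.
#' @examples
#' findBoxes("GGAUGAUGAGG", "C")  # one hit at 3..9 (R matched by A)
#' @export
findBoxes <- function(seq, kind, maxMismatch = 0L) {
  if (!kind %in% names(.BOX_CONSENSUS)) stop("unknown box kind: ", kind)
  stopifnot(maxMismatch %in% c(0L, 1L))
  s <- .asRna(as.character(seq))
  pat <- .chars(.BOX_CONSENSUS[[kind]])
  ch <- .chars(s)
  n <- length(ch); L <- length(pat)
  empty <- data.frame(kind = character(0), start = integer(0),
                      end = integer(0), seq = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  nw <- n - L + 1L
  mm <- integer(nw)
  for (j in seq_len(L)) {
    mm <- mm + !(ch[j:(j + nw - 1L)] %in% .IUPAC_RNA[[pat[j]]])
  }
  hit <- which(mm <= maxMismatch)
  if (length(hit) == 0L) return(empty)
  data.frame(kind = kind, start = hit, end = hit + L - 1L,
             seq = substring(s, hit, hit + L - 1L), mismatches = mm[hit],
             stringsAsFactors = FALSE)
}

# All maximal contiguous helices (base-pair stacks, WC + GU) in a region.
# run[i,j] = length of the stack whose outermost pair is (i,j), capped so
# the innermost pair still encloses >= minLoop unpaired residues.  Only
# maximal stacks (not extendable outward) are reported, ordered by pair
# count descending, then leftmost 5' arm, then widest span.
.allStacks <- function(ch, minLoop = 3L, minPairs = 1L) {
  n <- length(ch)
  none <- data.frame(i = integer(0), j = integer(0), pairs = integer(0))
  if (n < minLoop + 2L) return(none)
  P <- outer(ch, ch, .canPair)
  run <- matrix(0L, n, n)
  for (i in (n - 1L):1L) {
    j <- (i + 1L):n
    prev <- run[i + 1L, j - 1L]          # run[x,y] with y <= x is 0 by init
    run[i, j] <- ifelse(P[i, j], prev + 1L, 0L)
  }
  idx <- which(run > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(none)
  i <- idx[, 1L]; j <- idx[, 2L]
  maximal <- i == 1L | j == n
  inn <- !maximal
  maximal[inn] <- !P[cbind(i[inn] - 1L, j[inn] + 1L)]
  kgeo <- pmax(0L, (j - i + 1L - minLoop) %/% 2L)
  usable <- pmin(run[idx], kgeo)
  ok <- maximal & usable >= minPairs
  if (!any(ok)) return(none)
  out <- data.frame(i = i[ok], j = j[ok], pairs = usable[ok])
  out[order(-out$pairs, out$i, -(out$j - out$i)), , drop = FALSE]
}

#' Detect a hairpin (and its pseudouridylation pocket) in a region
#'
#' Complementary-segment search (Watson--Crick plus GU wobble, apical loop
#' of at least `minLoop`): a lower stem encloses the pseudouridylation
#' pocket, whose two unpaired strands flank a nested upper stem.  Candidate
#' stems are enumerated as maximal base-pair stacks; the outer/inner
#' combination with the most stem pairs that leaves a pocket strand of at
#' least `minPocket` nt on both sides (and, when `pocket3Window` is given,
#' whose 3' pocket strand starts inside that window) is returned.  When no
#' combination yields a pocket, the best bare stem of at least
#' `minStemPairs` pairs is reported without pocket annotation.
#'
#' @param seq RNA string of the candidate hairpin region.
#' @param minStemPairs minimum outer-stem pairs to call a hairpin (default 4).
#' @param minInnerPairs minimum upper-stem pairs to call a pocket (default 3).
#' @param minLoop minimum unpaired loop size (default 3).
#' @param minPocket minimum pocket-strand length (default 4).
#' @param pocket3Window optional `c(min, max)` bounds (coordinates in
#'   `seq`) for the start of the 3' pocket strand, used by the H/ACA
#'   scanner to enforce the pocket-to-box distance.
#' @param stem3End optional `c(min, max)` bounds for the last position of
#'   the outer stem's 3' arm; the H/ACA scanner uses this to demand that
#'   the lower stem abuts the downstream box.
#' @return `NULL` if no qualifying hairpin; otherwise a list with 1-based
#'   coordinates (relative to `seq`): `stem5`, `stem3`, `pairs`, `loop`, and
#'   when a nested stem exists, `innerStem5`, `innerStem3`, `innerPairs`,
#'   `pocket5`, `pocket3`, plus `totalPairs`.
#' @export
foldStems <- function(seq, minStemPairs = 4L, minInnerPairs = 3L,
                      minLoop = 3L, minPocket = 4L, pocket3Window = NULL,
                      stem3End = NULL) {
  ch <- .chars(.asRna(as.character(seq)))
  stacks <- .allStacks(ch, minLoop, minPairs = min(minStemPairs,
                                                   minInnerPairs))
  outers <- stacks[stacks$pairs >= minStemPairs, , drop = FALSE]
  if (!is.null(stem3End) && nrow(outers) > 0L)
    outers <- outers[outers$j >= stem3End[1L] & outers$j <= stem3End[2L], ,
                     drop = FALSE]
  if (nrow(outers) == 0L) return(NULL)
  asHairpin <- function(o, k) {
    list(stem5 = c(o$i, o$i + k - 1L), stem3 = c(o$j - k + 1L, o$j),
         pairs = k, loop = c(o$i + k, o$j - k), totalPairs = k)
  }
  for (oi in seq_len(nrow(outers))) {
    o <- outers[oi, ]
    k <- o$pairs
    lo <- o$i + k; hi <- o$j - k
    if (hi - lo + 1L < 2L * minInnerPairs + minLoop + 2L * minPocket) next
    inner <- stacks[stacks$i >= lo + minPocket &
                    stacks$j <= hi - minPocket &
                    stacks$pairs >= minInnerPairs, , drop = FALSE]
    if (!is.null(pocket3Window))
      inner <- inner[inner$j + 1L >= pocket3Window[1L] &
                     inner$j + 1L <= pocket3Window[2L], , drop = FALSE]
    if (nrow(inner) == 0L) next
    ii <- inner[1L, ]
    out <- asHairpin(o, k)
    out$innerStem5 <- c(ii$i, ii$i + ii$pairs - 1L)
    out$innerStem3 <- c(ii$j - ii$pairs + 1L, ii$j)
    out$innerPairs <- ii$pairs
    out$pocket5 <- c(lo, ii$i - 1L)
    out$pocket3 <- c(ii$j + 1L, hi)
    out$totalPairs <- k + ii$pairs
    return(out)
  }
  asHairpin(outers[1L, ], outers$pairs[1L])
}

# ---- candidate assembly ----------------------------------------------------

# Greedy overlap resolution: among candidates sharing > 50% of the shorter
# span, keep the one with fewer box mismatches, then longer, then leftmost.
.resolveOverlaps <- function(df) {
  if (nrow(df) <= 1L) return(df)
  ord <- order(df$n_box_mm, -(df$end - df$start), df$start)
  keep <- logical(nrow(df))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (df$tx[i] != df$tx[j]) next
      ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]) + 1L
      if (ov > 0.5 * min(df$end[i] - df$start[i] + 1L,
                         df$end[j] - df$start[j] + 1L)) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  df[sort(which(keep)), , drop = FALSE]
}

.candidateId <- function(tx, subfamily, start, end) {
  paste0(tx, ":", tolower(subfamily), ":", start, "-", end)
}

#' Scan transcripts for C/D box snoRNA candidates
#'
#' Pairs every C box (up to `cMaxMismatch` mismatches) with every downstream
#' exact D box such that the candidate span -- from `boundaryPad` nt before
#' the C box to `boundaryPad` nt after the D box -- stays within the length
#' bounds.  Internal D' and C' copies are attached when found with one
#' mismatch allowed.  Overlapping candidates (sharing more than half the
#' shorter span) are resolved in favour of fewer box mismatches, then
#' longer span, then leftmost start.
#'
#' @param transcripts `RNAStringSet` (or named character vector).
#' @param lenMin,lenMax candidate length bounds (default 50--300 nt).
#' @param cMaxMismatch mismatches allowed in the C box (default 1).
#' @param dMaxMismatch mismatches allowed in the D box (default 0).
#' @param internalMaxMismatch mismatches allowed in C'/D' (default 1).
#' @param boundaryPad nt added outside the terminal boxes (default 4).
#' @return `SnoCandidateSet`.
#' @export
scanCD <- function(transcripts, lenMin = 50L, lenMax = 300L,
                   cMaxMismatch = 1L, dMaxMismatch = 0L,
                   internalMaxMismatch = 1L, boundaryPad = 4L) {
  if (is.character(transcripts))
    transcripts <- Biostrings::RNAStringSet(transcripts)
  rows <- list(); boxRows <- list()
  for (tx in names(transcripts)) {
    s <- as.character(transcripts[[tx]])
    n <- nchar(s)
    if (n < lenMin) next
    cb <- findBoxes(s, "C", cMaxMismatch)
    db <- findBoxes(s, "D", dMaxMismatch)
    if (nrow(cb) == 0L || nrow(db) == 0L) next
    for (ci in seq_len(nrow(cb))) {
      cs <- cb$start[ci]; ce <- cb$end[ci]
      if (cs - boundaryPad < 1L) next
      for (di in seq_len(nrow(db))) {
        ds <- db$start[di]; de <- db$end[di]
        if (ds <= ce) next
        if (de + boundaryPad > n) next
        a <- cs - boundaryPad; b <- de + boundaryPad
        len <- b - a + 1L
        if (len < lenMin || len > lenMax) next
        # internal copies: canonical order C .. D' .. C' .. D
        dp <- findBoxes(substr(s, ce + 1L, ds - 1L), "Dprime",
                        internalMaxMismatch)
        dpRow <- NULL; cpRow <- NULL
        if (nrow(dp) > 0L) {
          dp$start <- dp$start + ce; dp$end <- dp$end + ce
          dp <- dp[dp$start > ce + 9L & dp$end < ds - 9L, , drop = FALSE]
          if (nrow(dp) > 0L)
            dpRow <- dp[order(dp$mismatches, dp$start)[1L], , drop = FALSE]
        }
        if (!is.null(dpRow)) {
          cp <- findBoxes(substr(s, dpRow$end + 1L, ds - 1L), "Cprime",
                          internalMaxMismatch)
          if (nrow(cp) > 0L) {
            cp$start <- cp$start + dpRow$end; cp$end <- cp$end + dpRow$end
            cpRow <- cp[order(cp$mismatches, cp$start)[1L], , drop = FALSE]
          }
        }
        nmm <- cb$mismatches[ci] + db$mismatches[di] +
          (if (is.null(dpRow)) 0L else dpRow$mismatches) +
          (if (is.null(cpRow)) 0L else cpRow$mismatches)
        rows[[length(rows) + 1L]] <- data.frame(
          tx = tx, start = a, end = b, subfamily = "CD", n_box_mm = nmm,
          stem_pairs = NA_integer_, stringsAsFactors = FALSE)
        bx <- data.frame(
          tx = tx,
          kind = c("C", "D",
                   if (!is.null(cpRow)) "Cprime", if (!is.null(dpRow)) "Dprime"),
          start = c(cs, ds,
                    if (!is.null(cpRow)) cpRow$start,
                    if (!is.null(dpRow)) dpRow$start),
          end = c(ce, de,
                  if (!is.null(cpRow)) cpRow$end,
                  if (!is.null(dpRow)) dpRow$end),
          hairpin = NA_integer_,
          mismatches = c(cb$mismatches[ci], db$mismatches[di],
                         if (!is.null(cpRow)) cpRow$mismatches,
                         if (!is.null(dpRow)) dpRow$mismatches),
          stringsAsFactors = FALSE)
        bx$cand <- length(rows)
        boxRows[[length(boxRows) + 1L]] <- bx
      }
    }
  }
  .assembleCandidateSet(rows, boxRows, transcripts)
}

# Shared assembly: overlap resolution, GRanges construction, sorting.
.assembleCandidateSet <- function(rows, boxRows, transcripts) {
  if (length(rows) == 0L)
    return(SnoCandidateSet(transcripts = transcripts))
  df <- do.call(rbind, rows)
  df$cand <- seq_len(nrow(df))
  df <- .resolveOverlaps(df)
  bx <- do.call(rbind, boxRows)
  bx <- bx[bx$cand %in% df$cand, , drop = FALSE]
  ids <- .candidateId(df$tx, df$subfamily, df$start, df$end)
  names(ids) <- as.character(df$cand)
  cand <- GenomicRanges::GRanges(df$tx, IRanges::IRanges(df$start, df$end),
    candidate_id = unname(ids), subfamily = df$subfamily,
    n_box_mm = df$n_box_mm,
    stem_pairs = df$stem_pairs, score = NA_real_, cls = "unclassified",
    exon_overlap = FALSE)
  boxes <- GenomicRanges::GRanges(bx$tx, IRanges::IRanges(bx$start, bx$end),
    candidate_id = unname(ids[as.character(bx$cand)]), kind = bx$kind,
    hairpin = bx$hairpin, mismatches = bx$mismatches)
  ordC <- order(as.character(GenomicRanges::seqnames(cand)),
                GenomicRanges::start(cand))
  ordB <- order(as.character(GenomicRanges::seqnames(boxes)),
                GenomicRanges::start(boxes),
                S4Vectors::mcols(boxes)$kind)
  SnoCandidateSet(cand[ordC], boxes[ordB], transcripts)
}

#' Scan transcripts for H/ACA box snoRNA candidates
#'
#' Anchors at each exact ACA motif ending `tailOffset` nt before the
#' candidate 3' end, pairs it with upstream H boxes (`ANANNA`, up to
#' `hMaxMismatch` mismatches), and requires a [foldStems()]-validated
#' hairpin with a pseudouridylation pocket on both sides of the H box.
#' The 3' pocket strand of each hairpin must start `pocketDistMin` to
#' `pocketDistMax` nt upstream of the downstream box (H for hairpin 1, ACA
#' for hairpin 2).  The candidate spans from the first hairpin's stem to
#' `tailOffset` nt past the ACA.
#'
#' @inheritParams scanCD
#' @param tailOffset nt between ACA end and candidate 3' end (default 3).
#' @param hMaxMismatch mismatches allowed in the H box (default 1).
#' @param minStemPairs,minInnerPairs,minLoop,minPocket see [foldStems()];
#'   defaults (5 outer pairs, 4 upper pairs, pocket strands of 6 nt)
#'   are set so random transcript sequence rarely satisfies the full
#'   architecture.
#' @param pocketDistMin,pocketDistMax allowed distance (nt) from the 3'
#'   pocket strand start to the downstream box start (default 13--17).
#' @param hairpinMin,hairpinMax hairpin region length bounds searched
#'   (default 20--60 nt).
#' @param stem3Slack maximum gap (nt) between the lower stem's 3' arm and
#'   the downstream box (default 2).
#' @return `SnoCandidateSet`.
#' @export
scanHACA <- function(transcripts, lenMin = 50L, lenMax = 300L,
                     tailOffset = 3L, hMaxMismatch = 1L,
                     minStemPairs = 5L, minInnerPairs = 4L, minLoop = 3L,
                     minPocket = 6L, pocketDistMin = 13L, pocketDistMax = 17L,
                     hairpinMin = 20L, hairpinMax = 60L, stem3Slack = 2L) {
  if (is.character(transcripts))
    transcripts <- Biostrings::RNAStringSet(transcripts)
  rows <- list(); boxRows <- list()
  for (tx in names(transcripts)) {
    s <- as.character(transcripts[[tx]])
    n <- nchar(s)
    if (n < lenMin) next
    aca <- findBoxes(s, "ACA", 0L)
    hb <- findBoxes(s, "H", hMaxMismatch)
    if (nrow(aca) == 0L || nrow(hb) == 0L) next
    hp1Cache <- new.env(parent = emptyenv())
    for (ai in seq_len(nrow(aca))) {
      as0 <- aca$start[ai]; ae <- aca$end[ai]
      if (ae + tailOffset > n) next
      hs <- hb[hb$end < as0 - hairpinMin &
               hb$end >= as0 - 1L - hairpinMax, , drop = FALSE]
      for (hi in seq_len(nrow(hs))) {
        hS <- hs$start[hi]; hE <- hs$end[hi]
        # hairpin 2: between H box and ACA
        r2a <- hE + 1L; r2b <- as0 - 1L
        w2 <- r2b - r2a + 1L
        hp2 <- foldStems(substr(s, r2a, r2b), minStemPairs, minInnerPairs,
                         minLoop, minPocket,
                         pocket3Window = c(w2 + 1L - pocketDistMax,
                                           w2 + 1L - pocketDistMin),
                         stem3End = c(w2 - stem3Slack, w2))
        if (is.null(hp2) || is.null(hp2$pocket3)) next
        d2 <- as0 - (r2a + hp2$pocket3[1L] - 1L)
        if (d2 < pocketDistMin || d2 > pocketDistMax) next
        # hairpin 1: window upstream of the H box (cached per H box)
        key <- as.character(hS)
        if (!is.null(hp1Cache[[key]])) {
          cached <- hp1Cache[[key]]
          r1a <- cached$r1a; hp1 <- cached$hp1
        } else {
          r1a <- max(1L, hS - hairpinMax)
          w1 <- hS - r1a
          hp1 <- if (w1 >= hairpinMin)
            foldStems(substr(s, r1a, hS - 1L), minStemPairs, minInnerPairs,
                      minLoop, minPocket,
                      pocket3Window = c(w1 + 1L - pocketDistMax,
                                        w1 + 1L - pocketDistMin),
                      stem3End = c(w1 - stem3Slack, w1)) else NULL
          hp1Cache[[key]] <- list(r1a = r1a, hp1 = hp1)
        }
        if (is.null(hp1) || is.null(hp1$pocket3)) next
        d1 <- hS - (r1a + hp1$pocket3[1L] - 1L)
        if (d1 < pocketDistMin || d1 > pocketDistMax) next
        a <- r1a + hp1$stem5[1L] - 1L
        b <- ae + tailOffset
        len <- b - a + 1L
        if (len < lenMin || len > lenMax) next
        nmm <- hs$mismatches[hi] + aca$mismatches[ai]
        stemPairs <- hp1$totalPairs + hp2$totalPairs
        rows[[length(rows) + 1L]] <- data.frame(
          tx = tx, start = a, end = b, subfamily = "HACA", n_box_mm = nmm,
          stem_pairs = stemPairs, stringsAsFactors = FALSE)
        abs1 <- function(p) p + r1a - 1L
        abs2 <- function(p) p + r2a - 1L
        bx <- data.frame(
          tx = tx,
          kind = c("H", "ACA",
                   "stem5", "stem3", "innerstem5", "innerstem3",
                   "pocket5", "pocket3",
                   "stem5", "stem3", "innerstem5", "innerstem3",
                   "pocket5", "pocket3"),
          start = c(hS, as0,
                    abs1(hp1$stem5[1L]), abs1(hp1$stem3[1L]),
                    abs1(hp1$innerStem5[1L]), abs1(hp1$innerStem3[1L]),
                    abs1(hp1$pocket5[1L]), abs1(hp1$pocket3[1L]),
                    abs2(hp2$stem5[1L]), abs2(hp2$stem3[1L]),
                    abs2(hp2$innerStem5[1L]), abs2(hp2$innerStem3[1L]),
                    abs2(hp2$pocket5[1L]), abs2(hp2$pocket3[1L])),
          end = c(hE, ae,
                  abs1(hp1$stem5[2L]), abs1(hp1$stem3[2L]),
                  abs1(hp1$innerStem5[2L]), abs1(hp1$innerStem3[2L]),
                  abs1(hp1$pocket5[2L]), abs1(hp1$pocket3[2L]),
                  abs2(hp2$stem5[2L]), abs2(hp2$stem3[2L]),
                  abs2(hp2$innerStem5[2L]), abs2(hp2$innerStem3[2L]),
                  abs2(hp2$pocket5[2L]), abs2(hp2$pocket3[2L])),
          hairpin = c(NA_integer_, NA_integer_, rep(1L, 6L), rep(2L, 6L)),
          mismatches = c(hs$mismatches[hi], aca$mismatches[ai],
                         rep(NA_integer_, 12L)),
          stringsAsFactors = FALSE)
        bx$cand <- length(rows)
        boxRows[[length(boxRows) + 1L]] <- bx
      }
    }
  }
  .assembleCandidateSet(rows, boxRows, transcripts)
}

#' Scan transcripts for both snoRNA subfamilies
#'
#' Runs [scanCD()] and [scanHACA()] and resolves overlaps across
#' subfamilies (one call per locus).
#'
#' @param transcripts `RNAStringSet`.
#' @param cdArgs,hacaArgs lists of extra arguments for the two scanners.
#' @return `SnoCandidateSet`.
#' @export
scanSnoRNAs <- function(transcripts, cdArgs = list(), hacaArgs = list()) {
  if (is.character(transcripts))
    transcripts <- Biostrings::RNAStringSet(transcripts)
  cd <- do.call(scanCD, c(list(transcripts), cdArgs))
  ha <- do.call(scanHACA, c(list(transcripts), hacaArgs))
  # the two scans can see disjoint transcript sets; merging seqlevels is
  # intended
  cand <- suppressWarnings(c(cd@candidates, ha@candidates))
  boxes <- suppressWarnings(c(cd@boxes, ha@boxes))
  if (length(cand) == 0L) return(SnoCandidateSet(transcripts = transcripts))
  df <- data.frame(tx = as.character(GenomicRanges::seqnames(cand)),
                   start = GenomicRanges::start(cand),
                   end = GenomicRanges::end(cand),
                   n_box_mm = S4Vectors::mcols(cand)$n_box_mm,
                   cand = seq_along(cand), stringsAsFactors = FALSE)
  kept <- .resolveOverlaps(df)
  cand <- cand[kept$cand]
  boxes <- boxes[S4Vectors::mcols(boxes)$candidate_id %in%
                   S4Vectors::mcols(cand)$candidate_id]
  ordC <- order(as.character(GenomicRanges::seqnames(cand)),
                GenomicRanges::start(cand))
  ordB <- order(as.character(GenomicRanges::seqnames(boxes)),
                GenomicRanges::start(boxes), S4Vectors::mcols(boxes)$kind)
  SnoCandidateSet(cand[ordC], boxes[ordB], transcripts)
}
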