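# Synthetic study bundle with planted ground truth.
#
# Generates every input the pipeline needs: synthetic rRNA analogues with a
# reference modification-site catalogue, transcripts carrying planted C/D
# and H/ACA snoRNAs whose antisense elements are built backwards from
# chosen rRNA sites, negative-binomial leaf/latex counts with a pre-rRNA
# reference row, an F1-style population with copula-controlled Spearman
# correlation between expression and TSC/C, and continuous-tapping time
# courses that drop sharply and then plateau.  Planted positives are
# re-scanned at generation time and regenerated until the scanner and
# classifier reproduce the intended truth exactly (self-validation);
# planted negatives (orphans, decoys) are regenerated until they produce
# nothing.

#' Generate synthetic rRNAs, a pre-rRNA and a reference site catalogue
#'
#' rRNA lengths default to plant-scale values (SSU 1800, LSU 3400, 5.8S
#' 160 nt); the pre-rRNA concatenates SSU + ITS1 + 5.8S + ITS2 + LSU so an
#' ITS1-spanning fragment distinguishes it from mature rRNAs.
#' Pseudouridylation sites are placed only on U residues; all sites keep a
#' margin from the rRNA ends so guide windows fit.
#'
#' @param lengths named lengths for `SSU`, `LSU`, `r5.8S`.
#' @param nNm,nPsi number of 2'-O-methylation / pseudouridylation sites.
#' @param its1Len,its2Len spacer lengths in the pre-rRNA.
#' @param margin minimum distance of a site from either rRNA end.
#' @param seed optional seed (local RNG scope).
#' @return list with `rrnas` (`RNAStringSet`), `prerrna` (`RNAStringSet`,
#'   one entry named `pre-rRNA`), `sites` (`GRanges`, provenance
#'   `reference`), and `summary` (per-rRNA site counts).
#' @export
simulateRRNAs <- function(lengths = c(SSU = 1800L, LSU = 3400L, r5.8S = 160L),
                          nNm = 80L, nPsi = 30L, its1Len = 250L,
                          its2Len = 200L, margin = 25L, seed = NULL) {
  .withSeed(seed, {
    nm <- c(SSU = "SSU", LSU = "LSU", r5.8S = "5.8S")[names(lengths)]
    seqs <- vapply(lengths, .randomRna, character(1))
    names(seqs) <- nm
    rrnas <- Biostrings::RNAStringSet(seqs)
    pre <- paste0(seqs["SSU"], .randomRna(its1Len), seqs["5.8S"],
                  .randomRna(its2Len), seqs["LSU"])
    prerrna <- Biostrings::RNAStringSet(c("pre-rRNA" = pre))
    # spread sites across rRNAs proportional to length
    lens <- setNames(nchar(seqs), names(seqs))
    prop <- lens / sum(lens)
    alloc <- function(total) {
      k <- floor(total * prop)
      left <- total - sum(k)
      if (left > 0) {
        extra <- order(-(total * prop - k))[seq_len(left)]
        k[extra] <- k[extra] + 1L
      }
      k
    }
    kNm <- alloc(nNm); kPsi <- alloc(nPsi)
    rid <- character(0); pos <- integer(0); nt <- character(0)
    ty <- character(0)
    for (r in names(seqs)) {
      ch <- .chars(seqs[[r]])
      inner <- seq(margin + 1L, lens[r] - margin)
      us <- inner[ch[inner] == "U"]
      if (length(us) < kPsi[r]) stop("not enough U positions on ", r)
      pPsi <- sort(sample(us, kPsi[r]))
      avail <- setdiff(inner, pPsi)
      if (length(avail) < kNm[r]) stop("requested sites exceed positions on ", r)
      pNm <- sort(sample(avail, kNm[r]))
      rid <- c(rid, rep(r, kNm[r] + kPsi[r]))
      pos <- c(pos, pNm, pPsi)
      nt <- c(nt, ch[pNm], ch[pPsi])
      ty <- c(ty, rep("Nm", kNm[r]), rep("psi", kPsi[r]))
    }
    sites <- .makeSites(rid, pos, nt, ty, rep("reference", length(pos)),
                        rrnas)
    summary <- data.frame(rrna_id = names(seqs),
                          nm = as.integer(kNm), psi = as.integer(kPsi),
                          row.names = NULL, stringsAsFactors = FALSE)
    list(rrnas = rrnas, prerrna = prerrna, sites = sites, summary = summary)
  })
}

# Introduce `n` mismatches into a box instance while keeping it within the
# degenerate-consensus mismatch budget (mutates concrete positions).
.mutateBox <- function(box, n) {
  if (n == 0L) return(box)
  ch <- .chars(box)
  idx <- sample(seq_along(ch), n)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "U"), ch[i]), 1L)
  paste(ch, collapse = "")
}

# One planted C/D snoRNA transcript targeting Nm site `p` on rRNA `rid`.
# Guide geometry: 11 antisense nt + the D-box first nucleotide form a 12-nt
# duplex over rRNA[p-5 .. p+6]; the D+5 rule then calls exactly `p`.
# Requires rRNA[p-5] == "G" so the duplex 3' terminus is the D-box C.
.buildCdTranscript <- function(rrnaSeq, p, scramble = FALSE, cMm = 0L,
                               candLen = NULL) {
  if (is.null(candLen)) candLen <- sample(70:110, 1L)
  antis12 <- if (scramble) .randomRna(12L) else
    reverseComplementRna(substr(rrnaSeq, p - 5L, p + 6L))
  cbox <- .mutateBox("AUGAUGA", cMm)          # R realised as A
  spacer <- .randomRna(candLen - 31L)
  cand <- paste0(.randomRna(4L), cbox, spacer, substr(antis12, 1L, 11L),
                 "CUGA", .randomRna(4L))
  fl5 <- .randomRna(sample(40:80, 1L)); fl3 <- .randomRna(sample(40:80, 1L))
  tx <- paste0(fl5, cand, fl3)
  a <- nchar(fl5) + 1L
  list(tx = tx, start = a, end = a + nchar(cand) - 1L,
       c_start = a + 4L, c_end = a + 10L,
       d_start = a + 4L + 7L + nchar(spacer) + 11L,
       d_end = a + 4L + 7L + nchar(spacer) + 14L,
       guide = paste0(substr(antis12, 1L, 11L), "C"))
}

# One H/ACA hairpin whose pocket strands bracket psi site `p`:
# lower5(6) pocket5(10) upper5(5) loop(5) upper3(5) pocket3(10) lower3(6).
# Pockets are generous (10 nt): if the lower stem happens to stack a pair
# or two further into the pocket strands, the remaining pocket still pairs
# its rRNA flank in the correct register.
.buildHacaHairpin <- function(rrnaSeq, p, scramble = FALSE) {
  pocket3 <- if (scramble) .randomRna(10L) else
    reverseComplementRna(substr(rrnaSeq, p - 10L, p - 1L))
  pocket5 <- if (scramble) .randomRna(10L) else
    reverseComplementRna(substr(rrnaSeq, p + 2L, p + 11L))
  lower <- .randomRna(6L); upper <- .randomRna(5L)
  paste0(lower, pocket5, upper, .randomRna(5L),
         reverseComplementRna(upper), pocket3,
         reverseComplementRna(lower))
}

# One planted H/ACA transcript; both hairpins carry pockets for site `p`.
# Geometry places each hairpin's 3' pocket strand 16 nt upstream of the
# downstream box (H for hairpin 1, ACA for hairpin 2).
.buildHacaTranscript <- function(rrnaSeq, p, scramble = FALSE, hMm = 0L) {
  hp1 <- .buildHacaHairpin(rrnaSeq, p, scramble)
  hp2 <- .buildHacaHairpin(rrnaSeq, p, scramble)
  hbox <- .mutateBox("AGAUUA", hMm)            # ANANNA realised
  cand <- paste0(hp1, hbox, .randomRna(2L), hp2, "ACA", .randomRna(3L))
  fl5 <- .randomRna(sample(40:80, 1L)); fl3 <- .randomRna(sample(40:80, 1L))
  tx <- paste0(fl5, cand, fl3)
  a <- nchar(fl5) + 1L
  list(tx = tx, start = a, end = a + nchar(cand) - 1L,
       h_start = a + 47L, h_end = a + 52L,
       aca_start = a + 102L, aca_end = a + 104L,
       guide = NA_character_)
}

# Self-validation: scan one planted transcript and check that the default
# scanner + classifier reproduce the intended truth.  C/D plants must be
# recovered with their exact span and C/D box coordinates; H/ACA plants
# must be recovered as a single overlapping candidate (the scanner's stem
# localisation on the 5' side is approximate by design).  Returns the
# scanned span on success, NULL on failure.
.validatePlant <- function(txSeq, txId, plant, subfamily, cls, rid, p,
                           mtype, rrnas) {
  txSet <- Biostrings::RNAStringSet(setNames(txSeq, txId))
  sc <- scanSnoRNAs(txSet)
  if (length(sc) != 1L) return(NULL)
  cand <- sc@candidates
  mc <- S4Vectors::mcols(cand)
  if (mc$subfamily != subfamily) return(NULL)
  a <- GenomicRanges::start(cand); b <- GenomicRanges::end(cand)
  if (subfamily == "CD") {
    if (a != plant$start || b != plant$end) return(NULL)
    mb <- S4Vectors::mcols(sc@boxes)
    cbox <- sc@boxes[mb$kind == "C"]; dbox <- sc@boxes[mb$kind == "D"]
    if (length(cbox) != 1L || GenomicRanges::start(cbox) != plant$c_start ||
        length(dbox) != 1L || GenomicRanges::start(dbox) != plant$d_start)
      return(NULL)
  } else {
    if (a > plant$end || b < plant$start) return(NULL)   # must overlap
  }
  pt <- predictTargets(sc, rrnas)
  got <- candidateClasses(pt$candidates)[[1L]]
  if (got != cls) return(NULL)
  if (cls == "guide") {
    prim <- pt$assignments[pt$assignments$primary, , drop = FALSE]
    if (nrow(prim) != 1L) return(NULL)
    if (prim$rrna_id != rid || prim$position != p || prim$mtype != mtype)
      return(NULL)
  }
  list(start = a, end = b, id = mc$candidate_id)
}

#' Plant snoRNAs (guides, orphans) and decoys in synthetic transcripts
#'
#' C/D guide plants carry an antisense element ending at the D-box first
#' nucleotide whose duplex places the D+5-paired base on an assigned Nm
#' site; H/ACA guide plants carry two pockets bracketing an assigned psi
#' U in both hairpins.  Orphans have valid boxes and structure but
#' scrambled guide/pocket sequences.  Every planted transcript is
#' re-scanned and re-classified with the default pipeline settings and
#' regenerated until the result matches the intended truth exactly; decoy
#' transcripts are regenerated until they contain no candidate at all.
#'
#' @param rrnas,sites output of [simulateRRNAs()].
#' @param nCdGuide,nHacaGuide,nOrphan,nDecoy plant counts (orphans are
#'   split between the subfamilies).
#' @param boxMismatch mismatches introduced into each plant's C/H box
#'   (0 or 1).
#' @param decoyLen decoy transcript length range.
#' @param maxTries resampling budget per plant before giving up.
#' @param seed optional seed.
#' @return list with `transcripts` (`RNAStringSet`) and `truth`
#'   (data.frame: id, transcript_id, start, end, subfamily, cls, rrna_id,
#'   site_pos, mtype, guide, box coordinates).
#' @export
plantSnoRNAs <- function(rrnas, sites, nCdGuide = 10L, nHacaGuide = 5L,
                         nOrphan = 5L, nDecoy = 30L, boxMismatch = 0L,
                         decoyLen = c(250L, 400L), maxTries = 40L,
                         seed = NULL) {
  .withSeed(seed, {
    mcS <- S4Vectors::mcols(sites)
    ridAll <- as.character(GenomicRanges::seqnames(sites))
    posAll <- GenomicRanges::start(sites)
    rrnaSeqs <- setNames(as.character(rrnas), names(rrnas))
    # eligible Nm targets need G at p-5 so the duplex ends on the D-box C
    elig <- which(mcS$mtype == "Nm" & posAll > 6L &
      vapply(seq_along(sites), function(i) {
        s <- rrnaSeqs[[ridAll[i]]]
        posAll[i] + 6L <= nchar(s) &&
          substr(s, posAll[i] - 5L, posAll[i] - 5L) == "G"
      }, logical(1)))
    # psi targets: room for both 10-nt pocket flanks, and the residues
    # flanking the unpaired U-N must not pair (otherwise the designed
    # upper stem would stack outward across the pocket and shift the
    # pseudouridylation register)
    eligPsi <- which(mcS$mtype == "psi" & posAll > 16L &
      vapply(seq_along(sites), function(i) {
        s <- rrnaSeqs[[ridAll[i]]]
        p <- posAll[i]
        if (p + 11L > nchar(s)) return(FALSE)
        if (.canPair(substr(s, p + 2L, p + 2L), substr(s, p - 1L, p - 1L)))
          return(FALSE)
        # the designed pocket strands are fixed by the rRNA flanks; if they
        # can form a stack rivalling the designed upper stem, the plant can
        # never be detected cleanly, so the site is not used
        p5d <- reverseComplementRna(substr(s, p + 2L, p + 11L))
        p3d <- reverseComplementRna(substr(s, p - 10L, p - 1L))
        st <- .allStacks(.chars(paste0(p5d, "NNNNN", p3d)), minPairs = 5L)
        nrow(st) == 0L
      }, logical(1)))
    nCdOrph <- ceiling(nOrphan / 2); nHacaOrph <- nOrphan - nCdOrph
    if (length(elig) < nCdGuide)
      stop("not enough eligible Nm sites for ", nCdGuide, " C/D guides")
    if (length(eligPsi) < nHacaGuide)
      stop("not enough eligible psi sites for ", nHacaGuide, " H/ACA guides")
    cdPool <- sample(elig); psiPool <- sample(eligPsi)

    txs <- character(0); truth <- list()
    addPlant <- function(kind, idx, siteIdx, scramble) {
      subfam <- if (kind %in% c("cd_guide", "cd_orphan")) "CD" else "HACA"
      cls <- if (scramble) "orphan" else "guide"
      rid <- if (is.na(siteIdx)) sample(names(rrnaSeqs), 1L) else ridAll[siteIdx]
      p <- if (is.na(siteIdx)) NA_integer_ else posAll[siteIdx]
      mtype <- if (subfam == "CD") "Nm" else "psi"
      txId <- sprintf("tx_%s_%02d", kind, idx)
      for (try in seq_len(maxTries)) {
        plant <- if (subfam == "CD") {
          pp <- if (scramble) 100L else p   # dummy pos for scrambled guides
          .buildCdTranscript(rrnaSeqs[[rid]], pp, scramble, boxMismatch)
        } else {
          pp <- if (scramble) 100L else p
          .buildHacaTranscript(rrnaSeqs[[rid]], pp, scramble, boxMismatch)
        }
        val <- .validatePlant(plant$tx, txId, plant, subfam, cls,
                              rid, p, mtype, rrnas)
        if (!is.null(val)) {
          txs[[txId]] <<- plant$tx
          truth[[length(truth) + 1L]] <<- data.frame(
            id = val$id,
            transcript_id = txId, start = val$start, end = val$end,
            subfamily = subfam, cls = cls,
            rrna_id = if (scramble) NA_character_ else rid,
            site_pos = if (scramble) NA_integer_ else p,
            mtype = if (scramble) NA_character_ else mtype,
            guide = if (subfam == "CD") plant$guide else NA_character_,
            c_start = if (subfam == "CD") plant$c_start else NA_integer_,
            d_start = if (subfam == "CD") plant$d_start else NA_integer_,
            h_start = if (subfam == "HACA") plant$h_start else NA_integer_,
            aca_start = if (subfam == "HACA") plant$aca_start else NA_integer_,
            stringsAsFactors = FALSE)
          return(TRUE)
        }
      }
      FALSE
    }
    # guides may exhaust a pathological site's retry budget; move on to the
    # next eligible site in the shuffled pool
    placeGuides <- function(kind, n, pool) {
      used <- 0L
      for (i in seq_len(n)) {
        placed <- FALSE
        while (used < length(pool)) {
          used <- used + 1L
          if (addPlant(kind, i, pool[used], scramble = FALSE)) {
            placed <- TRUE; break
          }
        }
        if (!placed)
          stop("could not place ", kind, " ", i,
               ": eligible sites exhausted")
      }
    }
    placeGuides("cd_guide", nCdGuide, cdPool)
    placeGuides("haca_guide", nHacaGuide, psiPool)
    for (i in seq_len(nCdOrph))
      if (!addPlant("cd_orphan", i, NA_integer_, scramble = TRUE))
        stop("could not generate a valid cd_orphan plant in ", maxTries,
             " tries")
    for (i in seq_len(nHacaOrph))
      if (!addPlant("haca_orphan", i, NA_integer_, scramble = TRUE))
        stop("could not generate a valid haca_orphan plant in ", maxTries,
             " tries")
    # decoys: random transcripts validated to contain no candidate
    for (i in seq_len(nDecoy)) {
      txId <- sprintf("tx_decoy_%02d", i)
      for (try in seq_len(maxTries)) {
        s <- .randomRna(sample(decoyLen[1L]:decoyLen[2L], 1L))
        sc <- scanSnoRNAs(Biostrings::RNAStringSet(setNames(s, txId)))
        if (length(sc) == 0L) { txs[[txId]] <- s; break }
        if (try == maxTries) stop("could not generate clean decoy ", txId)
      }
    }
    truthDf <- do.call(rbind, truth)
    rownames(truthDf) <- NULL
    list(transcripts = Biostrings::RNAStringSet(txs), truth = truthDf)
  })
}

#' Simulate a leaf/latex count table with a pre-rRNA reference row
#'
#' Negative-binomial counts with log-normal per-feature base means and
#' log-normal per-sample library-size factors; features in
#' `latexAbundantIds` get their latex mean multiplied by `fc`.  The
#' pre-rRNA row tracks the per-sample library factor at `prerrnaDepth`, so
#' pre-rRNA normalisation removes the library factors by construction.
#'
#' @param ids feature ids.
#' @param latexAbundantIds subset of `ids` planted as latex-abundant.
#' @param design list with `latex` and `leaf` sample name vectors.
#' @param fc latex/leaf fold change of the planted features (default 4).
#' @param dispersion NB dispersion of the snoRNA counts (default 0.1).
#' @param prerrnaDepth expected pre-rRNA count (default 10000).
#' @param prerrnaDispersion NB dispersion of the pre-rRNA reference row
#'   (default 0.01: a deep, technically stable reference amplicon).
#' @param baseMeanLog,baseMeanSdLog log-normal base-mean parameters.
#' @param libSdLog sd of log library factors (default 0.2).
#' @param seed optional seed.
#' @return integer matrix with rows `c(ids, "pre-rRNA")`; attribute
#'   `truth_fc` records each feature's planted fold change.
#' @export
simulateCounts <- function(ids, latexAbundantIds = character(0),
                           design = list(latex = paste0("latex_", 1:3),
                                         leaf = paste0("leaf_", 1:3)),
                           fc = 4, dispersion = 0.1, prerrnaDepth = 10000,
                           prerrnaDispersion = 0.01,
                           baseMeanLog = log(100), baseMeanSdLog = 1,
                           libSdLog = 0.2, seed = NULL) {
  stopifnot(fc > 0, all(latexAbundantIds %in% ids))
  .withSeed(seed, {
    samples <- c(design$latex, design$leaf)
    isLatex <- samples %in% design$latex
    lib <- stats::rlnorm(length(samples), 0, libSdLog)
    base <- stats::rlnorm(length(ids), baseMeanLog, baseMeanSdLog)
    fcVec <- ifelse(ids %in% latexAbundantIds, fc, 1)
    size <- 1 / dispersion
    m <- matrix(0L, nrow = length(ids) + 1L, ncol = length(samples),
                dimnames = list(c(ids, "pre-rRNA"), samples))
    for (s in seq_along(samples)) {
      mu <- base * (if (isLatex[s]) fcVec else 1) * lib[s]
      m[seq_along(ids), s] <- stats::rnbinom(length(ids), mu = mu,
                                             size = size)
      m["pre-rRNA", s] <- max(1L, stats::rnbinom(1L,
        mu = prerrnaDepth * lib[s], size = 1 / prerrnaDispersion))
    }
    attr(m, "truth_fc") <- setNames(fcVec, ids)
    m
  })
}

# Spearman target -> latent Pearson correlation (Gaussian copula).
.spearmanToPearson <- function(rho) 2 * sin(pi * rho / 6)

#' Simulate an F1 population with target expression-yield correlations
#'
#' Gaussian-copula draws: one latent normal drives TSC/C, and each
#' snoRNA's latent is correlated with it at `2*sin(pi*rho/6)` so the
#' realised Spearman correlation matches the target in expectation;
#' marginals are log-normal (expression, TSC/C) so everything is positive.
#'
#' @param rhoTargets named vector of target Spearman correlations per
#'   snoRNA (|rho| <= 0.95).
#' @param nTrees population size (default 50).
#' @param exprMeanLog,exprSdLog expression marginal parameters.
#' @param tscCMeanLog,tscCSdLog TSC/C marginal parameters.
#' @param circRange trunk circumference range, cm.
#' @param seed optional seed.
#' @return data.frame: `tree_id`, `circumference`, `tsc_c`, `tsc`, then one
#'   expression column per snoRNA.
#' @export
simulatePopulation <- function(rhoTargets, nTrees = 50L,
                               exprMeanLog = log(50), exprSdLog = 1,
                               tscCMeanLog = log(1.5), tscCSdLog = 0.3,
                               circRange = c(40, 60), seed = NULL) {
  if (any(abs(rhoTargets) > 0.95)) stop("|rho| targets must be <= 0.95")
  if (is.null(names(rhoTargets))) stop("rhoTargets must be named")
  .withSeed(seed, {
    zY <- stats::rnorm(nTrees)
    tscC <- stats::qlnorm(stats::pnorm(zY), tscCMeanLog, tscCSdLog)
    circ <- stats::runif(nTrees, circRange[1L], circRange[2L])
    out <- data.frame(tree_id = sprintf("tree_%02d", seq_len(nTrees)),
                      circumference = circ, tsc_c = tscC,
                      tsc = tscC * circ, stringsAsFactors = FALSE)
    for (s in names(rhoTargets)) {
      r <- .spearmanToPearson(rhoTargets[[s]])
      z <- r * zY + sqrt(1 - r^2) * stats::rnorm(nTrees)
      out[[s]] <- stats::qlnorm(stats::pnorm(z), exprMeanLog, exprSdLog)
    }
    out
  })
}

#' Simulate continuous-tapping TSC time courses
#'
#' Per tree, readings at fixed intervals drop sharply over the first
#' `sharpDropPoints` tappings (quadratic decay reaching the plateau exactly
#' at the last drop point) and then fluctuate around the plateau.  With
#' `noiseSd = 0` the reading at the stable point equals `plateauLevel`
#' exactly.
#'
#' @param nTrees number of trees (default 14).
#' @param intervalMin tapping interval, minutes (default 30).
#' @param sharpDropPoints tappings in the sharp-drop head (default 6).
#' @param plateauLevel plateau TSC per tree (scalar recycled, or vector);
#'   `NULL` (default) draws per-tree plateaus from a log-normal so trees
#'   differ in regeneration ability.
#' @param startFactor initial TSC as a multiple of the plateau (default 4).
#' @param nPoints readings per tree (default 10).
#' @param noiseSd multiplicative log-normal noise sd (default 0.05).
#' @param seed optional seed.
#' @return data.frame: `tree_id`, `time_min`, `tsc`; attribute `plateau`
#'   holds the per-tree plateau levels.
#' @export
simulateTimecourse <- function(nTrees = 14L, intervalMin = 30L,
                               sharpDropPoints = 6L, plateauLevel = NULL,
                               startFactor = 4, nPoints = 10L,
                               noiseSd = 0.05, seed = NULL) {
  stopifnot(is.null(plateauLevel) || all(plateauLevel > 0),
            nPoints >= sharpDropPoints)
  .withSeed(seed, {
    plateau <- if (is.null(plateauLevel))
      stats::rlnorm(nTrees, log(2), 0.4) else rep_len(plateauLevel, nTrees)
    rows <- list()
    for (t in seq_len(nTrees)) {
      times <- intervalMin * seq_len(nPoints)
      k <- seq_len(nPoints)
      frac <- pmax(0, (sharpDropPoints - k) / (sharpDropPoints - 1L))^2
      v <- plateau[t] + (startFactor - 1) * plateau[t] * frac
      if (noiseSd > 0) {
        v <- v * stats::rlnorm(nPoints, 0, noiseSd)
        head <- seq_len(sharpDropPoints)
        v[head] <- sort(v[head], decreasing = TRUE)   # keep the drop strict
      }
      rows[[t]] <- data.frame(tree_id = sprintf("tree_%02d", t),
                              time_min = times, tsc = v,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "plateau") <- setNames(plateau,
                                     sprintf("tree_%02d", seq_len(nTrees)))
    out
  })
}

#' Generate the full synthetic study bundle
#'
#' Orchestrates [simulateRRNAs()], [plantSnoRNAs()], [simulateCounts()],
#' [simulatePopulation()] and [simulateTimecourse()] under a single master
#' seed.  Half of the planted candidates (rounded up) are designated
#' latex-abundant; population Spearman targets give the first half of the
#' latex-abundant set evenly spaced positive correlations (0.5--0.85) and
#' the rest zero; the regeneration study correlates one designated snoRNA
#' with the per-tree plateau at target rho 0.78.
#'
#' @param seed master seed (default 42).
#' @param nCdGuide,nHacaGuide,nOrphan,nDecoy plant counts.
#' @param ... passed through to [plantSnoRNAs()].
#' @return a [SyntheticBundle-class] object.
#' @export
simulateBundle <- function(seed = 42L, nCdGuide = 10L, nHacaGuide = 5L,
                           nOrphan = 5L, nDecoy = 30L, ...) {
  .withSeed(seed, {
    rr <- simulateRRNAs()
    pl <- plantSnoRNAs(rr$rrnas, rr$sites, nCdGuide, nHacaGuide, nOrphan,
                       nDecoy, ...)
    ids <- pl$truth$id
    nAb <- ceiling(length(ids) / 2)
    latexIds <- sample(ids, nAb)
    counts <- simulateCounts(ids, latexIds)
    nPos <- ceiling(nAb / 2)
    rhoTargets <- setNames(rep(0, nAb), latexIds)
    rhoTargets[seq_len(nPos)] <- seq(0.5, 0.85, length.out = nPos)
    population <- simulatePopulation(rhoTargets)
    tc <- simulateTimecourse()
    plateau <- attr(tc, "plateau")
    regenCirc <- setNames(stats::runif(length(plateau), 40, 60),
                          names(plateau))
    # regeneration-study expression: one designated snoRNA tracks the
    # circumference-adjusted regeneration ability (rho 0.78), the others
    # are independent
    regenIds <- latexIds
    yTrue <- plateau / regenCirc
    zY <- stats::qnorm((rank(yTrue) - 0.5) / length(yTrue))
    regenExpr <- matrix(NA_real_, nrow = length(plateau),
                        ncol = length(regenIds),
                        dimnames = list(names(plateau), regenIds))
    regenTarget <- setNames(rep(0, length(regenIds)), regenIds)
    regenTarget[1L] <- 0.78
    for (s in regenIds) {
      r <- .spearmanToPearson(regenTarget[[s]])
      z <- r * zY + sqrt(1 - r^2) * stats::rnorm(length(plateau))
      regenExpr[, s] <- stats::qlnorm(stats::pnorm(z), log(50), 1)
    }
    params <- list(
      latex_abundant = latexIds, rho_targets = rhoTargets,
      regen = list(expression = regenExpr, target = regenTarget,
                   circumference = regenCirc, plateau = plateau),
      fc = 4, dispersion = 0.1, prerrna_depth = 10000)
    methods::new("SyntheticBundle",
      rrnas = rr$rrnas, prerrna = rr$prerrna, sites = rr$sites,
      transcripts = pl$transcripts, truth = pl$truth, counts = counts,
      design = list(latex = paste0("latex_", 1:3),
                    leaf = paste0("leaf_", 1:3)),
      population = population, timecourse = tc, params = params,
      seed = as.numeric(seed))
  })
}
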