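# Filtering cascade and expression stage: blacklist removal, redundancy
# removal, pre-rRNA normalisation, differential expression, latex-abundant
# calls.  The stage accounting telescopes like the published analysis-steps
# table: each stage's input count equals the previous stage's retained
# count.

.newFilterReport <- function() {
  data.frame(stage = character(0), input = integer(0), retained = integer(0),
             stringsAsFactors = FALSE)
}

.addStage <- function(report, stage, input, retained) {
  rbind(report, data.frame(stage = stage, input = input, retained = retained,
                           stringsAsFactors = FALSE))
}

#' Remove candidates matching a blacklist
#'
#' A candidate is dropped when it has a local alignment against any
#' blacklist sequence (eukaryotic rRNAs, published ESTs, ...) with identity
#' at least `minIdentity` over at least `minCov` of the candidate length.
#' Decisions use full Smith--Waterman local alignment
#' ([Biostrings::pairwiseAlignment], match +1 / mismatch -1, gap open 4 /
#' extend 1).
#'
#' @param candidateSeqs `RNAStringSet` (or named character) of candidates.
#' @param blacklist `RNAStringSet` (or named character) of blacklist
#'   sequences; must be non-empty.
#' @param minIdentity minimum fraction identical in the aligned region
#'   (default 0.9).
#' @param minCov minimum fraction of the candidate covered (default 0.8).
#' @return list with `retained` (`RNAStringSet`) and `report` (data.frame
#'   with per-candidate decision and, for dropped ones, the matching
#'   blacklist id).
#' @export
filterBlacklist <- function(candidateSeqs, blacklist,
                            minIdentity = 0.9, minCov = 0.8) {
  if (is.character(candidateSeqs))
    candidateSeqs <- Biostrings::RNAStringSet(candidateSeqs)
  if (is.character(blacklist))
    blacklist <- Biostrings::RNAStringSet(blacklist)
  if (length(blacklist) == 0L) stop("blacklist must be non-empty")
  sm <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE)
  blDna <- Biostrings::DNAStringSet(chartr("U", "T",
                                           as.character(blacklist)))
  drop <- logical(length(candidateSeqs))
  hit <- rep(NA_character_, length(candidateSeqs))
  for (i in seq_along(candidateSeqs)) {
    candDna <- Biostrings::DNAString(chartr("U", "T",
      as.character(candidateSeqs[[i]])))
    clen <- length(candDna)
    for (b in seq_along(blDna)) {
      aln <- Biostrings::pairwiseAlignment(candDna, blDna[[b]],
        substitutionMatrix = sm, gapOpening = 4, gapExtension = 1,
        type = "local")
      alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (alnLen == 0L) next
      ident <- Biostrings::nmatch(aln) / alnLen
      covered <- nchar(gsub("-", "",
        as.character(Biostrings::alignedPattern(aln)))) / clen
      if (ident >= minIdentity && covered >= minCov) {
        drop[i] <- TRUE
        hit[i] <- names(blacklist)[b]
        break
      }
    }
  }
  report <- data.frame(candidate_id = names(candidateSeqs),
                       dropped = drop, blacklist_hit = hit,
                       stringsAsFactors = FALSE)
  list(retained = candidateSeqs[!drop], report = report)
}

#' Remove redundant isoforms, keeping the most expressed per group
#'
#' One candidate is kept per group key (assembly subcomponent / cluster):
#' the one with the highest abundance, ties broken by longer sequence, then
#' lexicographically smaller id.
#'
#' @param ids candidate ids.
#' @param group group key per candidate.
#' @param abundance numeric abundance per candidate.
#' @param length_nt sequence length per candidate (used for tie-breaking;
#'   defaults to 0).
#' @return character vector of retained ids (in input order).
#' @export
dedupeCandidates <- function(ids, group, abundance,
                             length_nt = rep(0L, length(ids))) {
  stopifnot(length(ids) == length(group), length(ids) == length(abundance))
  keep <- logical(length(ids))
  for (g in unique(group)) {
    idx <- which(group == g)
    best <- idx[order(-abundance[idx], -length_nt[idx], ids[idx])[1L]]
    keep[best] <- TRUE
  }
  ids[keep]
}

#' Normalise a count table by the pre-rRNA reference
#'
#' The nuclear pre-rRNA (present only in the nucleus, hence a per-sample
#' internal reference) rescales each sample:
#' `normalized(i, s) = count(i, s) / prerrna(s) * median_s(prerrna)`.
#' The pre-rRNA row becomes constant, and multiplying any sample's whole
#' column by a constant leaves its normalised values unchanged.
#'
#' @param counts non-negative count matrix, features x samples, containing
#'   the row named by `prerrnaId`.
#' @param prerrnaId row name of the pre-rRNA reference (default
#'   `"pre-rRNA"`).
#' @return numeric matrix of the same shape.
#' @export
normalizePreRRNA <- function(counts, prerrnaId = "pre-rRNA") {
  if (!prerrnaId %in% rownames(counts))
    stop("count table lacks the pre-rRNA reference row '", prerrnaId, "'")
  if (any(counts < 0)) stop("negative counts")
  ref <- counts[prerrnaId, ]
  zero <- colnames(counts)[ref == 0]
  if (length(zero) > 0L)
    stop("zero pre-rRNA count in sample(s): ", paste(zero, collapse = ", "))
  sweep(counts, 2L, ref, "/") * stats::median(ref)
}

# Vectorised Welch t-test on rows of two matrices of log2 values.
.welchRows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1L, stats::var); v2 <- apply(b, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: no variance at all
  flat <- se2 == 0
  p[flat] <- ifelse(m1[flat] == m2[flat], 1, 0)
  p
}

#' Leaf-vs-latex differential expression
#'
#' A stand-in for the count-model package used in the original screening
#' (which is not re-implemented).  With at least three replicates per
#' condition the default is a moderated t-test (limma `lmFit`/`eBayes`) on
#' `log2(normalized + pseudocount)`, which pools variance information
#' across features -- essential for power at n = 3; `method = "welch"`
#' gives a plain Welch t-test instead.  With fewer replicates, an exact
#' conditional binomial test of pooled raw counts against the pre-rRNA
#' depth ratio (the two-sample Poisson rate test).  P-values are
#' Benjamini--Hochberg adjusted; `de` is `fdr <= alpha`.  `real_fc` is the
#' pseudocounted latex/leaf ratio of mean normalised abundance, so it is
#' always finite and positive.
#'
#' @param counts raw count matrix including the pre-rRNA row.
#' @param latex,leaf sample (column) names of the two conditions.
#' @param prerrnaId pre-rRNA row name.
#' @param alpha FDR threshold (default 0.05).
#' @param pseudocount added to both means for the fold change (default 0.5).
#' @param method `"auto"` (moderated t when replicated, binomial
#'   otherwise), `"limma"`, `"welch"` or `"binomial"`.
#' @return data.frame (one row per feature, pre-rRNA excluded):
#'   `candidate_id`, `mean_leaf`, `mean_latex` (normalised), `real_fc`,
#'   `pvalue`, `fdr`, `de`; attribute `method` names the test used.
#' @export
differentialExpression <- function(counts, latex, leaf,
                                   prerrnaId = "pre-rRNA", alpha = 0.05,
                                   pseudocount = 0.5,
                                   method = c("auto", "limma", "welch",
                                              "binomial")) {
  method <- match.arg(method)
  if (length(latex) < 1L || length(leaf) < 1L)
    stop("both conditions need at least one sample")
  stopifnot(all(c(latex, leaf) %in% colnames(counts)))
  norm <- normalizePreRRNA(counts, prerrnaId)
  feat <- setdiff(rownames(counts), prerrnaId)
  nlat <- norm[feat, latex, drop = FALSE]
  nleaf <- norm[feat, leaf, drop = FALSE]
  mLat <- rowMeans(nlat); mLeaf <- rowMeans(nleaf)
  fc <- (mLat + pseudocount) / (mLeaf + pseudocount)
  replicated <- min(length(latex), length(leaf)) >= 3L
  if (method == "auto") method <- if (replicated) "limma" else "binomial"
  if (method == "limma") {
    method <- "limma_moderated_t_log2_prerrna_normalized"
    y <- cbind(log2(nlat + pseudocount), log2(nleaf + pseudocount))
    grp <- rep(c(1, 0), c(length(latex), length(leaf)))
    fit <- limma::eBayes(limma::lmFit(y, cbind(Intercept = 1, latex = grp)))
    p <- fit$p.value[, "latex"]
  } else if (method == "welch") {
    method <- "welch_t_log2_prerrna_normalized"
    p <- .welchRows(log2(nlat + pseudocount), log2(nleaf + pseudocount))
  } else {
    method <- "exact_binomial_prerrna_offset"
    if (replicated)
      .msg("binomial test on pooled counts; replicate overdispersion ",
           "is not modelled")
    dLat <- sum(counts[prerrnaId, latex])
    dLeaf <- sum(counts[prerrnaId, leaf])
    xLat <- rowSums(counts[feat, latex, drop = FALSE])
    xLeaf <- rowSums(counts[feat, leaf, drop = FALSE])
    p <- vapply(seq_along(feat), function(i) {
      tot <- xLat[i] + xLeaf[i]
      if (tot == 0) return(1)
      stats::binom.test(xLat[i], tot, p = dLat / (dLat + dLeaf))$p.value
    }, numeric(1))
  }
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(candidate_id = feat, mean_leaf = mLeaf,
                    mean_latex = mLat, real_fc = fc, pvalue = p, fdr = fdr,
                    de = fdr <= alpha, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "method") <- method
  out
}

#' Call the latex-abundant snoRNA set
#'
#' Differentially expressed candidates with latex/leaf fold change at least
#' `minFc`, sorted by fold change descending.
#'
#' @param de output of [differentialExpression()].
#' @param minFc minimum real fold change (default 2).
#' @return subset of `de`, sorted by `real_fc` descending.
#' @export
callLatexAbundant <- function(de, minFc = 2.0) {
  out <- de[de$de & de$real_fc >= minFc, , drop = FALSE]
  out[order(-out$real_fc, out$candidate_id), , drop = FALSE]
}
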