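test_that("box motifs are found at planted positions", {
  hits <- findBoxes("GGAUGAUGAGG", "C", 0L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 9L)
  expect_equal(hits$seq, "AUGAUGA")
  expect_equal(nrow(findBoxes("CCCCCCCC", "D", 0L)), 0L)
  expect_error(findBoxes("ACGU", "Q"), "unknown")
})

test_that("box search matches an exhaustive window matcher", {
  set.seed(7)
  s <- random_rna(500)
  for (kind in c("C", "D", "H", "ACA")) {
    pat <- switch(kind, C = "RUGAUGA", D = "CUGA", H = "ANANNA", ACA = "ACA")
    for (mm in 0:1) {
      got <- findBoxes(s, kind, mm)
      L <- nchar(pat)
      want <- which(vapply(seq_len(nchar(s) - L + 1), function(i)
        oracle_degenerate_mismatch(pat, substr(s, i, i + L - 1)) <= mm,
        logical(1)))
      expect_equal(got$start, want, info = paste(kind, mm))
    }
  }
})

test_that("foldStems detects designed stems and rejects unpairable regions", {
  h <- foldStems("GGGGAAAACCCC")
  expect_equal(h$pairs, 4L)
  expect_equal(h$stem5, c(1L, 4L))
  expect_equal(h$stem3, c(9L, 12L))
  expect_null(foldStems(paste(rep("A", 40), collapse = "")))
})

test_that("stack pairing matches Nussinov maximisation on hairpin regions", {
  # a single perfect stem is the unique optimal nested structure when the
  # loop and flanks cannot pair
  set.seed(67)
  for (i in 1:20) {
    k <- sample(4:9, 1)
    stem <- paste(sample(c("G", "C", "A", "U"), k, replace = TRUE),
                  collapse = "")
    loop <- paste(rep("A", sample(3:6, 1)), collapse = "")
    s <- paste0(stem, loop, reverseComplementRna(stem))
    h <- foldStems(s, minStemPairs = 4L)
    if (is.null(h)) next  # stem contains self-complementary interference
    expect_equal(h$pairs, oracle_nussinov(s), info = s)
  }
})

test_that("a planted C/D snoRNA is recovered with exact box coordinates", {
  set.seed(71)
  rrna <- random_rna(800)
  p <- which(strsplit(rrna, "")[[1]] == "G")[20] + 5  # ensures G at p-5
  pl <- planted_cd_transcript(rrna, p)
  sc <- scanCD(c(tx1 = pl$tx))
  expect_equal(length(sc), 1L)
  cr <- candidateRanges(sc)
  expect_equal(GenomicRanges::start(cr), pl$cand_start)
  expect_equal(GenomicRanges::end(cr), pl$cand_end)
  mb <- S4Vectors::mcols(candidateBoxes(sc))
  cb <- candidateBoxes(sc)[mb$kind == "C"]
  db <- candidateBoxes(sc)[mb$kind == "D"]
  expect_equal(GenomicRanges::start(cb), pl$c_start)
  expect_equal(GenomicRanges::start(db), pl$d_start)
})

test_that("candidates below the length bound are rejected", {
  # same boxes inside a sequence too short for the 50-nt minimum
  s <- paste0("AUGAUGA", random_rna(20), "CUGA")
  expect_equal(length(scanCD(c(x = paste0("AAAA", s, "AAAA")))), 0L)
})

test_that("planted C/D snoRNAs across many transcripts are all recovered", {
  rr <- simulateRRNAs(seed = 1)
  pl <- plantSnoRNAs(rr$rrnas, rr$sites, nCdGuide = 8, nHacaGuide = 0,
                     nOrphan = 0, nDecoy = 12, seed = 1)
  sc <- scanSnoRNAs(pl$transcripts)
  tr <- pl$truth
  expect_equal(length(sc), nrow(tr))
  got <- as.data.frame(candidateRanges(sc))
  m <- match(tr$id, S4Vectors::mcols(candidateRanges(sc))$candidate_id)
  expect_false(anyNA(m))
  expect_equal(got$start[m], tr$start)
  expect_equal(got$end[m], tr$end)
  mb <- as.data.frame(candidateBoxes(sc))
  for (i in seq_len(nrow(tr))) {
    cb <- mb[mb$candidate_id == tr$id[i] & mb$kind == "C", ]
    db <- mb[mb$candidate_id == tr$id[i] & mb$kind == "D", ]
    expect_equal(cb$start, tr$c_start[i])
    expect_equal(db$start, tr$d_start[i])
  }
})

test_that("planted H/ACA snoRNAs are recovered and nothing else is called", {
  rr <- simulateRRNAs(seed = 3)
  pl <- plantSnoRNAs(rr$rrnas, rr$sites, nCdGuide = 0, nHacaGuide = 6,
                     nOrphan = 0, nDecoy = 12, seed = 3)
  sc <- scanSnoRNAs(pl$transcripts)
  tr <- pl$truth
  # every plant recovered (overlap), every call overlaps a plant
  got <- as.data.frame(candidateRanges(sc))
  recovered <- vapply(seq_len(nrow(tr)), function(i) {
    any(got$seqnames == tr$transcript_id[i] &
          got$start <= tr$end[i] & got$end >= tr$start[i])
  }, logical(1))
  expect_true(all(recovered))
  spurious <- vapply(seq_len(nrow(got)), function(j) {
    !any(tr$transcript_id == got$seqnames[j] &
           tr$start <= got$end[j] & tr$end >= got$start[j])
  }, logical(1))
  expect_false(any(spurious))
})

test_that("mutating the ACA motif abolishes the H/ACA candidate", {
  rr <- simulateRRNAs(seed = 3)
  pl <- plantSnoRNAs(rr$rrnas, rr$sites, nCdGuide = 0, nHacaGuide = 1,
                     nOrphan = 0, nDecoy = 0, seed = 5)
  tr <- pl$truth
  tx <- as.character(pl$transcripts[[tr$transcript_id]])
  substr(tx, tr$aca_start, tr$aca_start + 2) <- "AGA"
  sc <- scanHACA(setNames(tx, tr$transcript_id))
  expect_equal(length(sc), 0L)
})

test_that("scan results are deterministic and invariant to input order", {
  b <- test_bundle()
  txs <- bundleTranscripts(b)
  sc1 <- scanSnoRNAs(txs)
  sc2 <- scanSnoRNAs(txs[rev(seq_along(txs))])
  expect_equal(sort(candidateIds(sc1)), sort(candidateIds(sc2)))
  d1 <- as.data.frame(candidateRanges(sc1))
  d2 <- as.data.frame(candidateRanges(sc2))
  key <- function(d) d[order(d$candidate_id), ]
  expect_equal(key(d1)$start, key(d2)$start)
  expect_equal(key(d1)$end, key(d2)$end)
})

test_that("every emitted candidate satisfies its subfamily invariants", {
  b <- test_bundle()
  sc <- scanSnoRNAs(bundleTranscripts(b))
  cand <- as.data.frame(candidateRanges(sc))
  boxes <- as.data.frame(candidateBoxes(sc))
  expect_true(all(cand$width >= 50 & cand$width <= 300))
  for (i in seq_len(nrow(cand))) {
    myb <- boxes[boxes$candidate_id == cand$candidate_id[i], ]
    if (cand$subfamily[i] == "CD") {
      expect_equal(sum(myb$kind == "C"), 1L)
      expect_equal(sum(myb$kind == "D"), 1L)
      expect_true(myb$start[myb$kind == "C"] < myb$start[myb$kind == "D"])
    } else {
      expect_equal(sum(myb$kind == "H"), 1L)
      expect_equal(sum(myb$kind == "ACA"), 1L)
      h <- myb[myb$kind == "H", ]; aca <- myb[myb$kind == "ACA", ]
      stems1 <- myb[myb$kind == "stem5" & myb$hairpin == 1, ]
      stems2 <- myb[myb$kind == "stem5" & myb$hairpin == 2, ]
      expect_true(stems1$start < h$start)       # hairpin 1 before H box
      expect_true(stems2$start > h$end)         # hairpin 2 after H box
      expect_true(aca$start > stems2$start)     # ACA after hairpin 2
      expect_equal(aca$end + 3L, cand$end[i])   # tail offset
    }
  }
})
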