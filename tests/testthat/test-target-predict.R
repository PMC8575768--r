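test_that("C/D guide elements end at the D-box first nucleotide", {
  set.seed(73)
  rrna <- random_rna(600)
  p <- which(strsplit(rrna, "")[[1]] == "G")[15] + 5
  pl <- planted_cd_transcript(rrna, p)
  sc <- scanCD(c(tx = pl$tx))
  g <- extractGuides(sc, minGuide = 9L, maxGuide = 12L)
  gd <- g[g$box_kind == "D", ]
  expect_equal(nrow(gd), 1L)
  expect_equal(gd$end, pl$d_start)              # first D nucleotide included
  expect_equal(gd$start, pl$d_start - 11L)      # maxGuide = 12
  expect_equal(nchar(gd$residues), 12L)
  # planted antisense element: guide equals revcomp of the target window
  # with the terminal D-box C
  antis <- reverseComplementRna(substr(rrna, p - 5, p + 6))
  expect_equal(gd$residues, antis)
})

test_that("perfect duplexes are enumerated with exact pair accounting", {
  set.seed(79)
  rrna <- random_rna(400)
  guide <- reverseComplementRna(substr(rrna, 101, 112))
  d <- enumerateDuplexes(guide, rrna, "r")
  perfect <- d[d$guide_len == 12 & d$target_start == 101, ]
  expect_equal(nrow(perfect), 1L)
  expect_equal(perfect$wc + perfect$gu, 12L)
  expect_equal(perfect$mm, 0L)
  expect_equal(perfect$target_end, 112L)
})

test_that("a guide violating the mismatch cap everywhere finds nothing", {
  # rRNA of A only; guide of A only pairs nothing (A-A is a mismatch)
  rrna <- paste(rep("A", 60), collapse = "")
  guide <- paste(rep("A", 12), collapse = "")
  expect_equal(nrow(enumerateDuplexes(guide, rrna)), 0L)
})

test_that("duplex enumeration equals the brute-force oracle", {
  set.seed(5)
  for (rep in 1:4) {
    rrna <- random_rna(300)
    guide <- if (rep %% 2 == 0) random_rna(15) else
      reverseComplementRna(substr(rrna, 50, 63))
    got <- enumerateDuplexes(guide, rrna, "r")
    want <- oracle_enumerate_duplexes(guide, rrna)
    key <- function(d) d[order(d$guide_len, d$target_start), ]
    got <- key(got); want <- key(want)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$target_start, want$target_start)
    expect_equal(got$wc, want$wc)
    expect_equal(got$gu, want$gu)
    expect_equal(got$mm, want$mm)
    expect_equal(got$score, want$score)
  }
})

test_that("duplex scores follow the declared weights and are monotone", {
  expect_equal(scoreDuplex(12, 0, 0), 24)
  expect_equal(scoreDuplex(9, 2, 1), 13)
  w <- duplexWeights()
  expect_equal(scoreDuplex(7, 1, 0), 7 * w$wc + w$gu)
  set.seed(5)
  for (i in 1:50) {
    wc <- sample(0:15, 1); gu <- sample(0:2, 1); mm <- sample(0:1, 1)
    expect_gte(scoreDuplex(wc + 1, gu, mm), scoreDuplex(wc, gu, mm))
  }
})

test_that("the D+5 rule calls the methylated nucleotide by pairing-map lookup", {
  set.seed(83)
  rrna <- random_rna(300)
  p <- 120
  guide <- reverseComplementRna(substr(rrna, p - 5, p + 6))
  d <- enumerateDuplexes(guide, rrna, "r")
  row <- d[d$guide_len == 12 & d$target_start == p - 5, ]
  site <- callMethylationSite(row, rrna)
  # explicit pairing-map oracle: guide index (L - 5) pairs window start + 5
  expect_equal(site$position, p)
  expect_equal(site$nucleotide, substr(rrna, p, p))
  expect_equal(site$mtype, "Nm")
  # duplex covering fewer than 5 guide positions upstream of the D box
  short <- row; short$guide_len <- 5
  expect_null(callMethylationSite(short, rrna))
})

test_that("pseudouridylation calls return the bracketed U only", {
  set.seed(89)
  rrna <- random_rna(500)
  ch <- strsplit(rrna, "")[[1]]
  us <- which(ch == "U")
  p <- us[us > 12 & us < 480][10]
  p5 <- reverseComplementRna(substr(rrna, p + 2, p + 11))
  p3 <- reverseComplementRna(substr(rrna, p - 10, p - 1))
  d <- callPseudouridylationSite(p5, p3, rrna, "r")
  expect_true(p %in% d$position)
  best <- d[which.max(d$score), ]
  expect_equal(best$position, p)
  expect_equal(best$wc + best$gu, 20L)
  expect_equal(best$mm, 0L)
  expect_true(all(substring(rrna, d$position, d$position) == "U"))
})

test_that("a bracketed C is never called as a psi site", {
  set.seed(97)
  rrna <- random_rna(300)
  p <- which(strsplit(rrna, "")[[1]] == "C")[20]
  p5 <- reverseComplementRna(substr(rrna, p + 2, p + 11))
  p3 <- reverseComplementRna(substr(rrna, p - 10, p - 1))
  d <- callPseudouridylationSite(p5, p3, rrna, "r")
  expect_false(p %in% d$position)
})

test_that("pocket enumeration agrees with a naive exhaustive oracle", {
  set.seed(101)
  rrna <- random_rna(250)
  p5 <- random_rna(9); p3 <- random_rna(9)
  got <- callPseudouridylationSite(p5, p3, rrna, "r", minPocketPair = 5L)
  # oracle: for every U, best admissible prefix/suffix pair per side
  r <- strsplit(rrna, "")[[1]]
  w <- duplexWeights()
  side <- function(chars, rpos) {
    best <- -Inf
    for (L in 5:length(chars)) {
      wc <- gu <- mm <- 0
      for (k in 1:L) {
        pr <- paste0(chars[k], r[rpos(k)])
        if (pr %in% c("AU", "UA", "CG", "GC")) wc <- wc + 1
        else if (pr %in% c("GU", "UG")) gu <- gu + 1
        else mm <- mm + 1
      }
      if (mm <= 1 && gu <= 2)
        best <- max(best, w$wc * wc + w$gu * gu + w$mismatch * mm)
    }
    best
  }
  p3c <- strsplit(p3, "")[[1]]; p5c <- rev(strsplit(p5, "")[[1]])
  for (p in seq(11, 230)) {
    if (r[p] != "U") next
    s3 <- side(p3c, function(k) p - k)
    s5 <- side(p5c, function(k) p + 1 + k)
    inGot <- p %in% got$position
    expect_equal(inGot, is.finite(s3) && is.finite(s5), info = p)
    if (inGot)
      expect_equal(got$score[got$position == p], s3 + s5)
  }
})

test_that("guide classification applies the printed thresholds", {
  expect_equal(classifyGuide("CD", 15, FALSE), "guide")    # 15 > 14
  expect_equal(classifyGuide("CD", 14, FALSE), "orphan")   # strict
  expect_equal(classifyGuide("CD", 15, TRUE), "orphan")    # 15 < 20
  expect_equal(classifyGuide("CD", 20, TRUE), "guide")     # >= for exon
  expect_equal(classifyGuide("HACA", 41, FALSE), "guide")  # 41 > 40
  expect_equal(classifyGuide("HACA", 40, FALSE), "orphan")
  expect_equal(classifyGuide("HACA", 45, TRUE), "guide")
  expect_equal(classifyGuide("CD", NA, FALSE), "orphan")   # no duplex
})

test_that("raising thresholds never increases the guide count", {
  b <- test_bundle()
  sc <- scanSnoRNAs(bundleTranscripts(b))
  base <- scoreThresholds()
  pt0 <- predictTargets(sc, bundleRRNAs(b), thresholds = base)
  n0 <- sum(candidateClasses(pt0$candidates) == "guide")
  for (bump in c(2, 10, 30)) {
    thr <- base
    thr$cd <- thr$cd + bump; thr$haca <- thr$haca + bump
    ptb <- predictTargets(sc, bundleRRNAs(b), thresholds = thr)
    nb <- sum(candidateClasses(ptb$candidates) == "guide")
    expect_lte(nb, n0)
    n0 <- nb
  }
})

test_that("emitted duplex assignments satisfy the printed constraints", {
  b <- test_bundle()
  sc <- scanSnoRNAs(bundleTranscripts(b))
  pt <- predictTargets(sc, bundleRRNAs(b))
  a <- pt$assignments
  # C/D: one duplex per assignment; H/ACA: counts sum two pocket duplexes,
  # each individually capped
  cd <- a$subfamily == "CD"
  expect_true(all(a$mm[cd] <= 1))
  expect_true(all(a$gu[cd] <= 2))
  expect_true(all(a$mm[!cd] <= 2))
  expect_true(all(a$gu[!cd] <= 4))
  expect_true(all(a$position >= a$target_start & a$position <= a$target_end))
  expect_true(all(a$mtype %in% c("Nm", "psi")))
  expect_true(all(a$nucleotide[a$mtype == "psi"] == "U"))
  # one primary per assigned candidate
  prim <- table(a$candidate_id[a$primary])
  expect_true(all(prim == 1))
})
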