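test_that("global alignment of identical sequences is gapless full score", {
  set.seed(41)
  s <- random_rna(100)
  aln <- globalAlign(s, s)
  expect_equal(aln$score, 100)
  expect_equal(aln$ref_aln, s)
  expect_equal(aln$tgt_aln, s)
})

test_that("a single deletion costs one gap column", {
  aln <- globalAlign("ACGU", "ACU")
  expect_equal(nchar(aln$ref_aln), 4L)
  expect_equal(sum(strsplit(aln$tgt_aln, "")[[1]] == "-"), 1L)
  expect_equal(aln$score, 3 - (4 + 1))   # 3 matches, gap open 4 + extend 1
})

test_that("alignment score equals exhaustive enumeration on short inputs", {
  set.seed(43)
  for (i in 1:30) {
    a <- random_rna(sample(2:8, 1))
    b <- random_rna(sample(2:8, 1))
    expect_equal(globalAlign(a, b)$score, oracle_global_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("position mapping follows gaps and reports deletions as NA", {
  s <- random_rna(80, seed = 47)
  ident <- globalAlign(s, s)
  expect_equal(mapPosition(ident, 42), 42)
  expect_error(mapPosition(ident, 0), "out of range")
  expect_error(mapPosition(ident, 81), "out of range")
  # 3-nt insertion in the target before the site shifts it by +3
  tgt <- paste0(substr(s, 1, 30), "GCA", substr(s, 31, 80))
  aln <- globalAlign(s, tgt)
  expect_equal(mapPosition(aln, 50), 53)
  expect_equal(mapPosition(aln, 10), 10)
  # deletion covering the site maps to NA
  tgt2 <- paste0(substr(s, 1, 39), substr(s, 46, 80))
  aln2 <- globalAlign(s, tgt2)
  expect_true(is.na(mapPosition(aln2, 42)))
})

test_that("transfer onto an identical sequence is the identity", {
  set.seed(53)
  s <- random_rna(300)
  ch <- strsplit(s, "")[[1]]
  us <- which(ch == "U")[1:4]
  others <- setdiff(seq(20, 280, by = 25), us)[1:6]
  sites <- GenomicRanges::GRanges("ref",
    IRanges::IRanges(c(others, us), width = 1),
    nucleotide = ch[c(others, us)],
    mtype = rep(c("Nm", "psi"), c(6, 4)),
    provenance = "reference")
  aln <- globalAlign(s, s, referenceId = "ref", targetId = "tgt")
  out <- transferSites(aln, sites)
  expect_equal(length(out), 10L)
  expect_equal(GenomicRanges::start(out), c(others, us))
  expect_equal(S4Vectors::mcols(out)$mtype, rep(c("Nm", "psi"), c(6, 4)))
  expect_true(all(S4Vectors::mcols(out)$provenance == "transferred"))
  expect_equal(nrow(attr(out, "dropped")), 0L)
})

test_that("psi sites landing on a non-U target are dropped with a reason", {
  ref <- "AAAAAAAAAAUAAAAAAAAAA"
  tgt <- "AAAAAAAAAACAAAAAAAAAA"   # the U became a C
  sites <- GenomicRanges::GRanges("ref", IRanges::IRanges(11, width = 1),
    nucleotide = "U", mtype = "psi", provenance = "reference")
  aln <- globalAlign(ref, tgt, referenceId = "ref", targetId = "tgt")
  out <- transferSites(aln, sites)
  expect_equal(length(out), 0L)
  expect_equal(attr(out, "dropped")$reason, "nucleotide_mismatch")
})

test_that("sites referencing the wrong rRNA are rejected", {
  sites <- GenomicRanges::GRanges("otherRef", IRanges::IRanges(5, width = 1),
    nucleotide = "A", mtype = "Nm", provenance = "reference")
  aln <- globalAlign("ACGUACGU", "ACGUACGU", referenceId = "ref")
  expect_error(transferSites(aln, sites), "otherRef")
})

test_that("transfer through planted indels matches the ground-truth map", {
  set.seed(59)
  ref <- random_rna(600)
  # plant 3 indels at known reference positions: del 101-103, ins after
  # 300 (4 nt), del 451-452
  tgt <- paste0(substr(ref, 1, 100), substr(ref, 104, 300), "GGCC",
                substr(ref, 301, 450), substr(ref, 453, 600))
  shift <- function(p) {
    if (p <= 100) return(p + 0)
    if (p >= 104 && p <= 300) return(p - 3)
    if (p >= 301 && p <= 450) return(p - 3 + 4)
    if (p >= 453) return(p - 3 + 4 - 2)
    NA_real_   # site inside a deletion
  }
  pos <- c(50, 150, 250, 320, 400, 500, 560)
  ch <- strsplit(ref, "")[[1]]
  sites <- GenomicRanges::GRanges("ref", IRanges::IRanges(pos, width = 1),
    nucleotide = ch[pos], mtype = "Nm", provenance = "reference")
  aln <- globalAlign(ref, tgt, referenceId = "ref", targetId = "tgt")
  out <- transferSites(aln, sites)
  want <- vapply(pos, shift, numeric(1))
  expect_equal(GenomicRanges::start(out), as.integer(want[!is.na(want)]))
  # bookkeeping: outputs plus drop reasons partition the input
  expect_equal(length(out) + nrow(attr(out, "dropped")), length(pos))
})

test_that("low-context sites are dropped under the identity filter", {
  set.seed(61)
  ref <- random_rna(200)
  ch <- strsplit(ref, "")[[1]]
  # corrupt a 9-nt neighbourhood around position 100 in the target, but
  # keep the site residue itself
  mut <- ch
  for (i in c(96:99, 101:104)) {
    mut[i] <- setdiff(c("A", "C", "G", "U"), ch[i])[1]
  }
  tgt <- paste(mut, collapse = "")
  sites <- GenomicRanges::GRanges("ref", IRanges::IRanges(100, width = 1),
    nucleotide = ch[100], mtype = "Nm", provenance = "reference")
  aln <- globalAlign(ref, tgt, referenceId = "ref", targetId = "tgt")
  out <- transferSites(aln, sites, contextWindow = 5, minContextIdentity = 0.8)
  expect_equal(length(out), 0L)
  expect_equal(attr(out, "dropped")$reason, "low_context")
})
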