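test_that("blacklist filtering drops contained candidates and keeps others", {
  set.seed(13)
  bl <- c(rrna_a = random_rna(500), est_b = random_rna(400))
  contained <- substr(bl[["rrna_a"]], 101, 180)   # exact 80-nt substring
  unrelated <- random_rna(100)
  res <- filterBlacklist(c(hit = contained, miss = unrelated), bl)
  expect_equal(names(res$retained), "miss")
  expect_true(res$report$dropped[res$report$candidate_id == "hit"])
  expect_equal(res$report$blacklist_hit[res$report$candidate_id == "hit"],
               "rrna_a")
  expect_error(filterBlacklist(c(x = "ACGU"), character(0)), "non-empty")
})

test_that("blacklist decisions match the quadratic local-alignment oracle", {
  set.seed(13)
  decisions <- logical(0); oracleDecisions <- logical(0)
  for (i in 1:40) {
    bl <- random_rna(300)
    cand <- if (i %% 4 == 0) {
      # near-copy: substring with a couple of substitutions
      s <- substr(bl, 51, 150)
      ch <- strsplit(s, "")[[1]]
      for (k in sample(100, 3)) ch[k] <- setdiff(c("A","C","G","U"), ch[k])[1]
      paste(ch, collapse = "")
    } else random_rna(100)
    res <- filterBlacklist(setNames(cand, "c"), setNames(bl, "b"))
    orc <- oracle_local_align(cand, bl)
    decisions <- c(decisions, res$report$dropped)
    oracleDecisions <- c(oracleDecisions,
                         orc$identity >= 0.9 && orc$coverage >= 0.8)
    expect_equal(res$report$dropped, orc$identity >= 0.9 && orc$coverage >= 0.8,
                 info = i)
  }
  expect_true(any(decisions))        # the planted near-copies were dropped
  expect_false(all(decisions))
})

test_that("redundancy removal keeps the most expressed isoform per group", {
  ids <- c("a1", "a2", "b1", "c1", "c2", "c3")
  grp <- c("a", "a", "b", "c", "c", "c")
  ab <- c(5, 10, 2, 7, 7, 1)
  len <- c(100, 90, 80, 120, 150, 60)
  kept <- dedupeCandidates(ids, grp, ab, len)
  expect_setequal(kept, c("a2", "b1", "c2"))  # c: tie on 7, longer wins
  # random grouping equals a per-group argmax oracle
  set.seed(2)
  n <- 60
  ids <- sprintf("x%02d", 1:n)
  grp <- sample(letters[1:12], n, replace = TRUE)
  ab <- round(runif(n, 0, 50), 3)
  len <- sample(50:300, n, replace = TRUE)
  kept <- dedupeCandidates(ids, grp, ab, len)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    best <- idx[order(-ab[idx], -len[idx], ids[idx])[1]]
    expect_true(ids[best] %in% kept)
    expect_equal(sum(ids[idx] %in% kept), 1L)
  }
})

test_that("pre-rRNA normalisation equalises proportional samples", {
  cnt <- rbind(cand = c(A = 10, B = 20), `pre-rRNA` = c(A = 1000, B = 2000))
  norm <- normalizePreRRNA(cnt)
  expect_equal(norm["cand", "A"], norm["cand", "B"])
  expect_equal(unname(norm["pre-rRNA", ]), rep(median(c(1000, 2000)), 2),
               ignore_attr = TRUE)
  # equal pre-rRNA across samples: a global constant rescale
  cnt2 <- rbind(x = c(3, 9, 12), `pre-rRNA` = c(500, 500, 500))
  expect_equal(unname(normalizePreRRNA(cnt2)["x", ]), c(3, 9, 12))
  bad <- rbind(x = c(1, 2), `pre-rRNA` = c(100, 0))
  colnames(bad) <- c("s1", "s2")
  expect_error(normalizePreRRNA(bad), "s2")
  expect_error(normalizePreRRNA(rbind(x = c(1, 2))), "pre-rRNA")
})

test_that("normalisation is invariant to per-sample library rescaling", {
  set.seed(107)
  cnt <- matrix(rpois(40, 50), nrow = 10,
                dimnames = list(c(sprintf("f%d", 1:9), "pre-rRNA"),
                                sprintf("s%d", 1:4)))
  norm0 <- normalizePreRRNA(cnt)
  cnt2 <- cnt
  cnt2[, 2] <- cnt2[, 2] * 7          # scale a whole column, reference too
  norm2 <- normalizePreRRNA(cnt2)
  expect_equal(norm2[, 2] / norm0[, 2],
               rep(median(cnt2["pre-rRNA", ]) / median(cnt["pre-rRNA", ]), 10),
               ignore_attr = TRUE)
  # ratios between features within the rescaled sample are unchanged
  expect_equal(norm2[1:9, 2] / norm2[5, 2], norm0[1:9, 2] / norm0[5, 2])
})

test_that("BH adjustment matches the reference step-up computation", {
  set.seed(109)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("identical conditions give unit fold change and no calls", {
  cnt <- rbind(matrix(50, nrow = 4, ncol = 6,
                      dimnames = list(sprintf("f%d", 1:4), NULL)),
               `pre-rRNA` = 1000)
  colnames(cnt) <- c(paste0("latex_", 1:3), paste0("leaf_", 1:3))
  de <- differentialExpression(cnt, paste0("latex_", 1:3),
                               paste0("leaf_", 1:3))
  expect_equal(de$real_fc, rep(1, 4))
  expect_false(any(de$de))
})

test_that("the exact binomial branch is used for unreplicated designs", {
  set.seed(113)
  cnt <- rbind(f1 = c(400, 10), f2 = c(20, 22), `pre-rRNA` = c(1000, 1000))
  colnames(cnt) <- c("latex_1", "leaf_1")
  de <- differentialExpression(cnt, "latex_1", "leaf_1")
  expect_equal(attr(de, "method"), "exact_binomial_prerrna_offset")
  expect_lt(de$pvalue[de$candidate_id == "f1"], 1e-10)
  expect_gt(de$pvalue[de$candidate_id == "f2"], 0.5)
})

test_that("null counts stay quiet and planted fold changes are detected", {
  ids <- sprintf("f%03d", 1:400)
  planted <- ids[1:40]
  cnt <- simulateCounts(ids, planted, seed = 17)
  de <- differentialExpression(cnt, paste0("latex_", 1:3),
                               paste0("leaf_", 1:3))
  sens <- mean(de$de[de$candidate_id %in% planted])
  expect_gte(sens, 0.85)
  fdp <- sum(de$de & !(de$candidate_id %in% planted)) / max(1, sum(de$de))
  expect_lte(fdp, 0.15)
  null <- simulateCounts(ids, character(0), seed = 19)
  deN <- differentialExpression(null, paste0("latex_", 1:3),
                                paste0("leaf_", 1:3))
  expect_lte(mean(deN$de), 0.02)
})

test_that("latex-abundant calls honour the fold-change floor and ordering", {
  de <- data.frame(candidate_id = c("a", "b", "c", "d"),
                   mean_leaf = 1, mean_latex = 1,
                   real_fc = c(2.41, 1.5, 9.7, 3.3),
                   pvalue = 0.001, fdr = c(0.01, 0.01, 0.01, 0.2),
                   de = c(TRUE, TRUE, TRUE, FALSE))
  out <- callLatexAbundant(de, minFc = 2)
  expect_equal(out$candidate_id, c("c", "a"))   # b below floor, d not DE
  expect_true(all(diff(out$real_fc) <= 0))
})
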