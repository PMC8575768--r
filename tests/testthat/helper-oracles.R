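# Independent oracles: deliberately naive implementations used only to
# check the package's optimised code paths.

# per-position IUPAC set membership
oracle_degenerate_mismatch <- function(pattern, window) {
  sets <- list(A = "A", C = "C", G = "G", U = "U",
               R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"),
               W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
               B = c("C", "G", "U"), D = c("A", "G", "U"),
               H = c("A", "C", "U"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "U"))
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  n <- 0L
  for (i in seq_along(p)) if (!(w[i] %in% sets[[p[i]]])) n <- n + 1L
  n
}

# exhaustive global alignment score by recursive enumeration; gap run of
# length L costs gapOpen + L * gapExt (same convention as globalAlign)
oracle_global_align_score <- function(a, b, match = 1, mismatch = -1,
                                      gapOpen = 4, gapExt = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(a)) {   # gap in b
      cost <- if (prev == "gb") gapExt else gapOpen + gapExt
      best <- max(best, -cost + rec(i + 1, j, "gb"))
    }
    if (j <= length(b)) {   # gap in a
      cost <- if (prev == "ga") gapExt else gapOpen + gapExt
      best <- max(best, -cost + rec(i, j + 1, "ga"))
    }
    best
  }
  rec(1, 1, "m")
}

oracle_can_pair <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

# Nussinov-style maximum nested pairing (WC + GU, min loop)
oracle_nussinov <- function(s, minLoop = 3) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 2) return(0)
  M <- matrix(0L, n, n)
  for (span in 2:n) {
    for (i in seq_len(n - span + 1)) {
      j <- i + span - 1
      best <- M[i + 1, j]  # actually handled below; R indexing guard
      best <- if (i + 1 <= j) M[i + 1, j] else 0L
      for (k in (i + 1):j) {
        if (k - i - 1 >= minLoop && oracle_can_pair(ch[i], ch[k])) {
          left <- if (i + 1 <= k - 1) M[i + 1, k - 1] else 0L
          right <- if (k + 1 <= j) M[k + 1, j] else 0L
          best <- max(best, 1L + left + right)
        }
      }
      M[i, j] <- best
    }
  }
  M[1, n]
}

# naive duplex enumeration: every guide suffix length x every window
oracle_enumerate_duplexes <- function(guide, rrna, minLen = 9, maxLen = 21,
                                      maxMismatch = 1, maxGU = 2,
                                      wWc = 2, wGu = 0.5, wMm = -6) {
  g <- strsplit(guide, "")[[1]]; r <- strsplit(rrna, "")[[1]]
  out <- list()
  for (L in minLen:min(maxLen, length(g))) {
    gs <- g[(length(g) - L + 1):length(g)]
    for (w in seq_len(length(r) - L + 1)) {
      wc <- gu <- mm <- 0L
      for (k in seq_len(L)) {
        pair <- paste0(gs[k], r[w + L - k])
        if (pair %in% c("AU", "UA", "CG", "GC")) wc <- wc + 1L
        else if (pair %in% c("GU", "UG")) gu <- gu + 1L
        else mm <- mm + 1L
      }
      if (mm <= maxMismatch && gu <= maxGU)
        out[[length(out) + 1]] <- data.frame(
          guide_len = L, target_start = w, target_end = w + L - 1,
          wc = wc, gu = gu, mm = mm,
          score = wWc * wc + wGu * gu + wMm * mm)
    }
  }
  if (length(out) == 0)
    return(data.frame(guide_len = integer(0), target_start = integer(0),
                      target_end = integer(0), wc = integer(0),
                      gu = integer(0), mm = integer(0), score = numeric(0)))
  do.call(rbind, out)
}

# affine-gap Smith-Waterman with traceback; returns identity over aligned
# columns and coverage of `a`
oracle_local_align <- function(a, b, match = 1, mismatch = -1,
                               gapOpen = 4, gapExt = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- E <- FF <- matrix(0, n + 1, m + 1)
  E[] <- -Inf; FF[] <- -Inf
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gapOpen - gapExt, E[i, j - 1] - gapExt)
      FF[i, j] <- max(H[i - 1, j] - gapOpen - gapExt, FF[i - 1, j] - gapExt)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], FF[i, j])
      if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
    }
  }
  if (best == 0) return(list(score = 0, identity = 0, coverage = 0))
  # traceback
  i <- bi; j <- bj; matches <- 0; cols <- 0; acov <- 0
  state <- "H"
  while (i > 1 || j > 1) {
    if (state == "H") {
      if (H[i, j] == 0) break
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      if (i > 1 && j > 1 && H[i, j] == H[i - 1, j - 1] + s) {
        cols <- cols + 1; acov <- acov + 1
        if (A[i - 1] == B[j - 1]) matches <- matches + 1
        i <- i - 1; j <- j - 1
      } else if (H[i, j] == E[i, j]) state <- "E"
      else if (H[i, j] == FF[i, j]) state <- "F"
      else break
    } else if (state == "E") {
      cols <- cols + 1
      if (E[i, j] == H[i, j - 1] - gapOpen - gapExt) state <- "H"
      j <- j - 1
    } else {
      cols <- cols + 1; acov <- acov + 1
      if (FF[i, j] == H[i - 1, j] - gapOpen - gapExt) state <- "H"
      i <- i - 1
    }
  }
  list(score = best, identity = matches / cols, coverage = acov / n)
}

# definitional Spearman: Pearson on average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mean((rx - mean(rx)) * (ry - mean(ry))) / (sd(rx) * sd(ry)) *
    length(x) / (length(x) - 1)
}

# reference BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
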