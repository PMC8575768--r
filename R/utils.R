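# Internal helpers shared across modules.

.RNA_ALPHABET <- c("A", "C", "G", "U", "N")

# IUPAC degenerate codes over the RNA alphabet.
.IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.checkResidues <- function(s, id = "<sequence>") {
  ch <- unique(.chars(s))
  bad <- setdiff(ch, .RNA_ALPHABET)
  if (length(bad) > 0L) {
    stop("sequence '", id, "' contains non-RNA characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Normalise a raw string to the internal RNA alphabet: uppercase, T -> U.
.asRna <- function(s) chartr("Tt", "Uu", toupper(s))

# Classify base pairs of an antiparallel duplex: 2 = Watson-Crick,
# 1 = GU wobble, 0 = mismatch.  Vectorised over equal-length inputs.
.pairClass <- function(a, b) {
  key <- paste0(a, b)
  wc <- key %in% c("AU", "UA", "CG", "GC")
  gu <- key %in% c("GU", "UG")
  ifelse(wc, 2L, ifelse(gu, 1L, 0L))
}

# TRUE where two residues can pair (WC or GU).
.canPair <- function(a, b) .pairClass(a, b) > 0L

.msg <- function(..., verbose = getOption("snoLatex.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

# Deterministic local RNG scope: run `expr` under `seed` (if non-NULL)
# without clobbering the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.randomRna <- function(n, p = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
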