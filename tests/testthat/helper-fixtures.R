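# Shared fixtures, built in code.  The seed-42 bundle is expensive
# (planting is self-validating), so it is built once per test run.

.fixture_env <- new.env(parent = emptyenv())

test_bundle <- function() {
  if (is.null(.fixture_env$bundle42))
    .fixture_env$bundle42 <- simulateBundle(seed = 42)
  .fixture_env$bundle42
}

random_rna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# a transcript with one planted C/D snoRNA and known coordinates:
# flank | pad4 C-box spacer antisense11 D-box pad4 | flank
planted_cd_transcript <- function(rrna, p, flank5 = 50, flank3 = 50,
                                  spacerLen = 45) {
  antis12 <- reverseComplementRna(substr(rrna, p - 5, p + 6))
  stopifnot(substr(antis12, 12, 12) == "C")  # requires rrna[p-5] == "G"
  # fixed C pads cannot complete a shifted RUGAUGA/CUGA, keeping the box
  # coordinates unambiguous
  cand <- paste0("CCCC", "AUGAUGA", random_rna(spacerLen),
                 substr(antis12, 1, 11), "CUGA", "CCCC")
  tx <- paste0(random_rna(flank5), cand, random_rna(flank3))
  a <- flank5 + 1
  list(tx = tx, cand_start = a, cand_end = a + nchar(cand) - 1,
       c_start = a + 4, d_start = a + 4 + 7 + spacerLen + 11)
}

extdata_path <- function(file) {
  system.file("extdata", file, package = "snoLatex", mustWork = TRUE)
}
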