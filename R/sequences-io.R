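#' Read RNA sequences from FASTA
#'
#' Reads a FASTA file into an [Biostrings::RNAStringSet].  DNA input is
#' silently normalised to the RNA alphabet (`T` -> `U`), residues are
#' case-folded to upper case and sequence ids are taken as the first
#' whitespace token of each header.  Duplicate ids, empty files, empty
#' records and non-IUPAC characters are rejected with the offending record
#' named.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return `RNAStringSet` over the alphabet `A,C,G,U,N`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x some description", "ACGT"), f)
#' as.character(readRnaFasta(f))  # "ACGU"
#' @export
readRnaFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- .asRna(as.character(raw))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) < 1L) stop("empty sequence for record '", ids[i], "'")
    .checkResidues(seqs[i], ids[i])
  }
  Biostrings::RNAStringSet(setNames(seqs, ids))
}

#' Write RNA sequences to FASTA
#'
#' @param x `RNAStringSet` (or named character vector of RNA strings).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRnaFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::RNAStringSet(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all sequences must be named")
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Antiparallel reverse complement of an RNA string
#'
#' `A<->U`, `C<->G`, `N<->N`.  Applying the function twice is the identity.
#'
#' @param s RNA residue string over `A,C,G,U,N`.
#' @return reverse-complemented string.
#' @examples
#' reverseComplementRna("AAGG")  # "CCUU"
#' @export
reverseComplementRna <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  .checkResidues(s)
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
}

#' Mismatches of a window against a degenerate IUPAC pattern
#'
#' Counts positions where the window residue falls outside the allowed set
#' of the pattern's IUPAC code (e.g. `R = {A,G}`, `N = {A,C,G,U}`).  Used
#' for box-motif matching (C box `RUGAUGA`, H box `ANANNA`, ...).
#'
#' @param pattern IUPAC RNA string.
#' @param window plain RNA string of the same length.
#' @return integer mismatch count.
#' @examples
#' matchDegenerate("RUGAUGA", "AUGAUGA")  # 0
#' matchDegenerate("RUGAUGA", "CUGAUGA")  # 1
#' @export
matchDegenerate <- function(pattern, window) {
  stopifnot(is.character(pattern), is.character(window))
  if (nchar(pattern) != nchar(window))
    stop("pattern and window lengths differ (", nchar(pattern), " vs ",
         nchar(window), ")")
  p <- .chars(pattern)
  w <- .chars(window)
  bad <- setdiff(unique(p), names(.IUPAC_RNA))
  if (length(bad) > 0L)
    stop("invalid IUPAC code(s) in pattern: ", paste(bad, collapse = ", "))
  .checkResidues(window)
  sum(vapply(seq_along(p),
             function(i) !(w[i] %in% .IUPAC_RNA[[p[i]]]), logical(1)))
}

# ---- candidate GFF3 / TSV output ------------------------------------------

#' Write snoRNA candidates as GFF3
#'
#' Candidates are emitted as `snoRNA` features with `subfamily`, `cls` and
#' `score` attributes; box and structure elements as child features typed by
#' their kind.  Coordinates are 1-based inclusive.  Rows are ordered by
#' transcript id then start so output is deterministic.
#'
#' @param x `SnoCandidateSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCandidatesGFF3 <- function(x, path) {
  stopifnot(methods::is(x, "SnoCandidateSet"))
  cand <- x@candidates
  if (length(cand) > 0L) {
    mc <- S4Vectors::mcols(cand)
    ord <- order(as.character(GenomicRanges::seqnames(cand)),
                 GenomicRanges::start(cand), mc$candidate_id)
    cand <- cand[ord]
    mc <- S4Vectors::mcols(cand)
    S4Vectors::mcols(cand) <- S4Vectors::DataFrame(
      source = "snoLatex", type = "snoRNA",
      score = as.numeric(mc$score),
      ID = mc$candidate_id, subfamily = mc$subfamily, cls = mc$cls,
      n_box_mm = as.integer(mc$n_box_mm),
      stem_pairs = as.integer(mc$stem_pairs),
      exon_overlap = as.logical(mc$exon_overlap))
  }
  boxes <- x@boxes
  if (length(boxes) > 0L) {
    mb <- S4Vectors::mcols(boxes)
    ord <- order(as.character(GenomicRanges::seqnames(boxes)),
                 GenomicRanges::start(boxes), mb$candidate_id, mb$kind)
    boxes <- boxes[ord]
    mb <- S4Vectors::mcols(boxes)
    S4Vectors::mcols(boxes) <- S4Vectors::DataFrame(
      source = "snoLatex", type = mb$kind,
      Parent = mb$candidate_id,
      hairpin = as.integer(mb$hairpin),
      mismatches = as.integer(mb$mismatches))
  }
  all <- c(cand, boxes)
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Re-read candidates written by [writeCandidatesGFF3()]
#'
#' @param path GFF3 file.
#' @param transcripts optional `RNAStringSet` to re-attach.
#' @return `SnoCandidateSet`.
#' @export
readCandidatesGFF3 <- function(path, transcripts = Biostrings::RNAStringSet()) {
  g <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(g)
  isCand <- as.character(mc$type) == "snoRNA"
  cand <- g[isCand]
  boxes <- g[!isCand]
  cm <- S4Vectors::mcols(cand)
  S4Vectors::mcols(cand) <- S4Vectors::DataFrame(
    candidate_id = as.character(cm$ID),
    subfamily = as.character(cm$subfamily),
    n_box_mm = as.integer(cm$n_box_mm),
    stem_pairs = as.integer(cm$stem_pairs),
    score = as.numeric(cm$score),
    cls = as.character(cm$cls),
    exon_overlap = as.logical(cm$exon_overlap))
  if (length(boxes) > 0L) {
    bm <- S4Vectors::mcols(boxes)
    parent <- vapply(bm$Parent, function(p) as.character(p)[1L], character(1))
    S4Vectors::mcols(boxes) <- S4Vectors::DataFrame(
      candidate_id = parent,
      kind = as.character(bm$type),
      hairpin = as.integer(bm$hairpin),
      mismatches = as.integer(bm$mismatches))
  }
  SnoCandidateSet(cand, boxes, transcripts)
}

#' Write a result table as TSV
#'
#' Header always included; an empty record set yields a header-only file.
#'
#' @param df data.frame or DataFrame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeResultsTsv <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [writeResultsTsv()]
#' @param path file path.
#' @return data.frame.
#' @export
readResultsTsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# Modification-site tables: rrna_id, position, nucleotide, mtype, provenance.

#' Write a modification-site catalogue as TSV
#' @param sites `GRanges` with mcols `nucleotide`, `mtype`, `provenance`.
#' @param path output file.
#' @export
writeSitesTsv <- function(sites, path) {
  df <- data.frame(
    rrna_id = as.character(GenomicRanges::seqnames(sites)),
    position = GenomicRanges::start(sites),
    nucleotide = S4Vectors::mcols(sites)$nucleotide,
    mtype = S4Vectors::mcols(sites)$mtype,
    provenance = S4Vectors::mcols(sites)$provenance,
    stringsAsFactors = FALSE)
  df <- df[order(df$rrna_id, df$position), , drop = FALSE]
  writeResultsTsv(df, path)
}

#' Read a modification-site catalogue from TSV
#' @param path file path.
#' @return `GRanges` of width-1 sites.
#' @export
readSitesTsv <- function(path) {
  df <- readResultsTsv(path)
  need <- c("rrna_id", "position", "nucleotide", "mtype")
  if (!all(need %in% colnames(df)))
    stop("site TSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$provenance)) df$provenance <- "reference"
  GenomicRanges::GRanges(df$rrna_id,
    IRanges::IRanges(df$position, width = 1L),
    nucleotide = df$nucleotide, mtype = df$mtype, provenance = df$provenance)
}

# Build a site GRanges from parallel vectors, checking site invariants
# against the rRNA sequences when provided.
.makeSites <- function(rrna_id, position, nucleotide, mtype, provenance,
                       rrnas = NULL) {
  stopifnot(all(mtype %in% c("Nm", "psi")))
  if (any(mtype == "psi" & nucleotide != "U"))
    stop("pseudouridylation sites must sit on U")
  if (!is.null(rrnas)) {
    for (i in seq_along(rrna_id)) {
      s <- as.character(rrnas[[rrna_id[i]]])
      if (position[i] < 1L || position[i] > nchar(s))
        stop("site position out of range on ", rrna_id[i])
      if (substr(s, position[i], position[i]) != nucleotide[i])
        stop("site nucleotide disagrees with ", rrna_id[i], ":", position[i])
    }
  }
  GenomicRanges::GRanges(rrna_id, IRanges::IRanges(position, width = 1L),
                         nucleotide = nucleotide, mtype = mtype,
                         provenance = provenance)
}
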