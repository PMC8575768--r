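---
title: "snoLatex: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snoLatex: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`snoLatex` implements a laticifer snoRNA screen for the rubber tree as a
chain of testable stages. This vignette explains the science each stage
implements, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, and the design choices
made where the underlying methodology left the design open.

## Modification-site transfer

Known rRNA modification positions (2′-O-methylation, `Nm`; pseudouridine,
`psi`) from model organisms are lifted onto the target rRNA through a
single global pairwise alignment (`globalAlign`, Needleman–Wunsch with
affine gaps via `Biostrings::pairwiseAlignment`; match +1, mismatch −1, a
gap run of length $L$ costing $4 + L$). A site is transferred
(`transferSites`) only if

1. its alignment column is not a target gap,
2. the target nucleotide equals the site nucleotide (ψ additionally
   requires a U), and
3. at least 80% of the alignment columns within ±5 of the site column are
   identical (`contextWindow = 5`, `minContextIdentity = 0.8`).

The context filter stands in for the "consensus sequence" notion of the
original screen, which published no identity cutoff; both knobs are
exposed. Dropped sites are returned with machine-readable reason codes so
the outputs plus drops always partition the inputs.

## C/D box scanning

`scanCD` pairs every C box (`RUGAUGA`, ≤1 mismatch against the degenerate
consensus) with every downstream exact D box (`CUGA`) such that the
candidate — defined as running from 4 nt before the C box to 4 nt after
the D box — is 50–300 nt long. Internal D′/C′ copies are attached with one
mismatch allowed ("less conserved internal copies"). The candidate
boundary rule (±4 nt pads) is a declared package default: canonical C/D
snoRNAs carry their boxes within a few nucleotides of the termini, and no
boundary rule was published. Overlapping candidates sharing more than half
the shorter span are resolved in favour of fewer total box mismatches,
then longer span, then leftmost start (one call per locus).

## H/ACA box scanning and structure detection

H/ACA snoRNAs have a hairpin–hinge–hairpin–tail architecture with the H
box (`ANANNA`) in the hinge and an ACA motif whose last nucleotide sits
`tailOffset = 3` nt before the 3′ end. Structure detection
(`foldStems`) is a complementary-segment search rather than thermodynamic
folding: maximal contiguous base-pair stacks (Watson–Crick plus GU, apical
loop ≥ 3 nt) are enumerated, the lower stem and a nested upper stem are
selected, and the unpaired strands between them are the pseudouridylation
pocket. A candidate hairpin must satisfy the full pocket architecture:

* outer (lower) stem ≥ 5 pairs, ending within 2 nt of the downstream box;
* nested (upper) stem ≥ 4 pairs;
* pocket strands ≥ 6 nt on both sides;
* the 3′ pocket strand starting 13–17 nt upstream of the downstream box
  (H box for hairpin 1, ACA for hairpin 2).

These minima were chosen so that random transcript sequence rarely
satisfies the whole architecture; a bare "two hairpins exist" rule fires
on most random 300-nt sequences once GU pairs are allowed, which would
make the scanner useless as a discovery filter. On designed hairpin
regions, where a single stack is the optimal nested structure, the stack
pairing equals Nussinov-style maximisation (tested against an exhaustive
oracle); on arbitrary sequence a single stack is a lower bound, which is
the intended behaviour of a segment search.

The scanner localises the 5′ boundary of hairpin 1 only approximately on
random flanks (the lower stem's 5′ arm may recruit flanking residues), so
H/ACA candidate spans are treated as approximate; recovery of planted
H/ACA snoRNAs is therefore asserted by overlap, whereas C/D recovery is
asserted with exact box coordinates.

## Guide–target duplexes and site calling

The C/D antisense element ends at — and includes — the first nucleotide of
the D or D′ box. `enumerateDuplexes` considers every 3′-anchored
sub-length from 9 to 21 nt and every rRNA window, pairing antiparallel and
contiguously (no bulges), and keeps windows with ≤ 1 mismatch and ≤ 2 GU
pairs, as printed. The methylated nucleotide is the one paired with the
guide position five nucleotides upstream of the D-box first nucleotide
(D+5 rule), which under the contiguous pairing map is window start + 5;
the counting convention is a config flag (`dOffset`) and is verified in
tests by explicit pairing-map lookup.

ψ calling anchors at the target U: the 3′ pocket strand pairs the rRNA 5′
flank (`pocket3[i]` with `rRNA[p − i]`), the 5′ pocket strand pairs the
flank beyond the unpaired U–N dinucleotide (`pocket5[j]` with
`rRNA[p + 2 + L − j]`). Prefixes/suffixes of the pocket strands (≥ 5 nt)
are enumerated and each side takes its best admissible duplex, so slack in
stem localisation cannot shift the ψ register.

**Scoring.** The original tools' numeric thresholds (14 for C/D, 40 for
H/ACA, 20/45 for exonic candidates) were inherited without a published
scoring function. The package score is additive: Watson–Crick +2, GU
wobble +0.5, mismatch −6; H/ACA candidates add the two pocket duplex
scores plus a structure bonus of one point per stem pair beyond
2 × `minStemPairs`, capped at 10. The weights were chosen so that (i) a
canonical 9–12-nt perfect C/D duplex clears 14 and a designed two-pocket
H/ACA guide clears 40, and (ii) a random antisense element's best duplex
across several kilobases of rRNA stays below threshold with high
probability. Milder penalty weights (e.g. GU +1, mismatch −2) fail
requirement (ii) badly: with 13 sub-lengths × thousands of windows, almost
every random element finds some 7-WC-plus-wobble window above 14, erasing
the guide/orphan distinction that the screen depends on. All weights are
config-exposed and echoed in output metadata so scores are never mistaken
for the original tools' bit-scores. Threshold comparisons are strict (>)
for the plain thresholds and ≥ for the exon thresholds, as printed.

## Filtering and differential expression

Blacklist removal uses full Smith–Waterman local alignment; a candidate is
dropped at ≥ 90% identity over ≥ 80% of its length (declared defaults
standing in for unreported BLASTn cutoffs). Redundancy removal keeps the
most-expressed isoform per assembly subcomponent, ties broken by length
then id.

Counts are normalised by the nucleus-specific pre-rRNA reference:
$\tilde c_{is} = c_{is} / r_s \cdot \mathrm{median}_s(r_s)$. This makes
normalised values invariant to any per-sample rescaling (the property the
internal reference exists to provide) and is tested as such.

The differential test is a stand-in for the count-model package used in
the original screen, which is deliberately not re-implemented. For
replicated designs (≥ 3 per condition) the default is a moderated t-test
(limma `lmFit`/`eBayes`) on `log2(normalized + 0.5)`: with three
replicates a plain Welch t has ~4 degrees of freedom and cannot reach
useful sensitivity at BH 0.05 under realistic overdispersion
(dispersion 0.1), whereas variance moderation restores calibrated power;
the Welch test remains available (`method = "welch"`), and unreplicated
designs fall back to the exact conditional binomial (two-sample Poisson
rate) test on pooled counts with the pre-rRNA depths as offsets. P-values
are Benjamini–Hochberg adjusted; the latex-abundant set is
`fdr ≤ 0.05` and fold change ≥ 2 (the fold-change floor is a declared
default consistent with the smallest published latex-abundant fold
change, 2.41).

## Yield and regeneration analysis

Latex yield potential is the trunk-circumference-adjusted total solid
content, TSC/C (g/cm). Expression–yield screening uses the Spearman
coefficient of average ranks; a snoRNA is yield-correlated iff ρ > 0 and
ρ² > 0.2, both strict, as printed. "R²" is read as the square of the
Spearman coefficient; the signed coefficient is carried alongside so
either reading is reproducible. Regeneration ability is the TSC at the
first tapping at or past 180 min of a continuous 30-min series (the
published stable point); a coefficient-of-variation check (default 0.25)
warns when the plateau is not stable.

## The synthetic-data generator

`simulateBundle` generates the whole study from one master seed:

* **rRNAs**: i.i.d.-uniform sequences at plant scale (SSU 1800, LSU 3400,
  5.8S 160 nt; config values, not organism claims) plus a pre-rRNA
  concatenating the mature rRNAs with ITS1/ITS2 spacers. 80 Nm and 30 ψ
  reference sites are placed with end margins; ψ only on U.
* **Plants**: C/D guides are built backwards from an assigned Nm site
  (11 antisense nt + the D-box first nucleotide pair rRNA
  $[p-5, p+6]$, so D+5 calls exactly $p$; eligible sites need a G at
  $p-5$ so the duplex terminus is the D-box C). H/ACA guides carry two
  hairpins whose 10-nt pocket strands bracket an assigned ψ U with the
  16-nt pocket-to-box geometry. Orphans have valid boxes and structure but
  scrambled guide/pocket sequences. Every planted transcript is re-scanned
  and re-classified with the default pipeline and regenerated until the
  intended truth is reproduced (ψ sites whose designed pockets self-pair,
  or whose flanking residues would extend the upper stem across the
  pocket, are excluded up front as undetectable by construction); decoys
  are regenerated until they contain no candidate. Self-validation is what
  makes the planted-recovery tests exact rather than probabilistic.
* **Counts**: negative binomial, dispersion 0.1, log-normal base means
  (log-mean `log(100)`, sd 1) and per-sample library factors (sd 0.2, log
  scale); latex-abundant plants get fold change 4 in latex; the pre-rRNA
  row tracks the library factor at depth 10,000 with dispersion 0.01 (a
  deep, technically stable reference — reference noise is a property of
  the normaliser, not of the expression test under study).
* **Population**: a Gaussian copula with one latent driver for TSC/C;
  per-snoRNA latents correlated at $2\sin(\pi\rho_s/6)$ so realised
  Spearman matches the target in expectation; log-normal marginals keep
  everything positive. n = 50 trees, as in the F1 design emulated.
* **Time courses**: 14 trees, 30-min interval, a strictly decreasing
  quadratic head reaching the per-tree plateau exactly at the sixth
  tapping, then multiplicative noise (sd 0.05); plateaus are log-normal
  across trees so regeneration ability varies. One designated snoRNA's
  expression tracks circumference-adjusted ability at target ρ = 0.78.

What the generator does **not** emulate: read-level sequencing error,
assembly artefacts and chimeras, phylogenetically structured rRNA
divergence, snoRNA gene families and host-gene context, multi-target
guides, or biologically structured count correlation. Passing the planted
tests therefore demonstrates the correctness of the pipeline's logic under
its own assumptions, not its sensitivity on real nuclear RNA-seq.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere; DNA input is silently
  normalised to RNA (`T → U`); transcripts are scanned as given (assembled
  transcripts carry their own orientation; no reverse-strand scan by
  default).
* Duplex ties on score keep all assignments and flag the
  lexicographically first (rRNA id, position) as primary.
* Constant vectors make the Spearman coefficient undefined and raise an
  error rather than propagating `NaN`; empty blacklists, zero pre-rRNA
  counts and non-increasing tapping times are hard errors naming the
  offender.
* Fold changes are pseudocounted (0.5) so they are always finite and
  positive.
* Problem sizes in the test-suite simulations (2,000 features × 20
  replicates for calibration, 200 copula replicates, oracle equivalence on
  ≤ 2 kb rRNA) were chosen to give stable Monte-Carlo estimates at
  interactive runtimes.

## Known limitations

* The additive duplex score is a transparent surrogate, not a
  re-derivation of the original tools' probabilistic scores; absolute
  score values are not comparable to snoScan/snoSeeker output even though
  the decision thresholds are inherited.
* H/ACA boundary localisation is approximate on the 5′ side, and the
  segment search reports one stem pair arrangement, not an ensemble.
* The DE stage models two conditions only; multi-factor designs and
  posterior fold-change models are out of scope.
* Site transfer uses a single pairwise alignment; paralogous rRNA copies
  and structure-aware alignment are not handled.
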