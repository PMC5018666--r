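---
title: "Characterizing a WRKY transcription-factor gene family with wrkyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a WRKY transcription-factor gene family with wrkyscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkyscan)
```

## The problem

WRKY proteins are plant transcription factors defined by a ~60-residue
DNA-binding domain: a conserved `WRKYGQK` heptapeptide followed, some twenty
residues downstream, by a spaced zinc finger.  Genome-wide family surveys
follow a well-worn recipe: find every protein carrying the domain, classify
each member into group I (two domains), group II (one domain, C2H2-type
finger; subgroups IIa–IIe assigned phylogenetically) or group III (one
domain, C2HC finger), characterize gene structure and physicochemical
properties, place genes on chromosomes, and ask how the family expanded —
tandem versus segmental duplication, orthology with reference species,
selection pressure via Ka/Ks — before profiling expression across tissues.

`wrkyscan` implements that recipe as composable, tibble-first functions plus
a synthetic-genome generator that plants every feature the pipeline must
detect, so the whole workflow is testable end to end without any downloads.

## Domain detection

Detection is pattern-based rather than profile-HMM-based.  A heptapeptide
hit is any 7-mer in the variant set (`WRKYGQK`, `WRKYGRK`, `WKKYGQK`,
`WRKYGKK`, `WRKYGEK`) or within one substitution of the canonical sequence
(`max_mismatch = 1`).  The zinc finger is searched downstream as literal
spacing patterns:

* C2H2: `C-X(4,5)-C-X(22,23)-H-X-H`
* C2HC (group III): `C-X7-C-X23-H-X-C`
* shortened variants: `C-X4-C-X21-H-X-H` and `C-X5-C-X19-H-X-H`

Among candidate matches the leftmost first cysteine wins, then the shortest
spacing, then the order above — a deterministic tie-break the tests rely on.
The distance between heptapeptide and finger is not fixed in real domains;
the window defaults to 80 residues (`scan_config(finger_window = )`), a
deliberately permissive choice for domains that are only ~60 residues long.
A heptapeptide with no detectable finger is kept as an *incomplete* domain
(such genes are real family members that lost finger residues), and a single
heptapeptide followed by two consecutive fingers is flagged via `n_fingers`,
because that architecture marks a two-domain gene that lost one
heptapeptide and belongs in group I.

## Classification

Group assignment is structural (domain count and finger type).  Subgroup
assignment within group II is reference-guided, mirroring the practice of
placing query domains in a phylogeny with labelled domains from a reference
species.  Two methods are provided: `"nearest"` (smallest p-distance to a
labelled reference domain) and the default `"tree"` (neighbor-joining tree
of query plus references; the query inherits the majority label of the
smallest adjacent clade that contains a reference, with ties falling back
to `"nearest"`).  Proteins whose only domain lacks a finger inherit the
placement of their nearest reference — including group I or III templates,
since fingerless domains occur in those groups too.

## Gene features

Molecular weight is the sum of average residue masses plus one water; `X`
contributes a flat 110 Da.  The isoelectric point solves the
Henderson–Hasselbalch net-charge equation by bisection on pH 0–14 using the
Bjellqvist pKa set (N-terminus 7.50, C-terminus 3.55; D 4.05, E 4.45,
C 9.00, Y 10.00, H 5.98, K 10.00, R 12.00).  The charge curve is monotone,
so the root is unique; iteration stops below 1e-4 pH and values are
reported to two decimals.  Agreement with any particular web calculator is
approximate by construction (pKa sets differ); the packaged willow table is
the fixed point the tests aggregate against.

Intron positions are mapped through the CDS: an intron after `L` coding
bases has phase `L mod 3` and interrupts protein residue `L %/% 3 + 1`.
Introns inside a complete domain are typed **R-type** when the splice point
sits at an arginine about five residues before the first finger cysteine
and **V-type** when it sits at a valine about six residues after the second
cysteine.  Because "about" is approximate in the field's descriptions, a
±2-residue tolerance window is applied around both offsets.  Whether an
arrowhead in a published domain alignment marks a codon boundary or a
within-codon break is ambiguous; the mapping here is phase-aware, so both
cases are represented exactly.

## Genome organization

Family genes are renamed ordinally along chromosomes (natural sort, so
`Chr2` precedes `Chr10`), with unplaced genes taking the final ordinals.
Clusters follow the 200-kb rule: consecutive genes within 200 kb
(start-to-start) chain transitively, and maximal chains of two or more
genes are reported.  Start-to-start was chosen over midpoints because the
rule is applied to gene *positions*, and chaining was chosen because dense
regions spanning more than 200 kb end to end are still described as single
high-density clusters in family surveys.

## Duplication, orthology, selection

Candidate duplicate pairs must align (locally, BLOSUM62, affine gaps
10/0.5) with coverage ≥ 80% of the longer protein and identity ≥ 65% over
alignment columns (gap columns count in the denominator — "similarity of
the aligned regions" is ambiguous, and this is the stricter reading).
Same-chromosome pairs that are adjacent (no family gene between) and within
200 kb are tandem; cross-chromosome pairs are segmental; anything else is
unclassified unless configured otherwise.

Orthology is reciprocal-best-hit by alignment score with an absolute score
floor (`min_score = 100`) in place of a database E-value, which is
meaningless without a database size; the floor is far above what unrelated
random 300-mers attain (verified by simulation in the tests).  For group I
genes the N- and C-terminal domains must independently agree with the
pairing — each domain must be a nearest partner of its counterpart — since
a pair whose two domains tell different stories is not accepted as
orthologous.

Ka/Ks uses the Nei–Gojobori counting method: 1/3-per-position synonymous
site counting (mutations to stops count as nonsynonymous, so sites sum to
exactly 3 per codon), pathway-averaged difference counting that skips
stop-passing pathways when avoidable, and Jukes–Cantor correction.  A
proportion at or beyond 3/4 saturates to `Inf`; with `ks = Inf` the ratio
is 0, and `ks = 0` leaves the ratio undefined.  Pairs with
`ka/ks < 0.5` are flagged as evolving under purifying selection.  Maximum
likelihood estimation would be an alternative; the counting method was
chosen because it is fully transparent, exactly testable by hand
enumeration, and the purifying-selection screen is robust to the method at
the effect sizes simulated here.

## Phylogeny

The domain tree pipeline is: progressive profile alignment (NJ guide tree
from pairwise global-alignment identities, midpoint-rooted; profile–profile
merges scored by sum-of-pairs BLOSUM62 with a linear gap penalty of −8 per
column), p-distance with pairwise gap deletion, neighbor joining with
lowest-index tie-breaks and negative branch lengths clamped to zero (with a
warning), and bootstrap support from column resampling.  The aligner's
fidelity target is "good for ~60-residue domains", enforced by planted-clade
recovery properties rather than by matching any specific aligner's output.
Bootstrap defaults to 100 replicates at desk scale; the conventional 1,000
is one argument away.

## Expression

RPKM is `count / (length_kb × million mapped reads)`, with per-tissue
library sizes defaulting to the count-table column sums (genome-wide totals
are not available at family scale; an override is provided).  The heat-map
matrix is `log2(RPKM)` with `NA` wherever the count is zero, so unexpressed
cells render blank.  Tissues are clustered by average-linkage hierarchical
clustering of Euclidean distances on the log2 matrix, with `NA` treated as
0 for the distance computation only — a deterministic choice that keeps
unexpressed cells from propagating missingness.

## The synthetic genome generator

`generate_genome()` is first-class, tested code, not a fixture.  Its
defaults emulate the architecture of a real plant WRKY survey at desk
scale: ~34 genes with group proportions echoing a real family, fixed
60-residue subgroup templates (divergent at >20% of positions, guarded by
an unlearnability check), group-specific finger types, R-type introns for
groups I(C)/IIc/IId/IIe/III and V-type for IIa/IIb, group III genes with
exactly two introns, planted clusters with sub-200-kb internal gaps and
400-kb spacing between placement units, tandem and segmental duplicate
pairs at 90% target protein identity, and negative-binomial expression
counts over five tissues (root, stem, bark, bud, leaf).

Two deliberate idealizations keep planted ground truth exactly recoverable:
background (non-domain) sequence is drawn i.i.d. from a 15-letter alphabet
*without cysteine* (so no spurious zinc-finger pattern can arise by
chance), and duplicate/ortholog mutations avoid the planted heptapeptide
and finger residues.  Real proteomes have neither property, so passing the
recovery tests demonstrates correctness of the detection logic and its
thresholds, not robustness to noisy domain boundaries or profile-level
divergence — that is what the permissive variant set, mismatch allowance
and incomplete-domain retention are for.  The generator also does not model
codon-usage bias or indel evolution.

Every emitted CDS is checked at generation time to translate back to its
protein, and every planted domain is re-detected by the scanner before the
genome is returned.

## Worked example

```{r example, eval = FALSE}
g <- generate_genome(synth_config(seed = 1))
res <- run_pipeline(
  g$proteins, cds = g$cds, gene_models = g$gene_models,
  counts = g$counts, gene_lengths = g$gene_lengths,
  references = generate_reference_panel(), prefix = "SynWRKY"
)
glance(res)   # one-row family summary
tidy(res)     # per-gene characterization table
autoplot(res) # chromosome map
```

The packaged willow table reproduces the published aggregates directly:

```{r fixture}
summarize_family(load_family_table())
```

## Numerical and scale choices

Problem sizes were chosen so the full test suite and the acceptance script
each run in a couple of minutes on a single core: ~34-gene synthetic
genomes, 150-codon Ka/Ks simulations with 200 replicates, 100-replicate
bootstraps.  All randomness flows through explicit seeds; the generator
restores the caller's RNG state.

Known limitations: the pattern scanner is not a profile HMM and will not
find domains whose heptapeptide drifts beyond one substitution; subgroup
assignment quality is bounded by the reference panel; the progressive
aligner is a simple sum-of-pairs profile method, adequate for short domains
but not a general MSA tool; and the Nei–Gojobori estimator is known to be
conservative relative to ML at high divergence.
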