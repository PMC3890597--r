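---
title: "Methods: proneuropeptide discovery, processing and expression profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proneuropeptide discovery, processing and expression profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpkit)
```

## The biological problem

Neuropeptides are synthesized as inactive precursor proteins
(proneuropeptides, pNPs) with a stereotyped architecture: an N-terminal
signal peptide (SP) routes the precursor into the secretory pathway, and
one or more bioactive peptide elements sit between basic cleavage sites
recognized by prohormone convertases. After cleavage, peptides are often
modified — a C-terminal glycine is converted into an amide, an N-terminal
glutamine cyclizes into pyroglutamate, and cysteine pairs can form
disulfide bridges. Cataloguing the pNP complement of a species from a
transcriptome assembly therefore means chaining together several small,
rule-driven analyses: ORF calling, secretome gating, cleavage-site
detection, peptide liberation with modification calls, family assignment,
and expression profiling across life-cycle stages. `pnpkit` implements
that chain as composable functions plus a single orchestrator,
`run_pipeline()`.

Because a real catalog also depends on external predictors (signal-peptide
neural networks, BLAST, spectral search engines), `pnpkit` draws a strict
line: everything rule-driven is implemented here; everything that is the
business of an external tool is *imported* as a plain table (signal-peptide
calls, domain hits, pairwise similarity hits in the 12-column BLAST
tabular dialect, observed MS peptide lists) and only interpreted here.

## ORF calling

`find_longest_orf()` scans all six reading frames and prefers the longest
ATG-initiated ORF (ATG to the next in-frame stop, or to the transcript
end). EST and short-read assemblies are frequently 5'-truncated, so a
strict ATG requirement would discard genuinely coding fragments; when no
ATG-initiated ORF reaches the length cutoff, the longest stop-free
stretch is reported instead, labelled `open_end`. Ties are broken
deterministically by frame order (+1, +2, +3, -1, -2, -3), then by the
smallest forward-strand start. The proteome cutoff defaults to 120
residues, the conventional threshold for EST-derived protein sets; it is
a plain argument and should be lowered for deliberately short synthetic
precursors. Translation uses the standard genetic code only — stop-codon
read-through precursors (two coding regions separated by an in-frame
stop, as known for some annelid fulicin-class genes) are handled by
annotating the downstream chain as a second user-supplied record, never
by altering the code.

Codons containing `N` translate to `X`. The initiator codon receives no
special treatment: alternative initiators such as TTG are translated by
the table, not rewritten to methionine.

## Signal peptides

External predictor output can be imported and is then returned verbatim.
The built-in heuristic is deliberately simple and fully auditable. Within
residues 1–45 it requires:

1. a hydrophobic core (h-region): the longest maximal run of residues
   with Kyte–Doolittle hydropathy above 1.6 (i.e. `A,C,F,I,L,M,V`), at
   least 6 residues long, leftmost on ties;
2. a non-negative net charge over residues 1–5 (n-region; `K,R` count +1,
   `D,E` −1);
3. a cleavage point: the first position after the core whose residues at
   −1 and −3 relative to cleavage are small/neutral (`A,G,S,C,T,V` — the
   classical (−3,−1) rule).

The reported score maps the core's mean hydropathy into [0, 1] as
`min(1, (mean − 1.6) / 2.9)`; it is monotone in core hydrophobicity and
makes no claim to calibration against neural predictors. This heuristic
recovers cleanly constructed signal peptides (see the generator below)
but is *not* a substitute for a modern predictor on real proteomes —
imported calls always win.

## Precursor processing

`detect_cleavage_sites()` reports every **maximal run** of K/R as a
single cleavage event: length 1 is monobasic (reported only when
enabled), length 2 dibasic (only when the ordered pair is accepted;
default all four of KR, RR, KK, RK, as no subset is privileged a
priori), length ≥ 3 multibasic (always). Treating a run as
one event avoids the combinatorial explosion of re-cleaving within a
run, which would produce spurious single-residue peptides.

`liberate_peptides()` takes the substrings strictly between the SP end,
the basic runs, and the C-terminus. A trailing glycine immediately before
a basic run is removed and flags amidation — the glycine-extended
intermediate is the enzymatic signature, so a glycine at the precursor
terminus (no following site) is *not* an amidation call. A leading
glutamine flags pyroglutamate but is retained in the sequence so
predicted peptides remain string-matchable against MS lists (glutamate is
not flagged). Segments shorter than `min_peptide_length` (default 3)
after processing are dropped. Peptides flanked by a monobasic site carry
a provenance flag, because monobasic processing is used selectively in
real precursors (e.g. myomodulins). Everything is reported in 1-based
inclusive coordinates, both on the full precursor and in post-SP frame.

The repeat scanner implements the discovery motif `x(3–10)-K[K/R]`
literally: a maximal K/R-free run of spacer length 3–10 followed by K
then K or R. A precursor is called repetitive at ≥ 2 matches (the
threshold is configurable; the choice of 2 is a documented default, not a
data-derived value). The window is intentionally literal — peptides
longer than 10 residues are still liberated by the processing rules, so
the pipeline loses no sensitivity; the scanner is a flag for repetitive
architecture, not a processing rule.

`build_pfm()` right-justifies peptide copies (C-terminal anchoring, no
internal gaps, no pseudocounts) — the correct alignment convention for
families whose conserved residues sit at the amidated C-terminus — and
reports per-column support so downstream logo rendering can scale letter
heights honestly.

`qualify_precursor()` encodes the bona fide prohormone rule: a signal
peptide, at least one cleavage site, no conflicting protein-domain hit,
and at least one line of evidence (homology, expression, MS,
conservation — supplied externally — or structural, set automatically
for repetitive precursors and for amidated/pyroglutaminated/Cys-rich
peptides, with Cys-rich meaning ≥ 2 cysteines by default). Every failed
conjunct is listed as a rejection reason.

## Family assignment and cluster maps

`build_cluster_map()` consumes imported pairwise hits, keeps the best
e-value per unordered pair, retains edges strictly below the threshold
(`evalue < t`, the usual convention of similarity-map legends), and
extracts connected components; unconnected nodes can be dropped, as
published cluster maps commonly are. The analytical content is the thresholding and component structure — no force-directed 2-D layout is computed. The
two-stage practice of clustering a full dataset at a strict threshold
(e.g. 1e-10) and re-clustering a dense center at a looser one (e.g.
1e-5) is expressed as two calls on two hit files; selecting the center
is the user's node list, since that selection is inherently visual.

Family motifs use a deliberately small grammar — fixed residues,
bracketed classes, `x{m,n}` spacers, an optional C-terminal anchor, and
an amidation requirement — so that every shipped motif is auditable at a
glance. The default table covers classical family-defining patterns
(Wamide/MIP `xWx{6,7}W[GIL]$`; C-terminally amidated RFamide `R[FY]$`,
FVamide, RGWamide, FVRIamide) and is user-extensible via YAML; it makes
no attempt to enumerate every known family. The first matching motif in
table order wins; a precursor's family is the modal family of its
peptides, with ties left unassigned.

## Expression profiling

Counts are normalized to rpm (`raw / library_size × 1e6`) and optionally
RPKM (`rpm × 1e3 / length_in_bases`). The low-expression filter retains
genes with **at least** 2 rpm in **at least one** stage (inclusive
boundary — a gene at exactly 2.0 rpm stays). Profiles are clustered
hierarchically under a Pearson correlation distance
(`d = 1 − r`); average linkage is the default; the distance, not the
linkage, is the defining choice of this approach. Whether distances are computed on rpm or RPKM
values is a flag (`cluster_on`), defaulting to RPKM when lengths are
available. Genes are sorted lexicographically before clustering so
results are independent of input order, and zero-variance profiles are
assigned the maximal distance 1 to all rows rather than erroring, so
constant low-expressors end up together instead of crashing the run.
"Transformed to a fraction of 1" is read as row-sum normalization, with
row-max scaling available behind `by = "max"` since the phrase is
ambiguous; all-zero rows stay zero.

## The synthetic generator

`generate_precursor_set()` emits precursors with known ground truth:
SP + peptide copies (optionally interleaved with inactive spacers)
separated by basic runs, with amidation (appended glycine), leading-Gln
pyroglutamate and two-cysteine signatures at configurable rates, and
seeded reverse-translated transcripts (uniform synonymous codons, ATG
start, terminal stop, no internal stops). Defaults: 1–16 copies per
precursor, peptides of 4–18 residues, SPs of 15–30 residues, spacers of
2–12, 13 stages, amidation 0.5 / pyroglutamate 0.2 / Cys-rich 0.1 —
magnitudes chosen to resemble a real precursor catalog (copy numbers up
to the strongly repetitive precursors, modification rates of the order
seen in annotated complements) rather than fitted to any dataset.

Three construction choices keep the ground truth *exact* rather than
probabilistic:

* peptides and spacers contain no K/R, so cleavage boundaries are
  exactly the inserted runs;
* SPs are built to be recovered by the built-in heuristic (hydrophobic
  core, then a polar tail presenting the (−3,−1) pattern exactly at the
  SP end), so processing tests isolate processing logic from SP-predictor
  accuracy;
* multi-copy precursors with no modification signature keep their
  peptides within the 3–10 spacer window, use K-initiated runs, and get
  a cleavage site directly after the SP — otherwise their repetitive
  architecture would be invisible to the literal scanner (the first
  copy's K/R-free run would reach back through the SP) and the
  generator's own qualification invariant could not hold.

The truth records **every** segment correct processing should liberate —
designated peptides plus spacer/tail segments at or above the minimum
length, and segments dropped for length — so "peptide count equals truth
count" is a well-defined end-to-end property, not an approximation.

What the generator does **not** emulate: realistic codon usage, EST
error profiles, homopolymer noise, overdispersed counts (expression
noise is Poisson; negative-binomial overdispersion was deliberately left
out absent any distributional claim to match), internal K/R in mature
peptides (real RFamides have one — recovering those requires the
selective monobasic biology the package only flags, not models), or
signal peptides hard for the heuristic (an option for "hard" SPs would
only test the heuristic, which imported calls supersede anyway). Passing
the synthetic suite therefore demonstrates the correctness of the
processing rules, not predictor accuracy on real proteomes.

`generate_expression_matrix()` partitions genes into clusters with
bump-shaped stage-mean profiles (Gaussian bump over stage index, σ = 1.2
stages, cluster centers spread across the stage axis), scales them by
per-gene log-normal baselines (median ≈ 40 rpm), samples per-stage
library sizes, and draws Poisson counts around
`mean_rpm × library_size / 1e6`. Same-cluster noiseless profiles
correlate perfectly, which makes label-recovery tests sharp.

## Numerical and degenerate-input choices

* FASTA parsing is strict: duplicate identifiers and out-of-alphabet
  characters are errors (with positions); an empty file is an empty list.
* Tables are tab-separated; `#` comments are skipped; a header is
  detected only when *every* expected-numeric cell of the first line is
  non-numeric, so a single corrupt e-value is an error, not a header.
* PFM columns sum to 1 over their support to within 1e-9; no
  pseudocounts are ever added.
* Cluster-map thresholds are strict inequalities; components are
  computed by graph connectivity (igraph) and cross-checked against a
  union-find oracle in the tests.
* Hierarchical clustering delegates to `stats::hclust`; the test suite
  verifies its merge heights against a naive O(n³) agglomeration oracle
  for all three linkages.
* All generator randomness flows from one integer seed through a scoped
  RNG (the caller's `.Random.seed` is restored), so identical configs are
  byte-identical.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script checks run at desk scale: 200
synthetic precursors for end-to-end recovery, 1,000 random sequences for
the repeat-scanner oracle, 100 random transcripts for the ORF oracle,
200-node random graphs for the component oracle, 40 profiles for the
clustering oracle, and 60 genes in 3 clusters for label recovery. These
sizes were chosen as the smallest at which the properties are
non-trivial while the whole suite stays comfortably interactive.

The two dataset-level checks (79 of 98 genes retained by the 2-rpm
filter; 13 and 16 liberated copies from the two repetitive DH44-type
precursors) run on synthetic stand-ins shipped under `inst/extdata/`
(`synthetic_*`), constructed to those documented characteristics because
the corresponding real datasets are not redistributable inside the
package.
They validate the implemented rules on realistically shaped data, not
the original measurements.

## Known limitations

* The SP heuristic is a gate for synthetic and exploratory use; real
  analyses should import predictor calls.
* Family assignment is motif-based and first-match-wins; it does not
  model profile HMMs or orthology.
* No differential-expression testing is provided — only normalization,
  the minimum-expression filter, clustering, totals and the fraction
  transform.
* Monobasic cleavage is all-or-nothing per run; the selective biology of
  monobasic processing is only surfaced as a provenance flag.
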