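# pnpkit

Tools for cataloguing **proneuropeptides (pNPs)** — the inactive
precursor proteins from which bioactive neuropeptides are cleaved — from
a transcriptome assembly, and for profiling their expression across
life-cycle stages.

A canonical pNP consists of an N-terminal **signal peptide** (SP), one or
more peptide elements flanked by **basic cleavage sites** (mono-, di- or
multibasic runs of K/R recognized by prohormone convertases), and
modification signatures on the liberated peptides: a C-terminal glycine
that becomes an amide, an N-terminal glutamine that cyclizes to
pyroglutamate, and cysteine-rich stretches. `pnpkit` implements the full
desk-scale discovery chain around that architecture:

* **ORF calling** — six-frame longest-ORF search with an ATG preference
  and a stop-free fallback for 5'-truncated transcripts
  (`find_longest_orf`, `predict_proteome`; default proteome cutoff 120
  aa).
* **Secretome** — signal-peptide gating (imported predictor calls, or a
  built-in hydrophobic-core + (−3,−1)-rule heuristic) and in-silico SP
  removal (`predict_secretome`).
* **Processing** — the analytical core: maximal-K/R-run cleavage sites,
  peptide liberation with amidation/pyroglutamate/Cys calls, the
  `x(3–10)-K[K/R]` repeat scanner, C-terminally anchored position
  frequency matrices for peptide logos, MS-evidence matching, and the
  bona fide prohormone qualification rule (SP ∧ ≥1 site ∧ no conflicting
  domain ∧ ≥1 line of evidence).
* **Classification** — e-value-thresholded similarity cluster maps
  (strict `evalue < t`, best hit per unordered pair, connected
  components) from imported BLAST-tabular hits, and motif-based family
  assignment (RFamide `R[FY]$`-amide, Wamide/MIP `xWx{6,7}W[GIL]$`, ...).
* **Expression profiling** — rpm (`raw/library_size × 1e6`) and RPKM
  (`rpm × 1e3/length`) normalization, the ≥ 2 rpm in ≥ 1 stage filter,
  Pearson-distance (`1 − r`) hierarchical clustering, per-stage totals,
  and fraction-of-1 profile transforms.
* **Synthetic data** — a fully seeded generator of precursor sets and
  stage count matrices with exact ground truth, so every stage is
  testable without any download (`generate_precursor_set`,
  `generate_expression_matrix`).
* **Orchestration** — `run_pipeline()` chains the stages from a config
  (R object or YAML) and writes TSV outputs plus a JSON manifest.

External predictors are never re-implemented: SignalP-class calls, BLAST
hits, PFAM domain hits and MS peptide identifications are imported as
plain tables and interpreted by the rules above.

## Worked example

Annotate a repetitive precursor (a synthetic DH44/ELH-type stand-in
shipped with the package):

```r
library(pnpkit)

fa   <- system.file("extdata", "synthetic_dh44_precursors.fasta",
                    package = "pnpkit")
prec <- read_fasta(fa, "protein")[[1]]

sp <- predict_signal_peptide(prec)
sp
#> <sp_annotation> DH44-1_synthetic sp_end=19 score=0.67 (heuristic)

pep <- liberate_peptides(prec, sp)
head(pep[, c("start", "end", "sequence", "amidated", "pyroglutaminated")], 4)
#>   start end          sequence amidated pyroglutaminated
#> 1    20  36 ISAMHALPDALSPELAA     TRUE            FALSE
#> 2    40  56 ISAMHNLPDALSLELAA     TRUE            FALSE
#> 3    60  76 ISAMHVLPNALSQELAA     TRUE            FALSE
#> 4    80  96 ISHMHNLPDAFSQELAA     TRUE            FALSE
nrow(pep)
#> [1] 13

qualify_precursor(annotate_precursor(prec, sp))
#> <precursor_annotation> DH44-1_synthetic (281 aa)
#>   SP: 1-19; sites: 14; peptides: 13; repetitive: FALSE
#>   evidence: structural; qualified: TRUE

build_pfm(pep$sequence)
#> <pnp_pfm> 17 columns (C-terminally anchored), support 13 at -1
#>   consensus: ISAMHNLPDALSQELAA
```

Reading the output: the heuristic places the SP end at residue 19; the
13 liberated copies each ended in a glycine abutting a dibasic KR site,
so all are flagged amidated (the glycine is removed from the reported
sequence); the precursor qualifies as a bona fide prohormone on
structural evidence (amidated repetitive copies). The `repetitive` flag
from the `x(3–10)-K[K/R]` scanner is FALSE here because these peptides
are 17 residues long — longer than the literal 3–10 spacer window — which
is exactly why liberation, not the discovery motif, is the processing
authority. The PFM consensus recovers the shared peptide core across
copies.

For the full chain on synthetic data with known truth:

```r
cfg <- generator_config(n_precursors = 50, seed = 1)
gen <- generate_precursor_set(cfg)
write_fasta(gen$transcripts, "transcripts.fasta")
manifest <- run_pipeline(pipeline_config(
  out_dir = "out", transcripts = "transcripts.fasta",
  min_protein_length = 20, seed = 1))
```

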