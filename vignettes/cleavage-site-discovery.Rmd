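---
title: "Mapping ribonuclease cleavage sites from 5'-end RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ribonuclease cleavage sites from 5'-end RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavemap)
```

## The problem

When a target-activated ribonuclease (for example a type VI CRISPR
effector switched on by recognition of a target transcript) cleaves
cellular RNAs, every cut leaves a new 5' end. Libraries prepared to
capture monophosphorylated 5' ends therefore accumulate reads whose
5'-most base marks the downstream product of cleavage. Comparing
per-nucleotide, strand-specific 5'-end counts between *targeting*
cells (nuclease active) and *nontargeting* controls (nuclease idle)
turns cleavage-site discovery into a per-position count-enrichment
problem. cleavemap implements that comparison end to end, together
with the products needed to interpret the calls for an anticodon
nuclease: tRNA anticodon-loop profiles, sequence logos around the
scissile bond, and cross-experiment intersections on collapsed
transcripts.

## The statistical model

For position $p$ and library $l$, the 5'-end count $y_{pl}$ is modeled
as negative binomial,

$$y_{pl} \sim \mathrm{NB}(\mu_{pl}, \phi), \qquad
\log \mu_{pl} = \beta_{0p} + \beta_{1p} x_l + o_l,$$

where $x_l$ indicates the targeting condition, $o_l = \log(N_l f_l)$
is a fixed offset built from the library size $N_l$ (retained
fragments) and its TMM scaling factor $f_l$, and $\phi$ is a
dispersion shared by all positions. The condition effect
$\beta_{1p}$ is tested per position by a likelihood-ratio test of the
two-mean model against the one-mean null, referred to $\chi^2_1$;
p-values are Benjamini–Hochberg corrected over all retained positions
of the contrast. The reported effect size is
$\log_2\mathrm{FC} = \beta_{1p} / \ln 2$.

The full recipe, in order:

1. **Filter.** Keep positions with at least `min_cpm` (default 10)
   counts per million mapped fragments in at least `min_replicates`
   (default 3) *targeting* libraries. The criterion deliberately looks
   only at the enriched condition — a genuine cleavage product can be
   absent from controls — and uses raw library sizes, since filtering
   precedes normalization.
2. **Normalize.** TMM factors from trimmed (30% on M, 5% on A),
   precision-weighted means of log2 count ratios against the library
   whose upper-quartile count is most typical; factors are rescaled to
   geometric mean 1 and enter the model only through the offsets.
3. **Dispersion.** A single $\phi$ maximizing the Cox–Reid adjusted
   profile likelihood (model log-likelihood at the per-position fit
   minus half the log-determinant of the Fisher information), profiled
   over a log-scale grid and refined by golden-section search, floored
   at $10^{-6}$. A per-position method-of-moments mode exists for
   sensitivity analysis; the common mode is the default because
   per-position counts (6 libraries) carry too little replication for
   stable individual estimates.
4. **Test.** Per-position IRLS fits (Fisher scoring, tolerance
   $10^{-8}$ on the linear predictor, at most 100 iterations) of full
   and null models; non-converged positions get `NA` p-values and are
   excluded from the BH correction with a warning.
5. **Call.** Sort by FDR ascending (ties: $|\log_2\mathrm{FC}|$
   descending, then genomic coordinate), take the top 100, then keep
   positions with $\log_2\mathrm{FC} > 4$ — strictly, so a fold change
   of exactly 16 does not qualify. The set may be empty.

TSS detection reuses the identical machinery with the "enriched" role
played by RppH-treated libraries: pyrophosphohydrolase treatment
converts 5'-triphosphate (primary, transcription-start) ends into
ligatable monophosphates, so positions enriched in treated over
untreated libraries are transcription start sites, not processing
products. Cross-checking the top TSS calls against the top cleavage
calls guards against mistaking newly activated promoters for cleavage.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_cpm` | 10 CPM | per-position support required in targeting libraries |
| `min_replicates` | 3 | targeting replicates that must pass the filter |
| `top_n` | 100 | FDR-ranked candidates considered for calling |
| `lfc_threshold` | 4 (log2) | strict enrichment cutoff after top-N |
| `dispersion_mode` | common | Cox–Reid common APL, or per-position moments |
| `prior_count` | 0 | fold-change shrinkage (model fit is unaffected) |
| `trim_m`, `trim_a` | 0.30, 0.05 | TMM two-sided trim fractions |
| `min_mapq` | 0 | mapping-quality floor for fragment reconstruction |

Two conventions worth stating explicitly:

* **Coordinates.** 0-based half-open everywhere internally; all TSV
  exports print 1-based positions.
* **Cleavage position.** A called 5' end at position $p$ means the
  phosphodiester bond 5' of $p$ (in transcript orientation) was cut;
  the 10-nt logo window is the 5 nt upstream and 5 nt downstream of
  that bond, with the cleaved base the first downstream column, and is
  reverse-complemented for minus-strand sites. The alternative reading
  of "ten nucleotides surrounding the site" (positions $p-5..p+4$ of
  the 5'-end base) differs only by a one-column shift; the
  bond-centred convention was chosen because a fragment's 5' end marks
  the downstream product of cleavage.

## Fragment reconstruction

A properly paired read pair collapses to one fragment spanning its
leftmost to rightmost mapped base, with the strand of read 1; orphaned
or unpaired mapped reads count as single fragments over their
alignment span. Secondary and supplementary alignments are dropped by
default. Read-level counting (no pair collapsing) is available behind
a flag for libraries where pair information is unreliable. Library
size is the number of retained fragments, used consistently for the
CPM filter and the model offsets. Axes are sparse: positions never
observed in any library are not materialized, and no downstream stage
assumes density.

## What the synthetic generator emulates — and what it does not

`generate_reference()` packs CDS, rRNA and tRNA genes (76 nt, anticodon
at canonical positions 34–36, loop 32–38 annotated via a
transcript-relative N1 offset) into a random sequence, alternating
tRNA strands and always duplicating one tRNA gene verbatim so that
collapsing of identical multi-copy genes is exercised.
`simulate_counts()` lays background fragmentation 5' ends over
transcript positions proportional to lognormal per-feature abundances,
implants TSS mass in both conditions (multiplied 32-fold in
RppH-treated libraries — the magnitude a triphosphate end's
conversion realistically produces, and comfortably above the
$\log_2\mathrm{FC} > 4$ gate), implants cleavage mass
(`base_mean` $\times 2^{\mathrm{effect}}$) in targeting libraries only,
and draws replicate counts NB with a single dispersion (default 0.15).
`simulate_alignments()` realizes every counted 5' end as a properly
paired 2×35 nt fragment, mirroring short paired-end sequencing of
~50 nt cleavage products, so that counting the emitted SAM reproduces
the count table exactly.

Deliberately *not* emulated: sequencing errors and quality variation,
ligation and PCR biases at 5' ends, RNA secondary-structure effects on
fragmentation, partial RppH conversion, multi-mapping ambiguity
(simulated reads are placed, not aligned), and gene-expression changes
between conditions beyond the implanted signal. Passing the recovery
and calibration checks therefore demonstrates that the statistical
machinery is correct under its own assumptions — not that those
assumptions hold for any particular real library.

**Problem sizes.** Count-level checks (null calibration, TSS
discrimination, logo composition) use deep libraries (10^6 fragments)
over small genomes (~3000–7000 positions), where the 10-CPM filter
corresponds to ~10 counts as in real data. Alignment-level checks use
20 000 background fragments per library so SAM fixtures stay light;
at that depth the CPM filter is permissive and the top-100 rule
admits low-confidence tail positions with infinite fold change — the
same behavior the rule has on shallow real libraries — which is why
recovery is measured as the fraction of implants found, not as
precision of the called set.

## Numerical choices and edge cases

* Group means in the IRLS fit are clamped to $[10^{-10}, 10^{10}]$;
  a group with all-zero counts drives its coefficient to the clamp
  rather than $-\infty$, and the reported $\log_2\mathrm{FC}$ is then
  $\pm\infty$, replaced by $\pm 20$ *only* for ranking and
  thresholding. No pseudocounts enter the model; `prior_count`
  affects the reported fold change alone.
* $\phi < 10^{-10}$ switches the likelihood to its Poisson limit.
* BH correction ignores `NA` p-values (they do not count as tests);
  it is applied once per contrast over all retained positions.
* Ties in the FDR ranking are broken by $|\log_2\mathrm{FC}|$
  descending, then reference/strand/position — the full ordering is
  total, so reruns are byte-identical.
* TMM returns factor 1 (with a warning) for a library with no
  positive-count overlap with the reference library, and exactly 1
  when all M-values vanish.

## Design choices where the design was open

* **tRNA loop coordinates from annotation, not alignment.** The
  anticodon-loop heatmap could be built from a multiple alignment of
  tRNA genes; cleavemap instead anchors loop positions 32–38 on the
  annotated N1 offset of each gene. For the anticodon loop itself the
  two are equivalent, and the annotation route needs no aligner and is
  deterministic. Consequently anticodon positions are taken from the
  annotation columns and validated against the genome sequence, never
  predicted.
* **Top-100 before the fold-change cut.** The calling rule is stated
  ambiguously in running text; the figure-caption wording (select
  $\log_2\mathrm{FC} > 4$ *from* the top 100 by FDR) is the one
  implemented.
* **Filter on targeting libraries only**, following the protocol's
  wording literally; a position absent from controls is precisely the
  interesting case.
* **Common dispersion.** The protocol delegates dispersion handling to
  a package whose defaults have changed across versions; a single
  Cox–Reid-adjusted common dispersion is the simplest faithful choice
  and matches the generator's data-generating process.
* **Pair-collapsed fragments by default** (the libraries are
  paired-end), with read-level counting available, since the protocol
  does not state which was counted.
* **BED6+3 annotation.** Feature class cannot ride in plain BED6+2
  alongside the two anticodon columns, so the interchange format adds
  one explicit class column (CDS/tRNA/rRNA/other).
* **Venn intersections on transcripts**, with tRNA sites mapped to
  their collapsed group (identical multi-copy genes count once), since
  the same RNA may be cut at different positions in different
  experiments; exact positional intersection remains available through
  the TSS/cleavage cross-check.

## Known limitations

* One two-level condition per contrast (plus the RppH contrast); no
  multi-factor designs, quasi-likelihood tests or exact tests.
* No CIGAR-aware splice handling — appropriate for bacterial
  transcriptomes, wrong for spliced transcripts.
* The filter's CPM scale depends on library size, so the effective
  stringency of the default 10-CPM cut varies with depth; shallow
  libraries pass weakly supported positions into the top-100 tail.
* Sites within `flank` nucleotides of a reference edge are dropped
  from logos (counted, and an error only if nothing remains).
* `collapse_identical_trnas` groups byte-identical gene bodies only;
  near-identical isodecoders stay separate.
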