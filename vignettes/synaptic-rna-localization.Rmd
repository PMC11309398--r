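---
title: "Mislocalized RNAs, circular RNAs and miRNA sites in fractionated RNA-seq"
author: "synloc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mislocalized RNAs, circular RNAs and miRNA sites in fractionated RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synloc)
```

# The design and the question

synloc analyzes bulk RNA-seq experiments with a 2x2 factorial structure:
each biological sample contributes two RNA fractions — a *synaptosome*
preparation (resealed synaptic terminals enriched by density-gradient
purification, whose RNA content approximates the synapse-localized
transcriptome) and the pre-fractionation *homogenate* (the bulk tissue
background) — and samples come from two conditions, *case* and *control*.

Three questions map onto three analysis stages:

1. **Mislocalization.** For which transcripts does the case/control fold
   change differ between the synaptosome and the homogenate fraction? A
   transcript whose global abundance is unchanged can still be depleted (or
   enriched) specifically at the synapse; that fraction-by-condition
   interaction is the quantity of interest.
2. **Circular RNAs.** Which back-splice junctions (a downstream exon's 3'
   end joined to an upstream exon's 5' end) are present, how abundant are
   the corresponding circRNAs per fraction, and do isoforms of one gene
   move in opposite directions between conditions?
3. **miRNA binding sites.** Are particular miRNA binding sites
   over-represented in the 3'UTRs of a shortlist (for example, the
   mislocalized genes) relative to a transcriptome-wide background?

# The mislocalization statistic

Each fraction is analyzed separately with a two-group case-vs-control
comparison that yields a per-feature log2 fold change and its standard
error. On the log2 scale the mislocalization fold change is the ratio of
ratios,

$$\mathrm{FC}_g \;=\; \mathrm{lfc}^{syn}_g - \mathrm{lfc}^{hom}_g ,$$

and the test statistic weights each fold change by its standard error —
i.e., it is the difference of the two Wald statistics:

$$R_{w,g} \;=\; \frac{\mathrm{lfc}^{syn}_g}{\mathrm{SE}^{syn}_g}
            - \frac{\mathrm{lfc}^{hom}_g}{\mathrm{SE}^{hom}_g}.$$

`misloc_test()` standardizes $R_w$ by its root mean square over all $G$
tested features, shrunk by $\sqrt{N}$:

$$T_g \;=\; \frac{R_{w,g}}
  {\sqrt{\left(\sum_{j=1}^{G} R_{w,j}^2 \,/\, G\right) / N}} .$$

Two-sided p-values come from a standard normal reference (default) or a
Student t with $N-1$ degrees of freedom, followed by Benjamini–Hochberg
FDR control. Direction calls (`up`/`down`) are made at an FDR cutoff of
0.001 by default, with 0.01 the recommended preset for designs with fewer
samples.

## Why the default is N = 1 with a normal reference

Under a null in which the $R_w$ are i.i.d. with some scale $\sigma$, the
empirical RMS converges to $\sigma$, so $T = \sqrt{N}\, R_w/\hat\sigma$.
For any $N > 1$ the statistic is inflated by $\sqrt{N}$ while the
reference distribution is not, and the nominal tail areas become strongly
anti-conservative: the null rejection rate at p < 0.05 is
$2\{1 - \Phi(t_{0.975,\,N-1}/\sqrt{N})\}$, which is about 0.50 at
$N = 12$ and grows with $N$. Only $N = 1$ with a normal reference — the
plain empirically standardized z-score $R_w/\mathrm{RMS}(R_w)$ — gives
calibrated p-values, and the package's null simulations confirm a
rejection rate of about 0.05 and essentially no false calls at q < 0.001
under that default. The literal $N$-sample construction (RMS treated as
the standard error of an $N$-sample aggregate, Student-t tails with
$N-1$ df) remains available through `n_samples` and
`null_dist = "student_t"`, and `analysis_config(n_samples = "auto")`
resolves to the total sample count in that mode; it is provided for
fidelity and comparison, not for inference.

Two further properties worth knowing: $T$ is invariant to rescaling all
$R_w$ by a common factor (so it cannot detect a global shift in variance),
and because the RMS is computed over *all* features, a large planted
signal inflates the denominator and makes the test conservative for
everything else. With realistic dispersions (around 0.1) and a handful of
replicates per cell, an interaction of 1.5 on the log2 scale yields
$|R_w| \approx 1.5/\mathrm{SE} \approx 5$–6 against a null spread of
about 1.4; after empirical standardization and FDR control at q < 0.01
the achievable sensitivity is modest (on the order of 10%), and no choice
of reference distribution can raise it substantially without destroying
FDR control — a genuine power limit of this statistic at that effect
size, not an implementation artifact.

# The differential-expression engine

`two_group_de()` is a deliberately small negative-binomial Wald engine;
its only job is to produce the (log2fc, SE) pairs the mislocalization
stage consumes, so tables from a full-featured DE package can be
substituted wherever synloc expects them.

* **Normalization** is classical median-of-ratios
  (`estimate_size_factors()`): the reference is the per-feature geometric
  mean across samples (features containing any zero are excluded), and a
  sample's size factor is the median of its count/reference ratios.
* **Filtering** keeps a feature with at least `min_count` reads in at
  least `min_samples` samples — 10 in 9 for mRNAs, 4 in 5 for circRNA
  junctions (`filter_features()`).
* **Dispersion** is a pooled within-group method-of-moments estimate
  $\hat\alpha_g = (v_g - m_g)/m_g^2$ (variance $\mu + \alpha\mu^2$),
  floored at $10^{-8}$ and *moderated* toward the across-feature median
  with a prior weight of `dispersion_prior_df = 8` pseudo-degrees of
  freedom. Moderation matters: raw per-feature moments at 3 replicates
  per group make the Wald null heavy-tailed, which shows up downstream as
  sporadic extreme mislocalization calls at q < 0.001 that vanish once
  the dispersion is moderated. This is the same idea (much simplified)
  that mature DE engines implement as empirical-Bayes dispersion
  shrinkage. Setting the prior df to 0 recovers the raw estimate.
* **Fold changes** use a pseudo-count $c = 0.5/\widetilde{sf}$ (the
  geometric-mean size factor), keeping log2fc finite for features absent
  from one group, and are computed as a difference of logs so that
  swapping the contrast negates log2fc and reproduces p-values
  bit-identically.
* **Standard errors** come from the delta method on the NB variance of
  the group means; p-values are two-sided normal; q-values are
  Benjamini–Hochberg.

Not implemented, by design: fold-change shrinkage, multi-level GLMs,
dispersion trend fitting, and outlier refitting. An additive two-factor
model over all four cells is also not fitted: the headline statistics
only consume the four subset two-group contrasts that
`run_full_analysis()` produces.

# The circRNA workflow

1. **Reference construction** (`build_backsplice_reference()`): for every
   transcript with $E$ exons, all donor/acceptor pairings with
   donor ≥ acceptor are enumerated — $E(E+1)/2$ junctions, including each
   single exon spliced back on itself. The junction sequence is the last
   `flank_len` (default 150) nt of the circularized exon block followed by
   its first `flank_len` nt. Flanks are clamped to the circle and never
   wrap, so short circles yield shorter flanks rather than duplicated
   sequence that would double-count reads; the effective flank lengths
   are recorded per junction. Junctions identical at the (gene, donor
   exon span, acceptor exon span) level across redundant transcripts are
   collapsed. Enumeration is per transcript; pooling exons per gene would
   also generate inter-isoform pairings and is intentionally not done.
2. **Read partitioning** (`partition_reads_by_linear_alignment()`): a
   read is "linear" if it has an ungapped full-length placement in any
   spliced transcript sequence, in either orientation, within
   `max_mismatch` Hamming mismatches. Alignment is substitution-only —
   the synthetic read model emits exact substrings with substitution
   errors, so gapped alignment would add cost without adding coverage.
3. **Junction counting** (`count_junction_reads()`): an unmapped read
   counts toward a junction if it aligns the same way to the junction
   sequence and covers at least `min_anchor` (default 10) nt on each side
   of the breakpoint. Among multiple qualifying junctions the unique
   mismatch-minimum wins; ties across distinct junctions are discarded
   deterministically and tallied (`ambiguous_discarded`) rather than
   assigned arbitrarily, so repeated runs are reproducible.
4. **Joint DE** (`combined_circ_de()`): junction counts are appended to
   the linear count matrix, size factors are estimated on the combined
   table (normalizing circles in the context of the whole transcriptome),
   circular features are filtered at 4 counts in 5 samples, and the
   requested two-group contrast is reported for circular features only.
5. **Summaries**: `detect_isoform_switches()` reports genes carrying two
   significantly changed junctions of opposite sign, and
   `exon_span_summary()` histograms donor − acceptor over detected
   junctions (0 = single-exon circle).

# The simulators

`simulate_count_dataset()` draws counts
$K_{gs} \sim \mathrm{NB}(\mu_{gs}, \alpha_g)$ with
$\mu_{gs} = m_s 2^{\beta_{0g} + \beta_{Fg}[\mathrm{syn}] +
\beta_{Cg}[\mathrm{case}] + \beta_{Ig}[\mathrm{syn\wedge case}]}$ and
variance $\mu + \alpha\mu^2$ ($\alpha = 0$ degenerates to Poisson). The
defaults are the desk-scale study conditions used throughout the tests:
2000 genes, 6 replicates per fraction-by-condition cell, log2 baselines
$\mathcal{N}(5, 2^2)$ (median counts in the tens, spanning four orders of
magnitude), per-gene fraction effects of sd 1 (synaptic enrichment is
strong and widespread), condition effects of sd 0.3, dispersion 0.1
(typical for bulk brain tissue), and log-normal library-size multipliers
of sd 0.2. The interaction coefficients $\beta_I$ — zero except for a
chosen subset with alternating signs — are the recorded mislocalization
truth.

`simulate_transcriptome()` / `simulate_reads()` build random multi-exon
transcripts (2–8 exons of 100–400 nt by default, uniform A/C/G/T) and
emit single-end reads: linear reads start uniformly over the spliced
transcript, circular reads start uniformly over the circularized exon
block and wrap across the back-splice point. A read spanning the
breakpoint with at least $a$ nt on each side arises with probability
$(L - 2a + 1)/C$ for a circle of length $C \ge L$, which the recorded
truth converts into expected junction counts; circles shorter than the
read are generated with wrap-around and flagged, since no full-length
ungapped alignment to their junction sequence exists. Bases are flipped
i.i.d. at `error_rate`; FASTQ qualities are constant `'I'` and never
read. Reads are sense-strand only — library strandedness is orthogonal
to every statistic tested. Fragment-length modeling, indels, GC bias,
paired ends and batch effects are out of scope.

`simulate_mirna_sites()` draws per-gene binding-site counts
$\mathrm{Poisson}(\lambda_m)$ with $\lambda_m$ log-normal across miRNAs;
shortlist genes scale $\lambda_m$ by the planted fold factor. The
background table is transcriptome-wide and *includes* the shortlist
genes, matching the enrichment test's default expected-value convention
(`subtract_shortlist = TRUE` gives the disjoint alternative).

# The miRNA enrichment test

For each miRNA, `site_enrichment_test()` compares the fraction of all
shortlist sites attributed to it, $s_m/S$, with the background fraction
$b_m/B$: the log2 fold change is $\log_2\{(s_m/S)/(b_m/B)\}$ and
significance is a chi-squared test on the 2x2 table
$[[s_m, S-s_m], [b_m, B-b_m]]$ with 1 df — one p-value per miRNA —
without continuity correction (a Yates toggle exists), followed by
Benjamini–Hochberg. Zero cells get a +0.5 offset for the fold change
only, flagged in the output. Exchanging shortlist and background negates
every log2fc and preserves the chi-squared values exactly.

# Numerical choices and degenerate inputs

* All-zero features: log2fc 0, Wald 0, p 1 (no feature is dropped by the
  engine itself; filtering is explicit).
* All $R_w = 0$: the standardization denominator vanishes; the test
  returns t = 0, p = 1 for every feature with a warning.
* Standard errors are floored at $10^{-8}$; `wald * se == log2fc` holds
  to machine precision.
* Coordinates are 0-based half-open internally; GTF/GFF 1-based
  inclusive records are converted exactly at the IO boundary, and exon 1
  is always the transcript 5' end regardless of genomic strand.
* Ties in junction alignment are resolved by discarding (never by
  arbitrary pick); ties in linear assignment take the first transcript
  in input order, which only feeds count totals.
* The orchestrator (`run_full_analysis()`) is deterministic given
  (config, seed, inputs); outputs are byte-identical across runs.

# Known limitations

* **Compositional effects are real and reproduced.** Sequencing a fixed
  read budget means planted abundance *weights* do not translate 1:1
  into observable count ratios: quadrupling circle weights at fixed
  depth yields less than a 4x count ratio because the circles dilute
  everything else, and interior (non-junction) circular reads map to
  their host transcript and inflate its "linear" counts. The package's
  recovery tests therefore model enrichment as deeper sequencing at
  constant linear abundance, and keep circles a small minority of the
  library — as they are in real ribodepleted data. Likewise, miRNA site
  fractions are closed: one strongly enriched miRNA depresses every
  other fraction, which is detectable when that miRNA dominates the
  site total.
* **Power of the mislocalization statistic** is bounded as described
  above; at dispersion 0.1 and 6 replicates per cell, interactions below
  about 2 on the log2 scale are detected with low sensitivity at strict
  FDR. The statistic's RMS denominator also couples features: large
  effects in some features make calls on others more conservative.
* The DE engine's moderated moment dispersion is adequate for the
  synthetic calibrations shipped here; for real data a full DE package
  remains preferable, and its output tables can be fed directly to
  `build_misloc_input()` / `misloc_test()`.
* The aligner contract is ungapped and substitution-only; real-data
  gapped alignment, soft-clipping and quality-aware scoring are out of
  scope, as are chimeric-alignment-based circRNA detection, inter-gene
  fusions and intron-retaining circles.
* Passing the synthetic recovery tests demonstrates internal
  consistency of the pipeline under its own generative model — uniform
  read starts, independent NB counts, no batch structure — not
  performance on real libraries.

# Problem sizes used by the shipped tests

The test suite and the acceptance script run at desk scale, chosen so
each calibration has enough resolution to be meaningful: null and
recovery simulations use 2000 genes with 3 or 6 replicates per cell
across 10 and 3 seeds respectively; the circRNA counting oracle uses 20
transcripts, 15 circles and 50,000 error-free reads; the circular
enrichment recovery uses 40 transcripts with 10 circles on 5 hosts and
about 20,000 reads in each of 10 samples; the miRNA recovery uses 200
miRNAs over a 5000-gene background with a 200-gene shortlist.
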