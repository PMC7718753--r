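---
title: "Rule-based CRISPRa guide design: model, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based CRISPRa guide design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprascan)
```

## The design problem

CRISPR activation (CRISPRa) steers a catalytically dead Cas9 fused or
recruited to transcriptional activators to a gene's promoter, where it
upregulates transcription. In dCas9-activator systems such as flySAM in
*Drosophila*, the same activator construct produces anywhere from no
activation to a 35-fold induction depending solely on which sgRNA is
chosen. Three guide properties carry almost all of that variation:

1. **Placement relative to the TSS.** Effective guides bind a window from
   −450 to −150 bp upstream of the transcription start site; placement
   around −200 bp is best. Guides in the flanks (0 to −150, or −450 to
   −600) give moderate activation; guides further than 600 bp upstream,
   or in the 5′UTR / gene body / 3′UTR, give essentially none.
2. **Spacer GC content.** Activation rises monotonically with the GC
   fraction of the 20-nt spacer — plausibly because stronger G:C pairing
   stabilizes the guide–DNA duplex that anchors the activator complex.
   Whether the G/C bases sit PAM-proximal or PAM-distal does not matter,
   so only the total GC fraction enters the model.
3. **Targeted strand.** Guides base-pairing with the non-template (NT)
   strand outperform guides pairing with the template (T) strand.

Placement *dominates*: a guide beyond −600 bp fails even at 75% GC.

`crisprascan` turns these ordinal findings into a deterministic scoring
and ranking procedure over all protospacers with an NGG PAM in a
promoter window.

## The scoring model

For a candidate at signed distance $d$ (bp, upstream negative, measured
in the direction of transcription), GC fraction $g \in [0,1]$ and strand
indicator $\mathrm{nt} \in \{0,1\}$:

$$P(d) = \begin{cases}
1 & d \in [-450, -150] \\
0.5 & d \in (-150, 0) \cup [-600, -450) \\
0 & d \ge 0 \text{ or } d < -600
\end{cases}
\qquad
S = P(d)\,\bigl(w_0 + w_{gc}\, g + w_{nt}\, \mathrm{nt}\bigr)$$

with defaults $w_0 = 0.2$, $w_{gc} = 0.6$, $w_{nt} = 0.2$ (summing to 1
so $S \in [0,1]$). Design choices behind this form:

* **Piecewise-constant position score.** The evidence for placement is
  ordinal (severe / moderate / no phenotype by region), so a window +
  flanks step function is the honest functional form; a smooth kernel
  would encode precision the data do not have. The −200 bp optimum
  enters only as the first ranking tie-break
  ($|d + 200|$ ascending), not as a bump in $P$.
* **Multiplicative dominance.** $S = P \times (\cdot)$ makes $P = 0$
  annihilate the score: the computational restatement of the observation
  that high-GC guides beyond the cutoff still fail. With the default
  weights every candidate with $P > 0$ scores at least
  $0.5 \cdot w_0 = 0.1 > 0$, so dominance is strict.
* **Identity GC score.** Any strictly increasing function of $g$ would
  preserve the ordinal finding; the identity is the least-committed
  choice, and no intra-spacer positional weighting is offered because GC
  placement within the spacer was explicitly found not to matter.
* **Weights.** The numeric values 0.2/0.6/0.2 are not measured
  quantities — the underlying experiments report phenotype classes, not
  a regression. They are package defaults chosen so that GC
  monotonicity, strand preference and placement dominance all hold
  structurally for *any* valid weights ($w_{gc} > 0$, $w_{nt} \ge 0$,
  weights summing to 1), and they are fully exposed in `design_config()`.
* **Both flanks score 0.5.** Whether the proximal flank (0..−150)
  differs from the distal one (−450..−600) is unresolved; absent
  evidence, they share one value. The flank intervals are derived from
  the optimal window and cutoff rather than configured separately, so a
  config cannot make the regions overlap or leave gaps.

### Fold-activation calibration

Two calibration measurements tie GC content to an activation magnitude:
2-fold at 0% GC and 35-fold at 90% GC. Fold-changes are ratio-scale
quantities, so the interpolation is log-linear:

$$\mathrm{fold}(g) = 2 \cdot (35/2)^{g/0.9}$$

```{r}
predicted_fold_activation(c(0, 0.45, 0.9), design_config())
```

Intermediate published values exist only as figure bars and are
deliberately not digitized — figure-read numbers are unreliable — so the
curve is anchored on the two printed values alone. Above 90% GC the
curve is an extrapolation and candidates there carry an
`extrapolated_gc` flag. The prediction is an indicative expectation for
relative comparison, not a calibrated assay prediction.

## Conventions that matter

* **Coordinates.** Internally everything is 0-based, half-open;
  GFF3 (1-based inclusive) and BED (0-based half-open) are converted at
  the format boundary only. The TSS of a `-` strand GFF3 feature is its
  `end` coordinate, the standard GFF3 reading.
* **Distance reference.** $d$ is measured to the PAM-proximal
  protospacer base. No published definition of the distance reference
  exists; any fixed choice differs by at most 22 bp, small against the
  150–300 bp granularity of the position regions. The alternatives
  (spacer midpoint, 5′ end) are available via
  `design_config(distance_reference = ...)`.
* **Strand naming.** `strand_class` names the strand the spacer
  *base-pairs with*: a guide is class T when its protospacer lies on the
  gene's own strand (the spacer then hybridizes to the template strand),
  NT otherwise. The opposite "protospacer identity" reading would invert
  the labels, so the convention is restated in every report's metadata.
* **Ranking.** Composite score descending, then $|d+200|$, then GC
  descending, then NT before T, then contig coordinate, then `+` strand.
  The order is total and input-order independent; reports are therefore
  byte-identical across reruns and input permutations. The last two keys
  are arbitrary spatial tie-breaks, which is why mirror symmetry of
  *ranks* holds in practice but is not guaranteed for exact four-way
  ties.
* **Filters.** Spacers containing `TTTT` are flagged (`polyT`) because
  runs of T terminate pol III transcription of U6-driven sgRNA
  cassettes; flagging rather than dropping is the default since the
  evidence base itself used U6-driven guides without reporting such a
  filter. `drop` mode is available.
* **Degenerate inputs.** Candidates with N in spacer or PAM are dropped
  (undefined GC, ambiguous synthesis) with a counted warning; ambiguity
  codes in input FASTA are normalized to N; windows clipped at contig
  edges are flagged `truncated_window`; a gene whose window yields no
  candidate is reported with an explicit reason rather than silently
  omitted, and one bad record never aborts a batch run.

## The synthetic fixture generator

`make_fixture()` emulates the experimental panels computationally: it
plants protospacers with exact distance, GC count and strand class into
i.i.d. background sequence (per-base GC probability `background_gc`,
default 0.5) and re-scans each promoter window, resampling the
background (bounded retries) until every planted spacer is recovered
exactly once at its intended coordinates. Ground truth is therefore
exact, not probabilistic. `make_panel()` builds the three canonical
comparisons — a same-region GC ladder, an in-window 45%-GC guide versus
a beyond-cutoff 75%-GC guide, and a matched NT/T pair — on an A/T-only
background, so the planted guides (plus candidates internal to GC-rich
plants, which background resampling cannot remove) are the only
candidates, and places each panel's expected winner exactly at −200 bp
so it cannot be displaced by a tie.

What the generator does *not* emulate: real promoter composition
(dinucleotide structure, CpG islands), chromatin accessibility,
off-target sites, or measurement noise in activation readouts. Passing
tests on fixtures therefore demonstrate that the scanning, annotation
and ranking machinery implements the stated criteria exactly — they do
not validate the criteria against new biological data.

## Problem sizes and numerical notes

The test suite runs the scanner-versus-oracle comparison on 200 random
1-kb windows (GC 0.2–0.8), the dominance property on 1,000 randomized
candidate pairs, and planted-guide recovery on 100 seeded panel
replicates; these sizes give exhaustive coverage of the discrete rule
set in well under a minute on one core. All scores are exact
floating-point expressions of the config (no iteration, no tolerance
issues); the calibration anchors reproduce to better than $10^{-9}$.
Determinism relies on a single user-supplied seed per fixture and on the
total ranking order.

## Known limitations

* No off-target / genome-wide uniqueness screening — pair with a
  specificity tool before synthesis.
* No machine-learned on-target efficacy model; the score is a faithful
  encoding of three coarse empirical rules, valuable precisely because
  it is transparent and auditable.
* The fold-activation curve rests on two printed anchors from one
  reporter system; treat it as a ranking aid, not an assay prediction.
* TSSs come from the annotation as given; alternative promoters are
  handled only insofar as each distinct annotated TSS gets its own
  independent design run (no collapsing across transcripts).
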