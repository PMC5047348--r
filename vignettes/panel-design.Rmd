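---
title: "Designing cost-effective cancer gene panels with panelforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing cost-effective cancer gene panels with panelforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelforge)
```

## The model

A targeted panel is a set of genomic intervals. Its value on a cohort of
$N$ tumor samples is the fraction of samples it detects — samples with at
least one protein-affecting mutation (PAM) inside the intervals — and its
cost is the total interval length in kilobase-pairs (Kbps).
`panelforge` designs panels that maximize the former while growing the
latter as slowly as possible.

### Protein-affecting mutations

Only mutations that plausibly alter the protein count toward coverage:
missense, nonsense (stop-gain), stop-loss, start-loss, splice-site,
frameshift and in-frame indels. Synonymous, intronic, UTR and intergenic
changes — and any unrecognized consequence string — are excluded. The
whitelist (`PAM_CLASSES`) is fixed but overridable (`pam_classes`
argument throughout), because consequence-calling pipelines differ in
vocabulary. Unknown strings warn and never fail: a cohort should not be
rejected because one row says `upstream_gene_variant`.

### Hotspot detection

Recurrent driver mutations cluster in short regions (classic examples:
*BRAF* V600, *KRAS* codons 12/13, *EGFR* exon 21). Sequencing a 50-bp
hotspot instead of a 5-kb exome buys the same detections at a fraction of
the cost. The detector works directly on mutated genomic positions of one
gene:

1. Among all windows spanning at most $L$ bp (default 100), find the one
   containing the most mutations; shrink it to the minimal span whose
   bounds are mutated sites. An optimal window can always slide until its
   left edge touches a mutated site, so only site-anchored windows are
   scanned. Ties prefer the smaller span, then the smaller start
   coordinate — compactness first, then determinism.
2. Remove the window's mutations and repeat.
3. Stop when every remaining site has fewer than two mutations.

Emitted hotspots therefore always contain $\ge 2$ mutations and consume
disjoint mutation sets. If the hotspots jointly capture at least
`min_fraction` (default 0.8) of the gene's PAMs, the gene enters the
panel as its individual hotspots; otherwise its complete coding exome is
used (the *whole-exome fallback*). Setting `min_fraction = 1` disables
hotspot mode for any gene with a single non-recurrent mutation.

Windows are measured in **genomic** coordinates, ignoring exon
boundaries: a hotspot may bridge a short intron if the mutated positions
are within $L$ bp on the chromosome. Transcript-space windowing would
need a transcript model for every gene and an arbitrary choice among
isoforms; genomic space is the simpler, reproducible choice. Indels are
anchored at their start coordinate for counting.

### Greedy CMF ranking

Candidate items (hotspots and whole genes) are ordered by greedy maximum
marginal coverage. With $S_i$ the set of samples whose PAMs fall inside
item $i$'s intervals, the item chosen at rank $n$ maximizes
$|S_i \setminus \bigcup_{m<n} S_{(m)}|$, and the cumulative mutational
frequency advances by that count over $N$:

$$\mathrm{CMF}_n = \mathrm{CMF}_{n-1} +
  \frac{\bigl|\,S_{(n)} \setminus \bigcup_{m<n} S_{(m)}\bigr|}{N}.$$

$N$ counts *all* cohort samples, including samples without a single
mutation (supplied via the sample manifest) — a panel's coverage must be
honest about tumors it cannot detect. Greedy selection makes marginal
gains non-increasing and is the order that maximizes the initial slope of
the CMF curve; it is not guaranteed to be the optimal set cover (that
problem is NP-hard), but for coverage functions the greedy prefix is the
canonical, reproducible choice. Ties break by larger total covered set,
then lexicographic item id, so the ranking is a pure function of the
input. Zero-gain items are appended rather than dropped — they are
reported as Tier 3.

### Tiers

Let $s$ be the expected per-rank CMF gain over contributing items: the
mean marginal gain fraction across items with positive gain, equivalently
the slope of the line through the origin reaching the final CMF after the
last contributing rank. Items with gain $\ge s$ are **Tier 1** (they pull
the CMF curve above its own trend), items with $0 <$ gain $< s$ are
**Tier 2**, zero-gain items are **Tier 3**. The *stringent* option raises
the Tier-1 threshold to $2s$ for users who want a short core panel; an
explicit `threshold` override is also exposed. Because greedy gains are
non-increasing, tiers are always contiguous in rank (asserted in code),
so restricting a design to Tiers 1–2 or Tier 1 keeps a prefix of the
ranking and leaves every retained item's statistics unchanged. With
fewer than two contributing items no trend exists; all contributing items
become Tier 1.

We considered an ordinary least-squares line on $(n, \mathrm{CMF}_n)$
with a free intercept, but its slope understates the early gains the
tiers are meant to single out (the fitted intercept absorbs the first
item's jump); the through-origin trend is the reading that matches the
definition of $s$ as an expected per-rank gain, and is what the tier
examples in the test suite freeze.

### Multi-mutation coverage and evaluation

`coverage_k` reports the fraction of samples with PAMs in at least $k$
**distinct panel items** ($k \le 3$), not $k$ distinct mutations — two
hits in the same hotspot still count once. Evaluation of any panel
(designed or an external BED) matches mutations to intervals by genomic
position, merges overlapping intervals before length accounting (DNA is
sequenced once), and groups intervals by their label for item counting.
Designing a panel and re-evaluating its own exported BED reproduces
coverage and Kbps bit-exactly; this closure is an acceptance criterion.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `L` (`--max-hotspot-bp`) | 100 | bp | Window cap; ~3 amplicons of short-read sequencing. Larger L merges nearby clusters and grows the panel. |
| `min_fraction` (`--min-captured-fraction`) | 0.8 | fraction | Below this captured share, hotspots misrepresent the gene and the whole exome is safer. |
| `stringent` | off | — | Doubles the Tier-1 threshold to 2s for shorter core panels. |
| `keep_tiers` (`--tiers`) | 1,2,3 | — | Restrict the emitted panel; Tier-3 removal never changes coverage. |
| `flank_bp` (`--flank-bp`) | 0 | bp | Pads BED output only (probe design slack); never counted in Kbps. |
| `pam_classes` | fixed list | — | Consequence whitelist; override to match the upstream annotator. |

## What the simulator emulates — and what it does not

`simulate_cohort` generates the world the tests reason about: $N$ samples
(default 200) over 30 genes, of which 8 are drivers mutated in a sample
with probability 0.15 each; the first 5 drivers carry one implanted
hotspot window of 50 bp placed wholly inside an exon, receiving a share
(default 0.9) of each carrier's driver mutation; every gene accrues
background mutations per sample at rate 0.01; 10% of mutations are marked
non-protein-affecting. Positions are drawn in exon space and mapped to
genomic coordinates, so simulated PAMs are always exonic. All draws occur
in a single seeded stream ordered by (gene, sample): realizations are
byte-reproducible and independent of iteration order. Each carrier
receives exactly one driver mutation — multiplicity per carrier is not
modeled.

Defaults were chosen once as a plausible mid-size cohort: carrier
probability 0.15 yields ~30 carriers per driver (comfortably above the
recurrence threshold), background 0.01/gene/sample yields ~2 passenger
observations per gene, and the 0.9 hotspot share leaves realistic
off-hotspot driver mutations that exercise the captured-fraction rule.

The simulator does **not** model mutational signatures (trinucleotide
context), selection, subclonal structure, copy-number or non-coding
alterations, or overlapping genes. A green test therefore establishes
algorithmic correctness — window optimality, greedy dominance, tier
consistency, closure, determinism — not biological fidelity of any
particular panel, and the published cohort-scale coverage numbers are
deliberately out of reach without the original data.

## Numerical choices

- Coverage fractions are ratios of exact integer counts over $N$; sums of
  marginal gains equal final coverage to the last bit, which is why
  closure tests can use `identical()` rather than tolerances.
- Input mutation coordinates are 1-based inclusive (MAF convention); all
  emitted BED is 0-based half-open. Internally intervals live in
  `GRanges` (1-based closed) and rtracklayer performs the conversion at
  the file boundary.
- Duplicate mutation rows (same sample, gene, position, alternate allele)
  are collapsed before any counting; cohorts are stored in a canonical
  row order so parsing is independent of input row order.
- Hotspot intervals carry no flanking padding in size accounting; the
  optional flank pads BED output only, keeping the cost metric
  conservative.
- Degenerate inputs: an empty mutation file, a missing required column,
  or a candidate list without a single mutated gene are fatal, with the
  offending column or diagnostic counts in the message; unknown
  consequence strings or malformed rows are warnings.

## Known limitations

- Gene identity is exact-string symbol matching; no identifier mapping.
- Hotspots ignore exon boundaries (see above) and carry no statistical
  significance test — the stop rule is purely count-based, as there is no
  background mutation model in the design procedure.
- The greedy ranking is a heuristic for the optimal-coverage panel of a
  given size; it is exact for the CMF definition but not a set-cover
  solver.
- External panels are evaluated on the same PAM definition as designed
  ones; if a commercial panel targets non-coding regions, those regions
  add Kbps but can never add coverage under this model.
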