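---
title: "Measuring virus-host codon usage co-adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring virus-host codon usage co-adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`codonadapt` quantifies codon usage bias (CUB) in coding sequences and the
degree to which a virus's synonymous codon choice is adapted to its host's.
This vignette is the package's account of the underlying statistics, the
conventions it adopts where the literature leaves room, and what its
synthetic-data tests do and do not establish about real genomes.

## Input model and CDS hygiene

Input is a pair of multi-FASTA files of coding sequences. A record is valid
when its length is a positive multiple of 3 and it contains only `ACGT`
(after uppercasing and `U -> T`). The default `strict` policy rejects
anything else and logs the reason; the `lenient` policy trims a trailing
partial codon and drops codons containing ambiguity codes, logging the
repair. Internal stop codons are *kept* but flagged: viral CDS annotations
are frequently imperfect, and every downstream index ignores stop codons
anyway, so rejecting such records would discard usable signal. Terminal
stops stay in the record; positional GC includes them, while RSCU, ENc,
SCUO, CAI, RCDI, SiD and PR2 all exclude them by construction.

All indices accept the standard NCBI translation tables (`table_id`,
default 1); the genetic-code tibble drives family membership and
degeneracy everywhere, so no index hard-codes the standard code's layout.

## The indices

**RSCU.** For codon $j$ of family $i$ with observed family total $X_i$ and
degeneracy $m_i$: $\mathrm{RSCU}_{ij} = x_{ij}/(X_i/m_i)$. Families never
observed in a gene are *undefined* (`NA`), not zero — a gene that encodes
no leucine says nothing about leucine preference. Stop codons and the
singleton families Met and Trp carry no information and are excluded,
leaving 59 informative codons under the standard code. Pooled tables are
always computed on summed codon counts, never by averaging per-gene values:
averaging would weight a 100-codon gene equally with a 3,000-codon one and
break the family-sum invariant ($\sum_j \mathrm{RSCU}_{ij} = m_i$).

**ENc.** Wright's estimator computes, per family with $n \ge 2$ observed
codons, the corrected homozygosity $\hat F = (n\sum_j \hat p_j^2 - 1)/(n-1)$,
averages within degeneracy classes, and combines
$\mathrm{ENc} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$.
Conventions where Wright's paper leaves gaps: families with fewer than two
observed codons are dropped from their class mean; a missing threefold class
(no isoleucine) is imputed as $\bar F_3 = (\bar F_2 + \bar F_4)/2$; any
other missing class renormalises the total over the amino acids actually
represented; non-positive class means (possible at tiny $n$) are treated as
missing; and the result is clamped to $[20, 61]$ — the uniform-usage value
slightly exceeds 61 because of the finite-sample correction, and the clamp
restores the interpretable range. A gene with no usable family gets `NA`;
an input where *every* gene is unusable is an error.

The Novembre variant replaces $\hat F$ with
$(\chi^2 + n - m)/(m(n-1))$, where $\chi^2$ measures the family's deviation
from the codon frequencies *expected under a background nucleotide
composition* (each codon's expectation is the product of its three base
frequencies, renormalised within the family). The default background is the
gene's own mononucleotide composition, which makes the correction
self-contained per gene; a genome-wide composition can be supplied instead.
The pipeline defaults to this estimator; `method = "wright"` is available
throughout.

**SCUO.** Per observed multi-codon family, the normalised entropy deficit
$O_i = (\log m_i - H_i)/\log m_i$; SCUO is the codon-share-weighted mean
$\sum_i (X_i/\sum X) O_i \in [0, 1]$. It is 0 exactly at uniform synonymous
usage and 1 exactly when every family uses a single codon.

**CAI.** Weights are relative adaptivenesses
$w_{ij} = \mathrm{RSCU}_{ij}/\mathrm{RSCU}_{i,\max}$ from the pooled counts
of a reference gene set; a gene's CAI is the geometric mean of $w$ over its
informative codons. Zero reference counts receive a pseudo-count of 0.5
before RSCU (Sharp & Li's own recommendation), which keeps every weight
positive and makes an entirely unobserved family fall back to uniform
weights of 1 — a neutral statement rather than a spurious penalty.

**The host-ENc reference set.** The reference genes are the fraction of
host genes with the *lowest* ENc — the most biased genes, the standard
expression proxy when expression data are absent. The default fraction is
0.05: small enough to capture the strongly-selected tail of a bacterial-
scale genome, large enough to pool stable counts. It is configurable
(`cai_fraction`), and ties are broken deterministically by `(enc, gene_id)`
so runs are reproducible. Genes with undefined ENc are ignored by the
selection.

**RCDI.** $\mathrm{RCDI} = \sum_j (\mathrm{CiF}_{a,j}/\mathrm{CiF}_{h,j})
\cdot N_j/N$ over the gene's sense codons, where $\mathrm{CiF}$ are
within-amino-acid codon frequencies in the viral gene ($a$) and the pooled
host ($h$). By Cauchy-Schwarz the index is $\ge 1$, with equality exactly
when the gene's synonymous frequencies match the host's on every family it
uses. Host codons with zero pooled count get a 0.5 pseudo-count before
frequencies, so ratios stay finite; a codon the host genuinely never uses
then contributes a large (not infinite) deoptimization signal.

**SiD.** $(1 - R)/2$ with $R$ the cosine similarity of the two pooled RSCU
vectors over the 59 informative codons, undefined entries as 0. Because
RSCU values are non-negative, $R \ge 0$ and SiD is mathematically confined
to $[0, 0.5]$, although published descriptions quote the nominal range
$[0, 1]$; the package asserts (and its tests enforce) the tighter bound.
0 means identical relative synonymous preferences; 0.5 means disjoint ones.

## Composition and PR2

Positional GC is computed over *all* codons, so `gc_overall` equals the
mean of `gc1`, `gc2`, `gc3` exactly for any in-frame CDS — a deliberate
coherence choice. Alongside plain `gc3`, `gc3s` reports third-position GC
over multi-codon-family codons only (Met, Trp and stops excluded). The
distinction matters: ATG and TGG contribute invariant G third positions,
inflating plain GC3 by roughly +0.1 in a typical gene, and Wright's
expected-ENc curve $2 + s + 29/(s^2 + (1-s)^2)$ is defined on silent-site
$s$. The ENc-GC3 plot therefore uses `gc3s` as its abscissa while the
per-gene tables report both.

PR2 biases are $A_3/(A_3{+}T_3)$ and $G_3/(G_3{+}C_3)$ over the
fourfold-degenerate families. By default the fourfold *boxes* of the
sixfold amino acids (CGN arginine, CTN leucine, TCN serine) count as
fourfold, the usual Sueoka convention; `include_sixfold_boxes = FALSE`
restricts to the five strictly fourfold amino acids. A bias whose
denominator is zero is `NA` — an explicit "undefined", never silently 0.5
or 0 — and the PR2 plot drops such genes while counting them in its
caption.

## Dinucleotide null models

Observed counts are overlapping windows over the whole sequence, junctions
included (a length-$L$ sequence has $L-1$ windows); no circularisation.
Three shuffling nulls are offered, each preserving a different feature:

| model      | preserves (without replacement)                 |
|------------|--------------------------------------------------|
| `base`     | mononucleotide counts                            |
| `codon`    | the codon multiset                               |
| `syncodon` | the protein sequence and per-family codon counts |

`with` replacement instead draws i.i.d. from the observed base/codon/family
multiset, so the conserved quantities hold in expectation only. The
z-scores are Monte-Carlo standardisations over `n_perm` shuffles (default
500, sample standard deviation); analytic moments exist for some of these
nulls but a simulation null is uniformly correct across all three models
and directly testable. A dinucleotide with zero null standard deviation
(e.g. any dinucleotide of a homopolymer under `base`) gets `NA`, never
$\pm\infty$. Results are a pure function of
`(sequence, model, replacement, n_perm, seed)`, and the caller's RNG state
is restored afterwards.

## The synthetic CDS generator

The generator exists so that every index and null model is testable without
downloads, with codon-usage structure as the controlled variable. Genes are
built as ATG + body + stop; body amino acids are drawn uniformly over the
20 standard residues (or taken from a fixed protein), and synonymous codons
are drawn per family from a weight table. Weight tables come from:

- `codon_weights(alpha)` — symmetric Dirichlet per family; `alpha = Inf`
  is uniform usage, small `alpha` strong preference. The study default for
  virus-host pairs is `alpha = 0.5`, which yields within-family skews of
  the magnitude seen in strongly biased microbial genomes.
- `codon_weights(one_hot = TRUE)` — one codon per family: the analytic
  maximal-bias case (ENc 20, SCUO 1).
- `gc3_codon_weights(s)` — third-position composition as the only force:
  genes under these weights scatter around Wright's expected curve.
- `target_gc3` tilting — any weight table can be exponentially reweighted
  to a target expected GC3, with a clear error when the target is
  unreachable (e.g. one-hot weights fix GC3 entirely).

`simulate_virus_host(delta)` draws host weights once and sets virus weights
to $(1-\delta)\,w_{host} + \delta\,w_{inverted}$, where inversion reverses
each family's preference *ranking* (keeping the weight multiset — a simple,
degeneracy-safe divergence knob). $\delta = 0$ is a maximally host-adapted
virus; $\delta = 1$ a maximally deoptimized one. Defaults (100 host genes,
30 virus genes, 200-500 codons per gene) are a deliberately scaled-down
genome: large enough for stable pooled RSCU and a meaningful low-ENc tail,
small enough that the full test suite and the acceptance script run in
seconds to minutes. `simulate_cpg_depleted()` plants a CpG deficit by
swapping a fraction of `CG` occurrences to `GC`, which preserves
mononucleotide counts exactly and is therefore a genuine signal under the
base-permutation null.

What the generator does *not* emulate: real dinucleotide landscapes beyond
that planted CpG deficit, amino-acid composition bias, gene-length/
expression correlations, or within-genome heterogeneity of codon preference
(every simulated gene shares one weight table). Passing tests therefore
demonstrate correctness of the estimators and the directionality of the
co-adaptation indices under controlled conditions — not that any particular
biological inference is licensed for a given real genome.

## Numerical and design notes

- All 64 codons are always represented in count tables (zeros included);
  undefined values are explicit `NA`s end to end, written as `"NA"` in TSVs.
- CAI is computed in the log domain, so 3,000-codon genes lose no precision
  to repeated multiplication.
- The δ-sweep (SiD and RCDI non-decreasing, CAI non-increasing in δ) is the
  headline end-to-end property test of the whole toolkit, and every index
  is additionally checked against an independent naive reimplementation at
  tolerance 1e-9.
- The pipeline's three analysis branches (composition; gene-level indices;
  codon-level RSCU/SiD) are independent — disabling one never changes
  another's numbers — with one documented exception *inside* the gene
  branch: CAI consumes the host-ENc reference set.
- Plots are data-first: the coordinate tables are the tested contract, and
  images (PNG/SVG, 300 dpi) are rendered from them on request.

## Known limitations

- ENc on very short genes (under ~100 codons) is noisy and the class-mean
  conventions matter; the clamp to $[20, 61]$ hides part of that noise.
- The CAI reference fraction default (0.05) is a convention, not an
  estimate; for small host gene sets, raise it so the reference pool stays
  meaningful.
- RCDI grows without bound as host frequencies for virus-preferred codons
  approach the pseudo-count floor; compare RCDI values only under a fixed
  host.
- SiD compresses 59 dimensions into one number; genomes with very different
  usage can still have moderate SiD. Inspect the RSCU matrices when the
  scalar surprises.
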