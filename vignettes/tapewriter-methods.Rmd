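---
title: "tapewriter: models and methods for sequential-editing DNA tape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tapewriter: models and methods for sequential-editing DNA tape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapewriter)
```

## The recorder model

A DNA tape is a tandem array of `n_sites` copies of a short monomer (default
the 14-nt `TGATGGTGAGCACG`), preceded by a constant key (default `GGA`). Only
the 5'-most *completed* target site -- the "type guide" -- is a valid
prime-editing substrate at any moment: every insertion writes
`barcode + key`, which simultaneously (i) records the identity of the pegRNA
that wrote it, (ii) destroys the current target and (iii) completes the
spacer of the next monomer. Three consequences structure everything in this
package:

* **Prefix property.** Edited sites always form a prefix of the array; the
  spatial order of barcodes *is* the temporal order of events. Patterns that
  are not a prefix ("nonsequential") can only arise from errors, and their
  share among edited reads is the *sequential error rate*.
* **Constant write rate.** Each tape has exactly one active site until it is
  exhausted, so the per-tape write rate does not decay as the tape fills
  (until saturation).
* **State-space size.** A tape with m sites over an s-symbol alphabet has
  `sum(k=0..m) s^k` sequential states; independent tapes multiply. For the
  default clonal geometry (nine 5-site, three 4-site and one 2-site tape; 19
  symbols) `state_space_log10()` gives ~10^75.8 joint states.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `monomer`, `key` | `TGATGGTGAGCACG`, `GGA` | nt | the HEK3-derived chemistry; the key is what completes the next spacer |
| `barcode_len` | 2 (programmes), 3 (text codec, clones) | nt | 2-nt barcodes give 16 symbols, 3-nt give 64 |
| `per_epoch_edit_prob` | 0.1 | per tape per epoch | a transient transfection writes at most one edit per tape; ~10-25% editing of the active site per round is the realistic regime |
| edit score | 0 (neutral) | log2 | relative write efficiency of a barcode; observed spreads are roughly -2.4..+1 with most symbols within two-fold of neutral, hence the simulators' default spread sd = 0.5 |
| `per_tape_per_division_edit_prob` | 0.154 | per tape per division | calibrated so 13 tapes accrue ~2 edits per cell division, ~40 edits over 20 doublings |
| `generations` / `sample_size` | 20 / user | doublings / cells | a monoclonal expansion to ~10^6 cells of which a few thousand are assayed |
| bootstrap `n_reps` | 100 | replicates | block resampling of whole tapes (sites within a tape are not independent) |

## Epoch simulation and the ordering decoder

`simulate_programme()` treats each epoch as one transient transfection: a
non-full tape gains at most one edit, the barcode drawn with probability
proportional to `mix_weight * 2^edit_score`. One deliberate design choice:
the per-epoch edit *probability* is also scaled by the weight-averaged
`2^edit_score` of the epoch's mix (capped at 1). With one barcode per epoch
an efficiency spread would otherwise have no observable effect at all, and
site-1 unigram frequencies would already be ordered by epoch -- whereas in
real recordings it is precisely the efficiency differences between pegRNAs
that corrupt the unigram order and make the bigram step necessary. Setting
`scale_rate_by_efficiency = FALSE` restores the flat-rate behaviour.

The decoder is two-stage. `initial_order()` sorts symbols by site-1
frequency (descending; lexicographic ties). `refine_order()` then scans
adjacent pairs (A before B) and swaps whenever `counts[B, A] > counts[A, B]`
in the pooled adjacent-site bigram matrix, restarting the pass after every
swap, until a clean pass or `n(n-1)/2 + 1` passes. Ties -- including 0 vs
0 -- never swap, so the incoming order is the tiebreak, and the output is
always a permutation of the input. Because every tournament contains a
Hamiltonian path, the scan terminates at an adjacent-consistent order even
when the pairwise evidence is cyclic; pass exhaustion is reported via
`converged = FALSE`, never as an error. The swap test uses raw counts:
row/column normalization (offered by `normalize_bigram()` for heatmap
display) cancels out of any single pairwise comparison.

## The TAPE64 codec

`tape64_table()` maps a 31-character alphabet (A-Z, `.`, `,`, `?`, `!`,
space) onto all 64 3-nt barcodes. Redundancy is 2 per character except
whitespace, which gets 4: 30x2 + 4 = 64, and whitespace is the most frequent
character in English text. This default assignment (lexicographic walk of
the 3-mers) is the package's own convention; a published assignment table
can be passed in and is validated instead. Repeated characters cycle
round-robin through their redundant codes; a character repeated beyond its
redundancy silently reuses codes, which manifests as deletion errors on
decoding -- a property of any 64-code scheme, not an implementation defect.

Decoding clusters the whitelisted barcodes into co-transfection sets by
complete-linkage hierarchical clustering of Euclidean distances between
bigram context profiles. Each symbol's profile concatenates its outgoing and
incoming transition distributions, *each normalized to unit sum*: with 7:5:3:1
within-set weights the raw counts of set members differ up to seven-fold, and
clustering unnormalized profiles groups symbols by abundance rather than by
temporal context. The dendrogram is cut at the smallest number of clusters at
which no cluster exceeds the set size (4) -- a deterministic surrogate for
the visual cut a human would make. Sets are ordered by the swap algorithm on
the set-aggregated bigram matrix; characters within a set are ordered by
efficiency-corrected unigram counts summed across all sites (descending),
since earlier characters were mixed at higher weight.

Reconstructions are scored by optimal string alignment (restricted
Damerau-Levenshtein, unit costs, deterministic backtrace preferring match >
transposition > substitution > deletion > insertion). In the reported
decomposition a substitution counts as one deletion plus one insertion, and
a transposition's two characters are not counted as correct, so
`correct + deletions + 2*transpositions = nchar(truth)` whenever no symbols
were invented.

## Lineage reconstruction

The lineage kernel is the order-aware shared-edit count: per tape, sites are
scanned from site 1 while both cells carry the *identical* insertion at
every site so far, and only sites inside this shared prefix count. A
matching symbol behind the first discordant or unedited site is most
parsimoniously explained as two cells independently drawing the same symbol
-- homoplasy -- and is discounted. Distance is
`max_shared - shared` with `max_shared` the panel's editable-site total (59
by default). Self-distance is defined as 0 even though `59 - shared(i,i)` is
positive; only off-diagonal entries feed the tree methods.

Trees come from `stats::hclust(average)` (UPGMA; rooted, ultrametric after
ape's height halving) and `ape::nj()`. Leaves are sorted by label before
clustering so equal-distance merges resolve deterministically; because the
tie policy of any other implementation may differ, parsimony scores of trees
built elsewhere should be compared approximately (about 1%), not exactly.
Fitch parsimony is computed in-package on bitmask state sets (states =
insertion identities plus explicit "unedited", at most 31 states per site),
exact on binary trees; polytomies are resolved arbitrarily with a warning.
Bootstrap resampling draws whole tapes with replacement (13 blocks),
because the prefix property makes sites within a tape strongly dependent;
`max_shared` is recomputed as the resampled site total.

Cell-table preparation follows the conservative reading of the published
filters: tape identifiers are corrected at Hamming distance exactly 1 from a
unique whitelist member and dropped at >= 2 (`drop_at` exposes the
behaviour at exactly 2, which the source text leaves ambiguous); per-cell
consensus requires >= 2 distinct UMIs, conflicting tape sequences resolve to
the larger UMI count and ties drop the group; cohort assembly keeps only
cells carrying the complete tape panel with all insertions on the whitelist.

## The synthetic-data generator, and what a green test establishes

`simulate_clone()` grows a synchronous binary genealogy for `generations`
doublings; at each division each daughter, per non-exhausted tape, gains one
edit with probability `per_tape_per_division_edit_prob`, the symbol drawn
proportional to `2^edit_score`. Only sampled lineages are simulated, so deep
trees are cheap, and traversal order is fixed for seed-reproducibility. The
generator emulates: strictly sequential per-tape writing, multi-copy tapes of
heterogeneous length, symbol-efficiency bias, uniform leaf sampling with the
induced true genealogy. It deliberately does not emulate: asynchronous or
time-based editing, cell-cycle or transfection heterogeneity, tape-length
instability (contractions are parsed, never simulated), doublets, dropout,
or indel/sequencing-quality noise beyond uniform substitutions
(`add_read_noise()`).

One dispersion caveat follows directly. A per-division Bernoulli writer
yields per-cell edit counts with variance strictly below the mean
(binomial thinning, further truncated by tape saturation and narrowed by
shared ancestry). At the default calibration (~37 edits against 59 sites)
the variance is ~40% below the mean, whereas real recordings at the same
depth are essentially Poisson (variance roughly equal to the mean). The
discrepancy is informative: Poisson-like accrual at high edit counts
implies overdispersed, plausibly time-based writing rather than one
Bernoulli trial per division -- a question the source system explicitly
leaves open. The package therefore tests the Poisson-like property in the
regime where its own model predicts it (total sites much greater than
expected edits, e.g. `per_tape_per_division_edit_prob = 0.03`), and makes no
claim that the default calibration reproduces the empirical dispersion.
Likewise, a green tree-recovery test establishes that the order-aware
distance extracts the lineage signal the simulator put in -- not that real
cohorts, with their dropout and heterogeneity, will reach the same accuracy.

## Numerical choices

* **Edit-score pseudofrequency**: `eps = 0.5/total_reads` (half-count
  correction) keeps log2 scores finite for unobserved barcodes; pass counts,
  not pre-normalized frequencies, so the total is known.
* **Whitelist two-means**: exhaustive 1-D split on `log10(count + 1)`
  minimizing within-cluster SS -- deterministic, no random initialization.
  The low cluster is only discarded when the cluster means are at least one
  decade apart (`min_separation`); otherwise the spectrum is treated as
  signal-only. Without this guard, clean data whose true counts legitimately
  span a decade (e.g. 7:5:3:1-weighted message barcodes) would lose their
  low-weight members. `min_separation = 0` gives plain two-means.
* **Parser tolerance**: monomer matching is exact by default;
  `max_monomer_mismatch = 1` covers the single-substitution correction used
  for 14-nt monomers in single-cell data. The key must always match exactly
  (wrong-key reads are removed, as in the published filter).
* **Long-read representatives**: max monomer count, then max edits, then
  lexicographically smallest read -- fully deterministic.
* **Degenerate inputs**: an exhausted tape raises a classed condition from
  `step_edit()` but is silently inactive inside simulators; zero edited
  reads make the sequential error rate `NA` rather than 0; an all-equal
  count spectrum whitelists everything.

## Known limitations

* Temporal inference is pairwise-adjacent only; no likelihood model, no
  skip-pair evidence, no uncertainty quantification on the recovered order.
* The codec does not attempt error-correcting codes; decoding accuracy
  degrades gracefully with coverage but repeated characters beyond their
  redundancy are irrecoverable by design.
* Tree methods are distance-based (UPGMA/NJ); no maximum-likelihood or
  Bayesian reconstruction, no time calibration of branch lengths.
* The per-division clock is the only clock; a time-based editing mode is
  future work.
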