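# tapewriter

Sequential genome-editing tape simulation, parsing, event ordering, text
decoding and lineage reconstruction.

## The problem

Insertional molecular recorders write events into the genome of living cells
as short prime-editing insertions on a **DNA tape**: a tandem array of
truncated CRISPR target monomers in which only the 5'-most completed site
(the *type guide*) is editable. Every insertion deposits a pegRNA-specific
barcode plus a constant key that activates the next monomer, so edits accrue
**strictly sequentially** -- the physical order of barcodes along the array
is the temporal order of the recorded events. This package is the
computational stack around such recorders, for people who need to simulate
them, parse their amplicons, decode event order (including text messages
encoded in barcode mixtures), and reconstruct cell lineages from single-cell
tape tables.

## What is computed

* **Sequential state space.** A tape with m sites over s symbols has
  ∑ₖ₌₀..ₘ sᵏ states; tapes multiply. `state_space_log10()`.
* **Editing metrics.** efficiency = edited/total reads; *sequential error
  rate* = nonsequential/edited; per-site conditional rates
  P(site i edited | sites < i edited). `editing_metrics()`.
* **Edit scores.** scoreᵦ = mean over replicates of
  log₂((fᵦ + ε)/(aᵦ + ε)), the log2 enrichment of insertion frequency over
  pegRNA pool abundance. `compute_edit_scores()`.
* **Event ordering.** Initialize by descending site-1 unigram frequency,
  then scan adjacent pairs (A, B) of the candidate order and swap while the
  pooled adjacent-site bigram counts satisfy N(B→A) > N(A→B), restarting
  after each swap. For n events this uses (n² + n)/2 pairwise rules instead
  of searching n! permutations. `initial_order()`, `refine_order()`.
* **TAPE64.** 31 text characters → 64 3-nt barcodes with 2- or 4-fold
  redundancy; four-character sets per epoch mixed 7:5:3:1 so the weight
  ranking encodes within-set order. Decoding = whitelist → bigram clustering
  (complete linkage) → set ordering by bigram swaps → within-set ordering by
  efficiency-corrected counts. `encode_message()`, `decode_message()`.
* **Order-aware lineage distance.** shared(i,j) counts identical edits
  inside the per-tape identical prefix only (matches behind a discordant
  site are homoplasy and discounted); d(i,j) = max_shared − shared(i,j).
  Trees by UPGMA/NJ, exact Fitch parsimony, tape-block bootstrap.
  `distance_matrix()`, `build_tree()`, `fitch_parsimony()`,
  `bootstrap_support()`.

## Worked example

Record sixteen transfection epochs (one unique barcode each, realistic
efficiency spread) on 10,000 five-site tapes, then decode the event order:

```r
library(tapewriter)
symbols <- default_symbols(16, 2)
set.seed(1); eff <- efficiency_map(setNames(rnorm(16, 0, 0.5), symbols))
prog <- programme_spec(lapply(symbols, function(b) setNames(1, b)),
                       per_epoch_edit_prob = 0.1)
sim    <- simulate_programme(prog, tape_config(n_sites = 5), 10000, eff, seed = 2)
parsed <- parse_reads(sim)
editing_metrics(parsed)
#> <edit_metrics: efficiency 0.843 | sequential error 0.000 | 10000 reads>
initial_order(site_unigrams(parsed)[[1]])
#> <event_order: AT < AC < AA < CA < CG < AG < CT < GG < GA < CC < GT < GC < TG < TA < TT < TC [initial]>
refine_order(initial_order(site_unigrams(parsed)[[1]]),
             bigram_counts(parsed, symbols = symbols))
#> <event_order: AA < AC < AG < AT < CA < CC < CG < CT < GA < GC < GG < GT < TA < TC < TG < TT>
```

The unigram initialization is scrambled by the per-pegRNA efficiency spread
(only 2/16 events in place); the bigram swap pass recovers the programmed
order exactly (16/16). Lineage reconstruction on a simulated clonal
expansion (20 doublings, 13 tapes / 59 sites, ~2 edits per division):

```r
params <- clone_sim_params(sample_size = 40, seed = 8)
clone  <- simulate_clone(params)
cohort <- select_complete_cells(clone$cells, params$target_bcs,
                                capacity = params$tape_site_counts)
cohort_summaries(cohort)
#> <cohort_summary: 40 cells | edits/cell mean 34.9 var 19.5 | 40 unique patterns | mean active tapes 9.7>
tree <- build_tree(distance_matrix(cohort), "upgma")
fitch_parsimony(tree, cohort)
#> [1] 1073
ape::dist.topo(ape::unroot(tree), ape::unroot(clone$tree))[1]
#> [1] 10        # of a maximum of 74 for 40 leaves; label permutations score ~72
```

Every cell has a unique 59-site pattern, ~10 of 13 tapes are still
recording, and the order-aware UPGMA tree sits far closer to the true
genealogy (Robinson-Foulds 10/74) than any relabelled control.

## Command line

```sh
inst/exec/tapewriter simulate-programme --epochs epochs.txt --n-tapes 10000 \
    --edit-prob 0.1 --seed 7 --out sim.fa
inst/exec/tapewriter order --reads sim.fa --out order.txt
inst/exec/tapewriter simulate-clone --seed 7 --sample-size 100 --out cells.tsv
inst/exec/tapewriter lineage-summary --cells cells.tsv --out summary.json
```

Subcommands: simulate-programme, simulate-clone, parse, metrics,
edit-scores, order, encode, decode, lineage-distance, lineage-tree,
lineage-bootstrap, lineage-summary. Stochastic commands require `--seed`;
exit codes are 0 (success), 1 (runtime error), 2 (usage error).

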