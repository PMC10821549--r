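# essnet

Essential-protein prediction from **dynamic** protein–protein interaction
(PPI) networks.

Essential proteins — those whose deletion is lethal or causes infertility —
are a small minority of any interactome, and finding them computationally
is a classic imbalanced-classification problem in systems biology. Most
network methods score a *static* PPI graph by centrality. `essnet` instead
uses a gene-expression time course to make the network dynamic, mines the
network's *evolution* for overlapping communities, and classifies proteins
from those communities together with subcellular-localization annotations.

## Method

1. **3-sigma dynamic network.** For each protein with expression series
   `EV_1..EV_n`, compute `mu`, the sample variance `sigma^2`, the
   fluctuation factor `F = 1/(1 + sigma^2)` and the activity threshold

   ```
   t = mu + 3 * sigma * (1 - F)
   ```

   A protein is active at time `i` when `EV_i >= t`; snapshot `E_t` keeps
   the static edges whose endpoints are both active (by default the first
   snapshot is the full static network).

2. **Interaction stream.** Consecutive snapshots are differenced into
   time-ordered edge **birth** and **death** events `(u, v, t)`; replaying
   the stream reconstructs every snapshot exactly.

3. **Streaming community discovery.** A label-propagation engine maintains
   overlapping communities with **core** members (each in a triangle of
   three cores of the same community) and **peripheral** members (one-hop
   neighbours of cores); only cores transmit membership. Live communities
   are recorded at every observation window, and the distinct observed
   member sets become binary membership features.

4. **SVM-RFE.** A linear soft-margin SVM (dual with kernel
   `x_h.x_k + lambda*delta_hk`, box `0 <= alpha <= C`) is trained
   repeatedly; each round removes the feature with the smallest squared
   weight `c_i = w_i^2`. The top 64 communities are kept. Subcellular
   terms are ranked by protein count; the top 1024 minus ranks 11–64
   (at most 970 columns) form the second feature block.

5. **Two-branch classifier.** Each feature block passes through fully
   connected layers with batch normalization and ReLU down to a 16-length
   representation; the concatenated 32-vector feeds a sigmoid head.
   Training uses binary cross-entropy and balanced per-epoch downsampling:
   all `M` positives plus `M` sampled negatives per epoch, with the epoch
   count chosen so that any negative is missed with probability at most
   `P = 0.001` (`(1 - M/N)^k <= P`).

Inputs are plain text: a two-column TSV edge list (BioGRID-style exports
work as-is), an expression TSV (header of timepoints, one row per
protein), a protein-to-term TSV, and a one-ID-per-line essential list. A
synthetic-data generator with planted communities, phased expression,
localization enrichment and configurable essential fraction makes the
whole pipeline testable offline.

## Worked example

```r
library(essnet)

ds  <- generate_dataset(easy_regime_config(seed = 1))  # 200 proteins, 5 blocks
ad  <- as_aligned_dataset(ds)
res <- run_essnet_pipeline(ad, seed = 1)
#> stage align: 200 nodes, 3856 edges, 40 essential
#> stage snapshots: 12 snapshots, edges 3856/736/738/738/739/739/739/745/745/738/738/738
#> stage stream: 12894 events (6816 births, 6078 deaths)
#> stage communities: 1 live, 12 windows, 640 records
#> stage candidates: 6 candidate community features
#> stage rfe: kept 6 of 6 community features
#> stage subcellular: 10 feature columns
#> stage train: 100 epochs, final balanced loss 0.0227
#> stage evaluate: AUC 1.000  AP 1.000  F 0.941

res$report
#> metric_report: acc 0.975  prec 0.889  rec 1.000  F 0.941  AUC 1.000  AP 1.000

round(recovery_check(ds, res$candidates), 2)
#> 1 2 3 4 5
#> 1 1 1 1 1
```

The run reads as follows: the stream carries ~13k edge events because each
planted block is active only during its own phase; the engine tracks one
live community per phase and the six distinct member sets observed across
windows become the community features; with the strong planted signal the
held-out test set (40 proteins, 8 essential) is ranked perfectly (AP 1.0)
and thresholded classification reaches F = 0.941. `recovery_check` shows
every planted block matched by a discovered community at Jaccard 1.0.

The ablation harnesses reuse one split and seed per comparison:
`ablate_branches()` trains community-only / subcellular-only / combined
variants, and `detach_sweep()` drops each snapshot in turn and reruns the
whole pipeline.

A thin command-line wrapper with subcommands (`simulate`, `dynamic-net`,
`communities`, `run-all`, `ablate-branches`, `ablate-snapshots`) is
installed at `inst/cli/essnet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/essnet.R", package="essnet"))')" \
    simulate --out demo --seed 1
```

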