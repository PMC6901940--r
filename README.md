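# bcpflow

Simulation and analysis of human bone-marrow **B-cell precursor (BCP)
maturation**, for immunologists and cytometry/repertoire bioinformaticians
who want the whole measurement loop — from raw 10-marker event tables and
IGH reads to blockade calls — as reproducible, tested code.

B-cell development runs pro-B → pre-BI → pre-BII → immature → mature,
paced by IGH V(D)J recombination and pre-BCR/BCR signalling, and is
asynchronous: cells transit as a continuum, and non-BCR markers (CD34, TdT,
CD20) change out of step with cytoplasmic Igμ. `bcpflow` provides four
connected components:

1. **Synthetic data** — multi-donor bone-marrow event tables for the
   10-colour BCP panel (CD20, smIgM, CD38, TdT, cyCD79a, IgD, cyIgM, CD19,
   CD34, CD10) with healthy, RAG-deficient and BTK-deficient donor
   profiles, transitioning cells and donor shifts; plus IGH V(D)J
   rearrangement repertoires per sorted pre-B compartment with exact ground
   truth. In-frame clone fractions are calibrated per compartment:
   pre-BI+/+ 0.10, pre-BI−/− 0.75, pre-BII−/− 0.80, pre-BII+/+ 0.75.
2. **Gating** — arcsinh transform, density-valley positivity thresholds,
   deterministic stage classification from BCR-associated markers
   (cyCD79a → CD19/TdT → smIgM/IgD → cyIgM), CD34/TdT subdivision of
   pre-BI/pre-BII, and precursor-compartment composition (mature B cells
   excluded from the denominator).
3. **Reference model** — pooled-healthy-control PCA ("automated population
   separator" view): per-population contours at Mahalanobis distance
   *k* = 2 in PC1–PC2, the fraction of BCP outside **both** the pre-BI and
   pre-BII 2SD contours (transitioning/aberrant cells), composition
   reference ranges, and maturation blockade calls
   (`complete_block_preBI`, `partial_block_preBII`, `none`).
4. **Repertoire** — built-in V/J assignment (ungapped semi-global
   alignment with free end-trimming), CDR3 extraction between the conserved
   Cys and Trp anchors, productivity classification (in-frame iff the
   V-to-J-anchor distance ≡ 0 mod 3 and stop-free through the anchor),
   clone collapsing on (V, J, CDR3-nt), and clone-level statistics:
   in-frame fraction, in-frame:unproductive ratio, CDR3 length and
   positive-charge (R/K/H) class distributions.

A thin command-line wrapper (`inst/cli/bcp-pipeline`, subcommands
`simulate-bm`, `simulate-rep`, `gate`, `build-ref`, `compare`,
`repertoire`, `report`) drives the same functions from a shell.

## Worked example

```r
library(bcpflow)
# simulate five healthy controls and build the reference
controls <- lapply(1:5, function(i)
  gate_sample(simulate_bm_sample(donor_profile("healthy"), 30000,
                                 donor_id = sprintf("hc%d", i), seed = 40 + i)))
model <- build_reference(controls, k = 2)

# a BTK-deficient patient against the reference
patient <- gate_sample(simulate_bm_sample(donor_profile("btk_deficient"),
                                          30000, donor_id = "pt1", seed = 46))
report <- deviation_report(patient, model)

# repertoire of sorted pre-BII-/- cells
rep <- simulate_compartment_repertoire("preBII_nn", n_clones = 2000, seed = 47)
stats <- repertoire_stats(list(preBII_nn = analyze_repertoire(rep)$clones))

writeLines(render_report(report, stats))
```

```
== BCP compartment deviation report ==
stage         percent    ref_min    ref_max  in_range
pro-B            9.70       5.80       6.08        NO
pre-BI          80.92      23.52      24.01        NO
pre-BII          8.81      40.48      41.31        NO
immature         0.58      29.04      29.70        NO
BCP outside both pre-BI and pre-BII 2SD contours: 4.58%
blockade call: partial_block_preBII
== IGH repertoire statistics (clone level) ==
compartment    clones  inframe% ratio(if:un)  CDR3aa    charge>=3
preBII_nn        2000     79.60      3.90:1    14.8         0.45
```

Reading it: the patient's composition sits far outside every healthy
reference range — pre-BI piles up at 81% while only 8.8% of BCP reach
pre-BII and almost none become immature, the partial-block signature of
defective pre-BCR signalling. The repertoire table shows the pre-BII−/−
compartment at ~80% in-frame clones (ratio ≈ 4:1) with a mean productive
CDR3 of ~15 amino acids.

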