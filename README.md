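# ConcernFusion

Triage of short free-text messages — typically patient portal messages — by
identifying the **single primary-concern class** of each message. The default
schema has four classes: Active symptom concerns (**A**), Logistical concerns
(**L**), Prescription concerns (**P**) and Other concerns / general updates
(**U**).

The package is for informatics teams building message-triage classifiers who
want to combine several pretrained sentence encoders (a generic, a
domain-specific and a source-specific language model, say) instead of betting
on one, and for anyone who needs a reproducible, offline-testable harness for
that kind of multi-encoder pipeline.

## The method

No single encoder is best for clinical portal language, but different
encoder families fail on *different* messages. ConcernFusion exploits that
with **disagreement routing**:

1. **Baselines.** One classifier per encoder: frozen sentence embedding
   `e_k ∈ R^d` plus a softmax head, fine-tuned with a class-rebalancing
   strategy (inverse-frequency class weights `w_c = N/(K·n_c)`, random
   oversampling to the majority count, or focal loss
   `−α(1−p)^γ log p`).
2. **Routing.** Messages on which all baselines predict the same label keep
   that consensus label. Only the messages the baselines *disagree* on are
   routed further.
3. **Fusion head.** The per-encoder embeddings of a disagreement message are
   stacked into a `K × d` grid and mapped to class probabilities by one of
   three trainable heads, fitted on disagreement examples only:
   - *average*: column mean of the stack → dense + softmax;
   - *attention*: additive attention `softmax_k(vᵀ tanh(W e_k))` weights the
     rows before the dense layer;
   - *cnn*: a 2-D CNN (valid convolution, ReLU, global max pooling per
     filter size, dropout, dense + softmax) over the stack.
4. **Final prediction.** Consensus labels and fusion predictions are
   recombined; every message's label has exactly one provenance
   (`consensus` xor `fusion`).

Majority-vote ensembles (ties broken by the schema's alphabetical order
A < L < P < U) are included as the classical comparison, and a repeated
stratified k-fold harness (default 10 folds × 3 repeats) reports accuracy
and macro precision/recall/F1 with mean, SD and 95% CI over all runs, plus
a *disagreement-bucket* analysis (messages grouped by whether the 3
baselines produced 0, 2 or 3 distinct labels).

Because real clinical corpora cannot be redistributed, the package ships a
deterministic mock encoder (token-hash embeddings) and a synthetic
corpus/embedding generator whose encoders have complementary class-specific
signal, so the whole pipeline is testable offline.

## Worked example

```r
library(ConcernFusion)

cfg  <- syntheticConfig(n = 2000, seed = 11)   # 44.3/13.4/14.1/28.2% class mix
cp   <- generateCorpus(cfg)
classDistribution(cp)
#>   label count percent
#> 1     A   911    45.6
#> 2     L   278    13.9
#> 3     P   282    14.1
#> 4     U   529    26.5

bench <- syntheticFusionBenchmark(seeds = 11, n = 2000)
bench[, c("bestBaselineMacroF1", "fusionMacroF1", "gainBucket2", "gainBucket3")]
#>   bestBaselineMacroF1 fusionMacroF1 gainBucket2 gainBucket3
#> 1           0.7867148     0.8675162  0.03367003   0.1805556
```

The benchmark fine-tunes three baseline heads on complementary synthetic
encoders, routes the held-out messages by agreement, trains a 2-D CNN
fusion head on the training-side disagreements, and compares macro-F1. Here
the routed fusion model beats the best single baseline by ~0.08 macro-F1,
and its accuracy gain is concentrated on the disagreement buckets (bucket 0
— unanimous messages — is 0 by construction, since the routed model returns
the consensus there): +3.4 points on 2-distinct-label messages and +18
points on 3-distinct-label messages.

A full cross-validated experiment over any corpus:

```r
plan <- makeFoldPlan(cp, nFolds = 10, nRepeats = 3, seed = 1)
res  <- runExperiment(cp, generateEmbeddings(cfg, cp),
                      fusionConfig("cnn", commonDim = cfg$dim),
                      rebalance = rebalanceSpec("class_weight"),
                      plan = plan, seed = 1)
res$aggregates$routed_fusion$macroF1   # mean / sd / 95% CI over 30 runs
```

A thin command-line wrapper (`inst/scripts/concernfusion`) exposes the
stages as subcommands (`simulate`, `encode`, `train-baselines`, `fuse`,
`ensemble`, `evaluate`, `report`) over the same functions.

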