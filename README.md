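# srnec

Alignment-free prediction of Enzyme Commission (EC) classes and
subclasses from protein sequence recurrence networks.

## What it does, and for whom

Annotating an enzyme's EC number by sequence alignment fails in both
directions: sequences above 90% identity can catalyze different
reactions, and enzymes sharing a class can sit below 30% identity. And
since the 2018 addition of translocases (EC 7), class inventories built
before it are incomplete. `srnec` is for computational biologists who
need an alignment-free screen for the first two EC digits
(class.subclass), or who want to retrain such a screen on their own
annotated collections.

The method:

1. **Sequence recurrence network (SRN).** Each residue position is a
   node; edges join chain neighbours (i, i+1) and each position to the
   nearest earlier occurrence of the same residue type (recurrence
   edges), plus a dummy node attached to position 1. The adjacency
   matrix α is binary and symmetric.
2. **Markov descriptors.** Row-normalizing α gives the transition matrix
   Π with p_ab = α_ab / Σ_b α_ab. The descriptors are traces of its
   powers, Tr_k = tr(Π^k) — the closed-walk probability mass at order k,
   a direct readout of residue-recurrence density — and Markov–Shannon
   entropies θ_k = −Σ_a π_k(a) ln π_k(a) of the occupancy π_k = π_0 Π^k
   from a uniform start.
3. **Multi-task featurization.** One two-class model covers all
   subclasses by scoring (sequence, candidate class) pairs with the
   class means ⟨Tr3⟩, ⟨Tr5⟩ and the deviations DTr_k = Tr_k − ⟨Tr_k⟩.
4. **Classifiers.** The published linear discriminant

   EC = −0.95·⟨Tr3⟩ − 0.80·⟨Tr5⟩ − 0.80·DTr5 + 1.01·DTr3 − 2.05,

   thresholded at 0, ships as the packaged default; a Fisher-rule linear
   discriminant and a 4-h-2 perceptron can be refitted on your own pair
   records. Evaluation reports per-class rates, accuracy, the Matthews
   correlation coefficient, and the single-discriminant identities
   (Wilks' Λ, canonical R).

A seeded synthetic-data generator with class-structured residue
composition makes every stage testable without downloading anything.

## Worked example

```r
library(srnec)

d <- synth_generate(synth_spec(n_classes = 3, sequences_per_class = 10,
                               n_nonenzymes = 10,
                               length_range = c(120L, 180L), seed = 7))
head(descriptor_table(d$sequences[1:3, ]), 3)
#>   sequence_id      Tr3      Tr5   Theta3   Theta5
#> 1 enz_1.1_001 5.142361 5.879670 5.071831 5.070480
#> 2 enz_1.1_002 4.270833 5.055700 5.107083 5.105909
#> 3 enz_1.1_003 3.538194 4.194597 5.098885 5.097725

res <- run_pipeline(d$sequences, d$annotations, seed = 7)
res$report
#>   tp fp tn fn rate_class_pos rate_class_neg accuracy       mcc
#> 1 23  0 10  7       76.66667            100     82.5 0.6715507
```

The descriptor rows are one sequence each: `Tr3`/`Tr5` are the
closed-walk traces (larger for repeat-dense compositions), `Theta3`/
`Theta5` the walk entropies in nats (near ln n when occupancy stays
spread out). The report counts (sequence, candidate class) pairs:
here all 10 non-enzymes are rejected (`rate_class_neg` 100%), 23 of 30
enzymes are accepted against their own subclass, and the pair-level
agreement is accuracy 82.5%, MCC 0.67 — a deliberately small, moderately
separated example; the strongly separated test conditions reach 97–99%.

```r
wilks_from_eigenvalue(1.241879)
#> $wilks
#> [1] 0.4460544
#> $canonical_r
#> [1] 0.7442752
```

A command-line dispatcher over the same functions lives at
`inst/cli/srnec.R` with subcommands `synth`, `descriptors`, `profiles`,
`pairs`, `fit`, `predict`, `evaluate` (TSV in/out, metadata JSON per
run, exit codes 0/2/3).

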