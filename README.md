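# synendure

Quantitative analysis of synaptic vesicle recycling and presynaptic ATP
dynamics under metabolic stress, for experiments that probe how nerve
terminals — dopaminergic ones in particular — draw on glycogen reserves when
external glucose is withdrawn.

It is written for imaging labs that record:

* **synaptophysin-pHluorin traces** during repeated action-potential (AP)
  trains, to measure vesicle exo/endocytosis;
* **ratiometric ATP-biosensor pairs** (an intensiometric ATP sensor plus an
  expression reference) during prolonged stimulation;
* **multi-channel immunofluorescence images** of tyrosine hydroxylase (TH),
  glycogen and glycogen synthase (GS) staining.

## The statistics at the core

For each stimulus round of a pHluorin trace, the **endocytic block**
statistic is the percentage of the exocytic signal remaining three reference
decay constants after the peak,

    EB = 100 x (F(t_peak + 3*tau_ref) - F_pre) / (F_peak - F_pre) %

where `tau_ref` is the single-exponential re-acidification constant fitted
in 5 mM glucose. Perfect retrieval gives `EB = 100*exp(-3) ≈ 5%`; complete
endocytic arrest gives 100%. **Synaptic endurance** is the number of rounds
(50 APs at 10 Hz, one per minute, glucose-free) before EB first exceeds 50%,
right-censored at 30 rounds. ATP traces are decomposed into
baseline / drop / recovery percentages of the pre-stimulation baseline, and
immunofluorescence intensities are culture-normalized before computing the
glycogen–GS regression, per-coverslip TH+/TH− ratios, and treatment percent
reductions. Group comparisons use the Wilcoxon–Mann–Whitney test, exact by
full enumeration (ties included) for small groups.

A seeded mechanistic simulator (nerve-terminal ATP/glycogen model coupled to
vesicle recycling) generates pHluorin traces, two-channel ATP traces and
triple-labelled images with known ground truth, so the entire pipeline is
testable without experimental data. See the methods vignette
(`vignettes/synaptic-endurance.Rmd`) for the model and every analysis
convention.

## Worked example

Simulate two arms of an endurance experiment — untreated dopaminergic
neurons vs. acute glycogen-phosphorylase inhibition, both in glucose-free
saline — analyze both, and compare:

```r
library(synendure)

cfg <- list(
  analysis = "endurance",
  arms = list(control = "da_0gluc", gp_inhibitor = "da_gpi"),
  n_per_arm = 8, max_rounds = 30
)
rep <- run_pipeline(cfg, seed = 42)
for (a in rep$arms)
  cat(sprintf("%-14s n=%d  rounds to block: %s  censored: %s\n",
              a$arm, a$n, a$label, a$n_censored))
rep$comparisons
```

```
control        n=8  rounds to block: 21.9 ± 2.61  censored: 2
gp_inhibitor   n=8  rounds to block: 1 ± 0  censored: 0
# A tibble: 1 × 9
  group1  group2          n1    n2     u  p_value method alternative stars
  <chr>   <chr>        <int> <int> <dbl>    <dbl> <chr>  <chr>       <chr>
1 control gp_inhibitor     8     8    64 0.000155 exact  two.sided   ***
```

Control terminals keep recycling vesicles for ~22 rounds on their glycogen
reserve (2 of 8 never arrest within the 30-round horizon and are censored
there), while blocking glycogenolysis collapses recycling after a single
round; the exact rank test puts three stars on the difference.

The same analyses run on real data from the shared CSV/TIFF interfaces:

```r
stack  <- read_image_stack_tiff("phluorin_stack.tif")
rois   <- read_roi_csv("boutons.csv")
proto  <- read_protocol_yaml("protocol.yaml")
traces <- extract_roi_traces(stack, rois, frame_interval = proto$frame_interval) |>
  select_responding_rois(proto)
res <- analyze_endurance(traces, proto)
glance(res)   # group summary:  n, mean ± SEM rounds, censored count
tidy(res)     # per-round EB table
autoplot(res) # EB vs round with the 50% threshold
```

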