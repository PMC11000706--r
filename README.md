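# seizunit

Detection of epileptic seizures from single-channel EEG with repeating
**Conv1D → bidirectional LSTM/GRU → average-pooling** feature-extraction
units feeding dense softmax classifiers.

Scalp and intracranial EEG separates healthy background activity,
interictal epileptiform discharges and ictal (seizure) rhythms, and the
Bonn University corpus is the standard benchmark: five sets of 100
single-channel records (A/B healthy eyes open/closed, C/D interictal from
the contralateral hippocampus / epileptogenic zone, E ictal), each 4,097
samples at 173.61 Hz, stored as plain-text integer files. `seizunit`
implements, as a tested R package:

* **Bonn-layout I/O** — one-sample-per-line text records, configurable
  set-to-folder mapping, and the five published classification tasks
  (A–E, B–E, AB–CD–E, AB–C–D–E, A–B–C–D–E) with their set-to-class maps;
* **a seeded surrogate-EEG generator** with class-distinct spectral and
  amplitude structure (1/f background, alpha peaks, interictal spikes,
  high-amplitude 3–12 Hz ictal bursts), so the entire pipeline runs and is
  tested without any clinical download;
* **preprocessing** — zero-phase order-2 Butterworth band-pass (0.5–50 Hz,
  forward–backward application) and non-overlapping segmentation into
  full-length, 2,048-sample (11.8 s) or 178-sample (1 s) windows across
  six input regimes ("studies" 1–6: odd raw, even filtered);
* **a declarative registry of all 30 published network configurations**
  (unit widths, kernel sizes, dense stacks, dropout rates, epoch counts),
  each instantiable with Bi-LSTM or Bi-GRU cells — 60 combinations — plus
  the ablation transforms that strip every conv or every recurrent stage;
* **a built-in training engine** (RcppArmadillo): Conv1D, bidirectional
  LSTM/GRU, average pooling, dropout, dense layers; categorical
  cross-entropy with Adam; backpropagation through time verified against
  finite differences in the test suite;
* **stratified five-fold cross-validation** with the four published
  metrics computed from per-fold confusion matrices — accuracy,
  specificity, sensitivity (seizure recall in the binary tasks, macro
  one-vs-rest averages for 3–5 classes) and F1 — fold-averaged into a
  `metrics_report`.

For two classes, with the seizure class positive:
Acc = (TP+TN)/(TP+TN+FP+FN), Sens = TP/(TP+FN), Spec = TN/(TN+FP),
F1 = 2TP/(2TP+FP+FN).

## Worked example

Train and evaluate the published filtered 1 s binary configuration
(Study 6, task A–E) with GRU cells on surrogate data — 100 records, band-pass
filtered, cut into 178-sample segments, five-fold cross-validated:

```r
library(seizunit)
report <- run_study(study = 6, task = "A-E", rnn_type = "BiGRU",
                    data_source = list(n_per_class = 50L),
                    seed = 2L, epochs = 10L)
print(report)
#> <metrics_report> BiGRU study 6 task A-E
#>  fold accuracy specificity sensitivity    f1
#>     1    98.04       98.70       97.39 98.03
#>     2    97.61       98.70       96.52 97.58
#>     3    99.35       99.57       99.13 99.35
#>     4    98.91       99.57       98.26 98.91
#>     5    99.35       99.57       99.13 99.35
#> fold means: accuracy 98.65%  specificity 99.22%  sensitivity 98.09%  F1 98.64%
```

Each row is one held-out fold of 1 s segments (percent); the final line is
the fold average that the published tables report. `run_study()` composes
`generate_dataset()` (or `load_set()` on a Bonn-layout directory),
`make_task()`, `build_study_dataset()`, `get_config()` and
`crossvalidate()`; each piece is exported and usable on its own, e.g.

```r
cfg <- get_config(1, "A-E", "BiLSTM")   # published Study-1 architecture
model <- build_model(cfg$model, input_length = 4097)
print(model)                            # layer stack with shapes
rep2 <- run_ablation(6, "A-E", drop = "rnn",
                     data_source = list(n_per_class = 50L), seed = 2L,
                     epochs = 10L)      # conv-only ablation, retrained
```

With a downloaded Bonn corpus (folders Z/O/N/F/S),
`run_study(1, "A-E", "BiLSTM", data_source = "path/to/bonn")` runs the
published protocol on the real data at the published epoch counts.

A command-line wrapper ships in `inst/cli/seizunit.R`:

```sh
Rscript inst/cli/seizunit.R simulate --n-per-class 100 --seed 7 --out data/
Rscript inst/cli/seizunit.R preprocess --study 3 --task AB-CD-E --in data/ --out ds.rds
Rscript inst/cli/seizunit.R show-config --study 1 --task A-E --rnn lstm
Rscript inst/cli/seizunit.R reproduce-study --study 6 --task A-E --rnn gru \
    --data synthetic --seed 2 --out run1
```

Every artifact-producing command writes a JSON run manifest (command line,
resolved configuration, seeds, package version, checksums).

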