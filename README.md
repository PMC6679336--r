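# flockdrift

Real-time classification of sheep behaviour — walking, standing, lying —
from ear-mounted tri-axial accelerometer and gyroscope streams, built to
survive **concept drift**: the degradation a classifier suffers when the
animals, terrain or season at deployment differ from the training trial.

The architecture combines three pieces:

1. **Offline nearest-prototype classifier** (`fit_prototypes()`,
   `knn_predict()`): an emulation of an on-chip pattern matching engine —
   a store of up to 128 byte-quantised labelled 20-feature vectors,
   queried by 1-nearest-neighbour (L1 on bytes by default). Frozen at
   deployment.
2. **Online k-means** (`init_centroids()`, `km_step()`, `run_stream()`):
   three 1-D centroids over the windowed, discretised mean acceleration
   magnitude (MeanAMag, in 0.1 g bins, 0–20), streamed predict-then-update
   with an exact running-mean update of the winning centre. Its clusters
   are read as high / medium / low activity and adapt to the deployed
   distribution.
3. **Decision-rule fusion** (`default_rules()`, `learn_rules()`,
   `apply_rules()`, `run_combined()`): a total mapping from the 9 cells of
   (offline label × activity level) to the final behaviour; the key rule
   promotes *standing-at-high-activity* to walking, which rescues drifted
   walking that the frozen classifier no longer recognises.

Feature extraction (7 s windows at 16 Hz every 10 s; mean, SD, IQR,
kurtosis, min over four magnitude/difference variables), one-vs-rest
performance metrics with macro "Overall" rows, a seeded synthetic
IMU/behaviour generator with injectable drift, and a CLI are included.
The methods vignette (`vignettes/flockdrift-methods.Rmd`) documents every
model convention and the generator's stated world.

## Worked example

The published fusion table, and the table arithmetic behind the headline
figures:

```r
library(flockdrift)
default_rules()
#> decision-rule table (literal), fallback = knn
#>  knn_label  level   output
#>    walking   high  walking
#>   standing   high  walking
#>      lying   high    <knn>
#>    walking medium  walking
#>   standing medium standing
#>      lying medium    lying
#>    walking    low  walking
#>   standing    low standing
#>      lying    low    lying

round(macro_average(reference_metrics("combined")), 2)
#>    accuracy specificity      recall   precision      fscore
#>       85.18       82.84       57.82       69.90       60.40
round(compare_methods(reference_metrics("combined"),
                      reference_metrics("online"))$grand_mean, 2)
#> [1] 10.88
```

The macro row is the unweighted mean of the shipped per-class reference
cells; 85.18 is the combined algorithm's overall accuracy and 10.88 the
average improvement over the online-only classifier across the five
metrics.

The end-to-end drift benchmark — train on a 2 h synthetic stream in the
high-activity regime, deploy on a 3 h drifted stream (lower MeanAMag
targets, halved gyro activity, slowed gait):

```r
ex <- drift_experiment(seed = 1)
round(ex$accuracy, 2)
#> knn_train_regime      knn_drifted   kmeans_drifted combined_drifted
#>            80.19            75.74            63.58            77.10
```

Read: the frozen prototype classifier loses 4.5 points of overall
accuracy under drift; the adaptive-k-means-only classifier is far weaker;
the fused classifier beats both single channels on the drifted stream.

## Command line

```sh
Rscript -e 'flockdrift::fd_cli()' simulate --out data --duration 1800 --seed 7
Rscript -e 'flockdrift::fd_cli()' extract-features --imu data/imu.csv --out data/features.csv
Rscript -e 'flockdrift::fd_cli()' train --features data/features.csv \
    --observations data/observations.csv \
    --model-out data/model.json --rules-out data/rules.csv --seed 7
Rscript -e 'flockdrift::fd_cli()' run --imu data/imu.csv --model data/model.json \
    --rules data/rules.csv --out-dir data/run --truth data/observations.csv \
    --priors 16.66,3.28,0.81
```

`run` writes the per-window records (timestamp, offline label, activity
level, MeanAMag, fused label), the centre trajectory, and a metrics
report with per-class rows plus the Overall row. A wrapper script is
installed under `inst/cli/flockdrift`.

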