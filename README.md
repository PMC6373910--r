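# deltam

Detection-free quantification of receptor endocytosis in time-course
fluorescence microscopy images.

## The problem

When an agonist activates a G-protein coupled receptor such as the mu
opioid (MOP) receptor, the receptor-bearing membrane internalizes into
endosomes — small, roughly Gaussian bright spots that accumulate in
the cytoplasm over minutes.  Counting those spots frame by frame is
fragile: it depends on detection thresholds, and on noisy images the
spots cannot be segmented reliably at all.  `deltam` implements a
quantifier of the response that never detects individual objects.

Each frame *I<sub>t</sub>* (one per minute, frame 0 before the drug)
is convolved with a compensated Laplacian-of-Gaussian (LoG) kernel

&psi;(x, y) = 1/(2&pi;R&#8308;) · (2 − (x²+y²)/R²) · exp(−(x²+y²)/2R²),

which annihilates constants and gradients and amplifies centrally
symmetric spots.  The scale *R* is chosen once, on the pre-drug frame,
by maximizing the spot amplification
&lambda; = (A′/s′)/(A/s), where A′/A = 2&gamma;²/(&gamma;²+R²)² is the
analytic peak gain for a Gaussian spot of size &gamma; (&approx; 2 px
for endosomes) and s, s′ are the background standard deviations before
and after filtering.  Over an automatically segmented region of
interest *B<sub>t</sub>* (Gaussian blur + minimum-algorithm histogram
threshold, with a whole-image fallback), the response is the relative
increment of the third central moment of the filtered frame:

&Delta;m<sub>t</sub> = (m<sub>t</sub> − m<sub>0</sub>) / m<sub>0</sub>,
&nbsp;&nbsp; m<sub>t</sub> = (1/n<sub>pix</sub>) &Sigma;<sub>x &isin; B<sub>t</sub></sub> (I′<sub>t</sub>(x) − mean)³.

Bright spots skew the filtered-intensity histogram to the right, so
&Delta;m grows with both the number and the brightness of endosomes —
a single dimensionless number per frame, comparable across
experiments.  Drug kinetics are then summarized by fitting
&mu;<sub>t</sub> = &mu;&#8320; + E<sub>max</sub> / (1 + exp[&alpha;(t&#8321;&#8322; − t)])
(efficacy E<sub>max</sub>, slope &alpha;, half-time t&#8321;&#8322;),
with an r² > 0.5 quality-control rule on either the sigmoid or a
linear null fit.

The package also contains the validation machinery: a synthetic
microscopy background generator, endosome field simulation with
constant-total-fluorescence normalization, the (n endosomes per cell)
× (amplitude k·s) discrimination study, and a reproducible end-to-end
pipeline over TIFF stacks.

## Worked example

Simulate a DAMGO-like experiment (15 frames, sigmoid schedule with
E<sub>max</sub> = 16.1, t&#8321;&#8322; = 10.4 min, &alpha; = 0.53/min),
write it as a 16-bit TIFF stack and run the full pipeline:

```r
library(deltam)
tc <- simulateTimecourse(seed = 42)
writeStack(tc$frames, "damgo_sim.tif")
rec <- runPipeline(list(experiment_id = "damgo_sim", drug = "DAMGO",
                        condition = "-DOX", frames = "damgo_sim.tif"),
                   "damgo_out", seed = 1)
rec
#> ExperimentRecord 'damgo_sim' (DAMGO, -DOX): sigmoid
#>   r2_lin = 0.846, r2_sig = 0.975
```

The pipeline segments every frame, harmonizes the regions of
interest, scans the LoG scale on frame 0, and writes the response
series, fitted parameters, masks, scale-scan table and a JSON run log
under `damgo_out/`:

```r
head(read.csv("damgo_out/damgo_sim_deltam.csv"), 4)
#>   experiment_id t_min        m     delta_m n_pix
#> 1     damgo_sim     0 2458.922 0.000000000 31261
#> 2     damgo_sim     1 2475.605 0.006784628 31261
#> 3     damgo_sim     2 2859.170 0.162773987 31250
#> 4     damgo_sim     3 3558.310 0.447101897 31314

read.csv("damgo_out/damgo_sim_parameters.csv")[, c("E_max", "t_half", "alpha", "r2_sig", "responder_class")]
#>      E_max   t_half     alpha    r2_sig responder_class
#> 1 18.70904 11.14345 0.4816222 0.9753535         sigmoid
```

The frame-0 baseline gives &Delta;m = 0 by construction; the series
rises along the scheduled sigmoid and the fit recovers the generating
kinetics (E<sub>max</sub> 18.7 vs 16.1 truth here — single-experiment
efficacy estimates are wide, see the methods vignette) and classifies
the experiment as a sigmoid responder.  A flat (morphine-like)
schedule leaves &Delta;m at 0 and the experiment is not called a
responder.

A thin command-line wrapper with the same verbs lives at
`inst/scripts/deltam.R`:

```sh
Rscript inst/scripts/deltam.R run      --manifest experiments.yml --out results/
Rscript inst/scripts/deltam.R simulate --out results/ --backgrounds 17
Rscript inst/scripts/deltam.R scan     --image frame0.tif --out scan.csv
Rscript inst/scripts/deltam.R fit      --deltam series.csv --out params.csv
```

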