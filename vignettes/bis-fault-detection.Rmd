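---
title: "Hybrid local-model BIS prediction and residual fault detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid local-model BIS prediction and residual fault detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisguard)
```

This vignette documents the modeling and detection methodology implemented by
`bisguard`: the assumptions behind each stage, the tunable parameters with
their defaults and units, the numerical choices, what the surgery simulator
does and does not emulate, and the known limitations.

## Problem setting and assumptions

During maintenance-phase general anesthesia the Bispectral Index (BIS, a
dimensionless 0–100 EEG-derived depth-of-hypnosis index) is regulated around
40–60 by the propofol infusion rate. The measured BIS is corrupted
episodically: electrode faults, motion, and above all electromyographic (EMG)
bursts from inadequate neuromuscular blockade, which raise the displayed BIS
without any change in hypnotic state. The package's premise is analytical
redundancy: if BIS can be predicted from the propofol dose and the EMG
signal, a measured value far from the prediction carries no clinical
information and should be excluded from dosing decisions.

Assumptions inherited by everything downstream:

* signals are uniformly sampled (the simulator's convention is 5 s; the
  CSV dialect carries explicit timestamps and the sampling interval is
  inferred and checked on read);
* the model is valid only in the maintenance phase — induction and recovery
  transients are outside the training distribution and must be trimmed
  (`trim_phases()`) before fitting;
* remifentanil (which also modulates BIS) is assumed constant and is not an
  input;
* the propofol rate unit is not interpreted, only required to be consistent
  between training and detection data.

## The regression form

Each sample is lag-embedded into eight inputs and one output:

\[
x(t) = [\mathrm{EMG}(t), \mathrm{EMG}(t{-}1), \mathrm{EMG}(t{-}2),
        u(t), u(t{-}1), u(t{-}2),
        \mathrm{BIS}(t{-}1), \mathrm{BIS}(t{-}2)], \qquad y(t) = \mathrm{BIS}(t),
\]

with \(u\) the propofol infusion rate. Two lags of every signal capture the
relevant short-range dynamics of the anesthetic process at this sampling
rate; longer regression vectors add parameters without measurable accuracy
gain on the data regimes the simulator produces. The embedding never mixes
samples across records, and each row is content-addressable back to its
source record and time index (`build_regression_dataset()`).

## Standardization

Features are z-scored before clustering and regression (default on). The BIS
lags live on a 0–100 scale while EMG and infusion-rate features are an order
of magnitude smaller; a raw Euclidean K-means would cluster on BIS lags
alone. The training-set means and standard deviations are stored in the
fitted model and re-applied verbatim at prediction time; constant columns
receive sd = 1 to keep the transform invertible. A switch
(`standardize = FALSE`) disables this to operate on raw units.

## Clustering

`kmeans_fit()` minimizes the squared-error objective
\(e = \sum_{k=1}^{C}\sum_{x \in Q_k} \lVert x - c_k \rVert^2\)
with Lloyd iterations from Forgy initializations (random distinct points),
20 restarts by default, keeping the run with minimal \(e\). Details fixed for
reproducibility:

* ties in nearest-centroid assignment break to the lowest index, both during
  training and at inference-time routing (`assign_cluster()`), so a serialized
  model routes identically everywhere;
* a cluster that empties mid-iteration is re-seeded at the point farthest
  from its assigned centroid;
* convergence is assignment stability (discrete, hence tolerance-free) or
  300 iterations;
* each converged run is finished with a Hartigan-style single-point
  improvement pass: Lloyd fixed points are not always local minima of \(e\),
  and moving one point \(x\) from cluster \(i\) to \(j\) changes the
  objective by \(\frac{n_j}{n_j+1}\lVert x - c_j\rVert^2 -
  \frac{n_i}{n_i-1}\lVert x - c_i\rVert^2\); strictly improving moves are
  applied until none remains, then the partition is settled back to a Lloyd
  fixed point. On small instances this closes most of the gap between
  restarted Lloyd and the exhaustive optimum (the test suite checks
  agreement with brute-force enumeration on instances with up to 10 points).

Cluster-count selection is *not* done by internal validity indices; every
K from 2 to 10 (plus the global single-model topology) competes on the
downstream cross-validated prediction error. A partition in which any
cluster holds fewer than `min_cluster_size = 15` samples is marked N/A and
excluded: 15 samples cannot support 5-fold per-cluster cross-validation with
any stability.

## Local regressor families

**MLP.** One tan-sigmoid hidden layer, linear output:
\(f_\theta(x) = \beta + \sum_{i=1}^{k} a_i \tanh(w_i^\top x + b_i)\),
hidden sizes 1–10. Training minimizes squared error by Levenberg–Marquardt:
each step solves \((J^\top J + \mu I)\,\delta = J^\top r\); \(\mu\) starts at
\(10^{-2}\), is divided by 10 on an accepted step (error decreased) and
multiplied by 10 on a rejected one (capped at \(10^{12}\), at which point the
fit stops at the current local minimum). The accepted-step MSE sequence is
non-increasing by construction and is stored in the model (`mse_trace`).
Weights initialize uniformly in \([-0.5, 0.5]\), input weights scaled by
\(1/\sqrt{d}\) (fan-in), the output offset at \(\bar y\); all seeded. The
default iteration budget inside the trainer grid is `mlp_max_iter = 40`,
enough for these small nets to converge on cluster-sized data while keeping
the full candidate grid affordable; direct calls default to 100.

**LS-SVR.** Least-squares support vector regression with the RBF kernel
\(K(x,x') = \exp(-\lVert x-x'\rVert^2/\sigma^2)\) — note the convention:
\(\sigma^2\) in the denominator, no factor 2, matching the classical LS-SVM
toolbox; conventions differ across libraries by that factor. The dual
solution comes from one \((n{+}1)\times(n{+}1)\) linear KKT system

\[
\begin{pmatrix} 0 & 1_n^\top \\ 1_n & K + \gamma^{-1} I \end{pmatrix}
\begin{pmatrix} b_0 \\ b \end{pmatrix} =
\begin{pmatrix} 0 \\ y \end{pmatrix},
\]

from which two identities follow and are tested: \(\sum_i b_i = 0\), and the
fitted value at training point \(i\) equals \(y_i - b_i/\gamma\).
Hyperparameters \((\gamma, \sigma)\) are tuned by Nelder–Mead simplex over
\((\log_{10}\gamma, \log_{10}\sigma^2) \in [-6,6]\times[-4,4]\), minimizing
the *exact* leave-one-out MSE computed in closed form from a single
factorization per candidate: the LOO residual at point \(i\) is
\(b_i / (A^{-1})_{i+1,i+1}\) with \(A\) the KKT matrix. The closed form is
verified against explicit \(n\)-fold re-solves in the test suite. The search
starts at \(\gamma = 1, \sigma = 1\) (so the tuned objective never exceeds
the start) with a 60-evaluation budget; when a fold-train set exceeds 150
rows, tuning runs on a seeded 150-row subsample and the final KKT solve uses
the full set — a cost cap that keeps the \(O(n^3)\) LOO inside the grid
affordable without touching the final model's fidelity.

**Polynomial.** Degrees 1 and 2 over the full monomial basis — for \(d\)
inputs, \(1+d\) or \(1+d+d(d{+}1)/2\) coefficients (45 at \(d=8\), degree 2),
in the fixed term order constant, linear, then \(x_i x_j\) for \(i \le j\).
Solved through the SVD, giving the minimal-norm solution under rank
deficiency. A candidate whose coefficient count exceeds the fold-train size
is infeasible on that data and drops out of the comparison (relevant for
degree 2 on minimum-size clusters).

## Selection and aggregation

Within each cluster, every candidate (polynomial degrees {1,2}, MLP hidden
{1..10}, tuned LS-SVR — 13 in the default grid) is scored by 5-fold
cross-validation: a seeded shuffle into near-equal folds, training on four
folds (stochastic trainers get fold-derived seeds), pooling all \(n\)
held-out squared errors. Pooling is identical to size-weighting per-fold
MSEs. Ties prefer the simpler candidate (polynomial before MLP before
LS-SVR, smaller hyperparameter first). Fold assignment is within-cluster:
each cluster is cross-validated independently, which is the only scheme
under which per-cluster MSEs are comparable across K.

Topologies are compared by the sample-weighted MSE
\(\sum_k n_k \mathrm{MSE}_k / \sum_k n_k\); without the weights a tiny
well-fit cluster would mask errors on the dominant regime. The minimal
weighted MSE wins; differences below \(10^{-12}\) BIS² are numerical dust
(they arise on noiseless synthetic fixtures where several K fit exactly) and
are treated as ties, resolved toward fewer clusters — a parsimony rule that
makes selection deterministic and scale-appropriate. K-means runs once per K
on the full training corpus, before the fold loops: clustering is part of
model structure, not of the per-candidate fit. After selection, each winning
candidate is retrained on all of its cluster's data.

## Fault detection

For each sample \(t \ge 3\) the detector builds the 8-input vector, predicts
BIS, and computes the residual (measured − predicted). A sample is
out-of-range when the absolute residual exceeds `range_limit` — an absolute
band in BIS units, because the index is dimensionless on a fixed 0–100
scale; 10 is the default operating point, 15 a more permissive one. With
`consecutive_m > 1`, only runs of at least \(m\) consecutive out-of-range
samples raise a fault, and all samples of a qualifying run are flagged so
episode extents match the visible excursion; \(m = 2\)–3 suppresses
single-sample noise excursions at some onset latency cost. The first two
samples of a record are lag warm-up and reported unscored (`NA`), not as
clean. Two invariants follow from the construction and are tested: the fault
set at a larger range is a subset of that at a smaller range, and the fault
set at larger \(m\) is a subset of that at smaller \(m\).

**Lag policy.** Past measured BIS values are model inputs, so a faulty
reading would contaminate the predictor during the very episode to be
detected, and the predictor would "follow" a sustained offset after one
step. Two policies are provided: `MEASURED` always feeds measured lags (the
literal one-step-ahead reading), and `FREEZE` (default) substitutes the
model's own prediction into the lag buffer whenever the current residual is
out of range, reverting to measured values as soon as it returns within
range. `FREEZE` keeps a sustained offset visible for its whole duration.

**Preprocessing bandwidth.** `detect_faults()` applies the model's stored
low-pass preconditioning to the incoming record so residuals compare like
with like. This has an operating consequence: a one-step residual detector
cannot see any excursion slower than its preprocessing bandwidth. At the
prediction-oriented default (0.02 Hz at 5 s sampling) a step fault is smeared
into a ramp whose per-sample increment stays inside the lag-fed prediction,
and sensitivity collapses to zero. Models intended for fault detection should
therefore be trained with the filter off (`lowpass_cutoff_hz = 0`) or at a
cutoff well above the fault timescale of interest; the package's own
detection examples and acceptance checks do exactly this. The threshold is
constant per run; scheduled or adaptive thresholds are future work.

## The surgery simulator

Clinical BIS logs are not distributed, so `simulate_surgery()` generates
maintenance-phase records with the structural features the pipeline needs:

* **PK/PD**: one-compartment plasma kinetics with a first-order effect site —
  \(\dot C_p = -k_{10} C_p + u/(60 V_d)\), \(\dot C_e = k_{e0}(C_p - C_e)\) —
  and a sigmoid Emax (Hill) effect
  \(E_0 - E_{max}\, C_e^{\gamma_h}/(C_{e50}^{\gamma_h} + C_e^{\gamma_h})\).
  Defaults \(k_{10} = 0.12\)/min, \(k_{e0} = 0.456\)/min, \(V_d = 0.25\)
  L/kg, \(E_0 = 93\), \(E_{max} = 87\), \(C_{e50} = 4.5\) µg/mL,
  \(\gamma_h = 2.5\) are conventional propofol pharmacodynamic magnitudes
  chosen so a typical 8 mg/kg/h maintenance rate settles in the 40–60
  general-anesthesia band. They are simulator conventions, not estimates.
  Integration is fixed-step RK4 at the sampling interval (the system is
  mildly stiff at worst; rates are of order 0.1–0.5/min). States initialize
  at the steady state of the first scheduled rate — the record is a
  maintenance log, not an induction transient.
* **EMG**: a quiet baseline (level 2) plus Poisson-arriving bursts
  (1.5 events/h) with a smooth \( (t/\tau)e^{1-t/\tau} \) envelope
  (\(\tau = 30\) s, truncated below 1% of peak), amplitudes around 15. At
  these defaults a few percent of samples sit in the burst regime and the
  rest in the quiet regime — the strongly imbalanced two-regime structure
  that motivates local models. EMG above baseline couples *additively and
  rectified* into the true BIS (`k_emg = 0.8` BIS per EMG unit), encoding
  that EMG disturbances raise the displayed index.
* **Faults**: `inject_faults()` overlays constant offsets, isolated spikes,
  or frozen dropouts on the measured signal only, with an exact ground-truth
  mask; the fault-free `bis_true` channel is preserved for oracle testing.

What the simulator does **not** emulate: multi-compartment redistribution,
interpatient variability, remifentanil/rocuronium pharmacology, raw-EEG
artifacts, or the monitor's own signal-quality preprocessing. Tests passing
on simulated data therefore demonstrate the pipeline's mechanics — regime
separation, candidate selection, weighted aggregation, residual detection —
not clinical-grade predictive accuracy.

## Reproducibility and problem sizes

Every stochastic step (K-means restarts, MLP initialization, fold shuffles,
tuning subsamples, the simulator) derives its stream from one configuration
seed, and the whole simulate → train → detect pipeline is byte-reproducible
under a fixed seed (asserted in the test suite). Models serialize to
versioned JSON at 17 significant digits, so a reloaded model predicts
identically to the original.

The test and acceptance fixtures use desk-scale sizes chosen to exercise the
full default grid while keeping a complete run in the low minutes: planted
two-regime recovery at 500 + 500 samples with the full K = 1..10 × 13
candidate grid; detection studies on 50-minute simulated surgeries
(~600 samples) with measurement noise sd 2; K-means oracle equivalence on
50 instances of up to 10 points against exhaustive enumeration.

## Known limitations

* The detector flags deviations; it cannot distinguish a sensor fault from a
  genuine unusual patient reaction — both present as sustained residuals,
  and the clinician makes that call.
* A record whose rate units differ from the training data's cannot be
  detected as mismatched (units are uninterpreted by design).
* The one-step form with measured lags limits detectable faults to those
  faster than the preprocessing bandwidth (see above); slow sensor drift
  within the band is invisible by construction.
* `MEASURED` lag policy detects only the onset of sustained offsets; use
  `FREEZE` (default) for full-episode flagging.
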