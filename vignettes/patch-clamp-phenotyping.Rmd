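---
title: "Patch-clamp phenotyping of developing neurons with clampkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-clamp phenotyping of developing neurons with clampkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(clampkit)
library(dplyr)
```

## The problem

Whole-cell patch-clamp phenotyping of cultured human neurons asks a
stereotyped set of questions of every cell: how many action potentials does
it fire to a family of current steps, what does its rheobase spike look
like (threshold, amplitude, width, fast afterhyperpolarization), how large
are its sodium and potassium currents under voltage clamp, how big is the
cell (capacitance), and how much spontaneous excitatory synaptic traffic
does it receive. Disease-vs-isogenic-control studies then compare these
per-cell measures between genotypes at several maturation time points.

clampkit implements that pipeline end to end, and pairs it with a
conductance-based synthetic recording generator so that every analysis
stage can be validated against ground truth without access to patient
recordings. The generator's default cohort emulates a developmental
phenotype reported for mutant dentate-gyrus granule neurons: early
hyperexcitability with a deepened fast AHP and narrowed spike, converting
to hypoexcitability with collapsed synaptic and network-burst activity at
the most mature time point.

## The model

Cells are single-compartment conductance models:

$$C_m \frac{dV}{dt} = -g_{Na} m^3 h (V - E_{Na}) - g_{Kd} n^4 (V - E_K)
  - g_A a b (V - E_K) - g_M p (V - E_K) - g_L (V - E_L) + I_{inj}(t) + \xi(t)$$

with Traub–Miles-style Na and delayed-rectifier kinetics shifted by a
single parameter `v_t` (default −50 mV) so that the measured spike
threshold falls near −30 to −23 mV, as typical for immature human neurons.
Two further potassium conductances carry the phenotype axes:

* **A-type (`g_a`)** — fast activation (Boltzmann steady state, τ = 1 ms)
  with slower inactivation (τ = 20 ms). It repolarizes the spike early, so
  increasing `g_a` deepens the fast AHP and narrows the spike width: the
  axis along which a KCNA5-like fast potassium channel acts.
* **M-type (`g_m`)** — slow (τ up to 300 ms), activating near spike
  voltages (`p_vhalf` = −20 mV). Without it the minimal Na/Kd/A model is
  bimodal: a cell either fires once and enters depolarization block or
  fires tonically at 30+ Hz for the whole step. Real immature neurons fire
  a handful of adapting spikes per step; the M conductance is the standard
  minimal ingredient that produces graded, sparse evoked counts. This is a
  deliberate extension of the minimal channel set, chosen during design
  because no setting of the four-conductance model reproduces sparse
  adapting discharge.

Integration is fixed-step RK4 at dt = 0.025 ms (stable for these kinetics
well past the 10 kHz output rate), recorded every fourth step. Noise is
additive Gaussian current, drawn per integration step; no seal or access
drift is modelled. Each sweep starts from the settled resting state (200 ms
at the holding current, noise off).

Under voltage clamp the command potential is imposed instantaneously, so
each gating variable relaxes exponentially toward its steady state at the
commanded voltage — the closed-form solution of the gating ODEs — and the
recorded current is the ionic sum plus a capacitive transient at every
command jump with total charge exactly $C_m\,\Delta V$ and decay constant
$R_s C_m$. The transient samples are bin-averaged, so the discrete integral
of the sampled transient carries the full charge at any sampling rate.

Spontaneous synaptic recordings are a baseline plus Gaussian noise plus a
sum of inward biexponential kernels
$A\,(e^{-t/\tau_d} - e^{-t/\tau_r})$, peak-normalized so the trace minimum
of an isolated event equals $-A$. Event times come from a doubly
stochastic process: a homogeneous background at `rate_hz` plus burst
epochs (Poisson at `burst_rate_hz`, gamma-distributed durations, shape 4)
carrying dense within-burst traffic at `burst_event_rate_hz`. Amplitudes
are log-normal. The ground-truth event and epoch tables are returned with
the trace.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `c_m` | pF | 30 | cell size; sets charging τ with `g_l` |
| `g_na`, `g_kd` | nS | 80, 20 | spike generation and repolarization |
| `g_a` | nS | 5 | fast AHP depth and spike width |
| `g_m` | nS | 2 | spike-frequency adaptation (sparse counts) |
| `v_t` | mV | −50 | places spike threshold near −30..−23 mV |
| `noise_sd` | pA | 2 (cohorts) | recording-noise scale |
| `dvdt_thresh` | mV/ms | 10 | spike onset criterion |
| `k_sd` | — | 3 | EPSC detection threshold in noise SDs |
| `max_isi_s`, `min_events` | s, — | 0.1, 3 | network-burst definition |

Acquisition defaults: current steps −10..+60 pA in 5 pA increments, 400 ms
steps at 10 kHz; voltage steps −90..+40 mV in 10 mV increments from −70 mV
holding; gap-free synaptic recordings 120 s at 5 kHz (5 kHz still
oversamples the 2 ms rise time fivefold and halves the per-cell analysis
cost). All are package choices, exposed through `protocol_spec()`.

## Feature extraction: definitions and numerical choices

**Spikes.** A spike is an upward crossing of dV/dt ≥ 10 mV/ms whose
voltage reaches −10 mV within 5 ms; peaks closer than 2 ms merge.
Threshold is the voltage at the last dV/dt crossing before the peak;
amplitude is peak minus threshold (the convention that matches reported
spike heights of ~25–45 mV); FWHM is the time above threshold + half
amplitude, with linear interpolation at the half crossings; the fast AHP
is the most negative voltage after the spike falls back below threshold,
within a 20 ms window truncated at the next spike's threshold crossing,
reported as trough − threshold (negative). Evoked counts are restricted
to the stimulus window; rheobase is the smallest step amplitude with at
least one spike, ties broken by sweep order.

**Voltage clamp.** Capacitance is the charge of the above-leak transient
of a subthreshold step divided by the step size; the integral runs from
onset to the 5% decay point and the truncated exponential tail is added
back analytically from the fitted decay ratio (without the tail term the
5% cutoff systematically loses 5% of the charge). Leak is fitted as
$I = g(V - E)$ on the steady currents of steps at or below −60 mV and
subtracted everywhere. Transients are blanked for 1.5 ms — five decay
constants at the default $R_s C_m$ = 0.3 ms; a 0.5 ms blank would leave
19% of the transient inside the Na measurement window. Then, per command
voltage: Na peak = minimum in 0.5–10 ms post-onset, fast K peak = maximum
in 2–25 ms, slow K = mean over the last 50 ms of the step. The component
windows are heuristics (time-based, not pharmacological separation) and
are configurable.

**EPSCs.** Baseline is a 1 s sliding median; noise a sliding MAD (both
computed on a 500 Hz decimated grid and interpolated — a 1 s window does
not need 5 kHz resolution). Candidates are local minima of a 0.6 ms
moving-average residual below −3 SD; local minima rather than threshold
runs, so overlapping within-burst events stay separable. A rebound rule
removes shoulder duplicates: a candidate near an already-kept deeper peak
is a distinct event only if the residual rose back above half the kept
peak's depth between them. A candidate is accepted if its 10–90% rise
time falls in 0.5–5 ms, the log-linear decay constant in 3–50 ms, decay
slower than rise, and the decay segment is actually exponential
(fit R² ≥ 0.75) — the R² gate is what rejects noise excursions that
happen to be 3 SD deep. At the reference operating point (30 pA mean
amplitude, 2 pA noise) recall and precision are both above 0.95 and the
mean amplitude error is ~5%.

**Bursts.** A network burst is a maximal run of ≥ 3 events with all
inter-event intervals ≤ 100 ms (configurable); duration is first-to-last
event time, the burst rate is bursts per recording, and interburst
intervals are end-to-start gaps. Bursts are detected on single-cell
synaptic traffic — the network is observed through one patched cell.

**Statistics.** Group comparisons use the pooled-variance two-tailed
Student t-test (Welch by option). The pooled test, not Welch, reproduces
printed summary-statistic results: rebuilding
(14.6 ± 2, n = 7) vs (4.7 ± 0.8, n = 7) gives t = 4.60, df = 12,
p = 6.1e−4, and (35 ± 5, n = 37) vs (12 ± 3, n = 14) gives p = 0.0084
(0.01 to two decimals). `compare_from_summary()` documents that a
reconstructed p can differ from a printed one when the per-measure n
differs from the cohort n. Star codes use strict inequalities
(p = 0.05 is "ns"). No multiple-testing correction is applied by default,
matching per-measure reporting conventions; `p.adjust` can be applied to
the trajectory grid's p column. Distribution shifts are compared with the
two-sample KS statistic plus the sign of the median difference.

## The default cohort: what it emulates and what it does not

`cohort_spec()` draws per-cell parameters around per-condition means
(log-normal with CV 0.2 for conductances, normal with CV 0.1 for
capacitance); a master seed determines everything, with per-cell child
seeds derived by a fixed counter scheme. The condition means were
calibrated by forward simulation so that the extracted features reproduce
the developmental contrast pattern: mutant total and maximum evoked
spikes above control at week 5 and below at week 11; deeper mutant fAHP
and narrower FWHM at weeks 5 and 7 (carried by larger `g_a`, `g_kd`,
`g_na`); capacitance matched between genotypes and growing with
maturation (25 → 28 → 52 pF); and a week-11 synaptic collapse in the
mutant (total event rate ~0.14× control, burst-epoch rate 0.125×,
interburst spacing 8×).

```{r cohort-preview}
gt <- draw_cohort(cohort_spec(n_per_condition = 20, seed = 1))
gt |>
  group_by(genotype, week) |>
  summarise(g_na = mean(g_na), g_a = mean(g_a), c_m = mean(c_m),
            syn_rate = mean(total_syn_rate_hz), .groups = "drop")
```

What passing tests on this generator do **not** show about real data: the
model has no slow AHP, no sag/rebound, no seal or access-resistance
drift, no electrode artifacts, and its noise is white — real recordings
have colored noise and line interference. Maximum per-step spike counts
run higher than typically reported for these cultures because the model
adapts only through the M conductance and sodium inactivation. The
synaptic generator produces bursts statistically, not from a recurrent
network, so burst shapes are simpler than biological network events.
Detector operating points quoted here are therefore operating points
under the generator's assumptions, not guarantees for arbitrary
recordings.

## A worked run

```{r worked, eval = FALSE}
res <- run_pipeline(list(
  simulate = list(n_per_condition = 20, seed = 1),
  output = list(dir = "out")
))
autoplot(res$trajectory)
```

The grid lists, per measure and week, both group means with SEM and n,
the t statistic, p, star code, percent change and the sign of
mutant − control. Sizes used throughout this vignette and the shipped
checks (20 cells per condition, 120 s gap-free recordings, 400 ms steps)
are the package's reference problem sizes; all scale up through the
config.

## Known limitations

* Single compartment only; no morphology, no stochastic channel gating.
* Fast/slow potassium separation is by time window, not pharmacology; the
  windows are honest about being conventions.
* Series resistance shapes only the capacitive transient; ionic currents
  are computed at the commanded potential (no voltage-clamp error).
* The EPSC detector's kinetic gates assume roughly biexponential events;
  heavily filtered or compound events would need retuned bounds.
* `compare_from_summary()` inherits the usual caveat of summary-statistic
  inference: it cannot know the per-measure n of a published figure.
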