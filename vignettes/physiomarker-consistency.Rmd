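---
title: "Assessing the between-visit consistency of subthalamic LFP physiomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the between-visit consistency of subthalamic LFP physiomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stnlfp)
```

## The scientific problem

Adaptive deep brain stimulation (aDBS) for Parkinson's disease needs a
*physiomarker*: a feature of the subthalamic local field potential (LFP)
that tracks the patient's clinical state and stays interpretable over the
weeks to months between programming visits. The leading candidates live in
the power spectrum of the bipolar STN-LFP recorded by the stimulator
itself:

* **periodic features** — Gaussian-shaped beta-band peaks (13--35 Hz),
  summarized by their center frequency, width, and the band power in a
  narrow band around the peak;
* **aperiodic features** — the 1/f-like background, summarized by an
  *offset* (broadband level) and an *exponent* (magnitude of the log--log
  slope), whose value has been linked to the excitation/inhibition balance
  of the recorded nucleus.

A feature is only usable as a feedback signal if it is *consistent*: its
value, and its response to stimulation and to motor tasks, should be
reproducible when the same hemisphere is recorded again months later.
`stnlfp` implements the full analysis chain for that question — signal
cleaning, spectral decomposition, beta-peak tracking across visits,
stimulation-responsiveness scoring — together with the reliability
statistics (ICC, repeated-measures ANOVA, paired tests with effect sizes),
and a simulation layer that generates Percept-like cohorts with known
ground truth so every stage can be validated quantitatively.

## The spectral model

All spectra are one-sided Welch power spectral densities. In log10 space
the model for a PSD is

$$\log_{10} P(f) \;=\; \underbrace{b - \chi \,\log_{10} f}_{\text{aperiodic}}
\;+\; \sum_{i=1}^{\le 4} h_i
\exp\!\left\{-\frac{(f-c_i)^2}{2 s_i^2}\right\},$$

with offset $b$ (log10 µV²/Hz at 1 Hz), exponent $\chi \ge 0$, and up to
four Gaussian peaks of height $h_i$ (log10 power above the aperiodic
curve), center $c_i$, and width $s_i$ constrained to 1--6 Hz (bandwidth
$2s_i \in [2, 12]$ Hz). The fit range is fixed at 3--49 Hz for every
spectrum: wide enough to bracket the full beta band, narrow enough to
avoid the high-frequency cleaning region and the high-pass transition
band.

`parameterize_spectrum()` fits this model in three stages:

1. **Robust aperiodic fit** (`fit_aperiodic()`): ordinary least squares of
   log-power on log-frequency, then a refit restricted to bins whose
   positive residual lies below the 2.5th percentile of the flattened
   spectrum — this anchors the line to the spectral floor between peaks.
2. **Iterative peak extraction** (`extract_peaks()`): repeatedly take the
   maximum of the flattened spectrum while it exceeds 2.0 standard
   deviations of the flattened spectrum; each candidate is refined by a
   bounded single-Gaussian least-squares fit before subtraction (a raw
   half-height width guess is noisy and leaves side lobes that would be
   picked up as spurious peaks). After at most four extractions the
   Gaussians are refit jointly by bounded least squares
   (`stats::optim`, L-BFGS-B). Two peaks whose centers sit within one
   standard deviation (of the wider) of each other are merged by keeping
   the taller — a single broad bump must not be fitted as a stack of
   narrow ones. Peaks whose center lies within one `sd` of a fit-range
   edge are dropped.
3. **Final aperiodic refit** on the peak-subtracted spectrum, and
   goodness-of-fit ($r^2$, RMSE in log10 power) over the fit range.

Equal flattened maxima are resolved towards the lower frequency. The
model curve is exactly the aperiodic line plus the Gaussian sum
(`model_curve()`), which the tests assert to machine precision.

### Welch estimation

Ten-second segments at 250 Hz are analyzed with 1.5-s Hamming windows
(375 samples) at 50% overlap (step 187 samples, rounded down), giving the
0.67 Hz grid ($250/375$ Hz) on which all downstream band definitions
live. Densities are one-sided and Parseval-consistent.

## The cleaning chain

`clean_recording()` applies five steps in a fixed order, then selects
segments:

(a) zero-phase (bidirectional) 4th-order Butterworth high-pass at 3 Hz —
    note that bidirectional filtering squares the magnitude response, so
    a tone at the cutoff emerges at amplitude 1/2;
(b) a **spectral Hampel filter** over 30--125 Hz: the magnitude spectrum
    of the whole recording is compared bin-wise against its sliding
    11-bin median; bins deviating by more than `threshold` × 1.4826 × the
    sliding median absolute deviation are replaced by the local median
    (phases kept) and the signal inverse-transformed. Thresholds are
    per-recording values constrained to 2.6--3.5 (default 3.0);
(c) zero-phase second-order IIR notches (1 Hz bandwidth) at 50 Hz and any
    additional narrow-band artifact frequencies. A tone at *half the
    stimulation frequency* — stimulation-entrained finely-tuned gamma
    (FTG) — is auto-proposed into the notch list when the periodogram bin
    nearest that frequency exceeds 10× the local median; the proposal is
    evaluated on the high-passed series, before step (b) can swallow the
    tone. Whether a half-stimulation notch was applied is the operational
    definition of FTG presence (`detect_ftg()`);
(d) **ECG suppression by beat-locked SVD** (`suppress_ecg_svd()`): epochs
    from 250 ms before to 400 ms after each detected R-peak are stacked
    and decomposed; components whose temporal pattern correlates with the
    mean beat at $|r| \ge 0.8$ (at most 3) are treated as cardiac. Two
    refinements stabilize the subtraction: selected components are masked
    to the support of the mean-beat envelope (cardiac energy must
    outweigh oscillations outside the QRS region), and per-epoch
    coefficients are shrunk towards their across-beat mean with the noise
    level estimated from the non-cardiac components — stable coupling
    then subtracts a common template with no background leakage, while
    genuinely varying coupling is still tracked. Overlapping epochs are
    truncated at the midpoint between beats; fewer than 8 beats means no
    suppression (flagged in the log);
(e) a second spectral Hampel filter over 3.8--40 Hz (threshold range
    2.6--3.3) for artifacts that surface after ECG cleaning.

**Segment selection** tiles the cleaned recording into consecutive 10-s
windows and keeps, earliest first, up to two tiles in which every sample
lies within the recording mean ± 5 SD. Finding no valid tile is an
explicit error; at the cohort level `analyze_cohort(on_error = "skip")`
drops such cells and records them, and the statistics layer excludes
units with incomplete condition sets.

Two documented limitations of the chain: bins within one full Hampel
window of the spectrum edge are never flagged (they would be judged
against a shrunken window), and repeating the chain erodes the 3--4.5 Hz
high-pass transition band again, so the approximate idempotence of
cleaning holds for band powers above that transition band.

## Physiomarkers

**Beta peaks** are model peaks with center in [13, 35] Hz (inclusive).
**Consistency across visits** is defined on the stimulation-OFF rest
recordings: peaks from the two visits are matched one-to-one under a
maximum frequency difference of 2.5 Hz (0.67 Hz — one bin — as the strict
variant). The matching is computed as an exact optimal assignment:
maximize the number of matched peaks, then minimize the total frequency
difference, with exact ties resolved towards the taller visit-1 peak and
then the lower frequency. We chose exhaustive optimal assignment over a
greedy pass because peak lists are tiny (≤ 4 per visit), the optimum is
deterministic and verifiable against brute-force enumeration, and greedy
matching can mispair crowded configurations (measured on random sets: a
~1% disagreement rate with the optimal assignment). One consequence worth
knowing: a strict-tolerance match is almost always a subset of the loose
matching, but can be sacrificed when dropping it lets the loose matching
pair strictly more peaks — the property tests assert exactly this
characterization.

**Band power** is the trapezoidal integral of the *raw* PSD (aperiodic
component included) over a 4 Hz band: the peak center is snapped to the
nearest 0.67 Hz bin and three bins are taken on each side. The center
frequency is frozen per hemisphere *and visit* from that visit's OFF-rest
fit and reused for every condition of that hemisphere/visit; the
per-visit scoping matches how selected peak frequencies drift slightly
between visits in practice.

**Stimulation responsiveness** of a consistent peak is its
stimulation-induced power suppression expressed as a percentage of the
*natural fluctuation* NF — the absolute difference of OFF-rest band power
between the two visits:

$$\text{suppression} = 100 \cdot
\frac{(P^{\text{off}}_1 - P^{\text{on}}_1) +
      (P^{\text{off}}_2 - P^{\text{on}}_2)}{2\,\text{NF}}.$$

100% means the stimulation effect is as large as the natural
between-visit variability. NF = 0 is an explicit error (the peak is
unrankable) rather than an epsilon floor, so degenerate synthetic cases
stay visible. The most responsive consistent peak per hemisphere is the
argmax of this score; a single consistent peak is selected as-is.

## Reliability statistics

* **ICC** (`icc_absolute_single()`): two-way model, absolute agreement,
  single measurement,
  $\mathrm{ICC}(A,1) = (MS_R - MS_E) / (MS_R + (k-1)MS_E +
  \tfrac{k}{n}(MS_C - MS_E))$, with the standard F-based 95% CI using a
  Satterthwaite approximation for the denominator degrees of freedom
  (McGraw--Wong convention; the two-way mixed and random formulations
  share this point estimate under absolute agreement). Categories: poor
  (< 0.5), moderate (0.5--0.75), good (0.75--0.9), excellent (≥ 0.9).
  Simulated coverage of the CI at n = 24, true ICC 0.7, is checked to be
  95% ± 3%.
* **Repeated-measures ANOVA** (`rm_anova_ws()`): fully within-unit
  decomposition for the Visit (2) × Stimulation (2) × Task (3) design
  with the hemisphere as the unit of analysis (n = 24, treated as
  independent — a known simplification that ignores within-patient
  pairing and is kept deliberately to match the reference analysis).
  Each effect is tested against its own effect-by-unit interaction;
  Mauchly's test and the Greenhouse--Geisser epsilon are computed from
  orthonormalized within-unit contrasts, and the GG-corrected p is
  reported only when Mauchly's p < 0.05. Effect sizes are partial
  eta-squared and Cohen's $f = \sqrt{\eta_p^2 / (1-\eta_p^2)}$.
* **Paired tests**: t test with $d = \bar{d}/s_d = t/\sqrt{n}$;
  Wilcoxon signed-rank with zeros dropped, average ranks, tie-corrected
  normal deviate without continuity correction (the convention that
  reproduces printed SPSS-style Z values), and an exact p by full
  enumeration of sign assignments whenever at most 12 non-zero pairs
  remain (a documented cut-off; the reference software's regime is
  unstated). The default effect size is $Z/\sqrt{n}$ with $n$ the number
  of supplied pairs — the convention the reference values satisfy even
  though they are labelled rank-biserial — and the matched-pairs
  rank-biserial $(W^+ - W^-)/(W^+ + W^-)$ is available as an option.
* **Bonferroni**: $\min(1, p\,m)$.

`consistency_report()` assembles the battery per feature: a Shapiro--Wilk
gate on the two-way residuals (unit and cell means removed — the additive
unit effects would otherwise reappear identically in every cell and trip
the test) chooses between the ANOVA branch (aperiodic features) and the
per-condition Wilcoxon branch; the verdict "consistent" means no Visit
main effect or Visit-involving interaction (ANOVA) or no per-condition
visit difference (Wilcoxon) at $\alpha = 0.05$. ICC tables have 11 rows
per feature: the 6 task × stimulation conditions, task-induced deltas
(rest→finger-to-nose, rest→speech, stimulation OFF), and
stimulation-induced deltas (OFF−ON per task).

## The synthetic cohort

`generate_cohort()` emulates the reference study design: 12 subjects × 2
hemispheres × 2 visits × 2 stimulation states, with ~60 s rest, 30 s
finger-to-nose per hand (analyzed contralaterally), and 30 s speech at
250 Hz, plus a simultaneous ECG channel.

The generator works in the frequency domain: Gaussian white noise is
shaped so its expected one-sided PSD equals the target aperiodic curve
(`generate_aperiodic_background()`), and each oscillation multiplies the
FFT magnitudes by $10^{G(f)/2}$ so the log-PSD bump is exactly Gaussian
in expectation (`add_oscillation()`). Artifacts are then added
(`add_artifacts()`): a stylized biphasic QRS wavelet train (~80 ms,
fixed morphology, 2% RR jitter) coupled into the LFP and returned as a
clean ECG channel, a 50 Hz line-noise sinusoid, and optionally an FTG
tone at half the stimulation frequency in ON-state recordings of
FTG-positive hemispheres.

Defaults, chosen once as plausible for chronically implanted STN
recordings and *not* calibrated against any outcome:

| parameter | default | meaning |
|---|---|---|
| offset, exponent | N(1.0, 0.4), N(1.5, 0.3) | subject-level aperiodic baseline |
| beta peaks per hemisphere | 1--3 (p = .15/.45/.40), ≥ 4 Hz apart | centers 14--32 Hz, heights 0.35--0.8, sd 1--2.5 Hz |
| stim ON effects | offset +0.15, exponent +0.25, beta height −0.25 × peak responsiveness | responsiveness U(0.4, 1.6) per peak makes one peak "most responsive" |
| task effects (OFF) | beta height −0.18; speech offset +0.10 | ON-state task effect scaled ×0.3 (interaction); ON tasks add +0.08 offset / exponent |
| between-visit jitter | offset 0.10, exponent 0.10, height 0.08, center 0.8 Hz | 12% visit-wise dropout of non-primary peaks produces unmatched peaks |
| artifacts | ECG gain 1.0, line noise 0.15, FTG 0.4 (× signal SD); heart rate 70 bpm | FTG-positive hemispheres with probability 0.5 |

Effect *directions* mirror the reference findings (stimulation raises the
aperiodic parameters and suppresses beta power; movement and speech
suppress beta power with stimulation OFF; speech raises the offset, more
with stimulation ON); the magnitudes are free parameters of the
simulation, since per-condition ground-truth magnitudes are not published.
The ground-truth ledger stores every cell's generating spectrum, so
recovery is scored against construction, never re-derived from data.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: genuine LFP nonstationarity and bursting
beta dynamics, tremor-band activity, movement artifacts with realistic
spectro-temporal structure, physiological ECG morphology and heart-rate
variability beyond small RR jitter, device packet loss, or
stimulation-artifact aliasing. The validation shows the *pipeline*
recovers what it assumes; it cannot show those assumptions hold in
patients.

## Numerical choices and degenerate inputs

* Frequencies below 0.5 Hz are clamped in the synthesis target (the DC
  bin is zeroed); the high-pass removes this region anyway.
* The Hampel robust scale is floored at $10^{-9}$ × the local median so
  numerically constant neighbourhoods are not all flagged.
* Peak-fit bounds: center within ±2 bins (single-candidate refinement) or
  ±2 guess-sd (joint refit), height ≥ 0, sd within [1, 6] Hz.
* Zero-variance paired differences, all-zero Wilcoxon differences, zero
  total ICC variance, and NF = 0 responsiveness are errors, not silent
  NAs.
* All randomness funnels through per-recording seeds derived from the
  single cohort seed: identical configurations are bit-identical.

## Problem sizes used in the packaged checks

The packaged tests and the acceptance script validate at sizes chosen to
exercise every code path at full fidelity: spectral recovery on 100
simulated 20-s recordings (two 10-s segments each, the study's segment
layout); exact-Wilcoxon enumeration on 200 datasets of 5--10 pairs; ICC
coverage on 500 simulated 24 × 2 matrices; and end-to-end sign recovery
on 20 cohorts of 3 subjects with 30-s tasks. The full 12-subject default
cohort runs through `run_pipeline()` in well under a minute and is
exercised in the examples; the reduced cohort count in the repeated-run
check simply trades replicate count for per-replicate size at equal
statistical intent.

## Known limitations

* The hemisphere-as-unit assumption overstates the effective sample size,
  exactly as in the reference analysis; a nested random-effects model is
  out of scope by design.
* FTG presence is defined operationally by the notch rule; a hemisphere
  whose tone evades the 10× proposer threshold is counted FTG-negative.
* The ±5 SD segment criterion, computed on the cleaned recording, can
  reject every tile of a heavily contaminated short recording; the
  package surfaces this as an explicit error (or a recorded skip at
  cohort level) rather than loosening the criterion.
* The exact-assignment peak matching guarantees reproducibility and
  optimality but, like any one-to-one rule under a hard tolerance, is not
  monotone in the tolerance in pathological configurations (see above).
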