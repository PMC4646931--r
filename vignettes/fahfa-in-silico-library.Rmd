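---
title: "Rule-based in silico MS/MS libraries for FAHFA lipids: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based in silico MS/MS libraries for FAHFA lipids: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fahfalib)
```

## Why an in silico library

FAHFAs (fatty acid esters of hydroxy fatty acids) are observed in
negative-mode electrospray as [M−H]⁻ anions, but only a handful of
authentic standards are commercially available, so experimental spectral
libraries cover a tiny corner of the structure space. Because FAHFA
fragmentation is highly regular — the ester bond and the backbone
carboxyl dominate the chemistry — the spectra of the whole class can be
predicted from a template calibrated on the standards. `fahfalib`
implements that template approach end to end: enumeration, spectrum
generation, standard-format I/O, and dot-product annotation, plus a
seeded simulator so the pipeline can be validated without instrument
data.

## Mass arithmetic

All masses are monoisotopic (C 12, H 1.007825032, O 15.994914620 Da);
no isotope envelope is modelled, because isotope satellites in acquired
MS/MS spectra are an isolation-width artefact rather than a property of
the fragment ions. Deprotonation subtracts the proton mass
(1.007276467 Da), i.e. the electron stays on the anion. This choice is
deliberate: it gives 537.48883 for the 9-PAHSA precursor, matching the
printed three-decimal value 537.489, whereas dropping the electron would
give 537.48828 and round to 537.488. Fragment anions from a homolytic
view of the split likewise carry one extra electron each, which is why
the identity

fa_anion + hfa_anion − precursor = H₂O − H + e⁻

holds to 10⁻⁶ Da for every species (asserted as a property test).

Chain descriptors are validated with sanity rails (4 ≤ n ≤ 40,
d ≤ (n−2)/2) that rule out impossible lipids without constraining any
realistic panel.

## The structure space

The general library is every ordered (acyl, backbone) pair from a
33-entry fatty acid panel spanning 14:0–24:6 — 1089 structures. The
published panel itself is not printed anywhere, so the shipped default
(`default_fa_panel()`, also as `inst/extdata/fa_panel_33.tsv`) is a
reconstruction: the 33 fatty acids most commonly profiled in mammalian
lipidomics in that range, with trivial abbreviations (PA, OA, LA, …)
for the well-known ones. Every count-level result depends only on the
panel size; users with the authoritative list can substitute it via
`read_fa_panel()` without touching code.

The positional library needs saturated backbones (no reference spectra
exist for unsaturated hydroxy chains, so they are excluded rather than
guessed). The default length set {14, 15, 16, 17, 18, 20, 22, 24} is
likewise a reconstruction: it is the natural set of common saturated
chains for which the hydroxyl-position rule — every carbon except the
carboxyl C1 and the terminal carbon, i.e. p ∈ 2..(n−1) — yields
Σ(n−2) = 130 backbones and hence 130 × 33 = 4290 positional structures,
the published library size. Double-bond positions are never encoded:
profiling spectra cannot resolve them, so the structures are
deliberately "general, semi-characterized".

Enumeration order is deterministic (acyl-major, panel order, then
backbone length, then position) so that a rebuilt library is
byte-identical — important because the MSP file is the distributable
artefact.

## Spectrum generation

Each (collision energy, acquisition mode) cell of the intensity template
maps ion roles to relative intensities (base peak = 100). The defaults
are:

| CE (V) | precursor | fa anion | hfa anion | hfa −H₂O | tail | head |
|---|---|---|---|---|---|---|
| 10, profiling | 100 | 30 | 10 | 5 | — | — |
| 20, profiling | 40 | 100 | 30 | 15 | — | — |
| 40, profiling | 2 | 100 | 25 | 20 | — | — |
| 40, fragment-rich | 2 | 100 | 25 | 20 | 0.2 | 0.1 |

Only two quantitative facts about intensities are reported for this
lipid class: the precursor intensity falls monotonically with collision
energy, and the positional fragments appear at roughly 0.1–0.2 % of the
base peak in 1 spectrum/s acquisition. The template defaults encode
exactly those facts and are otherwise free choices; `validate_template()`
enforces the monotonicity and the sub-percent bound on positional roles,
and `read_intensity_template()` lets users calibrate every cell to their
own instrument from a YAML file. The tail ion takes 0.2 and the head ion
0.1 — where the sources disagree (0.2/0.2 vs 0.2/0.1) we take the
conservative merge that keeps the two ions distinguishable.

Positional fragment compositions are C₍n−p+1₎H₍2(n−p)+1₎O⁻ (tail, methyl
end) and C₍p−1₎H₍2p−3₎O⁻ (head, carboxyl end), with m/z = composition
mass + one electron. These compositions were chosen because they
reproduce three of the four printed anchor values (155.144 for n=18 p=9;
113.097/169.160 for n=18 p=12) to within 1 mDa and shift consistently by
CH₂ per position. The fourth printed anchor, 127.133 for the 9-position
head ion, is 21 mDa above the composition-consistent 127.113 while its
partner matches to 0.3 mDa; we treat it as a misprint or calibration
artefact and emit the composition-derived value. No other printed value
is "corrected".

Coincident peaks (e.g. the 18:2 fatty-acid anion and the dehydrated
hydroxy-18:2 ion, which are the same composition) are merged within
10⁻⁴ Da, summing intensities and keeping the m/z of the stronger member,
then the spectrum is rescaled to base peak 100. A profiling spectrum
therefore has 3–4 peaks. A fragment-rich spectrum has 4–6: besides the
single-coincidence case, an n:1 acyl on an O-n:0 backbone with the
hydroxyl at the chain midpoint p = (n+2)/2 merges twice (the tail and
head ions coincide there too), e.g. 18:1-(10-O-18:0).

## Matching

Candidates are retrieved by binary search within a precursor window
(default ±0.005 Da, the tolerance used for FAHFA annotation in
practice). Scoring is the conventional open reading of the NIST dot
product: peaks are aligned greedily by nearest m/z within ±0.01 Da
(one-to-one), weights are w = I^0.5 (the m/z exponent defaults to 0),
and the score is 999·(Σ w_q w_r)² / (Σ w_q² · Σ w_r²). The reverse
variant excludes unmatched query peaks from the query norm, so chimeric
or noisy queries are not penalised — reverse ≥ forward always. The
closed-source NIST implementation is not reproduced digit-for-digit;
what carries over is the threshold semantics (report ≥ 900, validate
≥ 950), and a brute-force optimal-assignment oracle bounds the greedy
alignment's deviation on small spectra in the test suite.

Three numerical decisions matter here:

* **Full-precision ranking.** Hydroxyl positions p and n+2−p produce
  *mirror* fragment pairs: identical m/z, swapped 0.2/0.1 intensities.
  Their integer scores both round to 999 against a clean query, so
  ranking on the rounded score would fall through to the name tie-break
  and pick isomers alphabetically. The ranker therefore sorts on the
  unrounded similarity (then forward dot, then |precursor error|, then
  name) and reports the rounded integers. Under the default noise model
  the tail/head intensity order still flips in ~1 % of simulations —
  an honest reflection of how thin the evidence for mirror
  discrimination is at 0.2 % relative abundance.
* **Mode-matched search.** The profiling and fragment-rich record sets
  are separate libraries, matching how they are used: a 40 V profiling
  record is exactly a fragment-rich record minus the two sub-percent
  positional peaks, so reverse-dot scoring of a rich query against the
  mixed set is ill-posed (the profiling twin of the true species ties
  or outranks it). Queries should be annotated against the library for
  their acquisition mode, as the examples and tests do.
* **Determinism.** All tie-breaks are total, so reports are reproducible
  byte for byte.

## The simulator

`simulate_query()` emulates acquired spectra: Gaussian m/z jitter
(default SD 0.002 Da — a typical QTOF calibration error, also applied to
the precursor), multiplicative log-normal intensity noise (CV 0.2),
five uniform background peaks capped at 2 % (acquired FAHFA spectra show
occasional stray background peaks at minor intensity), optional +1/+2 Da
isotope satellites (off by default, matching the library's no-isotope
model), and a flag that removes the positional pair to emulate
4 spectra/s profiling acquisition. All randomness is governed by an
explicit per-call seed; the caller's RNG state is saved and restored.

What the simulator does *not* emulate: chromatography (retention times,
co-elution), matrix effects, detector saturation, centroiding artefacts,
and realistic isotope patterns. Passing the simulation-based tests
therefore demonstrates the *internal* consistency of the
generate-and-match loop under calibrated noise — not performance on real
extracts, which additionally depends on those unmodelled effects. The
observation that profiling-rate queries cannot localise the hydroxyl
(all positional isomers tie exactly) is a structural property of the
model and carries over to real data.

With the default noise model, 200 seeded simulations of random library
records (each annotated against its own acquisition mode's library at
the ≥900 threshold) give ≥95 % rank-1 correct annotation; the losses are
dominated by precursor jitter beyond the 5 mDa window (~1 %) and mirror
flips of positional isomers (~1 %). The deterministic fixture set
(`reference_fixtures()`) covers the four commercial standards at every
CE/mode and the six species annotated in egg yolk, as rule-generated
stand-ins for the corresponding experimental spectra.

## Problem sizes and runtimes

The test suite builds the full 7557-record default library once (~3 s),
runs the 200-simulation robustness check (~7 s), and verifies MSP
byte-stability on the full library; the whole suite runs in under a
minute on one core. These sizes are the library's natural scale, not a
reduction.

## Known limitations

* The 33-FA panel and the positional length set are count-consistent
  reconstructions; substitute the authoritative lists via configuration
  if you have them.
* Template intensities beyond the two published constraints are
  defaults, not measurements — calibrate per instrument for best scores.
* Unsaturated hydroxy backbones, positive mode, adducts other than
  [M−H]⁻, isotope envelopes in library spectra, MS³ trees and
  retention-time modelling are out of scope (the elution-order
  observation 12- < 9- < 5-OAHSA is metadata commentary only).
* Absolute agreement with closed-source NIST scores is not claimed; use
  the thresholds, not the digits.
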