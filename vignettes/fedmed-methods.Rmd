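---
title: "Methods: federated analytics and learning over simulated hospital sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated analytics and learning over simulated hospital sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fedmed` simulates, inside one R process, a federated clinical research
network: several hospital *site nodes* that hold de-identified patient-level
data, and an *orchestration hub* that can only exchange whitelisted,
schema-validated, audited aggregate messages with them. This vignette is the
package's account of the statistical and computational methods, the
assumptions behind them, and the design decisions taken where more than one
reasonable choice existed.

## The trust model

The hub is assumed honest-but-curious at most: it coordinates computations but
must never be able to reconstruct a patient record. Three mechanisms enforce
this, and each is a package component rather than a convention:

1. **Interface separation.** Hub functions only accept aggregates —
   `(n, Σx, Σx²)` triples, study estimates, weight tensors, messages. No hub
   code path takes a `site_store`.
2. **Operation whitelist + schema validation.** Every message names an
   operation from `inst/schema/operations.json` and must carry that
   operation's required payload fields; anything else is rejected. Exactly one
   party of every exchange must be the hub, so site-to-site messages are
   rejected by construction. Every verdict — acceptance or rejection, with
   reason — is appended to an append-only audit log, and `replay_audit()`
   re-executes the hub-side aggregation purely from logged messages.
3. **Disclosure control.** No released statistic may cover fewer than `k`
   patients (default `k = 5`, shared with the masking threshold below; both
   are exposed separately in case a deployment wants them decoupled). A
   suppressed result is transmitted as `{"suppressed": true}` and nothing
   else — in particular not the true count. Empty cells (`n = 0`) are reported
   as such, since "nobody matched" reveals no individual.

What the simulator deliberately does not model: network transport (the message
bus is in-process but carries the same contract a socket transport would),
authentication/identity, differential privacy, and secure aggregation. A
motivated adversary observing many overlapping queries could still difference
small cells; `k`-suppression is a per-query control, not a formal privacy
guarantee.

## De-identification

**Pseudonymization.** Database keys are replaced by
`PBKDF2-HMAC-SHA512(password = key ∥ pepper, salt = site salt, 100000
iterations, 64-byte output)`, rendered as 128 hex characters. Peppers are
drawn one per row and the salt one per site, each 512 random bits from a
CSPRNG (`/dev/urandom`; a seeded double exists for tests and refuses to run
unless explicitly flagged insecure). Composition choices that were open:
the pepper is *appended* to the key to form the password, and the derived key
length is 64 bytes to match the secrets' width. Determinism within a site
preserves referential integrity (every `subject_ref` still resolves after
hashing); distinct salts make digest sets of different sites disjoint, which
blocks cross-site linkage by digest equality. The iteration count is
configuration (default 100 000): tests use reduced counts where the quantity
under test is pipeline behavior, and the full count where the digest value
itself is the quantity under test.

**Masking of rare characteristics.** Before release, any categorical patient
characteristic value held by fewer than `k = 5` distinct patients is replaced
by the reserved code `MASKED`, while any observation/condition/medication
*code* present for fewer than `k` distinct patients has its whole series
removed. The asymmetry is intentional: a rare demographic value can be blanked
without destroying the row, but a rare lab series is identifying through its
mere presence, so it is deleted. Values held by exactly `k` patients are
retained.

**DICOM scrubbing** is whitelist-based: every metadata element not explicitly
allowed is dropped; pixel data passes through byte-identically; the directly
identifying tags (PatientName, PatientID, PatientBirthDate) cannot be added
to a whitelist. The default whitelist is minimal — SOP/study/series UIDs,
modality, and the geometry/photometric tags needed to interpret the pixels.
The Part 10 codec shipped here (explicit VR little endian only) exists because
the scrubber needs tag-level access; it is not a general DICOM library.

## Federated analytics

A `resource_selector` fixes the data scope of a query: resource type, coding
(system, code) filter, closed value range, half-open `[start, end)` time
window, patient predicate, and a per-patient reduction policy. Half-open
windows mean adjacent breakdown bins can never double-count a record. The
reduction policy defaults to `latest` — one value per patient, in the spirit
of "baseline measurement per patient" modeling — with `earliest` available
and `all` reserved for raw selection.

`summarize` returns `n`, mean, *sample* SD (n−1 denominator), and a 95% CI
using the normal approximation `mean ± 1.96·sd/√n` (a Student-t interval is a
configuration switch; at the `n ≥ k` sizes the two differ little, and the
normal form matches what the hub can reconstruct exactly from pooled
moments). Categorical variables get level counts and the mode, ties broken
lexicographically and flagged. The median is computed and reported per site
only: there is no exact merge of medians from aggregates, so the hub never
pools it. `breakdown` partitions by a categorical variable or by contiguous
half-open time bins and applies the same suppression rule per bin at the
site; bin totals (including the hidden counts of suppressed bins, which stay
in a site-local attribute) partition the overall selection, a property the
test suite checks.

**Exact pooling.** Sites transmit `(n, Σx, Σx²)`. The hub computes
`N = Σnᵢ`, `mean = Σsumᵢ/N`, `sd = √((Σsumsqᵢ − (Σsumᵢ)²/N)/(N−1))`. This is
algebraically identical to computing on the pooled rows, so fed-vs-pooled
agreement is tested at 1e-9 *relative* tolerance, not approximately.
Transmitting `(mean, sd)` per site would suffice too; the moment form keeps
the exactness argument one line long. Both are aggregates and equally
non-disclosive for `n ≥ k`.

**Meta-analysis** is DerSimonian–Laird: `wᵢ = 1/vᵢ`,
`θ_FE = Σwᵢθᵢ/Σwᵢ`, `Q = Σwᵢ(θᵢ−θ_FE)²`, `C = Σwᵢ − Σwᵢ²/Σwᵢ`,
`τ² = max(0, (Q−(k−1))/C)`, RE weights `1/(vᵢ+τ²)`, CI
`pooled ± 1.96·√(1/Σwᵢ*)`. DL was chosen as the canonical non-iterative
inverse-variance random-effects estimator; REML would need an iterative fit
and is left to dedicated meta-analysis software (which the test suite uses as
an independent oracle). Mean estimates derive `v = sd²/n` from site
summaries; proportions use the raw-scale normal approximation `v = p(1−p)/n`
(with a 0.5/n floor near the boundary) rather than the logit scale — raw
pooled proportions are what the site dashboards report, and the logit
transform is a one-line change where preferred.

## Federated learning

The demonstration model is a multi-input network: image branch = two 3×3
convolution blocks (8 then 16 filters, ReLU, 2×2 max-pool) → flatten → dense
16; tabular branch = dense 16 → dense 8 (ReLU); concatenation → dense 8 →
single sigmoid. Either branch can be removed and the dense stacks emptied,
which degenerates to logistic regression — that configuration is used for the
parameter-recovery check. Initialization is Glorot-uniform from a seed; loss
is binary cross-entropy (probabilities clipped at 1e-12 for finiteness);
optimizers are Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) or plain gradient
descent. Max-pool ties take the first maximum in column-major order;
convolution is valid (no padding), stride 1, via compiled im2col + GEMM.

A federated round broadcasts the global weights; each site runs
`epochs_per_round` local passes (1 = FedSGD, >1 = FedAVG) and returns weights
plus its local sample count; the hub averages tensors weighted by `nᵢ`
(standard FedAVG; an unweighted mean is available for sensitivity checks).
Adam state is site-local and reset every round — moment estimates are not
averaged across sites, because averaged second moments are not the second
moments of the averaged model. With plain gradient descent, full batch and
one local epoch, one round is *algebraically identical* to one centralized
full-batch step (the pooled-loss gradient is the n-weighted mean of site
gradients), which the tests verify at 1e-6 on random partitions. A site whose
training split is empty abstains (reported, excluded from the average); an
erroring site aborts the round, favoring auditability over availability.
Tabular inputs are z-scored with mean/SD computed federatively from the
train-split sufficient statistics, so no site reveals row-level values for
standardization either.

Evaluation: AUC by the Mann–Whitney rank method with half credit for ties
(invariant under monotone transforms of the scores), F1 at the fixed
threshold 0.5, and full ROC / precision-recall point sets over unique
thresholds. Model selection, transfer learning and hyperparameter search are
out of scope by design.

## The synthetic cohort generator

The generator defines the study conditions for everything above. Per patient:
age ~ round(N(64 + site shift, 15)) clipped to [18, 100]; sex ~
Bernoulli(0.55) (male = 1); arterial pH ~ N(7.40 + site shift, 0.08) clipped
to [6.8, 7.8] (UCUM `[pH]`, LOINC 2744-1); a latent severity z ~ N(0, 1); and
a 64×64 grayscale image whose central Gaussian blob has peak intensity
`0.45 + 0.15·z` over a noisy background (pixel noise SD 0.03, jittered blob
center and width) — so the image carries the severity signal only through
intensity, which a small CNN can learn but a tabular model cannot see.
Mortality is Bernoulli(logit⁻¹(η)) with

η = β₀ + site shift + β_age·z_age + β_sex·male + β_pH·z_pH + β_img·z,

on population-standardized age and pH. Defaults: β₀ = −1.1 (≈ICU-like
marginal mortality near 30%), β_age = 1.0, β_sex = 0.5, β_pH = −1.2 (acidosis
increases risk), β_img = 1.0. These effect sizes were calibrated once so the
planted signal supports test-set discrimination around AUC 0.8 — the level
the end-to-end demonstration is designed to exhibit — while leaving each
single covariate only weakly predictive (univariate AUC just above 0.55–0.65,
a property the tests assert). Site heterogeneity defaults to modest shifts of
the intercept (±0.2), age mean (±3 y) and pH mean (±0.02), which the
analytics queries recover and the meta-analysis expresses as τ² > 0.

What the generator does *not* emulate: realistic chest radiographs, missing
data, longitudinal trajectories, measurement error correlated with outcome,
or informative site differences in coding practice. Green tests therefore
show that the machinery is correct under a known generative model, not that
the demo architecture would reach any particular accuracy on real hospital
data.

**Splits.** 40% train / 10% validation / 50% test, stratified by outcome via
per-stratum largest-remainder allocation steered to hit the global split
sizes exactly when they are integers (1000 patients → exactly 400/100/500);
split prevalence therefore matches overall prevalence to rounding.

## Problem sizes and defaults

The full demonstration scale is 4 sites × 1000 patients. The package's
default experiment (`experiment_config()`), the acceptance script and the
test suite run the desk-scale analogue — 4 × 250 with 64×64 images, FedAVG 4
local epochs × 10 rounds versus a pooled baseline given the identical total
epoch budget (40), both arms evaluated on the same pooled test split —
which keeps a complete run around a minute on one CPU. Parameter recovery
uses 4 × 1000 with the image branch disabled. The `training_config()`
default learning rate is the protocol value 1e-5, appropriate for
large-cohort runs; the desk-scale experiment sets 3e-3 (with Adam, batch 32),
chosen because 500 optimizer steps on 400 training samples sit two orders of
magnitude below the protocol's step budget and the larger rate lets both arms
converge within it. Disclosure-control fuzzing runs over 1000 random small
stores; the pooling-exactness property over 100 random cohorts partitioned
into 2–8 sites; the DL oracle over 100 random study sets.

## Known limitations

- `k`-suppression does not compose across overlapping queries (no query
  budget or differencing protection), and there is no differential privacy or
  secure aggregation.
- The FHIR model covers the six demo resource types and common fields only;
  the UCUM check is membership against a bundled common-unit list, not a
  grammar.
- The DICOM codec reads/writes explicit VR little endian single-frame 8-bit
  grayscale; other transfer syntaxes are out of scope.
- Pooled medians are not available by design; per-site medians are.
- FedAVG with Adam is a heuristic (state reset per round); exact
  federated-centralized equivalence holds only for the plain-GD/full-batch/
  one-epoch regime where it is provable.
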