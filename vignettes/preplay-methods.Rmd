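---
title: "Clustered spiking networks, place fields and preplay: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered spiking networks, place fields and preplay: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(preplaynet)
```

## The scientific question

Hippocampal place cells fire in spike sequences during rest that resemble
trajectories through environments the animal has never visited ("preplay").
This package implements a model of how such sequences can arise without any
environment-specific wiring: a recurrent network of spiking neurons whose
excitatory cells are assigned to randomly overlapping clusters. The same
network, driven by spatially uninformative noise during simulated sleep,
spontaneously produces population burst events whose decoded position
content is more sequence-like than time-bin-shuffled controls; driven by
two linear spatial cues during simulated track running, it produces place
fields. The pipeline around the simulator reproduces the complete analysis
chain: place-field statistics, burst-event detection, memoryless Bayesian
decoding, shuffle-based significance, cluster-activation dynamics,
cell-identity controls, small-world graph metrics and multi-environment
remapping.

## The neuron and network model

Neurons are conductance-based leaky integrate-and-fire units. The membrane
potential of each cell follows

$$C_m \frac{dV}{dt} = -g_L (V - E_L) - g_E (V - E_E) - g_I (V - E_I)
  - g_{SRA} (V - E_{SRA}) - g_{ext} (V - E_E),$$

with a spike and reset to $V_{reset}$ when $V$ crosses $V_{th}$. Each
conductance decays exponentially between spikes and steps up at each
presynaptic (or, for the spike-rate adaptation conductance $g_{SRA}$, each
of the cell's own) spikes. We integrate with forward Euler. The printed
form of the membrane equation with $\tau_m$ on the left is dimensionally
inconsistent for conductance-based synapses; we use the capacitance form
above with $C_m = \tau_m g_L$ (0.4 nF = 40 ms $\times$ 10 nS), which
reproduces the stated membrane time constant, and we take the external
input reversal equal to $E_E = 0$ mV as written in the driving-force term.

Key parameters (all configurable through `ppn_config()`, defaults in
parentheses): membrane time constant 40 ms, leak 10 nS to $-70$ mV,
threshold $-50$ mV, reset $-70$ mV, excitatory/inhibitory/adaptation decay
constants 10/3/30 ms, synaptic steps $W_{E\to E}$ = 220 pS,
$W_{E\to I} = W_{I\to E}$ = 400 pS, adaptation step 3 pS, integration step
0.1 ms.

The network has $n$ = 500 neurons, 75% excitatory. Excitatory cells are
assigned to $n_c$ = 15 clusters with mean participation $\mu_c$ = 1.25:
every cell first receives one cluster (round-robin over a shuffled order,
so the first pass is balanced), then each cluster is topped up with
randomly chosen additional cells until all clusters have the identical
size $\mathrm{round}(n_E \mu_c / n_c)$. E-to-E connections exist only
within clusters and are drawn cluster-wise: within each cluster every
ordered pair of members receives an independent Bernoulli trial, and the
adjacency is the union over clusters. The within-cluster probability is
$p_c C_{tot}/C_{clust}$ with $C_{clust}$ evaluated at the realized integer
cluster sizes, which keeps the expected global density at $p_c$ = 0.08
(evaluating it at the real-valued size $n_E \mu_c / n_c$, as the closed
form is usually quoted, leaves a systematic deficit of about 2% at the
fiducial point; the small residual from pairs sharing several clusters is
under half a percent). E-to-I and I-to-E connections are uniform with
probability 0.25; there are no I-to-I connections.

## Inputs and sessions

All excitatory cells receive three independent Poisson inputs: two
location cues whose rates vary linearly between 0 and 5000 Hz across the
1 m track (their sum is position-independent), and a context cue at the
peak rate that carries no spatial information. Inhibitory cells receive
only the context cue. Input strengths are drawn log-normally with mean 72
pS (SD 5 pS for location cues, 1.25 pS for context); because the printed
parameterization of the log-normal is garbled, we use the standard
moment-matched form $\mu = \ln(W^2/\sqrt{\sigma^2 + W^2})$,
$\sigma^2_{\ln} = \ln(1 + \sigma^2/W^2)$, validated against sample moments
in the test suite. Each environment randomly orders the clusters and
assigns evenly spaced rank biases from $-1$ to $+1$; a cell's bias (mean
over its clusters, scaled by 0.04) multiplies its left cue weight by
$1 + b$ and its right cue weight by $1 - b$. Context weights are redrawn
per environment and for sleep. During track running the context weight to
E cells is scaled by 0.1; during sleep the location cues are silent and
the I-cell context weight is scaled by 0.75.

A run session is five 2 s constant-speed traversals of one trajectory;
sleep is 120 s of cue-free activity. Feed-forward conductances start at
Gaussian draws around their stationary mean $W r_G \tau_E$ with the
shot-noise standard deviation $W\sqrt{r_G \tau_E / 2}$ (the printed SD
expression is unreadable; Campbell's theorem gives this form); recurrent
and adaptation conductances start at zero and voltages at $E_L$.

### The input grid

Poisson inputs are realized as Bernoulli events on a fixed 0.1 ms input
grid (probability rate $\times$ 0.1 ms per tick, at most one event per
tick per input). Two consequences are worth recording. First, at the peak
rate the tick probability is 0.5, so the realized input process has
somewhat less shot-noise variance than an ideal Poisson train; this
truncation is part of the model definition here — replacing it with exact
per-step Poisson counts doubles the input variance and moves the network
out of its intended sparse-sleep operating regime. Second, the input grid
is decoupled from the integration step: refining `cells.dt` refines the
integrator but replays statistically identical input processes, so
convergence checks measure integration error alone. Run-session mean
rates change by about 3% when the step is halved. Sleep-session rates are
deliberately not used as a convergence observable: sleep spiking is a
threshold-tail quantity (the subthreshold voltage sits roughly 3 SDs
below threshold), so the $O(dt)$ Euler bias of a few hundredths of a
millivolt changes sleep rates by tens of percent at any practical step
size. This is a property of near-threshold integrate-and-fire dynamics
under forward Euler, not of this implementation.

## Place-field analysis

Rate maps are trial-averaged, occupancy-discounted spike counts in fifty
2 cm bins, smoothed with a truncated-renormalized Gaussian kernel of 4 cm
SD (the truncation keeps rate mass on the track and preserves constant
maps exactly). Under the constant-speed protocol occupancy is uniform, so
the discounting is a constant. Cells with smoothed peaks above 3 Hz are
place cells; statistics are computed per trajectory. Specificity is one
minus the fraction of bins above a quarter of the peak. Spatial
information is $\sum_i p_i (r_i/\bar r)\log_2(r_i/\bar r)$ bits/spike,
with zero-rate bins contributing zero. The peak-location distribution is
summarized by its Kullback-Leibler divergence from uniform and by the
fraction of peaks in the central third of the track, taken as bins 17-33
(the middle 17 of 50; the split of the remaining 33 bins into 16 + 17 is
a convention the source does not pin down). Peak ties take the leftmost
bin. Spatial information is evaluated on the smoothed maps, i.e. on the
fields as plotted.

Map correlations between trajectories average per-bin Pearson
correlations of the population rate vectors, after normalizing each
cell's field by its peak. The normalization matters: per-cell
excitability is set by the fixed recurrent connectivity and therefore
persists across environments, so raw-rate maps of different environments
retain a correlation of roughly 0.4 even though the fields remap; on
peak-normalized fields the within-environment correlation is about 0.85
and the cross-environment correlations center on zero, which is the
remapping contrast this statistic is meant to capture.

Time fields use the same estimator over fifty 40 ms bins spanning the
first two seconds of each traversal, with occupancy tracking which bins
each (possibly faster) traversal covers. At the fiducial point place
information exceeds time information for about 90% of cells.

## Burst events, decoding and significance

The population rate is the mean excitatory firing rate on the simulation
grid, smoothed with a 15 ms SD Gaussian (truncated at 4 SD). Population
burst events are excursions above mean + 1 SD (statistics taken over the
whole session, events included) lasting at least 30 ms with a peak of at
least 0.5 Hz; events separated by less than 10 ms merge; events at least
50 ms long with at least 5 participating excitatory cells are decodable.
Event boundaries are the threshold crossings of the smoothed trace.

Decoding is memoryless Bayesian with a uniform position prior and
independent-Poisson place-field likelihoods over 10 ms bins tiled from
event start (a final partial bin is dropped). Decoder rates are floored
at 0.01 Hz so no position has zero likelihood; zero-spike bins are
retained, where the likelihood reduces to the no-spike exposure term. Per
event we compute the probability-weighted space-time Pearson correlation
(direction in its sign, quality in its magnitude), the maximum jump of
the posterior argmax between adjacent bins (ties to the lowest bin), and
the mean column entropy.

Significance rests on time-bin shuffles: 100 uniformly random column
permutations per event (permuting posterior columns is exactly equivalent
to permuting binned spike vectors for a memoryless decoder, and lets the
shuffle statistics be computed from per-column sufficient statistics).
The ensemble tests are (i) a two-sample KS test of actual versus pooled
shuffled absolute weighted correlations, with the median shift as effect
size; (ii) a threshold-grid bootstrap: for each (minimum $|r|$, maximum
jump) gate, the fraction of passing events is compared with 100 shuffled
data sets formed by drawing one shuffle per event, the p-value being the
fraction of data sets whose passing fraction is at least the actual one —
ties count, so the all-pass corner is never significant (a strict reading
of "higher" would make that corner maximally significant, contradicting
what the statistic is for); (iii) per-event p-values as the fraction of
the event's own shuffles with larger $|r|$.

## Cluster dynamics and identity controls

Per-cluster rate curves (15 ms SD smoothing, the same kernel as event
detection, on a 1 ms grid) define a cluster as active if its rate ever
exceeds twice every other cluster's; activation order is the order of
first becoming the most-active cluster and durations are most-active
occupancy. Sequences of three active clusters are compared against
sampling three distinct clusters without replacement (monotone-in-bias
probability 1/3). Preplay quality versus the number of active clusters
z-scores each event's $|r|$ against the pooled shuffles of events with
the same count before rank-correlating.

Cell-identity controls relabel excitatory spikes before decoding.
Across-network: a uniform permutation. Within-cluster: a long random walk
of transpositions accepted only while both cells keep an identity sharing
at least one cluster with them — unconstrained transposition chains would
let labels migrate across the connected membership graph and degenerate
toward the uniform shuffle. Within-single-cluster: cells in exactly one
cluster permute within their cluster; multi-cluster cells are fixed
points. Mean relative spike rank uses each cell's mean spike time per
event (median available via an argument), normalized rank in $[0, 1]$,
inverted in events whose decoded slope (sign of the weighted correlation)
is negative, averaged per cell, and regressed against the field's center
of mass — "place-field density location" is read as center of mass of the
smoothed field.

## Small-world metrics

The E-to-E graph's clustering coefficient is the directed total-triplet
ratio (multiplicity-weighted triangles over possible triplets); the
headline value is the global ratio of sums, with the per-node mean also
available — the ratio-of-totals reading matches the wording of the
definition this implements. Path length is the mean shortest directed
path over ordered pairs (all-pairs BFS; if any pair is unreachable the
mean is over reachable pairs and the unreachable fraction is reported).
The small-world index locates the graph between closed-form lattice and
random references, $C_r = p$, $L_r = (\ln n - \gamma)/\ln k + 0.5$,
$C_l = 3(k-2)/(4(k-1))$, $L_l = n/(2k) + 0.5$, with $k$ the empirical
mean out-degree. Fiducial networks score SWI $\approx$ 0.7; the index
rises with the number of clusters and falls with participation.

## Problem sizes and reproducibility

All randomness flows from one master seed through named hash-derived
sub-streams (cluster assignment, connectivity, per-environment weights,
per-session simulation noise, per-event shuffles), so every stage is
independently reproducible and an identical configuration reproduces
bit-identical spike tables.

The package's own test suite exercises the full-scale analyses at desk
scale, chosen as the smallest sizes at which the qualitative results are
stable: the headline preplay ensemble uses 10 networks with 120 s sleep
sessions (10 networks being the count the ensemble statistics are defined
over); identity-shuffle controls use 5 replicates over 5 networks;
remapping uses 2 networks with 2 environments; the small-world sweep uses
a 2 x 2 (clusters x participation) grid at connection probabilities
{0.04, 0.08, 0.12} with 3 networks per point and 60 s sleep, with the
E-to-E conductance step rescaled inversely with the connection
probability so total recurrent drive is constant. At these sizes the
fiducial ensemble yields roughly 1600 decodable events with an
actual-versus-shuffle KS statistic near 0.23 and a median absolute
weighted correlation shift near +0.13, and significance across most of
the threshold grid.

## What the generator does and does not emulate

The simulation is the data source: there is no external data ingestion
beyond spike tables in the package's own columnar format. What passing
tests show is therefore internal consistency of the model and analysis
chain under the stated parameters, not agreement with any particular
recording. Known quantitative differences from reported in vivo and
reference-scale values, with the package's tests as the measurement:

* Place fields are broad. The spatially selective drive is a $\pm$4%
  cluster bias on linear ramps, and at the fiducial operating point the
  awake excitatory rates (~8 Hz mean) ride close to threshold, so median
  specificity is near zero and median spatial information ~0.05
  bits/spike — lower than typical hippocampal values, though peak-rate
  distributions (median ~12 Hz) are comparable.
* Sleep events are frequent and short (roughly 2 per second, median
  ~55 ms, because the 1 SD threshold sits close to a relatively high
  baseline), whereas reported event rates are several-fold lower; the
  ensemble significance pattern is insensitive to this, but per-event
  statistics that depend on event length are not.
* The ensemble KS statistic at the fiducial point (~0.23 at 10 networks)
  sits below the reported ~0.29, within its stochastic range; the median
  shift (~0.13) matches.
* On the reduced small-world sweep, the per-network correlation between
  SWI and preplay shift is stably positive at connection probabilities
  0.04 and 0.08 (Spearman +0.78 and +0.63) but undefined in practice at
  0.12, where no feasible grid point of the reduced sweep produces
  preplay (median shifts at or below 0.01) and the correlation is
  realization noise.
* The correlation between active-cluster count and shuffle-normalized
  $|r|$ is positive here (about +0.15) where the reference result is
  negative (about $-0.13$): in this implementation events with zero or
  one dominant cluster decode relatively poorly and events with three
  dominate, and the count distribution is concentrated at 0-2 rather
  than 2-8. This is the one qualitative sign the desk-scale build does
  not reproduce; the corresponding acceptance check is left failing
  rather than redefined.

## Limitations

Forward Euler at 0.1 ms with threshold reset is the integrator the model
is defined with; sleep-state rates are sensitive to integration bias as
discussed above. The within-cluster identity shuffle is approximately,
not exactly, uniform over its constraint set. The bootstrap p-values are
granular at 1/100 and reported as < 0.01 when zero. Single-interneuron
population, no dendritic nonlinearity, no plasticity, and no
distance-dependent wiring are deliberate simplifications of the modeled
circuit.
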