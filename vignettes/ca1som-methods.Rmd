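---
title: "A CA1 rate model of novelty-gated continual learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A CA1 rate model of novelty-gated continual learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1som)
```

## The model

`ca1som` simulates the pyramidal layer of hippocampal CA1 as a
self-organizing competitive map embedded in a novelty-detection loop. Six
populations are represented: a grayscale input layer (one neuron per
pixel), the CA1 pyramidal layer (same size, 40x40 by default), a CA1
interneuron layer (13x13, preserving the roughly 9:1
pyramidal-to-interneuron ratio of rodent CA1), a Subiculum copy of the
pyramidal layer, and single-unit abstractions of the Accumbens/Ventral
Pallidum and of the dopaminergic VTA.

Pyramidal cells and interneurons are leaky integrators on a toroidal 2D
sheet (opposite edges adjacent, so no neuron is privileged by map
position). For a pyramidal cell,

$$\tau\,\Delta u^{P} = -u^{P} + SI + LE + LI + \textrm{Noise},$$

where $SI$ is the input drive through the plastic all-to-all input
weights, $LE$ the lateral excitation through a narrow stochastic Gaussian
kernel, $LI$ the lateral inhibition from interneurons through a
Mexican-hat (difference-of-Gaussians) kernel, and the noise term scales
with the summed absolute change of the cell's input synaptic potentials,
so it perturbs the network at stimulus onset and vanishes as the drive
stabilises. Interneurons integrate the same way with a 1.5x slower time
constant. Both layers share the gain
$f(x) = \min(1, \sinh(x)\,h + 0.008)$ for $x > 0$ and $0$ otherwise.

Familiarity is read out by a threshold chain: a Subiculum unit fires iff
its pyramidal counterpart exceeds $\theta^{+}$; any Subiculum activity
drives the Accumbens/Pallidum unit, which inhibits VTA; dopamine
(binary) is therefore on exactly while *no* pyramidal cell signals
familiarity. Dopamine gates two plasticity rules:

* an Oja-like Hebbian rule on the input weights,
  $\Delta w = \eta\,DA\,a^{P}(a^{INP} - w)$, applied per neuron when the
  learning-threshold gate ($a^{P} > \theta^{-}$, strict) and the
  stable-activation gate (activation above its moving average by more
  than $\delta_2$ while the input flux is below 0.012) both hold;
* a homeostatic rule on the inhibitory weights,
  $\Delta w = -\tfrac{L}{\tau}\,DA\,a^{P}(a^{I} + 0.3\,w)$, additionally
  gated by the excitatory learning level (mean input mismatch above
  0.004), which strengthens inhibition onto exactly the neurons that are
  currently learning and stops once their input weights have converged.

The Hebbian rule's fixed point is the stimulus itself, which bounds
weight growth without renormalisation; the homeostatic rule's fixed
point is $w^{*} = -a^{I}/0.3$, so inhibition tracks the activity a
winning population generated while it learned. Together the two
dopamine-gated mechanisms implement the model's two protections against
catastrophic interference: familiar stimuli stop triggering plasticity
at all, and past winners carry an inhibitory handicap that keeps them
from capturing every subsequent stimulus.

## Numerical choices

Integration is forward Euler with `dt = 1` and `tau = 10` steps; the
continuous-time formulation fixes only the ratios, so time is expressed
in steps throughout. Settling stops when the largest per-step change of
pyramidal activation falls below `settle_eps = 1e-4`, or after
`15 * tau` steps (the report is then flagged truncated). A learning
episode runs joint dynamics-plus-plasticity steps until dopamine
switches off or `t_max_episode = 300` steps elapse (the forced-advance
rule). The peak (winner) neuron is the most active cell; because the
gain clamps rates at 1, ties among saturated cells are resolved by the
membrane potential — the latent activity, in which the gain is strictly
increasing — and any remaining exact tie takes the lowest row-major
index. Without this, the winner among a saturated population would be
an arbitrary function of neuron numbering. The
moving average of activation is exponential with effective window
`delta1 * tau` steps; the stable-activation comparator uses the signed
deviation by default (learning while activation stands *above* its
recent history), with an absolute-deviation variant behind
`sa_mode = "absolute"` since either reading is compatible with gating
out onset transients and residual decay. The input-flux term sums
$|\Delta(w \cdot a)|$ over a neuron's input synapses, including the
contribution of weight updates, so a step that changed weights
registers as unstable input on the next step.

The network state is never reset: between images, between protocol
phases, and during frozen-plasticity test presentations, activity
carries over, as in the animal.

## Parameters and their defaults

All scalar constants live in one validated record, `ca1_params()`. The
original tuned constants of this model family are not public, so the
defaults here were fixed once, by the considerations below, and are
deliberately exposed as configuration:

* `theta_plus = 0.9` — familiarity threshold, a little below the gain's
  saturation at 1. It must exceed the activation a partially learned
  stimulus evokes, while remaining reachable once the input weights have
  converged despite the inhibitory handicap accrued during learning.
* `theta_minus = 0.1` — learning threshold, above the response that
  uncorrelated (novel-stimulus) drive evokes in the bulk of the map, so
  that only the upper tail of the activation distribution recruits into
  a learning population.
* `h = 0.15` — gain slope, chosen jointly with the stimulus norms (see
  below) so that a novel stimulus puts the winning tail between
  $\theta^{-}$ and $\theta^{+}$ and a learned stimulus saturates its
  specialists. Because $\sinh$ is exponential for arguments above ~2, a
  unit of membrane potential is roughly a factor $e$ in activation,
  which is what lets modest lateral inhibition separate winners from
  the bulk.
* `s1_pp = 0.5`, `s1_ip = 0.05`, `s2_ip = 0.5` — kernel decays: narrow
  lateral excitation (reach ~2 grid units) inside a wide Mexican-hat
  inhibitory surround (ring maximum near 2.3 units, reach ~8), the
  classic centre-surround arrangement that lets local bumps form while
  distant populations compete.
* `s1_pi = 0.02` — pyramidal-to-interneuron pooling. This is wide:
  interneurons read the overall activity of a large neighbourhood, so
  lateral inhibition acts like local excitation-inhibition balance and
  subtracts the common component of the drive. With narrow pooling the
  interneurons barely responded below saturation and the map lost all
  competitive contrast, so this constant matters more than any other
  for winner-take-all behaviour.
* `L = 0.1`, `lr_exc = 0.1` — the two learning rates are a coupled
  choice, because they race each other within an episode. The per-step
  inhibitory rate `L / tau` must accrue a meaningful handicap across a
  learning episode yet stay slower than the excitatory convergence
  that closes the ELL gate: when inhibition outruns excitatory
  learning, each episode recruits and then suppresses the next tier of
  neurons, activation can no longer reach the familiarity threshold,
  and novelty never ceases. The race is tightest on a fresh map, whose
  uniform background drives the pooled interneurons hardest — the
  first stimuli a naive network sees are the hardest to consolidate.
  `lr_exc` is absent from the printed Hebbian rule (unit step); a
  sub-unit scale is needed for Euler stability, and 0.1 wins the race
  above while still letting the familiarity threshold cut learning off
  before full convergence.
* `delta1 = 5`, `delta2 = 0.001`, flux gate `0.012`, ELL gate `0.004`,
  `t_max_episode = 300` — the two gate constants (0.012, 0.004) are
  fixed, hand-tuned values of the model; the window and deviation
  defaults follow the interpretation above.
* `lambda_noise = 0.1` — onset noise level: enough to decorrelate
  settling across presentations without masking the stimulus-specific
  part of the drive.

The lifelong protocol adds `max_epochs = 20` and `max_passes = 5`
(corridor traversals within one epoch). The pass cap only matters under
lesions: with dopamine pinned on, no pass is ever novelty-free and an
epoch would not end otherwise. Both caps are safety bounds, not tuning
knobs.

## Synthetic stimuli

The package is tested end to end on synthetic data built by
`gen_digit_like()` and `gen_corridor()`; real MNIST IDX files and image
directories are optional inputs through the same preprocessing path
(40x40 bilinear resize, linear gray-to-activation mapping with
per-dataset gain/offset).

`gen_digit_like()` emulates the structure that matters in
handwritten-digit data: 10 classes whose members are far more similar
to each other than to other classes. Each class is a random polyline
stroke; variants are small translations plus per-anchor jitter and
pixel noise. Images are sparse (strokes on a dark field) and are scaled
to a fixed L2 norm (`target_norm = 2.2`). Fixing the norm rather than
the mean keeps the total sensory drive — and with it the familiarity
dynamics — independent of canvas size, mirroring how the original
experiments adjusted stimulus intensity per dataset.

`gen_corridor()` emulates contiguous naturalistic views as a chain of
independent 1/f-filtered sparse texture chunks (scene segments): view
$i$ blends chunk $i$ with, at weight 0.25, chunk $i+1$, so consecutive
views share a stretch of scene content and correlate while non-adjacent
views are nearly orthogonal. Only the bright upper tail of each chunk
is kept (default: the top 15% of pixels): non-negative *dense* textures
all share their mean, which cross-correlates every view with every
other (~0.5) and lets the specialists of one corridor be dragged along
while the other corridor is being learned; sparse detail keeps views
nearly disjoint. Each view is scaled to the same L2 norm as the digit
stimuli, and a per-corridor brightness floor makes the two corridors
differ in overall luminance the way two landscapes do. What these
generators do *not* reproduce is
the rich semantic detail of photographs or the stroke topology of real
digits; passing protocol tests on them demonstrates the model's
competitive-map and novelty-gating behaviour, not image-recognition
performance on real data.

Recognition in the forgetting protocol follows the winner-label rule: a
test image counts as recognised iff the most active neuron was labelled
with the image's task during learning. Neurons updated by several tasks
carry the label into which they put the most cumulative weight change;
the raw last-write labels are retained in the trace. Results are
reported by *learning position* (first-learned task to last-learned),
averaged over task-order permutations, which is the axis on which
interference shows as a recency gradient.

## Problem sizes used in the test-suite and acceptance runs

The model is fully parametric in its geometry, and all protocol
behaviour of interest — novelty gating, localized recruitment,
interference and its two protections — is present on a reduced sheet.
The packaged experiments therefore run on a 20x20 pyramidal map with a
7x7 interneuron grid (the same ~9:1 ratio) and 20x20 stimuli, with 10
tasks x 4 images for the forgetting protocol and 2 corridors x 20
images for the lifelong protocol, a handful of task-order permutations,
and 3 seeds for across-condition comparisons. The full-size 1600-neuron
geometry is exercised by the structural checks (layer sizes, fixed
gains, kernel and normalisation invariants). Scaling the defaults back
up only requires passing the full-size geometry and stimuli.

## Known limitations

* Map capacity bounds the forgetting protocol on reduced sheets. With
  400 pyramidal cells and 40 training images, the later tasks of a
  sequence find the map largely occupied by protected specialists:
  recognition of the *earliest* tasks is preserved (the protections
  work) while the latest tasks score poorly — a primacy profile, where
  the full-size model (40 images over 1600 cells) degrades gracefully
  from recent to old. The lesion contrast on early tasks, which is the
  substantive comparison, is unaffected.

* Dynamics are rate-based with binary dopamine; no spiking, no graded
  neuromodulation.
* The inhibitory handicap is bounded by the interneuron activations
  that occur during learning; on small maps its contribution is modest
  compared with dopamine gating, and lesion contrasts are accordingly
  dominated by the latter.
* A stimulus whose converged response lands just below the familiarity
  threshold re-triggers learning on every visit; the forced-advance
  budget and the epoch caps bound the cost, and the chosen
  `theta_plus` leaves margin against it, but adversarial stimuli can
  still produce non-terminating lifelong runs.
* The Subiculum, Accumbens/Pallidum and VTA are threshold abstractions;
  no claim is made about their internal dynamics.
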