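# polychron

Simulation and analysis of a homogeneous chaotic spiking network that
converts rate/population-coded stimuli into temporally coded responses —
without any synaptic plasticity.

## The science

Peripheral neural signals mostly use **rate/population coding** (a stimulus
= elevated firing of a specific subset of fibers), while cortical circuits
widely use **temporal coding** (information in precise, millisecond-scale
relative spike times). `polychron` implements a candidate converter between
the two: a recurrent network of 700 excitatory and 300 inhibitory leaky
integrate-and-fire neurons (threshold 1, refractory period T = 6 ms,
membrane decay τ = 3 ms, delta synapses) driven by 1000 input nodes.
Excitatory neuron-to-neuron conduction delays are proportional to geodesic
distances between random neuron positions on a sphere in 4-space, which
enriches the network in *polychronous neuronal groups* (PNGs) — sets of
neurons that fire in reproducible spatiotemporal patterns. A stimulus is a
30 ms, 300 Hz Poisson burst on a fixed subset of 100 input nodes over 3 Hz
background noise; conversion succeeds when every stimulus selectively
activates a PNG of its own.

Groups are detected from spike rasters by a shift-alignment algorithm:
stimulus-locked spike fragments `P_Ai` are greedily aligned into a count
matrix `C_at` (each fragment at the shift maximizing its overlap with the
accumulated counts), and the PNG at support `n` is `{(a, t) : C_at ≥ n}`.
Its response statistics are

* activity `A_Ai(G) = max_s |shift(G, s) ∩ P_Ai|`,
* reaction strength `R_A(G) = min_i A_Ai(G)`,
* selectivity `S(A, n) = N_A / |{(B, i) : A_Bi(G) ≥ R_A(G)}|` (1 = the
  group responds at threshold level only to its own stimulus),
* pairwise independence: observed shared-neuron count over the
  `|S1||S2|/N⁺` expectation for independent groups.

## Worked example

```r
library(polychron)
res <- runCondition(nStimuli = 3, nPresentations = 20, seed = 1)
resultRows(res)
#>   label support size reactionStrength relStrength selectivity success
#> 1    S1       9   46               12   0.2608696           1    TRUE
#> 2    S2       8   97               27   0.2783505           1    TRUE
#> 3    S3       8  113               36   0.3185841           1    TRUE
```

Each row is one stimulus: a PNG of `size` (neuron, ms) pairs was found at
the given alignment `support`; on its worst presentation
`reactionStrength` of its pairs were re-activated (`relStrength` as a
share), and `selectivity` 1 means no presentation of any other stimulus
matched the group at that level — all three stimuli were successfully
recoded into temporal form. The full experiment grid of the study
(stimulus count, stimulus intensity, noise level, and the
delay-randomization control) runs through `runStarSeries()`; single
pipeline stages are exposed as `buildNetwork()`, `makeStimulusSet()`,
`presentStimuli()`, `extractFragments()` and `findSelectivePNG()`, and a
thin command-line front end lives in `inst/scripts/polychron`.

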