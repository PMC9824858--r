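# stemecho

Non-destructive sensing of water status in plant stems from pulse-echo
ultrasound. A 1 MHz pulse is fired into the stem and the returning
radio-frequency A-scan is recorded; the onset time *t* of the **primary
echo** — the first reflection off the far interface — gives the
longitudinal velocity

    v_l = 2 D / t

for a half-path length *D*, and through the elastic relation

    v_l = sqrt( (E / ρ) · (1 − σ) / ((1 + σ)(1 − 2σ)) )

velocity tracks density ρ and hence stem water content: water uptake
raises ρ and slows the wave. The hard part is *t*. Stems are
heterogeneous, anisotropic and strongly attenuating, so the echo is weak
and preceded by a span where the ultrasound is drowned by noise.

The classical two-segment AIC change-point picker,

    AIC(k) = k · log var(s[1..k]) + (N − k + 1) · log var(s[k+1..N]),

places its global minimum at the junction between the transmit burst and
the noise span — not at the echo. `stemecho` implements a **hybrid
differential AIC** picker that recovers the echo anyway:

1. compute `AIC(k)` over the whole record;
2. keep the tail from the global minimum to the end (`AICseg`);
3. apply an M-th order forward difference (default M = 4), which turns
   the slope change at the echo onset into a localised spike;
4. cube and normalise the differential into a signed envelope in [−1, 1];
5. mix the envelope back into the tail (`Mixed = Envelope × AICseg`,
   in a shift-invariant form by default);
6. report the position of the global maximum of the mixed curve as the
   primary-echo onset.

Around the picker the package provides a seeded three-segment A-scan
simulator with ground truth, the immersion-experiment moisture physics
(bulk density, wet-basis and volumetric moisture content
`θ = (m_A − m_B)/(βV)`, quadratic velocity–moisture fits), time-series
correlation analytics, and a command-line interface.

Onsets are reported both as 1-based sample indices and in the printed
time unit of the reference tables (1 unit = 100 samples, so sample 153
prints as 1.53).

## Worked example

```r
library(stemecho)

# a synthetic stem A-scan: transmit burst to sample 100, noise-drowned
# span, primary echo starting at sample 153
sim <- simulate_ascan(ascan_spec(seed = 42))
pick_primary_echo(sim$trace)
#> <echo_pick> sim_seed42
#>   primary echo onset : sample 153  (1.53 pu)
#>   classic AIC minimum: sample 100  (1.00 pu)
#>   mixed-curve peak   : 85.6
```

The classical AIC minimum lands at sample 100 — the burst/noise junction,
half a printed unit early — while the hybrid pick recovers the true onset
at sample 153. The mixed-curve peak value is the height of the maximum
used for the pick.

```r
# water-immersion experiment: three cylindrical stem samples weighed and
# measured for velocity at 15 timepoints while soaking
res <- immersion_analysis(table2_immersion())
res
#> <immersion_analysis> 3 sample(s), 45 records
#>   cyl6   r = 0.9933 (n = 15)
#>   cyl7   r = 0.9930 (n = 15)
#>   cyl10  r = 0.9951 (n = 15)
#>   mean correlation: 0.9938
```

Each `r` is the Pearson correlation between the measured velocities and a
quadratic least-squares fit of velocity on volumetric moisture content;
the velocity–moisture relation is captured almost perfectly for all three
samples.

The same operations are available from a shell:

```sh
Rscript inst/cli/stemecho.R simulate --suite table1 --seed 7 --out sims/
Rscript inst/cli/stemecho.R pick --out picks.csv --dump-curves sims/table1_*.txt
Rscript inst/cli/stemecho.R immersion --out report/
```

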