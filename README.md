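# mupoolsim

Simulation of motor-unit pool firing, short-term synchronization and muscle
force for the rat medial gastrocnemius.

## What it is for

Synchronized discharges of motor units (MUs) are a prime suspect behind
physiological tremor: when pulses of different units coincide within a few
milliseconds, their twitches sum coherently and the muscle force oscillates
more.  Because real recordings never expose every unit of a muscle,
simulation is the standard way to ask *how much* synchrony changes the
force, and *which unit types* (slow S, fast fatigue-resistant FR, fast
fatigable FF) carry the effect.

`mupoolsim` builds the full 57-unit pool of the rat medial gastrocnemius
(8 S, 23 FR, 26 FF) from a packaged table of measured contractile and
firing parameters, generates stochastic firing for every unit, imposes
short-term synchronization by four different pulse-shifting schemes at
±2, ±4 or ±6 ms windows, and quantifies the outcome on the steady
2000–4000 ms of a simulated maximal contraction.

## The indices at its core

With $a_i, b_i \in \{0,1\}$ the 1-ms binary firing series of two units,

$$corMU = 100\cdot\frac{\sum_i a_i b_i}{\sqrt{\sum_i a_i^2\,\sum_i b_i^2}}\ [\%]$$

is the normalized binary-train correlation (100% = identical pulse
placement, independent of rate and record length).  For each reference unit
$i$ the cross-interval to a partner $j$ is $CI_x = t1_x - t2_{xy}$, the
signed lag from each reference pulse to the partner's nearest pulse; the
cross-interval synchronization index accumulates the central ±0.5 ms bin of
its histogram over all $N-1$ partners:

$$CISI(MU_i) = \frac{100}{N-1}\sum_{j\neq i}\frac{c_0\{CI(MU_i,MU_j)\}}{n_{MU_i}}\ [\%].$$

Force consequences are measured by `meanF`, `maxF`, `rangeF`, `rmsF`
(deviation RMS about the mean), the variance accounted for against the
non-synchronized force of the same seed,
$VAF = 100\,(1 - \mathrm{var}(F_S - F_{NS})/\mathrm{var}(F_{NS}))$,
and the PSD-weighted mean spectral frequency of the force oscillation.

## Worked example

```r
library(mupoolsim)
pool <- load_pool()                                   # the packaged 57-unit table

ns <- run_scenario(scenario_config(seed = 1), pool)   # non-synchronized baseline
m4 <- run_scenario(scenario_config(method = 4, window = 6, seed = 1),
                   pool, ns_ref = ns)                 # strongest scheme, +/-6 ms
print(m4$sync)
print(m4$stats, row.names = FALSE, digits = 4)
```

```
Synchronization summary (method4/dt6)
corMU [%] over unordered pairs:
 group mean   sd    n
     S 24.9 11.0   28
    FR 53.2 10.3  253
    FF 56.3 10.5  325
   all 23.5 24.8 1596
CISI [%] over units:
 group  mean   sd  n
     S  7.25 1.30  8
    FR 24.50 1.67 23
    FF 28.42 1.56 26
   all 23.87 7.18 57
  group  meanF    rmsF rangeF   maxF meanfreq     vaf
      S  141.8   3.525   26.4  150.9    37.01   57.04
     FR 1015.7  37.066  219.3 1094.0    55.33 -183.72
     FF 2536.8  96.966  613.8 2751.5    59.14 -207.94
 muscle 3694.3 101.140  621.6 3908.7    60.85 -199.36
```

Reading this: synchronizing every unit of a type to its first-recruited
reference at ±6 ms lifts within-type correlations from the ~5% chance level
of the baseline (the same seed gives `corMU` all = 5.0%, `CISI` all = 5.1%)
to 25–56%, and the typed `CISI` to 24–28%.  The mean muscle force barely
moves (3704 → 3694 mN, −0.3%), but its fluctuation nearly doubles
(`rmsF` 57 → 101 mN; `rangeF` 348 → 622 mN) and the synchronized force is
so unlike the baseline that `VAF` is deeply negative.

The full experiment grid — baseline plus 4 methods × 3 windows, averaged
over seeds — is one call:

```r
g <- run_grid(seeds = 1:10)
g$sync_table    # corMU / CISI mean +/- SD per scenario and unit type
g$force_table   # the six force statistics per scenario and group
g$trend_table   # correlation of each force-parameter trend with the CISI trend
```

A thin command-line front end lives in `inst/cli/mupoolsim.R`
(`simulate`, `replicate`, `metrics` subcommands); `metrics` accepts an
external firing table in the long CSV layout (`mu_index,label,pulse_time_ms`)
so independently produced firing patterns can be scored with the same
indices.

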