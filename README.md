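# thermidx

Rational thermal comfort indices and mean radiant temperature for
human biometeorology, in R.

Practitioners in urban climate, public health, building and tourism
research routinely need the *rational* thermal indices — indices
derived from a human heat-balance model rather than an empirical
formula — to assess how hot or cold an outdoor environment actually
feels.  `thermidx` computes the five standard ones from point
meteorological records:

| index | model core | output |
|-------|------------|--------|
| **PMV**  | Fanger steady-state load \(L\); \(\mathrm{PMV} = (0.303e^{-0.036M}+0.028)\,L\) | vote on the −3…+3 scale, plus equivalent temperature `Teq` and clothing heat loss `hclo` |
| **SET*** | Gagge two-node (core/skin) 60-min simulation | standard effective temperature, °C |
| **PET**  | MEMI steady-state heat balance \(M + W + R + C + E_D + E_{Re} + E_{Sw} = 0\) | physiologically equivalent temperature, °C, plus the body state and flux decomposition |
| **mPET** | compact multi-node physiology (4 segments × 4 tissue layers + blood pool), humidity-sensitive clothing, Ta-adaptive insulation | modified PET, °C, 14-field output |
| **UTCI** | published 6th-order operational polynomial in \((T_a, v_{10}, T_{mrt}-T_a, p_a)\) | universal thermal climate index, °C |

All engines share one input convention: air temperature `Ta` (°C),
vapour pressure `VP` (hPa) *or* relative humidity `RH` (%), wind at
the 1.1 m biometeorological reference height (UTCI's 10 m wind is
derived internally through a power-law profile), and mean radiant
temperature `Tmrt` (°C).  When `Tmrt` is not measured, `tmrt_calc()`
simulates it from site coordinates, time, cloud cover or measured
global radiation — solar geometry, clear-sky extinction, cloud
attenuation \(G = G_{max}(1-0.75(N/8)^{3.4})\), longwave budget and
the flux composition on a standing person,
\(T_{mrt} = (S_{str}/(\varepsilon_p\sigma))^{1/4} - 273.15\).

Auxiliary functions (`vp_rh_exchange`, `wind_at_height`,
`saturation_vapor_pressure`), a batch CSV pipeline
(`read_station_csv` → `compute_indices`), a deterministic
synthetic-weather generator (`generate_fixture_series`) and a CLI
(`thermidx_cli` / `inst/cli/thermidx`) round out the toolkit.

## Worked example

```r
library(thermidx)

# a hot, sunlit afternoon record (wind already at 1.1 m)
rec <- meteo_record(Ta = 32, RH = 55, v = 0.8, Tmrt = 55)

pmv_calc(rec)        # PMV = 4.28   Teq = 24.61 degC   hclo = -41.0 W/m^2
set_star(rec)        # 38.86
pet_calc(rec)        # PET = 42.32 degC (Tcore 37.23, Tsk 36.06, wetsk 0.52)
mpet_calc(rec)       # mPET = 39.95 degC (auto clothing 0.39 clo)
utci_calc(rec)       # 38.82
```

Reading the numbers: the environment is far beyond the comfort zone —
PMV saturates above +3 (`Teq` says this subject would be neutral at
24.6 °C), and all three equivalent temperatures land in the "strong to
extreme heat stress" bands (PET > 41, UTCI > 38).  mPET sits ~2.4 K
below PET because its subject adapts clothing down to 0.39 clo while
PET's reference subject is pinned at 0.9 clo — the compression of
extremes that motivates the modified index.

Simulating `Tmrt` instead of measuring it:

```r
st <- site_time(121.5, 23.5, 30, day_of_year = 210,
                hour_of_day = 15.8, timezone_offset = 8)
tmrt_calc(Ta = 32, RH = 55, v = 0.8, site = st,
          config = radiation_config(N = 2))
#> radiation_budget: Tmrt=67.90 degC (zenith=52.9 deg)
#>   shortwave W/m^2: Imax=832.3 Gmax=590.9 Dmax=89.1 | Itat=620.1 Gtat=586.9 Dtat=213.1
#>   longwave  W/m^2: A=408.2 Eu=564.8 Es=519.4 | Tob=45.18 degC
```

Batch mode over a station CSV (columns `Ta`, `RH` or `VP`, `v`,
`height`, optionally site/time columns for Tmrt simulation):

```r
tab <- read_station_csv("station.csv")
out <- compute_indices(tab, indices = c("PET", "mPET", "UTCI"),
                       simulate_tmrt = TRUE)
write_station_csv(out, "result.csv")
```

or from the shell:

```sh
Rscript inst/cli/thermidx compute --input station.csv \
    --indices pet,mpet,utci --simulate-tmrt --out result.csv
Rscript inst/cli/thermidx point --Ta 20 --RH 50 --v 0.1 --Tmrt 20 --index pet
Rscript inst/cli/thermidx fixture --seed 1 --days 2 --climate temperate --out fixture.csv
```

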