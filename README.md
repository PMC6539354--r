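# dndea — dynamic network slacks-based-measure DEA with undesirable outputs

`dndea` measures the relative efficiency of decision-making units (DMUs —
cities, hospitals, firms, regions) whose production process has **internal
structure in two directions**: it is split into *divisions* (e.g. a
production stage whose pollution feeds a health-treatment stage) and it
unfolds over *periods* connected by carry-over stocks (e.g. fixed-asset
investment). Outputs may be desirable (GDP, birth rate) or undesirable
(respiratory disease, mortality), and intermediate *link* variables (CO2,
air-quality index) flow from one division into another within each period.
It is aimed at efficiency and productivity analysts who would otherwise
reach for a static or black-box DEA model and lose the internal structure.

## The model

For evaluated unit *o*, the package minimizes the non-oriented
slacks-based-measure (SBM) ratio

```
            Σ_t W^t Σ_k W^k [ 1 − (1/(m_k+linkin_k)) ( Σ_i s⁻_{ik,t}/x_{iok,t} + Σ_l s^{in}_{lk,t}/z^{in}_{lok,t} ) ]
θ*_o = min ─────────────────────────────────────────────────────────────────────────────────────────────────────────
            Σ_t W^t Σ_k W^k [ 1 + (1/(r1_k+r2_k+ngood_k)) ( Σ_r s⁺_{rk,t}/y^{good}_{rok,t} + Σ_r s⁻_{rk,t}/y^{bad}_{rok,t} + Σ_c s_{ck,t}/z^{good}_{cok,t} ) ]
```

subject to, for every division *k* and period *t*, frontier constraints
with intensity vectors λ_k^t over the observed units:
x_o = Xλ + s⁻ (inputs), y_o^good = Yλ − s⁺, y_o^bad = Yλ + s⁻,
z_o^in = Zλ + s^in (incoming links), z_o^good = Zλ − s (carry-overs),
e'λ_k^t = 1 (variable returns to scale), and carry-over continuity
Σ_j z_j λ_{jk}^t = Σ_j z_j λ_{jk}^{t+1} between consecutive periods. All
slacks are nonnegative; θ*_o ∈ (0, 1], with θ*_o = 1 exactly for
undominated units.

The ratio program is linearized by the Charnes–Cooper transformation and
solved by a two-phase simplex method; a second lexicographic pass maximizes
total slack at the optimal score so reported slacks are deterministic among
alternate optima. The overall score decomposes into period, division and
division-period efficiencies (weighted mediants of the per-block
numerators/denominators), and each variable gets a total-factor efficiency
index — the ratio of its frontier target to its actual value.

## Worked example

```r
library(dndea)

spec <- two_stage_spec()       # production + health-treatment configuration
sim  <- generate_two_stage_panel(n_dmu = 8, n_periods = 2, seed = 42)
fit  <- run_two_stage(sim$panel)
summary(fit)
```

```
8 DMU(s) x 2 period(s); divisions: production, health_treatment

Overall efficiency distribution:
   Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
 0.5231  0.6221  0.6895  0.7303  0.8040  1.0000

Efficient DMU(s) (score = 1): city06, city08

Mean division efficiency:
      production health_treatment
          0.9109           0.5932
```

Two of the eight cities are on the best-practice frontier (no feasible
benchmark improves any of their variables); the health-treatment stage is
on average far less efficient than the production stage, and per-block
scores show where:

```r
round(efficiency(fit, "division_period")[1:4, ], 4)
```

```
       production:2013 production:2014 health_treatment:2013 health_treatment:2014
city01          0.8432          0.7814                0.1844                1.0000
city02          1.0000          1.0000                0.1850                0.1941
city03          0.7412          0.7480                1.0000                0.5134
city04          1.0000          1.0000                0.1825                1.0000
```

Per-variable factor indices report how far each input/output is from its
frontier target (1 = at target):

```r
fi <- factor_indices(fit)
head(fi[fi$dmu == "city01", c("division","period","variable","actual","slack","index")], 5)
```

```
    division period           variable   actual    slack     index
1 production   2013              labor 71.77080 2.911532 0.9594329
2 production   2013 energy_consumption 64.51139 7.461779 0.8843339
3 production   2013                gdp 90.07420 0.000000 1.0000000
4 production   2013       fixed_assets 45.17504 8.433652 0.8426813
5 production   2014              labor 56.49020 0.000000 1.0000000
```

`write_reports(fit, "out/")` emits the wide report tables (one score column
per year; one per year-stage pair; one per year-variable pair) plus a
machine-readable `results.json`, and a command line drives the same
pipeline: `inst/cli/dndea simulate|solve|two-stage|verify`.

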