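# agelearn

Age-structured models of cultural transmission coupled to demography.

Most models of cultural change assume people learn the same way throughout
life. Empirical "learning life histories" say otherwise: in forager
societies children learn predominantly from their parents well into late
childhood, while children of small-scale agriculturalists learn from peers
and unrelated adults from an early age. `agelearn` is for researchers in
cultural evolution and evolutionary demography who want to ask what those
schedules do to the spread of a cultural trait — and what the trait, in
turn, does to the population.

## The model

Five life stages (infancy, early childhood, late childhood, adulthood,
post-reproductive life). Stage counts advance through an adapted Leslie
matrix in which only stage 4 reproduces and stage-5 survivors remain in
stage 5:

```
        ( 0   0   0   f4  0  )
        ( s1  0   0   0   0  )
  L  =  ( 0   s2  0   0   0  )
        ( 0   0   s3  0   0  )
        ( 0   0   0   s4  s5 )
```

A dichotomous trait T at frequency x_i in stage i may raise fertility
(f4 = (b + w_f) x4 + b (1 − x4)) or survival (s_i + w_s x_i). Newborns
learn only vertically: x1' = p_v · g(x4), with g the fertility-weighted
parental frequency. A cohort entering stage j ∈ {2,3,4} keeps what it
knows and the naive remainder makes one attempt, vertical with share V_j
(success p_v against the parental frequency C, fitness-weighted) and
horizontal/oblique otherwise (success p_h against the size-weighted pool
of stages j..ω):

```
x_j' = x_{j-1} + (1 − x_{j-1}) [ V_j · C · p_v + (1 − V_j) · p_h · pool_j ]
```

Stage 5 no longer learns; it merges maturing adults with survivors. Under
*cultural niche construction*, V_j is replaced by a contact time
v = v_b (1 − ε · x4_lagged): the trait erodes vertical learning as it
spreads (think farming — parents in the fields, children with peers).

Four learning life histories are bundled: `all_vertical`,
`hunter_gatherer` (V = 0.8, 0.8, 0.4), `agriculturalist`
(V = 0.5, 0.25, 0.1), `all_horizontal`. A stochastic individual-based
twin of the same rules (`abm_run()`, `replicate_summary()`) serves as a
verification oracle for the deterministic recursion.

## Worked example

```r
library(agelearn)

cfg <- default_config(n_steps = 1000)   # b = 5, w_f = 1, p_v = p_h = 0.6,
                                        # hunter-gatherer schedule
sim <- run_simulation(cfg)
sim
#> Age-structured cultural transmission run (fertility mode, 1000 steps)
#>   final mean trait frequency: 0.823646
#>   final population size: 2.53815e+09 (log 21.6547)
summary(sim)
#> Final state:
#> Population state at tau = 1000 (total size 2.53815e+09)
#>         stage1       stage2      stage3       stage4       stage5
#> n 6.577122e+08 6.210595e+08 5.85197e+08 5.725525e+08 1.016328e+08
#> a 2.591300e-01 2.446890e-01 2.30560e-01 2.255780e-01 4.004200e-02
#> x 5.845850e-01 8.229360e-01 9.25077e-01 9.695230e-01 9.692230e-01
#> Mean trait frequency: 0.823646 (time average 0.74199)
```

The fertility-enhancing trait has swept through the adult stages (x4 ≈
0.97) but sits much lower among newborns (x1 ≈ 0.58, limited by p_v), so
the population mean settles near 0.82 — learning accumulates over a
lifetime, which is exactly why parents are good role models in this model.

Demographic rescue: a declining population (baseline growth factor 0.897)
carrying a fertility trait that would make it grow (all-carrier factor
1.004) survives or dies depending on how people learn:

```r
cfg6 <- sim_config(
  demography = demography_params(3, c(0.6, 0.6, 0.6, 0.6, 0.4), w_f = 1.7),
  learning = learning_params(0.6, 0.6), mode = "fertility",
  n_steps = 2500, initial_total = 50)
rescue_experiment(cfg6)
#>         scenario   final_n final_log_n final_mean_freq collapsed
#> 1   all_vertical 178.96146    5.187170       0.8222203     FALSE
#> 2 all_horizontal  39.01175    3.663863       0.8045959     FALSE
```

Vertical learners spread the trait fast enough to recover past their
starting size; horizontal learners lag and keep shrinking.

Other entry points: `sweep_fidelity_grid()` (final-frequency heatmaps over
the (p_v, p_h) plane), `compare_to_neutral()` (isolates the fitness
effect from pure transmission), niche-construction runs via
`niche_params(v_b, epsilon)`, and YAML configuration through
`load_config()`. A thin command-line wrapper lives at
`system.file("scripts", "agelearn", package = "agelearn")` with
subcommands `run`, `sweep`, `compare-neutral`, `rescue`, `scenarios`, and
`oracle-compare`.

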