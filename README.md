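# evoprimer

Specific-product PCR primer design in R, by genetic-algorithm (GA) and
memetic-algorithm (MA: GA + local search) optimization.

## What problem this solves, and for whom

Molecular biologists designing PCR assays need primer pairs that
satisfy many constraints *simultaneously*: primer length and length
difference, GC content, melting temperature (Tm) and Tm difference,
product size, no stable primer dimers or hairpins, a 3' GC clamp, and
— for a *specific* product — exactly one binding site per primer on
the template.  evoprimer searches the space of primer pairs on a
user-supplied DNA template (FASTA or pasted sequence; single template
or high-throughput multi-FASTA) and returns ranked, fully annotated
candidate pairs, plus local in-silico PCR and a virtual gel to preview
the experiment.

## The model

A candidate pair is encoded as a four-integer chromosome
`(f_start, f_len, amplicon_len, r_len)`: the forward primer's 1-based
5' position, both primer lengths, and the product length.  The reverse
primer is the reverse complement of the amplicon's last `r_len` bases.
Each design constraint contributes a non-negative penalty (distance
outside a range, excess over a cap, count of off-target sites, …); the
total is a weighted sum with **lower = better** and total 0 meaning
every constraint is met.  Specificity is weighted 10×, so one
off-target binding site outweighs any mild property violation.

Tm uses the nearest-neighbor thermodynamic model (unified dinucleotide
parameters, salt-corrected):

    Tm = ΔH / (ΔS + R ln(CT/x)) − 273.15 + 16.6 log10([Na+])

with the classic GC/salt/length formula available as an alternative.
The search is a generational GA (tournament selection, two-point
crossover, per-gene mutation, elitist replacement); the default MA
additionally hill-climbs every individual to a local minimum.  Five
independent seeded runs (population 50) each contribute their best
pair; candidates are ranked by (penalty, Tm difference, position).

See `vignettes/primer-design-methods.Rmd` for the full account.

## Worked example

```r
library(evoprimer)

# a 1-kb synthetic template with one planted feasible pair
cs <- design_constraints(product_min = 100, product_max = 600)
fx <- make_fixture(1000, n_feasible = 1, seed = 8, constraints = cs)

fit <- design_primers(fx$template, cs,
                      evolution_params(seed = 1, runs = 3,
                                       max_generations = 50))
fit
#> Primer design on 'fixture_L1000_n1_s8' (1000 bp), MA, 3 run(s), seed 1
#> Ranked primer pairs for template fixture_L1000_n1_s8
#>   rank                    f_seq                   r_seq f_start r_end
#> 1    1 TATTCGTGACGGTTCTCGACCTAC GTCCCCGTGAGATAAATGTCAGG     149   626
#> 2    2   AACACTACTCGTCGAGGAACCG   TCAGAGCCATGCGCTGATTGC     388   921
#> 3    3    CGGTAGGCTTCTGTTAGCTCG  CTATCACGTTCGGCTCTGGTGC     102   488
#>   product_size  tm_f  tm_r tm_diff penalty
#> 1          478 51.68 50.65    1.04       0
#> 2          534 51.81 53.88    2.08       0
#> 3          387 50.29 53.24    2.96       0
```

Penalty 0 means the rank-1 pair meets every constraint; it is ranked
first because its Tm difference (1.04 °C) is the smallest among the
feasible candidates.  Preview the PCR and the gel:

```r
tab <- fit$ranking$table
amp <- simulate_pcr(tab$f_seq[1], tab$r_seq[1], fx$template)
amp[, 1:5]
#>           template_id start end length orientation
#> 1 fixture_L1000_n1_s8   149 626    478     forward
migration(amp$length)      # render units from the well, 100-bp ladder scale
#> [1] 42.23
render_gel(list(product = amp$length), gel_model(), "gel.txt")
report(fit, "design_report.txt")   # full plain-text report
```

A thin command-line front end with `design`, `batch`, `check`, `pcr`,
`gel` and `fixture` subcommands is installed at
`inst/cli/evoprimer.R`.

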