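# glinet

Influential-node ranking for undirected, unweighted networks — protein–
protein interaction graphs, social networks, infrastructure graphs — from
**g**lobal and **l**ocal **i**nformation, with the epidemic-simulation
machinery needed to benchmark any ranking against ground truth.

## The score

Purely local centralities (degree) are cheap but coarse; global ones
(betweenness, closeness) are accurate but slow; the K-shell index is global
but assigns the same integer to whole layers of nodes. The GLI score
combines them. With $d(v)$ the degree, $maxD$ the network maximum degree,
$Ks(v)$ the K-shell (coreness) index and $n(v)$ the closed neighborhood
(node plus neighbors):

$$Jacc(v_i,v_j) = \frac{|n(v_i)\cap n(v_j)|}{|n(v_i)\cup n(v_j)|},\qquad
\Pi(v_j) = d(v_j)\,Jacc(v_i,v_j) + Ks(v_j)$$

$$I(v_i) \;=\; \underbrace{d(v_i) + \frac{1}{maxD}\sum_{v_j\in\Gamma(v_i)}\Pi(v_j)}_{Local(v_i)}
\;+\; \underbrace{Ks(v_i)}_{Global(v_i)}$$

Higher $I$ = more influential. The Jaccard weight makes neighbors with the
same degree and shell contribute differently, which breaks the K-shell
ties; isolated nodes score exactly 0 and cause no failures.

Alongside the scorer the package provides: plain-text edge-list I/O,
bucket-peeling K-shell decomposition, classical baselines (degree,
closeness, betweenness, eigenvector, PageRank, K-shell), discrete-time
stochastic SIR/SI simulators measuring per-node spreading power, a Kendall
tau-a evaluation harness with infection-probability sweeps, seeded
synthetic-network generators, and a packaged 15-node worked example.

## Worked example

```r
library(glinet)

g <- worked_example_graph()          # 15 nodes, 20 edges, 3 K-shell layers
fit <- gli(g)
fit
#> GLI influence scores: 15 nodes, 20 edges (maxD = 6)
#>  node P      Sum        N    Local Global        I rank
#>    v1 6 25.82937 4.304894 10.30489      3 13.30489    1
#>    v2 5 25.03571 4.172619  9.17262      3 12.17262    2
#>    v4 5 19.11905 3.186508  8.18651      3 11.18651    3
#>    v3 4 19.11429 3.185714  7.18571      3 10.18571    4
#>    v8 5 16.20476 2.700794  7.70079      2  9.70079    5
#>  ...
```

Node v1 has degree 6 (the network maximum), sits in shell 3, and its six
neighbors donate given values summing to 25.829365, so
`I = 6 + 25.829365/6 + 3 = 13.304894` — the top score. Benchmarking a
ranking against epidemic ground truth:

```r
pw <- spreading_power(g, alpha = 0.1, beta = 1, iterations = 1000, seed = 1)
kendall_tau(coef(fit), pw[names(coef(fit))])
#> Kendall tau-a: 0.847619 (n = 15, concordant = 96, discordant = 7)
```

and a full method comparison over an infection-probability grid:

```r
alpha_sweep_kendall(g, list(gli = fit, dc = baseline_scores(g, "dc")),
                    alphas = c(0.05, 0.10), iterations = 1000, seed = 1)
#>   method alpha       tau
#> 1    gli  0.05 0.8285714
#> 2     dc  0.05 0.8000000
#> 3    gli  0.10 0.8476190
#> 4     dc  0.10 0.8000000
```

A command-line interface wraps the same functions
(`Rscript inst/cli/glinet.R score network.edgelist --method gli`); see
`?run_glinet` for the subcommands.

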