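# miwe — mutual-information-weighted entropy for critical-transition detection

Staged biological systems — differentiating cell populations, progressing
tumours — often switch state abruptly: a stable pre-transition state, a
short unstable *critical state*, then a qualitatively different stable
state. Just before the switch, dynamic-network-biomarker (DNB) theory
predicts that a core group of genes shows sharply inflated variances and
mutual correlations while mean expression barely moves, so conventional
differential-expression analysis sees nothing. This package is for
analysts with staged (time-course or clinically staged) bulk or
single-cell expression matrices who want an early-warning score for that
transition and a ranked list of the genes driving it.

## The score

For each stage $T$ with samples $x_{ir}$ (gene $g_i$, sample $r$):

1. fit a Gaussian $(\mu_i, \sigma_i)$ per gene and map each value to the
   zero-truncated cumulative probability
   $P_i(x) = \Phi\big((x-\mu_i)/\sigma_i\big) - \Phi\big(-\mu_i/\sigma_i\big)$;
2. for each gene pair, compute the bivariate-normal rectangle probability
   $Q_{ij}$ on $[0,\bar g_i]\times[0,\bar g_j]$ with the within-stage
   Pearson correlation $\rho$, and the mutual-information edge weight
   $MI_T(g_i,g_j) = \sum_r Q_{ij} \ln\!\big(Q_{ij}/(P_i(x_{ir})P_j(x_{jr}))\big)$;
3. keep the strongest edges (top 10% of $|MI|$ by default, isolated nodes
   rescued) to form the stage network, and for every center gene $g^k$
   take its first-order neighborhood;
4. score each neighbor by its truncated differential entropy
   $DE_T(g_l) = -\int_0^{\bar g_l} f \ln f \,dx$ (closed form under the
   Gaussian fit);
5. the local score is $\mathrm{MIWE}_T^k = \sum_l W_T(g^k,g_l^k)\,DE_T(g_l^k)$
   and the global stage score is the mean over all centers.

A sharp increase of the global score flags the critical stage (fold-change
and sharpness gates, see the methods vignette); the top 5% of genes by
local score there are the *signaling genes*, and a separate screen finds
*dark genes* — no differential expression, strong score dynamics.

A built-in 10-node Michaelis–Menten regulatory-network simulator with a
fold bifurcation calibrated to sit exactly at control parameter $p = 0$
generates validation sweeps with a known tipping point.

## Worked example

Simulate the default validation sweep (16 stages spanning
$p \in [-0.5, 0.25]$, 50 samples each, intrinsic noise SD 0.05) and score
it:

```r
library(miwe)
model <- build_regnet_model()
sw  <- sweep_parameter(model, n = 50, seed = 1)
fit <- miwe(sw$set, run_gof = FALSE)
print(fit)
#> Mutual-information-weighted entropy fit
#>
#> Global score by stage:
#> p=-0.500 p=-0.450 p=-0.400 p=-0.350 p=-0.300 p=-0.250 p=-0.200 p=-0.150
#> -25.9693 -12.4031 -20.1914 -20.8577 -14.8658 -16.6446 -14.9285 -21.9790
#> p=-0.100 p=-0.050 p=+0.000 p=+0.050 p=+0.100 p=+0.150 p=+0.200 p=+0.250
#> -16.4003 -17.0691   6.8256 -16.8631 -16.4320 -14.3167 -13.8788 -14.1560
#>
#> Critical stage: p=+0.000
#> Signaling genes (top 5%): g1
```

The global score hovers at a low level through the sub-critical stages,
jumps by ~24 units exactly at the tipping point $p = 0$ — where the
marginally stable core produces strongly dispersed, strongly correlated
samples — and relaxes once the system settles in its new state. The
flagged stage is the simulator's known critical point, and the signaling
gene is one of the three core (DNB) nodes carrying the bifurcation.
(Scores are signed: entropies of tightly concentrated genes are negative,
and only the within-series dynamics are meaningful.)

On real data, build the input from files instead:

```r
mat <- read_expression("expression.tsv")
sm  <- read_stage_map("stages.tsv")
fit <- miwe(build_staged_set(mat, sm))
summary(fit); plot(fit)
```

or run everything from the shell via the bundled CLI
(`inst/cli/miwe.R run --matrix expression.tsv --stages stages.tsv`),
which also writes `miwe_scores.tsv`, the gene x stage local-score
landscape, the signaling-gene list and a JSON report.

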