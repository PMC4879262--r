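# finturing

Reaction–diffusion modelling of skeletal patterning in the catshark
(*Scyliorhinus canicula*) pectoral fin. The distal fin skeleton forms as a
curved row of nodular radials, prefigured by a periodic row of *Sox9*
expression spots. **finturing** implements the hypothesis that this row is
generated by a Bmp–Sox9–Wnt (BSW) Turing network — Bmp activates Sox9, Wnt
represses Sox9, Sox9 represses both diffusible ligands — spatially
organized by an FGF gradient from the distal fin edge, and simulates it on
growing unstructured triangular meshes of synthetic fin buds.

It is aimed at developmental/systems biologists who want to explore
gradient-modulated Turing patterning on realistic growing 2-D domains, and
at anyone needing a compact, fully scripted finite-volume
reaction–diffusion stack in R.

## The model

$$
\partial_t S = \beta (k_2 B - k_3 W),\qquad
\partial_t B = \beta (-k_4^{\rm eff} S - k_5 B + \alpha_B) + D_B\nabla^2 B,\qquad
\partial_t W = \beta (-k_7^{\rm eff} S - k_9 W + \alpha_W) + D_W\nabla^2 W,
$$

with a non-diffusive $S$ (Sox9), fast Bmp ($D_B = 160$) and slow Wnt
($D_W = 25$). An FGF field $F \in [0,1]$ (steady gradient from the tagged
distal "AER" arc, decay length $\sqrt{D_F/\mu_F} \approx 77.5$ units)
modulates the Sox9→ligand couplings,
$k_4^{\rm eff} = k_4(1-k_F F)$ and $k_7^{\rm eff} = k_7/(1-k_F F)$. Under
the model constraints the Turing space is the closed-form wedge

$$ D_W/D_B \;<\; \frac{k_3 k_7^{\rm eff}}{k_2 k_4^{\rm eff}} \;<\; 1, $$

and sweeping $F$ from 0 to 1 carries the fin parameter set into and out of
it — patterning is confined between two FGF thresholds, which is what
positions the spot row at a distance from the fin edge.

The package provides, as testable modules: synthetic fin-bud outline
series with posterior-biased growth; Delaunay meshing with tagged boundary
arcs; conservative growth maps (harmonic mesh deformation + exact
polygon-clipping transfer matrices) and virtual fate maps; a compiled
finite-volume Heun integrator with multiplicative noise; linear stability
analysis (dispersion relations, Turing-space scans, closed form vs numeric
cross-check); pattern metrics (segmentation, spot/stripe classification,
distal distances, phase correlations); and scripted control/perturbation
experiments (Bmp, Wnt, FGF inhibition), plus Gmsh MSH v2, VTK, CSV and
YAML-config I/O.

## Worked example

```r
library(finturing)

p <- bsw_preset("fin")
p
#> bsw_params: beta=8 k2=3 k3=1 k4=6 k5=0.1 k7=2.4 k9=0.1 alpha_B=0.1
#>   alpha_W=1.2 k_F=0.667 D_S=0 D_B=160 D_W=25

# the FGF path crosses the Turing space between two thresholds
v <- fgf_path_verdicts(p)
range(v$F[v$turing])
#> 0.12 0.96

# synthetic growing fin (three daily stages) and the control experiment
dom <- fin_domain()
dom$growth_map
#> growth_map: 3 stages (days 0..2), 1430--2717 triangles

rep <- run_control(dom$growth_map, seeds = 1:3)
rep
#> experiment 'control' (3 seeds)
#>   spots                        PASS
#>   intermediate_distance        PASS
#>   out_of_phase                 PASS

rep$per_seed[[1]]$summary
#> pattern: spots, 6 components, median elongation 1.67,
#>   largest area fraction 0.007, mean distal distance 6.84
```

The control fin forms a row of ~5–7 Sox9 spots at a mean distance of ~7
model units from the distal edge (proximodistal extent ~57), with ligand
fields anti-correlated with Sox9 (corr(S,B) ≈ −0.78, corr(S,W) ≈ −0.91):
the expression gaps of Bmp and Wnt coincide with the Sox9 spots, as in the
fin bud. `run_perturbation()` re-runs paired-seed simulations under Bmp,
Wnt or FGF inhibition, and `run_alpha_scan()` reproduces the
spots-versus-stripes dependence on the Wnt/Bmp production ratio on square
domains.

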