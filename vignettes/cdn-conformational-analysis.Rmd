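---
title: "Conformational analysis of cyclic di-nucleotides: models, fits and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational analysis of cyclic di-nucleotides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdnconf)
```

Cyclic di-nucleotides (CDNs) such as c-di-GMP, c-di-AMP and c-GAMP are
bacterial and metazoan second messengers: two nucleotides joined head-to-tail
by two phosphodiester bonds into a 12-membered sugar-phosphate macrocycle.
Their solution conformation — sugar pucker, glycosidic orientation, backbone
torsions — controls receptor recognition.  `cdnconf` implements the analytics
used to characterize that conformation from two complementary kinds of data:
conformer ensembles (e.g. filtered MD trajectories, multi-model PDB) and NMR
scalar coupling constants.  A synthetic-data module generates both kinds with
known ground truth, so every stage is testable without simulations or
spectrometers.

## Pseudorotation model

A furanose ring state is two numbers: phase angle $P$ and amplitude
$\psi_m$ (both degrees).  The five endocyclic torsions follow

$$\nu_j = \psi_m \cos\!\big(P + 144^\circ (j-2)\big), \quad j = 0,\dots,4,$$

so $\nu_2 = \psi_m \cos P$.  The inverse uses
$\tan P = \frac{(\nu_4+\nu_1)-(\nu_3+\nu_0)}{2\nu_2(\sin 36^\circ + \sin
72^\circ)}$, with the quadrant resolved by `atan2` on the sign of $\nu_2$
(the $\nu_2 = 0$ case lands on the $P = \pm 90^\circ$ branch; there is no
division).  On noise-free input the round trip is exact to $10^{-9}$ degrees
(tested on a 1-degree grid).  North-type sugars (C3'-endo-like) have $P$
near 0, South-type (C2'-endo-like) near 160.

Classification conventions (all angles wrapped to $[-180, 180)$):
N iff $P \in (-90, 90]$; *syn* iff $\chi \in (-90, 90]$; rotamers
$g^+ / t / g^-$ on $[0,120) / [120,240) / $ else.  Boundary angles belong to
the left-closed class — a convention chosen once so tests are
deterministic; the N/S boundary at $\pm 90^\circ$ is wider than the
"$-60$ to $60$" N-type band seen in well-behaved ensembles because
classification must be total over all $P$.

## Karplus registry

Three-bond couplings relate to the intervening torsion $\phi$ by
$J(\phi) = A\cos^2\phi + B\cos\phi + C$, optionally plus generalized
substituent corrections
$\sum_i \Delta\chi_i\,[D_i + E_i \cos^2(\xi_i \phi + F_i |\Delta\chi_i|)]$.
No single agreed coefficient set exists for these fragments, so the package
ships a named registry (`inst/extdata/karplus_params.json`) with literature
defaults, swappable without code changes:

* H-C-C-H ribose pairs: the Haasnoot–de Leeuw–Altona generalized form,
  $A,B,C = 13.70, -0.73, 0$ with $D,E,F = 0.56, -2.47, 16.9$ and group
  electronegativities O $1.27$, N $0.85$, C $0.68$.  The orientation signs
  $\xi_i$ per pair are idealized $\beta$-D-ribonucleoside defaults — they
  shift predictions by tenths of Hz and do not affect the diagnostic
  N/S orderings.
* H-C-O-P: $15.3, -6.1, 1.6$; C-C-O-P: $6.9, -3.4, 0.7$ (the
  phosphate-fragment parametrizations of the Lankhorst /
  Plavec–Chattopadhyaya lineage).
* H4'-H5'/H5'': a plain $10.2, -0.8, 0$ set.  With the proton-torsion map
  $\phi_{45'} = \gamma$, $\phi_{45''} = \gamma - 120^\circ$ this predicts
  both couplings below 4 Hz at the canonical $g^+$ rotamer
  ($\gamma = 53^\circ$) — the constraint that identifies a pure $g^+$
  population.

The proton-torsion map for the ribose pairs is affine in the governing
endocyclic torsion: $\phi_{1'2'} = 121.4 + 1.03\,\nu_1$,
$\phi_{2'3'} = 2.4 + 1.06\,\nu_2$, $\phi_{3'4'} = -124.0 + 1.06\,\nu_3$
(standard two-state pseudorotation-analysis conventions).  Backbone
fragments use idealized staggered offsets: for $\beta$ (P-O5'-C5'-C4'),
C4'P at $\beta$, H5'P at $\beta + 120$, H5''P at $\beta - 120$; for
$\epsilon$ (C4'-C3'-O3'-P), C4'P at $\epsilon$, C2'P at $\epsilon + 120$,
H3'P at $\epsilon - 120$.  Because every individual Karplus curve is even
in $\phi$, a single coupling cannot distinguish $\phi$ from $-\phi$;
combining fragments with distinct offsets breaks that degeneracy, which is
what makes a unique best backbone candidate well-posed.

$^4J_{H-P}$ couplings are accepted in input tables as annotations but are
not modelled by any Karplus form.

## Coupling fits

**Two-state pucker fit.** Observed ribose couplings are modelled as a
population-weighted average of a variable North state and a fixed South
state, $J = f_N J(P_N, \psi_N) + (1-f_N) J(P_S, \psi_S)$, with
$(P_S, \psi_S) = (163^\circ, 38^\circ)$ held fixed at all temperatures
(whether the minor state should be temperature-adjusted is unknown; fixing
it is the documented choice).  The objective is multimodal in $P_N$, so the
fit is multi-start: a coarse grid over
$P_N \in [-90, 90]$, $\psi_N \in [25, 50]$ (typical furanose amplitudes,
adopted as a package default), $f_N \in [0, 1]$ seeds L-BFGS-B refinements and
the best local solution wins.  Couplings are equally weighted unless
uncertainties are supplied (then inverse-variance).  With fewer couplings
than free parameters the fit refuses to run and names the parameters to fix.

**Gamma rotamer fit.** Three canonical rotamers at $53, 180, -70$ degrees
are assumed; fractions solve the simplex-constrained least-squares problem
exactly, by enumerating the faces of the 2-simplex and solving each face's
equality-constrained problem in closed form (KKT).  No iteration, no grid:
the result matches a 0.005-step simplex-grid brute force to its resolution.

**Backbone torsions.** $\beta$ and $\epsilon$ are scanned on a 1-degree
grid over $[-180, 180)$; all circular local minima within twice the global
minimum residual are reported (Karplus curves are multivalued), best first.

## Free-energy landscapes

Populations on the $(\chi, P)$ plane convert to free energies by
$G_i = -k_B T \ln(N_i / N_{\max})$, $k_B = 0.0019872$ kcal mol$^{-1}$
K$^{-1}$: the most populated bin sits at exactly $G = 0$, and empty bins
are undefined (`NA`), never 0.  The default grid is $72 \times 72$
(5-degree bins); published landscapes show their grids only graphically,
so this is a recorded default, not a claim.  Basins are connected components
(8-neighbour, periodic in both axes) of bins below a depth threshold; basin
structure is meaningful only on well-sampled landscapes, since isolated
occupied rim bins otherwise count as basins.

## Structure comparison

Superposition is Kabsch/SVD with reflections excluded — molecular
chirality must never be inverted.  The three-tier report superposes
*per tier* (each tier is superposed on its own atoms before measuring):
overall = all heavy atoms, macrocycle = exactly the 12 ring atoms (P, O5',
C5', C4', C3', O3' from each nucleotide), base = nucleobase heavy atoms.
Backbone-RMSD conventions differ between studies (superpose on the backbone
versus on all atoms first); per-tier superposition is this package's
documented choice.  Mixed-base comparisons (c-GAMP against a homodimer) require an
explicit residue pairing; there is no automatic best-of-two-pairings
search.

## Synthetic data: the stated world

`sample_torsion_ensemble()` draws each torsion from a mixture of von Mises
(circular-normal) components.  The packaged CDN-like spec uses the
published per-CDN means: $\alpha\,75$, $\beta\,-172$, $\gamma\,53$,
$\delta\,84$, $\epsilon\,-155$, $\zeta\,70$, anti-$\chi$ at $-149$
($=211$), pucker $P$ at $10$ degrees.  Concentrations are not printed
anywhere (the distributions exist only graphically), so they are chosen
once: $\kappa = 50$ (about 8-degree spread) for the backbone's tight
unimodal wheels, $\kappa = 20$ for $\chi$ and $P$.  Purine-like specs add
a syn mode at $+60$ whose weight follows a 1 kcal/mol free-energy gap at
300 K ($w_{syn}/w_{anti} = e^{-\Delta G / k_B T} \approx 0.187$),
mirroring the two-state purine landscapes; pyrimidine-like specs are
unimodal anti.  Generators are pure functions of (spec, seed).

`synthetic_supplementary_couplings()` forward-models per-CDN coupling
tables from the published fitted parameters (Table values for $P_N$,
$\psi_N$, $f_N$, $\beta$, $\epsilon$; pure $g^+$ for $\gamma$) through the
package's own Karplus registry.  This is a synthetic stand-in for the
original (non-redistributable) supplementary tables: green
table-reproduction tests establish that the inference machinery inverts
its forward model at the published parameter values — not agreement with
the original spectra, which would additionally require the authors' exact
Karplus coefficients.

`build_macrocycle_template()` constructs coordinates by sequential
internal-coordinate placement (ideal bond lengths and tetrahedral angles).
Neither the 12-membered macrocycle nor the furanose ring is closed: it is
a test fixture for torsion extraction and superposition, not a model
builder.  Torsions on the construction tree ($\beta,\gamma,\delta$ of both
residues, $\epsilon/\zeta$ of residue 1, $\alpha$ of residue 2, $\chi$,
$\nu_0$, $\nu_4$) are realized to $10^{-3}$ degrees; $\nu_1$–$\nu_3$
follow only approximately from the open-ring geometry.

## Numerical conventions

Angles in degrees, wrapped to $[-180, 180)$ everywhere; couplings in Hz;
energies in kcal/mol; coordinates in Angstrom.  Reported fit angles are
rounded to the nearest degree only for table comparison — full precision
is retained internally.  Backbone candidate filtering uses
$\mathrm{rmsd} \le 2\,\mathrm{rmsd}_{\min} + 10^{-9}$ so that an exact fit
(global residual 0) keeps only exact co-minima.

## Known limitations

* **$P_N$ identifiability near pure N-type.**  With three ribose couplings
  and 0.2 Hz noise, the median error of the recovered $P_N$ is about
  7 degrees, not the 3 degrees one might hope for.  This is not an
  optimizer artifact (the multi-start fit reproduces a brute-force
  0.5-degree grid's global minimum): near $P = 0$, $J_{1'2'}$ sits on the
  flat 90-degree region of its Karplus curve and
  $\partial\nu_2/\partial P = 0$, so the coupling-to-parameter Jacobian is
  ill-conditioned.  Population fractions $f_N$ are much better determined
  (median error about 0.02).  The corresponding acceptance test asserts
  the stricter bound and fails honestly.
* The macrocycle template is not ring-closed and carries only three-atom
  base stubs; it supports geometry tests, not energetics or visualization
  of realistic molecules.
* Frames are equally weighted throughout; trajectory reweighting across
  temperatures is out of scope, as is running any sampling itself.
* The landscape bin width and the von Mises concentrations are package
  defaults standing in for distributions that exist only graphically in
  published work.
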