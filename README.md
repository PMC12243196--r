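# ssnsubfam

Subfamily delineation for large protein families by sequence similarity
networks (SSNs) scored with closeness centrality, modelled on the analysis
used to divide glycoside hydrolase family 2 (GH2) into subfamilies, plus the
Michaelis–Menten kinetics computations used to characterize members of new
subfamilies.

## Who this is for

Curators and comparative genomicists who need to split a family of
thousands of homologous enzymes into functionally coherent subfamilies when
multiple alignments and phylogenies no longer scale. The package provides
the whole computational path — sequence curation, all-vs-all similarity,
threshold selection, rule-based subfamily release, descriptive summaries —
as tested, deterministic R functions, with a synthetic-family generator so
every stage can be validated against planted ground truth.

## The method

Nodes are domain sequences; an edge joins two sequences when the better of
their two directed alignments has E-value ≤ 10⁻ᵉ. For each threshold
exponent e = 20 … 99 (80 networks) the package scores the network by the
weighted average closeness centrality of its connected components

    W = (1/n) Σ_C Σ_{v∈C} (n_C − 1) / Σ_{u∈C} d(v,u)

(singletons contribute 0). Sharp rises of W between consecutive thresholds
("peaks") mark separations of large groups; the division threshold is the
exponent with maximal W. Components at that threshold are released as
subfamilies when they hold ≥ 30 post-redundancy representatives or at least
one experimentally characterized member; smaller uncharacterized groups are
withheld. Upstream, sequences are kept when they cover ≥ 50 % of the family
profile HMM and collapsed at 80 % identity by greedy longest-first
clustering; similarity comes from an internal Smith–Waterman aligner with
Karlin–Altschul statistics (E = K·m·n·e^(−λS)) or from DIAMOND/BLAST
12-column tabular files.

The kinetics module fits v = E₀·kcat·S/(K_M + S) by Levenberg–Marquardt
least squares (bench units: S in mM, E₀ in µM, kcat in min⁻¹, K_M in µM)
and, for enzymes that cannot be saturated, estimates kcat/K_M from the
slope of v on S through the origin, reported in M⁻¹·s⁻¹ via
kcat/K_M = (kcat/60)/(K_M·10⁻⁶).

## Worked example

The `analysis/` directory is a five-stage workflow over a simulated
GH2-like family with planted structure (7 subfamilies nested in 3
supergroups, exact duplicates and low-coverage fragments included). Run the
stages in order from the repository root:

```sh
Rscript analysis/01_simulate_family.R
Rscript analysis/02_prepare_sequences.R
Rscript analysis/03_ssn_sweep.R
Rscript analysis/04_subfamilies.R
Rscript analysis/05_kinetics.R
```

Stage 3 sweeps the 80 thresholds and prints:

```
Swept 80 thresholds; criterion peaks at 1e-29, 1e-59.
Selected division threshold: 1e-59 (W = 1.0000, 7 components).
```

i.e. the criterion first jumps when the three supergroups separate, and
reaches its maximum when the seven subfamilies individualize. Stage 4
releases the subfamilies, expands membership through the redundancy
clusters, and checks the recovered partition against the planted truth:

```
subfamily partition at 1e-59: 7 released, 0 withheld, 0 singleton(s) [expanded to full membership]
Released 7 subfamilies covering 100.0% of the family;
  adjusted Rand index vs planted truth: 1.000
```

Stage 5 reproduces the kinetics table computations — e.g. a saturating
enzyme fitted from triplicate rates over 0.025–14 mM:

```
SsGH2_7 : MM fit: kcat = 4.63 1/min, KM = 93.7 uM, kcat/KM = 824.3 1/(M s)
kcat = 4.6 1/min, KM = 93 uM converts to 824 1/(M s).
```

All outputs land as TSV/CSV/JSON under `results/`.

## Layout

- `R/`, `src/` — package code (the compiled Gotoh/identity aligners live in `src/`)
- `analysis/` — the numbered workflow scripts above
- `tests/testthat/` — unit, property and end-to-end tests with brute-force oracles
- `vignettes/ssn-subfamily-delineation.Rmd` — the methods vignette
- `inst/extdata/` — the printed kinetic-parameter table used as input
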