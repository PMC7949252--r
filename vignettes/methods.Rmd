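---
title: "Evidence-based metabolic network reconstruction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based metabolic network reconstruction: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmforge)
```

This vignette explains the science implemented by `gsmforge`: what each
stage assumes, which parameters matter and why their defaults are what
they are, what the synthetic data generator does and does not emulate,
and where the genuinely open design decisions were resolved.

## From homology hits to reaction presence

The unit of evidence is a homology hit of a reference protein sequence
against a genome, summarised by its bitscore, the fraction of the
reference covered, and percent identity. A hit is a *match* when the
bitscore is at least 200 bits and coverage at least 75%; individual
reactions can carry stricter per-reaction criteria (e.g. minimum
identity 75%) for enzyme families where coarse homology is misleading.
Per reaction, the evidence table keeps the best bitscore $b_i$ over all
hits mapped to it. Reference sequences that map to several reactions
contribute their score to each of them.

One deliberate choice: $b_i$ is the maximum bitscore over *all* hits,
regardless of coverage — coverage gates only the binary match call.
The gap-filling weights (below) are meant to encode graded sequence
evidence, and a high-scoring partial alignment is still evidence; the
binary inclusion decision is where the conservative coverage filter
belongs.

### Protein complexes

A single good hit is weak evidence for a multi-subunit enzyme. Subunit
structure is therefore mined from the reference FASTA headers
(keywords *subunit*, *chain*, *polypeptide*, *component*; roman, greek,
arabic and letter numbering homogenised to arabic labels). Two filters
guard against text-mining artefacts: labels occurring fewer than 5
times in a reference set are ignored, and when one label covers at
least 66% of the labelled entries the minority labels are dropped. The
66% rule is evaluated over labelled entries only, after the
frequency-floor demotion — the order of the two filters is not
canonical, but this order is stable under adding unlabelled noise
sequences, which is the direction real reference sets grow. A complex
is present when more than half of its recognised subunits have a
matching hit; at exactly half, a matching hit in the undefined-subunit
pool tips the balance. A tie with undefined entries present but none
matching stays *absent*: the tie-breaker is a positive signal, not a
benefit of the doubt.

### Pathways

A pathway is present when at least 80% of its reactions are found
(`completeness_cutoff_no_hints`). Two relaxations apply. If the pathway
defines key reactions and *all* of them are found — strictly found, a
vague or spontaneous key does not count — 2/3 completeness suffices.
Reactions with no reference sequences at all are *vague*; when they
make up strictly less than 1/3 of a pathway they are excluded from the
denominator rather than counted as missing. Excluding them from the
denominator (rather than counting them as found) keeps completeness an
estimate of what homology actually supports; both readings exist and
the cutoffs are exposed as `pathway_params()`. Spontaneous reactions
are present in any case.

## Draft assembly and provenance

Every reaction in a model records why it is there (`gs_origin`):
directly matched enzymes, present complexes, selected transporters and
spontaneous reactions get 0; members of present pathways without a
direct match get 9; the biomass reaction 6; exchanges 7; membrane
diffusion 8; gap-filling steps stamp 1–4. When several rules apply the
lowest code wins, so "direct evidence" always trumps "pathway
completion". Two infrastructure choices: an ATP maintenance reaction
(non-growth-associated ATP hydrolysis) is always included and stamped 6
alongside biomass — without an ATP sink independent of growth, testing
the producibility of a single biomass component is structurally
infeasible in any network whose catabolism is ATP-positive — and the
diffusion list (H₂, O₂, CO₂, H₂O, NH₃) is configurable.

GPR expressions are assembled from the passing reference sequences: one
pseudo-gene per sequence, OR-joined; for complexes, subunit groups are
AND-joined with OR within a group. How the original pipeline builds its
GPRs is not documented at this level; this construction is the simplest
one that makes gene-deletion analysis exercisable and is flagged as a
package-specific convention.

Gram staining selects between the two biomass templates
(peptidoglycan-heavy + teichoic acids vs. lipopolysaccharide). It is a
required parameter with default `"negative"`; inferring it from 16S
sequences is deliberately out of scope (it needs curated reference
data), and the parameter is the documented hook.

## Constraint-based core

All analyses share steady-state mass balance $S v = 0$ with flux bounds
±1000 mmol gDW⁻¹ h⁻¹ for "unbounded" reactions (the community
convention). FBA maximises an objective flux; MTF (pFBA) fixes the
objective at its optimum (relative slack 10⁻⁹) and minimises total
absolute flux, which silences zero-gain loops; FVA reports per-reaction
flux ranges at the constrained optimum. The LPs run on a built-in
two-phase bounded-variable primal simplex (dense algebra, Bland's rule
under degeneracy) — at this package's model sizes (tens to a few
hundred variables) a textbook simplex is exact, fast, and dependency
free. `|v|` terms are linearised with nonnegative split variables;
because every weight is positive, split-variable complementarity holds
automatically at the optimum.

The evidence-weighted gap-filling LP maximises
$v_{\mathrm{obj}} - c \sum_i w_i |v_i|$ with $c = 0.001$ and the
piecewise-linear weight ramp from $w_{\max} = 100$ below 50 bits to
$w_{\min} = 0.005$ above 200 bits; draft reactions always get
$w_{\min}$. Reactions absent from the evidence table get the
no-evidence branch ($w_{\max}$): no evidence means maximum penalty. The
weighted-flux sum runs over *all* reactions including exchanges and
biomass — exchanges belong to every draft (code 7) and so carry
$w_{\min}$ in practice; an `exempt_exchanges` flag exists for networks
where that does not hold. Flux above 10⁻⁶ counts as "carries flux";
this tolerance is not specified upstream and is exposed in
`gapfill_params()`.

Alternate optima are a fact of LP-based gap-filling. Tests therefore
assert properties of the solution (growth restored, total weight of the
added set optimal against brute-force subset enumeration) rather than
exact flux vectors, except on fixtures constructed to have unique
optima.

## The four-step protocol

Step 1 makes biomass feasible on the gap-filling medium using the full
universal reaction set (a complete medium if none is given). Steps 2–4
may only add *core* reactions — best bitscore strictly greater than 50
bits — so they never invent capabilities without genomic support:
step 2 checks each biomass component with a temporary sink on a minimal
medium, with and without oxygen (facultative anaerobes); step 3 checks
alternative energy sources by inserting three temporary
electron-carrier recycling reactions (menaquinol → menaquinone + 2H⁺,
quinol → quinone + 2H⁺, NADH → NAD⁺ + H⁺) and maximising their summed
flux — an in-silico analogue of BIOLOG redox-dye assays; step 4 checks
product formation on the original medium. The oxygen alternation is
implemented for step 2 only, as specified; whether it should extend to
steps 3–4 is left open upstream. Components that would need non-core
reactions stay unresolved and are reported, not fixed — that is the
point: steps 2–4 reduce the dependence of the final model on the
particular gap-filling medium. Temporary sinks and recycling reactions
never remain in a returned model.

## Phenotypes

Carbon-source utilisation uses the same recycling-reaction trio (one
source of truth for their stoichiometry, `esp_reactions()`): a
substance is utilisable when, on mineral medium plus that substance,
the summed recycling flux is positive. All secretion bounds stay open
during the test — the upstream description does not constrain
by-products, and closing secretion would reject fermentative
utilisation. Fermentation products are the exchanges with positive MTF
flux, normalised by growth rate to mmol gDW⁻¹, with an FVA maximum at
100% of the growth optimum ("across all optimal solutions" read as the
optimal face, not suboptimal ones). Gene essentiality closes every
reaction whose GPR evaluates false under a single-gene deletion and
calls the gene conditionally essential below 0.01 h⁻¹; the toy truth
table is insensitive to moving that threshold across 0.001–0.05 because
the fixture has no intermediate growth rates. GPR equivalence is an
exhaustive truth-table comparison over the union of gene ids, capped at
20 genes (2²⁰ assignments).

## Similarity of fragmented-genome models

For a model built from a species-level genome bin, similarity to a
reference panel is the frequency-weighted recall
$\sum_i a_i b_i / \sum_i b_i$ over the union of *gene-associated*
reference reactions ($b_i$ = fraction of reference models containing
reaction $i$, $a_i$ = membership in the query). "Gene-associated" is
implemented as a non-empty GPR, which excludes biomass, exchange, and
diffusion pseudo-reactions by construction. The score is monotone in
the query's reaction set and blind to reactions outside the union set.

## The synthetic study system

`make_toy_world()` builds a 42-reaction, 54-metabolite bacterium-like
chemistry: compressed glycolysis (with phosphoenolpyruvate explicit,
because the glucose PTS needs it), pyruvate dehydrogenase *and*
pyruvate-formate lyase, a compressed TCA cycle, a proton-pumping
respiratory chain with quinone and NADH pools, a reversible F1F0 ATP
synthase, lactate/acetate/ethanol fermentation branches, pentose and
polyol routes, nine transporters across TC classes 2–4, the
five-compound diffusion list, and eight-component Gram-positive and
Gram-negative biomass templates (40 mmol ATP gDW⁻¹ growth-associated
maintenance). Design invariants, all enforced by tests: every non-pseudo
reaction is mass- and charge-balanced (real elemental formulas
throughout); the closed-exchange ATP maximum is zero (no
thermodynamically infeasible energy-generating cycles — a deliberately
corrupted variant with an erroneous acetate uniporter exists to test
the validator); and biomass is producible aerobically and anaerobically
on glucose minimal medium. Three details exist because the invariants
forced them, and they are biologically the right details: formate lyase
(anaerobic acetyl-CoA without NADH), the reversible ATP synthase
(fermenting cells extrude protons by ATP hydrolysis), and import-only
amino-acid permeases (a reversible alanine symporter would act as a
spurious redox valve).

Organism profiles plant ground truth: `complete` (draft grows without
gap-filling; 4 of 6 pathways present), `single_gap` (peptidoglycan
synthase evidence at 150 bits — below the 200-bit cutoff but well
inside the weight ramp, so step 1 adds exactly that reaction),
`fermenter` (no respiration, Gram-positive), `auxotroph` (alanine
synthesis core-resolvable in step 2, glutamate auxotrophy persists),
and `fragmented(p)` (each hit dropped independently with probability
*p*; because the dropout draws are nested across *p* at a fixed seed,
similarity scores are exactly monotone per seed). Strong hits are drawn
at 250–350 bits / 80–95% coverage and sub-threshold hits at 110–150
bits so that seed jitter can never flip a planted call.

What the generator does **not** emulate: real sequence alignment (hit
tables are the interface; an external aligner adapter is documented but
not exercised), genome structure, paralogy and horizontal transfer,
promiscuous enzymes, regulatory effects on expression, and the sheer
scale of real biochemistry databases (~10⁴ reactions). Passing tests
therefore demonstrate the correctness of the decision rules and
optimisation machinery, not the field accuracy of reconstructions from
real genomes.

## Numerical choices and problem sizes

Simplex tolerances: 10⁻⁹ optimality/feasibility, 10⁻¹⁰ pivot; the
closed-system ATP check uses tolerance 10⁻⁹ (the curation criterion's
tolerance is not stated upstream; this value is documented and
configurable). Variable order in the gap-filling LP is lexicographic by
reaction id, making added sets deterministic. Ties in the leaving-
variable rule break toward the smallest reaction index (Bland) under
degeneracy. The test suite runs the full pipeline on models of ~60
reactions, FVA over all reactions, 200-draw monotonicity scans, and
20-seed fragmentation series; the complete suite takes about a minute
on one CPU.

## Known limitations

Two compartments only (no periplasm); exchange-driven proton artefacts
are possible in principle in any FBA model with open proton exchange —
here the curation validator (zero closed-system ATP) plus irreversible
proton pumps bound them; MILP-style minimal gap-fill sets, loopless
FBA, and thermodynamic constraints are out of scope; the CLI reads the
package's own exchange formats, not arbitrary external databases.
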