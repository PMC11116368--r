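---
title: "Comparing community genome-scale metabolic models: methods and design choices"
author: "commgem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing community genome-scale metabolic models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commgem)
```

## The problem

Automated reconstruction tools turn a genome (here, typically a
metagenome-assembled genome, MAG) into a genome-scale metabolic model
(GEM): a set of metabolites, stoichiometric reactions with flux bounds,
gene-protein-reaction (GPR) rules, and a biomass objective. Different
tools lean on different biochemical databases and different
gene-to-reaction mappings, so models of the *same* genome can disagree
substantially — in reaction content, in gene coverage, in the number of
dead-end metabolites, and ultimately in the metabolite exchanges a
community simulation predicts. `commgem` implements the comparison
workflow for this situation: harmonize identifiers, build a per-genome
consensus model, make every model growth-capable by community-aware
gap-filling, and quantify the structural and functional differences
between the reconstruction approaches.

## Model representation and structural diagnostics

A model is an S3 list (`gem_model`) of metabolites (id, name, formula,
charge, compartment), reactions (signed stoichiometry, bounds in
mmol·gDW⁻¹·h⁻¹, GPR string, EC numbers, functional kind, contributing
tools), a gene set, and an objective. Metabolite ids carry their
compartment as an `@<code>` suffix (`MNXM2@c`), one cytosolic and one
extracellular compartment per organism model. Reaction kinds are
inferred structurally: the objective is `biomass`; `EX_`/`SK_`-prefixed
single-metabolite reactions are `exchange`/`sink`; a reaction moving one
species across compartments is `transport`. When SBML omits flux bounds
they default to ±1000.

**Dead-end metabolites.** A metabolite is a dead end when it has no
potential producer or no potential consumer under the directions the
bounds allow; boundary (exchange/sink) reactions count as
producers/consumers. "Produced-only or consumed-only" is a genuine
modelling choice — the weaker "produced-only" and "consumed-only"
variants are also defensible — and we adopt the symmetric definition
because it is the common root/dead-end convention and makes the
dead-end counts of all four approaches directly comparable.

**Mass/charge balance.** Per-element signed sums of
coefficient × element-count (formulas parsed with parenthesized-group
support); a reaction is balanced iff all element sums and the charge sum
vanish. Exchange, sink, and biomass reactions are exempt by design; any
empty or unparsable formula yields an `undetermined` verdict rather than
a guess.

## Namespace harmonization

Cross-reference tables (TSV: `source_namespace`, `source_id`,
`common_id`; `#` comments allowed) map tool-specific identifiers to a
common reference namespace. Translation preserves compartment suffixes,
fuses metabolites that collapse onto one common id (rewriting
stoichiometries, dropping exactly cancelling coefficients, and removing
and logging reactions left empty), and keeps gene sets untouched.

Identifiers without a mapping are *retained* with an
`unmapped:<tool>:` prefix rather than dropped. This is deliberate:
Jaccard comparisons between tools should penalize namespace gaps the
same way incomplete cross-references penalize real draft models. Ids
that are already common (or already prefixed) pass through unchanged,
which is what makes translation idempotent.

## Consensus merging

Views are first stripped of exchange, sink, and biomass reactions — each
tool's boundary conventions and biomass formulation would otherwise
contaminate the merged network — and then folded into the consensus in a
fixed order (conventionally carveme, gapseq, kbase). Two reactions are
duplicates when they share an id or an identical canonical
stoichiometry: metabolite ids sorted, coefficients rescaled to the
lexicographically first metabolite, and orientation normalized so that a
conversion written in either direction gets one canonical key (scalar
multiples are therefore also duplicates). Exact negations are
`duplicate_reversed` and merge after negating the later reaction.

Merging a duplicate widens the bounds to the union of allowed
directions, ORs the GPR rules when their truth tables differ (keeping
the first form when they are logically equivalent), and unions EC
numbers and tool provenance. Metabolite attribute conflicts resolve
first-seen-wins and are logged — except that when duplicate candidates
disagree on the mass-balance verdict, the balanced variant's formula
annotations are adopted; the comparison criteria include mass balance
but no resolution rule, so an explicit one is declared here. The
consensus gene set is the exact union of the views' gene sets, and the
consensus dead-end set can only shrink relative to the views
(`consensus_dead_end_audit()` verifies both properties and is used as a
test oracle). Merged content is order-insensitive at the level of the
canonical stoichiometry digest, although kept reaction ids follow
first-seen order.

## Community gap-filling

Every draft model receives the same universal biomass reaction (the
fixtures use a small acetyl-CoA + alanine + magnesium demand; in
practice any composition table can be supplied), so growth demands are
comparable across approaches. Gap-filling then searches a universal
reaction database for a minimum-weight set of additions that lets the
model reach a biomass flux of at least ε:

* one binary indicator per candidate database reaction, linking
  constraints `lb·y ≤ v ≤ ub·y`, steady state `S v = 0`, biomass ≥ ε;
* objective `min Σ wᵢ yᵢ` with default weights 1, solved exactly by
  branch-and-bound on the LP relaxation (`relaxed = TRUE` switches to
  the LP relaxation alone, which is faster but loses the minimality
  guarantee);
* ties between equal-weight solutions break deterministically to the
  lexicographically smallest sorted reaction-id set, found by scanning
  candidates in id order and forcing each one in whenever a
  minimum-weight solution still contains it;
* added reactions carry no GPR (no genetic support), and exchange
  reactions opened for medium metabolites are infrastructure, never
  counted as additions;
* if even the full database cannot reach ε, the error names the blocked
  biomass precursors, isolated by per-precursor sink relaxation.

Defaults: ε = 0.05, flux tolerance 1e-6, pool uptake rate 10 — all
exposed as arguments and in the pipeline config, since no standard
values exist for these quantities.

**Iterative community gap-filling.** Members are processed in abundance
order (descending or ascending; ties break by member id for
determinism). The first member is gap-filled on the initial rich
(LB-like) medium; every later member on the minimal (M9-like) base
medium, with uptake reactions for all previously predicted permeable
metabolites added *to the candidate database* — importing a community
metabolite is a solution the optimizer may choose, and it costs one
addition like any other candidate. After each successful gap-fill the
member's permeable metabolites — extracellular metabolites whose sink
flux can exceed the tolerance while biomass stays ≥ ε — are predicted,
sinks are installed for them (defining the member's exported set), and
the shared pool grows monotonically. Metabolites the member can already
import are excluded from the permeable candidates: routing a medium
nutrient straight back out through a sink is a loop artifact, not
secretion of a synthesized product. Infeasible members are recorded and
the pipeline continues (`fail_fast` flips this).

The package's toy media are stand-ins: the rich medium is glucose,
ammonium and magnesium at high rates, the minimal medium the same at
lower rates. Real LB/M9 composition tables can be supplied as TSVs;
none are shipped because curated compositions are context-dependent.

## Flux analysis

FBA maximizes the objective subject to `S v = 0`, bounds, and
medium-derived exchange bounds; FVA reports per-reaction flux ranges,
optionally at a fraction of the FBA optimum. Blocked reactions are
those whose FVA range at fraction 0 is numerically zero: the blocked
filter asks about structural capability, not activity at optimal
growth, so no growth constraint is imposed (the fraction is an argument
for users who want the stricter question). Export flux ranges fix the
objective at its optimum (fraction 1) and scan the sink reaction of
each exported metabolite.

LPs are solved by an in-package two-phase dense tableau simplex
(Dantzig pricing, automatic Bland's-rule retry on stall, explicit
infeasible/unbounded statuses), with variables shifted by their lower
bounds and bounds clamped to ±1e6. A dense tableau is entirely adequate
at the problem sizes this package targets (tens of reactions per model);
for genome-scale inputs with thousands of reactions a sparse
revised-simplex or interior-point solver would be the right tool, and
the LP layer is isolated behind `solve_lp()`/`solve_milp()` so swapping
one in is local surgery.

## Comparison statistics

* **Jaccard similarity** `|a∩b| / |a∪b|` (defined as 1 for two empty
  sets) over reaction, metabolite, dead-end, or gene sets of models
  sharing a MAG.
* **EC-subclass enrichment**: EC numbers truncated to the enzyme
  subclass (first two numeric fields; partial codes like `3.-.-.-` are
  discarded). For a target set inside a background set, the population
  is the background reactions carrying at least one valid subclass; a
  reaction with ECs in several subclasses counts once per subclass
  (whether multi-EC reactions should be deduplicated is undocumented in
  the workflows this mirrors, so the rule is declared here). The
  p-value is the hypergeometric upper tail `P[X ≥ k]`, computed through
  the log-space-stable distribution function, with Benjamini–Hochberg
  adjustment at α = 0.05 — "significantly enriched" needs an explicit
  correction, and BH is the conventional choice.
* **Enrichment backgrounds**: for pairwise analyses the union of the two
  compared reaction pools; "unblocked shared" reactions must be
  unblocked in both approaches. Both choices are configurable.
* **Group comparisons** dispatch to Kruskal–Wallis (≥3 groups),
  two-sided Wilcoxon rank-sum (2 groups), or Pearson correlation
  (paired numeric), with tie-corrected rank statistics.

## Exchange analysis

Imported metabolites are those whose exchange reaction permits uptake
(lower bound < 0); exported metabolites those whose sink permits
secretion (upper bound > 0); community-exchanged metabolites are the
intersection of the community-wide unions of the two. Membership is
*bound-based* (transport capability), not flux-based: summary counts of
what a community could exchange are about capability, and the counts
would otherwise be entangled with one arbitrary optimal flux
distribution. Realized secretion is a different question, answered by
`export_flux_ranges()`. Per-model summaries use the sample (n−1)
standard deviation.

## The synthetic fixture generator

`generate_truth_network()` builds a connected, growth-capable toy
network — nutrient exchanges and transporters, a linear carbon core,
alanine synthesis, a biomass demand, and configurable secretable
byproduct branches — with a synthetic GPR on every internal/transport
reaction and EC numbers drawn from a fixed five-subclass alphabet with
configurable weights (so enrichment tests have controllable signal).
The truth network has zero dead ends and positive growth by
construction. Its universal database contains the truth's reactions
without genetic support, a three-step alternative alanine route, an
alanine importer, and blocked decoys; the organism's own
alanine-synthesis reaction is deliberately absent, so alanine
auxotrophs must either take the longer database route or import.

`derive_tool_view()` degrades a truth network the way automated draft
reconstructions differ in practice: random dropout of non-core
reactions (the core biomass path is protected), GPR deletion and
rewiring (optionally into a small shared gene pool, emulating tools
that map few genes onto many reactions), appended dead-end-producing
reactions, and wholesale relabeling into a tool-specific namespace with
the cross-reference tables emitted alongside. The appended dead-end
content has no common-namespace counterpart and stays unmapped — as
tool-specific content outside a shared reference would. The three
default profiles are chosen so that, statistically over seeds, the
gapseq-like view carries the most reactions and dead ends, the
carveme-like view the most genes, and the kbase-like view the fewest
reactions, reproducing the qualitative ordering reported for draft
reconstructions of the same genomes.

`generate_community()` shares the structural metabolite universe across
members (so cross-feeding is possible) while keeping gene ids
member-specific, injects an alanine auxotrophy into one member by
default, gives the others export machinery, and draws abundances from a
log-normal distribution (μ = 0, σ = 1, a typical coverage shape). The
`complementary_dropout` option makes the three views of each member
drop disjoint thirds of the droppable *internal* reactions with no
dead-end appendages: each view then has dead ends its siblings repair,
and the consensus — which restores the full truth content — has strictly
fewer. Internal reactions only, because dropping a transport can
instead delete the extracellular metabolite from the view altogether
and shift the count the other way.

What the generator does **not** emulate: realistic biochemistry or
formulas beyond a handful of seeded compounds, genome sequences or
annotation error processes, thermodynamics, and the scale of real GEMs
(thousands of reactions). Passing tests therefore demonstrate
correctness of the algorithms and their declared semantics on networks
where ground truth is enumerable — not predictive accuracy on real
communities.

## The pipeline

`run_pipeline()` drives the full analysis from one YAML config (paths,
tool order, abundance order, ε, α, tolerances): translate → merge →
per-approach community gap-fill → abundance correlations → structural
stats and similarity matrices → blocked-reaction detection and
EC-subclass enrichment → exchange summaries, all as TSV/JSON in a run
directory with a manifest (package version, parameters, input
checksums). Namespace tables are loaded per (tool, model) pair, since
the synthetic relabeling is per-view; a single global table works the
same way. Structural statistics and similarities are computed on the
stripped (boundary-free) models of all four approaches so the
comparison is like-for-like. Everything downstream of the generator is
RNG-free, which is why two runs on the same inputs are byte-identical —
a property the test suite asserts. `compare_orders()` repeats the run
in both abundance orders and pairs the results.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run, per invocation: 50
random gap-fill instances with candidate databases of 4–8 reactions
(small enough that the exhaustive-enumeration oracle is exact and
fast), blocked-set checks on networks of ≤ 8 reactions (vertex
enumeration is exact there), 20 + 20 seeded consensus triples, full
hypergeometric enumeration for populations up to N = 12, a two-member
cross-feeding community, and two-member pipeline runs. These sizes were
chosen so every oracle is exhaustive rather than sampled; the package
itself has no such limits.

## Known limitations

* The dense tableau simplex targets toy-to-small models; genome-scale
  inputs need an external LP backend (isolated behind `solve_lp()`).
* SBML support covers Level 3 + fbc version 2 as written by this
  package and by common reconstruction exporters: species, bounds as
  parameters, gene-product associations, objectives, EC annotations.
  Groups, layout, and kinetics are out of scope.
* Gap-filling weights are uniform by default; evidence-weighted
  gap-filling is expressible through the `weights` argument but no
  weighting scheme is bundled.
* The exchanged-metabolite calculus is set-based by design and does not
  infer directional cross-feeding graphs.
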