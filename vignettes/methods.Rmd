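---
title: "Methods: multilocus species delimitation, diversification models and DEC ancestral ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This package implements, as a staged and fully tested pipeline, the
analytical core of a multilocus study design that is common in fungal
systematics: screen candidate species with a single-locus distance cutoff,
confirm them by genealogical concordance across many single-copy nuclear
gene trees, ask whether the radiation's diversification rate was constant,
and reconstruct ancestral geographic ranges on a dated phylogeny. Every
stage can be exercised end to end on synthetic data with known truth,
which is how the test suite works. This vignette explains the models, the
tunable parameters, the numerical choices, and what the synthetic
experiments do and do not demonstrate.

## 1. Distance screen

Divergences are mean pairwise distances within and between candidate
groups, in the layout of a MEGA "average evolutionary divergence over
sequence pairs" table. The per-pair kernel is either the uncorrected
p-distance (default) or the Kimura two-parameter distance

$$d_{K2P} = -\tfrac12\,\ln(1 - 2P - Q) - \tfrac14\,\ln(1 - 2Q),$$

with $P$ and $Q$ the transition and transversion proportions over
comparable sites. Sites are comparable when both residues are in
`{A,C,G,T}`; gaps, `N` and IUPAC ambiguity codes are excluded per pair
(pairwise deletion, the default) or once for the whole alignment (complete
deletion). Published divergence tables of this kind rarely state the
model; uncorrected p-distance with pairwise deletion is the common default
for closely related taxa and is ours too, with the K2P and
complete-deletion alternates one flag away.

The species-delimitation cutoff is *reference calibrated*: the largest
mean intraspecific divergence among a set of well-studied reference
species is taken as a conservative bound on within-species variation. A
candidate group is accepted when its divergence from the *closest* other
group exceeds the cutoff, merged with that group otherwise, and — on an
independent axis — flagged as potentially containing several species when
its own within-group mean exceeds the cutoff. "Closest" is operationalised
as the group minimising the mean between-group distance, so the decision
is computable from the distance table alone without a guide tree; ties
break lexicographically and are logged. Groups with a single sequence
carry no within-group divergence and are routed to the GCPSR singleton
rule instead of being silently accepted.

## 2. Genealogical concordance (GCPSR)

Candidate species are evaluated against a set of rooted single-locus gene
trees carrying node support: maximum-likelihood bootstrap percentages
(`mlb`), Bayesian posterior probabilities (`bpp`), or both. A clade is
*well supported* when `mlb >= 70` or `bpp >= 0.95` (thresholds and the
any/all combiner are configurable; "any" is the default because jointly
annotated trees are commonly read that way).

For a candidate with member set $S$ in a tree, the verdict is:

* **untestable** — fewer than two members present;
* **supports** — $S$ is monophyletic and its MRCA is well supported;
* **contradicts** — some *well-supported* clade overlaps $S$ partially
  (shares members with both $S$ and its complement while not containing
  all of $S$); an unsupported conflicting topology is only noise, because
  contradiction must happen "at the same level of support";
* **uninformative** — otherwise.

Because clades of one tree are nested or disjoint, supports and
contradicts are mutually exclusive. Two acceptance criteria are applied
per candidate: (a) support in at least 3/4 of the *testable* genealogies —
a locus lacking the taxa cannot testify, and the boundary is inclusive
(`>=`); (b) support in at least one genealogy and contradiction in none.
Acceptance is (a) or (b). Groups are also binned by their number of
supporting genealogies (>30, >20, >10, the rest), mirroring the way such
results are reported. A candidate represented by a single multilocus
sample is accepted only provisionally, when it is more divergent than the
cutoff from every other group *and* a stable morphological difference is
asserted by the analyst (a boolean input; morphology is outside this
package's scope).

Trees are used as rooted as written; no implicit re-rooting happens,
because monophyly is root-dependent. Missing branch lengths become zero
with a warning, since support-only topologies are legitimate GCPSR inputs.
A bare numeric node label in `(1, 100]` is classified as `mlb`, in
`[0, 1]` as `bpp`; exactly 1 is ambiguous between the scales and is taken
as `bpp = 1` with a warning.

## 3. Diversification models

Branching times $a_2 \ge a_3 \ge \dots \ge a_n$ (ages backward from the
present; $a_2$ = crown age) are extracted from a bifurcating ultrametric
chronogram (ultrametricity tolerance $10^{-6}$ relative; exact ties are
perturbed by $10^{-9} \times$ crown age and logged so every inter-event
interval is positive). Five models are fitted by maximum likelihood,
conditioning on the crown age and tip count and dropping the constant
$\ln k$ terms consistently so AIC differences are meaningful:

* **pure birth**: $\log L(\lambda) = (n-2)\ln\lambda - \lambda G$ with
  $G = \sum_{k=2}^{n-1} k (a_k - a_{k+1}) + n a_n$ the total lineage-time;
  the MLE is closed form, $\hat\lambda = (n-2)/G$. ($k = 1$ parameter.)
* **birth–death**: the constant-rate reconstructed-process likelihood in
  the net-rate parameterisation $r = \lambda - \mu$,
  $a = \mu/\lambda \in [0, 1)$:
  $\log L = (n-2)\ln r + r\sum_{i=3}^{n} a_i + n \ln(1-a)
  - 2\sum_{i=2}^{n}\ln(e^{r a_i} - a)$, maximised numerically from three
  starts with $\ln(e^{rx}-a)$ computed as $rx + \log(1 - a e^{-rx})$ for
  stability. At $a = 0$ it reduces algebraically to the pure-birth
  likelihood — a tested invariant. ($k = 2$.)
* **density dependence**: the pure-birth likelihood structure with a
  per-lineage rate that depends on the standing lineage count $N$,
  logistic $\lambda(N) = \lambda_0 (1 - N/K)$ (**ddl**) or exponential
  $\lambda(N) = \lambda_0 N^{-x}$, $x \ge 0$ (**ddx**). For ddl the
  carrying capacity is searched above $n - 1$ so every realised event
  rate is positive, with the final-interval rate clamped at zero from
  below; ddx at $x = 0$ equals pure birth exactly. ($k = 2$ each.)
* **yule2rate**: pure birth with rate $\lambda_1$ older than a shift age
  $t_s$ and $\lambda_2$ younger. For fixed $t_s$ the two rates profile
  analytically ($\hat\lambda_i = c_i/G_i$ per segment), so $t_s$ is
  searched over the observed branching ages and their midpoints,
  restricted to candidates with at least one event on each side (the
  likelihood is flat in $t_s$ between events; an event exactly at the
  shift belongs to the older rate; ties resolve toward the older age).
  One event per side, rather than two, keeps the model defined down to
  its stated minimum of $n = 4$, where two-per-side would leave no
  admissible shift. ($k = 3$.)

The rate-constancy statistic is
$\Delta AIC_{RC} = \min(AIC_{PB}, AIC_{BD}) - \min(AIC_{DDL}, AIC_{DDX},
AIC_{Y2R})$; negative values favour rate constancy. AIC (not AICc) is
used. No missing-species sampling-fraction correction is applied to these
likelihoods; accounting for incomplete sampling (as rate-shift MCMC
frameworks do with a sampling fraction) is out of scope here and the
fitted rates should be read accordingly.

## 4. DEC ancestral ranges

Ranges are non-empty subsets of the area set (default `A`–`F`, capped by
`max_range_size`), ordered by size then lexicographically; the empty
"null" range exists only as an absorbing computational state and never
appears in output. Anagenetic transitions: expansion $R \to R \cup \{j\}$
at rate $d\,|R|$ (each occupied area is a source), contraction
$R \to R \setminus \{i\}$ at rate $e$ per occupied area, singletons to the
null range at $e$. Branch transition probabilities are matrix
exponentials (`Matrix::expm`, scaling-and-squaring with Padé
approximation; row-stochasticity to $10^{-9}$ is a tested contract).

At a node with ancestral range $R$: a single-area range is inherited by
both daughters; otherwise the allowed outcomes are subset sympatry
($\{i\} \subseteq R$ with the other daughter keeping $R$) and vicariance
($\{i\}$ versus $R \setminus \{i\}$), counting both left/right
assignments, as a *set* of outcomes weighted equally — no founder-event
parameter. The likelihood is computed by pruning with per-node rescaling,
and the root is summed over observable states with a flat (unweighted)
prior, so a dataset perfectly explained by one root state approaches
likelihood 1. Rates $(d, e)$ are fitted by bounded quasi-Newton
optimisation on the log scale (bounds $[10^{-8}, 100]$, three starts
scaled to one expected event per tree depth). Marginal node-range
probabilities come from the standard up-down (outside–inside) pass
consistent with the pruning recursion, normalised per node; display
strings list ranges with probability at least 0.05, as such tables are
conventionally printed.

The per-area binary reconstruction is explicitly a **surrogate** for
Bayesian binary MCMC ancestral-area estimation: each area is an
independent two-state CTMC with gain/loss rates fitted by ML and marginal
presence probabilities from two-state pruning under a flat root prior. It
is deterministic and fast, and it is labelled as a surrogate in its
output; it does not claim to reproduce an MCMC's posterior.

**Known limitation — extinction-rate degeneracy.** On realistic tip data
the DEC likelihood is nearly flat in $e$ and its ML estimate typically
collapses to the lower bound: singleton tip ranges are explained by
cladogenetic subset speciation rather than range loss. Our recovery
experiments reproduce this: the dispersal rate is recovered within a
factor of two of truth (median over replicates), while $\hat e$ sits at
the boundary essentially always, across simulation regimes. This is a
property of the model, well known from DEC practice, not of the
optimiser; the likelihood surface was verified against exhaustive
enumeration. Downstream conclusions should not rely on $\hat e$.

## 5. Synthetic data: what it emulates, and what it does not

The generators provide every stage with inputs whose truth is known.

* **Chronograms** are simulated forward in time under constant-rate (or
  two-rate) birth–death, run until the $(n{+}1)$-th extant lineage would
  arise, with the present drawn uniformly inside that final waiting
  interval and extinct lineages pruned — a simple approximate
  conditioning on $n$ that is adequate for estimator-recovery work. For
  the two-rate variant the shift is anchored forward in time (a fixed
  time after the crown), since a backward-anchored shift age is undefined
  while the tree's total depth is still being generated.
* **Gene trees** follow the multispecies coalescent: one allele per
  specimen, pairwise coalescence rate $2/\theta$ within each species-tree
  branch, survivors coalescing above the root. $\theta$ is constant
  across branches.
* **Sequences** evolve by HKY($\kappa$, $\pi$) with the root drawn from
  $\pi$, delegated to `phangorn::simSeq`; branch lengths are coalescent
  units times a single substitutions-per-site rate scalar. No indels, no
  among-site rate heterogeneity, no recombination.
* **Gene-tree estimation** for the end-to-end tests is neighbor joining
  on p-distances with column-resampling bootstrap (percent supports,
  stored as `mlb`), rooted at a designated outgroup grafted onto the
  species-tree stem. This is deliberate test scaffolding: it stands in
  for per-locus ML/Bayesian inference so the concordance machinery can be
  exercised offline, and nothing here claims NJ is equivalent to those
  methods.
* **Ranges** are simulated by Gillespie dynamics under the exact DEC
  generator, with uniform cladogenetic outcomes; replicates in which any
  lineage hits the null range are rejected and logged.

The benchmark fixture bundles all of this at desk scale — 8 species with
3 specimens each, 40 loci of 500 sites, 100 bootstrap replicates — chosen
to mirror the shape of a 51-specimen, 40-locus study while keeping a full
20-replicate experiment in the minutes range. Two presets fix the
coalescent parameter relative to the *realized* species tree so that
their defining property holds by construction: **deep** sets $\theta$ to
one tenth of the shallowest species split (every species depth
$\ge 10\,\theta$, hence negligible incomplete lineage sorting), and
**shallow** sets $\theta$ to the crown age (pervasive ILS). Species trees
are redrawn until internal nodes are mutually separated by at least 5% of
the crown age and none sits within 10% of the present, emulating a
complex whose members are distinguishable lineages rather than a hard
polytomy; the substitution-rate scalar (0.01/site per time unit at crown
age 10) then puts a handful of substitutions on even the shortest species
stem, so that per-locus trees carry the support the concordance criteria
need. Under the deep preset the pipeline recovers exactly the true
species in essentially all seeded replicates; under the shallow preset it
recovers strictly fewer — evidence that the machinery is calibrated, not
that any particular empirical dataset is easy. Passing these tests shows
correctness of the computations and sane behaviour of the decision rules
under clean and adversarial coalescent regimes; it does not certify
performance on real data with alignment error, gene-tree estimation
error beyond NJ noise, paralogy, or hybridisation.

## 6. Numerical conventions

Distances are proportions internally and percentages only at display
time. Alignments are character matrices; `U` is normalised to `T` and
case is folded on read. Newick round-trips preserve topology, branch
lengths to 10 significant digits, and support maps, in both support
dialects (bare labels, and `[&mlb=..,bpp=..]` annotations). The
p-distance matrix is computed by indicator cross-products (four matrix
products), which equals the per-pair kernel exactly and makes the
bootstrap loop cheap; clade identity during bootstrapping uses exact
power-of-two set keys over the taxon ordering (valid below 53 taxa).
Likelihood computations rescale per node and report natural-log
likelihoods; optimisers work on log-rate scales with multi-start.
Reported probabilities sum to one per node within $10^{-9}$.
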