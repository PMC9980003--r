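---
title: "Methods: gene-set assembly and over-representation statistics in setora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-set assembly and over-representation statistics in setora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setora)
```

# Scope and model

`setora` implements classified gene-set construction and hypergeometric
over-representation analysis (ORA) for six model organisms. It is an ORA
tool, not a ranked-list method: the input is an unordered gene list, the
null model is sampling without replacement from a background universe, and
the statistic per gene set is the upper hypergeometric tail
$P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, K, n)$ — $N$ background
genes, $K$ of them in the set, $n$ analysed genes, $k$ in the overlap. The
test is one-sided (over-representation only); depletion is out of scope.

The tail is computed as an explicit sum of
$\exp(\log C(K,i) + \log C(N-K,n-i) - \log C(N,n))$ over
$i = k \dots \min(n, K)$. On the complete grid of valid contingency tuples
with $N \le 25$ (44,225 cases) the maximum absolute deviation from exact
binomial-coefficient enumeration is below $10^{-14}$, well inside the
package's $10^{-12}$ working tolerance; `stats::phyper` serves as an
independent cross-check in the tests, never as the implementation.

Fold enrichment is $(k/n)/(K/N)$, defined only for $K>0,\ n>0$; sets with
$K = 0$ are untestable and excluded from the result table (and from the
multiple-testing count $m$).

## Multiple-testing corrections

Bonferroni, Benjamini-Hochberg (BH) and Benjamini-Yekutieli (BY) are
exposed; all three are delegated to `stats::p.adjust`, the standard
implementation of these procedures in R. The unit tests verify the step-up
definitions independently (literal $\min_{j \ge i} p_{(j)} m / j$ oracles,
and BY's $c(m) = \sum_{i=1}^m 1/i$ factor). $m$ is the number of sets
tested within one collection; corrections are per collection, not pooled
across categories, because categories are chosen independently by the user
and pooling would make one category's size distort another's error rate.

## Background choice

The default universe is the union of the collection's member genes and the
analysed genes. This default is reproducible without shipping whole-genome
tables and treats the collection itself as the annotation universe; the
practical alternative — the whole genome — systematically inflates
significance for well-annotated sets. A user-supplied background (the
focused-screen case, e.g. a kinase sub-library) overrides it: $N$ becomes
the background size, set memberships are intersected with the background,
and input genes outside it are dropped and reported rather than silently
added (a gene that could never have been drawn is not part of the
experiment). Shrinking the background to exactly set ∪ list can only
increase $p$, which the tests assert as a sanity property.

## Result ordering and cutoff semantics

Results are sorted by raw $p$, ties broken by fold enrichment descending,
then set id — fully deterministic. Cutoff filtering is strict (`< cutoff`),
so a result with $p = 1$ is dropped even at cutoff 1.0; the same strict
rule drives row selection in comparison matrices. Whether the cutoff is
applied to raw or adjusted $p$ is a parameter (`column` /
`cutoffColumn`), defaulting to raw.

# Gene-set assembly rules

**Direct vs propagated ontology sets.** GO-style collections are assembled
in two modes: *direct* (one set per term with its directly annotated
genes, useful to inspect annotation depth) and *propagated* ("flattened":
each gene contributes to all ancestors of its annotated terms, the
true-path rule, recommended for enrichment). Traversal covers `is_a` and
`part_of` only — the roll-up convention for GO subsumption; regulates-type
edges are not parentage and are ignored. The ontology is validated at load
(acyclicity, resolvable parents, no alt-id/primary collisions); obsolete
terms load but contribute no traversal edges, and annotations to them are
dropped with a warning count. Secondary (`alt_id`) annotations resolve to
primary ids.

**GO slim.** A gene joins slim set $s$ iff $s$ is an ancestor (reflexive)
of some directly annotated term. Whether to propagate first is moot for
ancestor-closed slims — the result is identical — so the cheaper
direct-annotation route is used; for non-closed slims this is the stated
behaviour.

**Evidence subsets.** The "experimental" subset removes (gene, term) pairs
supported *only* by computational codes
(IEA, IBA, IBD, IKR, IRD, ISS, ISO, ISA, ISM, IGC, RCA); the "no-HTP"
subset removes pairs supported *only* by high-throughput codes
(HTP, HDA, HMP, HGI, HEP). "Only" is interpreted at the (gene, term) pair
level: one qualifying record rescues the pair with all its records. The two
filters are idempotent and commute, which the tests check exhaustively over
all one- and two-code combinations. `NOT`-qualified GAF rows are dropped
before any set building — a negative annotation must never create
membership.

**Phenotype sets.** Only genotypes attributable to a single gene
contribute: exactly one allele, of class classical or insertional,
belonging to exactly one gene. RNAi and other reagent classes are excluded
(class `other`), as are multi-allele and multi-gene genotypes; exclusions
are counted. The fixture format lists distinct alleles, so a homozygous
genotype arrives as one allele token and counts as single. When a phenotype
CV DAG is supplied, the pairs are propagated through it like any ontology.

**Tissue-preferential expression.** Sample columns are grouped by tissue,
group means are arithmetic means of RPKM, and a gene is called preferential
in group $g$ iff $\mathrm{mean}_g \ge f \cdot \mathrm{mean}_h$ for every
other group $h$ *and* the floor passes. Defaults: $f = 3$ ("three-fold or
higher", read inclusively) and floor 10 RPKM. With $f > 1$ dominance is
mutually exclusive, so the classification is a partial map; ties at the
maximum fail both directions and yield no call, and all-zero genes are
never called. The floor is applied to the focal group's mean by default —
the artefact being excluded is precisely a "preferential" call on a
barely-expressed gene — with `floorOn = "overall"` offered because the
alternative reading (overall average) is defensible.

**Identifier synchronisation.** The mapping step partitions every input id
into mapped / updated (secondary id brought to current) / ambiguous /
unmapped. Ambiguous aliases are never auto-resolved, even when one
candidate is current: silent misassignment corrupts downstream counts in a
way the user cannot see, whereas exclusion is visible in the report. Two
inputs resolving to one canonical collapse to a single output gene
(enrichment must not double-count). Identifiers are case-sensitive
throughout — fly symbol case is significant (`wg` vs `Wg`).

# Synthetic data: what it emulates and what it does not

The generators produce every input format deterministically (byte-identical
under one `fixtureSpec`), each with a JSON manifest of planted ground
truth:

- **Ontology**: a random DAG, acyclic by construction (edges only from
  later to earlier term indices), single root, ~20% `part_of` edges.
- **GAF**: annotations uniform over genes with leaf-biased terms, evidence
  codes drawn from a declared experimental/computational/HTP mix, exact
  counts in the manifest.
- **Expression**: planted tissue-preferential genes (focal mean ≥ 3× others
  and ≥ 10 RPKM by construction) plus anti-planted genes violating exactly
  one condition; within-group sample noise is zero-sum, so empirical group
  means equal planned means exactly and manifest recovery can be asserted
  as identity rather than approximately.
- **Screens**: hit lists sampled from a planted set plus uniform noise;
  defaults emulate a focused-screen recovery scenario — 20 genes from one
  set of a 50-set collection, 5 noise genes, a 2,000-gene background.
- **Id map**: current, secondary, ambiguous and bogus aliases exercising
  every mapping path.

None of this claims biological realism: there is no correlation structure
between sets, no annotation bias beyond the leaf weighting, no
overdispersion in expression, no shared membership structure between
planted sets. Passing recovery tests therefore demonstrates correctness of
the implemented rules and adequate statistical power in a clean scenario —
not performance on real, correlated annotation databases.

# Numerical and engineering choices

- Problem sizes in the routine checks (200 random DAGs ≤ 50 terms for the
  propagation oracle, 200 seeded enrichment recovery runs, 10,000 random
  p-vectors for adjustment ordering, the complete $N \le 25$ contingency
  sweep) were chosen to exercise the properties densely while keeping the
  full suite under a minute on one CPU.
- GMT is the canonical on-disk set format (de-facto standard, diffable,
  trivially fixture-able); members are written sorted so output is
  deterministic and round-trips are identity. Empty sets are rejected at
  construction — they can never be enriched and break fold denominators.
- Graphs export to GraphML (via igraph; node type and label as attributes)
  and to a single sectioned TSV; both re-import losslessly. Network gene
  nodes are overlap genes only (input ∩ set): the display question is
  "which of *my* genes link these sets", and full-membership graphs are
  unreadable.
- Comparison-matrix cells distinguish three states: significant,
  tested-but-not-significant (true value kept, flagged), and untestable
  ($K = 0$ under that run's background; `NA`). Blanking non-significant
  values would hide exactly the information a side-by-side comparison is
  for.
- The CLI is a thin layer over the exported functions (`setoraCli()`,
  `exec/setora`), with flat `key=value` config files, flag override, input
  hashes and row counts in the log, and exit codes 0/1/2
  (success/runtime/usage).

# Known limitations

- No ranked-list (KS-style) enrichment, no depletion testing.
- No ontology reasoning beyond subsumption closure; no cross-ontology or
  cross-species (ortholog) mapping.
- The OBO parser covers the 1.2 `[Term]` subset needed for set assembly
  (id, name, namespace, `is_a`, `relationship`, `alt_id`, `is_obsolete`);
  it is not a general OBO toolchain.
- Expression input must arrive pre-quantified (RPKM); no normalisation or
  batch correction is performed.
- Collections are held in memory; there is no database layer or multi-user
  storage.
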