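---
title: "Multiscale network pharmacology: methods and design notes"
author: "netPharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale network pharmacology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netPharm)
```

# The problem

Multi-ingredient (herbal) drugs perturb many proteins weakly or moderately
rather than one target strongly, so their pharmacology is better described
as a cascade of linked layers than as a single dose-response curve:
ingredient molecules bind protein targets, targets sit in biological
pathways, pathways are annotated to diseases, and diseases present clinical
symptoms and -- in the traditional Chinese medicine (TCM) reading -- Cold or
Hot ZHENG syndrome classes. netPharm implements this chain as a tested
pipeline: a docking-hit filter defines the drug--target layer, bipartite
network statistics and projections propagate it downward to pathways and
diseases, phenotype tables summarize the clinical end of the chain, and a
rank-based connectivity score compares the drug's expression signature with
a reference set of treated profiles. Because the original score tables and
database snapshots behind such studies are essentially never released, the
package ships a seeded synthetic-data generator with planted structure so
that every stage is verifiable end to end.

# The model, stage by stage

## Hit selection

A docking record is a `(molecule, target, score, reference_score)` row,
with higher scores meaning stronger predicted binding and the reference
score belonging to the target's original co-crystal ligand. A pair is a hit
iff

$$\text{score} > \text{reference score} \quad\text{and}\quad
  \text{score} > \theta,\qquad \theta = 6.0 ,$$

both inequalities strict ("higher than" read literally; ties excluded).
When a pair has several records (alternative crystal structures), the
pair's best score is compared against the target's minimum reference score
-- the most permissive composition; the underlying studies do not specify a
rule, so we chose the one that never discards a pair that any single
structure would admit. Targets then pass three eligibility criteria:
human origin, at least one pathway annotation, and at least one annotated
pathway with a disease annotation. `selectHits()` is monotone in $\theta$
and idempotent, and both properties are asserted in the test suite.

## Network layers and node statistics

All layers are simple undirected bipartite graphs (`BipartiteNetwork`);
parallel edges collapse so each interaction pair counts once. Reported
statistics are degree and shortest-path betweenness with fractional credit
over equally short geodesics. Betweenness is computed on the bipartite
graph directly (not on a one-mode projection) and normalized by
$(n-1)(n-2)/2$ with $n$ the size of the node's connected component -- the
undirected convention of Cytoscape's NetworkAnalyzer, which keeps values in
$[0,1]$ and matches how such tables are usually reported. Components of
size below 3 score 0. The implementation delegates the raw computation to
igraph; the test suite checks it against an independent BFS
path-enumeration oracle on random graphs of up to 12 nodes at `1e-12`.

Molecules are stratified by degree into low $[1, c_1]$, middle
$[c_1{+}1, c_2]$ and high $[c_2{+}1, \infty)$ with default cut points
$c_1 = 10$, $c_2 = 30$. The high stratum is open-ended: the largest
observed degree (62) is an observation, not a rule, and synthetic worlds
with bigger hubs must remain classifiable.

For one stratum's interactions the *relevance frequency* of pathway $p$ is

$$\mathrm{score}(p) = \frac{N(p)}{\sum_q N(q)},$$

where $N(p)$ counts (molecule, target, pathway) incidence triples whose
target is annotated to $p$. We count triples rather than distinct pathways
per molecule: a pathway touched by many stratum interactions should weigh
more, which is the natural reading of a pathway's "impact" score. Scores
over a stratum form a probability vector, and merging two strata mixes
their score vectors with triple-count weights (a tested invariant).

## Projections and mechanism subnetworks

The drug--pathway layer is the composition of drug--target and
target--pathway through shared targets. Edge weights record the number of
shared targets, so total weight equals the number of triples exactly
(tested on 100 random networks); reported degrees use the *unweighted*
projection because "$k$ drugs interact with this pathway" is a drug count,
not a shared-target count. The pathway--disease layer transcribes the
annotation map over the pathways present. A mechanism subnetwork for one
disease pathway contains exactly the in-pathway targets with at least one
drug hit, the drugs hitting them, and those edges; the shared-target
comparison between two such subnetworks is a plain set intersection -- no
statistical test is attached, since none is defined for it.

## Phenotype layer

Category proportions count (disease, category) *assignments* -- a disease
with two categories contributes twice -- and are reported as percentages of
all assignments to two decimals. Symptom counts tally distinct diseases per
symptom. ZHENG labels are per-disease nonempty subsets of \{Cold, Hot\};
the partition reports cold-only, hot-only and dual sets, with *inclusive*
Cold and Hot counts, so total $=$ cold $+$ hot $-$ both. Inclusive counting
is the only reading under which a published 28/94/5 split totals 117
labelled diseases, and the generator's default proportions (0.25, 0.80,
0.05) are chosen to reproduce that split in expectation.

## Connectivity scoring

For a tag set of size $t$ with ascending ranks $V(j)$ in a ranking of $n$
tags (rank 1 = most up-regulated):

$$a = \max_j \left(\tfrac{j}{t} - \tfrac{V(j)}{n}\right),\qquad
  b = \max_j \left(\tfrac{V(j)}{n} - \tfrac{j-1}{t}\right),$$

and the one-sided statistic is $a$ if $a > b$, else $-b$. The instance
score is 0 when the up- and down-tag statistics share a sign and
$\mathrm{ks}_{up} - \mathrm{ks}_{down}$ otherwise; raw scores are scaled by
the batch maximum absolute value into $[-1, 1]$. One-sided signatures
(empty down list) are supported and use the available side alone.

Two symmetry facts matter for testing: swapping the up and down lists
negates every raw score *exactly*, while reversing a profile's ranking
negates scores only *approximately* (each tail statistic shifts by up to
$1/n$ under reversal, a small asymmetry inherent in the $(j-1)/t$ term).
The suite asserts the first identity exactly and the second within $2/n$.

Mean scores aggregate scaled instance scores per (perturbagen, cell line).
The permutation p-value redraws the signature's tags uniformly without
replacement (sizes preserved, sides disjoint) and uses the add-one
estimator

$$p = \frac{1 + \#\{|\bar s_{perm}| \ge |\bar s_{obs}|\}}{1 + n_{perm}},$$

which is never 0 and is sub-uniform under the null (empirical type-I error
at nominal 0.05 stays within $\pm 0.02$ over 1000 seeded null signatures in
the acceptance suite). Permuting signature tags rather than profile labels
matches "enrichment of a set of instances by chance" at desk scale, where a
combination may have only a couple of instances. The null comparison uses
raw means, which equals scaling every permutation by the observed batch
maximum -- a common positive constant cannot change the comparison.

# The synthetic world

The generator states one world and keeps it fixed; none of its parameters
were tuned against test outcomes.

* **Magnitudes.** 90 molecules and 270 targets (the docked library scaled
  to desk size), 40 pathways, 130 diseases, 50 symptoms. With hit fraction
  0.018 -- the edge density implied by a few hundred hits over a
  90-molecule screen -- a run yields roughly 450--600 drug--target edges.
* **Planted hits.** Reference scores are Normal(6.0, 0.4). Planted hits
  score `max(reference, 6) + 0.5 + Exp(2)`, misses
  `max(reference, 6) - Exp(0.8)`, so the hit filter at threshold 6 recovers
  exactly the planted pairs; hub molecules 1--3 are planted at post-filter
  degrees 62, 40 and 34, the top of the observed degree table, and land in
  the high stratum.
* **Annotations.** Set sizes are 1-truncated Poisson (mean 4.6 pathways
  per target from the observed target--pathway density, 3 diseases per
  pathway, 19 symptoms per disease). The first pathway's sampling weight is
  multiplied by 8, planting a dominant pathway the relevance score should
  rank first. Truncation at 1 makes eligibility criteria (b) and (c)
  satisfiable by construction.
* **ZHENG.** 17.5% of diseases are labelled with inclusive proportions
  (cold 0.25, hot 0.80, both 0.05).
* **Expression reference.** 22 perturbagens x 2 instances over 500 tags.
  Instance rankings order a latent standard-normal tag score; the planted
  mimic shifts the signature's up tags by +3 SD and down tags by -3 SD, the
  planted reverser does the opposite, and 20 nulls carry pure noise.

What the generator does **not** emulate: realistic docking-energy physics
(scores are statistical stand-ins), organism mixtures (all synthetic
targets are human, so the eligibility criterion (a) is exercised by
hand-built unit fixtures instead), correlated pathway membership, multiple
cell lines by default, and any real chemistry or sequence content. A green
planted-structure test therefore establishes that the pipeline's logic
recovers known structure from data of the stated shape -- not that it
reproduces any particular real-world screen.

# Numerical and degenerate-input choices

* Strict `>` everywhere in the hit rule; boundary scores are misses.
* Empty networks, zero-hit worlds and empty sides are legal: the pipeline
  runs through, mean degrees report `NA`, and the relevance score is the
  one operation that refuses an empty stratum (there is no frequency to
  normalize).
* Relevance-score and attribute-table ties break by id, and all written
  tables are sorted, so a fixed seed gives byte-identical artifacts.
* Betweenness on components of size < 3 is 0 by convention.
* In batches where every raw connectivity score is 0 the scaling step
  leaves them at 0 rather than dividing by zero.
* The flat `key: value` YAML subset is parsed by hand (no YAML package is
  assumed); nested YAML is out of scope.

# Open design points resolved here

* Node accounting follows the data model (nodes = endpoints plus declared
  isolates); published node totals that disagree with their own margins
  are not chased.
* Betweenness is computed on the bipartite graph, not a projection.
* Printed per-side average degrees that are mutually inconsistent with the
  layer's margins are not reproduced; `bipartiteMeanDegrees()` follows the
  arithmetic definition.
* Reproducing real connectivity-database scores would require the external
  reference set; the package reproduces the score's *semantics* (mean per
  chemical x cell line, permutation p) and verifies them on planted data.

# Worked example

```{r example, eval = FALSE}
spec <- simulationSpec(seed = 11)
fixture <- simulateAll(spec, tempfile("netpharm"))
config <- readPipelineConfig(fixture$files[["config"]])
bundle <- runPipeline(config)

head(nodeAttributes(bundle$drugTarget), 3)
head(bundle$connectivity, 3)
```

On this seed the drug--target layer has 316 nodes and 547 edges; the three
planted hubs rank first in the attribute table at degrees 62, 40 and 34,
the planted dominant pathway tops the high-stratum relevance scores, and
the mimic perturbagen leads the connectivity table with mean score 0.95 and
p = 0.0099 at 100 permutations.

# Limitations

Annotation maps are treated as flat sets: no pathway topology, no
propagation, no ontology structure. The hit filter assumes
higher-is-better scores; energy-like scores must be sign-flipped at
ingest. The permutation null assumes exchangeability of tags within the
universe, which ignores gene-gene correlation in real expression data --
p-values on real profiles are therefore optimistic in the usual way of
signature-matching tools.
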