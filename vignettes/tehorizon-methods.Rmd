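---
title: "Methods: transposon annotation, divergence landscapes, and horizontal-transfer inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transposon annotation, divergence landscapes, and horizontal-transfer inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, numerical
conventions and known limitations behind `tehorizon`. The package
re-implements, as tested R code, a census-and-transfer analysis for
cut-and-paste DNA transposons of the *pogo*/*Tigger* kind: locating
transposase homologies, delimiting element boundaries by terminal inverted
repeats (TIRs) and TA target-site duplications (TSDs), classifying copies,
building consensus sequences, estimating genetic distances, drawing Kimura
divergence landscapes, and inferring horizontal transfer (HT) from
element-versus-host-gene distance comparisons.

## 1. The synthetic-data generator

Every downstream stage is validated against simulated truth, so the
generator is first-class, tested code rather than a fixture.

**Species trees.** `simulate_yule_tree()` draws an ultrametric pure-birth
tree (via `ape::rphylo`) and rescales it to a chosen root-to-tip depth in
expected substitutions per site. Depth, not absolute time, is the natural
unit here: every downstream quantity (distances, divergence bins, transfer
times) is expressed in substitutions/site.

**Sequence evolution.** `evolve_along_tree()` evolves i.i.d. sites under a
reversible K2P or TN93 model; transition matrices come from the
eigendecomposition of the rate matrix, which is scaled to one expected
substitution per site per unit branch length. There are no indels:
simulated sequence sets stay co-linear, which keeps the distance estimators
testable against closed forms. Real data, of course, have indels — the
pipeline handles those through explicit pairwise alignment
(`align_pair()`), and the simulator's no-indel assumption is the main sense
in which passing tests understate real-data difficulty.

**Elements.** `make_te_element()` builds the canonical family layout: a
left TIR (default 20 bp, matching typically observed TIRs of 8–33 bp), a
spacer, one transposase ORF (default 492 aa, within the observed 300–685 aa
range), a spacer, and the reverse-complemented TIR; default total length
2.5 kb (observed full elements cluster near 2.8 kb, range roughly 1–4.5
kb). The three bases upstream of the ORF are an in-frame stop so the
planted ORF length is exact. `disrupt_element_orf()` derives a same-family
"full but not intact" variant by writing two internal stops.

**Insertion semantics.** `plant_te_copies()` inserts only at TA
dinucleotides and duplicates the TA, so every planted copy is flanked by a
TA TSD — making `check_tsd()` exactly testable. Copies are aged by a
per-copy divergence (substitutions/site applied directly to the copy; the
landscape's x-axis is divergence, so no per-species molecular clock is
assumed), and truncated copies lose a uniformly drawn prefix and/or suffix
of 10–45% of the element length. Decay by large deletions is a stand-in —
no generative model of element decay is being inferred — and truth tables
record the *realized* copy: an aged copy whose ORF picked up a premature
stop is recorded as full, not intact, because that is what is present in
the genome.

**Transfer histories.** `apply_ht_scenario()` evolves the element
vertically and then applies HT directives (donor leaf, recipient leaf, time
before present). The transferred state is sampled from the Markov bridge
conditioned on the two realized node states of the donor-lineage branch
spanning the transfer time; an unconditional re-simulation of that branch
segment would wrongly make donor and recipient diverge at their common
ancestor rather than at the transfer time. A directive older than the
pair's divergence is rejected: that would be vertical descent, not
transfer.

## 2. Mining

`translated_search()` is a deliberately small translated-homology engine:
six-frame translation, exact 4-mer amino-acid seeding, ungapped X-drop
extension under BLOSUM62, one extension per diagonal cluster. Its scores
are raw BLOSUM62 sums and its significance control is a fixed raw-score
cutoff (default 100); `calibrate_score_threshold()` provides an empirical
null from shuffled genomes (in the bundled checks the largest shuffle score
stays near 50, a factor of two under the cutoff, while true hits score in
the hundreds). It is a desk-scale tool: it does not compute E-values and is
not intended to reproduce a production search engine's scores.

Hit consolidation follows the census conventions: `parse_hit_table()`
ingests the standard 12-column tabular format, normalising subject
intervals to 0-based half-open with strand inferred from coordinate order;
`select_top_nonoverlapping()` keeps at most k = 10 hits greedily by
descending score (ties: smaller start), which is deterministic and
order-free; `extract_flanked()` adds 2 kb flanks, clips at contig ends and
reverse-complements minus-strand hits. `count_copies()` applies the three
census thresholds strictly (> 1000 bp, > 40% coverage, > 80% identity);
coverage is measured on the reference element, since a family is
represented by one reference/consensus, and identity over aligned non-gap
columns. All three thresholds are exclusive bounds, so boundary values do
not count.

## 3. Boundary annotation

`find_tir_pair()` searches for the highest-scoring inverted-repeat pair
whose left copy starts, and right copy ends, within a terminal window
(default 50 bp). Ranking is longest first, then fewest mismatches, then
smaller left start, then larger right end. Two search modes share one
contract: an exhaustive diagonal scan for windows up to 64 bp, and an exact
6-mer seeded scan for wider windows (used when boundaries must be found
inside 2 kb flanks). The seeded mode is guaranteed to find repeats
containing a 6 bp exact stretch; with the default tolerance that covers
TIRs of 18 bp and longer, which is the regime wide-window refinement
operates in.

**Mismatch tolerance.** The default budget is `ceiling(len/10)`, but
repeats shorter than 12 bp must be exact. The reason is binomial: in a
50 bp terminal window, an 8–11 bp inverted match with one tolerated
mismatch is *expected* to occur by chance about once per region, which
would systematically promote truncated copies to "full". Requiring
exactness below 12 bp drops that false-positive expectation to the 10^-3
range while leaving planted-TIR recovery essentially untouched (mismatched
short TIRs are still found when the caller passes an explicit
`max_mismatch`).

**Boundary drift and TSD pinning.** Because the ranking prefers longer
candidates and longer candidates get a larger mismatch budget, a raw
search in a wide window can pad a true TIR outward by a few mismatched
bases (up to the budget). `annotate_region()` therefore prefers candidates
whose implied element interval is flanked by TA on both sides; when a TSD
is present this pins the boundary exactly, and when none is found the
search falls back to the unconstrained ranking. Classification itself
never requires the TSD: full means a TIR pair is present, intact
additionally requires a transposase ORF strictly longer than 300 aa
(i.e. 301 aa counts, 300 does not), and everything else is truncated.

**ORFs.** `find_longest_orf()` scans all six frames for ATG-to-stop spans;
ties prefer the plus strand, then the 5'-most start. Protein length counts
the initiator methionine and excludes the stop.

**Consensus.** With at least 6 aligned copies ("more than 5"),
`build_consensus()` applies per-column majority over non-gap bases (ties
resolved alphabetically, deterministically) and emits a column only when at
least half the rows are non-gap; with fewer copies it returns the longest
copy — preferring intact ones — flagged as a representative rather than a
consensus.

## 4. Distances and clustering

`k2p_distance()` implements the closed form
`d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)` with pairwise deletion and the
standard closed-form sampling variance; non-positive logarithm arguments
flag the pair as saturated rather than returning a number.

`mcl_distance_matrix()` implements the shared-parameter ("maximum composite
likelihood") TN93 construction: substitution counts are pooled over all
pairs under pairwise deletion, base frequencies over all sequences; the two
transition/transversion rate ratios come from the TN93 moment inversion of
the pooled proportions; each pair's distance is then the maximum-likelihood
branch length under that shared model. The per-pair likelihood is taken
over the four substitution categories (identical, purine transition,
pyrimidine transition, transversion). That choice is deliberate: with the
aggregate likelihood, the two-sequence case reduces *exactly* to the
classical TN93 closed form (the moment solution saturates the three
observed proportions), which the full 16-cell likelihood would not do
because observed count matrices are never exactly symmetric. The branch
length is located by root-finding on the analytic score function
(`uniroot`, tolerance 1e-13); pairs whose likelihood keeps increasing past
d = 15 are flagged saturated, and saturated entries propagate as flags that
downstream filters treat as failures, never as imputed values. Whether a
real analysis should use nucleotide or amino-acid inputs for the element is
not prescribed; the matrix functions accept any aligned set, and the
pipeline uses nucleotide consensuses because that is what the consensus
stage produces.

`nj_tree()` is a standard neighbor-joining agglomeration with two stated
conventions: ties in the Q criterion join the lexicographically smallest
index pair, and negative branch lengths are clamped to zero with the
deficit moved to the sister branch so path lengths through the joined node
are preserved. It exists as a clustering utility for corroborating event
groupings; maximum-likelihood phylogenetics is explicitly out of scope.

## 5. Horizontal-transfer inference

Per species pair, three filters, with every constant exposed in
`pipeline_config()`:

1. element identity strictly above 0.70;
2. `d_te * 1.2 <= d_host` for *every* primary host gene ("1.2 times
   smaller" read multiplicatively; the additive alternative is
   dimensionally incoherent; an any-gene mode exists but is off by
   default);
3. a one-factor ANOVA (via `stats::aov`) across markers, p < 0.01 and the
   element group mean strictly smallest.

Events are connected components of the pass graph — the grouping rule that
turns pairs into events is otherwise under-determined — ordered by smallest
member label. Significance is assessed per event, with no multiple-testing
correction by default (a Bonferroni option exists).

**ANOVA groups.** The groups are the per-marker distances of the event's
*passing pairs*. The alternative — all pairwise distances among implicated
species — was implemented (`anova_groups = "component"`) and rejected as
the default for two reasons. First, it makes two-species events untestable
(one value per group) even when the pair evidence is overwhelming. Second,
it dilutes the signal: a component typically contains the donor's close
relatives, whose *vertical* within-clade pairs contribute small host
distances to the host groups, inflating within-group variance until a
clear three-species transfer fails the gate. The passing-pairs
construction tests precisely the pairs the filters implicated. Degenerate
inputs have fixed conventions: all values identical across groups gives
F = 0, p = 1; fewer than two values in any group is reported untestable
and the event is not called.

**Confirmation.** Called events are re-tested with a secondary conserved
gene — RAG1 for vertebrate pairs, tub3 for pairs involving an invertebrate.
The confirmation is a re-run of the filter pipeline under that gene: pairs
failing the secondary ratio filter (or lacking secondary data) drop out,
and the event is confirmed when the surviving pairs still produce a
significant ANOVA (element vs both primary genes vs the secondary) with
the element mean smallest. Requiring every original pair to survive would
let a single marginal pair veto an otherwise well-supported event, and a
secondary-only two-group ANOVA has too few degrees of freedom on small
events to reach p < 0.01 at all; both failure modes are artifacts of the
construction rather than evidence about the transfer. Events with missing
secondary data are flagged `partial`.

## 6. Divergence landscapes

`divergence_profile()` bins each copy's aligned kb by its K2P divergence to
the consensus (default 1% bins from 0); copies with saturated distances
are excluded and reported. Coverage is conserved exactly: the histogram
total equals the summed aligned lengths. `activity_assessment()` flags
recent activity when any mass lies below 2% divergence and a
fossil-dominated landscape when more than half the mass lies above 10%;
the 50% majority cut is this package's operationalisation of
"predominantly old", since only the 2% and 10% divergence cuts are given
by the underlying analysis. Plain K2P is used without CpG correction; the
profile is computed copy-to-consensus.

## 7. The pipeline and reproducibility

`run_pipeline()` executes simulate → mine → annotate → census/consensus →
distances → HT detection → landscapes from a single YAML/R config, writes
every stage output as a plain-text table and records an md5 manifest; a
rerun with the same config and seed is byte-identical. All stochastic
stages draw from one global stream seeded once at entry, so every function
is a pure function of (parameters, seed).

## 8. Validation conditions and problem sizes

The test suite and `scripts/acceptance.R` validate the pipeline at fixed,
documented study conditions chosen to be realistic for deep-animal
comparisons rather than tuned to any particular outcome: 20 species on a
Yule tree of root-to-tip depth 0.25 substitutions/site; two 10 kb primary
host genes and one 10 kb secondary gene; a 2.5 kb element evolving at the
host rate ("equal rates", the conservative case for the ratio filter);
K2P with transition/transversion ratio 2. The null study uses
vertical-only histories; the power study plants one transfer at 0.04
substitutions/site before present — donor and recipient elements roughly
92% identical, comfortably inside the "recent, >90% identity" regime —
between the two most divergent lineages. On an ultrametric tree every
cross-root leaf pair is maximally divergent, so the scenario takes the
donor from the leaf-richer side of the root (transfers out of a
lineage-rich clade) and the recipient from the other side. Replicate
counts are 100 seeds per study, 200 planted TIR elements, 50 planted
census copies, 100 random additive matrices, 1000/200 random alignments
for the closed-form checks.

## 9. Known limitations

- No indels in the simulator; alignment quality on real, indel-rich copies
  is untested here.
- The translated search is desk-scale: raw scores, empirical threshold, no
  E-values, no gapped extension.
- Element decay is modelled only as end-truncation; internal deletions and
  nested insertions are absent.
- Transposase verification is by ORF length alone; no protein-domain
  (CENP-B/DDE) detection is attempted, though the classification step is
  the natural hook for an external domain scanner.
- The ANOVA treats pairwise distances as exchangeable replicates; they
  share species and are therefore correlated. The permutation oracle in
  the tests bounds the practical effect at the study conditions, but the
  p-values should be read as filter scores, not calibrated probabilities.
- Transfer direction and absolute dating of events are out of scope.
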