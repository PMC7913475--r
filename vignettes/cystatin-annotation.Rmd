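---
title: "Annotating and classifying cystatin gene families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and classifying cystatin gene families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystakit)
```

## The problem

Cystatins (superfamily I25) are endogenous inhibitors of papain-like cysteine
proteases. Two single-domain subfamilies dominate animal genomes: **stefins**
(type 1), small intracellular proteins without a signal peptide or disulfide
bridges, and **type 2 cystatins**, secreted proteins with a signal peptide and
two sequential disulfide bridges. In parasites these molecules sit at the
host–parasite interface, and some parasite lineages (myxozoan cnidarians,
liver and intestinal flukes) carry a chimeric third architecture — the
**atypical stefin** — that combines a stefin-like protease-contact region
with the missing C-terminus (and sometimes the signal peptide) of type 2
cystatins.

`cystakit` turns the comparative workflow behind such surveys into a tested
pipeline: translated homology screening, motif-grammar annotation of the
cystatin domain, rule-based subtype classification, intron mapping from
genomic/cDNA comparison, conservation profiling, and parsimony analysis of
gene gain and loss across early-branching animal lineages.

## The motif grammar

The cystatin domain is recognized through a small grammar of conserved
regions, located on the *mature* sequence (after the predicted signal-peptide
cleavage, when present); all coordinates are 0-based, half-open:

* **Trunk glycine** (`G_trunk`): the first G among the first 10 mature
  residues.
* **Q-x-V-x-G** (`QxVxG`): the first-hairpin consensus, first match
  downstream of the trunk glycine.
* **Second-hairpin pair** (`hairpin2_pair`): the two-residue LP (stefins) or
  PW (type 2 cystatins) protease-contact pair, sought 15–30 residues
  downstream of the Q-x-V-x-G glycine. A canonical LP/PW wins outright; among
  catalogued replacements (LD, LS, LY, LR, FK, SA, FD, FS, FA, LK on the
  stefin side; AW, RW, SW, KF, GW, PF, PL on the cystatin side) the pair most
  similar to the canonical pairs under BLOSUM62 is chosen, leftmost on ties.
  Leftmost-only selection proved fragile: a scaffold's own C-terminal "LK"
  (inside D-A-L-K-Y-F) is itself a catalogued variant and would shadow a
  genuine low-similarity replacement downstream.
* **D-x-L-x-Y-F C-terminus** (`DxLxYF_cterm`): sought in the final 12
  residues. A full match is canonical; a 6-mer that keeps the tyrosine plus
  one more anchor, or both the D and L anchors, is *substituted* (the
  tyrosine's presence is flagged separately because of its role in
  stabilising the inhibitor–protease complex); anything else is absent.
  Atypical stefins are defined by the absence of this region.
* **H at pair−7 and K at Y−8** (`H_minus7`, `K_minus8`): two conserved
  flanking residues, interpreted as exact ungapped-sequence offsets from the
  pair's first residue and from the conserved C-terminal tyrosine. When the
  anchor motif is absent these are reported absent — never at a dangling
  position.

The search windows (trunk = 10, hairpin window = 15–30, C-terminal window =
12 residues) are conventions of this implementation, chosen from the domain's
architecture; they are exposed via `motif_windows()`.

## Classification rules

`classify()` is a pure function of the per-sequence feature vector, applied
in a fixed order:

1. **type 2 cystatin** — cystatin-class pair, signal peptide, ≥ 1 disulfide
   bridge, no D-x-L-x-Y-F. A single bridge is accepted because comb-jelly
   homologues are predicted with only one.
2. **classical stefin** — stefin-class pair, D-x-L-x-Y-F present (canonical
   or substituted), no signal peptide, no bridges.
3. **atypical stefin, type 1** — stefin-class pair, no D-x-L-x-Y-F, no
   signal peptide, no bridges.
4. **atypical stefin, type 2** — as 3 but with a signal peptide.
5. otherwise **unclassified**, with the failing criteria in the rule trace.

The rules are mutually exclusive by construction; contradictory feature
combinations (say an LP pair with two bridges) are left unclassified rather
than forced.

The signal-peptide call is a deliberately simple von-Heijne-style rule
(charged n-region in positions 0–5, ≥ 6 consecutive hydrophobic residues
starting in positions 2–12, small-residue A-x-A-type site ending at position
14–35); disulfides pair cysteines downstream of Q-x-V-x-G sequentially, the
non-crossing topology of the type 2 fold. Both are documented stand-ins for
dedicated predictors; externally produced annotations can be supplied as a
TSV and override the heuristics (`read_feature_overrides()`).

## Intron mapping

`map_introns()` reconciles a genomic sequence with its cDNA: exons must
match exactly, and the minimal number of internal introns is found by greedy
block matching (maximal common prefix, intron opened at the divergence,
resumption at the next exact match of the remaining cDNA) with a full
dynamic-programming fallback. When repeated nucleotides let a boundary slide,
the placement maximizing canonical GT…AG junctions is taken, then the
leftmost; noncanonical junctions are flagged with a warning, never rejected.
The minimum intron length is 4 nt (room for GT + AG), configurable.
Exactness on clean inputs was preferred over tolerance to sequencing error
because at desk scale the inputs are verified sequences; a mismatch-tolerant
mode is intentionally out of scope for v1.

`intron_positions_on_alignment()` projects each insertion point through its
codon to the mature residue and that residue's alignment column, so intron
conservation can be compared across genes; mid-codon introns carry their
phase (1 or 2) rather than being dropped.

## Conservation, distances, trees

Column information content is the WebLogo quantity IC = log2(20) − H over
non-gap residue frequencies. No small-sample correction is applied by
default so the analytic anchors are exact (a constant column gives
log2 20 ≈ 4.322 bits; a 4-way uniform column log2 20 − 2); the correction is
available as a flag. Distances are raw p-distances (mismatches over shared
non-gap columns) because the divergence figures quoted in such surveys are
raw, and `nj_tree()` performs standard neighbor joining (negative branch
lengths clamped to zero with a warning). This small toolkit supports
property-level checks — e.g. that a fast-evolving parasite family forms
relatively long branches (`long_branch_score()`) — and is not a substitute
for likelihood or Bayesian inference, which are out of scope.

## Gain–loss scenarios

Presence/absence of a gene-family character on a rooted species tree is
analysed three ways: Fitch small parsimony (`fitch_min_changes()`, root
state free), Dollo parsimony (`dollo_reconstruction()`, a single gain above
the MRCA of all carriers, minimal losses below), and exhaustive scenario
enumeration (`enumerate_scenarios()`): for every gain count up to
`max_gains` the loss-minimal history is computed by dynamic programming and
ranked by `gain_penalty * gains + losses`. The default gain penalty of 2
encodes that regaining a lost gene family is rarer than losing it; it is a
package convention, exposed as a parameter. Dollo and the enumerator treat
the character as absent *below* the root, so presence at the root costs one
gain on the root branch; Fitch leaves the root free (an all-present
character costs zero changes). With a unit gain penalty the top scenario
cost coincides with the Fitch count whenever a Fitch optimum assigns the
root state 0.

The packaged species tree (`basal_metazoa.nwk`) uses the Ctenophora-sister
rooting of the animal tree, with Cnidaria containing the medusozoan classes
and the parasitic Endocnidozoa (Polypodiozoa + Myxozoa), and Bilateria as a
single expandable tip. Deep metazoan branching is contested and the
"lost-then-regained" scenarios only make sense on a Ctenophora-basal
topology, so the tree is shipped as an editable fixture, not hard-coded.
On this tree, the packaged repertoire matrix (`fig1_repertoire.tsv`) yields
a single-gain Dollo reconstruction of the type 2 cystatin character with
losses on exactly the Porifera, Placozoa, Staurozoa and Myxozoa branches:

```{r dollo}
tree <- read_species_tree(cystakit_extdata("basal_metazoa.nwk"))
m <- read_presence_matrix(cystakit_extdata("fig1_repertoire.tsv"))
dollo_reconstruction(tree, tip_states_from_matrix(m, "type2_cystatin"),
                     "type2_cystatin")
```

## The homology screen

`screen()` is a desk-scale stand-in for an iterative translated-BLAST mining
loop: DNA subjects are translated in six frames, locally aligned
(Smith–Waterman with affine gaps, BLOSUM62, gap open 11 / extend 1 — the
kernel is compiled and checked against an exhaustive dynamic-programming
oracle), and hits are filtered by a Karlin–Altschul-form E-value
`E = K·m·n·exp(−λS)` with fixed ungapped constants λ = 0.267, K = 0.041.
The E-value is a *filter*, not a statistical claim — the usual 1e−5 cutoff is
database-size dependent — so a raw-score threshold is offered as an
alternative. With iteration enabled, matched subject regions join the query
set and screening repeats until no new subject gains a hit, which mirrors
reusing first-round homologues from related species as queries for a second
round; the fixpoint is reached in at most one round per subject.

## The synthetic generator

`make_family()` is the ground-truth source for every other module. It builds
proteins from four scaffolds that realize the subtype architectures (the
50-residue classical stefin `TOY_STEFIN_50`, the two atypical scaffolds
without/with the 15-residue signal peptide, and the type 2 scaffold with PW
pair and four cysteines), optionally plants catalogued pair variants, and
reverse-translates deterministically (one fixed codon per residue, so DNA
fixtures are reproducible across platforms; randomized codon usage is a
non-goal for v1). Introns (0–2 per gene, 8–200 nt, GT…AG) are inserted at
seeded positions kept ≥ 16 nt apart and ≥ 10 nt from the gene ends, because
adjacent or terminal insertion points would make exact placement
ill-defined; ground-truth coordinates are stored in the same canonical
(GT/AG-preferring, leftmost) sliding representation that `map_introns()`
reports, making exact comparison well defined.

Point mutations hit only unprotected sites (everything outside the detected
motif spans, the conserved H/K positions, the signal peptide and the
cysteines) and are drawn from the alphabet D, E, K, N, Q, R, S, T, which
cannot create or extend hydrophobic signal-peptide cores, canonical pairs,
C-terminal anchors or cysteines. A draw that would still perturb the
decision surface (for instance by assembling a catalogued pair upstream of
the planted one from an original residue plus a mutation) is rejected and
resampled. Labels are therefore recoverable by construction at any
configured mutation rate — which is precisely what makes the generator a
usable oracle, and also what its passing tests do *not* show: real
sequences mutate motif positions, insert and delete residues, and carry
signal peptides the heuristic rule misses. Performance on the generator
bounds correctness of the machinery, not recall on real data.

`make_presence_scenario()` plays a named gain/loss scenario (one ancestral
gain with four independent losses; a later eumetazoan gain; two independent
gains) on a tree and returns the tip pattern — on the packaged tree all
three produce the same observed pattern, which is the point: alternative
histories for the same repertoire, distinguished only by their
(gains, losses) signatures.

## Reproducibility and problem sizes

All randomness flows through explicit seeds; pipeline runs
(`run_pipeline()`) write per-stage TSVs with a commented header naming the
tool version and seed, plus a manifest of input/output MD5 digests, and
reruns with the same config are byte-identical. Run configs are plain R
lists or YAML (`read_run_config()`); note that subtype counts live under a
`counts` key because YAML 1.1 reads a bare `n` as a boolean.

The checked-in verification suite runs at these problem sizes, chosen to
exercise every code path while keeping a full run in well under a minute:
2,000 generated sequences (10 families × 50 per subtype) for label
recovery; 200 genes with 0–2 planted introns for the mapper; 1,000 random
pairs (length ≤ 12) against the alignment oracle; 100 random additive trees
(≤ 8 taxa) for neighbor joining; 50 random trees × all tip-state
assignments against exhaustive Fitch enumeration.

## Known limitations

* The signal-peptide and disulfide rules are heuristics; real SignalP/DISULFIND
  output should be supplied as overrides when available.
* The E-value approximation uses fixed ungapped constants; scores, not
  E-values, should be compared across databases.
* The intron mapper assumes exact exon/cDNA agreement; it is not a spliced
  aligner for noisy reads.
* Scenario enumeration and Dollo assume a rooted tree whose tips carry the
  lineage states; polytomies are resolved deterministically, which can
  split ties arbitrarily.
* Multi-domain cystatins (type 3, kininogens) are out of scope throughout.
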