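---
title: "Classifying enterobacterial lysine decarboxylases: genetic context, the C-terminal signature, and domain motions"
author: "ldcsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying enterobacterial lysine decarboxylases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Enterobacteria carry two close paralogues of the PLP-dependent lysine
decarboxylase: the acid-stress-inducible LdcI (also called CadA) and the
biosynthetic LdcC. Both assemble into D5-symmetric decamers, yet only LdcI
is recruited by the AAA+ ATPase RavA into a large cage complex, via a
two-stranded beta-sheet at the very C-terminus of the enzyme. Three
independent lines of evidence classify a given enterobacterial ldc gene as
"ldcI-like" or "ldcC-like":

1. **genetic environment** - *ldcI* sits in an operon with *cadB* (a
   lysine-cadaverine antiporter), while *ldcC* lies between *accA* and
   *yaeR*;
2. **the C-terminal beta-sheet signature** - two short regions (residues
   631-640 and 697 to the C-terminus in E. coli LdcI numbering) carry
   group-specific residues, most strikingly a strict tyrosine (Y697) in
   the ldcI-like group against a lysine in the ldcC-like group;
3. **whole-sequence phylogeny** - a neighbor-joining tree on protein
   distances splits the family into the same two clades.

`ldcsig` implements all three classifiers, checks their mutual
concordance, designs the in-silico analogues of the LdcIC / LdcCI
beta-sheet-swap chimeras, and quantifies the domain motions that
distinguish decamer models of the two enzymes (anchored wing domains
versus swinging C-terminal domains).

## Pipeline and models

### Genetic-environment classification

`classify_by_context()` applies two name-based rules to a gene
neighborhood table (`gene_id`, `taxon`, `strand`, `upstream_gene`,
`downstream_gene`, `same_operon_flag`, `stated_annotation`): an adjacent
cadB-family antiporter flagged same-operon calls *ldcI-like*; accA and
yaeR on the two flanks (either order) call *ldcC-like*. Matching is
case-insensitive exact matching against configurable synonym lists
(`context_synonyms()`); no sequence-level homology search is attempted,
because the classification operates on annotation names and positions.
A record satisfying both rules (possible only with overlapping synonym
lists) returns `unknown`/`ambiguous` rather than silently preferring a
rule; partial contexts (accA without yaeR) return `unknown` rather than
guessing. `audit_annotations()` compares each call with the stated
annotation (`cadA` counts as the ldcI group) and flags conflicts - the
audit that uncovers mis-annotated *ldcC* genes in *ldcI* environments and
vice versa.

### Alignment

`global_align()` is a three-state (Gotoh) Needleman-Wunsch with affine
gaps: a gap of length $k$ costs $g_{open} + k\,g_{ext}$, with BLOSUM62,
$g_{open} = 10$ and $g_{ext} = 0.5$ by default. Traceback ties prefer
substitution over gap states, deterministically. Terminal gaps are
penalized by default (`end_gaps = TRUE`); the free-end (semi-global) mode
is available for fragment comparisons and is used when pairing structure
chains of different length. **Percent identity** is identical residue
pairs over all columns not gapped in both rows (a gap against a residue
counts in the denominator); **percent similarity** additionally counts
pairs with a positive BLOSUM62 score. These conventions are stated
explicitly because published identity/similarity figures rarely specify
them; they are the most common choice for near-full-length homologues.

`progressive_msa()` is a deliberately minimal progressive aligner: UPGMA
guide tree on 3-mer distances ($d = 1 - \mathrm{shared}/(\min L - k + 1)$,
k-mers counted with multiplicity), then leaf-to-root profile-profile
merges under the same affine-gap DP, scoring column pairs by the expected
BLOSUM62 score between residue-frequency profiles. There is no iterative
refinement: for families above ~65% identity, as here, a single
progressive pass already recovers homologous columns, and exact
reproduction of any particular production aligner is a non-goal.
`map_to_reference()` converts alignment columns to the residue numbering
of a chosen row, which is how the E. coli-numbered signature regions are
located in every other sequence (numbering drifts across species, so
positions are *always* resolved through the alignment).

### Consensus profiles and the signature classifier

`build_consensus()` reports per-column residue+gap frequencies,
the majority residue and a conservation height, for the whole family and
per group. Conservation defaults to the majority-residue relative
frequency (0-1); an information-content mode ($\log_2 20 - H$, bits,
gaps excluded) is available. Ties in the majority residue resolve to the
first residue in the fixed alphabet order. Polarity classes for display
follow a fixed four-class table: acidic {D, E}, basic {K, R, H},
hydrophilic {S, T, N, Q, C, G, Y}, hydrophobic {A, V, L, I, P, F, M, W}.
Assigning Y to the hydrophilic class is a judgement call (tyrosine is
amphipathic); the table is stated so outputs are reproducible.

`classify_by_signature()` scores a signature string against per-group
position-specific profiles by log-odds with pseudocount
$\kappa = 0.5$ and a uniform $1/20$ background:
$$ s_g = \sum_{p}\ \log\frac{(c_{g,p}(a_p) + \kappa)/(n_g + 20\kappa)}{1/20}, $$
skipping gap positions. The label is the higher-scoring group, `unknown`
on an exact tie (or below a configurable margin) or when every position
is gapped. The pseudocount keeps small training groups (a handful of
species per group is typical) away from $-\infty$ log-odds; the uniform
background avoids importing composition biases into a 10-30 position
score. Discriminating positions - disjoint majority sets between groups -
are reported by `signature_profiles()`; in real families Y697/K697 is the
canonical example, and it is the one position the synthetic defaults
hard-code.

`design_chimera()` swaps the aligned signature-region residues of a donor
into a backbone, leaving everything else byte-identical, and reports the
junctions. This mirrors the wet-lab beta-sheet-swap constructs: a
backbone of one group with the sheet of the other classifies with the
donor group, just as the physical chimeras gain or lose RavA binding.

### Distances, trees, supports

`pairwise_distance()` offers the raw mismatch fraction (`"p"`), the
Poisson correction $-\ln(1-p)$ (saturated pairs with $p \ge 0.85$ are
capped at 5.0 substitutions/site and flagged rather than returned as
infinities), and `"wag"`: the pairwise maximum-likelihood distance under
the WAG empirical amino-acid model, computed by `phangorn::dist.ml`.
Gapped columns are excluded pairwise; a pair with no ungapped overlap is
an error, not an NA. `nj_tree()` is Saitou-Nei neighbor joining (via
`ape::nj`) with negative branch lengths clamped to zero with a warning.
The combination "NJ on WAG-ML pairwise distances" honors both named
components of the family analysis without a full tree-likelihood search,
which is out of scope.

`bootstrap_supports()` resamples alignment columns with replacement,
rebuilds the tree per replicate (Poisson distances by default - the
replicate loop is the hot path and the correction is closed-form), and
reports for every internal edge the percentage of replicates containing
the same leaf bipartition, computed by canonical split keys rather than
clade matching so that rootings cannot confound the count.
`bipartition_separates()` answers the headline question - does some
internal edge split the tree exactly into the two given groups - and
`group_edge_support()` counts that exact split across replicates.

### Structure comparison: in-context RMSD versus RMSD_min

A monomer is partitioned as wing 1-129, linker 130-183, PLP-binding
subdomain 184-417, subdomain 4 418-563 and CTD 564-715 (core = linker +
PLP-SD + subdomain 4). `domain_rmsd_report()` superposes two models
**once**, globally (default scope: all paired Calpha of the whole
decamer; per-monomer scope is an option since published protocols often
leave this unstated), and then reports per monomer and domain:

* **in-context RMSD** - deviation under the global fit, with *no*
  per-domain refit: sensitive to rigid-body domain motion;
* **RMSD_min** - deviation after the domain's own optimal superposition:
  sensitive only to internal deformation.

$\mathrm{RMSD_{min}} \le \mathrm{RMSD_{in-context}}$ always; a large gap
is the signature of a rigid domain that moved, which is exactly the
wing-versus-CTD contrast: wings anchored at the pore (both values small),
CTDs swinging at the periphery (large in-context, small RMSD_min).
Superposition is Kabsch via SVD with the reflection branch excluded
(determinant forced to +1); collinear point sets are rejected. Same
protein states pair by residue number; cross-protein comparisons (LdcI vs
LdcC) pair through sequence alignment of each chain pair with free end
gaps, dropping indel columns. `segment_centroid_shift()` measures
centroid displacements of short segments (e.g. active-site helices) and
their radial component relative to the 5-fold axis, which is estimated as
the direction of least coordinate variance when not supplied - a decamer
carries no axis annotation in its coordinate file.

Summaries report the min and max over the ten monomers, matching the way
ranges like "between 1.4 and 2 A" are usually quoted.

## The synthetic-data generator

`simulate_ldc_family()` produces, under one seed: a two-group tree (two
random subtrees joined by a long internal branch), sequences evolved
along it under WAG (via `phangorn::simSeq`) with group-specific residues
planted at the signature positions, and a neighborhood table giving
group-A genes a cadB operon partner and group-B genes accA/yaeR flanks,
optionally corrupting stated annotations at a known rate (logged, so
audits can be checked exactly). `gen_toy_decamer()` builds D5 decamers
from five Gaussian domain point clouds and applies a known rigid CTD
swing/stretch before symmetry replication, making the imposed motion the
analytically known answer for the RMSD machinery (a pure radial stretch
of $d$ Angstrom must come back as CTD in-context RMSD $= d$ with
RMSD_min $= 0$ - and does, to machine precision, because the D5-symmetric
displacement field leaves the optimal global superposition at the
identity).

Default study conditions are 11 taxa per group (22 total, the scale of
the published family), full protein length 715, signature regions
631-640 and 697-715 with the Y697/K697 dimorphism planted, 0.5 expected
substitutions/site between groups and 0.15 within, and no indels (so
reference numbering is trivial; when indels are enabled the signature
regions are protected, since the signature positions are ungapped in real
family alignments). The remaining default signature pairs are synthetic,
chosen once as polarity-contrasting disjoint sets - the published
group-specific residue content beyond position 697 is not machine-readable,
so the discriminating-position list is data-derived by design.

**What the generator does not emulate:** among-site rate heterogeneity,
residue coevolution, realistic indel processes, horizontal transfer, and
real protein geometry (the toy decamer is a point-cloud abstraction).
Passing the synthetic checks therefore demonstrates correctness of the
algorithms under the stated model, not robustness to every property of
real data; the reference-reproduction tests (below) exist precisely to
anchor the pipeline to real inputs.

## Problem sizes and numerical choices

The fast end-to-end checks run the pipeline at a reduced scale chosen to
keep a 50-seed sweep comfortable on one core: 20 + 20 taxa, 160-residue
proteins with the signature strands scaled to [60, 69] and [120, 138]
(the same residue pairs as the full-scale table), 0.5 substitutions/site
between groups, 100 bootstrap replicates per family. At this separation
the group edge is expected at >= 95% support - the same reliability
threshold used for the real family tree (500 replicates there; 100
suffice at reduced scale).

Other numerical choices: DP traceback prefers match over gap-in-b over
gap-in-a on exact ties; the Kabsch determinant correction uses the sign
of $\det(VU^\top)$; bootstrap and simulation seeds are explicit arguments
and fully determine outputs; Poisson saturation cap 5.0 at $p \ge 0.85$;
pseudocount 0.5; tie-breaks in consensus majorities follow the fixed
alphabet order.

## Reference data

Two checks reproduce published reference numbers and need public inputs
that are not bundled: the E. coli LdcI vs LdcC global alignment
(~69% identity, ~84% similarity) needs the two UniProt sequences, and the
domain RMSD ranges need the deposited decamer models (3N75, 5FKX, 5FKZ,
5FL2 biological assemblies). `scripts/fetch_reference_data.R` downloads
them into `inst/extdata/reference/` (network required); after
reinstalling, the corresponding acceptance tests run against them. In an
offline environment those two tests report the missing inputs and fail;
everything else is self-contained.

## A worked example

```{r example}
library(ldcsig)

params <- simulation_params(n_taxa_per_group = 11, seed = 42)
fam <- simulate_ldc_family(params)
seqs <- setNames(as.character(gsub("-", "", unclass(fam$alignment))),
                 names(fam$alignment))

report <- run_concordance(seqs, fam$neighborhoods,
                          n_boot = 100, seed = 1)
print(report)

prof <- build_consensus(fam$alignment, group_labels = fam$groups)
plot(prof, group = "A", columns = 690:715)

td <- gen_toy_decamer(toy_decamer_spec(ctd_stretch = 4))
domain_rmsd_report(td$reference, td$moved)
```

## Known limitations

* The context classifier trusts annotation names; a renamed antiporter
  gene defeats it (synonym lists are the extension point).
* The progressive aligner has no refinement pass and is not meant to
  match any specific production aligner column-for-column.
* Trees are unrooted and distance-based; no maximum-likelihood topology
  search, no rate heterogeneity.
* Structure comparison is Calpha-only and rigid-body; flexible fitting
  and density-map handling are out of scope.
* With only two flanking-gene slots per record, genuinely ambiguous
  environments are representable only through synonym overlap.
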