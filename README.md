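# ldcsig

Comparative analysis of the enterobacterial lysine decarboxylase family:
the acid-stress-inducible **LdcI** (CadA) and its biosynthetic paralogue
**LdcC**. Although the two enzymes are close paralogues forming
near-identical D5-symmetric decamers, only LdcI binds the AAA+ ATPase
RavA, through a two-stranded beta-sheet at its C-terminus. `ldcsig` is
for sequence/structure bioinformaticians who want to classify an
enterobacterial *ldc* gene and quantify what distinguishes the two
groups, three independent ways:

* **genetic environment** — *ldcI* is operonic with the antiporter gene
  *cadB*; *ldcC* sits between *accA* and *yaeR*. `classify_by_context()`
  applies these rules and `audit_annotations()` flags genes whose stated
  annotation contradicts their environment;
* **the C-terminal beta-sheet signature** — residues 631–640 and
  697–C-terminus (E. coli LdcI numbering), with a strict Y697 in the
  ldcI-like group versus K697 in the ldcC-like group.
  `classify_by_signature()` scores a sequence from these positions alone
  by per-group log-odds,
  `s_g = Σ_p log[((c_{g,p}(a_p)+κ)/(n_g+20κ)) / (1/20)]`,
  and `design_chimera()` builds the in-silico beta-sheet-swap chimeras
  (LdcIC / LdcCI);
* **phylogeny** — neighbor-joining on WAG maximum-likelihood (or
  Poisson-corrected) protein distances, column-resampling bootstrap
  supports, and an exact bipartition test for the two-group split
  (`nj_tree()`, `bootstrap_supports()`, `bipartition_separates()`).

`run_concordance()` chains all three and reports their pairwise
agreement. A structural module (`domain_rmsd_report()`) compares decamer
models domain by domain, separating **in-context RMSD** (after one global
superposition, no per-domain refit) from **RMSD_min** (each domain
optimally superposed): rigid domains that move — the swinging CTDs —
show a large gap between the two, while the wing domains anchoring the
decamer pore show neither. A seeded synthetic-data generator
(`simulate_ldc_family()`, `gen_toy_decamer()`) provides tree-evolved
two-group families with planted signatures and D5 toy decamers with
known rigid CTD motions, so the whole pipeline is testable offline.

## Worked example

```r
library(ldcsig)

params <- simulation_params(n_taxa_per_group = 11, seed = 42)
fam <- simulate_ldc_family(params)
seqs <- setNames(as.character(gsub("-", "", unclass(fam$alignment))),
                 names(fam$alignment))
run_concordance(seqs, fam$neighborhoods, n_boot = 100, seed = 1)
```

```
Concordance of context / signature / tree groupings
  taxa: 22   tree split separable: TRUE
  context vs signature: 100.0%
  context vs tree:      100.0%
  signature vs tree:    100.0%
  group-edge bootstrap support: 100.0% (100 replicates)
  no discordant taxa
```

All 22 simulated taxa are classified identically by their gene
neighborhood, by their C-terminal signature alone, and by the tree: the
internal edge separating the two groups is present in every bootstrap
replicate. The structural module recovers a known rigid CTD motion from
a toy decamer:

```r
td <- gen_toy_decamer(toy_decamer_spec(ctd_stretch = 4))
domain_rmsd_report(td$reference, td$moved)
```

```
Domain RMSD report (decamer-scope global fit, 10 monomers)
              in-context RMSD (A)          RMSD_min (A)
wing             0.00 -      0.00      0.00 -      0.00
linker           0.00 -      0.00      0.00 -      0.00
plp_sd           0.00 -      0.00      0.00 -      0.00
subdomain4       0.00 -      0.00      0.00 -      0.00
ctd              4.00 -      4.00      0.00 -      0.00
core             0.00 -      0.00      0.00 -      0.00
```

The imposed 4 Å rigid CTD translation appears as an in-context RMSD of
exactly 4 Å with RMSD_min 0 — the fingerprint of a rigid-body domain
motion — while every other domain is unchanged.

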