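# editoscan

Proteogenomic detection of A-to-I mRNA editing from peptide evidence.

## The problem

A-to-I mRNA editing deaminates adenosine to inosine, which the ribosome
reads as guanosine: at the codon level an edit behaves as an A→G
substitution. A nonsynonymous edit therefore produces a peptide carrying a
single-amino-acid variant (SAAV) that no genome-derived search database
contains — and editing of the amber stop codon (UAG→UGG, Trp) causes
translational readthrough and a novel protein C-terminus. editoscan is for
proteomics/proteogenomics researchers who want to find such events in
bottom-up MS data and, more broadly, to use peptide evidence to refine a
genome annotation.

## What the package computes

The codon-level core: a substitution `x → y` at protein position *p* is an
editing candidate iff the coding-strand codon `c` at *p* satisfies

    translate(c) = x  and  ∃ S ⊆ A-positions(c), S ≠ ∅ :
    translate(c with A→G at S) = y

(default |S| = 1). Its expected precursor mass shift is the residue-mass
difference `m(y) − m(x)` — e.g. K→E = +0.94763 Da, R→G = −99.07965 Da —
and candidates whose shift is indistinguishable from N-terminal
acetylation (+42.01056 Da at the peptide N-terminus) or deamidation
(+0.98402 Da anywhere) are discarded before the codon check.

Error control is class-specific target-decoy FDR: with decoy matches as a
null sample, FDR(s) = #decoys ≥ s / #targets ≥ s, monotonised into
q-values, computed independently per peptide class (known / novel / SAAV /
stop-loss) and per step of a stepped database search (spectra accepted at
q ≤ 0.01 in one step are excluded from the next, larger database).

Around the core: six-frame/decoy/hybrid database construction, in-silico
trypsin and Glu-C digestion, peptide-to-genome mapping with I/L
equivalence (BED12 and proBAM-style SAM export), rule-based annotation
refinement from novel peptides plus RNA-Seq coverage, phylostratigraphic
age assignment from homology hit tables, Fig-style QC metrics (ppm
deviation, retention-time vs hydrophobicity correlation, PRM transition
filtering), and a fully seeded synthetic-data generator with ground truth.
See `vignettes/editoscan-methods.Rmd` for the methods account.

## Worked example

```r
library(editoscan)

world <- synth_genome(n_genes = 40, n_novel_genes = 4, seed = 7)
world <- plant_edits(world, n_saav = 12, n_stoploss = 2, seed = 7)

saavs <- call_saavs(world$truth$edited_peptides, world$proteins,
                    world$genome, world$annotation)
dplyr::count(saavs, class, sort = TRUE)
#> # A tibble: 9 × 2
#>   class     n
#>   <chr> <int>
#> 1 K->E      3
#> 2 I->V      2
#> 3 K->R      1
#> 4 M->V      1
#> 5 Q->R      1
#> 6 R->G      1
#> 7 S->G      1
#> 8 T->A      1
#> 9 Y->C      1

stoploss <- detect_stop_loss(world$truth$edited_peptides, world$proteins,
                             world$genome, world$annotation)
stoploss$events[, c("gene_id", "stop_codon", "extension_length")]
#> # A tibble: 2 × 3
#>   gene_id stop_codon extension_length
#>   <chr>   <chr>                 <int>
#> 1 g0013   TAG                      35
#> 2 g0014   TAG                      69
```

All 12 planted SAAVs come back with their correct class, codon and edited
offset (`call_saavs()` verifies `translate(ref_codon) == ref_aa` and the
A→G reachability for every call), and both planted stop-loss genes are
recovered with their full readthrough extensions — TAG stops only; a Trp
junction peptide at a TAA/TGA stop is reported as rejected, not called.

Single constants print exactly as expected from the mass table:

```r
substitution_mass_shift("K", "E")
#> [1] 0.9476301
theoretical_denovo_fdr(118, 5)
#> [1] 4.2
```

A thin command-line wrapper over these functions ships in
`inst/cli/editoscan.R` (subcommands `build-db`, `editscan`, `refine`,
`phylo`, `synth`, `run-all`).

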