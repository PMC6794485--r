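---
title: "Detecting A-to-I mRNA editing from peptide evidence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I mRNA editing from peptide evidence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editoscan)
```

## The problem

Adenosine-to-inosine (A-to-I) mRNA editing changes single bases of a
transcript after transcription; because inosine pairs like guanosine, the
ribosome reads an edited codon as if A had been replaced by G. When the
edit is nonsynonymous, the translated protein carries a single-amino-acid
variant (SAAV) that is invisible to a conventional database search, since
the genome-derived protein database only contains the unedited residue. A
special case is stop-loss editing: editing the amber stop codon UAG to UGG
(Trp) lets translation continue to the next in-frame stop, producing a
C-terminally extended protein.

editoscan detects both event types from mass-spectrometry peptide
evidence, and embeds that detection in a proteogenomic workflow: six-frame
and hybrid search databases, stepped searches with class-specific
target-decoy false discovery rates, peptide-to-genome mapping with BED12
and proBAM-style SAM export, rule-based genome-annotation refinement with
RNA-Seq support, and phylostratigraphic age assignment. The package is
aimed at fungal-scale genomes (compact genes, short GT..AG introns), but
nothing in the code is organism-specific.

## Coordinates, translation, and databases

All internal coordinates are 0-based half-open on the forward genomic
strand; GFF3's 1-based closed convention is converted at the I/O boundary.
Translation uses the standard genetic code (NCBI table 1) by default, with
the table id configurable in `translate_nt()`.

`six_frame_translate()` numbers frames 0–2 per strand from position 0 of
that strand's reading, and keeps all fragment coordinates on the forward
strand, so back-mapping is unambiguous. Translations are split at stop
codons; fragments shorter than `min_fragment_len` (default 7 residues,
one more than the shortest peptide retained downstream) are dropped. Very
long contigs can be processed in overlapping chunks (`chunk_len`,
`chunk_overlap`); chunking is off by default because whole-contig
translation is exact, and when it is on, duplicate fragments from the
overlaps are removed at mapping time (`dedup_fragments()`). Frame numbers
are computed globally, so chunked and unchunked runs agree on provenance.

Decoys are full-sequence reversals, one per target, with a configurable id
prefix; reversal preserves amino-acid composition, which the decoy-based
error model relies on. Palindromic sequences whose decoy equals the target
are flagged rather than silently kept. The hybrid database for the
editing-candidate search round appends each candidate peptide as its own
entry next to the refined proteins, deduplicated after I/L collapsing.

## Digestion and mass arithmetic

Trypsin cleaves C-terminal to K/R but not before P (the rule can be
switched off); Glu-C cleaves after E only, matching its specificity in
ammonium-bicarbonate buffer, with cleavage after D available behind
`cleave_d`. Peptides default to 6–50 residues and up to 2 missed
cleavages. Monoisotopic residue masses are carried at full precision; the
mass shift of a substitution is simply the residue-mass difference, so the
twelve editable exchange classes (K→E +0.94763 Da through I→M
+17.95643 Da) follow from the mass table with no fitted constants.

Two shifts are intrinsically ambiguous and are removed before codon
checks: +42.0106 Da at a peptide N-terminus (Ser→Glu, indistinguishable
from N-terminal acetylation) and +0.9840 Da anywhere (Gln→Glu and
Asn→Asp, indistinguishable from deamidation). The prefilter tolerance is
5e-4 Da, an order of magnitude below the distinguishing precision of a
high-resolution instrument but far above double-precision noise.

## Stepped search and class-specific FDR

The search engine shipped with the package (`naive_score()`: matched
fraction of theoretical singly-charged b/y ions) exists so synthetic
end-to-end runs need no external software; it is deliberately simple and
deterministic, and any real study would substitute production search
engines. What the package does own is the error control around the
engine:

* q-values use FDR(s) = #decoys ≥ s / #targets ≥ s, monotonised over
  thresholds at or below each PSM's score. No +1 pseudocount is added by
  default (`plus_one` switches the conservative variant on). Tied scores
  share a threshold, with decoys counted before targets — the
  conservative direction.
* `stepped_search()` searches databases in order and removes spectra
  accepted at the per-step threshold (default q ≤ 0.01, PSM-level) before
  the next, larger database. This keeps the abundant matches to the known
  proteome from diluting the error estimate of the rare novel matches.
* `class_specific_fdr()` recomputes q-values independently within each
  peptide class (known, novel, SAAV, stop-loss). Class isolation is exact
  by construction: the acceptance set of one class cannot depend on the
  composition of another. A class without decoys cannot be error-
  controlled; its members get q = 0 plus an explicit warning record
  rather than a silent guess.

Posterior error probabilities are treated as pass-through annotations for
QC plots; the package does not estimate them.

## Calling SAAVs and stop-loss events

De novo peptides are aligned to the annotated proteins allowing at most
one substitution, after collapsing I to L on both sides (Ile/Leu are
isobaric; I↔L differences are never treated as variants, and peptides
with more than one mismatch are ignored). Surviving candidates go through
the ambiguity prefilter, then a strand-aware codon lookup: the reference
codon is always read on the coding strand, so a single code path serves
both strands, and the package's strand-symmetry test (reverse-complement
the whole genome, flip the annotation, expect the identical call set)
holds exactly. `a2i_feasible()` finally asks whether replacing one A by G
(or any non-empty subset of A positions, behind `allow_multi`) yields the
observed residue; the default is single-site edits because all twelve
observed exchange classes are single-edit reachable, and multi-site edits
of one codon are correspondingly rarer. Candidates record the codon, the
edited offsets, the mass shift, whether the unedited counterpart peptide
was also observed, and a reserved pass-through column for external
pathogenicity scores.

Stop-loss calls require three things at once: a peptide whose prefix
matches an annotated protein's C-terminal suffix, a Trp aligned exactly to
the stop position, and a genomic TAG at that stop. Evidence at TAA/TGA
stops is recorded as rejected ("non-UAG stop") instead of being dropped
silently, because a Trp-bearing junction peptide at a non-amber stop is
exactly the kind of observation a reviewer should see. The extension is
translated by TAG→Trp readthrough to the next in-frame stop, assuming no
intron between the old and the new stop — a deliberate simplification
that holds in the synthetic worlds and in compact genomes, and is stated
here as a limitation. Peptides falling entirely inside the extension
attach as supporting evidence.

`manual_review_export()` augments each candidate with isobaric
modification explanations (from an editable delta table) that could
equally explain the observed shift on the mismatched or a neighbouring
residue; nothing is auto-discarded at this stage, mirroring a
manual-review step.

## Annotation refinement rules

Evidence bundles collect, per locus, the distinct novel peptides (I/L
deduplicated), the known peptides, the median RNA-Seq depth, an external
homology flag, and geometry flags. The rule engine is a pure function of
the bundle:

* refinements of existing genes need either ≥2 distinct novel peptides,
  or 1 novel peptide plus ≥1 known peptide when the geometry indicates a
  splice-site or TIS change;
* novel genes in intergenic space are class I (high confidence) with ≥2
  distinct unmodified unique peptides longer than 8 residues and
  sufficient RNA-Seq depth; class II (medium confidence) with one such
  peptide and sufficient depth, or ≥2 peptides with insufficient depth
  but homology support; otherwise rejected.

"Sufficient depth" is a median-depth threshold, default 10×, configurable
and deliberately prominent: the underlying notion is qualitative and any
specific cutoff is a package decision. Intergenic hits cluster into one
locus while gaps stay under 500 nt (typical fungal intergenic scale).
When a bundle's geometry supports several types, precedence is
splice_site > TIS > extension > frameshift; fusion and fission come from
their own flags. Junction coverage counts a junction as covered when a
peptide's blocks abut the intron with at least one (possibly partially
encoded) residue on each side — the weakest defensible rule, with the
flank width configurable.

`apply_refinements()` only applies calls whose resulting gene model
re-validates (exon sorting, frame, terminal stop); conflicting calls on
one gene are logged and none applied. Frameshift/fission/fusion
restructuring requires explicit coordinates and is otherwise log-only,
reflecting that these edits are curation decisions rather than mechanical
ones.

## Phylostratigraphy

A protein's phylostratum is the oldest level of a 15-level taxonomy map
producing at least one homology hit with E-value strictly below 1e-5; no
qualifying hit assigns the youngest level. A hit's own level is the
deepest map entry whose taxon token equals a field of the subject's
semicolon-delimited lineage; field equality rather than substring
matching keeps nested rank names (a genus contained in an order name)
from cross-matching. The shipped 15-level map anchors the oldest level at
"cellular organisms" and the youngest at *Sordaria macrospora*; the
thirteen intermediate ranks are a reconstruction from the standard NCBI
lineage and ship as an editable TSV, since any other focal species needs
its own map. The heat-table export averages the log10 E-values of up to
the 5 best hits per level and orders rows by Ward-linkage hierarchical
clustering; empty cells carry a sentinel of 0 (= log10 of a hopeless
E-value of 1).

## QC metrics

Precursor deviations are reported in ppm against the theoretical
monoisotopic mass. The hydrophobicity index used for the retention-time
correlation is a simple additive per-residue model — the QC logic needs
only a score whose correlation with retention time separates genuine
identifications from decoys, and externally computed indices can be
supplied instead. PRM transition sets pass when the spectral dot product
(cosine similarity of square-root-transformed intensities — the named
statistic leaves the transform open, and the square root is the common
variance-stabilising choice) reaches 0.85, no transition deviates by more
than 1.3 ppm, at least 2 transitions were monitored, and edited peptides
include at least one SAAV-diagnostic transition.

## The synthetic-data generator

`synth_genome()` builds 2 contigs with 150 annotated genes (80–250
residues, 0–3 GT..AG introns in ~60 % of genes, both strands in equal
proportion) plus 10 hidden genes left out of the annotation, separated by
random spacers — a deliberately fungal-like geometry. `plant_edits()`
plants 40 SAAVs with class weights proportional to the observed class
frequencies (K→E most common) and 4 stop-loss events on TAG-terminated
genes whose readthrough extension is 10–150 residues, and records for
every event the digestible peptide that would reveal it.
`synth_observations()` samples peptide observations (detection
probability 0.7 for canonical peptides), draws true-match scores from
N(3.5, 1) against an N(0, 1) null shared by decoys and false matches,
plants Gaussian 1 ppm precursor errors, makes retention time linear in
hydrophobicity for targets and shuffled for decoys, and corrupts 5 % of
the de novo list (matching a 5 %-FDR de novo input). All randomness flows
through the seed arguments; identical seeds give identical objects.

What the generator does **not** emulate: chimeric and noise spectra,
intensity-dependent fragmentation, retention-time drift, shared peptides
between paralogues, sequencing errors in the genome itself, and partial
codon-level editing stoichiometry. Passing the recovery tests therefore
demonstrates that the logic is correct on clean data with known truth —
not that real-data sensitivity would reach the same numbers.

Problem sizes in the shipped tests and the acceptance script — a
150-gene default world, 20 replicate score mixtures of 5,000 PSMs for FDR
calibration, 100 proteins for phylostratigraphy — were chosen so the full
cycle runs in a few minutes on a single core while keeping every binomial
check adequately powered.

## Numerical and degenerate-input choices

* Mass-table comparisons use an absolute 1e-5 Da tolerance (the precision
  at which shift tables are conventionally printed); ppm tolerances are
  used for spectra.
* `compute_qvalues()` with zero targets returns q = 1 everywhere; an
  empty spectrum or peptide is an error, not a zero score.
* Codons containing N give an indeterminate (flagged) feasibility verdict
  rather than a guess.
* Hierarchical clustering is skipped for fewer than three rows; a single
  protein is returned unclustered.
* `locus_median_depth()` counts positions absent from the coverage table
  as zero — missing coverage is evidence of absence for this purpose.

## Known limitations

The stand-in scorer has no noise model, so search-level results on
synthetic data are cleaner than any real search. Stop-loss extensions are
translated without introns. Exon-spanning peptide mapping relies on the
gene models (spliced alignment to unannotated junctions is out of scope),
so a junction absent from the annotation can only be reached through the
refinement rules, not through direct mapping. Protein inference and
grouping are out of scope; peptide uniqueness is defined at the genomic
locus level after I/L collapsing.
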