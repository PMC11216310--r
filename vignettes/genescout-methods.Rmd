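---
title: "How genescout finds pathway genes in unannotated assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How genescout finds pathway genes in unannotated assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

genescout answers a narrow question: given an assembled but unannotated
genome and the protein sequences of a list of genes — typically all genes of
a pathway, with one or more isoforms per gene — where are those genes in the
assembly, and which of them are genuinely present at all? It is not a
whole-genome annotator; it spends effort only where a query gene plausibly
lives, and it is explicitly orthology-aware: a query gene may have no
ortholog in the target species, and reporting nothing for it is then the
correct answer.

## The pipeline

The method is a chain of six stages, each with a deliberately small
contract.

**1. Query quality control.** Isoform FASTA headers encode
`gene_id|isoform_id`. Sequences containing the ambiguous amino acids B, J,
O, U or Z are removed (`X` is kept and scores zero in every alignment
stage), and exact duplicate sequences are collapsed to their first
occurrence. If nothing survives, the run stops with "no usable queries".

**2. Translated similarity search.** Queries are compared against the
six-frame translation of the genome. Production runs can delegate this to an
external translated-search tool through a command template (anything that
writes 12-column BLAST tabular output works; `tblastn` is exercised in the
test suite). The package also ships a builtin reference backend so that
every downstream stage is testable without external binaries: exact 5-mer
seeds, at most one seed per (query, frame, diagonal), ungapped extension
under BLOSUM62 with an X-drop of 20, and a bit-score floor of 40
(Karlin–Altschul ungapped parameters λ = 0.3176, K = 0.134). The builtin
backend reports e-values only as a bits-derived placeholder; nothing filters
on them. Every high-scoring pair (HSP) is stored in 0-based half-open
forward-strand coordinates — a single internal convention, converted to
1-based GFF3 or BED only at file boundaries.

**3. Candidate regions.** HSPs are partitioned by (gene, contig, strand);
within a partition, coordinate-sorted HSPs separated by less than 100,000 bp
(end-to-start; overlapping HSPs always merge) are chained into one region,
which is then extended by a 10,000 bp margin on each side and clipped to the
contig. Where several isoforms align at an exactly identical location, only
the five best by bit score are retained (ties broken by isoform id). Each
region carries two summary features forward: the best percent identity and
the best query coverage among its members.

**4. Hints and gene prediction.** Within each region the retained isoforms
are re-aligned to the region sequence and every matched block becomes a
`CDSpart` protein hint (`src=P`), the dialect hint-aware predictors consume.
Gene prediction is again pluggable: an external predictor can be run per
region with the archetype-species parameter for the genome's taxonomic class
(mammals→human, fish→zebrafish, birds→chicken, eudicotyledons→arabidopsis,
liliopsida→wheat). The builtin reference predictor is intentionally modest:
every complete single-exon ORF (ATG through stop) of at least 60 protein
codons, on both strands, taking per in-frame stop the earliest start codon
after the previous stop. Models lacking a start or a stop are never
reported. Each model records its *hint support*: the percentage of CDS bases
covered by at least one same-strand hint — a set-union definition, so
fragmenting a hint into adjacent pieces does not move the number. Because
the builtin predictor is single-exon, the bundled simulator plants
intronless genes; this keeps the no-dependency test path honest rather than
pretending to be an HMM gene finder.

**5. Validation alignment.** Each predicted protein is re-aligned to every
retained isoform of its region's gene with an *ungapped* model: the query is
slid across the prediction over all relative offsets and the full overlap
window at each offset is scored under BLOSUM62 (ties go to the smallest
offset). The best window yields three statistics: percent identity, percent
similarity (columns with positive substitution score; identical columns
count as similar even when the residue scores zero, so similarity can never
fall below identity), and query coverage (window length over query length —
the query is the denominator, consistent with the search-stage coverage
feature). The best-scoring isoform represents the model.

**6. Filtering and selection.** Every candidate is summarised by six
features in fixed order — search percent identity, search gene coverage,
hint support, validation percent identity, validation percent similarity,
validation gene coverage — and scored by a small dense network (layers of 4,
2 and 1 neurons, sigmoid output) trained with Adam at learning rate 1e-5 on
binary cross-entropy. Scored candidates are reduced to the final report by
three ordered rules: among same-strand candidates whose CDS spans overlap
(transitively), only the highest probability survives; per gene, every
candidate above 0.95 times the gene's best probability is kept (near-ties
are real signal — polyploid genomes legitimately carry several copies); and
finally only candidates at or above the calibrated decision threshold are
reported.

## Training and calibrating the filter

The filter is trained per run (or reused from a serialized archive) on
labeled candidates: run the pipeline with `--no-filter` on data with known
loci, label each candidate 1 if its CDS span overlaps its own query gene's
true locus by at least one base and 0 otherwise. Labels are heavily
imbalanced — decoy ORFs outnumber true genes — so the minority class is
oversampled to exactly 1:1 with SMOTE (k = 5 minority neighbours, convex
interpolation, seeded; with a single minority example the fallback is
duplication, with a warning). The decision threshold is then chosen as the
largest value among the sorted unique training probabilities whose
sensitivity is still at least 0.95. Read literally, "the lowest threshold
with sensitivity above 0.95" is degenerate — every sufficiently low
threshold qualifies — so the package takes the other end of the admissible
prefix, which maximises specificity subject to the sensitivity floor.
Calibration is done on the *pre-balancing* candidates, so the quoted
sensitivity refers to real positives, not SMOTE interpolations.

Three numerical choices here were genuinely open and deserve their
rationale:

* **Hidden activation: leaky ReLU (slope 0.01), not plain ReLU.** All six
  features are non-negative, so every input lies in the positive orthant.
  With plain ReLU and Glorot initialisation this tiny network dies easily:
  an unlucky draw leaves both units of the second hidden layer inactive for
  every input, no gradient ever reaches the hidden weights, and the output
  collapses to a constant 0.5. On a wide-margin linearly separable set this
  happened for 10 of 10 data seeds; with the leaky slope the same
  configurations all reach perfect training accuracy. The slope is recorded
  in the model metadata.
* **Epochs: 10000 (batch 32), not a few hundred.** Adam normalises step
  sizes, so total parameter movement is bounded by epochs × batches × 1e-5;
  at a few hundred epochs the weights provably cannot leave their
  initialisation basin at this learning rate. 10000 epochs trains the
  separable reference set to accuracy 1.0 in seconds and the realistic
  simulated training sets in about three minutes on one CPU.
* **Raw features, no standardisation.** The feature ranges are bounded by
  construction (percentages and fractions), and the leaky activation removes
  the saturation pathology that scaling would otherwise have to fix.

The serialized model archive is JSON with layer shapes, the feature order,
training metadata, and every weight written as a C99 hexadecimal float
literal, so a reloaded model reproduces probabilities bit-identically
(decimal JSON loses the 17th significant digit).

## Evaluation semantics

A gene is the genomic region from its start codon through its stop codon.
Against a truth annotation plus an ortholog-presence table, a *present*
query gene counts as a true positive if any reported locus for it overlaps
its true region by at least one base, and a false negative otherwise; an
*absent* query gene with no reported locus is a true negative; every
reported locus that does not overlap its own gene's truth region is a false
positive (including all loci claimed for absent genes). Sensitivity,
specificity, PPV and NPV follow, with zero denominators reported as
undefined rather than silently zero. For true positives the package also
reports gene coverage (overlap of the predicted span with the truth region,
over the truth region length) and exon coverage (truth CDS bases covered by
predicted CDS intervals). Each reported locus is additionally categorised
against the annotation with fixed precedence: correct > paralog (an
annotated paralog of the query) > other gene > pseudogene > intergenic. A
`presence` mode scores presence/absence only — the right comparison for
fragmented assemblies where locations cannot be trusted.

## The simulator: what it does and does not emulate

`generate_fixture()` builds a self-consistent test world: multi-contig
genomes with i.i.d. background sequence at a configurable GC (default 0.40),
planted complete intronless ORFs (default five genes of 80–150 codons, both
strands), queries derived from the planted proteins at a controlled
substitution divergence (default 10%), paralog decoys (diverged copies,
default 30% divergence, planted elsewhere and recorded in a paralog table),
pseudogene decoys (copies with an internal 1-bp frameshift), and absent
queries with no planted source (random proteins). Truth GFF3 and
ortholog/paralog tables are emitted alongside. Everything is deterministic
in the seed, byte for byte.

Deliberate simplifications, and what they imply about test evidence:

* **Substitution-only divergence.** No indels, so the ungapped validation
  aligner is a faithful stage on fixtures. Real orthologs accumulate indels;
  on real data the validation statistics will be systematically lower and
  the filter threshold should be calibrated on realistic training genomes.
* **Intronless genes** (matching the builtin predictor). Multi-exon
  prediction quality is a property of the external predictor, not of this
  package, and is not measured by the test suite.
* **Planted loci at least 5 kb apart** (a simulator choice: spacing of two
  full 10 kb margins cannot host the default fixture in a 100 kb contig).
  Candidate regions of neighbouring loci therefore overlap, which is exactly
  the decoy pressure the filter must resist; overlap-based labels remain
  unambiguous at this spacing.
* **i.i.d. background.** Decoy ORFs emerge at the natural random rate — the
  negatives the filter learns to reject — but there are no repeat families,
  no synteny, no GC isochores.

Passing tests on these fixtures show the machinery is correct and
deterministic; they do not show field performance on real genomes.

## Problem sizes and degenerate inputs

The bundled test suite and the acceptance script run entirely on simulated
data chosen to exercise every code path at desk scale: oracle equivalence of
the region builder on 500 random HSP sets (≤ 200 HSPs), of the builtin
search against per-frame Smith–Waterman on 50 small genomes (4 kb), and of
the validation aligner against exhaustive-offset brute force on 200 random
pairs (≤ 100 aa); end-to-end recovery on a 100 kb fixture with five planted
genes, two paralogs, two pseudogenes and two absent queries; filter training
on a four-contig, 600 kb fixture with 40 planted genes and 20 absent
queries (~1000 candidates). Degenerate inputs have defined behaviour:
contigs shorter than one codon are skipped with a warning, regions shorter
than 180 nt yield no builtin predictions, an empty hint list gives zero hint
support, empty predicted proteins are a validation error, single-class
labels refuse to train, and a query set that is empty after QC stops the
run.

## Known limitations

The builtin backends are reference implementations, not replacements for a
profile-aware search or an HMM gene finder: no gapped extension in the
search, no introns or UTRs in prediction, no isoform graphs. The e-value of
the builtin search is uncalibrated by design. Orthology is consumed, never
inferred — the ortholog-presence table is an input. The near-tie retention
ratio applies at gene-level deduplication only. Thread-level parallelism is
not implemented; all stages are deterministic single-CPU code, which is also
what makes byte-identical reruns cheap to guarantee.
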