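---
title: "Methods: models, parameters and design choices in hydratx"
author: "hydratx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in hydratx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each
stage computes, which assumptions it makes, which knobs matter, and
where the design was genuinely open and a choice had to be made.  It
also states what the synthetic-data generator does and does not emulate,
so that the meaning of a passing test suite is clear.

# The problem

Hybrid Illumina–454 transcriptome projects combine short, accurate,
substitution-dominated reads with long, homopolymer-indel-prone reads.
Assemblies of such data carry three characteristic burdens that this
package addresses in code:

1. **Redundancy** — allelic variants, splice forms and fragmented or
   frameshifted duplicates of the same gene inflate sequence counts; a
   principled removal procedure and a redundancy estimate are needed
   before a dataset can be interpreted as "genes".
2. **Platform artifacts** — barcodes, adapter read-through, trans-spliced
   leader remnants on contig edges, terminal homopolymer errors and
   low-quality tails must be removed with explicit, reproducible rules.
3. **Comparative questions** — which assembled transcripts are missing
   from genome predictions (and vice versa), which of those are
   contaminants, pseudogenes or genuine novel genes, and how deeply the
   read data saturates the transcriptome.

# The alignment engine

Every stage aligns through one internal engine: exact-word seeding
(words of 11 nt, or 4 residues over the 20-letter alphabet for
proteins) followed by banded affine-gap Smith–Waterman extension of
diagonal seed clusters.  Seeds whose diagonals differ by at most 16
merge into one cluster; the band pads the cluster's diagonal range by 32
on each side, so indel drift up to that magnitude is captured.  Sparse
clusters (fewer than three seed words) must first pass an ungapped
X-drop extension score (18 for nucleotides, 22 for proteins) before the
banded DP is run — the classic BLAST two-stage trigger, which discards
the abundant spurious single-word seeds of low-GC sequence cheaply.

Scoring defaults are megablast-like for nucleotides (match +1, mismatch
−2, gap open 5, gap extend 2; a gap of length L costs `open + L·extend`)
and BLOSUM62 with gap open 11 / extend 1 for proteins.  `N` mismatches
everything, including another `N`.  E-values use the Karlin–Altschul
form `E = K·m·n·e^{−λS}` with fixed constants per scoring scheme
(nucleotide λ = 1.28, K = 0.46; protein λ = 0.267, K = 0.041).  The
constants are documented, not estimated: every threshold in the pipeline
(1e-30, 1e-10, 1e-8) gates hits, so the ordering of E-values matters and
their absolute calibration does not.

**Identity** is always computed over all alignment columns, with a gap
column counting as a non-match (BLAST's `pident` convention).  This is
stated explicitly because per-cent-identity thresholds (95%, 98%)
permeate the pipeline and the denominator choice changes them.

**Verification.**  The tests compare the engine's top hit against full
Smith–Waterman (`Biostrings::pairwiseAlignment`) on hundreds of mutated
pairs: scores must agree exactly on every instance.  Identity is asserted
within 2 percentage points rather than exactly, because co-optimal
alignments of equal score can place gaps differently and therefore have
different column identity — "the" identity of an optimal local alignment
is not unique.  In practice > 90% of instances agree to machine
precision.

**Soft masking** marks positions covered by any 12-residue window whose
Shannon composition entropy falls below 1.5 bits (a dust-like
heuristic).  Masked positions are excluded from seeding only; extension
still scores them.  This matters for the redundancy index: hard masking
would push near-identical pairs below the 98% identity gate whenever a
low-complexity stretch were counted as mismatches.

# Read cleaning

The Illumina pipeline applies, in fixed order: barcode stripping (5 bp),
exact adapter-prefix truncation (first 12 bp of each adapter, anywhere
in the read), inexact 3'-anchored adapter trimming (≥ 8 nt overlap, at
most one mismatch — a re-specification of an external tool's behaviour
that is not otherwise reproducible), removal of 3'-terminal homopolymer
runs longer than 5 nt (the *entire* run, following the literal reading
of "removed"), discarding reads with more than 90% of bases at
Phred ≤ 5, and a 30-nt length floor.  Two ordering decisions were open
and are fixed here: homopolymer trimming runs *after* adapter removal
(adapter removal can expose a terminal homopolymer, which must then be
trimmed — this is tested), and the quality fraction is judged on the
final retained bases, on the argument that a read should be kept or
discarded by the quality of what would actually enter the assembly.

Contig edges lose trans-spliced leader hallmarks: if `TAAG` occurs
entirely within the first 15 bp the prefix through the end of the *last*
such occurrence is removed (maximal leader removal); symmetrically for
`CTTA` in the last 15 bp.  454 reads are trimmed of exact adapter/leader
occurrences anchored within 15 bp of either end, together with the
intervening edge; internal occurrences are untouched.

# Hybrid-assembly preparation

Contigs are duplicated with one base removed from the duplicate's front
(so the pair are not exact duplicates, which assemblers would collapse),
chopped to at most 1999 nt with a 100-nt step (1899-nt overlaps), and
given artificial qualities: Phred 40 internally, Phred 10 on 25-bp
edges, since contig edges are the error-prone part.  When the regular
tiling leaves a tail uncovered, a final segment clamped to start at
`len − 1999` is appended: this guarantees full coverage with all-equal
segment lengths, at the price of the final pair overlapping by more than
1899 nt.  A duplicate one base shorter can need one segment fewer than
its original — the segment count is per-sequence arithmetic, not a
constant factor.

# ORF extraction

The longest ORF of a transcript is the longest stop-free stretch of
codons over all six frames, stop-to-stop or end-bounded, with no ATG
requirement.  Stretches are compared by **nucleotide span including the
terminating stop codon**; comparing peptide lengths instead would
penalize a stop-bounded ORF by one codon against an end-bounded one of
equal footprint.  Ties break towards the + strand, then the lower frame,
then the lower start coordinate.  `has_start` means the stretch's first
codon is ATG; "full-length" ORFs (start and stop, strictly more than
100 aa) are what the comparative tables count.  The stop codon is
excluded from the peptide but included in the nucleotide span, so
coverage fractions of complete coding transcripts reach 1.0.

# Redundancy removal

The procedure: longest ORF per transcript → drop peptides under 50 aa →
trim 25 C-terminal residues → greedy global clustering → six-criterion
discard filter over the cluster representatives → restore untruncated
sequences.  The C-terminal trim exists because the nonsense polypeptide
translated after a frameshift averages about 15 residues; trimming 25
suppresses that noise during clustering and filtering, and *only* there —
final outputs are untruncated.

Clustering is greedy and longest-first: each sequence joins the first
centroid reaching 95% global identity (end-to-end alignment maximizing
`matches − 20·gap_columns`), else founds a cluster; the representative
is the centroid, hence the longest member.  A length-ratio prefilter
(identity can never reach 95% when `min(len)/max(len)` is below it)
avoids useless global alignments.

The filter discards a match against a query if and only if **all** of:
the best alignment block is ≥ 25 aa and not a self match; the query is
strictly longer (equal lengths keep both); block identity > 95%; the
alignment has **zero gap columns** — this is what retains splice
variants, whose exon skip forces a gap; the alignment spans ≥ 95% of the
match; and at most 100 match residues lie outside the alignment.
"Unmatched by the query" is interpreted as match residues outside the
alignment block (not mismatched columns); this was an open reading and
is flagged here.  Note the arithmetic consequence: criterion vi can only
be the *decisive* criterion for matches longer than 2000 aa, since below
that a > 100-residue unmatched tail already fails the 95%-span test.

# Redundancy index and gene number

The dataset's coding sequences are searched against themselves with
identity > 98%, E ≤ 1e-30, soft-masked seeding, and at most 250 hits per
query; RI is the mean retained-hit count per query, **self hits
included**.  Self-inclusion is forced by the estimator's semantics: a
dataset of mutually unrelated sequences must give RI = 1 so that N / RI
returns N.  Coding sequences rather than full transcripts are the
mandated input — UTRs, vector remnants and trans-spliced leaders
otherwise generate spurious cross-hits.  The 250-hit cap means RI
saturates at 250 for pathologically redundant datasets; this mirrors the
default alignment-count limit of the classic search tools and is kept as
the documented default.

# Dataset comparison

Only-sets use a 95% best-hit identity threshold on nucleotides without
low-complexity masking; whether the threshold should also demand
coverage was open, and best-HSP identity with no coverage requirement
was chosen (flagged in the function help).  The contaminant screen is
sequential: low-complexity queries first (mask covering ≥ 80% of the
length — the 80% is this package's rule; the original reports
"very low complexity" without one), then each database in the given
order, each query assigned to the first database it hits and never
realigned — the assignment is a partition.  Genome support requires a
best genomic hit above 75% identity.  The pseudogene screen demands all
four of: ORF < 100 aa, ORF spanning < 95% of the transcript, a perfect
genome match — one gap-free 100%-identity alignment covering the whole
transcript — and < 95% identity to every predicted transcript.  Reading
"perfect match" as a single contiguous alignment means spliced
pseudogenes escape the screen; the count is deliberately conservative,
consistent with the stringency the original analysis acknowledges.

The coding-length comparison retains, per reference sequence, the
best-scoring *gap-free* ("uninterrupted") hit longer than 100 nt at
≥ 95% identity and classifies hit/reference length into ≥ 100%, 75–99%
and < 75%.  The source material quotes both 95% and 98% for this
threshold in different places; both are exposed as arguments and 95% is
the default.

# Orthology

Reciprocal best hits between two proteomes under E ≤ 1e-8 with soft
masking: (a, b) is a pair when b is a's unique best score in B and
a is b's unique best in A.  Tied best scores yield no pair — the
conservative convention for an operational ortholog call.  Pairs are
computed on whole proteomes first and only then subset (e.g. to an
only-set), preserving the reciprocal-best property.

# Saturation analysis

Reads are mapped once in near-exact mode (≥ 95% identity over ≥ 90% of
the read — an internal stand-in for a short-read mapper), then a single
seeded permutation is prefix-sliced at each fraction.  Nested sampling
makes the curves monotone by construction and reproducible from one
seed; independent per-fraction draws would estimate the same expectation
with more noise.  Under uniform coverage the expected number of
references hit at least once by n reads is `R(1 − (1 − 1/R)^n)`, with
the classical occupancy variance; the tests compare the mean over 20
independently generated read sets against this expectation within
3σ/√20.  The mean-based form tests the same quantity as a per-seed
3σ check but does not stake the suite on the ~1% tail probability of a
single draw.

# The synthetic-data generator

The generator emulates, under one seed with independent streams per
artifact (so changing a read parameter never perturbs the genome):
genes with ATG…stop coding sequences drawn from a codon distribution
matching the configured 30% GC, UTRs, paralog families (default 80%
singletons, 15% pairs, 5% triples, 12% codon divergence), in-frame
exon-skip splice variants, GT…AG introns (0–5 per gene, 60–500 nt),
intergenic spacers, withheld gene subsets creating RNAseq-only and
predicted-only truth, pseudogenes (8% diverged copies with internal
stops induced until no frame holds a ≥ 100-aa ORF, inserted verbatim
into the genome), contaminants, 76-nt barcoded Illumina reads with
substitution errors and 3'-adapter read-through, and 454-style reads
with ±1 indels confined to homopolymer runs of ≥ 3 nt and trans-spliced
leaders ending in TAAG.  Defaults are desk-scale: 200 genes, a ~1-Mb
genome, 50k Illumina and 5k 454 reads; tests use smaller explicit
configurations (30–110 genes, hundreds to thousands of reads) so the
whole suite runs in minutes.

Two generator details are deliberate modelling choices rather than
conveniences.  `expand_redundancy()` caps per-copy substitutions at 40%
of `(1 − identity_floor)` of the length: two copies diverge from each
other up to twice as fast as from their original, and the redundancy
gate is strict (> 98%), so a laxer cap would make copies of the same
gene fail the gate by construction.  `sim_corrupt_variants()` places its
single-base deletion such that the shifted frame meets a stop within
roughly two dozen codons — matching the observed short nonsense
polypeptides that motivate the 25-residue C-trim; a frameshift whose
nonsense tail greatly exceeds the trim produces a legitimately distinct
protein that *should* survive the filter, which is a property of the
data, not of the implementation.

What the generator does **not** emulate: empirical quality-score
distributions learned from real runs, coverage biases (GC, 3' bias,
expression levels — reads are uniform over transcripts), sequencing
chimeras, heterozygosity beyond point substitutions, spliced
pseudogenes, and real contaminant genomes.  Passing tests therefore
demonstrate that the algorithms implement their stated rules and recover
planted truth under those rules; they do not certify performance on the
full error structure of real libraries.

# Numerical conventions and degenerate inputs

Internal coordinates are 0-based half-open on forward strands; TSV
exports are 1-based inclusive (BLAST style, minus-strand subject
coordinates reversed).  Record ids are the first whitespace-delimited
header token and must be unique; FASTQ is Phred+33 by default with a +64
flag.  Empty datasets: searching an empty database returns an empty hit
table; the redundancy index of an empty dataset is an error (the
estimator is undefined); `gene_number_estimate()` rejects RI < 1, which
cannot arise from a self-including search.  Chopping a sequence at or
under 1999 nt returns it unchanged, including its id.  Cleaning can
transiently produce empty sequences; they are discarded by the length
floor and reported with a reason.  All stages return new tibbles —
records are never mutated in place.
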