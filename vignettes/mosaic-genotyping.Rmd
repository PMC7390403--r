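---
title: "Genotyping mosaic G0 CRISPR embryos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping mosaic G0 CRISPR embryos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplimosaic)
```

## The problem

Injecting a guide RNA (gRNA) and Cas9 into a one-cell embryo cuts the
targeted locus in essentially every allele, but each double-strand break
(DSB) is repaired independently, and repair continues through the first
cleavages. A G0 animal is therefore a *mosaic*: each locus carries a small
mixture of differently repaired alleles — typically one to six distinct
sequences, four or fewer being most common — distributed unevenly across
cell lineages. In an allotetraploid genome such as that of *Xenopus laevis*
the mixture is doubled across the two homeologous gene copies (the S- and
L-alleles).

Whether such an animal shows a knockout phenotype depends on the exact
repair outcomes. At repeat-rich cut sites, microhomology-mediated
end-joining (MMEJ, also called Alt-NHEJ) anneals short direct repeats
flanking the break and deletes the intervening sequence plus one repeat
copy, biasing repairs toward a handful of stereotyped deletions — often
in-frame. Amplicon sequencing (Sanger-cloned amplicons, or deep short-read
sequencing of a small PCR product) reads out the allele mixture, and the
question becomes statistical: which repaired alleles does each embryo
carry, at what frequency, and does the presence of functional (wild-type)
alleles explain which embryos develop normally?

amplimosaic implements that analysis chain end to end: target-site and cut
modelling, MMEJ deletion prediction, per-read lesion calling on homeologous
references, protein-consequence annotation, a six-level genotype score,
per-embryo mosaic spectra, and an exact association test — plus a simulator
that generates mosaic cohorts with a per-read ground-truth manifest.

## Target sites, cuts and the seed rule

A guide is a 18–25-nt spacer plus an IUPAC PAM pattern (default `NGG`).
`locate_target()` scans both strands of a reference for spacer matches
within a mismatch budget whose PAM matches immediately 3' of the
protospacer; mismatch positions are recorded as spacer indices from the 5'
end. The blunt DSB is placed `cut_distance` bp 5' of the PAM on the
protospacer strand — default 3 bp, the canonical SpCas9 cut between spacer
positions 17 and 18 of a 20-mer; the distance is configurable because a
minority of cuts occur 4 bp out. `predict_activity()` applies the
seed-sequence rule: cleavage requires a perfect match of the PAM-proximal
seed, by default the last 10 spacer positions (reported seed lengths range
from 8 to 10; 10 is the conservative default and a single parameter). A
guide with any seed mismatch is called `inactive`, anything else `active`.
This is deliberately a hard rule, not a scoring model: it reproduces the
published behaviour of single- and double-mismatch control guides and makes
no claim about graded activity.

## MMEJ deletion enumeration

`enumerate_mmej()` treats a deletion interval as an MMEJ product when (i)
its size is at most `max_deletion` (default 30 bp), (ii) it can be placed
to contain or abut the cut, and (iii) the junction flanks share a direct
repeat of at least `min_microhomology` bases — measured as the longer of
the left-flank suffix identity and right-flank prefix identity at that
junction. Because deleting any copy of a repeat yields the same joined
molecule, products are deduplicated by product sequence; all contributing
repeat pairs are kept as an attribute and the reported interval is the
right-most placement, matching the 3'-shift convention used everywhere
else.

Each product gets a weight `mh_length * exp(-deletion_size / weight_scale)`
(default scale 20 bp), normalized over products: longer homology favours a
product, longer deletions are progressively disfavoured. No quantitative
MMEJ outcome distribution is available for this locus, so the weighting is
a stated monotone convention used *only* by the simulator — the caller and
annotator never consult it. Users wanting learned repair models
(inDelphi-class predictors) should treat the enumeration as the candidate
set and supply their own weights.

The enumeration default `min_microhomology = 2` is permissive by design;
the simulator's repair channel uses 3 (see *Study conditions* below).

## Read calling

Each read is aligned to every homeologous reference with an affine-gap
aligner (match +2, mismatch −4, gap open −10, gap extend −1; a gap of
length *g* costs 10 + *g*). Full-length Sanger clone inserts are aligned
globally; NGS reads shorter than the amplicon use a fitting alignment (free
end gaps on the reference). Both orientations are tried and the better
strand kept; a strand reaching 80% of the perfect score is accepted without
computing the other, since a read and its reverse complement cannot both
align near-perfectly unless the sequence is close to palindromic.
Traceback tie-breaks are fixed (diagonal, then deletion, then insertion,
gaps opened leftmost), and all indels are subsequently right-aligned
(3'-shifted) within repeats, so the residual ambiguity of placement inside
repeat runs never reaches the caller's output. The alignment scores are
verified in the test suite against an independently written brute-force
affine DP on short random strings.

Reads are assigned to the homeolog with the higher score;
when the two scores differ by at most one mismatch (threshold 4,
configurable) the read falls back to identity over its 5'-terminal 40
bases. This reproduces the rule used for PCR-chimeric clones, which carry
one homeolog's sequence at the 5' end of the fragment and the other's
toward the 3' end; unresolvable reads are labelled `ambiguous` and dropped
from spectra rather than guessed.

`call_lesion()` reduces the alignment to a normalized event list
(substitutions, insertions, deletions), intersects it with the PAM-anchored
variant window, and computes the realized window sequence from the
normalized events (placement-stable by construction). A read that does not
span the whole window, or carries N bases inside it, is *uninformative* —
never counted as mutant. `is_wildtype_read()` applies the peptide-level
wild-type definition: the realized window sequence, translated in the
model's frame, must equal the reference window peptide (GGRRG for the exon
6 window). A synonymous substitution inside the window therefore still
counts as wild type; this is a documented consequence of defining wild type
at the peptide level, and out-of-window events are reported separately
rather than folded into the call.

## Protein consequences and the genotype score

`annotate_consequence()` rebuilds the mutant CDS from the events and
compares translated peptides after maximal common prefix trimming followed
by suffix trimming, which yields the 3'-most (HGVS-normalized) description:
`p.(Arg272del)`, `p.(Arg271_Gly273del)` and `p.(Gly270_Gly273del)` for the
stereotyped exon 6 products regardless of the physical junction. A net
indel not divisible by 3 is a frameshift; a premature stop is nonsense.
Amino-acid changes count substituted + inserted + deleted residues, a
delins counting `max(deleted, inserted)`; this additive reading reproduces
every published score example we could reconstruct.

Splice assumptions take precedence over codon arithmetic: a deletion
removing an exon's acceptor dinucleotide is assumed to skip the exon (an
in-frame skip deletes `exon_length/3` residues; an out-of-frame skip is
truncating), and a deletion removing a donor is assumed to retain the
following intron, which is translated until the first stop — almost always
truncating, but a stop-free intron of whole-codon length is scored as an
in-frame insertion of `intron_length/3` residues, the biologically literal
reading of the retention assumption.

The genotype score grades each allele: 01 inactive (frameshift-stop or
nonsense, including truncating splice outcomes — a frameshifting event
dominates any co-occurring events), 02 in-frame with >20 amino-acid
changes, 03 with 11–20, 04 with 6–10, 05 with 1–5, 06 a normal amino-acid
sequence. The score is a *sequence* classification, not a functional
prediction: a conservative missense such as p.(Arg271Lys) scores 05 even
where phenotype data suggest the substitution destroys function. We keep
that divergence rather than special-casing residues.

## Cohort statistics

`summarize_embryo()` groups an embryo's informative calls into distinct
alleles by exact in-window sequence identity (so different junctions with
identical products merge), but tallies genotype scores per read: window
identity can pool reads whose lesions extend differently beyond the window
— large deletions that erase the window entirely — and a single group-level
score would misattribute those. `score_frequencies()` produces
parts-of-whole tables overall and for the defect-vs-normal dichotomy
(inert ventricle, thin-walled ventricle and other malformations versus
normal morphology; the four-class labels are retained in reports).

`wildtype_phenotype_association()` tests whether wild-type-allele presence
is enriched among embryos with normal hearts, using one-sided exact
hypergeometric enumeration (no approximation); odds ratios with a zero cell
are flagged degenerate rather than reported infinite. Exactly one
pre-specified test is run per cohort and no multiple-testing correction is
applied — stated explicitly so that users adding tests know the contract.
Note that the one-sided exact p of a perfectly balanced table is not 1
(e.g. 53/70 for a 2/2 vs 2/2 table); p reaches 1 only when the observed
count is at its margin-imposed floor.

## The simulator and its study conditions

`simulate_cohort()` generates mosaic embryos with a per-read truth
manifest. Per locus, an embryo draws its number of distinct alleles from a
categorical distribution over 1–6 (default mass `.20/.30/.25/.15/.07/.03`,
concentrating on four or fewer), symmetric-Dirichlet allele frequencies
(α = 1), and multinomial clone counts. Each allele escapes cutting with
probability `p_wildtype_escape` (default 0.15); otherwise the repair is a
1-bp missense substitution near the cut (probability 0.02 — such
substitutions were rare singletons in the data the defaults emulate), an
MMEJ product drawn by weight (probability 0.7), or an NHEJ indel with
truncated-geometric sizes (deletions 1–30 bp, p = 0.2, matching observed
deletions up to ~24 bp; insertions 1–6 bp, p = 0.4, insertion branch
probability 0.2). Sizes-only reports admit no distributional estimate, so
the truncated geometric is the conventional minimal choice, with every
parameter exposed.

The simulator's MMEJ channel uses `min_microhomology = 3`: at the exon 6
site the ≥3-bp repeat pairs are precisely the repeats that explain the
stereotyped 3/9/12-bp deletions, the in-frame share of MMEJ weight is then
0.70, and an empirical in-frame mutation frequency of 0.69 is reachable by
`calibrate_inframe()`; admitting 2-bp homologies floods the channel with
minor out-of-frame products and caps the in-frame fraction at 0.49,
contradicting the in-frame dominance the defaults are meant to emulate.

Mosaicism is modelled phenomenologically — a categorical allele count, not
a mechanistic model of S-phase replication at the one-to-two-cell
transition, which the available observations do not constrain. Phenotype
follows a minimal operationalization of the lineage argument: each allele
gets a Beta(1, 1) cardiac lineage weight, and the embryo develops a normal
heart iff the lineage-weighted fraction of *functional* alleles reaches
θ = 0.15. Functional defaults to genotype score 06 only: at this site the
small in-frame deletions (score 05) demonstrably eliminate protein
function, so counting scores 05–06 as functional would make nearly every
embryo normal and erase the association the cohort module exists to test.
`functional_scores` is a parameter for loci where 05 alleles do retain
function. The pair (escape 0.15, θ 0.15) was fixed once, by matching the
emulated study's marginals — about 5 of 16 embryos with normal hearts,
wild-type alleles detectable in about half, and 2–3 wild-type-positive
embryos nonetheless developing defects (lineage-restricted wild type) —
and gives the association test a power of ~0.82 at n = 16 over 200
replicates. With θ = 0.2 the simulated cohorts undershoot those marginals
and the power drops to ~0.66.

What the simulator does *not* emulate: PCR chimera formation (a fixture
covers the assignment rule instead), quality-score structure (errors are
uniform substitutions), lineage inference from reads (lineage restriction
exists only in the generative model), and any learned repair-outcome
distribution. Passing the round-trip tests therefore shows that the caller
inverts *this* generative model exactly on error-free data — it does not
certify performance on real chromatograms or on repair spectra unlike the
modelled one.

## Numerical and engineering choices

* Coordinates are 0-based half-open internally; reports and HGVS strings
  are 1-based. Minus-strand models are reverse-complemented into CDS
  orientation at load time so downstream logic has one code path.
* A local CDS fragment can carry full-protein residue numbering via
  `residue_offset` (the bundled 24-nt exon 6 fragment anchors its window to
  residues 269–273).
* Variant windows must be codon-aligned; `snap_window_to_codons()` expands
  a window outwards to codon boundaries and records the snap.
* The full locus sequence of the motivating gene is not machine-readable,
  so `synthetic_locus_pair()` is an explicitly synthetic two-homeolog
  amplicon pair (412/403 bp) embedding the published 24-nt exon 6 site, with
  seven flank substitutions and a 9-bp intron-length difference between
  homeologs. Everything outside the published site is invented; tests
  validate the machinery on this pair and on random sequences, not on
  unpublished locus context.
* Problem sizes in the test suite — 1,000 random pairs for the alignment
  oracle, 500 40-mers for the MMEJ oracle, all 46,376 2×2 tables with
  n ≤ 30 for the exact test, a 16-embryo/~500-clone round trip, and
  200-replicate power and recovery studies — were chosen to exercise every
  code path at desk scale while keeping the default run in minutes.

## Known limitations

* The seed rule is binary; partially active guides are out of scope.
* `aa_changes` for several widely separated in-frame events spans the
  whole prefix/suffix-trimmed region; alleles carrying multiple distant
  repairs (not observed in the emulated data, and not generated by the
  simulator) would be counted conservatively.
* Exon-skip and intron-retention consequences implement stated assumptions
  about splicing, not a splicing model; they are only as good as those
  assumptions.
* The wild-type definition is strictly window-scoped; reads wild type in
  the window but mutant elsewhere are flagged via their out-of-window
  events, and how to treat them is left to the analyst.
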