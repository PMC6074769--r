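---
title: "Toxin candidate triage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Toxin candidate triage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxtriage)
```

## The problem

Venom gland transcriptomes are the usual entry point for characterizing
toxin diversity in a venomous animal. After assembly and expression
quantification, the analysis path is remarkably uniform across taxa:
search the assembled transcripts against a curated panel of characterized
venom proteins, pull the matching transcripts into groups named after the
panel proteins, translate them, check for secretion signals, align each
group, build a quick gene tree, and cross-reference tissue-level
expression. `toxtriage` implements this triage as a tested, deterministic
library plus a command-line tool. It starts where the heavy external
machinery ends: its inputs are the assembled transcriptome (FASTA), one or
more per-transcript expression tables, and a 12-column tabular
protein-versus-transcriptome homology search with toxin proteins as
queries.

The package deliberately does **not** assemble reads, quantify
expression, or execute any external aligner or predictor: those stages
are consumed as files, and the computational stages in between — ORF
prediction, grouping, reciprocal screening, multiple alignment,
evolutionary distances, neighbor joining — are implemented in-house so
the whole path is reproducible and testable offline.

## Grouping and the reciprocal screen

Hits with E-value at or below the lenient cutoff (default `1e-6`) are
partitioned by the **protein name** of their query, not the accession:
panel entries that share a name (e.g. two "Neprilysin-1" proteins from
different species) seed a single group. A transcript joins *every* group
it hits, because closely related toxin families legitimately attract the
same candidates; a `multi_group = FALSE` switch restricts each transcript
to the group of its single best hit for users who prefer disjoint groups.
Within a (group, transcript) pair the stored best hit minimizes E-value,
with ties broken by bit score and then accession, so output is
deterministic. Group names can carry misleading lineage labels (a group
named after a cone-snail protein may well collect neurophysin-like
transcripts in an ant); the package groups by name and leaves
interpretation to the user rather than guessing.

A translated candidate passes the **reciprocal screen** when its best
toxin E-value beats its best non-toxin E-value by at least
`margin_orders` orders of magnitude. The margin quantifies
"significantly better", which is otherwise undefined; the default of 0 is
the strictest literal reading (any advantage counts, and an exact tie
passes since the log-difference is then 0). Zero E-values are floored at
`1e-200` before logs — a documented constant well below anything a search
tool reports. A candidate with no non-toxin hit passes vacuously; one
with no toxin hit is `unevaluated`. Verdicts are monotone: improving the
toxin E-value can never demote a candidate, and the suite checks this by
fuzzing.

Two stringency levels (defaults `1e-20` and `1e-6`) are reported as one
pass at the lenient cutoff plus a sweep table of group/transcript counts
per cutoff, since the stringent set is always a subset of the lenient one.

## ORF prediction

ORFs are scanned in all six frames. Within each strand/frame, stop codons
partition the codon sequence into regions, and each region yields at most
one ORF — its maximal extension — so nested same-frame ORFs are
suppressed, matching common predictor behavior. Completeness follows the
usual four-way classification: `complete` (M to stop),
`five_prime_partial` (runs in from the transcript edge without a leading
M, ends at a stop), `three_prime_partial` (starts at M, runs off the 3'
end), `internal` (truncated at both ends). Coordinates are 1-based
inclusive on the forward strand and include the terminating stop codon.
The "best" ORF of a transcript is the longest *complete* one (ties: plus
strand, then smaller start); partials are used only when no complete ORF
reaches the length floor.

The minimum ORF length defaults to **50 residues** and is exposed as
`min_orf_aa`. Mature toxins are short — conotoxins and many peptide
toxins run well under the 100-residue default of general-purpose ORF
predictors, which is known to silently discard most short toxin
precursors — so the default here is deliberately permissive, and the
whole scan is re-checked against a brute-force six-frame enumerator in
the test suite.

## Signal and mature peptides

External signal predictions, when supplied in the short tabular format,
always override the built-in predictor. The built-in rule exists so the
pipeline runs with no external binary: it encodes the textbook tripartite
architecture — at least one K/R in the first five residues (n-region), a
contiguous hydrophobic stretch of ≥ 6 of `A I L F V M W C` within
residues 3..k−3 (h-region), and small residues (`A G S C T`) at positions
k−2 and k (A-X-A-like c-region) — scanning candidate signal lengths k
from 12 to 35 and cleaving after the smallest qualifying k. "Cleavage
after k" always means the bond between residues k and k+1; the signal is
residues 1..k. This is a structural heuristic, not a neural predictor;
it is deterministic, stable under C-terminal extension, and calibrated
only in the sense that the synthetic generator plants signals satisfying
it by construction.

## Alignment, distances and trees

The pairwise engine is global Needleman–Wunsch with affine gaps (Gotoh's
three-state recursion) on the bundled BLOSUM62 matrix, default gap open
−10 and extend −1 in half-bit score units. A gap of length g costs
`open + (g − 1) × extend`, and traceback ties resolve diagonal > up >
left, so alignments are unique and reproducible. The multiple aligner is
progressive: a neighbor-joining guide on 3-mer cosine distances fixes the
merge order, profiles merge by profile–profile NW with mean-of-pairs
column scoring (gap–residue pairs contribute nothing), and a gap column,
once inserted, is never removed. Every row of every alignment ungaps back
to its input exactly — an invariant the suite fuzzes. An external aligner
can of course be applied to the unaligned per-group FASTA the pipeline
writes; the in-house path is simply the tested default.

Distances are p-distances with pairwise deletion; a Poisson correction
(`−ln(1 − p)`, with p ≥ 1 floored at 0.999 under a warning) is available
but off by default — the trees here are screening aids, not published
phylogenies, and the uncorrected distance is the most transparent choice.
Neighbor joining is the classic Q-criterion algorithm with the standard
two-point branch-length formulas; negative branch estimates are clamped
to zero with the deficit moved to the sister branch (preserving the
pair's summed length), and ties in Q break on the lexicographically
smallest pair of cluster representatives, making the tree deterministic.
On additive matrices NJ provably recovers the generating topology and
branch lengths, and the acceptance suite verifies this on 100 simulated
trees against an independent tree-comparison implementation. Two-sequence
groups skip NJ and split the pairwise distance evenly across a two-leaf
tree; single-sequence groups emit a trivial one-node file so every group
directory keeps the same file set.

Newick output is canonical — children ordered by the smallest leaf label
in their subtree, branch lengths at six decimals — so identical trees
always serialize identically, which is what makes whole-run determinism
checkable by checksum.

## Expression

The TPM filter keeps transcripts whose maximum TPM across samples is
**strictly** greater than the cutoff (default 1.0; a transcript at
exactly 1.0 is excluded — the boundary matters and is documented). With
multiple tissues a transcript passes if *any* sample exceeds the cutoff:
the inclusive reading, chosen so that a venom-gland-specific transcript
is never lost because it is silent elsewhere. The tissue report flags
candidates whose maximal TPM exceeds `highlight_tpm` (default 100, the
conventional "highly expressed" bar in venom-gland screens) and records
the tissue of maximal expression, breaking exact ties lexicographically
with an explicit tie flag. FPKM is carried through every report but never
filtered on.

## The synthetic study

`simulate_inputs()` generates the study the tests and the acceptance
script run on. Defaults: **5 toxin families × 4 members + 150 decoy
transcripts** over two tissues (venom gland and carcass). Each family is
a cysteine-rich secreted precursor: a 40–80-residue mature core with 6–8
cysteines at family-fixed positions, members diverged by point
substitutions at non-cysteine sites (per-site rate drawn once per family
from 0.05–0.2, so the cysteine skeleton is conserved the way real
disulfide-rich toxin families conserve theirs), all prefixed by a signal
peptide that the built-in predictor provably cleaves at the planted site.
Toxin transcripts embed the reverse-translated precursor between UTRs
(with an in-frame upstream stop so the planted ORF is exactly what the
scanner must report), and a random half are reverse-complemented to
exercise minus-strand handling. Hit E-values are log-uniform on
[1e−50, 1e−10] for toxins; every transcript also gets a deliberately
weaker non-toxin hit (5–15 orders worse for toxins) so the reciprocal
screen is exercised rather than vacuous. Venom-gland TPM is 50–500 for
toxins and 0–20 for decoys and other tissues.

What the generator does **not** emulate: read-level noise, assembly
artifacts (chimeras, fragmentation, redundant isoforms), codon-usage
bias, paralog interference, or a real search tool's alignment envelope —
E-values and coordinates are consistent with the planted ORFs but not
modeled. Perfect precision/recall on this fixture therefore demonstrates
that the pipeline's logic is correct end to end, not that real
transcriptomes will yield clean candidate sets; on real data the usual
caveats about assembly quality and database coverage dominate.

## Numerical and design notes

- All randomness is confined to the generator, which takes an explicit
  seed and restores the caller's RNG state; the pipeline itself draws no
  random numbers, so identical configurations produce byte-identical
  output trees (verified by directory checksums).
- Ordering everywhere is C-locale lexicographic, so results do not depend
  on the session locale.
- Problem sizes in the shipped tests (300-nt fuzz transcripts, peptide
  pairs up to length 6 for exhaustive alignment enumeration, 100
  simulated trees of 5–12 leaves, the 170-transcript standard fixture)
  were chosen so each oracle comparison is exact yet the whole suite runs
  in about a minute on one core.
- The pipeline requires a query-protein FASTA only for the combined
  alignment, tree and per-group query outputs; the grouping and screening
  stages run from the hit table and metadata alone.
- The per-group output files are numbered `01_`–`11_` so the directory
  contents can be audited at a glance; names are a fixed contract of this
  package.
- The "query records" file (`04_query_records.txt`) is a simplified keyed
  text dump of the query metadata, not a syntactically valid flat-file
  database record.

## Known limitations

Coding-potential scoring, propeptide cleavage, machine-learning toxin
classification, maximum-likelihood trees and bootstrap support are out of
scope by design; the alignments and NJ trees are first-pass screening
aids. Group names inherit whatever biases the query panel carries, and
multi-membership means one transcript can appear in several related
directories — both are properties of the triage, to be resolved by
downstream analysis, not by this package.
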