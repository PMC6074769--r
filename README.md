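# toxtriage

Toxin candidate triage for venom gland transcriptomes.

After a venom gland transcriptome has been assembled and quantified, the
characterization path is nearly the same in every venomics study: search
the transcripts against a curated panel of characterized venom proteins,
group the matching transcripts by the panel protein they resemble,
translate them, check for secretion signals, align each group, build a
quick gene tree, and cross-reference expression across tissues.
`toxtriage` packages that triage as a tested R library with a
command-line interface, for researchers screening toxin-like transcripts
in any venomous (or putatively venomous) taxon.

It takes three primary inputs:

1. the assembled transcriptome (nucleotide FASTA);
2. one or more per-transcript expression tables (tab-delimited, transcript
   id in the first column, TPM located by header name);
3. a 12-column tabular homology search (`outfmt 6`) with toxin proteins
   as queries and transcripts as subjects, plus a small metadata table
   (accession → protein name, organism, lineage) describing the queries.

Optionally: the query protein FASTA (enables the combined alignments and
trees), a non-toxin hit table (enables the reciprocal screen), and an
external signal-peptide prediction table (overrides the built-in rule).

## The method

- **Grouping.** Hits with E ≤ cutoff (default 1e−6; a stringent 1e−20
  sweep is reported alongside) are partitioned by query *protein name*
  into toxin groups; a transcript joins every group it hits. Per
  (group, transcript) the best hit minimizes E-value (ties: bit score,
  then accession).
- **ORFs.** Six-frame scan; one maximal ORF per stop-bounded region,
  classified complete / 5′-partial / 3′-partial / internal; the best ORF
  is the longest complete one. Minimum length 50 aa by default — toxin
  precursors are short.
- **Reciprocal screen.** A translated candidate passes when
  log10(best non-toxin E) − log10(best toxin E) ≥ margin (default 0;
  zero E-values floored at 1e−200). No toxin hit → unevaluated; no
  non-toxin hit → candidate.
- **Alignment and trees.** In-house global affine-gap Needleman–Wunsch
  (BLOSUM62, open −10 / extend −1), progressive profile alignment on an
  NJ guide, p-distances with pairwise deletion (optional Poisson
  correction), and classic neighbor joining with
  Q(i,j) = (n−2)·d(i,j) − Σₖd(i,k) − Σₖd(j,k), deterministic
  tie-breaking, and negative branch estimates clamped with the deficit
  moved to the sister branch.
- **Expression.** `TPM.fasta` keeps transcripts with any-sample
  TPM strictly > 1.0; tissue reports flag candidates with maximal TPM
  > 100 and name the tissue of maximal expression.

Every run writes one directory per toxin group containing exactly eleven
files (`01_candidates_nt.fasta` … `11_expression.tsv`: candidate
nucleotide ORFs, query proteins, query taxonomy, query records, complete
translated candidates, combined sequences unaligned and aligned, signal
predictions, mature peptides, the NJ tree, and the expression table),
plus top-level `TPM.fasta`, screening verdicts, the stringency sweep, a
tissue report, and a JSON run manifest. Runs are fully deterministic:
identical inputs and configuration give byte-identical output.

A deterministic synthetic-data generator (`simulate_inputs()`) produces
all inputs with planted ground truth — cysteine-rich toxin families with
signal peptides, decoy transcripts, hit tables, tissue expression — so
the entire pipeline is testable offline.

## Worked example

```r
library(toxtriage)

sim <- simulate_inputs(n_families = 3, members_per_family = 4, n_decoys = 40,
                       tissues = c("venom_gland", "carcass"),
                       seed = 7, outdir = "fix")
summary <- run_pipeline(pipeline_config(
  transcriptome = sim$paths$transcriptome,
  expression    = unlist(sim$paths$expression),
  hits          = sim$paths$toxin_hits,
  meta          = sim$paths$query_meta,
  queries       = sim$paths$queries,
  nontoxin_hits = sim$paths$nontoxin_hits,
  outdir        = "triage_out", seed = 7))
#> [toxtriage] inputs: 52 transcripts, 12 toxin hits, 3 queries, 2 sample(s)
#> [toxtriage] 3 toxin group(s), 12 member transcript(s)
#> [toxtriage] 12 candidate(s) after reciprocal screening

summary$sweep
#>   cutoff n_groups n_transcripts
#> 1  1e-20        3             7
#> 2  1e-06        3            12
```

Twelve synthetic toxin transcripts hit three query proteins, form three
groups, and all twelve survive the reciprocal screen (their toxin
E-values beat their non-toxin E-values by 7–12 orders of magnitude, as
`summary$verdicts` shows). The stringent 1e−20 cutoff would have kept
only 7 of the 12. Each group directory now holds the eleven files; the
gene tree for the first group, for example, places the consensus query
`TXQ001` among its four derived members:

```
(((Alpha-conotoxin_S1_m1:0.102222,Alpha-conotoxin_S1_m3:0.071111):0.011667,
  TXQ001:0.008333):0.005000,
 Alpha-conotoxin_S1_m2:0.108333,Alpha-conotoxin_S1_m4:0.091667);
```

The same run from the shell:

```sh
Rscript inst/scripts/toxtriage simulate --out fix --seed 7 \
    --families 3 --members 4 --decoys 40
Rscript inst/scripts/toxtriage run \
    --transcriptome fix/transcriptome.fasta \
    --expression venom_gland=fix/expression_venom_gland.tsv \
    --expression carcass=fix/expression_carcass.tsv \
    --hits fix/toxin_hits.tsv --meta fix/query_meta.tsv \
    --queries fix/queries.fasta --nontoxin-hits fix/nontoxin_hits.tsv \
    --out triage_out
```

`orfs`, `screen` and `tree` subcommands expose the individual stages;
`--help` lists every threshold and its default.

## Scope

Read assembly, expression quantification, execution of external search /
alignment / signal-prediction binaries, coding-potential scoring,
machine-learning toxin classification, and maximum-likelihood trees with
bootstraps are out of scope: this package consumes the standard file
formats those tools produce and keeps everything downstream
deterministic and testable. See the methods vignette
(`vignettes/toxin-triage-methods.Rmd`) for the full model description,
parameter rationale, and limitations.
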