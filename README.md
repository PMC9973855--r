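# transannot

Automated annotation of membrane transport proteins in prokaryotic
proteomes.

Genome annotation pipelines routinely mislabel transporters: the
Pfam profile for the ATP-binding cassette (PF00005, `ABC_tran`) matches
genuine ABC transporters *and* a crowd of non-transport ATPases —
excinuclease UvrA, chromosome-segregation Smc, recombinational-repair
RecF, partitioning ATPases Soj/Mrp — as well as CBS-domain regulators.
Conversely, the transmembrane subunits of ABC systems and other weakly
conserved transporter families are easy to miss. `transannot` is a
desk-scale engine for the classic solution: cast a deliberately
promiscuous net over several independent evidence tracks, then prune the
catch with explicit negative rules, and only transfer functional detail
when the homology supports it.

The pipeline, per protein *p* in the query proteome:

1. **Evidence aggregation.** Hits from three protein-alignment tracks
   (a curated transporter database, TCDB and NR), a profile-HMM domain
   track, a COG track, and a transmembrane-topology track (an external
   TMHMM-style file, or a built-in Kyte–Doolittle sliding-window caller)
   are collected into one bundle with per-track threshold flags.
   Candidacy is the *mutually inclusive union*: *p* is a candidate iff
   any homology/domain/COG track passes its E-value ceiling, or the
   predicted helix count reaches the standalone TM criterion
   (default ≥ 6).
2. **Negative decision tree.** Ordered declarative rules delete false
   positives. A rule is *armed* by a threshold-passing domain hit in its
   scope and *fires* on its payload. The shipped default encodes the ABC
   rules: 12 exclusion COGs (COG0178 … COG0517) and 8 NR-description
   keywords ("Excinuclease", "CBS domain", …) scanned over the top-5 NR
   hits; first firing rule wins. Rulesets are YAML files and fully
   user-extensible.
3. **Classification & substrate transfer.** Family, subfamily and TC
   number are copied from the best resolvable curated/TCDB hit
   (highest bitscore, ties by E-value then accession). Substrate
   prediction is tiered with abstention: identity ≥ 60 % and coverage
   ≥ 70 % transfers the specific substrate ("maltose"); identity ≥ 30 %
   and coverage ≥ 50 % transfers only the class ("sugars"); anything
   weaker abstains. When in doubt, no substrate call is made.
4. **Evaluation.** Predictions are scored against a manual gold
   standard: confirmed = intersection, FP rate = (predicted − confirmed)
   / predicted, FN rate = (manual − confirmed) / manual, plus a count of
   substrate corrections among confirmed proteins.

A deterministic fixture generator plants true transporters (ABC ATPases,
12-helix MFS permeases), decoys for every default rule, CPA3-family
antiporter subunits that resemble NADH:ubiquinone oxidoreductase (the
canonical *retained* false positive — no shipped rule can touch them),
and low-identity membrane subunits that are missed (the canonical false
negative), so the whole pipeline is testable without any external
databases.

## Worked example

```r
library(transannot)

dir <- file.path(tempdir(), "demo")
fb  <- worked_example(dir)          # writes a 6-protein fixture bundle
ann <- annotate_fixture_dir(dir)    # read every file, run the pipeline
ann
#> transannot annotations: 6 protein(s)
#>   retained 3 | excluded 2 | never_candidate 1
#>   specific substrate calls: 1; class-only: 1; abstained: 1

as.data.frame(ann)[, c("protein_id", "status", "family", "tc_number",
                       "substrate", "confidence", "excluded_by")]
#>       protein_id          status       family  tc_number substrate confidence             excluded_by
#>        malK_like        retained          ABC  3.A.1.1.1   maltose       high                    <NA>
#>       uvrA_decoy        excluded         <NA>       <NA>      <NA>       <NA> abc_nontransporter_cogs
#>    keyword_decoy        excluded         <NA>       <NA>      <NA>       <NA>         abc_nr_keywords
#>  cpa3_confusable        retained         CPA3 2.A.63.1.1      <NA>     medium                    <NA>
#>          tm_only        retained unclassified       <NA>      <NA>        low                    <NA>
#>     background_1 never_candidate         <NA>       <NA>      <NA>       <NA>                    <NA>

evaluate_annotations(ann, read_gold_standard(fb$paths[["gold"]]))
#> Predicted transporters   3
#> Manual annotation        2
#> Confirmed                2
#> False positives          1 (33%)
#> False negatives          0 (0.0%)
#> Substrate corrections    0
```

Reading the table: the MalK-like ATPase keeps its curated annotation
down to the specific substrate; the UvrA decoy dies by the COG rule and
the keyword decoy by the NR-keyword rule; the CPA3 subunit is retained
(and is the one false positive against the gold standard) because its
evidence never arms an ABC-scoped rule; the TM-only protein is kept at
low confidence on topology alone; the background protein never becomes
a candidate.

The same pipeline is available from a shell via the bundled executable
(`inst/exec/transannot`, installed under `exec/`):

```sh
transannot fixtures --out demo --preset worked-example
transannot annotate --proteome demo/proteome.faa \
    --curated demo/hits_curated_tdb.tsv --tcdb demo/hits_tcdb.tsv \
    --nr demo/hits_nr.tsv --domains demo/domains.tbl --cogs demo/cogs.tsv \
    --tm-file demo/tm_short.txt --reference demo/reference.tsv \
    --out annotations.tsv
transannot evaluate --predictions annotations.tsv --gold demo/gold.tsv
```

## Package layout

- `R/formats-io.R` — readers/writers: FASTA, 12+-column tabular
  alignment hits, HMMER3 domtblout, COG tables, TMHMM short format,
  reference/gold/annotation TSVs
- `R/tm-predict.R` — Kyte–Doolittle hydropathy profile and segment
  caller
- `R/evidence.R` — thresholds, evidence bundles, candidate nomination
- `R/rules.R` — negative decision tree and the shipped ABC ruleset
- `R/annotate.R` — classification and tiered substrate transfer
- `R/evaluate.R` — concordance arithmetic and report rendering
- `R/fixtures.R` — deterministic synthetic-data generator
- `R/cli.R` — the `transannot` subcommand dispatcher

See `vignettes/transporter-annotation.Rmd` for the full methods
description, parameter rationale and known limitations.
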