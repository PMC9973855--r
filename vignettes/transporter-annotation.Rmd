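---
title: "Annotating membrane transporters with evidence aggregation and negative rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating membrane transporters with evidence aggregation and negative rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transannot)
```

## The annotation problem

Membrane transport proteins are hard to annotate automatically for two
opposite reasons. The best-conserved transporter domain — the
ATP-binding cassette matched by Pfam profile PF00005 — is *too*
promiscuous: it also matches excinuclease ATPases (UvrA),
chromosome-segregation ATPases (Smc), recombinational-repair ATPases
(RecF, SbcC), partitioning ATPases (Soj, Mrp) and CBS-domain
regulators, none of which transport anything. Meanwhile the membrane
and substrate-binding subunits of the same ABC systems are so weakly
conserved that no good domain model exists for them, and families such
as CPA3 (multicomponent cation:proton antiporters, TC 2.A.63) are
homologous to NADH:ubiquinone oxidoreductase subunits and get confused
in both directions.

`transannot` addresses this with a three-stage design: an inclusive,
promiscuous union over independent evidence tracks; an explicit,
auditable negative decision tree; and tiered homology transfer that
abstains rather than guesses.

## Stage 1: evidence aggregation

Every protein gets an *evidence bundle*: alignment hits from three
tracks (a curated transporter reference database, TCDB, NR), profile-HMM
domain hits, COG hits, and a transmembrane topology. Each track has an
E-value ceiling (`transannot_thresholds()`):

| parameter | default | meaning |
|---|---|---|
| `blast_evalue_max` | 1e-5 per track | alignment-hit ceiling |
| `hmm_domain_evalue_max` | 1e-4 | per-domain *independent* E-value ceiling |
| `cog_evalue_max` | 1e-5 | COG-hit ceiling |
| `tm_standalone_min` | 6 helices | standalone TM candidacy |
| `cog_allowlist` | 4 transporter COGs | COGs usable as positive evidence |

The ceilings are conventional homology-screen values; the method's
robustness comes from the downstream filter, not from threshold tuning,
so they are deliberately ordinary and fully configurable (every value is
recorded in the output provenance header). Per-domain thresholds use the
independent (i-)E-value from the HMMER3 per-domain table, the quantity
that measures the domain hit in isolation.

Candidacy is the disjunction across tracks ("mutually inclusive"
searching): one passing track suffices. Two deliberate asymmetries:

* **COG allowlist.** Only COGs on a small transporter allowlist count as
  *positive* evidence. The exclusion COGs of the negative ruleset are
  consumed by the rule engine regardless; without the allowlist, a UvrA
  decoy's COG0178 hit would itself nominate the decoy.
* **TM-only candidacy.** Topology alone is weak evidence; a protein
  whose only signal is ≥ 6 predicted helices is admitted but can never
  rise above the lowest confidence tier. Six is the canonical
  helix count of an ABC membrane subunit, the family this pathway is
  meant to catch.

Unknown query coverage (a 12-column hit file with no proteome supplied)
is treated as failing every coverage floor — conservative by design.

## Stage 2: the negative decision tree

Rules are declarative (`negative_rule()`, YAML-serializable): a *scope*
(profile accessions that arm the rule), a *kind*, and a *payload*. The
shipped default (`default_ruleset()`) is the ABC set: armed by a
threshold-passing PF00005 hit, firing either on any of 12 exclusion COGs
(COG0178, COG1196, COG1106, COG1195, COG0419, COG3910, COG1192, COG0489,
COG2524, COG2905, COG4109, COG0517) or on any of 8 keywords
(cAMP-binding, CBS domain, Chromosome partition, Cytochrome c assembly,
Cytochrome c biogenesis, Excinuclease, RNase L inhibitor, UvrABC) found
case-insensitively as plain substrings in the descriptions of the top
`nr_top_k` NR hits by bitscore.

Design choices that were genuinely open:

* `nr_top_k = 5`: "top hits" needs a count; five is small enough that a
  single deep homolog dominates, large enough to survive one noisy
  description. Configurable and recorded in provenance.
* Keyword matching is plain case-folded substring search, no
  tokenization: the simplest semantics a curator can predict.
* First-fire-wins sequential evaluation: a decision tree is ordered by
  nature and this makes ties impossible. With the shipped set the order
  is COGs before keywords, so a UvrA decoy carrying both signals records
  the COG rule.
* Arming requires the scope domain hit to *pass* the HMM threshold, not
  merely exist — the filter prunes the inclusive search, it does not do
  its own searching.
* Keyword scanning inspects the NR track only. Curated/TCDB
  descriptions come from transporter references and would make the
  keywords fire on true transporters.

Only the ABC ruleset ships, because it is the only one with a published
specification; the rules file format exists precisely so users can
encode filters for further families. Note what this implies: a
CPA3-family candidate with oxidoreductase-flavoured NR descriptions is
*retained* — no rule is scoped to its domains. That retained false
positive is the method's documented failure mode, and the fixture
generator plants it (see below).

## Stage 3: classification and substrate transfer

The best reference hit is the highest-bitscore threshold-passing
curated/TCDB hit whose accession resolves in the reference table (ties:
lower E-value, then lexicographic accession — full determinism).
Family, subfamily and TC number are copied from it; failing that, a
minimal profile→family map (`PF00005 → ABC`, user-extensible) gives a
family without a TC number; failing that, `unclassified`.

Substrate prediction is tiered (`transfer_tiers()`): identity ≥ 60 % and
coverage ≥ 70 % transfers the specific substrate plus its class;
identity ≥ 30 % and coverage ≥ 50 % transfers the class only; otherwise
both abstain. Missing reference fields propagate as abstention at that
level. The floors are standard annotation-transfer practice (specific
function is generally not transferable below ~60 % identity;
class-level function survives into the twilight zone but needs genuine
alignment coverage); they are configurable and recorded in provenance.
Confidence tiers follow the same ladder: `high` = specific-tier
reference hit, `medium` = class-tier hit or transporter-profile-only
evidence, `low` = anything weaker (TM-only candidates in particular).

Annotation is per protein. Multi-subunit systems (ABC importers, CPA3
complexes) are *not* assembled into systems; the benchmark arithmetic
counts transport proteins, and system assembly would need genomic
context this tool does not ingest.

## The built-in TM caller

The topology track accepts an external TMHMM-short file; when none is
given, a transparent stand-in runs: mean Kyte–Doolittle hydropathy in a
sliding window (default 19 residues, truncated at the ends), thresholded
at 1.6, supra-threshold runs merged across gaps ≤ 3 positions, merged
runs < 15 residues discarded. These are the literature-standard
hydropathy settings for membrane-helix scanning; ambiguous residues
(X/B/Z/U) score 0 so real proteomes never error.

One subtlety: with gap merging enabled, the *count* of called segments
is not monotone in the threshold — raising the threshold can split a
merged run into two segments that each clear `min_len`. What is
monotone is the supra-threshold position set, and on well-separated
hydrophobic runs (the realistic membrane-protein shape) the count too.
The test suite asserts exactly these properties.

## Evaluation arithmetic

`compare_sets()` implements the concordance table: confirmed =
|predicted ∩ manual|, FP = predicted − confirmed with rate over the
predicted count, FN = manual − confirmed with rate over the manual
count. Those denominators are the only ones consistent with rates like
7/364 ≈ 2 % and 1/358 ≈ 0.3 %. Reports print the FP rate to the nearest
integer percent and the FN rate to one decimal. Substrate corrections
are counted among confirmed proteins only, as exact string mismatches
after case-folding and trimming; abstentions are never corrections, and
no synonym ontology is attempted.

## What the fixture generator emulates — and what it does not

`generate_fixtures()` writes a complete, internally consistent bundle:
FASTA proteome, reference and gold TSVs, three alignment-hit files, a
HMMER3-style domain table, a COG table, a TMHMM-short file, and a
manifest of planted truth. Scenario classes: ABC ATPases with curated
hits at engineered identity tiers (60/20/20 specific/class/abstain by
default, met *exactly* via cumulative-rounding quotas); 12-helix
MFS-like permeases hit via TCDB; UvrA and CBS decoys for each default
rule; CPA3 confusables (curated CPA3 hit + oxidoreductase NR
description, no PF00005 — untouchable by the shipped rules); ABC
membrane subunits with only sub-threshold hits and 5 planted helices
(one short of standalone TM candidacy, so they are missed — the false
negatives); and background proteins. E-values are sampled log-uniformly
inside pass/fail bands that keep a factor-of-10 guard margin from every
ceiling, so no fixture sits on a threshold boundary. Generation is a
pure function of the seed; two runs are byte-identical.

Planted evidence is *not* produced by running blastp/hmmscan/rpsblast:
realism is at the format and value-distribution level, which is the
level the pipeline consumes. Passing tests therefore demonstrate the
correctness of the aggregation, filtering, transfer and evaluation
logic — they do not demonstrate search sensitivity on real genomes,
alignment-statistic realism, or the coverage of a real curated
reference database. Published genome-scale figures (hundreds of
transporters per genome, ~18 % substrate abstention) depend on a private
multi-hundred-thousand-entry reference database and are out of reach of
any fixture; the package reproduces the benchmark *arithmetic* and the
qualitative FP/FN anatomy, not those corpus-dependent rates.

## Problem sizes and runtime

The default test-suite and acceptance problem sizes are: a 115-protein
benchmark preset (50 ABC + 10 MFS + 10 UvrA + 5 CBS + 5 CPA3 + 5
membrane subunits + 30 background), 500 randomized bundles for the
rule-engine oracle comparison, 100 random sequences for the TM-caller
oracle, and 1000 random lines for the tabular round trip. These sizes
exercise every code path and the engineered tier quotas exactly while
keeping a full run in well under a minute on one CPU.

## Known limitations

* Only the ABC negative ruleset ships; other families' filters must be
  user-authored. Retained CPA3-like false positives are expected.
* Per-protein annotation only; no operon/genomic-context rescue of
  excluded or missed subunits.
* The hydropathy caller does not model helix orientation or signal
  peptides and is not a substitute for a trained topology HMM when one
  is available — hence the external-file pathway.
* Substrate comparison in evaluation is string equality after
  normalization; synonyms ("glucose" vs "D-glucose") count as
  corrections.
* Thresholds and tier floors are global, not per-family.
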