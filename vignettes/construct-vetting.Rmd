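---
title: "Vetting constructs for cryptic splice donors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vetting constructs for cryptic splice donors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicevet)
```

## The phenomenon being modelled

Expression constructs are usually intronless cDNAs, so sequences resembling
splice donors inside them are inert. Two design choices change that.
First, fusing an epitope tag in frame to the 3' end of an ORF creates a new
junction sequence; the common V5 tag begins `GGTAAGCCT...`, so any CDS
whose stop-stripped sequence ends in a pyrimidine-rich codon such as the
leucine `CTT` yields the junction `TTGGTAAG` — a single mismatch from the
minimal consensus donor `(A/C)AGGTAAG`. Second, retaining natural 3'
genomic elements (untranslated exons, introns, a distal polyA signal)
supplies functional splice acceptors downstream. Together these let the
spliceosome excise the tag, the stop codon, and the intervening linker/UTR,
joining the ORF's 3' end directly onto a downstream exon. Translation then
runs through normally untranslated sequence to the next in-frame stop,
appending a missense peptide: with the stop 168 nt past the junction, a
424-residue protein gains 55 residues for a 479-residue product whose
function can be destroyed.

splicevet treats this as a construct-QC problem: detect candidate donors,
simulate what splicing could produce, classify the protein damage, propose
minimal repairs, and design a restriction-digest readout.

## The donor model

Donors are classified by exact pattern matching on the 8-mer window
`[cut - 3, cut + 5)`, where `cut` is the 0-based offset of the first
intronic nucleotide (the G of GT):

| tier | pattern | interpretation |
|------|---------|----------------|
| `CONSENSUS` | `(A/C)AGGTAAG` | minimal consensus donor |
| `GGTAAG_CLASS` | `NNGGTAAG` | one exonic mismatch; the V5-junction class |
| `MINIMAL` | `NNNGTAAG` | intronic pentamer only |
| `CORE` | `NNNGT NNN` | bare GT; reported only on explicit request |

The tiers are nested by pattern containment, so raising the reporting
threshold can only remove sites. An `N` in the sequence never satisfies a
constrained pattern position. This is deliberately *not* a trained
position-weight matrix or neural-network scorer: the empirical basis for
the tool is a handful of observed functional donors plus the printed
consensus, and inventing weights would fabricate precision the data do not
support. A user-supplied PWM can be layered on top by scanning at `CORE`
and post-filtering, but no default matrix ships. Known consequence: tools
trained on genomic donors (NNSPLICE, Human Splicing Finder) will report
sites this model ignores, and vice versa; empirically functional donors
have all contained at least `GT`, and every donor this model was built
around is `MINIMAL` or better, which is why `MINIMAL` is the default
reporting tier for vetting.

The default vetting posture is conservative in one specific sense: the
enumeration over-reports. Cells showed clear preferences among candidate
donors (a single product dominating), but no quantitative strength model is
available at this tier resolution, so `enumerate_isoforms()` produces every
donor/acceptor-consistent event set (donor before acceptor, removed
intervals pairwise disjoint — which also guarantees each donor and acceptor
is used at most once) up to `max_events` (default 3), deduplicated by
mature sequence, ordered by event count then leftmost removed interval.
Re-splicing of already-spliced products is not modelled; it was never
needed to explain an observed product. A hard cap (default 10,000 isoforms)
turns combinatorial explosions into errors rather than silent truncation.

## Protein-consequence calling

`call_consequence()` compares the translation of an isoform (from the ORF
start, mapped through the splice events) against the *intended* protein —
the translation of the isoform carrying exactly the annotated intron
events. Classes:

* `INTENDED` — mature mRNA identical to the intended isoform.
* `UTR_ONLY` — identical protein, different mature mRNA: splicing occurred
  but only downstream of the stop codon (tag retained).
* `TAG_LOST_EXTENDED` — native ORF intact, tag peptide absent, missense
  extension appended. This is the tag-excision signature; counts satisfy
  `total_length = native_retained + appended_missense`.
* `EXTENDED` — full intended protein (tag included) plus an extension.
* `TRUNCATED` — divergence or early stop relative to the intended protein.
* `NO_STOP` — translation runs off the mature mRNA (e.g. the polyA exon was
  spliced out).
* `ORF_START_LOST` — the splice removed the ORF start itself; reported as a
  distinct class rather than an error so batch simulations never abort.

For `TAG_LOST_EXTENDED`, `native_retained` is the length of the native
(tag-less) protein rather than a longest-common-prefix, so the appended
count is stable even if the first appended residue coincidentally matches
the tag's first residue.

## Repair search

`suggest_repairs()` evaluates every synonymous substitution of every codon
overlapping the donor window. A candidate is accepted only if (i) the tier
at the repaired cut strictly drops (to `none` ideally) and (ii) rescanning
a ±`flank` window (default 24 nt) reveals no donor at or above `MINIMAL`
that was not already present. Candidates are ordered by fewest nucleotides
changed, then donor-destroying first, then 5'-most codon — encoding a
wobble-first preference without resorting to codon-usage tables, since the
motivating fix was a single wobble change (`GGT -> GGG`, both glycine,
removing the invariant T). Acceptance is verified by translating, not by
codon-table reasoning alone, and `verify_repair()` re-scans the *entire*
construct: the motivating case's first repair succeeded at the junction yet
the transcript was still mis-spliced at a second linker donor 47 nt before
the exon-1 3' end, so a local-only audit is known to be insufficient.
Donors outside the coding span (linker/UTR) are repaired by unconstrained
single-nucleotide edits of the GT, returned under a `noncoding` flag.
Methionine/tryptophan codons admit no synonymous escape; the search then
returns an empty table with a diagnostic rather than guessing.

## The junction screen and its two modes

`run_screen()` reimplements the library-wide question "which CDSs would
acquire a donor if V5-tagged?". Two classification rules ship because the
source protocol is internally ambiguous about how many CDS nucleotides the
search used:

* `methods-10mer` (default): exact search for `AGGTAAGCCT` (consensus) and
  `TGGTAAGCCT` (DUX4-like) across the fusion junction. With a V5-type tag
  the class depends only on the CDS's final nucleotide, so the expected
  consensus fraction under uniform composition is P(last nt = A) = 1/4.
* `minimal-8mer`: the donor 8-mer is classified with the tiered model; the
  consensus class requires the CDS's terminal dinucleotide to be `AA` or
  `CA` (2/16 under uniformity) and the DUX4-like class requires `TT`
  (1/16).

Under uniform base composition the two rules therefore expect 25% versus
12.5% consensus-class junctions (and 25% versus 6.25% DUX4-like), so the
choice of rule matters for any transcriptome-wide tally. Real CDS
libraries are version-drifting downloads whose composition is neither
uniform nor stable, so the automated tests assert the analytic expectation
on synthetic libraries instead: on 10,000 uniform-terminal CDSs the class
fractions must fall inside the 99% binomial confidence intervals of 2/16
and 1/16 under the `minimal-8mer` rule. Running the screen on a
real CCDS FASTA is supported but its counts are not asserted anywhere.
Transcripts that cannot be screened (non-ACGT characters, length not a
codon multiple, missing terminal stop, internal stop) are counted and
reported with a reason, never dropped.

## Digest diagnostics

`digest_linear()` predicts fragment patterns for a linear molecule given an
IUPAC recognition site and a cut offset (default: blunt midpoint). Two
BsaAI definitions ship: `BsaAI_paper` (`TACGTG`, as printed for the V5
assay) and `BsaAI_iupac` (`YACGTR`, the enzyme's accepted degenerate site);
reports name which was used. Matching is sense-strand only — both shipped
patterns are strand-symmetric under their degeneracy, so nothing is lost
for the intended use. The diagnostic logic is purely positional: a site
inside the excised interval makes the mis-spliced product resistant while
the intended product cleaves (for the printed assay geometry, a 472-bp
product cutting to 381 + 91 bp versus a resistant 383-bp product).
Electrophoretic mobility is not modelled.

## The synthetic fixtures

`make_model_construct()` emulates the *geometry* of the motivating vector,
not its sequence (the real element is available only as a GenBank accession
and is treated as optional user input). Defaults, each chosen to match a
stated quantity: 424-codon ORF ending `CTT` (leucine), V5 tag (the
printed 42-mer, `V5_methods`) plus `TAA` stop, 40-nt linker (the N40),
11-nt exon-1 UTR, canonical introns of 200/150 nt flanking a 100-nt exon 2,
and a 120-nt exon 3 whose first in-frame stop on the mis-spliced reading
frame sits exactly `exon3_stop_offset` = 168 nt past the ORF-tag junction.
The stop codon's 3 nt are counted inside the 168 (168/3 = 56 codons
including the stop), which is the only reading under which the appended
peptide is 55 residues; the fixture adopts it and the invariant
`appended = exon3_stop_offset/3 - 1` is property-tested. A second donor is
planted in the linker 47 nt before the exon-1 3' end, present in both the
model and repaired fixtures (it is the same linker); it is only *used*
once the junction donor is gone, which the repaired fixture reproduces.
Intron lengths, the promoter stuffer (60 nt), and exon lengths have no
stated values; they were set once to small round numbers that keep the
construct under 2 kb so exhaustive enumeration in tests is instant.

Background sequence is uniform over ACGT with rejection sampling: a draw is
discarded if the assembled construct contains any donor at or above
`MINIMAL` beyond the planted set, any unplanned `YACGTR` site, or a
premature stop on the mis-spliced reading frame. Rejection (rather than
masking) keeps scans honest — every reported site in a fixture is a planted
site, so "exactly the planted signals" is testable. The natural intron
donors are planted at `MINIMAL` tier (the weakest of the construct's
donors, matching the observation that the natural exon-1 donor is the
weakest site in its construct) and the junction/linker donors at
`GGTAAG_CLASS`.

One deliberate infidelity: the printed diagnostic site `TACGTG` cannot
occur in the shipped default tag, because the protocol's printed V5 42-mer
ends `...TCTAGC` and no stop codon appended to it completes `YACGTR`. The
canonical V5 epitope (`...TCTACG`, peptide ...DST) followed by a `TGA` stop
*does* produce `TACGTG` spanning the tag-stop boundary — which reconciles
the printed enzyme site with the canonical epitope, and is how the shipped
`V5_canonical` TagSpec is defined. Since the default tag follows the
printed 42-mer verbatim, the fixture instead plants the site in the N40
linker, which lies in the same excised interval; the diagnostic logic
(intended product cuts, tag-deleted product resistant) is unchanged. Both
tag variants share the 5' end `GGTAAGCCT`, so junction behaviour is
identical and neither variant's intent is guessed.

`make_random_cds_set()` generates screen inputs: ATG start, sense codons
only (no internal stop by construction), terminal dinucleotide drawn from a
user-specified distribution (default uniform over all 16), then a stop
codon. It emulates composition at the fusion-relevant position only; real
CDS libraries have biased codon usage, so a passing synthetic screen says
the *rule* is implemented correctly, not that any particular database will
show 12.5% consensus junctions.

## Numerical and interface choices

* Coordinates: 0-based half-open everywhere internally; 1-based only as
  extra columns in human-readable reports. Intervals tile the construct
  with no gaps, and every position round-trips through the coordinate map.
* Sense strand only; the phenomenon lives on the transgene mRNA.
* Standard genetic code only; stop set {TAA, TAG, TGA}. Stop-codon swaps
  count as synonymous for repair purposes.
* Sequence alphabet {A,C,G,T,N}: `U` is normalized to `T`, IUPAC ambiguity
  codes collapse to `N` with a warning, `N` inside a translated span is an
  error, and `N` never matches a donor or enzyme pattern position.
* Determinism: all generators take explicit seeds and restore the caller's
  RNG state; two runs with the same configuration produce byte-identical
  outputs (the CLI records its resolved parameters next to every output).
* Ties in repair suggestions sort by (nucleotides changed, donor destroyed,
  codon position); ties in isoform ordering by (event count, removed
  starts). Equal-cut donors are impossible by construction.
* Test problem sizes: the exhaustive window check covers all 4^8 windows;
  scan oracles run on 100 sequences of 10 kb; enumeration is cross-checked
  against brute force for every instance shape up to 4 donors × 3
  acceptors; the screen's analytic check uses 10,000 CDSs. These sizes were
  chosen so the whole suite completes in well under a minute while leaving
  no untested branch of the combinatorics.

## Known limitations

Splice-site *strength* is not quantified, so the tool cannot say which of
several enumerated isoforms a cell will prefer — only what is possible and
what each possibility would do to the protein. Acceptors are taken from
annotation by default (the heuristic pyrimidine-tract scanner is available
but deliberately not part of the vetting default). Branch points, trans-
splicing, co-transcriptional kinetics, RNA secondary structure around
repaired codons, and codon-usage optimization of repairs are all out of
scope. The fixtures reproduce geometry, not real vector sequence, so
fragment sizes from fixture digests differ from gel sizes printed for the
real assay even though the resistant-versus-cut logic is identical.
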