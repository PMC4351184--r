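# splicevet

Vetting expression constructs for cryptic splice donors created by
epitope-tag fusions and other engineered junctions.

## The problem

Fusing a tag such as V5 in frame to the 3' end of an ORF, or any other
junction engineering, can create a functional splice donor in the transgene
pre-mRNA. On its own such a site is silent — but if the construct also
carries a downstream splice acceptor (for example because natural 3' exons
and introns were retained to provide a polyadenylation signal), the
spliceosome can use the cryptic donor and excise the tag, the stop codon,
and everything up to the acceptor. The mature mRNA then encodes an
unintended protein: the native ORF reads through the splice junction into
normally untranslated exon sequence until the next in-frame stop, appending
a missense peptide to the protein's carboxyl terminus. A V5 fusion after a
CDS ending `...CTT` creates exactly this situation: the junction reads
`5'-TTGGTAAG-3'`, one mismatch away from the minimal consensus donor
`5'-(A/C)AGGTAAG-3'`, and in a two-intron 3' context it is spliced
essentially quantitatively.

splicevet models the failure mode end to end:

* **Donor detection** — `scan_donors()` classifies every 8-mer window
  `[cut-3, cut+5)` into nested tiers `CONSENSUS` ((A/C)AGGTAAG) ⊃
  `GGTAAG_CLASS` (NNGGTAAG) ⊃ `MINIMAL` (NNNGTAAG) ⊃ `CORE` (bare GT).
* **Splice simulation** — `enumerate_isoforms()` generates every
  donor/acceptor-consistent combination of splice events;
  `call_consequence()` translates each mature mRNA and classifies it
  (`INTENDED`, `UTR_ONLY`, `TAG_LOST_EXTENDED`, `EXTENDED`, `TRUNCATED`,
  `NO_STOP`).
* **Repair** — `suggest_repairs()` proposes synonymous codon substitutions
  (wobble-first) that destroy a donor without changing the protein, e.g.
  `GGT -> GGG` (both glycine) at a V5 junction, and rejects edits that
  create new donors nearby; `verify_repair()` re-audits the whole construct.
* **Library screen** — `run_screen()` asks, for every CDS in a FASTA, what
  junction a 3' tag fusion would create (the consensus `AGGTAAGCCT` and
  DUX4-like `TGGTAAGCCT` 10-mer search strings, or the tiered 8-mer rule).
* **Digest diagnostics** — `find_sites()`/`digest_linear()` predict
  restriction fragments so mis-splicing can be read off a gel: a site
  resident in the excisable region (BsaAI `TACGTG` for V5-type fusions)
  cuts the intended product but leaves the tag-deleted product resistant.
* **Fixtures** — `make_model_construct()` and friends generate
  deterministic synthetic constructs with the full geometry (424-codon ORF
  ending CTT, V5 tag, N40 linker, 11-nt exon-1 UTR, two canonical introns,
  first in-frame stop 168 nt past the junction), so everything above is
  testable without downloads.

Coordinates are 0-based and half-open throughout the API; reports add
1-based positions. Constructs are sense-strand only.

## Worked example

```r
library(splicevet)

x <- make_model_construct()      # deterministic synthetic construct
scan_donors(x$seq)
#>    cut         tier context8
#> 1 1333 GGTAAG_CLASS TTGGTAAG   <- ORF|V5 junction donor
#> 2 1381 GGTAAG_CLASS CTGGTAAG   <- linker donor, 47 nt before exon-1 end
#> 3 1428      MINIMAL CCCGTAAG   <- natural intron-1 donor
#> 4 1728      MINIMAL TTCGTAAG   <- natural intron-2 donor

# tag-excision mis-splice: junction donor -> intron-1 acceptor, plus intron 2
acc <- x$annotated_acceptors
mis <- apply_splice(x, splice_events(c(1333L, 1728L), acc))
call_consequence(mis, x, tag_spec("V5_methods"))
#> <protein_consequence> TAG_LOST_EXTENDED: 479 aa total
#>   (424 native + 55 missense), tag lost

# the intended product, by contrast
intended <- apply_splice(x, splice_events(x$annotated_donors, acc))
call_consequence(intended, x, tag_spec("V5_methods"))
#> <protein_consequence> INTENDED: 438 aa total (424 native + 0 missense),
#>   tag retained

# digest diagnostic: intended product cuts, tag-deleted product is resistant
bsa <- restriction_site("BsaAI_paper")
digest_linear(intended$mature, bsa)
#> <digest> BsaAI_paper: 1 cut(s), fragments 1392 + 256 nt
digest_linear(mis$mature, bsa)
#> <digest> BsaAI_paper: 0 cut(s), fragments 1553 nt

# repairing the junction donor synonymously
fus <- fuse_tag("ATGGCCAAGCTT", tag_spec("V5_methods"))
suggest_repairs(fus$fused_cds, scan_donors(fus$fused_cds))
#>   codon_index old_codon new_codon residue  tier_before tier_after nt_changed
#> 1           4       GGT       GGC       G GGTAAG_CLASS       <NA>          1
#> 2           4       GGT       GGA       G GGTAAG_CLASS       <NA>          1
#> 3           4       GGT       GGG       G GGTAAG_CLASS       <NA>          1
#> 4           5       AAG       AAA       K GGTAAG_CLASS       CORE          1
```

The mis-spliced isoform retains the ORF's final leucine (CTT) codon plus
the first tag nucleotide, then reads through exon 2 into exon 3 where the
first in-frame stop sits 168 nt past the junction: 168/3 − 1 = 55 appended
missense residues, 424 + 55 = 479 residues in total. The glycine wobble
edits (`GGT -> GGC/GGA/GGG`) destroy the donor outright.

A command-line front-end with the same operations is installed as
`exec/splicevet` (subcommands `assemble`, `scan`, `fuse`, `simulate`,
`repair`, `screen`, `digest`, `fixtures`).

## Scope

The donor model is exact tiered pattern matching, not a trained
position-weight-matrix or neural-network scorer; the tool enumerates and
ranks candidate isoforms rather than predicting which one a cell will
prefer. Branch-point prediction, acceptor strength scoring, splice-strength
quantitation, GenBank parsing, and circular topologies are out of scope.
See `vignettes/construct-vetting.Rmd` for the full methods discussion.
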