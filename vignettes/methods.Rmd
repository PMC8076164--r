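---
title: "Methods: morphometrics, keys and biogeography for Greenland Hebeloma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometrics, keys and biogeography for Greenland Hebeloma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hebelomaGL)
```

## The problem

*Hebeloma* is an ectomycorrhizal agaric genus whose arctic-alpine species
are morphologically close: field characters are unreliable, and species
concepts rest on per-collection spore and cheilocystidium morphometry,
ordinal staining and ornamentation codes read in Melzer's reagent, and ITS
sequence comparison. This package implements that workflow for the 28
species recognised from Greenland: the measurement conventions, a
machine-readable trait database compiled from the species descriptions,
the four printed identification keys as executable decision trees, the
378-collection voucher catalogue with its regional tabulations, and the
ITS-variant layer. Everything is deterministic or explicitly seeded, so
each stage is testable without any external data.

## Morphometric conventions

Spores are measured as maximum length and width (apiculus excluded); the
shape index Q = length/width is computed **per spore** and then
summarised. `mean_q` is the mean of the per-spore ratios, which in general
differs from `mean_length / mean_width`; the same convention applies to
the cheilocystidium ratios A/M, A/B and B/M (apex, narrowest central, and
maximum lower-half widths), which are formed per cystidium and averaged.
The ratio of the mean widths is reported as a separate diagnostic field
(`ratio_of_means_*`) because it can fall outside the range spanned by the
per-cystidium ratios; nothing downstream consumes it.

Three conventions are not fixed by the source material and are set here
once, documented and configurable:

* **Percentiles.** The 5%/95% figures use linear interpolation between
  order statistics (`stats::quantile` type 7, the default inclusive
  convention); `quantile_type` is an argument for users who prefer
  nearest-rank.
* **Standard deviation.** Sample SD (n − 1), since each collection's
  spores are a sample from the basidioma.
* **Protocol shortfalls.** The protocol asks for ≥ 50 spores, ≥ 20 full
  cystidium quadruples and ~100 apex widths per collection "wherever
  possible"; smaller samples therefore warn (a flag on the summary) rather
  than fail.

Summaries are stored at full precision; display rounding (0.1 µm, 0.01 for
ratios) happens only in `print()` methods.

Ordinal codes — ornamentation O0–O4, perispore loosening P0–P3,
dextrinoidity D0–D4 — are parsed from the description notation in which
parentheses mark rare states (`"(D2) D3 (D4)"`). A class is *present* if
it occurs at all and *common* if it occurs unparenthesised; key leads
phrased "many spores X" test the common reading (`opd_many()`).

## The trait database

One record per species stores the "on average" spore length, width and Q
intervals (these are ranges of **collection means**, which is what the
keys compare), the lamellae count range {L}, the O/P/D code sets, the
cystidium dimension and ratio ranges, the qualitative characters the keys
consult, the distribution group, the specialist/opportunist strategy, and
the collection count. Decisions taken while compiling it:

* Qualitative traits absent from a description stay unknown, never
  default to false — the key engine treats unknowns by branching.
* `spore_shape_majority` for *H. fuscatum* is stored as `limoniform`, the
  state its own key couplet diagnoses ("many spores limoniform"), although
  its description lists amygdaloid first. Similarly *H. islandicum* is
  stored with `veil_present = FALSE` and hourglass cheilocystidia,
  matching its position in the section key, although the description
  mentions occasional veil remnants and mixed cystidium forms. Both are
  key-driven codings and are confined to those fields.
* *H. marginatulum* is counted with 42 collections (the catalogue and the
  group table agree); the habitat text's "forty-five" is kept in a
  separate field (`n_collections_habitat`) as a recorded source
  inconsistency.
* The catalogue's full-ITS and partial-ITS counts (367 + 10) sum to 377
  against 378 catalogued collections; all 378 rows are kept and the
  discrepancy is simply noted, not repaired.

`centroid_profile()` builds a specimen profile at the interval midpoints
with the recorded categorical states — the canonical "typical specimen"
used to cross-validate keys against descriptions.

## The key engine

Keys are data, not code: each couplet's leads carry a predicate tree over
profile fields (numeric comparisons, ordinal class tests, qualitative
equality, and AND/OR/NOT) plus an outcome — a species, another couplet,
or an entry point into another key. The section key's subsection outcomes
are wired as entry points: the Hiemalia outcome is the *H. hiemale*
terminal, Clepsydroida enters the *Denudata* key at couplet 2,
Crustuliniformia at couplet 4, and the Velutipes outcome enters the
*Velutipes* key.

Evaluation is three-valued. A predicate over an unrecorded trait is
unknown; unknowns propagate through AND/OR/NOT with Kleene semantics.
Traversal follows the **first lead in printed order whose predicate is
true**, exploring beforehand any earlier lead that is unknown; this
ordering matters once, where a width threshold is printed above a shape
condition and must win when both hold. A purely verbal alternative
("spores smaller") is encoded as the complement of the printed lead, so
each threshold is half-open exactly once. When no lead is true and none
is unknown — a profile outside the key's assumptions — the engine follows
every lead, records the couplet as a conflict, and returns the union; it
never dead-ends, and candidate sets are never empty.

Two interpretive decisions were needed where the printed text conflicts
with the descriptions:

* The section key's couplet 4 ("many spores O1 or O2 and many spores D0
  or D1 ...") read as a bare disjunction would pull *H. ingratum* (O2O3)
  and *H. vaccinum* ((O2)O3O4) into the *H. hiemale* terminal,
  contradicting the species key that separates them. The encoding adds
  "and not many O3", the same exclusion couplet 3 spells out explicitly
  ("O2 and not O3"); with it, all three Clepsydroida/Hiemalia taxa route
  as the species key requires.
* *H. arcticum* is described with ornamentation O1, but the *Denudata*
  couplet that diagnoses it demands "O2 to O3 ... many D3", and the
  alternative lead ("at most D2") also fails for a D2D3 specimen. The key
  is encoded as printed; the arcticum centroid therefore triggers the
  conflict rule and returns the candidate set {arcticum, louiseae}. This
  is reported by the validation layer, not silently fixed.

`validate_keys_against_taxa()` routes every centroid through the keys and
additionally reports **boundary collisions**: for every numeric predicate
on a species' traversal path, the couplet is re-evaluated with the trait
moved to either end of the species' described interval, widened by a 3%
sampling-noise margin for continuous traits (an observed collection mean
of ~50 spores at 5% relative noise scatters about 0.7% around the true
mean; 3% is a conservative ~4 SD) and by nothing for lamellae counts,
which are read exactly. If any lead flips, collections of that species
can genuinely fall on either side of the printed threshold — e.g. *H.
colvinii* (12.0–14.5 µm against a "≥ 12.5 µm" lead) or *H.
spetsbergense*, whose 7.5 µm lower width bound sits exactly on its
couplet's threshold. Eighteen of the 28 species have at least one such
straddle or touch; this is a property of the printed ranges and keys, and
the validation report is the honest statement of it. One species, *H.
aurantioumbrinum* (10–12 µm, threshold at 11), misroutes even from its
centroid.

## Biogeography

Regions: South Greenland is below 62.20°N, North above 74°N, and the
western/eastern coasts in between are split at 44°W — the source defines
West and East only as "sides" of the ice sheet, and 44°W separates all its
listed west-coast sites (48–56°W) from east-coast sites (17–37°W) in that
latitude band. Latitudes exactly on a boundary fall on the northern side;
both the divide and the boundary convention are arguments. The Low/High
Arctic line is modelled as the single latitude 70°N (the mapped line runs
Disko Island → Blosseville Coast); the small Subarctic zone is botanically
defined and is only ever assigned from an explicit site flag or the
61.25°N analysis cutoff, never inferred.

Groups: a species' occupied region set maps to group 1 ({S}), 2 ({S,W}),
3 (S and E, no N), 4 (S and N) or 5 (no S). The mapping is total — a
hypothetical {W} species falls under group 5's "never collected in South
Greenland" rule.

Six catalogue rows are filed by the source under "S-Greenland" while
carrying printed coordinates north of 62.20°N (e.g. Sermiliarsuk at
"65.53°N", a locality that lies near 61.6°N — almost certainly a
coordinate transcription slip). The catalogue keeps both facts: a
`region_stated` column holds the source's own regional filing, and
`tabulate_groups()` prefers it where present, flagging every disagreement
in a `mismatches` attribute. `assign_region()` itself stays purely
coordinate-driven. Without this precedence the published group structure
is not reproducible; with it, all 28 species land in their published
groups and the six odd rows remain visible rather than silently
reassigned.

## ITS variants

A "variant" is an equivalence class of aligned per-collection consensus
sequences under exact column-by-column identity: gap characters are
compared like any other symbol (indels were scored as insertions, so
alignment columns are the unit), and IUPAC ambiguity codes are compared
literally — a consensus of an unphased dikaryon legitimately carries R or
Y, and collapsing R with A would merge biologically distinct consensus
states. An optional relaxed mode treats intersecting base sets as equal;
it is off by default, and because relaxed matching is not transitive it
greedily assigns each sequence to the first matching class in input
order. Distances between variants are Hamming counts over columns (gap vs
base = 1). The quasi-median network construction that consumes such
distances in the original workflow is third-party software and out of
scope; this module stops at the variant/distance/shared-class layer,
writing a PHYLIP square matrix for downstream tools.

## The synthetic-data generator

`generate_specimen()` draws a collection mean inside the species' "on
average" interval from a truncated normal centred at the midpoint with SD
= interval/4 — i.e. the printed interval is read as a ±2 SD envelope of
collection means, a calibration the descriptions cannot specify and which
is therefore a documented, configurable modelling choice. Individual
measurements scatter around the collection mean with 5% relative SD
(`measurement_noise`), at the protocol sizes (50 spores, 20 cystidia) by
default. Parenthetical ordinal classes are included with probability
0.15; qualitative characters are copied verbatim from the taxon record.
`generate_catalogue()` places collections around the five main collecting
localities (Narsarsuaq, Paamiut, Kangerlussuaq, Zackenberg, Jameson
Land), covering every region the species' distribution group requires, so
group tabulation on a synthetic catalogue recovers every stored group.
`generate_toy_alignment()` engineers known private and shared variant
classes with a ground-truth manifest. All three are bit-for-bit
reproducible under a seed.

What the generator does **not** emulate: within-collection correlation of
length and width, collector effort bias, geographic clustering beyond the
five sites, intraspecific ITS diversity with realistic substitution
processes, and measurement rounding. Passing closed-loop tests therefore
show that the keys, morphometrics and tabulations are mutually consistent
with the described ranges — not that the keys resolve real material whose
traits fall in the documented overlap zones; the validation report is the
statement of where those zones are.

## Problem sizes and numerical choices in the tests

The closed-loop identification property runs 100 seeded specimens for
each species whose validation report shows neither a conflict nor a
boundary collision (10 species under the 3% margin); parameter recovery
checks that seeded sample means land within 4σ/√n in ≥ 99% of 200 seeds;
the variant brute-force oracle enumerates all pairs on random toy
alignments of up to 10 sequences; the envelope calibration is checked on
1000 seeded specimens of the two-spored, large-spored species. These
sizes keep the full suite under half a minute while leaving each property
statistically meaningful. Ties and degenerate inputs: degenerate
intervals collapse to their single value; zero measurement noise yields
identical measurements with SD 0; empty inputs error with explicit
messages ("no measurements", "empty catalogue").

## Known limitations

* The key encoding of qualitative couplets (cap bicoloration, overhanging
  margins, reddish tones) relies on explicit booleans in the trait
  database; no colour arithmetic is attempted.
* The East/West divide and the 70°N zone line are single-meridian /
  single-parallel approximations of physiographic boundaries.
* The validation layer flags range/threshold overlaps but does not
  attempt to re-engineer the keys around them; ambiguities inherited from
  the printed keys (the arcticum couplet, the aurantioumbrinum midpoint)
  are reported as findings.
* Sequence alignment itself is out of scope; variant collapsing assumes
  its input alignment.
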