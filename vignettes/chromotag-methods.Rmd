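---
title: "chromotag: methods, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromotag: methods, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Given a genome whose gene models carry chromosome-anchoring positions —
physical coordinates in base pairs for assembled genomes, or genetic-map
positions in centiMorgan for genomes ordered by recombination data — and a
set of "tagged" genes produced by a query (an identifier list, an exact
GO/PFAM annotation term, or a sequence-homology search), `chromotag`
quantifies and visualizes *where* the tagged genes lie: per-bin density
tracks rendered as chromosome heat maps, and a per-chromosome(-arm)
enrichment test. Candidate sets can additionally be filtered with
user-supplied expression data. Genomes may be only partially anchored;
unanchored genes are retained, counted and reported, but never binned.

## Coordinate model

Each genome fixes one unit (`bp` or `cM`) for all its chromosomes and one
bin width in that unit. The conventional widths are 1 Mb for compact
assembled genomes, 10 Mb for large genomes anchored via ordered physical
contigs ("virtual chromosomes" strung together from BAC contigs are
treated as ordinary bp coordinates — the stringing is upstream of this
tool), and 5 cM for genetic maps.

Internally positions are zero-based. File positions in bp are 1-based
(GFF3-compatible) and shifted on input; cM positions are real-valued
genetic-map distances where 0.0 cM is a legitimate start, so subtracting 1
from them would be meaningless and they are taken as given. This is the
one place we deviate from a strict "all inputs are 1-based" reading; the
deviation is deliberate and unit-driven.

**Bins are half-open**: bin *b* of width *w* covers `[b·w, (b+1)·w)`, with
zero-based labels printed in display units ("9-10 Mb"), so a gene at
exactly 9.5 Mb under 1 Mb binning is in bin 9 and a gene at exactly
10.0 Mb is in bin 10. A cM position exactly equal to the chromosome length
(possible after map rounding) is folded into the last bin rather than
rejected.

**Arms**: a chromosome may declare an arm boundary strictly inside
`(0, length)`. Positions below it belong to the short arm (`S`), positions
at or above it to the long arm (`L`); the boundary itself goes to the long
arm because public genome releases do not state the cut convention and a
deterministic choice is required. Chromosomes without a declared boundary
form a single whole-chromosome unit, so arm-level enrichment is possible
on mixed genomes where only some chromosomes are arm-sorted.

## Homology and the best-bidirectional-hit criterion

Hit tables use the standard 12-column tabular dialect. Thresholds are
**inclusive** (`evalue ≤ E`, `identity ≥ I`) — "at least 70% identity"
keeps a 70.0% hit — and are applied per hit row. The best hit of a query
is the maximal-bitscore hit; ties break by lower e-value, then higher
identity, then lexicographically smallest subject id. Ties must break
deterministically for reproducibility; the field does not prescribe an
order, so we fixed one and test against a pairwise-comparison oracle. A
pair (a, b) is a best bidirectional hit iff b is a's best forward hit and
a is b's best reverse hit; the result is a one-to-one partial matching and
is symmetric under swapping the tables. Homology queries tag **subject**
genes: external query sequences are mapped onto the displayed genome.

The built-in `naive_search` exists so the suite needs no external aligner:
exact k-mer seeding (both strands, one extension per diagonal), ungapped
extension under +1/−2 scoring with an X-drop of 20, one best local hit per
(query, subject). Its "bitscore" is the raw score and its e-value is the
crude surrogate `m·n·2^(−score)` (m = query length, n = total subject
length) — *not* comparable to BLAST statistics, and documented as
test-only. Minus-strand hits report `s_start > s_end` per the tabular
convention. Protein-level searches are supported only via imported hit
tables.

## Density and enrichment

For each chromosome, `all_counts[b]` and `tagged_counts[b]` count anchored
genes per bin; the relative density is `tagged/all`, defined as 0 with an
explicit `empty` flag when a bin holds no genes (so heat maps render
uniformly instead of propagating NaN). The per-bin TSV carries both counts
so either normalization (per-bin fraction, or fraction of all tagged
genes) can be recomputed downstream.

Enrichment uses, per unit *u* (chromosome or arm), the 2×2 table of
anchored genes (tagged/untagged × on-*u*/off-*u*). Unanchored genes are
excluded — they have no unit, and their inclusion is not well defined. The
one-sided p-value is the hypergeometric upper tail

> p = P(X ≥ a),  X ~ Hypergeom(N = anchored genes, K = tagged, n = on-unit)

computed as a sum of point masses (capped at 1, since summing can overshoot
by a few ulp) and verified in the tests against an independent
`lchoose`-based enumeration of all tables with N ≤ 60 at 1e-12 relative
error. Bonferroni multiplies by the number of units actually tested in the
run — not a fixed chromosome count — and the multiplier is recorded in the
output. Only over-representation is tested; depletion and FDR-style
corrections are out of scope.

## Expression filters

- `CV = sd/mean` with the **sample** standard deviation (n−1). Genes with
  zero mean have undefined CV and fail every CV filter; flat genes have
  CV 0.
- "Minimum expression" accepts genes whose value **strictly exceeds** the
  threshold in at least one condition ("surpass" read as strict).
- DEG filtering is plain membership in the uploaded list.
- Group mappings must be functions (one group per gene); a gene listed
  under two groups is a validation error, not a silent overwrite. Tagged
  genes without a group are collected under a reserved `"ungrouped"`
  label, so group partitions are true partitions.

Upload validation mirrors a data-manager workflow: unknown ids and
malformed lines are reported, and an upload with zero overlap with the
genome is rejected outright. No normalization of expression units is
attempted, and differential expression itself is computed upstream.

## Rendering

Heat maps are plain SVG 1.1: one row per chromosome, one `<rect>` per bin,
a linear white-to-red ramp scaled to the **global maximum over all panels
of the figure** (per-figure scaling keeps panels comparable; the choice is
printed in the legend), light grey for empty bins, and a `<title>` child
per bin carrying the absolute and relative tagged counts — the static
equivalent of an interactive tooltip. Group-wise rendering stacks one
panel per group on a shared axis. Rendering is static by design; linking
out to gene pages and interactive zooming are web-frontend concerns.

## Synthetic data: what it emulates, and what a green test shows

The fixture generator stands in for real genome releases. It emulates:
partially anchored gene complements (default 10% unanchored), uniform gene
placement with optional planted bin clusters, GO/PFAM-style term
assignment, planted 1:1 ortholog pairs (mutated sequence copies with
target identity drawn from 70–100%) guarded by strictly lower-scoring
decoy paralogs, log-normal expression with a flat subpopulation and a
high-variance subpopulation that doubles as the DEG list, and a planted
arm-enrichment signal whose genes also form their own co-expression-style
group.

Defaults state a small desk-scale world: 2 chromosomes × 20 Mb, 1 Mb bins,
200 genes, sequences of 300–3000 uniform i.i.d. nucleotides, 6 expression
conditions (log-normal, meanlog 3, sdlog 1, 20% flat genes, 10%
high-variance genes), arm boundaries at chromosome midpoints, and 25
background tagged genes in enrichment fixtures (≈5% of a 500-gene genome,
a plausible background for a candidate-gene study; chosen once, stated
here). Enrichment-recovery simulations disable sequence generation — a
capability flag, not a change to the stated world, since those runs use
positions only.

It does **not** emulate: codon structure or realistic base composition,
synteny-block evolution, gene-length/density correlations, map-order
error, or BLAST score statistics. A green planted-ortholog test therefore
establishes the correctness of the reciprocal-best-hit logic, not aligner
accuracy; a green enrichment-recovery test establishes that the Fisher
machinery ranks a planted signal first, not field sensitivity on real
data.

Determinism: one base seed per fixture; each sub-generator (positions,
sequences, terms, expression, hits, tag selection) consumes its own
derived stream `seed + fixed offset`, so extending one sub-generator never
reshuffles the others, and identical specs yield byte-identical files.

## Numerical and interface choices

- Probability sums are capped at 1; p-values are reported unrounded in
  memory and at 15 significant digits in TSVs, which round-trip.
- Annotation terms match as exact strings; no GO-graph ancestor expansion.
- Annotation queries report "anchored (total)" carrier counts, since
  unanchored carriers are real but unbinnable.
- FASTA ids are the first whitespace-delimited header token; FASTA records
  without a matching gene go to an orphan report rather than erroring
  (partial sequence sets, e.g. exports of tagged genes only, are
  legitimate inputs).
- Config files are JSON. The CLI enforces exactly one query mode per
  invocation and exposes set algebra (`intersect_filters`, unions at the
  caller level) instead of guessing how to combine modes.
- CLI runs write a manifest (parameters + input checksums) sufficient to
  reproduce the run; logs go to stderr, results to files.

## Known limitations

No gapped alignment or HSP chaining in the built-in search; no
per-query-coverage identity thresholds (per-hit only); no depletion tests
or FDR; no session/persistence layer; GFF3 ingestion reads `gene` features
only, anchoring them at their midpoint. Real genome releases are not
bundled: all shipped data are synthetic and labelled as such.
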