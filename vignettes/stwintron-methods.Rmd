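---
title: "Methods: models, parameters and design of the stwintron toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design of the stwintron toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stwintron)
```

## The problem

In fungal nuclear genes, an intervening sequence can consist of two nested
U2 spliceosomal introns — a *stwintron* (spliceosomal twin intron). The
internal intron must be excised first; only then is a functional splice
element of the external intron reconstituted (or exposed), allowing the
second, standard splicing reaction. In the reticulon-like gene of the yeast
genus *Lipomyces*, a single conserved intron position is occupied by three
differently nested architectures, one of which supports authentic
alternative splicing: the whole region can be excised either in two
consecutive reactions or by one long canonical intron, leaving mature
mRNAs that differ by six nucleotides.

This package implements that analysis as a reusable toolkit: splice-element
models, candidate enumeration, an ordered-excision engine with
alternative-path enumeration, nesting classification, gene-model
arithmetic, a synthetic sequence generator, and a Monte-Carlo simulator of
how such nested architectures can arise inside a pre-existing intron
("stwintronisation").

## Splice-element model

U2 introns are recognised through three elements, modelled with the fungal
consensus motifs:

| element  | pattern  | length | validity | tiers |
|----------|----------|--------|----------|-------|
| 5' donor | `GURWGY` | 6 nt   | literal `GU` prefix, then at most 1 mismatch over positions 3–6 | strong (0 mismatches) / weak |
| lariat branch point | `DYURAY` (primary), `HCURAC` (strict secondary) | 6 nt | at most 1 primary mismatch and combined strength < 5 | strong (strength ≤ 1) / weak |
| 3' acceptor | `HAG` | 3 nt | exact IUPAC match | strong only |

The branch element needs two tiers because functionally weak elements can
match the primary consensus perfectly: `UUUAAU` fits `DYURAY` with zero
mismatches yet behaves as an aberrant branch point in vivo. We therefore
define *strength* as the mismatch count against `DYURAY` plus the mismatch
count against the stricter reference `HCURAC`; an element is strong only
when the sum is at most 1. This is the minimal formalization consistent
with every strong/weak judgement the analysed splicing outcomes require
(`ACUAAC`, `ACUGAC`, `UCUAAC`, `GCUGAC` strong; `AUUCAU`, `UUUAAU` weak).
It is one possible formalization of "imperfect", and we flag it as a design
choice rather than a measured property. Acceptors are not graded: the
source material never distinguishes acceptor quality.

The internal alphabet is RNA (input DNA is transcribed on ingest); all file
output is written back in the DNA alphabet to match FASTA/GFF convention.

## Candidate enumeration

`find_candidate_introns()` lists every (donor, branch, acceptor) triple
subject to:

* intron length within `min_intron_len`–`max_intron_len` (default 40–400
  nt). The defaults bracket the observed intron sizes in this gene family
  (46–320 nt) with margin; fungal introns are typically under 100 nt.
* the branch hexamer ends 5–25 nt upstream of the acceptor start
  (`branch_to_acceptor_min/max`). Observed spacers in the analysed
  architectures are 7–17 nt; the window brackets them. This window also
  *excludes* implausibly distal branch/acceptor pairings — in the
  alternative-splicing architecture it is what rules out the upstream
  `AUUCAU` as the partner of the internal `CAG`, leaving the weak `UUUAAU`
  attached.
* when several branch hexamers serve one donor/acceptor pair, the
  candidate carries the strongest (lowest strength, ties to the 3'-most,
  mimicking proximity to the acceptor); the others are kept as alternates.

`brute_force_candidates()` recomputes the same set by cubic enumeration
with per-window scoring and is kept deliberately independent of the
vectorized scanner; the test suite asserts equivalence on random sequences
and on all built-in templates (regions ≤ 1000 nt).

Coordinates are 0-based half-open everywhere inside the package and
converted to 1-based inclusive only at GFF3/user-facing output.

## The splicing engine

`resolve_splicing()` operationalizes *intron definition* — pairing of the
nearest 5' and 3' splice sites — as **smallest candidate first**: at each
step the candidates within the residual intervening region are enumerated
and the smallest is excised. Ties break by fewest combined element
mismatches, then the 5'-most start, making resolution deterministic.

**Bifurcation.** If the smallest candidate depends on a weak element (weak
donor or weak branch), the outcome forks: path (a) excises it; path (b)
models non-recognition of its 3' splice-site group by the spliceosome —
every candidate sharing that branch/acceptor pairing is suppressed for the
remainder of the path, and the next-smallest candidate is taken. This is
the mechanism behind the alternative splice: the internal intron of the
252-nt architecture relies on an aberrant branch element, so one path
excises it (then the external intron), while the other ignores the
internal 3' group and excises one long canonical intron.

**Completeness.** A terminated path is returned only when (i) at least one
excision occurred, (ii) a fresh, unsuppressed scan of the residual region
finds no candidate intron (the molecule is splicing-inert), and (iii) the
residual length is divisible by 3. Condition (iii) encodes that retained
intervening nucleotides become exonic and must preserve the reading frame
across the junction — in the alternative splice both products are intact
ORFs, the longer one retaining the 6-nt 5'-most donor hexamer. Without it,
frame-shifting pseudo-products (e.g. a 7-nt residue left by pairing the
distal donor of the 140-nt architecture with its terminal acceptor) would
be reported as valid paths; no such product is observed. The number of
complete paths is capped (default 16) to guarantee termination on
adversarial synthetic input; exceeding the cap is an explicit error.

The engine operates on a designated intervening region whose boundaries
are supplied by the caller (or by truth annotation of a synthetic
fixture), not on whole unannotated transcripts: in comparative practice
the exon junction is known from orthology, and unrestricted scanning of
exonic sequence is out of scope. No kinetic or quantitative model of
isoform abundance is attempted; relative isoform frequencies are outside
the model.

## Classification

`classify_nesting()` labels a nested pair by the insertion offset *k* (the
number of external-intron nucleotides 5' of the internal intron):

* k = 1–5: the internal intron interrupts the 6-nt donor — `[Dk,k+1]`,
  *sensu stricto*;
* k = 6 (abutting donors) and k = 7 (donors one nt apart): the donor is
  intact but consecutive excision is still obligatory — *sensu lato*;
* insertion inside the external branch hexamer or acceptor trimer:
  `[Lm,m+1]` / `[Am,m+1]` numbered within the element, *sensu stricto*;
* any other position: *sensu lato* between elements. Offsets k ≥ 8 outside
  every element keep the `[Dk,k+1]`-style label but carry a warning flag,
  since such configurations are an extrapolation beyond attested cases.

`build_cis()` is the exact inverse (insert an internal sequence after the
k-th external residue and return the truth relation); the test suite
verifies `classify ∘ build = identity` on k over random sequences.

## Gene models and conservation mapping

`introns_of()` computes intron phases as cumulative coding length mod 3;
`mature_mrna()` concatenates exons (reverse-complementing on the minus
strand). For conservation mapping, an intron position is identified by the
pair *(alignment column of the codon containing the insertion point,
phase)*; two introns in different species occupy "the same position" iff
both coincide. This is the standard positional-homology convention.
Protein alignments are consumed as given (aligned FASTA); alignment
computation itself is out of scope, as is any phylogenetic inference.
`conserved_position_matrix()` takes the genome sequences alongside the
models because translating a CDS requires them.

## Synthetic data: templates and the decoy policy

A `cis_template()` is an ordered list of literal motifs and spacers plus a
truth annotation (internal placement, class label, expected path
signatures). The four built-in templates transcribe the printed
architectures literally — every splice element and every spacer length —
including both branch candidates of the alternatively spliced internal
intron, so the weak-branch bifurcation is exercised exactly as attested.
What is synthetic, by design, is only the spacer content; no attempt is
made to reproduce the deposited natural spacer residues.

Spacers are filled with seeded uniform residues under a decoy policy that
guarantees the realized sequence has exactly the intended parse:

1. no donor-valid hexamer may overlap a spacer position;
2. no acceptor trimer overlapping a spacer may lie within the
   branch-to-acceptor window downstream of any valid branch hexamer;
3. no valid branch hexamer overlapping a spacer may sit within the window
   upstream of an intended (all-literal) acceptor.

Offending windows are resampled iteratively (literals are sacrosanct and
never repaired; a violation confined to literals is an error). A final
verification pass runs the splicing engine and compares path signatures to
the template truth; a mismatch triggers a full respin, and exhausting the
budget is an explicit failure naming the offending spacer. Realization is
byte-deterministic in (template, seed, policy).

What passing tests on such fixtures do show: the engine, classifier and
generator are mutually consistent, and the published architectures are
recovered from first principles. What they do not show: performance on
real genomic sequence, where spurious splice-like motifs *do* occur in
intronic spacers and candidate sets are noisier — on real data the
designated-region assumption and the weak/strong calibration carry the
weight, and results should be read as hypotheses for experimental
verification (as the original splicing intermediates were verified by
RT-PCR).

`make_gene_fixture()` embeds a realized template between two coding exons
(AUG at position 0, no premature stop, stop codon at the last complete
codon of the mature mRNA, any remainder treated as 3' UTR), which yields
the expected phase-1 first intron when the default 100-nt first exon is
used. `make_orthologue_set()` builds up to nine single-gene species over
up to five conserved positions sharing one CDS, so the protein "alignment"
is trivially consistent and the occupancy matrix is exactly the input
specification.

## The evolution simulator

`simulate_trajectories()` models stwintronisation: per generation, at most
one tandem duplication (probability `p_dup`) of 4–7 nt anchored in the
donor hexamer — the footprint expected from repair of an asymmetric
double-strand break with a short 3' overhang — followed by independent
per-site substitutions (probability `mu`, to a uniformly chosen different
base). No other indels are modelled; this is the simplest mechanism that
exercises both routes to a new internal donor (duplication, or point
mutations near the 5' end). Under `reject_lethal` selection, an event set
that leaves the region unspliceable is discarded and the previous state
retained — a purifying-selection proxy; `neutral` mode disables it for
null comparisons. States are re-assessed after every accepted event with
the full engine, so a trajectory can reach `stwintron_stricto`,
`stwintron_lato`, `alternative`, or remain `canonical`.

Assessment maps outcomes to states as follows: no complete path is
`nonfunctional`; two or more distinct mature products is `alternative`;
otherwise the unique clean (residue-free) path decides between `canonical`
(single step) and the stwintron states (via the classifier). Outcomes
whose only complete paths retain residual nucleotides are treated as
`nonfunctional` for selection purposes: they alter exon content, and the
enum deliberately reserves `alternative` for genuinely multi-product
outcomes. One event stream per replicate is derived by splitting the
master seed, so runs are exactly reproducible; duplication precedes
substitution within a generation.

Default rates (`p_dup = 0.05`, `mu = 0.002` per site per generation, 50
generations, 100 replicates) are not calibrated to real mutation rates —
the source material quantifies none — and the simulator makes no claim to
estimate evolutionary dates or fixation probabilities (no population
genetics). It demonstrates *reachability and ordering* of the mechanism's
intermediate states, e.g. that donor duplication alone, on a decoy-free
ancestral intron, cannot produce a sensu stricto stwintron without
secondary mutations creating internal 3' elements (verified empirically in
the test suite), and that duplication and 3'-site formation can occur in
either order.

## Numerical and interface choices

* **Degenerate inputs**: empty regions resolve to an empty outcome rather
  than an error; a zero-length excision is rejected; normalization rejects
  IUPAC ambiguity codes in concrete sequences, naming the offending
  position.
* **Determinism**: every stochastic entry point takes an explicit seed;
  RNG state is saved and restored around internal draws so library calls
  do not perturb the caller's stream.
* **Problem sizes**: the shipped tests realize each of the four built-in
  templates over 100 seeds, check oracle equivalence up to 1000 nt, and
  run simulator checks at tens of replicates over tens of generations —
  sizes chosen so the full suite documents the claims at desk scale in
  well under a minute per check.
* **CLI**: the `stw_main()` dispatcher (installed as
  `inst/scripts/stwintron`) exposes `scan`, `splice`, `classify`,
  `make-synthetic`, `evolve` and `conserve` as thin wrappers over the
  exported functions, with a JSON provenance record per run; the R
  functions remain the primary interface. The `conserve` subcommand
  operates on the synthetic orthologue emulation; conservation mapping of
  real annotations goes through `read_gff3()`/`gene_model()`/
  `conserved_position_matrix()` directly.

## Known limitations

* The weak/strong calibration reproduces all attested judgements but is
  fitted to a small set of elements; on other genomes it may need
  re-tuning (`splice_motif_model()` exposes every threshold).
* The smallest-first rule does not address why a spliceosome would never
  pair the 5'-most donor of an abutting-donor architecture with the
  terminal acceptor (a 252-nt single intron); the rule selects the 246-nt
  candidate, consistent with the observed products, but the biological
  exclusion mechanism is unknown.
* `[L]` and `[A]` classes are implemented and tested synthetically; none
  are attested in the gene family analysed here.
* The simulator's viability proxy is binary; real purifying selection on
  splicing efficiency is graded.

## A worked example

```{r example}
tpl <- builtin_templates()$starkeyi_D67
r <- realize_template(tpl, seed = 1)
out <- resolve_splicing(r$seq, c(0, 252))
out
classify_nesting(derive_relation(out))
```
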