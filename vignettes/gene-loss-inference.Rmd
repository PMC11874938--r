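---
title: "Calling neuropeptide gene presence, pseudogenization and loss from genomes and read archives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling neuropeptide gene presence, pseudogenization and loss from genomes and read archives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptidetect)
```

## The inference problem

Comparative neuropeptidomics frequently has to decide whether a gene —
a neuropeptide precursor or its G-protein coupled receptor — is
*present*, *pseudogenized* or genuinely *absent* in a species for which
only a genome assembly or, more often, an unassembled short-read
archive is available.  Declaring absence is the statistically delicate
part: failure to find a gene in an assembly may reflect assembly gaps,
large introns, or a small and weakly conserved coding sequence rather
than true loss.  `peptidetect` implements the full inference chain as
reusable, tested components:

1. **Translated search** (`search_sequence()`, `search_archive()`):
   local alignment of protein queries against six-frame translations of
   contigs or of every individual read, with counting at the *spot*
   level (a read or read pair, the archive's sequencing unit).
2. **Coverage-based absence bound** (`coverage_model()`,
   `absence_probability()`): a Poisson model that turns "zero
   supporting spots" into an explicit probability that a present gene
   was missed.
3. **Precursor annotation** (`annotate_precursor()` and friends):
   signal peptide, convertase cleavage sites, C-terminal amidation,
   paracopy counting and family classification.
4. **Pseudogene analysis** (`align_locus_to_reference()`,
   `call_gene_status()`): frameshift-tolerant protein-to-nucleotide
   alignment that recovers frameshifts and premature stops and decides
   intact vs pseudogene.
5. **Loss mapping** (`dollo_min_losses()`, `summarize_events()`):
   minimum independent loss events on a rooted species tree under Dollo
   parsimony.
6. **Synthetic data** (`build_genome()`, `simulate_reads()`,
   `inject_lesions()`): generators that plant known genes, archives and
   lesions so that every stage is testable against ground truth without
   any download.

## The coverage model

A PCR-free genomic archive samples reads approximately uniformly from
the genome.  For a genome of size $G$, an archive of $N$ reads of
length $L_r$, and a detectable target of length $L_t$, a read supports
the target when it overlaps it by at least $o_{\min}$ bases.  Read
start positions supporting the target span a window of
$L_r + L_t - 2\,o_{\min} + 1$ positions, so the number of supporting
reads is approximately Poisson with mean

$$\lambda \;=\; N\,\frac{L_r + L_t - 2\,o_{\min} + 1}{G},$$

and the probability that a genuinely present target leaves *no* trace
is $e^{-\lambda}$ (multiplied by a per-read detection probability
$d \le 1$ when only part of the target — say, the conserved
transmembrane blocks of a receptor — is recognizable in a translated
read).  Setting $L_t = 2\,o_{\min} - 1$ collapses $\lambda$ to the
genome coverage $c = N L_r / G$, which recovers the familiar rule of
thumb: at $c = 50$,

```{r}
absence_probability(50)
```

some sixteen orders of magnitude below the $10^{-6}$ significance level
`call_rules()` uses by default (`alpha`).  `calibrate_by_simulation()`
checks the closed form against Monte-Carlo archives; the package's own
acceptance suite does this at $c \in \{0.5, 1, 2, 5\}$ with 1000
replicates per level on a 20 kb genome with a 300 bp target, verifying
the observed miss fraction against a binomial 95% interval of
$e^{-\lambda}$.

Three qualifications are built into the calling rules:

* **PCR-free is a precondition.**  Amplified archives do not sample the
  genome uniformly; with `require_pcr_free = TRUE` (default), zero
  spots in an amplified archive yield *indeterminate*, never *absent*.
* **Low coverage never proves absence.**  Zero spots with
  $e^{-\lambda} > \alpha$ yield *indeterminate* with an explanatory
  note (the gene "may have escaped detection").
* **Detection is not guaranteed per overlapping read.**
  `detection_prob_per_read` scales $\lambda$ down when conserved blocks
  cover only part of the target.

## Translated search

The searcher mirrors the semantics of translated-homology tools used
against assemblies and read archives.  Scoring is BLOSUM62 with affine
gap penalties (open 11, extend 1), raw scores.  Two deliberate choices:

* **Alignments never cross a stop codon** in the subject frame: each
  frame translation is split at stops and each stop-free segment is
  aligned separately.  This mirrors how translated search treats
  nonsense codons and is load-bearing for pseudogene truncation logic.
* **Exhaustive per-segment Smith–Waterman** is used for both reads and
  contigs rather than seed-word heuristics.  At the scales this package
  targets (reads, and contigs up to a few hundred kb), the exact search
  is fast enough, is deterministic, and removes heuristic-sensitivity
  questions; the test suite holds the implementation equal to an
  independently written Smith–Waterman oracle on random instances.

Default acceptance thresholds are raw score ≥ 55 on contigs and ≥ 45 on
150 bp reads, chosen so that a conserved block of roughly ten to
fifteen identical residues — the practical unit of read-level
detectability for neuropeptide cores and receptor transmembrane
regions — is reliably detected, while unrelated ~100-residue proteins
produce no spurious spots at 50× coverage (an invariant the acceptance
suite checks over 100 archives).  Both thresholds are configuration
(`search_scoring()`), because the field tools they mirror do not
publish a universal cutoff.  Note that *family* specificity is not the
search's job: genuinely homologous precursors (shared signal-peptide
architecture, shared cleavage cassettes) cross-hit by design, exactly
as tblastn returns related homologs; discriminating families is the
annotation module's role.

## Precursor annotation rules

The annotator is deliberately rule-based and self-contained.

* **Signal peptide**: a span starting at residue 1, 15–35 residues
  long, containing ≥ 6 consecutive hydrophobic residues
  ({A,I,L,M,F,V,W,C}) and ending at the first position where the
  signal-peptidase (−3, −1) small-residue rule (both in {A,G,S,C,T})
  holds after the hydrophobic core.  This is a heuristic stand-in for a
  dedicated predictor, kept internal so the package has no external
  model dependency; it is exact on generator-built precursors and
  approximate on real ones.
* **Cleavage sites**: all KR/RR/KK doublets (runs of basics count once,
  cut after the run).  Monobasic arginines are accepted only with a
  basic residue 4, 6 or 8 positions upstream that is not itself part of
  a site, no flanking proline, and a product of ≥ 4 residues.  The
  proline guard is what protects the internal arginine of
  PRXamide-type cores (…P-R-L) from being treated as a site; without
  it, every tryptopyrokinin paracopy would be shredded.  All pieces of
  the rule are arguments of `find_cleavage_sites()`.
* **Amidation**: a glycine immediately preceding a cleavage site is
  stripped and marks the mature peptide amidated — so
  `...SLGSELLGKR...` yields the amidated peptide `SLGSELL`.
* **Classification**: families are matched by C-terminal core patterns
  (`default_motif_table()`), e.g. tryptopyrokinin `[WY]..PR[LIV]$` with
  amidation required.  The table is literature-informed *configuration*,
  not hard-coded biology.  Longest matched core wins; exact ties leave
  a peptide unassigned with a warning.  A mutated paracopy is excluded
  from the count precisely when it fails its family's C-terminal
  pattern — the package's operational reading of "no longer
  biologically active", chosen because it is checkable; alternative
  definitions (e.g. cleavage-site integrity) would be stricter.

## Pseudogene analysis

`align_locus_to_reference()` aligns an intact ortholog precursor
against the candidate locus with a dynamic program in which one
reference residue may consume 3 nt (an in-frame codon), 2 nt (a 1 bp
deletion in the locus) or 4 nt (a 1 bp insertion); non-codon widths pay
a frame-jump penalty (default 15 raw-score units, configurable), and
residue gaps cost one affine open-plus-extend step (13).  Frame jumps
and aligned stop codons are reported as lesions with locus coordinates
and reference positions.  The protein is aligned globally, the locus
ends are free; when no translated-search anchor of score ≥ 45 exists,
the function returns an explicit no-alignment result rather than any
verdict.

`call_gene_status()` then applies the calling rule: the locus
is a **pseudogene** iff a frameshift or premature stop lies at or
before the end of the reference's last paracopy cassette.  Core
mutations alone never pseudogenize; they only reduce the intact
paracopy count.  A frameshift strictly downstream of all paracopies
leaves the verdict intact and is flagged in the notes — the
conservative reading, since a precursor truncated after its last
paracopy can still deliver every peptide.

One numerical caveat: within perfectly repetitive paracopy cassettes,
an indel has score-equivalent placements one or two codons away, so
lesion *positions* are reproducible only to about two codons while
lesion *counts and types* are exact; the tests assert exactly that.

## Dollo loss mapping

Presence states are mapped on a rooted species tree under Dollo
parsimony: a single gain at or above the root (the root state is fixed
*present* — in the motivating application the outgroup lineages
possess the genes, which is also why an all-absent ingroup costs one
loss per root child lineage, not a single stem loss), any number of
losses, no regain.  The minimum equals the number of maximal subtrees
containing at least one constrained-absent tip and no present tip;
`unknown` tips are unconstrained and never force a loss.  Among
equal-count placements the loss branch is pushed toward the tips (the
edge above the most recent common ancestor of the component's absent
tips), and `unique_optimum` records whether any slack existed.  The
implementation is held equal to exhaustive search over loss-branch
subsets on 200 random trees of up to 12 tips.

Pseudogene tips are counted both ways, because the two questions
differ: for *gene* loss the DNA persists (`pseudogene_as = "present"`),
while for *functional* loss a pseudogene is as good as absent
(`pseudogene_as = "absent"`).  `summarize_events()` additionally flags
tips that retain a ligand gene after losing the receptor — the
signature of a signalling system in decay.

## What the synthetic data do and do not emulate

`build_genome()` plants genes with 1–5 coding exons and configurable
intron lengths in an i.i.d. uniform A/C/G/T background;
`simulate_reads()` draws uniform read positions and strands (PCR-free
behaviour), with optional uniform substitution errors (default 0) and
read pairing; `inject_lesions()` introduces 1 bp indels and premature
stops at recorded coding coordinates, shifting all downstream
coordinates consistently.  Defaults are 150 bp reads, chosen as the
common short-read length since the archives the method targets do not
fix one.

Deliberately *not* modelled: GC bias and repeat landscapes, indel
sequencing errors and realistic error profiles, splice-signal sequence
(splicing is bookkept, not signal-modelled), assembly artefacts, and
cross-species sequence divergence inside the pipeline scenario (each
species carries the same ortholog protein; codon usage differs by
seed).  Green tests therefore demonstrate the *inference machinery* —
detectability at stated coverage, calibration of the absence bound,
lesion recovery, loss counting — not robustness to real-data artefacts
such as mappability, heterozygosity or reference bias, which are out of
scope.

Problem sizes used by the tests and the acceptance script (the
package's choices for a reproducible desk-scale demonstration): 2–20 kb
genomes, coverages 0.5–50, 100 archive replicates for detection, 1000
replicates per coverage for calibration, 100 random lesion injections,
200 random precursor specs, 200 random trees.

## Interfaces and reproducibility

Every stage reads and writes the field's plain-text formats: FASTA
(genomes, queries, transcript pools), FASTQ (archives; fixed Phred+33
quality), GFF3 (planted-gene truth), newick (trees, with losses as
`#loss` labels), TSV (hits, spot tables, calls, loss tables).
`run_pipeline()` binds the stages for a multi-species synthetic
scenario, writes every intermediate plus a `config_echo.yaml`
restating all thresholds and seeds, and is byte-identical across
reruns of the same configuration.  Every random step takes an explicit
seed, and seeded functions restore the caller's RNG state.  The
exported functions and `scripts/acceptance.R` are the package's
interface; there is no shell entry point, as the intended users drive
the analysis from R.

## Known limitations

* The signal-peptide rule is a heuristic; on real precursors a
  dedicated predictor will disagree near the boundary.
* The monobasic cleavage rule is a reasonable default, not a learned
  model; unusual processing contexts need a custom rule configuration.
* The frameshift aligner assumes the locus is a (possibly lesioned)
  ortholog of the reference at alignable identity; deeply diverged or
  partially deleted loci should be interpreted through the
  no-alignment and core-mutation outputs rather than trusted verdicts.
* The absence bound assumes uniform read sampling; real PCR-free
  libraries deviate mildly, so the bound should be read as an order of
  magnitude, which is how the calling rule uses it.
* Dollo parsimony gives a *minimum*; probabilistic gain/loss models are
  out of scope.
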