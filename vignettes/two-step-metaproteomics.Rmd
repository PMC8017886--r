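---
title: "Two-step metaproteomic identification guided by high-abundance proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step metaproteomic identification guided by high-abundance proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Identifying peptides from a microbial community's MS/MS spectra requires a
protein database, and for a community of unknown composition the natural
candidate — every protein from every genome that might be present — runs to
millions of sequences. Searching a database that large is slow, and the
score threshold needed to hold the false discovery rate (FDR) at a fixed
level rises with database size, so sensitivity suffers too.

`profex` implements a two-step strategy built on a simple biological
premise: ribosomal proteins and translation elongation factors are among
the most abundant proteins in any actively growing bacterium. If these
*high-abundance proteins* (HAPs) of a species are not detected in a sample,
other proteins of that species are unlikely to be detected either. HAPs
therefore make an economical fingerprint for deciding which genomes are
worth searching in full:

1. **Profiling.** Spectra are searched against a compact database holding
   only the HAPs of every genome in the collection (the *HAPdb*, typically
   ~1% of the full proteome collection). The FDR-filtered identifications
   are used to rank genomes and to pick, by a greedy set cover, the minimal
   genome set explaining a target fraction (default 80%) of the identified
   spectra.
2. **Expanded search.** Spectra are re-searched against all proteins of the
   selected genomes, supplemented with every HAP that had spectral support
   in step 1. Only step-2 identifications are reported: the two searches
   are never merged, so the reported FDR is estimated within a single
   search and is not inflated by combining lists.

## Search model

The built-in engine is a deliberately small, fully deterministic
peptide-spectrum matcher intended for desk-scale data and synthetic
validation; external engines can drive the pipeline instead through the
PSM-table adapter (`parse_external_psms()`), since the contribution here is
the database strategy, not the scorer.

* **Digestion** (`digest_protein()`): cleavage C-terminal to K/R, with the
  `trypsin/P` dialect (cleavage even before proline, the default) or strict
  `trypsin`; up to 2 missed cleavages by default; optional semi-tryptic
  peptides (exactly one non-tryptic terminus; protein termini count as
  tryptic). Peptide length defaults to 6–50 residues — neither bound is
  dictated by the method, both are configurable.
* **Masses**: monoisotopic residue masses, water 18.010565 Da, proton
  1.007276 Da. Carbamidomethyl-C (+57.02146) is a fixed modification;
  oxidised methionine (+15.99491) is variable, at most 3 per peptide.
* **Precursor filter**: `|M_obs − M_pep − k·1.00335| ≤ 15 ppm · M_pep` for
  an isotope error `k ∈ {−1, 0, 1, 2}`, with
  `M_obs = m/z · z − z · 1.007276`, charge 1–7.
* **Scoring**: singly charged b/y ladders matched within 20 ppm;
  `score = ln(Nb!) + ln(Ny!) + ln(1 + Σ matched intensities)` — a
  hyperscore-style statistic. Ties are broken by peptide string, then
  target before decoy, making every search byte-reproducible.

Decoys are whole-sequence reversals, generated after exact deduplication so
that `|decoys| = |targets|`. The FDR estimate at a cutoff `t` is
`D(t)/max(1, T(t))` (the symmetric `2D/(T+D)` variant is available); the
reported threshold is the lowest score whose estimate is at or below the
target, i.e. the one keeping the most target PSMs. The FDR is controlled at
the PSM level; peptide-level control is out of scope.

## Profiling semantics

"Unique spectra per genome" is read with set-cover semantics: a spectrum
whose peptide occurs in several genomes is creditable to any of them but is
only ever counted once, and the greedy cover re-ranks genomes after each
pick (the iterative algorithm, not a one-shot ranking — only the iterative
variant approximates a *minimum* cover). Ties are broken by lexicographic
genome id. The alternative reading — count only spectra mapping to exactly
one genome — is available as `greedy_cover(..., unique_only = TRUE)`.

Proteins identical across genomes are collapsed to one representative
before searching, but the collapse map is retained and expanded when
building the spectrum→genome incidence, so every genome carrying an
identical copy of a shared HAP is credited during profiling. This resolves
the ambiguity of whether deduplication should precede or follow genome
attribution: it precedes it for the search, and is undone for profiling.

HAP flagging accepts keyword evidence (case-insensitive substring match on
`"ribosomal protein"` and `"elongation factor"`; annotation capitalisation
is inconsistent across sources) and/or domain-scan evidence (hits against
an allowed-profile list at E ≤ 1e-10). The cutoff is applied to each
reported hit row — for HMMER3 domain tables that is the per-domain
independent E-value; whether a full-sequence E-value would be more
appropriate is genuinely ambiguous, and the per-row rule is the
conservative, self-contained choice. When both evidence types are given
their union is flagged: keywords seed the concept, profiles generalise it
to unannotated MAG proteins, and the union is the recall-oriented reading.

## Evaluation metrics

* `consistency_rate()` — over spectra identified in two nested-database
  runs, the fraction assigned the same peptide. Comparison is I/L-blind
  (isoleucine and leucine are isobaric) and ignores modification placement;
  `strict = TRUE` compares exact modified strings.
* `identification_rate()` — percent of acquired spectra identified.
* `peptide_overlap()` — Venn counts after I/L canonicalisation (I→L).
* `protein_support()` — distinct spectra per protein, a spectrum crediting
  every protein containing its peptide, with per-genome percentages of
  supported proteins.
* `detect_expressed_operons()` — chains of same-contig, same-strand genes
  with intergenic gap ≤ 100 bases whose mean spectral support exceeds 10.
  Coordinates are 1-based inclusive and the gap is end-to-start
  (`start₂ − end₁ − 1`); a midpoint convention would also be defensible,
  but end-to-start is the one stated and tested. Overlapping genes count
  as gap 0.

## The synthetic-data generator

`simulate_community()` and `simulate_spectra()` produce seeded, fully
reproducible communities with known ground truth:

* Protein sequences are random, 80–400 residues, uniform over the 20
  standard amino acids with K/R boosted to a combined frequency of ~0.14 so
  tryptic peptides of usable length exist (mean segment ≈ 7 residues).
* The default abundance vector is `(0.30, 0.22, 0.18, 0.16, 0.13, 0.006,
  0.003, 0.001)`: five genomes carry 99% of the mass and three are trace.
  This mirrors a defined gut-community standard in which the top five
  species accounted for essentially all identified spectra and the rarest
  members went undetected — the regime the profiling step is designed for.
* HAPs (default 4 of 20 proteins per genome) are expressed
  `hap_expression_boost` (default 5) times more than other proteins,
  encoding the premise that makes HAP profiling work.
* Spectra are b/y ladders of tryptic peptides sampled
  abundance-proportionally, with Gaussian m/z noise (default 5 ppm),
  lognormal intensities (heavy-tailed, like real peak heights, keeping the
  intensity term of the score informative), precursors at charge 2 — the
  simplest setting that still exercises the neutral-mass arithmetic — and
  a configurable fraction (default 0.2) of pure-noise spectra.
* Optionally, the first `homolog_genomes` genomes are derived from a
  shared ancestral proteome by mass-preserving adjacent-residue
  transpositions that never involve K/R (`transposition_rate`, default 0.1
  per residue). Homologous peptides are then exact isobars of each other
  that differ in sequence — an idealisation of the near-isobaric homologous
  peptides that real strain collections contain in abundance. This is what
  makes database-size effects visible at desk scale: with fully independent
  random proteomes a too-small database simply fails the precursor filter
  and misses the spectrum, whereas real small databases *mis*identify it.
  At rate 0.1 a ~10-residue peptide has roughly an `e^{−1}` chance of being
  untouched, so homolog pairs are identical often enough to share peptides
  and divergent often enough to disagree.

What the generator does **not** emulate: fragmentation physics and ion
series beyond singly charged b/y, isotope envelopes, retention time,
chimeric spectra, charge variation, and real homology structure
(substitutions that change mass). Passing tests on this generator therefore
validate the pipeline's logic — database construction, FDR control,
cover selection, bookkeeping — not engine-level sensitivity on real data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: an 8-genome, 20-protein
community with 2,000 spectra for profiling recovery; 8 genomes × 10
proteins with 600 spectra, repeated over seeds, for FDR calibration; and a
100-genome homologous community (6 proteins each, 1,200 spectra, fully
tryptic search) for the nested-database consistency experiment. These sizes
were chosen as the smallest at which the studied effects are
well-separated from sampling noise.

Degenerate inputs are handled explicitly: palindromic sequences produce
decoys equal to their target (allowed, reported); spectra with fewer than
10 peaks are skipped; empty incidence or an all-decoy-dominated score list
yield an informative error or an `Inf` threshold with nothing kept;
overlapping gene loci count as gap 0.

## Limitations

The built-in scorer is intentionally simple (no neutral losses, no higher
fragment charges, no rescoring) and should not be used to benchmark
engine sensitivity. Exact-identity deduplication replaces similarity
clustering — at the 100% threshold the outcome is identical, below it no
clustering is attempted. Quantification is spectral counting only;
intensity-based label-free methods are out of scope, as is peptide-level
FDR control and any third search step over well-supported proteins.
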