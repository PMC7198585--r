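---
title: "Identifying TG2-gluten isopeptides: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying TG2-gluten isopeptides: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glutenxl)
```

## The problem

Human tissue transglutaminase (TG2) either deamidates glutamine residues of
wheat, rye and barley gluten peptides or crosslinks a glutamine
γ-carboxamide to a lysine ε-amine, forming a covalent
N^ε^-(γ-glutamyl)-lysine isopeptide bond with loss of NH~3~. The resulting
TG2-gluten complexes are central to celiac-disease autoimmunity. `glutenxl`
implements the reciprocal mass-spectrometric strategy for identifying such
isopeptides between enzymatic gluten hydrolysates and seven single-lysine
tryptic TG2 peptides (carrying K205, K265, K429, K468, K590, K600 and K677),
end to end: in-silico digestion, crosslink-as-modification mass arithmetic,
crosslink-aware fragment enumeration, spectrum search with site
localization, replicate/negative-control confirmation, targeted (PRM)
validation, and glutamine specificity-motif bookkeeping.

## Crosslinks as modifications

A crosslinked species is modelled with the gluten peptide as the α-side and
the TG2 peptide as the β-side. Because the isopeptide bond releases
ammonia, the β-side enters the mass arithmetic as a formal modification
with composition `peptide − NH3`:

```{r}
format_formula(xlink_modification_composition("FLKNAGR"))
precursor_mass(isopeptide("AQIPQQL", "FLKNAGR", alpha_q_pos = 2))
```

All matching uses monoisotopic masses — the precursor tolerance of 4.5 ppm
is meaningless on average masses — and protonated m/z,
`(M + z·1.007276)/z`. Cysteine is treated as a free thiol (no
carbamidomethylation) by default, which is what the printed composition of
the K265 peptide WKNHGCQR requires; alkylation is available as an option.
Deamidation is the delta `−H −N +O` (+0.98402 Da) at N/Q, oxidation `+O`
at M, and at most five variable modifications per peptide are allowed,
counting the crosslink.

## Digestion

Gluten databases are digested with the union of trypsin, pepsin and
chymotrypsin sites and up to two missed cleavages, counted against that
union (single-pass multi-enzyme "specific" semantics). The enzymes' site
definitions are not part of the published search parameters, so standard
rules are used and are configurable: trypsin after K/R, chymotrypsin
(high-specificity) after F/Y/W, pepsin (pH 1.3-2 convention) after F/L —
each suppressed before proline. Candidate peptides default to 5-30
residues. Semi-specific digestion (one ragged terminus) is available for
peptides with unspecific cleavage at one end. The TG2 donor peptides are
tryptic peptides containing exactly one lysine, which keeps the β-side free
of positional ambiguity.

## Fragment enumeration

For each side, b- and y-ions of every prefix/suffix are generated, a-ions
as b − CO, and interior b-type internal ions of 2-12 residues. Any fragment
whose residue range contains the crosslink position carries the full
partner peptide minus NH~3~. "Double fragmentation on both crosslinked
sequences" admits a second reading — spanning ions whose attached partner
is itself truncated to a b/y sub-fragment still containing its crosslink
residue — and both classes are implemented and independently switchable
(standard internals on, truncated-partner off by default, since the
third-party calculator the field uses does not publish its enumeration
rules). Water loss is generated for fragments containing S/T/E/D, ammonia
loss for R/K/N/Q (the carried partner counts), configurable to
"always". Fragment charges run to 3+, precursor charges to 5+. Matching is
deterministic and one-to-one: nearest peak within 0.5 Da, ties toward
higher intensity.

## Scoring and site localization

Published engine scores are produced by a proprietary formula and are
treated as descriptive only. The package scores a match explicitly as a
binomial survival score,

$$S = -10\log_{10} P(X \ge k), \qquad X \sim \mathrm{Bin}(n, p),$$

with $k$ matched of $n$ theoretical fragments and $p$ the per-fragment
chance-match probability estimated from peak density × 2·tol / m/z span.
The minimum score for modified peptides defaults to 40 on this scale.
Site placements (crosslink Q, deamidation positions) are each scored on
their own fragment set; placement probabilities are the softmax of
$10^{S/10}$, per-site probabilities are sums over placements containing the
site, and sites above 0.75 are called localized — the same threshold the
confirmation rules use. Because deamidation combinations explode on Q-rich
peptides, combinations beyond a cap (default 200; tests use 32) are not
enumerated: a dynamic program reads the deamidation increments off the b/y
ladders (using only charge states whose 0.984/z shift exceeds the fragment
tolerance, with closeness-weighted peak gains) and selects one best
combination per crosslink site. The DP is exact whenever the distinguishing
ladder ions are present in the spectrum.

One spectrum yields one identification: the seven reciprocal search runs
(one TG2 modification each) compete, and only each spectrum's best-scoring
match survives. Without this rule, a coincidentally isobaric candidate
under the wrong TG2 modification can imitate a confirmable species.

## Confirmation rules

An isopeptide is confirmed when it is detected in all sample replicates
(configurable to k-of-n), absent from every negative control, supported by
at least seven b/y fragments (unique side/type/index, charge and loss
variants collapsed; internal ions do not count), contains a consecutive
ladder of at least three, has a precursor isotope dot product (idotp,
cosine of expected vs observed envelope) above 0.9, and shows consistent
replicate retention times. The retention-time window is not stated in the
published criteria; the default is ±0.5 min around the replicate median,
typical of nano-LC reproducibility, and configurable. Failing only the
75 % localization threshold yields the verdict `ambiguous-site`; any other
failure yields `rejected`, and the reason codes always reconstruct the
verdict. Verdicts are monotone: improving any single piece of evidence can
never demote a verdict.

## PRM validation

Isolation lists contain one row per (isopeptide, representation, charge),
with both the α-base and β-base (reversed) representations — the same
molecule, hence identical precursor m/z. PRM analysis assigns MS2 scans to
targets through the declared quadrupole isolation window (default 1.7 Th),
extracts per-transition traces, and picks peaks deterministically: baseline
is the trace median, boundaries at 5 % of apex-over-baseline, trapezoidal
area. Interactive-software curation is replaced by explicit rules: at least
seven co-eluting b/y transitions, a consecutive ladder of three, retention
time consistent with discovery, precursor idotp where traces exist, and no
signals in negative controls. Site assignment uses pairwise
site-determining transitions: a candidate site is assigned when its
determining ions are detected while every alternative's are not. The PRM
fragment tolerance reuses the discovery value (0.5 Da) since no separate
figure is published.

## Glutamine specificity motifs

TG2 prefers glutamines in QXP, QXXF(Y/W/M/L/I/V) and QXPF(Y/W/M/L/I/V)
contexts (X ≠ P) and disfavors QP and QXXP. The classifier applies fixed
precedence QP → QXPF\* → QXP → QXXF\* → QXXP → other; contexts truncated by
the peptide C-terminus before any rule can fire are labelled
insufficient-context, and context is always evaluated within the peptide as
identified, not its parent protein. In summaries the QXPF\* sub-motif is
folded into QXP by default (it satisfies the QXP definition; the fine label
remains available with `collapse_qxpf = FALSE`). On the packaged 29-record
set this reproduces the published crosslink counts — 12 QXP, 5 QP,
3 QXX(Y/I) — and 5 deamidations in QXP context.

## Fixtures

The 29 identified isopeptides (W1-W13, R1-R6, B1-B10) ship as a validated
TSV. Crosslink positions for W5, W11 and B5 follow the motif groupings and
site figures rather than the typeset table bolding, and each such record
carries a note. Deamidation positions lost to table typography are
reconstructed from the textual site statements and motif groupings, again
with per-record notes; the ambiguous sites are exactly the published ones
(crosslink: B4, B6; deamidation: B6, B8). The TG2 and gluten FASTA files
are *synthetic scaffolds*, labelled so in their filenames and headers: the
TG2 scaffold places the seven genuine donor peptides so their lysines sit
at the true positions K205-K677 in a 687-residue sequence with no other
lysine; the gluten scaffolds embed the identified gluten peptides with
cleavage-compatible context. They support digestion and search without any
network access but are not the real protein sequences.

## The synthetic benchmark

`generate_reference_set()` draws gluten-like proteins residue-wise at
configurable frequencies (defaults Q 0.30, P 0.20, F 0.05, L 0.08, no K/C —
prolamin-like), digests them, and pairs Q-containing peptides with the
seven TG2 donors; crosslink sites are drawn from preferred motif contexts
with probability `motif_bias` (default 0.7) and deamidation is added per
eligible site (default 0.25, at most four). `simulate_dda_run()` injects
each species into every sample replicate at a configurable fragment
coverage with uniform m/z jitter (default ±0.15 Da, inside the matching
tolerance), log-normal intensities, uniform noise peaks, and a precursor
isotope envelope; negative controls carry only the non-crosslinked
peptides. `simulate_prm_run()` produces Gaussian transition traces with
optional withholding of site-determining ions. All randomness flows from
one seed, echoed into output headers; identical seeds give byte-identical
files.

What the generator does *not* emulate: chromatographic peak shape in DDA,
ionization efficiency, isotope-resolved fragments, co-isolation chimeras,
and real gluten homology structure (repeats are emulated only through
residue frequencies). Passing round trips therefore demonstrate the
internal consistency and discriminative behavior of the pipeline under the
assumed noise model, not performance on real instrument data.

Benchmark sizes were chosen to keep the full check-suite comfortably
interactive: the end-to-end round trip uses 50 injected isopeptides in
triplicate samples plus triplicate controls at coverage 1.0 and zero noise
(where confirmed-set sensitivity and specificity are both exactly 1), and
the rank-1 accuracy benchmark uses 102 spectra at coverage 0.8 with 25
noise peaks.

## Numerical choices and degenerate inputs

Atomic masses and isotope abundances are IUPAC values; isotope envelopes
are computed by per-element convolution with exponentiation-by-squaring,
aggregated by nominal neutron offset (the form idotp operates on), and
agree with exhaustive isotopologue enumeration to 10^-10^. Scores are
computed through `pbinom(..., log.p = TRUE)` to stay finite for extreme
tails. Ranking ties break toward more matched fragments, then
lexicographic sequence, for determinism. Empty spectra yield empty results;
malformed spectrum records are skipped with a warning; all-zero observed
envelopes, peptides without lysine on the β-side, deamidation on the
crosslinked Q, and designs without controls are rejected with explicit
errors.

## Known limitations

Localization probabilities are calibrated only in the softmax sense — they
are not the published engine's probabilities and will not reproduce its
printed percentages. No FDR machinery beyond shuffled-sequence decoys is
provided, matching the original workflow's reliance on negative controls
and manual criteria. c/z ions, isotope-resolved fragment matching,
intensity prediction, scheduled PRM and label-free quantification are out
of scope.
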