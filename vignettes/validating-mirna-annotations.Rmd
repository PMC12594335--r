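---
title: "Validating MIRNA annotations: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating MIRNA annotations: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

miRvet decides, for each candidate *MIRNA* locus, whether a hairpin
precursor and its annotated miRNA/miRNA\* duplex look and behave like
a canonical Dicer/DCL product in the supplied small RNA-seq
libraries. This vignette explains the model behind each criterion,
the numerical conventions the package commits to where the biology
does not dictate one, and what the synthetic fixtures used for
testing do and do not demonstrate.

## The structural model

A candidate hairpin is folded as a single strand at 37 °C with
RNAfold (ViennaRNA), and all structural reasoning happens on the
resulting minimum-free-energy (MFE) dot-bracket string, parsed into a
partner table `p` with `p[i] = j` for each pair. The package folds
the hairpin exactly as provided — no boundary trimming, no constraint
folding — because the user is instructed to extend the precursor past
the processing sites, and the mature miRNA must not start or end the
precursor (such inputs are rejected up front: the 3′-overhang
criterion is undefined at the sequence boundary).

Assumptions inherited from this model: one MFE structure (no
ensembles or suboptimal structures), nested pairing only (no
pseudoknots), and determinism for a fixed engine version. Branched
precursors whose extra stems disrupt the duplex are not modelled
explicitly; they surface as the "Hairpin structure invalid" flag when
the mature strand pairs with itself or loses contact with the star.

### Extrapolated partners

Duplex termini are often frayed or bulged, yet the 3′-overhang
criterion needs a definite integer. For an unpaired position $i$ of a
strand, the helix is extrapolated antiparallel and linearly from the
nearest paired position $i_n$ of the same strand (ties resolved
toward the strand's 5′ end):

$$q(i) = p[i_n] - (i - i_n).$$

The extrapolated partner may fall outside the hairpin. This rule
makes an asymmetric bulge *inside* an annotated overhang read as a
3-nt overhang — deliberately: a duplex whose terminal geometry is
distorted by a bulge does not present the canonical 2-nt overhang to
the processing machinery, and the criterion should say so
deterministically rather than depend on how a particular fold places
the terminal pairs.

### Star prediction and the overhang criterion

With 1-based closed coordinates (the package's internal convention,
matching IRanges-style R practice and the 1-based coordinates in
reports), the predicted star of a mature spanning
$[m_s, m_e]$ is

$$[\,q(m_e - 2),\; q(m_s) + 2\,],$$

i.e. the sequence that forms a duplex with 2-nt 3′ overhangs on both
strands — the prediction is *defined* by that property, and
`evaluate_duplex()` on a predicted star returns overhangs (2, 2)
whenever it is valid. Prediction fails (flag "Hairpin structure
invalid") when the mature pairs with itself (it spans the terminal
loop or a secondary stem), is entirely unpaired, or the implied
interval is reversed, out of range, or overlaps the mature.

The overhang criterion itself is measured from both directions:
$\mathrm{oh}_{star} = s_e - q_m(m_s)$ and
$\mathrm{oh}_{mature} = m_e - q_s(s_s)$, and holds iff both equal 2.

### Mismatches and asymmetric bulges

The published criteria bound "mismatched nucleotides" and "asymmetric
bulges" without defining either arithmetically. miRvet commits to a
per-loop convention, applied over the *duplex span* (both strands
between and including their outermost mutually paired bases, which by
construction excludes the overhangs): each internal loop with $a$
unpaired mature-side and $b$ unpaired star-side nucleotides
contributes

* $\max(a, b)$ to the mismatch count, and
* $|a - b|$ as a candidate for the maximum asymmetric bulge.

A symmetric 2+2 loop therefore counts 2 mismatches (one per
nucleotide position, not per strand), and a one-sided 4-nt bulge
counts 4 mismatches and a 4-nt bulge. The rule is monotone in defect
size and reduces to the intuitive count on symmetric loops. Mature
positions paired to something *outside* the star interval count as
unpaired for duplex purposes. This convention is a documented choice;
other readings (e.g. per-strand counting) would shift the mismatch
thresholds' effective stringency.

## The expression model

Reads are aligned to each hairpin by exact, full-length,
forward-strand substring matching, keeping *all* placements of a
multi-occurring read (the semantics of a `-v0 -a --norc --no-unal`
short-read alignment; implemented with `Biostrings::matchPattern`,
which also finds overlapping occurrences). Counting uses raw copy
numbers: the criteria concern reproducibility — seeing the duplex
many times in one library — not cross-sample quantification, so no
normalization is applied.

A placement counts toward a strand when its start **and** end both
lie within ±1 nt of the annotated boundaries. The window is two-sided
by design: a read starting 2 nt upstream is background even if it
ends correctly. A placement satisfying both windows (impossible for
disjoint arms, guarded regardless) counts once, toward the mature.

Per library, a locus needs combined mature+star copies ≥ 10, at least
one read from *each* strand, and precision ≥ 0.75, where precision is
duplex-window copies over all copies on the hairpin. The comparison
is `>=` and exact at the boundary (0.75 is dyadic, so 75/100 passes
and 7 499/10 000 fails with no floating-point ambiguity). The
criteria are *existential over libraries*: one passing library
suffices, because failures are defined within a single library and
per-library evaluation is what gives a readout of replication;
requiring all libraries to pass would fail nearly every real locus
with tissue-specific expression. Only passing libraries are surfaced
in the results table; every library appears in the reads table.

## Flags, severities and the verdict

Fifteen diagnostic flags cover the criteria; each carries *fail* or
*warning* severity, and a locus fails iff at least one fail-severity
flag is present. Evaluation deliberately continues past the first
failure so the flag list is complete — except when the mature (or a
user-supplied star) cannot be indexed uniquely on the hairpin, in
which case geometry and expression are unevaluable and skipped.

Two conventions resolve gaps in the published flag vocabulary:

* An annotated sequence *absent* from its hairpin has no dedicated
  flag (only multimapping does); it is reported as "Hairpin structure
  invalid" with an explanatory detail, keeping the vocabulary to the
  fifteen codes.
* The two mismatch flags are mutually exclusive per evaluation: in
  plant mode, any count above 5 raises the ">5" flag (fail); in
  animal mode, counts of 6–7 raise ">5" (warning) and counts above 7
  raise only ">7" (fail). This keeps each flag's meaning sharp within
  its mode; the alternative (raising both above 7) would convey no
  extra information.

When both a `-5p` and a `-3p` record exist for one hairpin with no
star decoration, the record listed first in the mature file is taken
as the mature. The duplex evaluation is symmetric in the two strands,
so this tie-break affects labelling, not the verdict.

## Tunable parameters

| Parameter | Default (plant / animal) | Meaning |
|---|---|---|
| `duplex_len_min`–`duplex_len_max` | 20–24 / 20–26 nt | allowed strand lengths; 23–24 nt additionally warns in both modes |
| `mismatch_fail` | 5 / 7 | duplex mismatches above this fail |
| `mismatch_warn` | — / 5 | animal counts above this warn |
| `asym_bulge_max` | 3 nt | largest tolerated asymmetric bulge |
| `hairpin_min_len` | 50 nt | shorter hairpins fail |
| `precursor_warn_len` | 300 / 200 nt | longer precursors warn (each mode checks only its own bound) |
| `read_floor` | 10 copies | combined duplex copies per library |
| `precision_min` | 0.75 | per-library precision threshold (`>=`) |
| `variance` | 1 nt | positional-variance half-width |

All are overridable through `mode_config()`. Adapter handling has its
own knobs: the trim key (ath-miR166a for plants, hsa-let-7a for
animals), an adapter probe length of 12 nt, a default evidence floor
of 100 key-bearing reads, an 8-nt internal match seed, and terminal
matches down to 4 nt. Retained read lengths default to 15–34 nt —
generous bounds around the 20–26 nt duplex sizes. The key is matched
exactly (no mismatches): it is chosen to be a highly abundant
conserved miRNA, so exact occurrences are plentiful whenever the key
is appropriate for the organism, and suffix-plurality ties break
lexicographically for determinism.

In the rescue path, alternative candidates are restricted to
20–24 nt as published, in both modes; abundance is aggregated across
libraries for candidate selection (re-evaluation then uses the
standard per-library rules), and ties break to the smaller start,
then the longer candidate. Rescue never alters the primary result,
and rescued loci deserve manual scrutiny before any registry
submission.

## The synthetic fixtures

`make_hairpin()` builds `flank + mature + loop +
modified-reverse-complement(mature) + flank` (or its 3′-arm mirror),
with mismatches planted by de-complementing star positions (avoiding
wobble pairs), bulges by inserting into or deleting from the star
arm, and overhang defects by shifting the annotated star interval.
Loops and flanks are drawn from {A, C}, which cannot pair with each
other (including G·U wobble), so the designed stem is almost always
the MFE structure — but MFE folding cannot be guaranteed a priori, so
the generator folds every draw and verifies the realized geometry
(overhangs, mismatch count, bulge size, unique indexing) against the
plant, redrawing on deviation. A spec is ground truth only after this
verification. `make_library()` then emits reads at the annotated
intervals (with an optional ±1 variant profile), background reads
starting outside both variance windows, and optional 3′ adapters,
all deterministically from the seed.

What the fixtures emulate: duplex geometry defects at planted
positions and sizes, read stacks with controlled copy numbers,
precision exactly at thresholds, mis-annotated loci (offset
annotations) for the rescue path, and adapter-bearing raw reads.
What they do not emulate: sequencing errors, quality decay, isomiR
distributions beyond ±1 nt, multimapping across paralogous loci,
branched precursors, or the composition biases of real genomes.
Passing the suite therefore demonstrates that the criteria, counting
rules and thresholds are implemented exactly as specified — not that
the thresholds themselves separate true from false *MIRNAs* in any
particular organism; that judgement belongs to the criteria's
literature.

Problem sizes: the test suite verifies the counting oracle on 10⁴
randomized placements, duplex geometry against an independent
loop-walking oracle on 100 planted-defect hairpins (plus 40 in the
unit tests), star prediction on 100 fixtures, and rescue recovery on
50 offset fixtures; `scripts/acceptance.R` recomputes the same
quantities at slightly smaller sizes (50 star fixtures, 25 rescue
fixtures, 20 clean loci). These sizes give every criterion multiple
independent draws while keeping a full run in tens of seconds.

## Degenerate inputs and edge cases

* Empty library files yield zero-read libraries; every locus then
  fails expression with the read-floor and no-reads flags.
* Reads containing non-ACGU characters (e.g. N) are dropped on
  loading: exact matching could never place them.
* A read library is collapsed to distinct sequences with summed
  copies; collapsing conserves totals and placement copies multiply
  through.
* Multimapping reads contribute full copies at every placement within
  a hairpin, and loci are quantified independently — no cross-locus
  read apportionment. This is a documented limitation for families of
  near-identical paralogs.
* Trimming is idempotent on its own output except in the rare case
  where a trimmed insert happens to end with ≥4 nt of adapter prefix;
  terminal trimming removes only the longest such match.

## Known limitations

The MFE structure is a point estimate; loci whose duplex is only
well-formed in suboptimal structures will fail structurally. The
mismatch convention, the absent-sequence flag assignment, the
mismatch-flag exclusivity, and the 5p/3p tie-break are package
conventions where the published criteria are silent; all are
documented above and localized in `evaluate_duplex()`,
`evaluate_locus()` and `match_loci()`.
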