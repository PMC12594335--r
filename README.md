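# miRvet

Structural and expression-based validation of *MIRNA* annotations from
small RNA-seq data, without a reference genome.

Genome-wide small-RNA annotation pipelines produce many candidate
*MIRNA* loci, and a substantial fraction of them are false positives:
siRNA loci, degradation products, or hairpins whose annotated duplex
does not match the reads. miRvet is a secondary filter for the people
who triage such candidates — annotators preparing database submissions,
curators re-examining existing entries — and checks each candidate
against the community criteria for plant and animal miRNAs.

## What is checked

Each candidate is a hairpin precursor sequence (extended past the
processing sites) plus its mature miRNA (and optionally miRNA\*)
sequence. The hairpin is folded to its minimum-free-energy secondary
structure with RNAfold, the duplex strands are indexed on it, and the
locus is scored on:

**Structural criteria**

1. a single miRNA/miRNA\* duplex with a two-nucleotide 3′ overhang on
   both strands (if no miRNA\* is supplied, the one satisfying this
   property is predicted from the fold);
2. at most 5 (plants) or 7 (animals) mismatched nucleotides in the
   duplex;
3. no asymmetric bulge larger than 3 nt in the duplex;
4. duplex strands of 20–24 nt (plants) or 20–26 nt (animals).

**Expression criteria**, evaluated per library from perfect
forward-strand read alignments to the hairpin:

5. at least 10 combined miRNA + miRNA\* reads in a single library,
   counting reads whose start **and** end fall within ±1 nt of the
   annotated strand boundaries (the positional-variance window);
6. precision ≥ 75 %, where

   precision = (miRNA reads + miRNA\* reads) / (all reads on the hairpin),

   computed from raw counts within each library.

Every violated criterion raises one of fifteen diagnostic flags, each
carrying a *fail* or *warning* severity (some mode-dependent, e.g.
more than 5 duplex mismatches fails plants but warns animals). A locus
fails iff at least one fail-severity flag is present; warning-only
loci pass. Failed loci can optionally be *rescued*: the most abundant
aligned 20–24 nt sequence is re-evaluated as an alternative mature
miRNA and reported separately when it passes.

## Worked example

The package ships a fixture generator that builds hairpins with
planted, post-fold-verified geometry; the same generator drives the
test suite. Two synthetic loci — one clean, one with 30 % background
reads diluting precision — evaluated against two libraries:

```r
library(miRvet)
tr1 <- make_hairpin(fixture_spec(seed = 1))
tr2 <- make_hairpin(fixture_spec(seed = 2, mature_copies = 30,
                                 star_copies = 10, background_copies = 30))
write_fasta(data.frame(id = c("syn-MIR1", "syn-MIR2"),
                       seq = c(tr1$hairpin, tr2$hairpin)), "hairpins.fa")
write_fasta(data.frame(id = c("syn-miR1", "syn-miR1*", "syn-miR2"),
                       seq = c(tr1$mature_seq, tr1$star_seq, tr2$mature_seq)),
            "mature.fa")
write_library_fastq(make_library(tr1), "lib1.fastq")
write_library_fastq(make_library(tr2, 2), "lib2.fastq")

run <- mirvet("hairpins.fa", "mature.fa", c("lib1.fastq", "lib2.fastq"),
              mode = "plant", rescue = TRUE, out_dir = "out")
summary(run)
```

```
syn-MIR1: pass
syn-MIR2: fail [Precision less than 75%]
run summary: 1 pass / 1 fail / 0 rescued
 locus_id verdict flags
 syn-MIR1 pass
 syn-MIR2 fail    Precision less than 75%
```

`syn-MIR1` meets every criterion in `lib1` (100 mature + 20 star
reads, precision 1.0); `syn-MIR2` has 40 duplex reads against 30
background reads in `lib2`, precision 40/70 ≈ 0.57 < 0.75, and fails
on that criterion alone. `out/results.csv` holds one row per locus
(sequences, 1-based duplex coordinates, mismatch/bulge/overhang
metrics, per-passing-library counts, flags, verdict):

```
"locus_id","mature_seq","mature_start","mature_end",...,"flags","verdict"
"syn-MIR1","CGGACAAUUCCCUGUGUAGUA",11,31,...,"","pass"
"syn-MIR2","CUGCAACAGGGCUCGAACGCU",11,31,...,"Precision less than 75%","fail"
```

while `out/reads.csv` reports counts and precision for *all*
locus × library pairs, including failing ones. With `plot = TRUE`,
per-locus structure (mature orange, star blue) and read-depth plots
are rendered as PNG.

The same pipeline is available from the shell:

```sh
Rscript exec/mirvet --hairpins hairpins.fa --mature mature.fa \
    --reads lib1.fastq,lib2.fastq --mode plant --rescue --out out
```

Untrimmed libraries can be processed with `--autotrim`, which locates
reads containing an abundant conserved miRNA (the *trim key*;
defaults: ath-miR166a for plants, hsa-let-7a for animals) and takes
the most frequent 12 nt following it as the 3′ adapter.

## Documentation

The methods vignette (`vignettes/validating-mirna-annotations.Rmd`)
describes the folding and duplex-geometry model, the counting
conventions, every tunable threshold, and the limits of what the
synthetic fixtures demonstrate.
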