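# ssrminer

Genic microsatellite (SSR) mining and marker development from transcriptome
assemblies.

## The problem

Simple sequence repeats — tandem repetitions of a 1–6 bp DNA unit — are the
workhorse co-dominant markers for crops with few genomic resources.  Given
an assembled transcriptome (a FASTA of unigenes), a marker-development
pipeline must:

1. summarize the assembly (sequence count, mean length, N50, GC, length
   distribution);
2. find every *perfect* microsatellite whose repeat count reaches a
   per-unit-length minimum (here 11 for mono-, 6 for di-, 5 for tri- and
   tetra-, 4 for penta- and hexanucleotide units), group motifs into
   classes invariant under cyclic rotation and reverse complementation
   (`GA`, `AG`, `TC`, `CT` are all `AG/CT`), and flag *compound* SSRs —
   neighbouring repeats separated by at most a stated interruption
   distance;
3. keep loci with enough flanking sequence (≥150 bp each side) and design
   primer pairs under standard constraints: length 18–22 bp (optimum 20),
   melting temperature 50–60 °C with ≤4 °C difference within a pair,
   product 100–300 bp;
4. score validation panels: number of alleles (Na), observed
   heterozygosity (Ho = fraction of scored individuals with two different
   alleles), and polymorphic information content,

   PIC = 1 − Σᵢ pᵢ² − Σᵢ<ⱼ 2 pᵢ² pⱼ²,

   from the allele frequencies pᵢ at each marker.

`ssrminer` implements all of this as composable R functions, plus
seed-reproducible synthetic generators (sequences with implanted repeats of
known position, genotype panels drawn from stated allele frequencies with
an inbreeding coefficient) so every stage can be validated against known
truth, and a command-line interface.

## Worked example

```r
library(ssrminer)

# a 50-sequence synthetic transcriptome with implanted SSRs of known truth
sim <- generate_sequences(implant_plan(n_seqs = 50, seed = 7))
assembly_stats(sim$records)
#> Assembly statistics
#>   sequences : 50
#>   total bp  : 45338
#>   mean len  : 906.8 bp
#>   N50       : 1151 bp
#>   GC        : 0.467
#>   length distribution:
#>     201-500    19
#>     501-1000   16
#>     1001-1500  9
#>     1501-2000  1
#>     >2000      5

loci <- find_ssrs(sim$records)   # default thresholds 11/6/5/5/4/4
head(loci[, c("seq_id", "start", "end", "motif", "class", "repeats")], 3)
#>     seq_id start  end motif   class repeats
#> 1 syn00001  1483 1493     A     A/T      11
#> 2 syn00002   125  136    AG   AG/CT       6
#> 3 syn00003   178  192   AAG AAG/CTT       5

summarize_ssrs(loci)$grand_total
#> [1] 12

mk <- design_markers(loci, sim$records)   # flank >= 150 bp, primer rules
mk[1, c("marker_id", "fwd", "rev", "fwd_tm", "rev_tm", "product_len")]
#>   marker_id                    fwd                 rev fwd_tm rev_tm product_len
#> 1    mk0001 ACGGTCAACCGCACCTAATGTC GAGCGGATGACAATTGCGG   56.7  53.25         300

# genotype panel statistics (Na / Ho / PIC)
gsim <- simulate_genotypes(geno_sim_plan(seed = 7))
summarize_markers(gsim$genotypes)$per_marker
#>   marker_id na      ho       pic n_scored
#> 1        m1  2 0.18750 0.3710632       32
#> 2        m2  3 0.09375 0.4496354       32
```

Interpretation: every locus row is a maximal perfect repeat (the sequence
between `start` and `end`, 1-based inclusive, is exactly `motif` repeated
`repeats` times); `class` pools all rotations and reverse complements of
the motif.  A designed marker's product interval spans the whole repeat
and satisfies every primer constraint — `verify_marker()` rechecks them
all independently.  In the panel, low Ho with intermediate PIC is the
signature of a strongly selfing species (the simulation default is
inbreeding F = 0.9).

## Command line

```sh
inst/cli/ssrminer mine --fasta unigenes.fasta --min-repeats 1:11,2:6,3:5,4:5,5:4,6:4 --out run1
inst/cli/ssrminer design --fasta unigenes.fasta --min-flank 150 --product 100:300 --tm 50:60 --out run2
inst/cli/ssrminer genostats --genotypes calls.tsv --out run3
```

Each run writes its outputs atomically together with a `manifest.txt`
recording the resolved configuration and seed, so any run is reproducible
from its manifest.

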