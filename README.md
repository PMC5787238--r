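# smurf16S

Joint maximum-likelihood profiling of microbial communities from short
reads sequenced over **several independently amplified 16S rRNA gene
regions**.

## The problem

Standard amplicon surveys sequence a single 16S variable region, and many
distinct full-length 16S sequences are identical over any one short
region, so a single-region profile cannot tell them apart.  Sequencing
several regions in separate PCRs recovers much of the lost resolution —
but only if the regions are *combined in one reconstruction* rather than
profiled separately.  This package implements that joint reconstruction
for anyone profiling communities with a multi-primer-pair protocol
(or re-analysing per-region data such as paired HMP mock-community runs),
together with the resolution analysis and simulation machinery needed to
design and evaluate such protocols.

## The model

A protocol-specific k-mer database is built from a full-length reference
(Greengenes/SILVA-style FASTA + taxonomy).  A reference sequence *j* is
**amplified** in a region if each primer matches it with at most two
mismatches; each amplified region contributes the read-length k-mer(s) the
sequence would produce (for paired-end reads, the concatenation of the
first *k* bases of the amplicon and the first *k* bases of its reverse
complement).  The sparse mixture matrix *M* holds

    M_hj = Pr(kmer = h | bacterium = j) = 1 / R_j        (paired-end)

where *R_j* is the number of regions amplified for *j* (0.5/*R_j* per end
for single-end reads).  Each read *i* is matched against its region's
k-mers; with a constant per-base error probability *p_e* and at most two
read/k-mer mismatches,

    E_ih = Pr(read = i | kmer = h) = (p_e/3)^n_e (1 - p_e)^(L - n_e).

With `Q = E M`, the likelihood of the *N* matched reads,
`prod_i sum_j Q_ij pi_j`, is convex in the read-proportion vector `pi`,
which is estimated by the EM fixed point

    pi_j <- pi_j * (1/N) * sum_i Q_ij / (sum_j' Q_ij' pi_j')

and converted to relative taxon frequencies
`x_j = (pi_j/R_j) / sum_j (pi_j/R_j)`.

Reference sequences sharing one **footprint** (identical k-mers over all
amplified regions) are inherently indistinguishable and are reported as
**groups**; resolution per organism is summarised as the **ambiguity** —
the exponent of the Shannon entropy of the per-sequence weights assigned
to it (a single group of equally weighted members has ambiguity equal to
the group size; lower is better).

## Worked example

Profile a simulated 6-member power-law community over three regions
(20-sequence toy reference, 30,000 reads, 0.5% sequencing error):

```r
library(smurf16S)
syn <- synthetic_reference(n_taxa = 20, n_regions = 3, core_len = 150, seed = 11)
db  <- build_region_kmer_db(syn$reference, syn$primers, k = 60, mode = "paired")
comm  <- sample_power_law_community(syn$reference, n = 6, seed = 12)
reads <- simulate_region_reads(comm, db, total_reads = 30000,
                               error_rate = 0.005, seed = 13)
fit <- smurf(reads, db)
summary(fit, min_x = 1e-3)
#> Community profile: 6 taxa with x > 0.001 (29338 reads, logLik -198184.9)
#>
#>   taxon_id taxonomy                                              pi      x       R
#> 1 syn0002  Bacteria;SynthPhylum;SynthGenus;Synthetic_species_002 0.40790 0.40790 3
#> 2 syn0016  Bacteria;SynthPhylum;SynthGenus;Synthetic_species_016 0.20440 0.20440 3
#> 3 syn0014  Bacteria;SynthPhylum;SynthGenus;Synthetic_species_014 0.13780 0.13780 3
#> ...
weighted_precision_recall(comm, fit)
#> weighted recall 1.0000, weighted precision 1.0000 (6 reconstructed taxa)
```

`x` is each sequence's estimated relative frequency (here close to the
simulated 1/rank frequencies 0.408, 0.204, 0.136, ...); 29,338 of the
30,000 reads survived matching and the low-frequency filter.  `R` is the
number of regions each sequence is amplified in.

The resolution gain from combining regions, on a reference engineered so
that single regions are ambiguous (60 sequences drawn from 6 core
variants per region):

```r
syn <- synthetic_reference(n_taxa = 60, n_regions = 3, core_len = 120,
                           pool_sizes = 6, seed = 21)
db  <- build_region_kmer_db(syn$reference, syn$primers, k = 50)
compute_theoretical_groups(db, regions = 1)
#> smurf_footprints over regions {1}: 6 groups over 60 taxa; 0.0% uniquely identifiable
compute_theoretical_groups(db)
#> smurf_footprints over regions {1,2,3}: 60 groups over 60 taxa; 100.0% uniquely identifiable
comm <- sample_power_law_community(syn$reference, n = 10, seed = 22)
region_sweep(db, comm, total_reads = 20000, error_rate = 0.005, seed = 23)
#>   n_regions regions precision recall n_reconstructed mean_member_ambiguity
#> 1         1       1     0.196      1              51                  10.5
#> 2         2     1,2     0.318      1              51                   2.5
#> 3         3   1,2,3     0.594      1              43                   1.0
```

Recall stays perfect while weighted precision rises and the mean
ambiguity of community members falls from 10.5 to 1 as regions are added
at a constant total read budget.

The packaged primer tables (`default_primers()`, the six-pair
multi-region set, and `v4_primers()`) can be used against a real
Greengenes or SILVA export via `read_reference()` /
`build_region_kmer_db()`; full-database runs are outside the test suite's
scope.

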