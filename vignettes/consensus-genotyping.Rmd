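---
title: "Consensus SNP genotyping across variant callers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus SNP genotyping across variant callers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensnp)
```

## The problem

Calling SNPs from sequencing reads — in particular from RNA-seq reads mapped
to a cross-species reference — produces call sets that differ between
variant callers, both in which sites are detected and in the genotypes
assigned to individual samples. `consensnp` implements the post-calling half
of such a workflow: it starts from one VCF per caller over a shared sample
roster and produces filtered, combined, validated genotype sets plus the
basic genetic summaries a population-genetics user needs first (allele
frequency spectrum, genomic density, functional annotation, sample
clustering).

## Combination rules

Let $n$ callers report call sets over the same roster. Two records are *the
same site* only if chromosome, position, reference and alternate allele all
match after decomposition of complex records into primitives; comparing
genotypes across different allele pairs is meaningless, so a position
detected with different alternate alleles counts as not co-detected.

Three combination modalities are provided:

* **Strict $k$-of-$n$ intersection** (`intersect_strict`): a site is kept
  iff it is detected by at least $k$ callers *and* every detecting caller
  reports an identical genotype vector over all samples (missing calls must
  also match). Callers that did not detect the site do not veto it; an
  optional flag additionally requires detection by all $n$.
* **Consensus genotyping** (`consensus_genotypes`): candidate sites are
  those detected by at least $k$ callers; per sample, the consensus call is
  the genotype reported identically by at least $k$ callers, otherwise the
  call is set to missing. A missing call never votes and never wins: it is
  only the fallback. We require $k > n/2$, which makes ties impossible by
  construction; the default $k = 3$ of $n = 4$ matches the usual setup.
* **The modality grid** (`modality_grid`): every single caller, the strict
  $(n{-}1)$- and $n$-caller intersections and the $(n{-}1)$-caller consensus,
  each crossed with the three missing-value modalities below. By
  construction the strict sets nest ($n$-caller $\subseteq$
  $(n{-}1)$-caller $\subseteq$ consensus) and counts grow with the
  missingness allowance; the test suite asserts this lattice on every noisy
  simulation.

With independent per-caller genotype errors at rate $\varepsilon$ (a wrong
call is one of the two other biallelic genotypes, $\varepsilon/2$ each),
the probability that a 3-of-4 consensus call equals the truth can be
computed by exhaustively enumerating the $3^4$ caller-outcome table. The
test suite performs this enumeration (it is the oracle, not a closed-form
shortcut) and checks simulated consensus accuracy against it within three
binomial standard errors; at $\varepsilon = 0.1$ the enumeration gives
0.9477.

## The filter cascade

Each caller's decomposed table passes through per-site predicates, applied
in this order (they commute, so only per-stage counts — not the final set —
depend on the order):

1. **Biallelic SNPs** — indels and multiallelic SNPs removed.
2. **Site quality** — QUAL $\geq$ 30, inclusive; records without QUAL are
   removed and counted.
3. **Intra-specific polymorphism** — when reads are mapped to another
   species' genome, many records are fixed interspecific differences: every
   individual the same non-reference homozygote. We keep a site only if it
   segregates within the roster (at least one heterozygote, or two distinct
   homozygotes, among non-missing calls). This is an operational definition:
   no conspecific reference is available to compare against. All-
   heterozygous sites (possible collapsed paralogs) are retained but
   counted in the filter log, since no paralog filter is part of the
   cascade.
4. **Missingness modalities** — `noNA` (0 missing calls), `2NA`
   ($\leq 2$), `anyNA` (no filter). Missingness is counted at the roster
   level (one call per genotype), not per sequencing replicate, because the
   thresholds refer to genotypes.

Decomposition (`decompose`) reduces MNP/complex records to primitives by
trimming the shared prefix/suffix of each ref/alt pair, splitting
equal-length remainders per differing base and keeping unequal-length
remainders as a single left-anchored indel. This deliberately avoids a full
pairwise aligner: for caller output (short MNPs and simple complex records)
positional pairing is exact, and anything irreducible is left as one record
and removed later by the biallelic filter. Primitives inherit the source
record's QUAL; per-sample genotypes are projected allele-wise, and
primitives identical across alternate alleles of one record are merged.

## Validation against an array truth set

`match_truth` pairs called sites to array markers on (chromosome,
position) and keeps a pair only when the marker's allele set equals
{ref, alt}. Markers whose alleles instead match the reverse complement are
flagged strand-ambiguous and excluded rather than guessed — without chip
strand metadata the orientation is unguessable, and A/T and C/G sites are
always their own reverse complement, so they are always excluded.

Genotyping accuracy is the percentage of identical calls over pairs where
both sides are non-missing; missing-vs-call pairs are excluded from both
numerator and denominator (not counted as errors), and a sample with no
comparable pair has *undefined* accuracy rather than zero. Samples below a
90% accuracy threshold are flagged as likely labeling errors or sample
swaps. Repeatability between two experiments is reported both as the
fraction of the second experiment's sites re-found at the same site key and
as the stricter fraction whose *full* genotype vector (missing pattern
included) is identical; a per-sample concordance is also reported since the
strict full-vector reading is one of two defensible interpretations.
`accuracy_vs_count_regression` fits accuracy on SNP count by OLS; residuals
are signed so that positive means better than predicted.

## Genome summaries

* **MAF**: folded alternate-allele frequency over non-missing calls;
  `filter_maf` uses a strict inequality ("higher than" the threshold,
  default 0.05).
* **Windowed density**: fixed tiling $[kw{+}1, (k{+}1)w]$ with $w =$
  100 kb by default, last window truncated; SNPs on chromosomes absent from
  the annotation are excluded and counted.
* **Density vs expression**: each gene is assigned to the window containing
  its start coordinate (the simplest reading of "genes located in the same
  window"; overlap-weighting would change little at 100 kb), x = summed
  log2 counts-per-million expression, y = SNP count, OLS $R^2$ and slope.
  The package consumes the expression table; it does not quantify reads.
* **Region annotation**: exactly one of CDS\_exonic, UTR5, UTR3, splicing,
  intronic, intergenic per SNP. "Splicing" is the first/last 2 bp of an
  intron (the canonical splice dinucleotides); the margin is a parameter
  since category schemes differ between annotators. Precedence across
  overlapping genes is CDS > UTR > splicing > intronic. Exonic positions
  lacking an explicit CDS/UTR feature get the UTR side implied by their
  position relative to the gene's CDS span.
* **Coding effects**: the codon is located via CDS intervals, strand and
  phase of the first (only) transcript model; reference and alternate
  codons are translated with the standard genetic code; classes are
  synonymous / nonsynonymous / stopgain / stoploss / not\_coding. A
  disagreement between the VCF reference allele and the reference sequence
  is an error, not a silent recode.

## Population structure

`ibs_distance` computes $d = 1 - \mathrm{IBS}$, where IBS counts shared
alleles with multiplicity (2 for identical genotypes, 1 for one shared
allele, 0 for opposite homozygotes) over twice the number of jointly
non-missing sites, pairwise-complete — the allele-count IBS convention of
standard genotype toolkits (note that some tools also offer a
genotype-match weighting; exact cross-tool replication should use the
allele-count mode). `hierarchical_clustering` performs agglomerative
clustering; the linkage is a parameter because published descriptions of
"hierarchical ascendant clustering" rarely state it, and UPGMA (average
linkage) is the default as the standard choice for genetic distance
matrices. Samples are sorted lexicographically before clustering so ties
break deterministically.

## The synthetic data generator

The generator defines the study conditions under which the package is
tested, and every stochastic step is seeded and bookkept so that each
downstream count has an exact or analytic expectation.

* **Population structure**: 6 populations × 2 genotypes by default
  (12 samples). Per site, an ancestral frequency
  $p \sim U(0.05, 0.95)$ and per-population frequencies from the
  Balding–Nichols Beta$\!\left(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\right)$
  with $F = 0.1$; Hardy–Weinberg genotypes within populations. The moment
  identity $\mathrm{Var} = p(1-p)F$ is tested directly.
* **Caller error model**: per caller, independent site detection
  (default 0.9), genotype error (defaults 0.002–0.02 across the four
  callers, chosen to land per-caller chip accuracy in the 90–99% band),
  missingness (0.02), and QUAL drawn with 10% of sites below the
  threshold of 30. Contaminant records — indels (5%), multiallelic SNPs
  (3%) and interspecific fixed-difference sites (10%) — are injected with
  QUAL $\geq$ 30 so exactly one filter stage is responsible for removing
  each class, which makes the filter log exactly predictable.
* **Correlated errors**: real callers consume the same alignments, so
  their errors are not independent. Independence is the deliberate default
  because it admits exact enumeration oracles; a `shared_error_rate` knob
  copies a fraction of errors into all callers to reproduce the regime
  where combining callers trades quantity for quality qualitatively.
* **Genome and expression**: non-overlapping multi-exon gene models (one
  per equal-width slot so genes cover every window), explicit UTRs, CDS
  with phases and total length divisible by 3, log-normal per-gene
  expression, and SNP placement per 100-kb window proportional to summed
  window expression plus a small intergenic baseline — making the
  density–expression correlation testable by construction.
* **Chip simulation**: a random marker subset recoded to nucleotide
  genotypes, optional independent chip errors, and optional column swaps to
  create detectable sample-identity failures.

What the generator does **not** emulate: read-level processes (coverage,
allelic imbalance, mapping bias), linkage disequilibrium between sites,
caller-specific error signatures, or reference-annotation mismatch between
species. Passing tests therefore demonstrate the correctness of the
combination/validation/summary logic under a clean error model, not the
field performance of any particular caller combination on real reads.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (VCF convention); windowing
  converts internally.
* Genotypes are unordered and unphased; phase separators in input are
  discarded, since every comparison in the pipeline is genotype-level.
* FORMAT fields other than GT are dropped: no downstream operation consumes
  them.
* Primitives are *not* re-merged into multiallelic records after
  decomposition; multiallelic leftovers are removed by the biallelic filter,
  which reaches the same final set.
* QUAL of a combined site is the mean over detecting callers (the spec of
  a combined record needs one value; any monotone summary would do, and the
  mean is order-independent).
* The consensus candidate rule requires *detection* by at least `min_agree`
  callers, the stronger of the two readings of "a consensus set between 3
  callers"; presence in pairwise unions would admit sites only two callers
  ever saw.
* Degenerate inputs: empty tables round-trip as header-only VCFs; an
  all-equal-x regression is an error while a constant-y regression returns
  $R^2 = 0$; a sample pair with no jointly non-missing site is an error
  naming the pair.

## Problem sizes in the test suite

The suite exercises the consensus logic against a brute-force
reimplementation on 200 random 4-caller × 12-sample micro-fixtures, the
error-model calibrations at 50,000–60,000 site × sample cells, detection
rates at 20,000 sites, structure recovery on 20 replicates of 12,000 SNPs
(10,000 after MAF filtering) and the annotation logic on a 30-case
hand-derived table. These sizes put Monte-Carlo standard errors well below
the asserted tolerances (all stochastic checks use three standard errors)
while keeping the default test run fast.

## Known limitations

* Only one transcript model per gene is used for effect classification;
  multi-isoform genes are resolved by their first model.
* The intra-specific filter cannot distinguish a true fixed interspecific
  difference from a site monomorphic in a small roster; with 12 genotypes a
  low-frequency allele is sometimes absent by chance and the site is
  dropped.
* Strand-ambiguous array markers are excluded from validation rather than
  resolved; accuracy estimates ignore them entirely.
* The generator draws sites independently; statistics that depend on
  linkage (e.g. imputation quality, haplotype methods) cannot be studied
  with it.
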