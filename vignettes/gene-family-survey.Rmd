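---
title: "Methods: gene-family surveys with genefamkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family surveys with genefamkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefamkit)
```

# Scope

`genefamkit` implements the computational stages of a genome-wide
gene-family survey of the kind routinely published for plant protease,
kinase and transcription-factor families: identify the family members in a
proteome from domain evidence, profile their physicochemistry, detect and
date duplicate pairs, scan promoters for cis-regulatory elements, build a
bootstrapped family tree with exon–intron statistics, and apply the standard
expression and phenotype formulas. A seeded synthetic-data generator plants
ground truth for every stage, so the whole pipeline is testable with no
download.

This vignette documents the models, the defaults and why they were chosen,
the numerical choices, and what the synthetic tests do and do not
demonstrate about real data.

# Member identification

Real surveys run HMMER (`hmmsearch --domtblout`) and BLASTP against a
proteome and intersect the evidence manually. `parse_domain_table()` accepts
both tabular dialects; `select_members()` applies the conventional E-value
cutoff of 1e-10 (strict `<=`), merges evidence sources (union by default —
the combined candidate pool a survey builds before manual domain
confirmation; intersection available via `require_sources = "all"`), and
collapses isoforms to one representative per locus, keeping the longest
protein. Longest-isoform is the standard convention when a survey does not
state which transcript it analyzed.

Because neither HMMER nor BLAST is a dependency, the package also ships a
position-specific scoring-matrix scanner (`build_profile()`,
`profile_scan()`). Columns score `log2((f + pc*bg)/((1+pc)*bg))` with a
pseudocount `pc = 1` and uniform background by default; columns with more
than 50% gaps are dropped. E-values come from `calibrate_profile()`: a
Gumbel distribution fitted by the method of moments to the maximum window
score of shuffled proteome sequences, in the spirit of Karlin–Altschul
statistics. This calibration is an explicit approximation — scores are not
length-normalized beyond the per-sequence maximum, and the far tail is an
extrapolation — but planted-domain scores in the synthetic data sit
hundreds of bits above the null, so threshold placement is uncritical
there. On real proteomes the scanner is a screening tool, not a replacement
for profile HMMs.

# Physicochemical profiling

`physicochemical_profile()` reproduces the columns of the standard
family-characterization table from sequence alone:

* **Molecular weight** — sum of isotope-averaged residue masses plus one
  water (18.01524 Da); `X` contributes the mean residue mass.
* **Theoretical pI** — the unique root of the Henderson–Hasselbalch net
  charge over the termini and the D/E/C/Y/H/K/R side chains, found by
  bisection on pH 0–14 to `tol = 1e-3`. The default pKa set is the
  Bjellqvist/ExPASy set (with residue-specific N-terminal pKa values),
  matching the web tool used by most surveys; the EMBOSS set is selectable
  (`pka_set = "emboss"`). The charge is strictly decreasing in pH, so
  bisection cannot miss the root; tests verify agreement with a dense grid
  search (step 1e-4) within 2e-3 pH units.
* **Instability index** — `(10/L) * sum(DIWV)` over consecutive residue
  pairs with the published Guruprasad dipeptide weights; dipeptides
  containing `X` contribute 0. The conventional `II > 40` unstable call is
  exposed even though surveys often print the index without classifying.
  Note the index is order-dependent by construction — the only statistic
  here that is not permutation-invariant.
* **Aliphatic index** — `X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` in mole
  percent over the full length.
* **GRAVY** — mean Kyte–Doolittle hydropathy, `X` excluded from numerator
  and denominator. The hydrophilic/hydrophobic dichotomy uses a strict
  zero threshold (negative = hydrophilic): the only reading consistent
  with a clean negative/positive split of published GRAVY columns.

# Duplicate pairs, Ka/Ks and dating

Candidate duplicates come from Needleman–Wunsch global protein alignment
(BLOSUM62, gap open 10, extend 0.5; a gap of length k costs
`open + k*extend`). Identity is computed over columns where both sequences
are aligned; coverage is those columns over the longer input. A pair is a
duplicate when identity `> 85%` **and** coverage `> 0.75` — both strict,
the conventional thresholds; boundary behavior is pinned by tests.
Identity is protein-level throughout: surveys sometimes mix "amino acid
identity" with nucleotide BLAST, and the protein-level reading is the
self-consistent choice.

`classify_duplication()` calls a pair tandem iff the genes share a
chromosome and are either within 100 kb or separated by at most 5
annotated intervening genes; everything else is segmental. Surveys
typically assert "genetically separated" without a numeric rule, so both
parameters are explicit and configurable.

Ka and Ks come from the Nei–Gojobori (1986) unweighted-pathway method on a
codon alignment back-translated through the protein alignment
(`codon_align()` drops columns gapped in either row, so the input to
`nei_gojobori()` is gap-free and stop-free):

* synonymous site fractions per codon by enumerating all nine single-base
  changes, with stop-producing changes excluded from the per-position
  denominator (the MEGA convention), so `N + S = 3` per codon exactly;
* difference counts averaged over all orderings of the differing
  positions, with orderings that pass through a stop codon excluded
  (should every ordering hit a stop — rare — steps through stops count as
  nonsynonymous);
* Jukes–Cantor correction `d = -(3/4) ln(1 - 4p/3)` applied to pN and pS
  separately; proportions at or beyond 3/4 are flagged saturated.

Dating uses the molecular clock `T = Ks / (2 lambda)` with the standard
grass synonymous rate `lambda = 1.5e-8` substitutions/site/year, and pairs
with `Ks > 2` are discarded to avoid saturation artifacts.

**Estimator bias at high divergence under positive selection.** The
synthetic generator (`evolve_codon_pair()`) evolves two lineages with
uniform single-base proposals, rejecting stop-creating changes and
thinning nonsynonymous changes by `omega` (or synonymous changes by
`1/omega` when `omega > 1`) — deliberately the estimator's own model, so
recovery tests probe the estimator rather than model mismatch. Recovery is
accurate (within a few percent) across most of the tested grid, but at the
most diverged positive-selection condition (pairwise Ks 0.5 with omega 2,
i.e. Ka near 1) the Ks estimate is biased upward by roughly 12% and omega
downward by a similar amount. The cause is intrinsic to unweighted pathway
averaging: selection thinning makes the *realized* substitution histories
of multi-hit codons nonsynonymous-heavy, while the estimator averages all
orderings equally and so re-allocates part of those differences to the
synonymous class. The package reports the estimate as the method defines
it rather than adjusting for this; the acceptance suite records the
condition as outside the 10%/15% recovery bands.

# Promoter cis-elements

Promoters are the 2000 bp immediately 5' of the start codon
(`extract_promoter()`, strand-aware, truncated with a warning at contig
edges). Plant surveys describe this window as upstream of the "TSS (ATG)";
the parenthetical pins it to the translation start, which is what the
package measures from.

Scanning is exact-IUPAC string matching against a catalogue of published
consensus elements (`load_catalog()`): deterministic, auditable, and
sufficient for the presence/absence claims surveys make. The proprietary
matrix models of web tools are deliberately not reproduced. Both strands
are scanned (minus-strand hits are reported at plus-strand coordinates),
overlapping hits are all reported, and `N` in a promoter never matches.
The built-in catalogue spans the four conventional functional categories
(light, hormone, stress, growth/metabolic); the drought flag of
`summarize_categories()` is raised by ABRE or MBS, the two
drought-diagnostic elements. ABRE is filed under stress (its ABA-response
role straddles hormone and stress; the drought flag is what downstream
claims use). Note that some catalogue consensi overlap intrinsically —
ABRE (ACGTG) is a substring of G-box (CACGTG), which is itself palindromic
— so a planted G-box necessarily carries ABRE hits; the generator's
"scrubbing" removes only spurious matches that do not overlap a planted
site.

# Phylogeny and gene structure

The family tree is neighbor joining on Poisson-corrected distances
`d = -ln(1 - p)`, with `p` the proportion of differing residues over
shared non-gap columns. NJ on these distances replaces the ML/JTT trees
that surveys typically build in MEGA: it is fully specifiable, exact on
additive distances (a property the tests exercise on random 4–8 taxon
trees), and adequate for the class structure of a small family — the
class partition, not branch lengths, is the reproduction target. Multiple
sequence alignment itself is out of scope; the module consumes any
protein alignment (the synthetic generator emits equal-length member
proteins that serve as one).

Bootstrap support resamples alignment columns with replacement, rebuilds
the NJ tree, and reports the percentage of replicates containing each
bipartition (1000 replicates by default; a fixed seed gives identical
supports). `assign_classes(k)` cuts the `k-1` longest edges whose removal
separates two leaf-bearing parts — for well-separated clades this is
exactly "cut the longest internal edges", and the leaf-bearing guard also
handles degenerate requests (down to one-leaf classes) deterministically,
with ties broken by the smallest tip label and classes numbered by
decreasing size. Family surveys sometimes report strongly unbalanced
classes including singletons; a singleton class can only fall out of a
pendant-edge cut, which the guard permits when `k` demands it.

`exon_intron_stats()` counts exons and introns per gene model
(`introns = exons - 1` for single-transcript models) and totals CDS
length.

# Expression and phenotype formulas

* `log2_fpkm()` — `log2(x + 1)`. Expression matrices contain zeros, so a
  pseudocount is mandatory for the conventional "log2-transformed FPKM"
  heatmap; +1 maps 0 to 0 and is configurable.
* `relative_expression()` — the Livak 2^-ddCt model with an internal
  control gene and a calibrator sample; surveys name the reference gene
  and cycler program but rarely the formula, and 2^-ddCt is the standard
  reading. `qpcr_fold_changes()` applies it across a long-format Ct table.
* `survival_rate()` — `100 * survived / total`.
* `relative_water_content()` — `100 * (FW - DW) / (TW - DW)`.
* `plot_expression_heatmap()` — cosmetic pheatmap wrapper (row order by
  tree class, no quantitative content beyond `log2_fpkm()`); untested by
  design.

# The synthetic-data generator

`simulate_family_genome()` emits a 7-chromosome genome (FASTA + GFF3 +
in-memory models) carrying 18 family members and 50 decoys by default —
the shape of a small plant protease family survey. Members descend from
one root protein (300 residues) through three class ancestors; the planted
60-residue domain mutates slowly (2% per within-class lineage, 8% per
class branch) while the rest of the protein mutates fast (18% and 35%),
giving classes that are unambiguous on the tree while within-class
identity stays safely below the 85% duplicate threshold. The third class
is a tight cluster (1.5% divergence), planting three duplicate pairs above
the threshold — mirroring the common finding of one recently duplicated
subclade. Class sizes default to 9/6/3: published families can be even
more unbalanced (including singleton classes), but a singleton is not a
clade and carries no internal-edge bipartition whose bootstrap support
could be assessed, so the preset plants every class with at least three
members. Exon
counts are drawn from 1–34 so intron counts span 0–33. Every member
promoter carries a planted ABRE or MBS plus extra elements at known
positions and strands; decoy promoters are plain background.

What the generator does **not** emulate, and what passing tests therefore
do not show: real amino-acid composition and codon-usage bias, indels
(member proteins are equal-length, so alignment is trivial), splice-site
dinucleotides, transposable elements, matrix-model cis-element scoring,
qPCR efficiency differences, or biological replicate structure. Recovery
of planted truth demonstrates the algorithms are implemented correctly
under their own assumptions — not that the pipeline's thresholds are
optimal for any particular real genome.

`evolve_codon_pair()` is described under Ka/Ks above. `simulate_tables()`
generates an FPKM matrix (log-normal around per-gene means over 23
tissues), a long-format Ct table realizing a planted fold-change array
(Ct noise SD 0.15 cycles, 3 replicates — typical bench values), and a
phenotype table whose weights follow a declining relative-water-content
trajectory with per-line wilt rates and survival probabilities. The
default design plants four genes induced in the order tolerant >
intermediate > sensitive and two repressed in the mirror order, the
pattern drought-tolerance comparisons report.

All generators draw every random quantity from one `set.seed(seed)`
stream; the same (parameters, seed) gives byte-identical output.

# Problem sizes and numerical choices

The test and acceptance workloads use: 500-codon pairs with 50 replicates
per condition for estimator recovery; a 68-gene genome for the end-to-end
run; 1000 bootstrap replicates; 1000 shuffles for scanner calibration; 100
random peptides for the pI oracle. These sizes make every stochastic check
stable under reseeding while keeping a full run in minutes on one core.
Ties in hit merging are broken by score then position; NJ negative branch
lengths are clamped to zero; bisection and grid oracles use tolerances
stated above; degenerate inputs (empty hit tables, k = 1 or k = leaves,
promoters at contig edges, saturated distances) are all defined behaviors
with tests.

# Known limitations

* The PSSM scanner is not a profile HMM; no insert/delete states, and its
  E-values are an empirical approximation.
* Nei–Gojobori is a counting method: no transition/transversion weighting,
  no codon-frequency model, and the documented bias at high divergence
  under positive selection. For publication-grade selection inference on
  real data, a codon-model method should corroborate.
* Exact-IUPAC promoter scanning finds consensus occurrences, not
  binding-site probability.
* NJ class assignment assumes classes are clades separated by long edges;
  it will not reproduce manual groupings that cut across the tree.
* Published characterization values bundled with the package
  (`maize_sps8_gravy()`, `maize_sps8_pairs()`) are inputs for the ratio,
  dating and classification operations; the underlying sequences are not
  bundled, so those table values cannot be re-derived from scratch here.
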