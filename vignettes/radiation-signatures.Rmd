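---
title: "Diagnosing rapid radiations in R2 retrotransposon phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing rapid radiations in R2 retrotransposon phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsig)
```

# The problem

R2 elements are non-LTR retrotransposons that insert site-specifically into
the 28S rRNA gene. Their protein phylogeny has three striking features: four
major clades whose membership tracks the N-terminal zinc-finger complement;
deep branches that are very short and poorly supported while terminal
branches are long, suggesting that the major lineages arose in an ancient
burst of cladogenesis; and coexisting conspecific lineages that almost never
form sister pairs, as expected if descendant genomes differentially amplify
or silence lineages inherited from an ancestral collection (the "library"
model). `radsig` turns each of these observations into an explicit,
seedable computation, and ships generators that produce data with known
ground truth under each scenario, so every diagnostic can be validated on
data where the answer is known.

# Likelihood mapping

For a quartet of taxa $\{a,b,c,d\}$ there are three unrooted topologies
$T_1 = (ab|cd)$, $T_2 = (ac|bd)$, $T_3 = (ad|bc)$. `quartet_ml()` restricts
the alignment to the four sequences (dropping sites that are gap or `X` in
all four), maximizes each topology's likelihood over its five branch
lengths, and converts the log-likelihoods to barycentric weights

$$p_i = \frac{e^{\ell_i}}{e^{\ell_1}+e^{\ell_2}+e^{\ell_3}},$$

an equal-prior posterior over topologies. A decisive quartet puts nearly all
weight in one corner of the simplex; conflicting signal spreads weight over
two topologies; absence of signal leaves the weights near the center.

`classify_region()` partitions the simplex with two thresholds: a quartet is
*unresolved* (center) when the largest weight is below 1/2, *resolved*
(corner of the largest weight) when the second weight is below 1/3, and
*conflicting* (edge of the two largest) otherwise. Published
likelihood-mapping figures do not print their boundary equations, so this
explicit rule is our documented approximation; both thresholds are
arguments. The choice matters most for data generated on a star tree: the
maximized gain of each bifurcating topology over the star does not vanish
with alignment length (it is a boundary $\tfrac12\chi^2_1$-type noise term),
so a noticeable fraction of star quartets lands just above a 0.5 corner
boundary that a 2/3 boundary would classify as center. The suite measures
both behaviors; with the default rule the corner fraction on star data sits
near one fifth, several-fold above its value under a 2/3 boundary.

Two sampling schemes mirror the two analyses the pipeline compares:
`sample_quartets_random()` draws uniformly; `sample_quartets_clustered()`
forces one taxon per zinc-finger cluster so that $T_1$ is the
(cluster1,cluster2 | cluster3,cluster4) hypothesis. `compare_runs_chi2()`
compares two runs' resolved/conflicting/unresolved counts; the default is a
goodness-of-fit of the test run against the reference run's proportions
(df = 2), with a 2×3 contingency orientation as an option. The
goodness-of-fit statistic is infinite when a reference category is empty but
the test category is not (the result carries an `infinite` flag); the
contingency orientation drops categories empty in both runs and stays
finite, which is why the acceptance script reports it.

# Substitution models and the likelihood engine

Two amino-acid models are provided. The Poisson model (all exchangeabilities
equal, uniform frequencies) admits the closed form
$P_{ii}(t) = \tfrac1{20} + \tfrac{19}{20}e^{-20t/19}$ and anchors the
analytic tests. The rtREV model embeds the published retrovirus-derived
exchangeabilities and frequencies, the model class used for R2 reverse
transcriptases. Rates across sites are discrete gamma with $k$ equally
probable categories (default 4), each category's rate being the mean of its
quantile bin, so the category rates average exactly 1; the shape $\alpha$
defaults to 1 and can be estimated on a fixed tree by a 1-D
maximum-likelihood search (`estimate_gamma_shape()`), since typical source
analyses report the model name but not the fitted shape.

The rate matrix is $Q = S\,\mathrm{diag}(\pi)$ scaled so that
$-\sum_i \pi_i Q_{ii} = 1$ (branch lengths in expected substitutions per
site). Transition matrices come from a symmetric eigendecomposition of
$\mathrm{diag}(\pi)^{1/2} Q\, \mathrm{diag}(\pi)^{-1/2}$; the contract is
the postconditions (stochastic rows, $P(0)=I$, detailed balance), not the
factorization. `tree_loglik()` is standard Felsenstein pruning with
per-node rescaling against underflow; gaps and `X` are fully ambiguous
(conditional likelihood 1 in every state). Branch-length optimization in
`quartet_ml()` is coordinate-wise golden-section search on $[10^{-6}, 10]$
to tolerance $10^{-6}$, terminals first and the internal branch last within
each sweep, at most 50 sweeps — a deterministic schedule chosen for
reproducibility; while one branch varies, the other four branches'
messages are cached, with the root moved across the internal branch where
needed (legitimate for reversible models).

# Radiation statistics

`partition_branches()` splits edges into terminal (child is a leaf) and
internodal (child is internal). A degree-2 root whose children are both
internal is first collapsed, because such a root merely splits one true
internodal edge in two when an unrooted tree is serialized; a root with a
leaf child is kept as a genuine attachment point. `welch_test()` then
contrasts the two length samples (unequal-variance *t*, Satterthwaite
fractional df, two-sided p — the source analyses print fractional df, which
identifies Welch's test).

`relative_node_heights()` implements height = distance to the farthest
descendant leaf, divided by the sum of all branch lengths. The ratio is the
published definition; the choice of *max* (rather than mean) distance is
ours, made so that "deeper node" monotonically means "larger height", and a
`mode = "mean"` alternative is provided. Rows cover internal non-root nodes
that carry a support; supports are percentages, with posterior
probabilities in $[0,1]$ rescalable at parse time
(`read_newick(supports_as_fraction = TRUE)`). `radiation_report()` bundles
both diagnostics with the verdict rule: radiation-consistent iff terminal
lengths significantly exceed internodal lengths *and* the height/support
correlation is significantly negative, both at a configurable
$\alpha = 0.05$.

# Tree inference

`neighbor_joining()` is a deterministic NJ: ties in the Q criterion break by
the lexicographically smallest pair of cluster representative labels, and a
negative branch length arising at a join is clamped to zero with the deficit
moved to its sibling so their sum (and the distances among the joined
clusters) is preserved. NJ stands in for an external minimum-evolution
search — ME uses NJ as its starting tree and differences at these scales are
rare — and trees from external ME/ML/Bayesian programs are equally valid
inputs. `p_distance()` uses pairwise deletion (positions with a gap or `X`
in either sequence are excluded per pair), the less destructive of the two
common options. `bootstrap_supports()` resamples columns with replacement
and scores each internal bipartition of the full-data tree by the
percentage of replicate trees containing it.

# Structural annotation

`scan_zinc_fingers()` recognizes `C-x(a..b)-C-x(c..d)-H-x(e..f)-[H|C]` with
default spacings (1–5, 8–17, 2–6) taken from canonical C2H2/CCHC fingers —
the source figures mark only the coordinating residues, so spacings are
configuration, not a fidelity claim. Scanning is greedy leftmost within a
450-residue N-terminal window: at each cysteine the smallest-offset
completion is accepted and scanning resumes after the motif, which makes
the output deterministic and ordered N→C. `call_clade()` maps the ordered
motif types to clades (A: CCHH,CCHC,CCHH = positions I+II+III; B:
CCHC,CCHH = II+III; C: CCHH,CCHH = I+III; D: CCHH = III); every other
pattern is `unknown`, a value rather than an error, since real data contain
truncated and divergent N-termini.

`find_target_sites()` is a Hamming scan for the 28S target
(5′-TTAAGG↓TAGCCA-3′); the cleavage coordinate is the junction after the
sixth base, and 20-nt flanks are reported on both sides (shorter flanks at
sequence ends are flagged). Both strands are scanned by default — genome
mining context — with hits reporting strand. `detect_insertion_junctions()`
pairs an upstream half-site (`AAGG` exact, its `TT` context allowed to
mismatch, matching the observed point mutation immediately upstream of the
site in one host) with the nearest downstream `TAGC` that is adjacent
(intact site) or at least `min_element` = 100 nt away; the floor prevents a
site from pairing with itself, and a junction containing a second upstream
half-site is flagged ambiguous rather than erroring.
`cluster_families()` applies the >90%-identity family rule as
single-linkage components, identity being matches over global-alignment
columns — a bare pairwise threshold is exactly a single-linkage graph rule.

# The library test

`sister_pair_statistic()` counts conspecific lineage pairs whose MRCA
contains no other species' leaf. `library_permutation_test()` builds the
null by shuffling species labels across lineages on the fixed tree
(within clades when `stratify_by_clade`, preserving the species-by-clade
margins) and reports the add-one one-sided p-value
$p = (1 + \#\{S_\mathrm{null} \le S_\mathrm{obs}\})/(n_\mathrm{perm}+1)$
for the "less clustering than chance" direction; an exhaustive enumeration
over all distinct assignments is available for small problems. The
statistic, null and sidedness are this package's formalization of a
qualitative published observation, and its power is intrinsically limited
at small designs: with two lineages per species, $S$ counts monochromatic
cherries, a 12-leaf tree has at most six cherries, and a shuffled cherry is
monochromatic with probability 1/11, so at six species × two classes the
null mass at $S=0$ stays above one half and the one-sided p cannot reach
0.05 no matter the seed. The test is therefore informative for larger
designs (more lineages per species) while at the 6×2 design the observed
$S=0$ is reported with an honestly large p; the suite asserts both this
limitation's arithmetic consequences and the duplication-scenario contrast
($S$ maximal, $p = 1$).

# Synthetic data

The generators define the study conditions rather than adapting to them.
`simulate_tree()` draws a random coalescent-join topology, unroots it, and
assigns independent exponential branch lengths: terminal mean 0.225 and
internodal mean 0.042 substitutions/site by default — the minimum-evolution
regime the partition test contrasts — with 87 taxa, the compilation size the
diagnostics were designed around; exponential lengths were chosen for their
analytic mean checks, the source implying only "short internodes, long
terminals". `evolve_alignment()` (default 542 sites, the refined alignment
length) draws each site's gamma category once and keeps it along the tree
(a rates-across-sites model, not per-branch redrawing) and simulates no
indels. `make_r2_protein()` plants motifs with spacers free of C and H so
the planted motifs are provably the only grammar matches;
`make_rdna_locus()` grows its random sequence free of the `AAGG`/`TAGC`
4-mers outside the planted sites for the same reason. `simulate_library()`
diverges the lineage classes on a deep star before any species split, each
class then tracking one shared species topology ("library" mode), or
attaches each species' lineages as a cherry ("duplication" mode). What the
generators do *not* emulate — alignment error, indels, homoplasy filtering,
rate variation across lineages, concerted evolution of rDNA units — bounds
what passing tests show about real data: they validate the statistics'
behavior under their own assumptions, not robustness to real-data
violations of them.

# Numerical choices and problem sizes

Branch lengths are non-negative and finite by validation; missing lengths
are an opt-in zero. Coordinates in all annotation output are 0-based,
half-open. The permutation p is add-one and never exactly zero. The test
suite and the acceptance script run the simulation studies at: 200 + 200
quartets of 500 sites for the resolved/star classification study (Poisson,
homogeneous rates, terminals 0.25, internal 0.5 or ~0); 100 replicate
87-taxon trees for the Welch power and size study; 50 replicates of
87 taxa × 300 sites × 100 bootstrap replicates for the height/support sign
study; 1000 proteins and 100 loci for the annotation round-trips; 100
additive matrices of up to 12 taxa for NJ exactness; and 100 seeds of the
6 × 2 library design. These sizes are the package's documented study
conditions; rerunning `scripts/acceptance.R` with any seed regenerates
every number from scratch.

# Limitations

The likelihood engine is for small trees (quartets and test fixtures), not
large-tree ML search; no topology search, dating, or host-tree-aware
co-phylogenetic statistic is included; the simplex region boundaries are an
approximation with configurable thresholds; and the NJ/bootstrap stage is a
stand-in whose results should be replaced by externally inferred trees when
those are available.
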