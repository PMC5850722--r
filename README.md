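# duproot

Outgroup-free rooting of species trees from gene duplication events in
unrooted gene trees.

Phylogenetic inference under time-reversible models produces *unrooted*
trees, and the usual remedy — adding an outgroup — is itself a major source
of error. Gene duplications break the time symmetry: a duplication node in a
gene tree has two subtrees with overlapping species sets (the copies) and a
third edge pointing toward the root. Each well-supported duplication whose
copies are confined to one block of a species-tree bipartition is evidence
that this block is a monophyletic clade, excluding the root from its
interior. `duproot` detects such events across a whole set of unrooted gene
trees (one per orthogroup), reports the maximum-parsimony root (the branch
violating the fewest events), and computes a posterior probability for every
branch of the unrooted species tree being the root.

The probability model treats the `(m, n)` duplication counts on a branch as
two Poisson processes — true positives at rate `λ = N/(1+α)` and false
positives at rate `αλ`, `N = m + n` — giving

* `P(d | ←) = Po(m; λ) · Po(n; αλ)` (and the mirror image for `→`), and
* `P(d | root) = Σ_s Σ_t B(m−s+t+1, n−t+s+1) e^{−λ(1+α)}
  λ^{m−s}/(m−s)! · (αλ)^t/t! · λ^{n−t}/(n−t)! · (αλ)^s/s!`,

the closed form of an integral over the position of the root along the
branch. `α` is estimated as one tenth of the ratio of conflicting to
nonconflicting events at the maximum-parsimony root. Per-branch orientation
posteriors (with priors `P(root) = 1/b`, `P(←) = P(→) = (b−1)/2b`,
`b = 2t−3`) combine into a tree-level distribution over all branches;
terminal branches are modelled through their inward duplications only. A
seeded duplication–loss simulator with ground-truth event logs is included
for validation. See the vignette
(`vignettes/rooting-from-duplications.Rmd`) for the full model description.

## Worked example

Three orthogroups on a four-species tree: a family that duplicated at the
base of the elephant+dog clade, one that duplicated in the ancestor of
elephant+dog+bird, and one with that same duplication plus a fish gene:

```r
library(duproot)
st  <- species_tree("((elephant,dog),(bird,fish));")
gt1 <- gene_tree("((elephant_1,dog_1),(elephant_2,dog_2));", st, id = "og1")
gt2 <- gene_tree("(((elephant_3,dog_3),bird_1),((elephant_4,dog_4),bird_2));",
                 st, id = "og2")
gt3 <- gene_tree("((((elephant_5,dog_5),bird_3),((elephant_6,dog_6),bird_4)),fish_1);",
                 st, id = "og3")
res <- root_inference(st, list(gt1, gt2, gt3))
res
#> Species tree root inference
#>   3 gene trees; 3 duplication events (3 informative, 0 single-species)
#>   conflicting events at MP root: 0; alpha = 1e-06
#>   maximum-parsimony root branch: 2
#>   most probable root: branch 2 (bird;dog;elephant | fish), p = 1.0000
res$distribution[, c("branch_id", "block_a", "block_b", "m", "n", "p_root")]
#>   branch_id            block_a           block_b m n      p_root
#> 1         1               bird dog;elephant;fish 0 0 2.50000e-13
#> 2         2  bird;dog;elephant              fish 2 0 1.00000e+00
#> 3         3      bird;dog;fish          elephant 0 0 2.50000e-19
#> 4         4 bird;elephant;fish               dog 0 0 2.50000e-19
#> 5         5          bird;fish      dog;elephant 0 1 9.23632e-13
```

The duplication shared by elephant and dog and the two shared by elephant,
dog and bird exclude the root from those clades; the only branch violating
no event is the fish terminal branch (branch 2: `bird;dog;elephant | fish`),
which receives essentially all of the probability. The `(m, n)` columns
count events assigned to `block_a` and `block_b` of each branch: the two
three-species events sit on branch 2 (`m = 2`), the elephant+dog event on
branch 5 (`n = 1`).

Each row of `res$distribution` is one branch of the unrooted species tree,
identified by its bipartition (`block_a | block_b`, semicolon-joined
species); `p_root` sums to 1 across rows. `res$events` lists the individual
events (gene tree, node, branch, duplicate block, species observed), and
`res$parsimony$scores` the violation count per branch.

## Command line

```sh
SCRIPT=$(Rscript -e 'cat(system.file("scripts", "duproot.R", package = "duproot"))')
Rscript $SCRIPT simulate --n-species 12 --n-trees 500 --seed 1 -o simdata
Rscript $SCRIPT infer -s simdata/species_tree.nwk -d simdata/gene_trees -o out
```

`infer` writes `events.tsv`, `branch_scores.tsv` (branch_id, blocks,
n_violations, is_mp_root), `root_distribution.tsv` (per-branch counts and
`p_root`), `species_tree_annotated.nwk` (rooted on the most probable branch,
with each branch's root probability stored as its branch length), and
`summary.json` (event tallies, `alpha`, terminal rates, the parsimony
plateau, the most probable root, and per-reason counts of rejected
candidates — no species overlap, block tie, missing grandchild clade,
unresolved or mismatching copy topology — which explain why recall is
deliberately conservative). Gene labels map to species by a
configurable rule: prefix before a delimiter (default `_`), a regex capture
group (`--regex`), or an explicit two-column TSV (`--map`).

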