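# glyloopr

Sequence analysis of loricrin-like cornified-envelope (CE) proteins.

Loricrins are glycine/serine-rich structural proteins of the cornified
envelope, built from conserved N- and C-terminal domains flanking a highly
variable central repeat domain. The central domain is organised as
quasi-repeats of the form *x*(*y*)<sub>*n*</sub> — a glycine/serine-rich
loop body (*y*)<sub>*n*</sub> anchored ("indexed") on an aromatic or
aliphatic residue *x* — predicted to fold into flexible **Gly-loops**.
Draft-genome loricrin sequences are frequently interrupted by assembly gaps
(NNN runs), which translate to unknown residues (X) and complicate every
downstream analysis.

`glyloopr` is aimed at researchers studying CE protein evolution in birds,
reptiles and mammals. It provides:

* **Gly-loop detection** under the x(y)<sub>n</sub> grammar
  (`detect_gly_loops()`, `loop_profile()`, `xy_annotation()`), with the
  anchor set {F,Y,W,A,V,L,I,M}, loop alphabet {G,S,C,K} (+X), and Q/P/H
  acting as loop-terminating spacers.
* **Domain partitioning** of a protein into N-terminal / central repeat /
  C-terminal spans (`partition_domains()`), explicit or heuristic.
* **Gap-aware translation and quality classification**: `translate_cds()`
  maps any N-containing codon to X and flags missing start/stop, premature
  stops and length-mod-3 frameshifts; `classify_completeness()` applies the
  15%/70% central-domain unknown thresholds and `assign_quality_code()` the
  nine-level quality scheme.
* **Composition statistics**: per-residue percentage vectors over known
  residues (`composition_vector()`), one-way ANOVA and Welch's t-test
  (`residue_anova()`, `welch_t_test()`), and SVD-based PCA (`pca_svd()`).
* **Gene-conversion fragment scan**: a maximal-scoring-segment statistic
  over polymorphic alignment columns with a column-permutation null
  (`polymorphic_columns()`, `pair_fragment_scan()`, `permutation_test()`),
  a documented stand-in for the classical global-fragment statistic.
* **A synthetic-data generator** (`generate_loricrin_protein()`,
  `degrade_with_unknowns()`, `generate_duplicate_pair()`) that emulates
  loricrin architecture with known ground truth, so the whole pipeline is
  testable offline.

## Worked example

The canonical human loricrin fragment (residues 52–76) contains two
consecutive Gly-loops:

```r
library(glyloopr)
loops <- detect_gly_loops("YSGGGGYSGGGGCGGGSSGGGGGGGI")
loops[, c("start", "end", "size", "x_residue", "right_boundary_kind")]
#>   start end size x_residue right_boundary_kind
#> 1     1   6    5         Y               index
#> 2     7  25   18         Y               index
xy_annotation(loops[1, ], "YSGGGGYSGGGGCGGGSSGGGGGGGI")
#> [1] "Y(y)_5"
loop_profile(loops)
#>   total_loops largest smallest mean_size
#> 1           2      18        5      11.5
```

The two loops are Y(y)<sub>5</sub> and Y(y)<sub>18</sub>: a 5-residue and an
18-residue glycine/serine body, each anchored on a tyrosine, each terminated
by the next anchor residue. `loop_profile()` is the per-gene summary used to
tabulate loop counts and size ranges across species.

A synthetic round trip with ground truth:

```r
g <- generate_loricrin_protein(generator_params(seed = 6))  # 43 loops, sizes 3-26
central <- substring(g$record$residues,
                     g$truth$central_span[1] + 1, g$truth$central_span[2])
loop_profile(detect_gly_loops(central))
#>   total_loops largest smallest mean_size
#> 1          43      26        3     13.67
```

The detector recovers all 43 planted loops exactly (the profile equals the
generator's truth).

## Command line

A thin CLI ships in `inst/cli/glyloop`:

```sh
glyloop scan     --in proteins.fasta --out loops.tsv --profiles profiles.tsv
glyloop classify --in proteins.fasta --reference-lengths ref.tsv --out quality.tsv
glyloop compose  --in proteins.fasta --out composition.tsv
glyloop geneconv --aln aligned.fasta --perms 10000 --seed 17 --out fragments.tsv
glyloop simulate --preset lor3 --n 20 --seed 7 --out-proteins sim.fasta --out-truth truth.json
```

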