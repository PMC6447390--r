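---
title: "Gly-loop detection and quality profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gly-loop detection and quality profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyloopr)
```

# The biological model

Loricrins are cornified-envelope structural proteins with a tripartite
architecture: conserved lysine/glutamine-rich N- and C-terminal domains
flank a highly variable central repeat domain. The central domain consists
of quasi-repeats of the form $x(y)_n$: a stretch of $n$ polar residues
(mostly glycine and serine) anchored on an aromatic or aliphatic *index
residue* $x$. When at least two such repeats occur in tandem, the polar
stretches are predicted to fold back as flexible *Gly-loops* while the index
residues associate hydrophobically, giving the cornified envelope its
combination of elasticity and mechanical resistance.

In draft genomes the highly repetitive central domain assembles poorly, so
loricrin coding sequences are frequently interrupted by runs of unknown
nucleotides (NNN). Any codon containing an N translates to the unknown
residue X, and the fraction of X in the central domain is the basis of the
quality classification.

# The x(y)n grammar and its parameters

`detect_gly_loops()` scans a segment left to right. A maximal run of index
residues opens a candidate loop immediately to its right; the loop extends
through consecutive loop-alphabet residues and closes at the first residue
outside that alphabet. The closing residue is recorded as `index` (it
anchors the next loop), `terminator` (a spacer residue such as Q, P or H),
or `sequence_end`.

The tunable parameters, all in `loop_config()`:

* **`index_residues`** (default `{F,Y,W} ∪ {A,V,L,I,M}`) — the anchors $x$.
  Aliphatic anchors commonly occur as dimers/trimers (II, MM, III); a
  maximal run collapses to a single boundary, and the loop size counts only
  the residues strictly between boundaries.
* **`loop_alphabet`** (default `{G,S,C,K}`) — residues allowed inside a
  loop. Besides the G/S body, conserved cysteines and lysines occur inside
  avian loops (at loop apices, where they are thought to participate in
  disulfide bonding and transglutamination). This choice, with Q/P/H as
  terminators, simultaneously reproduces the published worked examples: the
  human fragment loops of 5 and 18 residues, the 26-residue chicken
  LOR3-type loop (which spans C, C and K), and the 14-residue largest
  LOR1-type loop, which must terminate at the H of an `HQSQGP` spacer. A
  literal "between aromatic/aliphatic residues" reading would instead give
  20 for that LOR1 fragment and contradict the published per-gene table, so
  H is excluded from the loop alphabet by default.
* **X handling** — X is allowed to *extend* a loop body (an unknown residue
  may stand for any residue), but `exclude_loops_with_X = TRUE` (default)
  suppresses loops containing X. This is what "repeat units present without
  NNNs" means operationally in the completeness rules. Setting the flag to
  `FALSE` retains degraded loops for exploratory work.
* **`min_loop_len`** (default 2) — the shortest loops observed in avian
  loricrins contain two residues.
* **`min_gs_fraction`** (default 0.6) — operationalises "gly-ser-rich";
  no published value exists, so the default is the weakest majority-style
  threshold that still rejects C/K-dominated runs.

Coordinates are 0-based half-open throughout the API; 1-based labels appear
only in rendered annotations such as `"Y(y)_5"`.

```{r}
detect_gly_loops("YSGGGGYSGGGGCGGGSSGGGGGGGI")
```

# Domain partitioning

The published analyses assume domain boundaries but never define them, so
`partition_domains()` supports two modes. In *explicit* mode the caller
supplies curated spans (recommended when reproducing published per-gene
counts). In *auto* mode every `window`-residue window (default 10) whose
G+S+X fraction reaches `gs_threshold` (default 0.5) marks the residues it
covers, and the longest contiguous covered run becomes the central domain.
Covered runs separated by a gap shorter than `bridge` (default `2 * window`)
are merged first: genuine inter-domain boundaries are conserved termini tens
of residues long, so a sub-20-residue dip in G/S content (a spacer/index
cluster around a small C/K-heavy loop) should not split the repeat domain.
On synthetic records the auto partition overlaps the true central span by
more than 90% (typically >98%) of its length.

# Quality classification

`classify_completeness()` implements the three published completeness
conditions: a sequence is **complete** iff (1) both termini are X-free,
(2) at least three X-free loops are present, and (3) the central unknown
fraction is at most 15%. With (1)–(2) satisfied and the fraction in
(15%, 70%) the sequence is **partial**; everything else is **fragmentary**.
The boundary semantics are closed on the left rule (15% is still complete;
70% is no longer partial), and are pinned by tests.

`assign_quality_code()` collapses defects and gap content into codes 1–9.
The precedence — 9 (gene evidence only, <10% of the reference orthologue
length), then frameshift (7), premature stop (8), missing start (6), missing
stop (5), then the NNN bands 1/2/3/4 — is this package's convention: the
published table prints one code per gene but never states a tie-break, so we
order structural defects by severity before gap-content bands. The interval
reading of the bands is (0.15, 0.75] for code 3 and everything above 0.75
for code 4. Note the deliberate coexistence of two upper thresholds: 70%
(completeness rule) and 75% (code band) come from different published rules
and are both kept, each applied where its source applies. Likewise the
composition filter (10%) and the completeness threshold (15%) are distinct
configuration values.

Frameshifts are detected only via the length-mod-3 rule on the provided CDS
span; alignment-based frameshift detection against a reference orthologue is
out of scope. A trailing incomplete codon is ignored during translation (the
handling of partial codons at scaffold breaks is not published; this is our
convention).

# Composition statistics

`composition_vector()` computes percentages over the 20 standard residues
using *known residues only*: X is excluded from the denominator so that
percentages remain comparable across degradation levels (the source analyses
are silent on this point). Records above `max_unknown_fraction` (default
10%) are rejected.

`residue_anova()` is classical one-way fixed-effects ANOVA on one residue's
percentages; `welch_t_test()` is the unequal-variance t-test with
Welch–Satterthwaite degrees of freedom. No multiple-testing correction is
applied by default, matching the raw per-residue reporting convention;
Bonferroni can be applied downstream. `pca_svd()` centres (and optionally
unit-scales) the samples × residues matrix and decomposes it by SVD; the
default is centre-only, matching the SVD default of the PCA implementation
cited for this kind of composition analysis. Whether unit-variance scaling
was used in the published PCA is unstated, so both settings are exposed.

# The gene-conversion fragment scan

Gene conversion between tandem paralogs homogenizes a tract of sequence. The
published analysis used an external tool whose internals are not described
in the text, so `pair_fragment_scan()` implements the transparent core idea:
over the *polymorphic columns* of the alignment (columns with at least two
distinct bases; columns containing N or gaps are excluded entirely), a pair
scores +1 where it agrees and −*g* where it differs, and the candidate
fragment is the maximal-sum contiguous segment (linear-time scan; ties go to
the shortest, then leftmost segment, so fragments carry no zero-sum flanks).

Two properties deserve emphasis:

* **Polymorphism is defined by the whole group.** A pair on its own is
  degenerate — by definition it disagrees at every polymorphic column — so
  meaningful scans require additional rows (outgroup sequences), exactly as
  the original multi-species analyses included several species.
* **The penalty must scale with background agreement.** With a fixed
  penalty *g*, a pair agreeing at more than $g/(g+1)$ of polymorphic sites
  has positive expected per-site score and the maximal segment degenerates
  towards the whole sequence. `permutation_test()` therefore defaults to
  `mismatch_penalty = "auto"`: $g = \max(1, 2a/(1-a))$ at background
  agreement rate $a$, keeping the drift negative. Because $g$ is a function
  of the score multiset, it is identical across permutations and preserves
  exchangeability. The numeric default of `pair_fragment_scan()` remains 2.

The permutation null jointly permutes the order of polymorphic columns (the
same permutation for all rows), rescans every pair, and records the
per-permutation maximum over the scanned pairs, giving family-wise control
across pairs; $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$,
deterministic given the seed. Calibration (p uniform under a no-tract null)
and power (≥95% detection of a 90-column tract between 20%-diverged
duplicates, at p < 0.01 with 500 permutations) are verified in the
acceptance suite.

# The synthetic stated world

The generator (`generate_loricrin_protein()`) emulates what the analyses
need and nothing more: tripartite architecture, per-style index runs and
spacers (`HQSQGP`-style for LOR1-like, M-indexed for LOR2-like, Y/II/III
for LOR3-like), loop bodies drawn from weighted {G,S,C,K} with the G+S
fraction forced to ≥0.6 so every planted loop is detectable, and defaults
stating a chicken-LOR3-like gene: 43 loops with sizes uniform on 3–26, the
published range for that gene. Termini default to short K/Q/P-rich strings
free of index residues.

`degrade_with_unknowns()` plants X in contiguous runs (run lengths 3–10)
until the target fraction is hit to within one residue, emulating assembly
gaps. Spacer-only placement additionally protects the residue immediately
after each loop (an X there would be absorbed into the loop body and
disqualify it), which is what makes the "degradation confined to spacers
leaves the loop profile unchanged" invariant provable.

`generate_duplicate_pair()` back-translates a generated protein with uniform
synonymous codon choice (no codon-usage table — sufficient for
divergence/tract statistics), duplicates it, applies i.i.d. per-site
substitutions uniform over the three alternative bases (Jukes–Cantor-like;
no published model claim exists), overwrites the optional conversion tract,
and can append diverged outgroup rows (default divergence 0.3; the
calibration tests use 0.2, equal to the pair divergence, stating species at
comparable distance). All randomness flows through one integer seed per
call via a private RNG stream; no global state is disturbed.

**What a green test does not establish.** The generator's world is far
cleaner than real draft genomes: loops are exactly recoverable by
construction, spacers never resemble loop bodies, there are no alignment
errors, no indels, no codon-usage bias, no recombination other than the
planted tract, and termini are fixed templates rather than evolving
sequences. Green round-trip tests establish internal consistency of the
pipeline, not field performance on real assemblies. Published full-gene
loop counts (e.g. 43 loops for chicken LOR3) depend on curated domain
boundaries and full central-domain sequences that exist only as figures, so
they are emulated (as generator defaults) rather than asserted; the
fragment-level worked examples are asserted exactly.

# Numerical choices and degenerate inputs

* Loop-size averages are reported to 2 decimal places; TSV output renders
  doubles with that fixed convention.
* Empty segments, zero-loop records and empty central spans return empty
  results (not errors); an all-X record is rejected by the composition
  filter with an informative message.
* ANOVA with no variance anywhere returns F = 0, p = 1; Welch's test on two
  zero-variance equal-mean samples returns t = 0, p = 1.
* PCA on a constant matrix errors (variance proportions undefined); with
  `scale = TRUE` constant columns are dropped before unit scaling.
* The permutation p-value uses the add-one formula and compares observed
  and null scores computed along the same arithmetic route, so exact ties
  compare exactly.
* Degradation targets are met to within one residue of the requested
  fraction (exact integer count), and impossible targets error with the
  achievable fraction.

# Known limitations

* The auto domain partition is a windowed heuristic; curated spans should
  be supplied when reproducing published per-gene numbers.
* The fragment scan is a methodological stand-in for the classical
  global-fragment statistic, not a reimplementation of its scoring
  constants or its inner/outer fragment distinction; acceptance for this
  module is property-based (calibration and power), not a published
  p-value.
* Published PCA variance proportions and per-gene composition means derive
  from supplementary percentage tables not deposited with the text; the
  package verifies the machinery on synthetic data with known structure
  instead of asserting those numbers.
* Gene labels beyond LOR1/LOR2/LOR2B/LOR3/LOR3B map to OTHER; the header
  dialect `id|SPECIES|GENE` is this package's convention.
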