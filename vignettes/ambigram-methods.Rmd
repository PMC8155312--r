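---
title: "Methods: double synonyms and polymorphism tests for ambigrammatic genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double synonyms and polymorphism tests for ambigrammatic genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambigram)
```

## The problem

Some RNA viruses — most prominently narnaviruses — carry *ambigrammatic*
genes: the reading frame on the complementary strand whose codons are
aligned with the forward frame is also free of stop codons, so the genome
can in principle be translated in both directions.  Two explanations
compete: the reverse open reading frame (rORF) codes for a functional
protein, or only the *absence of stops* matters (for example, to keep
ribosomes loaded on the complementary strand).  These hypotheses make
different predictions about the polymorphism observed in a sample of
sequences, and this package implements the machinery to test them.

Two facts about the standard genetic code drive everything here.

**Stops on the complement are always removable.**  The aligned reverse
complements of the stop codons UAA, UAG and UGA are UUA, CUA and UCA —
codons for Leu, Leu and Ser.  Each of these can be replaced by a synonym
whose reverse complement is not a stop, by a single substitution
(`stop_fixes("UUA")` gives UUG, and so on).  An ambigrammatic version of
any protein sequence can therefore evolve through synonymous changes
alone; this is what `random_ambigram()` exploits to build stop-free
ancestors, and what the scanner assumes when it treats ambigrammaticity as
a property a gene can maintain.

**Double synonyms exist.**  A *double synonym* is a pair of codons one
substitution apart that code the same amino acid in the forward frame
*and* whose aligned reverse complements code the same amino acid.  For
example AGG → CGG is Arg → Arg forward, while the reverse complements
CCU → CCG are Pro → Pro.  Exhaustive enumeration over the code
(`synonym_table()`) shows exactly twelve codons admit such a mutation:
UUG, CUG, CCU, CCG, CAA, CAG, CGA, CGG, AGA, AGG, UCU and UCG, in six
amino-acid pairings (Leu/Gln, Gln/Leu, Pro/Arg, Arg/Pro, Ser/Arg,
Arg/Ser), two codons each.

The package counts, for every codon that is a sense codon in both aligned
frames, its single-nucleotide synonyms split into transitions `S(n)` and
transversions `S(v)`, and the doubly synonymous subset `D(n)`, `D(v)`.
Synonyms whose reverse complement is a stop are excluded throughout,
because they cannot occur in an ambigrammatic gene.  One consequence worth
flagging: UCG's only transition synonym is UCA, whose reverse complement
is the stop UGA, so after exclusion UCG has `S(n) = 0` — enumeration, not
convention, fixes this cell, and the package's table is generated by the
enumeration rather than transcribed.

## Polymorphism statistics

Input is a set of M codon-aligned sequences of length 3N (read from
multi-FASTA by `read_alignment()`; `select_frame()` picks the frame
offset minimising internal stops, ties to the smallest offset).  The
consensus takes the modal base per column, ties broken by the fixed order
A < C < G < U for determinism.

`ambigram_polymorphism()` is the central fitting function.  At the
nucleotide level it counts codon cells differing from the consensus codon
by exactly one base, split into transitions $N_n$ and transversions
$N_v$ and by codon position $(n_1, n_2, n_3)$, and reports

$$r = \frac{n_1 + n_2 + n_3}{3NM}, \qquad
  \hat\alpha = \frac{r_n}{r_v} = \frac{2 N_n}{N_v},$$

the factor 2 reflecting that each site has one transition but two
transversion targets.  Cells differing at 2–3 bases are excluded from the
nucleotide-level counts (they enter the codon-level `N_mult` instead), so
$n_1 + n_2 + n_3 = N_n + N_v$ by construction.

At the codon level, the *variant set* of locus k is the set of distinct
codons observed there that differ from the consensus; `n(k)` is its size
and `f(k)` the fraction of sequences off-consensus.  Single-nucleotide
variants are classified synonymous/non-synonymous in a chosen read
direction (a stop is never synonymous), giving $R = N_{ns}/N_{sy}$, which
is compared with the non-coding null

$$R_\mathrm{exp} =
  \frac{\sum_k \alpha\, n_k^{(n)} + n_k^{(v)}}
       {\sum_k \alpha\, s_k^{(n)} + s_k^{(v)}},$$

where $s_k$/$n_k$ are the synonymous/non-synonymous counts among the 9
single-nucleotide neighbours of consensus codon k (they always total 9;
mutations to a stop count as non-synonymous).  An ORF-wide dN/dS uses the
same opportunity sums with a fixed transition/transversion weight
$\kappa$ (default 2) and counts every distinct variant once — a
conservative "each mutation happened once" convention chosen because the
statistics deliberately ignore phylogenetic structure; multi-base
variants are included in the observed counts but leave the opportunity
sums unchanged (single-base opportunities are what the Kimura model
rates).

**Counting conventions.**  Whether repeated observations of the same
variant codon should count once or once per carrier sequence is a real
choice; distinct-variant counting is the default everywhere
(`counting = "occurrence"` switches to carrier weighting).  Neither is
asserted as canonical.

## The two discriminators

`hotspot_test()` asks whether doubly synonymous loci (consensus codon in
the twelve-codon set) are mutational hotspots:
$R_n = \langle n(k)\rangle_\mathrm{ds} / \langle n(k)\rangle_\mathrm{other}$
and the analogous $R_f$.  If the rORF is coding, the only assuredly
neutral mutations are the doubly synonymous ones, so $R_n, R_f \gg 1$;
ratios near 1 fit a non-coding rORF.  No formal significance procedure is
attached to the ratios by the underlying theory; the optional
label-permutation interval (`n_perm`) is this package's own plumbing for
judging "near 1" and is clearly not part of the original procedure.

`dsyn_test()` looks *within* the variable doubly synonymous loci
$\{k^*\}$ (those with `n(k) >= min_variants`; default 1 — note that
"variable" could also be read as `n(k) > 1`, so the threshold is
exposed): $n_s(k)$ counts distinct single-nucleotide forward-synonymous
variants whose reverse complement is not a stop, $n_d(k)$ the doubly
synonymous subset, with $n(k) \ge n_s(k) \ge n_d(k)$ per locus.  With
$N_s = \sum n_s$, $N_d = \sum n_d$, a coding rORF drives
$R = N_s/N_d \to 1$; a non-coding one leaves $R$ near the Kimura null

$$R_0 = \frac{\sum_{k^*} \alpha S_k^{(n)} + S_k^{(v)}}
             {\sum_{k^*} \alpha D_k^{(n)} + D_k^{(v)}},$$

computed from the synonym profile of the consensus codons at $\{k^*\}$
(`null_ratio_r0()`).  $\alpha$ defaults to the alignment's own
$\hat\alpha$ and can be overridden.  When $N_d = 0$ the ratio is reported
as undefined rather than inflated — at realistic divergence the count of
doubly synonymous mutations is small, and that limitation is honest.

## The simulator: ground truth by construction

`evolve_alignment()` generates M descendants of a random ambigrammatic
ancestor on a *star phylogeny* — descendants are independent, which
matches the statistics' own indifference to phylogenetic correlation and
is a documented simplification, not a claim about real genealogies.  Each
descendant receives Poisson($\mu \cdot 3N$) proposed substitutions; a
proposal picks a site uniformly and is a transition with probability
$\kappa/(\kappa+2)$, otherwise one of the two transversions.  Selection
acts by *rejection*:

* `neutral` accepts everything;
* `forward_purifying` accepts only proposals preserving the forward
  amino acid (relative to the current codon);
* `dual_purifying` requires both frames' amino acids preserved — by
  construction every accepted change is a double synonym, so
  `dsyn_test()` must return exactly R = 1 on such data.

`keep_ambigrammatic` (default on) additionally rejects proposals creating
a stop in either frame, matching the empirical observation that sampled
ambigrammatic genomes carry no internal stops.  Because selection is
rejection-based, $\mu$ is a *proposed* rate; at the low divergences
simulated here the distinction is small.

Defaults are M = 50, N = 500, $\mu = 0.01$, $\kappa = 2$: fifty
polymorphs of a 1.5-kb gene at roughly 1% divergence, the regime in which
these statistics are actually applied to field samples of ambigrammatic
viruses.

One subtlety the simulator exposes: under `keep_ambigrammatic`, codons
adjacent to stop codons lose about one of their nine mutational targets —
and the twelve double-synonym codons are disproportionately stop-adjacent
(they sit next to the codons whose reverse complements are stops).
Neutral simulations therefore show hotspot ratios slightly *below* one
(around 0.92 at the default conditions) rather than exactly one.  This is
a property of evolution constrained to stay ambigrammatic, not an
estimator bias, and it does not affect the tests' direction of
discrimination.

What the simulator does **not** emulate: shared genealogy (star tree
only), indels, recombination, codon-usage bias (ancestors draw sense
codons uniformly), rate heterogeneity along the gene, and sequencing
error.  A test passing on simulations therefore validates the counting
machinery and the direction of each discriminator under the stated model
— it does not certify behaviour on real data with strong tree structure
or recombination.

## Numerical and degenerate-input choices

* Undefined statistics are `NA` with an explanatory flag, never a crash:
  $\hat\alpha$ with $N_v = 0$, $R$ with $N_{sy} = 0$, the z-triplet with
  no mutations, dsyn R with $N_d = 0$.  A hotspot ratio with variant-free
  "other" loci but active doubly synonymous loci is `Inf` (the signal is
  one-sided), and `NA` only when both classes are silent.
* A consensus with zero synonymous opportunity (e.g. a single Met codon)
  makes $R_\mathrm{exp}$ meaningless and is an error, not a number.
* Codons containing gaps or ambiguity codes contribute nothing at that
  locus for that sequence; denominators keep M, so `f(k)` is a fraction
  of *sampled* sequences.  Columns with no unambiguous base at all are an
  error naming the column.
* All tie-breaks are fixed (base order A < C < G < U; smallest frame
  offset; `+` strand on scanner ties) so identical inputs and seeds give
  byte-identical outputs.

## Scanner

`ambig_spans()` reports maximal codon runs free of stops in both aligned
frames; `scan_ambigrams()` takes the best span per record over all three
offsets and both orientations and applies two thresholds: minimum span
length (default 200 nt) and minimum spanned fraction of the record
(default 90%).  The fraction is relative to the whole record, so the
defaults are calibrated for contigs that *are* mostly one ambigrammatic
gene; to find an ambigrammatic island inside a longer contig, lower
`min_frac` and filter on `span_length`.  Random sequence sustains
stop-free dual-frame runs only briefly (stop density about 6/64 per codon
summed over the two frames), which is why the defaults are effectively
zero-background.

## Validation problem sizes

The shipped tests validate the machinery at the scale it is meant for:
oracle equivalence of $R_\mathrm{exp}$ and $R_0$ against brute-force
neighbour enumeration over 1,000 random 100-codon consensus sequences at
$\alpha \in \{0.5, 1, 2, 5\}$ (agreement to $10^{-12}$ relative error);
200 neutral replicates at M = 50, N = 500 for $\hat\alpha$ recovery and
hotspot calibration; 100 replicates each for the dual- and
forward-purifying separations; and 100 seeded scanner datasets of ten
random 2-kb contigs plus one 900-nt simulated gene.  `scripts/acceptance.R`
re-runs a scaled version of the same pipeline end to end and emits the
headline numbers as JSON.
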