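# abagbench

Curation toolkit for antibody–antigen docking benchmarks.

Rigid-body and flexible docking methods are evaluated against benchmark sets
of antibody–antigen complexes for which both the *bound* complex structure
and experimentally solved *unbound* structures of the antibody and antigen
are available. Assembling such a benchmark is a pipeline problem: find
unbound partners among sequence-search hits, trim and clean coordinate
files, quantify how much each partner deforms on binding, grade docking
difficulty, remove redundant complexes, and keep the set current as new
structures are released. `abagbench` implements that pipeline as a set of R
functions plus a small command-line front end, aimed at structural
bioinformaticians who maintain or extend docking benchmarks.

## The methodology in brief

**Unbound-structure screening.** A sequence-search hit (BLAST tabular
layout) identifies a usable unbound structure for a bound chain when

```
identity > 93%,  alignment coverage > 80%,  E-value < 1e-5
```

(all strict). Complexes are then grouped by which sides have unbound
structures: unbound–unbound (UU), unbound–bound (UB), bound–unbound (BU)
or bound–bound (BB).

**Conformational change.** Interface residues are those with any
non-hydrogen atom within 10 Å of the binding partner; contacts use the same
definition at 5 Å as residue pairs. The interface RMSD (I-RMSD) is the
Cα RMSD over interface residues after least-squares (Kabsch) superposition
of the unbound interface onto the bound one; the fraction of non-native
contacts (f_non-nat) is the share of the superposed unbound pair's contacts
absent from the native contact map. Buried surface area (ΔASA) comes from a
Shrake–Rupley solvent-accessible-surface calculation, and CDR loop RMSDs
are measured on Chothia-numbered loops after a framework-only fit.

**Difficulty.** Cases are graded with the entire-interface I-RMSD:

| Category  | Criterion                          |
|-----------|------------------------------------|
| Rigid     | I-RMSD < 1.5 Å and f_non-nat < 0.40 |
| Difficult | I-RMSD > 2.2 Å                      |
| Medium    | otherwise                           |

**Redundancy removal.** Two complexes are redundant when every
corresponding chain type matches at sequence level (identity > 60%,
E-value < 1e-30) *and* the superposed whole-complex Cα RMSD is below 5 Å.
Redundant pairs form the edges of an undirected graph over case ids; the
node of maximum degree is deleted (ties broken deterministically, or
randomly under a seed) and the process repeats until every degree is zero,
leaving a non-redundant retained set. An incremental update path compares
newly released complexes against the stored set and re-prunes only the
affected connected components.

A synthetic-fixture module generates toy antibody–antigen complexes with
controlled interface perturbations, so the entire pipeline is testable
without downloading structures.

## Worked example

```r
library(abagbench)

# a toy UU case whose antigen interface is displaced by 2.5 A RMS
cs <- generate_toy_case(
  fixture_spec(perturbation = "rigid_shift", magnitude = 2.5, seed = 7),
  case_id = "demo")

i_rmsd(cs, "antigen")        # 2.5      <- the construction is recovered
i_rmsd(cs, "combined")       # 1.704986 <- pooled over both sides
as.numeric(f_non_nat(cs))    # 0.8571429 <- most contacts displaced
classify_case(i_rmsd(cs, "combined"), as.numeric(f_non_nat(cs)))
# "Medium"                   <- 1.5 < 1.705 < 2.2

# composition arithmetic of a 112-case benchmark
counts <- matrix(c(8, 23, 2, 43, 4, 32), nrow = 3, byrow = TRUE,
                 dimnames = list(c("Rigid", "Medium", "Difficult"),
                                 c("sdAb", "mAb")))
benchmark_summary(counts)
# Benchmark composition (112 cases)
#           sdAb mAb All Share(%)
# Rigid        8  23  31    27.68
# Medium       2  43  45    40.18
# Difficult    4  32  36    32.14
# Rigid share within type (%): sdAb 57.14, mAb 23.47
```

The numbers mean: the displaced antigen interface deviates by exactly the
requested 2.5 Å after optimal superposition; pooling with the unperturbed
antibody side gives 1.705 Å, which lies between the Rigid (1.5 Å) and
Difficult (2.2 Å) thresholds, so the case is Medium. The summary reproduces
the two-decimal share arithmetic used in benchmark composition tables.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/abagbench simulate --out-dir cases --seed 5 --n-cases 3
Rscript inst/cli/abagbench metrics  --cases cases --out metrics.csv
Rscript inst/cli/abagbench classify --metrics metrics.csv --out labels.csv --summary summary.csv
Rscript inst/cli/abagbench dedupe   --cases cases --out retained.csv --log prune.jsonl
```

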