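# foldinit

Sequence-based prediction of protein **folding-initiation segments**.

Experiments show that proteins sharing one topology (e.g. the
ferredoxin-like fold: βαββαβ) can fold through different parts of their
chain. `foldinit` locates the candidate initiation segments using only the
amino-acid sequence plus a table of *inter-residue average distance
statistics* — means r̄ and standard deviations σ of Cα–Cα distances,
keyed by the residue-type pair and the sequence-separation range M
(k = 1–8, 9–20, 21–30, then width-10 bins).

Three analyses are provided, for structural bioinformaticians and protein
folding researchers:

* **Average Distance Map (ADM)** — a predicted contact map
  (contact ⇔ r̄ ≤ cutoff). For an interval [a,b], the score
  η(a,b) = contact density inside [a,b] − whole-map density; dense
  diagonal blocks are extracted as *compact regions* (predicted folding
  segments), ranked primary/auxiliary with an N/C dominance label.
* **F-value Monte Carlo** — a Cα bead chain (3.8 Å virtual bonds) sampled
  by Metropolis moves (bend + torsion, ±10° per joint) under the Gaussian
  pair potential E(r) ∝ (r−r̄)²/2σ², with kT auto-calibrated to a 0.5
  acceptance ratio. Contact frequencies g(i,j) are z-scored per separation
  range (Q) and summed per residue: F_i = Σ_j Q(i,j). F peaks (terminal
  residues excluded) mark putative hydrophobic-cluster centers.
* **Conservation & native contacts** — Shrake–Rupley SASA with the
  two-carbon burial reference 2π(1.7+1.4)·1.4 = 27.27 Å² fixing a 27 Å²
  side-chain burial contact threshold; conserved hydrophobic residues
  (>99 % across an alignment, interchanges within {A,M,W,L,F,V,I,Y}
  tolerated); per-residue conserved-contact profiles with Gaussian
  smoothing. Family-level conservation of predicted segments is measured
  by an **ADM similarity** (% of mutually non-gapped alignment sites
  agreeing on region membership) with inclusion histograms,
  similarity-vs-identity curves, and neighbor-joining trees.

A first-class synthetic-data module (`make_compact_chain`,
`make_two_domain_family`, `make_msa`, `make_sasa_fixture`) generates
structures, statistics, and alignments with planted ground truth so the
whole pipeline runs and is tested without downloads.

## Worked example

```r
library(foldinit)

# a synthetic two-domain family: 5 structures, boundary planted at 40/100
fam <- make_two_domain_family(100, 40, n_structures = 5, seed = 42)
adm <- build_adm(fam$probe_sequence, fam$stats)   # 13 A contact cutoff
extract_regions(adm)
#>   start end start_src end_src      eta      rank dominance
#> 1     1  40         1      40 0.579731   primary         N
#> 2    41 100        41     100 0.331225 auxiliary         C
```

The extractor recovers the planted domain boundary exactly: the first
block (residues 1–40) is the denser, `primary` segment (η ≈ 0.58, i.e.
58 percentage points above background contact density), the rest is
`auxiliary`. On real sequences the two terminal regions correspond to the
N- and C-terminal folding segments and η ranks which one initiates
folding.

```r
# F-value analysis at desk scale (full scale: n_steps = 60000, n_runs = 100)
cf <- run_simulation(fam$probe_sequence, fam$stats,
                     n_steps = 2000, n_runs = 5, seed = 1)
mean(cf$acceptance)          # ~0.5: kT was auto-calibrated per run
fp <- f_profile(normalize_contacts(cf))
fp$peaks                     # residue indices of F peaks

# conservation on a synthetic alignment with planted conserved sites
m <- make_msa(n_records = 15, length = 50, region = c(16, 35),
              conserved_sites = data.frame(site = c(20, 25), target = 1),
              seed = 1)
prof <- hydrophobic_conservation(m$alignment, "ref")
which(prof$sites$conserved)
#> [1] 20 25
```

An end-to-end run (`run_all(config, out_dir)`) writes TSV artifacts
(regions, F profile, conservation, similarity matrix, inclusion
histogram, Newick tree, Φ-by-secondary-structure comparison) under
`out_dir`; a thin CLI wrapper lives in `inst/scripts/foldinit-cli.R`
(subcommands `fixtures`, `stats`, `adm`, `report`).

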