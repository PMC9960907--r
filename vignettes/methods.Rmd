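---
title: "Methods: mapping cross-links onto structures and scoring structural dynamism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping cross-links onto structures and scoring structural dynamism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlmapr)
```

## The measurement model

A cross-link identified by mass spectrometry is a residue-pair distance
restraint. `xlmapr` evaluates each protein–protein interaction (PPI)
against each candidate structure in four steps: normalize the cross-link
table, map each protein's database coordinates onto structure chains by
local alignment, measure a Cα–Cα Euclidean distance per link, and condense
each PPI–structure pair into a bounded score. The assumptions behind each
step, and the parameters a user can move, are laid out below.

### Cross-link normalization

Links are canonically ordered so that `(protein_a, pos_a)` ≤
`(protein_b, pos_b)` lexicographically, then deduplicated over the key
`(protein_a, pos_a, protein_b, pos_b, linker)`; the number of collapsed
PSM rows (or the explicit `count` column of the generic TSV) becomes the
link's `spectral_count`. The linker belongs in the key: the same site pair
bridged by DSS and by DSBU is two different restraints. Identifications
are taken as given — there is no re-scoring or FDR estimation here — but
links whose accession is absent from the FASTA, or whose position exceeds
the sequence length, are rejected into a per-run log rather than silently
dropped. pLink2 rows whose site string contains more than one candidate
pair (ambiguous localization) are skipped with a warning; guessing a
localization would fabricate a restraint.

No residue-type filter is applied anywhere: any position is a legal site,
so site-nonspecific chemistries (e.g. photo-cross-linkers) pass through
unchanged. This is deliberate — tools that hard-code Lys–Lys linking
cannot represent them.

### Sequence-to-structure mapping

The database sequence and the structure chain sequence routinely disagree:
constructs are truncated, tags added, loops unresolved, residues modified.
Mapping therefore goes through pairwise local alignment rather than
through naive position equality. We use exact Smith–Waterman (as
implemented by `Biostrings::pairwiseAlignment`) with BLOSUM62 and affine
gap penalties 11/1 — the classic protein-BLAST parameterization — so a gap
of length *L* costs 11 + *L*. An exact algorithm rather than a heuristic
one removes seed-dependent variability and an external binary dependency;
at chain scale (10²–10³ residues) the cost is irrelevant. The test suite
cross-checks the alignment scores against an independently written
brute-force dynamic-programming oracle on a thousand random pairs.

A chain is accepted for a protein when

* **identity** (identical residues / aligned columns) ≥ `min_identity`,
  default **0.9** — high, because the danger at proteome scale is mapping
  a link onto a paralog's structure; and
* **coverage** (aligned query-span length / query length) ≥
  `min_coverage`, default **0.3** — low, because crystal constructs are
  often a single domain of the identified protein.

Both are plain config knobs; neither value is claimed to be universal.
All accepted chains are kept. In a homodimer, one protein maps to two
chains, and a site resolves to two structure residues — multiplicity is
handled downstream, not collapsed here. Positions in gap columns, and
positions mapping only to residues whose Cα is not resolved, yield no hit
and are tallied as unmapped.

Author numbering (`auth_asym_id`, `auth_seq_id`, insertion codes) is the
coordinate system for everything user-facing, because PyMOL resolves
selections in author numbering; `label_seq_id` is discarded after parsing.
There is no SIFTS-style external residue mapping: numbering comes from the
alignment only.

### Distance measurement and classification

The anchor atom is Cα: it exists for glycine, it is the dominant
convention in cross-link validation, and the default linker table is
calibrated to it. A residue whose Cα is missing is treated as unmapped for
that chain copy — falling back to another atom would make one threshold
govern two different geometries. Only the first model of an entry is used
(a single deterministic distance per link), and the asymmetric unit is
taken as deposited, without biological-assembly expansion.

For one link, every combination of chain-copy hits for site A and site B
is enumerated; for intra-protein links the identical `(chain, residue)`
self-pairing is excluded. The link's distance is the **minimum** over
combinations: a restraint only requires *one* geometrically feasible copy
pair. The winning combination's chain identifiers are recorded, so
intra-chain and cross-chain satisfaction of an intra-protein link remain
distinguishable in the output. Classification is `satisfied` when
distance ≤ the linker's `max_ca_distance`, else `over_length`; links with
no valid combination are `unmapped`. The default table sets DSS, BS3 and
DSBU to 30 Å Cα–Cα (spacer arm plus two lysine side chains plus
coordinate uncertainty, the common rule of thumb); thresholds are data in
a TSV, not constants, and a linker name missing from the table is a fatal
error rather than a silent default.

### The pair score

Each PPI–structure pair is condensed into features: satisfaction fraction
`f_sat = n_satisfied / n_mapped` (0 when nothing maps), coverage
`n_mapped / n_total`, mean relative violation of the over-length links
`mean((d − max) / max)`, and an evidence term `n_mapped / (n_mapped + k)`.
The score is

```
score = 100 · evidence · max(0, w_s·f_sat + w_c·coverage − w_v·min(violation, 1))
```

with defaults `w_s = 0.7`, `w_c = 0.3` (constrained to sum to 1),
`w_v = 0.2`, `k = 3`. Design intent, in order: (i) *bounded and
orientation-fixed* — always in [0, 100], high ⇔ cross-links consistent
with a static deposited structure, low ⇔ dynamic or mismatched; (ii)
*monotone* — non-decreasing in `f_sat` and coverage, non-increasing in
violation, properties the test suite asserts on randomized inputs; (iii)
*evidence-damped* — the pseudo-count `k = 3` means a pair with a single
satisfied link scores at most 25, while three mapped links reach half the
asymptotic confidence, so abundant consistent evidence (not lucky
sparsity) is what earns a high score. The violation term is capped at 1 so
a single absurd distance (a mis-mapped site, not biology) cannot dominate.
All four constants are config keys, echoed into the score-file header.
The functional form is this package's own transparent definition for
"agreement between cross-links and a structure"; it is not a re-derivation
of any published scoring function, and the weights were fixed at these
defaults when the score was designed, not tuned against data.

## Structure selection per PPI

Which structures should a PPI be evaluated on? Two modes are provided and
neither is privileged: an explicit protein→entry mapping table (columns
`accession`, `entry_id`) pairs a PPI only with entries listed for either
partner; with no table, every PPI is paired with every loaded structure
and the identity threshold discards non-matches. The all-vs-all mode is
quadratic but safe at typical set sizes; the mapping mode is what a
proteome-scale run should use. Online fetching is intentionally not
implemented: `load_structure_set` reads a local directory, which a
download step can populate beforehand, keeping the analysis itself fully
reproducible offline.

## Numerical and formatting choices

* Distances are reported to 3 decimal places (round-half-even). Sub-mÅ
  digits carry no physical meaning and unrounded doubles would break
  byte-level determinism of outputs across platforms.
* All output tables are TSV with `#` header lines echoing the tool version
  and key config; files are written atomically (temp file + rename).
* Deterministic ordering everywhere: links by canonical key, structures by
  entry id, score rows by score descending with entry-id tie-break.
  Repeated runs on identical inputs are byte-identical, which the tests
  assert; batch parallelism is deliberately absent for the same reason.
* Degenerate inputs: an empty FASTA, a linker missing from the table, no
  loadable structure, and invalid score weights are fatal with named
  errors; malformed rows, duplicate accessions, unparsable structure files
  and unmappable links degrade gracefully into warnings and logs.
* Local alignments with no positive-scoring column return the empty
  alignment with score 0 rather than a forced negative-scoring alignment.
* Cα altloc selection: highest occupancy wins, ties break to the
  alphabetically first altloc — arbitrary but fixed.

## What the synthetic scenes do and do not show

`make_scene()` places residues on idealized helical traces (rise 1.5 Å,
radius 2.3 Å, 100°/residue; chains offset 8 Å along x), draws random
sequences, and plants cross-links by sampling site pairs whose *written*
(3-decimal) coordinates are within or beyond the linker maximum, in a
controlled ratio. Because planned distances are computed from the same
rounded coordinates the mmCIF contains, the pipeline must reproduce them
essentially exactly (the tests demand 10⁻⁶ Å), and planted
satisfied/over-length counts must be recovered exactly.

This validates the *bookkeeping and the math*: parsing, alignment-based
coordinate transfer, copy-combination enumeration, classification,
aggregation, export, determinism. It does not validate behavior on real
data: synthetic chains have no missing residues, no altlocs, no modified
residues, no paralogs, no disagreement between database and construct,
and their geometry is not protein-like. Those complications are exercised
separately by hand-built mmCIF fixtures in the unit tests (missing Cα,
altloc occupancy ties, insertion codes, HETATM polymers, multi-model
files), but a passing suite is a statement about the machinery, not about
any biological dataset.

Problem sizes in the shipped tests — scenes of 1–3 chains × 25–40
residues, 4–12 links, ~20 seeds spanning over-length fractions 0, ½ and 1,
and 1000 random alignment pairs of length 5–40 — were chosen as the
smallest sizes that exercise every code path, including multi-chain
multiplicity and both classification outcomes, while keeping the whole
suite fast enough to run habitually.

## Known limitations

* Euclidean Cα–Cα distance, not solvent-accessible-surface distance
  (SASD); Euclidean distances systematically understate the path a linker
  must actually take around the protein body.
* First model only; an NMR ensemble's conformational spread is invisible.
* No biological-assembly expansion: links satisfied only across symmetry
  mates will appear over-length or unmapped.
* The score is a transparent surrogate with fixed semantics, not a
  statistically calibrated quantity: no significance, no FDR, and scores
  are comparable across pairs only under the same weights.
* Alignment-based numbering transfer can misplace sites in low-complexity
  or repeat regions where the local alignment is ambiguous, even at high
  identity.

## Worked demonstration

```{r demo, eval = FALSE}
res <- xlmap_demo(out_dir = tempfile("demo"), seed = 1)
glance(res$reports)   # 12 links mapped, 9 satisfied, 3 over-length
score_table(res$reports)
autoplot(res$reports)
```

The demo's three-chain scene plants 12 DSS links, 25% of them
over-length; the pipeline recovers exactly the planted counts, and the
score ranking illustrates the evidence damping (a 3-link pair with
perfect satisfaction scores 50; a 6-link pair with one mild violation
scores 57.8).
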