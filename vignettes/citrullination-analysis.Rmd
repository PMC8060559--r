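---
title: "Assigning and validating plant citrullination sites from tandem MS evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning and validating plant citrullination sites from tandem MS evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citrullinr)
```

## The problem

Citrullination (deimination) hydrolyses the guanidinium group of a
peptidyl-arginine to a ureido group, converting the residue to
citrulline. The modification adds +0.984016 Da and removes a positive
charge. Two facts make it hard to assign from tandem mass spectra:

1. **The isobaric confound.** Deamidation of asparagine or glutamine
   produces the same nominal +0.984 Da shift. At the precursor level
   the two are indistinguishable to within a nanodalton, so the site
   must be pinned down from b/y fragment ions that bracket it.
2. **The diagnostic loss.** During collision-induced dissociation the
   citrulline ureido group can shed isocyanic acid, HNCO, with
   monoisotopic mass 43.005814 Da. Deamidated residues cannot. A peak
   43 Da (or 43/z m/z units) below the precursor or below a
   citrulline-containing fragment is therefore positive evidence for
   citrullination over deamidation.

`citrullinr` implements the full validation chain used to call
citrullination sites in a plant (Arabidopsis) nuclear proteome across
a cold-stress time course, plus the surrounding machinery: tryptic
digestion, fragment mass bookkeeping, MGF input/output, peak
matching, sequence-context logos, motif scanning, and fold-change
categorization. All randomised components run from explicit integer
seeds.

## Mass bookkeeping

All masses are monoisotopic (the data the package targets come from
an Orbitrap instrument) and are derived at load time from the atomic
masses of H, C, N, O and S plus residue elemental formulas — not
from a transcribed residue table. This reproduces the constants used
throughout:

```{r}
mass_table()$water
mass_table()$proton
mass_table()$hnco_loss
cit_delta()
```

Only the b and y series are generated (CID chemistry); a/c/z ions,
internal fragments, immonium ions and isotope envelopes are out of
scope. For a peptide of length $n$, each series has ions $1..n-1$,
and for singly charged ions the telescoping identity
$b_i + y_{n-i} = M + 2 m_p$ holds; the test suite checks it to
$10^{-6}$ Da on random modified peptides.

## Digestion

Trypsin cuts after K or R except before proline. Two choices deserve
note:

* **Citrulline blocks cleavage.** Deimination removes the charged
  group trypsin recognises, so a citrullinated arginine is not a cut
  site and does not count toward missed cleavages. The
  `cleave_cit = TRUE` flag restores naive behaviour, which is needed
  to regenerate published peptide lists that include a reportedly
  citrullinated C-terminal arginine — a combination that is
  chemically inconsistent but occurs in printed tables. Such peptides
  are retained rather than rejected.
* **No N-terminal methionine clipping.** No rule is imposed because
  the upstream search pipeline the package mirrors states none.

## Site localization and scoring

Given a spectrum, a peptide sequence and the number of +0.984 Da
deltas, `candidate_placements()` enumerates every placement on R
(citrullination) and N/Q (deamidation); `localize()` scores each
candidate and reports the winner.

The score is a chance-corrected binomial tail on the familiar
$-10\log_{10}$ scale: with $n$ theoretical singly charged b/y ions,
$k$ of them matched within the fragment tolerance, and a per-ion
chance-match probability
$p = \min(1, \text{peaks} \times 2\,\text{tol} / \text{span})$,
the score is $-10\log_{10} P(X \ge k)$, $X \sim B(n, p)$. It is a
purpose-built replacement for the proprietary search-engine score
whose thresholds the package takes over (peptide $\ge 30$, protein
$\ge 32$); published engine scores are carried as annotations, never
recomputed. The defaults for matching are 0.5 Da for fragments
(absolute) and 10 ppm for the precursor (relative), both
configurable.

Peak assignment maximises the number of matched ions (maximum
bipartite matching via augmenting paths, seeded in order of
increasing mass error, ties to higher intensity) instead of one-pass
greedy nearest-neighbour assignment. Greedy can discard a feasible
match when two ions compete for one peak; the count-maximal
assignment makes the match count well-defined and equal to an
exhaustive-assignment oracle, which the tests exploit.

A localization is

* **accepted** when the best placement is all-arginine, its score
  clears the peptide threshold, and the runner-up trails by at least
  the ambiguity margin (default 5 score units — the upstream pipeline
  specifies none, so this is a package choice, overridable);
* **ambiguous** when the margin is thin or the best placement
  involves N/Q (deamidation is never reported as citrullination);
* **rejected** below threshold.

`accept()` additionally demands, when configured, the neutral-loss
diagnostic and verification that every assigned site is an arginine
in the unmodified counterpart peptide. The diagnostic checks both the
precursor companion and fragment companions and reports which fired,
since upstream practice does not say which was inspected; its
intensity floor defaults to 1% of the base peak.

## Synthetic data: what it emulates and what it does not

The study's raw spectra are not publicly deposited, so the package
certifies its localization chain on simulated data with known ground
truth. `simulate_spectrum()` produces the 1+ b/y ions of a modified
peptide with: ion dropout (Bernoulli, default off), Gaussian m/z
jitter, uniform decoy peaks over [100, precursor m/z] with
exponential intensities, a linear intensity decay across each
fragment series, and — for citrullinated peptides — the planted
precursor−43.005814/z companion. `simulate_proteome()` plants motif
realizations into background sequences drawn from stated residue
frequencies; `simulate_quant_table()` plants baseline / increased /
decreased / de-novo / lost records.

Validation batches use peptides of length 8–16 ending in K/R that
contain both an arginine and an N/Q, so every spectrum genuinely
poses the citrullination-versus-deamidation question. Under the
declared noise regime (dropout 0.2, 10 decoy peaks, 0.05 Da jitter)
the localizer recovers the true site in ≥ 95% of 200 spectra; in the
noiseless limit, always. These numbers are recomputed by the test
suite and the acceptance script, never asserted from memory.

What the simulator does **not** model: isotope envelopes, charge
state mixtures, chimeric spectra, retention time, intensity
heteroscedasticity, or co-eluting modifications. Passing these suites
therefore certifies the inference logic, not instrument-level
robustness on real data.

## Sequence context: logos and motif scanning

`build_logo()` aligns ±w windows (default w = 7) around citrullinated
arginines and reports per-offset residue frequencies and information
content, $\log_2 20 - H$ bits. Windows are not padded: offsets beyond
a protein terminus contribute nothing and frequencies normalise over
the observations present.

`consensus_pattern()` translates a logo into a search pattern: an
offset is specified when its top residue frequency reaches the
threshold (default 0.5), and the class at a specified offset keeps
every residue whose frequency is at least `min_class_freq` (default
0.2, four times the uniform 1/20 background). The background-floor
rule is deliberate: an evenly split two-residue preference such as
[RS] should survive sampling noise rather than collapse to whichever
member happened to be in the majority. Runs of sub-threshold offsets
render as `x{n}` and uninformative flanks are trimmed.

The published context pattern `[RS]xRx{4}RL` places, reading the
pattern literally, an arginine five positions and a leucine six
positions C-terminal of the citrullinated R (the prose around it
counts "four" and "five" residues removed; the package follows the
pattern text). The logo tests plant exactly this context and recover
the R at offset +5 and the L at +6.

`scan_motif()` accepts both the compact dialect (`[RS]xRx{4}RL`) and
the dashed PROSITE-like dialect
(`W-X-R-D-[TS]-G-X(100,140)-H-[VIL]-D`, the deiminase catalytic-site
motif). Bounded gaps are matched by positional arithmetic — each
admissible gap length is compiled to a fixed-length lookahead regex —
so worst-case cost is sequence length × (max − min + 1), with no
backtracking blow-up. Ambiguity letters X/B/Z/U in sequences satisfy
only wildcards, never residue classes (conservative matching), and
protein-level counts collapse isoforms to loci because published
counts are per protein.

## Differential citrullination

`categorize_changes()` classifies each record per timepoint against
control: `unchanged` within (1/1.5, 1.5), `increased`/`decreased`
outside, `de_novo` and `lost` per detection sentinels. The defaults
reproduce the published labels: the smallest printed differential
fold change is 1.53 and the only printed decrease is 0.67.

One numerical subtlety: printed fold changes are rounded. The
published decrease "0.67" is the rounded image of a value at or below
1/1.5 = 0.666…, and comparing the printed number against the exact
threshold would misclassify it as unchanged. Annotation-derived fold
changes are therefore compared against thresholds rounded to the
annotation's printed precision; intensity-derived fold changes use
exact thresholds. "ns" annotations are honoured as unchanged and "nd"
as not detected when intensities are absent.

`summarize_changes()` collapses the two timepoints into disjoint
classes with precedence de novo → differential → lost → baseline. On
the packaged events table this yields 14 control-detected proteins:
10 baseline, 4 differential, 5 de novo. Significance testing is
deliberately out of scope — the upstream analysis reports none for
these fold changes — so the categories are purely threshold-based.

## The packaged events table

`load_table1()` returns the transcription shipped under
`inst/extdata/table1_fixture.tsv`: 19 records in three sections, with
peptides in flanked `X.PEPTIDE.Y` notation parsed into sequence,
flanks and the positions of the table's unexplained lowercase letters
(these are case-folded and carry no mass shift; only lowercase m has
a conventional reading as oxidised methionine). The table follows its
source verbatim, including an accession whose prose spelling differs
(`AT1G29040` in the table).

## Problem sizes and determinism

The validation studies are sized to run in seconds to a few minutes
on one CPU: 50 noiseless plus 200 noisy spectra for recovery rates,
100-protein simulated proteomes with 25 planted motif occurrences,
and brute-force oracles on sequences of ≤ 50 residues or ≤ 8-ion
score cases. Every stochastic step takes an explicit integer seed and
threads it through a single RNG scope (`withr::with_seed`), so two
runs with the same configuration are identical; the acceptance script
derives all its seeds from its `--seed` argument.

## Known limitations

* No database-wide peptide-spectrum search or decoy FDR: the package
  validates assignments for given peptides, mirroring a manual
  validation workflow.
* The two published proteome-scan counts (signature pattern in > 900
  loci; the deiminase motif unique to one locus) require the TAIR10
  representative proteome FASTA, which is too large to redistribute
  here; the scan machinery is certified on planted proteomes instead
  and the TAIR10 checks run only when the file is supplied.
* The ion score is a calibrated replacement, not a re-implementation,
  of the proprietary engine score; absolute score values are not
  comparable between the two, only the threshold logic is.
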