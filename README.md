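# mamtools

Multi-attribute method (MAM) toolkit for monoclonal-antibody quality
monitoring from peptide-map LC-MS data.

Biopharmaceutical QC increasingly replaces panels of orthogonal assays
(glycan profiling, charge variants, oxidation assays, ...) with a single
bottom-up LC-MS workflow that quantifies many product quality attributes
(PQAs) at once: the multi-attribute method. `mamtools` implements such a
workflow end to end for process-development and QC scientists who need an
open, scriptable, fully testable alternative to vendor software:

* **Antibody model** — chain sequences from FASTA, in-silico tryptic
  digestion (cleave after K/R, not before P; configurable missed
  cleavages), exact monoisotopic mass arithmetic, and automatic
  enumeration of a PQA panel: deamidation (N/Q), oxidation (M),
  dioxidation (M/W), N-terminal pyroglutamate (Q/E), C-terminal lysine
  loss, and site-specific N-glycoforms in Oxford notation.
* **Quantification engine** — extracted-ion chromatograms (XICs) at the
  theoretical m/z of every monitored charge state, chromatographic peak
  detection and integration (Gaussian smoothing, S/N gating, valley
  splitting, linear baseline), and relative abundance per attribute:

  ```
  PQA (%) = 100 * sum(peak areas, modified peptide)
                / sum(peak areas, all forms of the same peptide)
  ```

  Glycoform profiles are percentages over all detected glycoforms,
  counting the aglycosylated peptide as a form.
* **New-peak detection (NPD)** — untargeted MS1 feature detection with
  isotope-spacing charge assignment, cross-run pairing (10 ppm,
  retention-time delta <= 0.2 min), and rule-based flags: *new*,
  *missing*, *changed* (area fold change >= 20 untargeted / >= 3
  targeted), *unchanged*, with singly charged ions excluded and gates at
  height > 500 counts and Gaussian-shape quality > 0.6.
* **Subunit glycation** — charge-state deconvolution of reduced-mAb
  spectra by iterative peak stripping (20 iterations, S/N >= 20,
  resolution 2500, +/- 5 Da matching), quantifying light-chain glycation
  from the +162.0528 Da (C6H10O5) hexose adduct.
* **QC statistics** — detection (0.1%) and quantification (1%)
  thresholds; tiered pass/fail criteria (2x / 1.5x / 1x reference SD for
  reference abundances < 5%, 5–15%, > 15%); RSD precision; Bland-Altman
  comparability (mean bias, limits of agreement = bias +/- 1.96 x SD of
  paired differences).
* **Simulator** — seeded generator of ground-truthed DDA peptide-map runs
  (averagine isotope envelopes, Gaussian elution, additive noise) and
  reduced-subunit multi-charge envelopes, so every stage is testable
  without instrument data.

I/O: mzML (via Bioconductor `mzR`) and a peak-list CSV debug dialect;
results are written as commented, schema-versioned CSVs.

## Worked example

Simulate a five-site oxidation study with known truth, write it to mzML,
then quantify it back from the file with the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts","mam_cli.R",package="mamtools"))')
Rscript $CLI simulate --seed 2 --out-dir out/
printf '>heavy synthetic\nAVSGMDELKTLYMNQAGKVFDMSPELRGHWMTTESKYAAMGDVLK\n' > chain.fasta
Rscript $CLI quantify --fasta chain.fasta --runs out/simulated.mzML --out-dir out/
head -3 out/batch_summary.csv
```

```
# mamtools batch_summary v1
"run_id","Deamidation_1","Deamidation_2","Oxidation_1","Oxidation_2",...
"simulated",0,0,0.495421071261511,0.699875948164788,2.0929090647342,
            2.96063807248132,5.93761604872675,...
```

The simulated truth put the five methionine-oxidation sites at 0.5, 0.7,
2.1, 3.0 and 6.0% relative abundance; the pipeline recovers 0.50, 0.70,
2.09, 2.96 and 5.94% from the mzML file — every site within 0.07 absolute
percent. Attributes whose modified species were not injected (deamidation,
dioxidation, lysine loss) read 0.

The same study in R, with expected retention-time windows taken from the
characterization truth:

```r
library(mamtools)
demo  <- demo_oxidation_panel()
truth <- build_ground_truth(demo$panel,
           c(Oxidation_1 = 0.005, Oxidation_2 = 0.007, Oxidation_3 = 0.021,
             Oxidation_4 = 0.030, Oxidation_5 = 0.060), seed = 1)
run   <- simulate_peptide_run(truth, sim_config())
panel <- attach_expected_rt(demo$panel, truth)
run_quantify(panel, list(r = run))$per_run$r
```

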