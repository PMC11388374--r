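# Published supplementary data (user-supplied)

The checks that reproduce the published cemetery results need the
study's supplementary data tables, which are distributed by the
publisher and are not bundled here.  Export them as plain text into
this directory:

* `dataset_s09_segments.tsv` — IBD segments: tab-separated
  `id1, id2, chrom, start_cm, end_cm, length_cm`.
* `dataset_s09_siblings.tsv` — known sibling pairs (optional):
  tab-separated `id1, id2`.
* `dataset_s04_consensus.csv` — relatedness calls:
  `id1, id2, estimator, degree` with degrees in
  `parent-offspring, sibling, 2nd, 3rd, unrelated`.
* `dataset_s01_metadata.csv` — per-individual `id, age_class, sex`
  (optional, used for parent-offspring orientation).
* `dataset_s01_isotopes.csv` — `id, sr_ratio, age_class` for the human
  samples.
* `dataset_s01_environmental.csv` — `id, sr_ratio` for environmental
  samples (optional).

With these present, `tests/testthat/test-acceptance.R` recomputes the
IBD network topology, the largest pedigree, and the strontium locality
counts from them.
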