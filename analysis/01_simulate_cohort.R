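#!/usr/bin/env Rscript
# Build the study cohorts.
#
# Two synthetic cohorts stand in for the 19-control / 20-case patient data:
#   (a) a spectral cohort on the 650-4000 cm^-1 instrument grid with the
#       case-group effects the study observed (raised lipid CH-stretch
#       intensity, shifted amide I line shape), analysed by the downstream
#       scripts exactly as measured spectra would be; and
#   (b) a marker-level cohort drawing the seven spectral biomarkers from the
#       reference cohort's published means/SDs, used by the replication
#       study in 05.
# Everything is deterministic given the seed below.

library(evftir)

seed <- 949
dir.create("results", showWarnings = FALSE)

spec <- plant_group_effect(cohort_spec(), d = 3, amide_shift = 5)
cohort <- generate_cohort(spec, seed = seed)
write_spectra(cohort, "results/cohort_spectra.csv", "csv_wide")

features_ref <- generate_feature_cohort(feature_cohort_spec(), seed = seed)
write.csv(features_ref, "results/cohort_features_reference.csv",
          row.names = FALSE)

cat(sprintf(
  "Simulated %d spectra (%d control / %d case, %d grid points) -> results/cohort_spectra.csv\n",
  n_subjects(cohort), sum(cohort$group == "control"),
  sum(cohort$group == "case"), length(cohort$wavenumber)))
cat(sprintf(
  "Marker-level reference cohort (%d subjects x %d markers) -> results/cohort_features_reference.csv\n",
  nrow(features_ref), ncol(features_ref) - 2L))
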