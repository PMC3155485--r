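#!/usr/bin/env Rscript
# Build the 13-predictor dyadic covariate panel: same-category indicators
# for the categorical attributes, absolute differences for the continuous
# ones, the co-authorship tie matrix, and the site-level geographic
# distance matrix. Serialized as one TSV per covariate plus a manifest.

suppressPackageStartupMessages(library(collabnet))

data_dir <- "results/study/data"
out <- "results/study/covariates"

rost <- read_roster(file.path(data_dir, "roster.csv"))
pubs <- read_publications(file.path(data_dir, "publications.csv"),
                          roster_ids(rost))
sites <- read_site_distances(file.path(data_dir, "site_distances.csv"))

panel <- covariate_panel(rost, publications = pubs, site_distances = sites)
write_panel(panel, out)

for (cv in panel) {
  off <- row(cv$values) != col(cv$values)
  cat(sprintf("%-28s %-10s mean %8.3f  masked %d\n", cv$name, cv$kind,
              mean(cv$values[off & !cv$mask]),
              sum(cv$mask[off])))
}
cat(sprintf("panel written under %s\n", out))
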