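#!/usr/bin/env Rscript
# Ingest the simulated survey files, rebuild the valued and dichotomized
# networks, and produce the descriptive outputs: the two-column network
# summary, the dyad census, the attribute summary, and a GraphML export.

suppressPackageStartupMessages(library(collabnet))

data_dir <- "results/study/data"
out <- "results/study"

rost <- read_roster(file.path(data_dir, "roster.csv"))
noms <- read_nominations(file.path(data_dir, "nominations.csv"), rost)
cat(sprintf("nominations: %d kept, %d off-roster excluded\n",
            nrow(noms$nominations), noms$n_off_roster))

net <- build_valued_network(rost, noms$nominations)
bin <- dichotomize(net, threshold = 1)

sv <- network_summary(net)
sb <- network_summary(bin)
write_summary(sv, sb, file.path(out, "network_summary.tsv"),
              file.path(out, "network_summary.json"))
cen <- dyad_census(bin)
cat(sprintf("valued density (mean x100) %.2f, arc density %.2f%%\n",
            sv$density_pct, sb$density_pct))
cat(sprintf("arc reciprocity %.2f%%, census: %d mutual / %d asymmetric / %d null\n",
            sb$reciprocated_ties_pct, cen$mutual, cen$asymmetric, cen$null))

attr_tab <- summarize_attributes(rost)
utils::write.table(attr_tab, file.path(out, "attribute_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_graphml(bin, rost, file.path(out, "network.graphml"))
cat(sprintf("descriptives written under %s\n", out))
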