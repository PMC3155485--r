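#!/usr/bin/env Rscript
# Simulate a survey-shaped study: 297 physicians across six hospitals and
# three directorates, attributes drawn from the published marginals, and a
# directed valued collaboration network generated by the planted logistic
# tie model. Writes the study inputs in the same CSV dialects the ingest
# path reads, so every later step consumes them unchanged.

suppressPackageStartupMessages(library(collabnet))

seed <- 20260923L
out <- "results/study/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config(n_nodes = 297, seed = seed)
sim <- simulate_study(cfg)

write_roster(sim$roster, file.path(out, "roster.csv"))
write_publications(sim$publications, file.path(out, "publications.csv"))
write_site_distances(sim$site_distances, file.path(out, "site_distances.csv"))
write_matrix(sim$network, file.path(out, "network_valued.tsv"))

# nomination edge list equivalent to the generated network, for the ingest
# path
idx <- which(sim$network > 0, arr.ind = TRUE)
noms <- data.frame(ego = rownames(sim$network)[idx[, 1]],
                   alter = colnames(sim$network)[idx[, 2]],
                   strength = sim$network[idx])
noms <- noms[order(noms$ego, noms$alter), ]
utils::write.csv(noms, file.path(out, "nominations.csv"), row.names = FALSE)

b <- dichotomize(sim$network)
cat(sprintf("simulated %d physicians, %d nominations\n",
            nrow(sim$roster), nrow(noms)))
cat(sprintf("arc density %.2f%%, valued mean x100 = %.2f\n",
            100 * sum(b) / (297 * 296),
            network_summary(sim$network)$density_pct))
cat(sprintf("inputs written under %s\n", out))
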