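#!/usr/bin/env Rscript
# Step 1: generate the synthetic cross-reference snapshot the downstream
# audits run on. Six databases of 200 identifiers each, with a realistic
# synonym-count distribution, 5% planted ambiguous names, 10% of
# identifiers per database pair sharing a MNXRef identifier, five planted
# cross-database name conflicts and two planted synonym chains. The
# generator also writes its independently counted ground truth, which the
# later steps are checked against.

suppressPackageStartupMessages(library(xrefaudit))

out_dir <- "results/simulated"
cfg <- synthetic_config(seed = 20181031 %% 1000L)
gen <- run_simulate(cfg, out_dir, quiet = TRUE)

cat(sprintf("simulated %d records across %d databases -> %s\n",
            nrow(gen$records), cfg$n_databases, gen$files[["records"]]))
cat(sprintf("planted: %d cross-database conflicts, %d synonym chains\n",
            cfg$n_cross_db_conflicts, cfg$n_chains))
cat(sprintf("ground truth written to %s\n", gen$files[["truth"]]))
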