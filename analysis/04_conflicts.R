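#!/usr/bin/env Rscript
# Step 4: inconsistency detection. First on the curated real-world examples
# (the succinate/sucrose "suc", proton/histidine "H", four-way "tmp" and
# "PPP" clashes), then on the simulated snapshot, where the planted
# conflicts and synonym chains must be recovered.

suppressPackageStartupMessages(library(xrefaudit))

example_file <- system.file("extdata", "conflict_examples.tsv", package = "xrefaudit")
res_ex <- run_conflicts(example_file, "results/conflicts_examples", quiet = TRUE)
nms <- unique(na.omit(vapply(res_ex$findings, `[[`, "", "name")))
cat(sprintf("curated examples: %d findings; conflicting abbreviations: %s\n",
            length(res_ex$findings), paste(sort(nms), collapse = ", ")))

input <- "results/simulated/chem_xref_synthetic.tsv"
if (!file.exists(input)) stop("run analysis/01_simulate.R first")
res <- run_conflicts(input, "results/conflicts_simulated", quiet = TRUE)
truth <- jsonlite::fromJSON("results/simulated/ground_truth.json",
                            simplifyVector = FALSE)
found <- vapply(res$findings, `[[`, "", "name")
planted <- vapply(truth$conflicts, function(x) x$name, "")

kinds <- table(vapply(res$findings, `[[`, "", "kind"))
cat(sprintf("simulated snapshot: %d findings (%s)\n", length(res$findings),
            paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", ")))
cat(sprintf("planted conflicts recovered: %d/%d\n",
            sum(planted %in% found), length(planted)))
cat(sprintf("findings reports: %s\n",
            paste(c(res_ex$files, res$files), collapse = ", ")))
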