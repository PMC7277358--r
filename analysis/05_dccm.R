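#!/usr/bin/env Rscript
# Dynamic cross-correlation maps of the paired block-correlated
# trajectories, with the two-region summary used to compare wild-type
# and mutant coupling: within 455-832 and between 455-832 / 932-1300.
# The block scenarios carry no rigid-body motion, so the maps are
# computed on the raw (unfitted) displacements.

library(splicedyn)

seed <- 1L
out <- "results/dccm"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scen <- sample_paired_scenarios(seed = seed, n_frames = 600L)
r1 <- scen$regions[[1]]; r2 <- scen$regions[[2]]

stats <- list()
for (sys in c("wild_type", "mutant")) {
  m <- compute_dccm(scen[[sys]]$block$trajectory, superpose = FALSE)
  write_dccm(m, file.path(out, paste0(sys, "_dccm.tsv")),
             png_path = file.path(out, paste0(sys, "_dccm.png")))
  stats[[sys]] <- c(within = block_stat(m, r1),
                    between = block_stat(m, r1, r2))
  cat(sprintf("%s: mean DCC within %d-%d = %+.3f; between regions = %+.3f\n",
              sys, r1[1], r1[2], stats[[sys]]["within"],
              stats[[sys]]["between"]))
}

cat(sprintf("within-region coupling drops %.3f -> %.3f in the mutant;\n",
            stats$wild_type["within"], stats$mutant["within"]))
cat(sprintf("anti-correlation between regions attenuates %+.3f -> %+.3f\n",
            stats$wild_type["between"], stats$mutant["between"]))
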