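#!/usr/bin/env Rscript
# Build the synthetic study system: a small genome whose recently active TE
# families are collapsed in the assembly, plus read alignments whose depth
# encodes the collapse. Everything downstream (02-04) runs off these files.

suppressMessages(library(tecensus))

outdir <- "results/world"
cfg <- sim_config(seed = 7)                      # 5 x 200 kb, 6 families, C = 50x
world <- build_world(cfg)
paths <- write_world(world, outdir)
simulate_alignments(world, "depth", path = file.path(outdir, "depth.tsv"))

lens <- vapply(world$assembly, nchar, 0L)
write.table(data.frame(scaffold = names(lens), length = as.integer(lens)),
            file.path(outdir, "scaffold_lengths.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rep <- truth_report(world$truth)
write_tsv_prov(rep, file.path(outdir, "truth_report.tsv"),
               list(seed = cfg$seed, stage = "simulate"))

message(sprintf("true genome %.0f kb; collapsed assembly %.0f kb (%d of %d TE copies retained)",
                sum(nchar(world$true_genome)) / 1e3,
                sum(nchar(world$assembly)) / 1e3,
                sum(world$truth$families$m), sum(world$truth$families$n)))
message(sprintf("TE mass: true %.1f kb, assembled %.1f kb -> expected overall factor %.2f",
                sum(world$truth$families$true_bp) / 1e3,
                sum(world$truth$families$assembled_bp) / 1e3,
                rep$expected_factor[rep$level == "total"]))
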