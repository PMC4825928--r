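#!/usr/bin/env Rscript
# Quantify retention: count transcript/intron/junction reads per sample,
# compute gene CPM and per-intron retention levels (intron reads over
# transcript reads), and apply the CPM >= 10 expression filter. Reads the
# simulated study from results/data/ and writes results/retention.tsv.

suppressMessages(library(spliceff))

data_dir <- "results/data"
model <- parse_annotation(file.path(data_dir, "genome", "genes.gff3"),
                          file.path(data_dir, "genome", "genome.fa"))
design <- read.delim(file.path(data_dir, "design.tsv"))
sams <- list.files(file.path(data_dir, "sam"), pattern = "\\.sam$",
                   full.names = TRUE)
names(sams) <- sub("\\.sam$", "", basename(sams))

catalog <- intron_catalog(model)
counts <- lapply(sams, function(p)
  count_reads(read_spliced_alignments(p), model, catalog = catalog))
retention <- retention_level(counts, cpm_threshold = 10)

if (!dir.exists("results")) dir.create("results")
write.table(retention, "results/retention.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(counts, "results/data/counts.rds")   # reused by later steps

message("library sizes: ",
        paste(names(counts), vapply(counts, `[[`, 0, "library_size"),
              sep = "=", collapse = ", "))
message("mean wild-type IR: ",
        signif(mean(retention$ir[grepl("^WT", retention$sample)],
                    na.rm = TRUE), 3),
        "; mean mutant IR: ",
        signif(mean(retention$ir[grepl("^MUT", retention$sample)],
                    na.rm = TRUE), 3))
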