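#!/usr/bin/env Rscript
# Stage 3 — map sites onto the ortholog alignments and score
# conservation.
#
# Selects every alignment column carrying at least one observed
# phosphosite, computes the 11-mer window identity of each reference
# site against every ortholog, averages them, and calls sites with
# average similarity > 0.5 conserved.

suppressPackageStartupMessages(library(phosevo))

data_dir <- "results/data"
out <- "results/conservation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fa <- list.files(data_dir, pattern = "^proteome_.*\\.fasta$",
                 full.names = TRUE)
proteome <- do.call(rbind, lapply(fa, read_proteome_fasta))
map <- read_ortholog_map(file.path(data_dir, "ortholog_map.tsv"))
groups <- read_ortholog_groups(map, file.path(data_dir, "alignments"),
                               proteome = proteome)
catalog <- read_site_table(file.path("results/integrate",
                                     "merged_catalog.tsv"))

aligned <- do.call(rbind, c(lapply(groups, select_aligned_acceptor_sites,
                                   catalog = catalog),
                            make.row.names = FALSE))
write.table(aligned, file.path(out, "aligned_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cons <- site_conservation(aligned, groups, proteome, "Dmel")
write.table(cons, file.path(out, "conservation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

bins <- bin_sites_by_identity(cons$average_similarity)
cat(sprintf("Aligned %d phospho-acceptor columns; %d carry an observed Dmel site.\n",
            length(unique(paste(aligned$group_id, aligned$column))),
            nrow(cons)))
cat(sprintf("%d of %d Dmel sites (%.1f%%) are conserved (average similarity > 0.5).\n",
            sum(cons$conserved), nrow(cons),
            100 * mean(cons$conserved)))
cat("Sites per identity bin (nested cutoffs):\n")
print(bins$counts, row.names = FALSE)
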