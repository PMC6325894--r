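#!/usr/bin/env Rscript
# Stage 7 — proximity of conserved phosphosites to disease variants.
#
# Reference phosphosites are carried through the alignment to the
# comparator species that bears the variant annotations; for each
# identity cutoff the fraction of sites within 10 residues of a variant
# is tabulated (acceptor-conserved and acceptor-lost strata separately),
# and the high-identity stratum is tested for enrichment against the
# below-cutoff baseline.

suppressPackageStartupMessages(library(phosevo))

out <- "results/disease"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cons <- read.delim(file.path("results/conservation", "conservation.tsv"))
aligned <- read.delim(file.path("results/conservation",
                                "aligned_sites.tsv"))
variants <- read_variant_table(file.path("results/data", "variants.tsv"))

comp <- "Dvir"
al <- aligned[aligned$species == comp, ]
idx <- match(paste(cons$group_id, cons$column),
             paste(al$group_id, al$column))
sites <- data.frame(protein_id = al$protein_id[idx],
                    position = al$position[idx],
                    identity = cons[[paste0("sim_", comp)]],
                    acceptor_conserved =
                      !is.na(cons[[paste0("class_", comp)]]) &
                      cons[[paste0("class_", comp)]] %in%
                      c("identical_acceptor",
                        "identical_acceptor_observed_both",
                        "acceptor_class_changed"))
sites <- sites[!is.na(sites$protein_id) & !is.na(sites$position), ]

px <- proximity_by_identity(sites, variants)
write.table(px, file.path(out, "proximity_by_identity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
enr <- enrichment_test(sites, variants, identity_cutoff = 0.8)

cat(sprintf("%d reference phosphosites mapped onto %s coordinates; %d variants.\n",
            nrow(sites), comp, nrow(variants)))
cat("Fraction of sites within 10 residues of a variant, by identity cutoff and acceptor stratum:\n")
print(px, row.names = FALSE, digits = 3)
cat(sprintf("Enrichment at identity >= 0.8 vs below: %.3f vs %.3f proximal, OR %.2f, p = %.3g\n",
            enr$fraction_high, enr$fraction_low, enr$odds_ratio,
            enr$p_value))
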