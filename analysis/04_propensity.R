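#!/usr/bin/env Rscript
# Stage 4 — train the phosphorylation-propensity models.
#
# One model per acceptor class (pooled S+T, and Y) for the reference
# species: 40 kinase-motif PSSM features, deterministic hinge-loss
# classifier, logistic calibration. Observed sites are pinned to
# propensity 1; every remaining acceptor receives a calibrated 0-1
# score.

suppressPackageStartupMessages(library(phosevo))

data_dir <- "results/data"
out <- "results/propensity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fa <- list.files(data_dir, pattern = "^proteome_.*\\.fasta$",
                 full.names = TRUE)
proteome <- do.call(rbind, lapply(fa, read_proteome_fasta))
prot <- proteome[proteome$species == "Dmel", ]
catalog <- read_site_table(file.path("results/integrate",
                                     "merged_catalog.tsv"))
cat_ref <- catalog[catalog$species == "Dmel", ]
bank <- default_pssm_bank()

scored <- list()
for (cl in c("ST", "Y")) {
  ts <- assemble_training_sets(cat_ref, prot, cl, seed = 2026L)
  withr::with_seed(2027L, {
    tr_p <- sample(nrow(ts$positives), floor(0.7 * nrow(ts$positives)))
    tr_n <- sample(nrow(ts$negatives), floor(0.7 * nrow(ts$negatives)))
  })
  model <- train_propensity_model(ts$positives[tr_p, ],
                                  ts$negatives[tr_n, ], prot, bank,
                                  species = "Dmel", class = cl)
  save_propensity_model(model, file.path(out,
                                         paste0("model_", cl, ".json")))
  te <- rbind(ts$positives[-tr_p, ], ts$negatives[-tr_n, ])
  lab <- rep(c(TRUE, FALSE), c(nrow(ts$positives) - length(tr_p),
                               nrow(ts$negatives) - length(tr_n)))
  auc <- auc_score(predict_propensity(model, padded_windows(prot, te),
                                      FALSE, bank), lab)
  cat(sprintf("%s model: %d positives / %d negatives, held-out AUC %.3f\n",
              cl, length(tr_p), length(tr_n), auc))

  acc <- all_acceptor_sites(prot, cl)
  obs <- paste(acc$protein_id, acc$position) %in%
    paste(cat_ref$protein_id, cat_ref$position)
  acc$propensity <- predict_propensity(model,
                                       padded_windows(prot, acc),
                                       obs, bank)
  acc$observed <- obs
  scored[[cl]] <- acc
}
scores <- do.call(rbind, c(scored, make.row.names = FALSE))
write.table(scores, file.path(out, "propensity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Scored %d acceptors (%d observed, pinned to 1); mean score of unobserved acceptors %.3f.\n",
            nrow(scores), sum(scores$observed),
            mean(scores$propensity[!scores$observed])))
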