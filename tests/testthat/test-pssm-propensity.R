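# PSSM feature scoring and the propensity classifier.

test_that("score_features sums the motif weights along the window", {
  # all-zero PSSM -> feature 0
  zero <- pssm_bank(data.frame(kinase = "Z", acceptor_class = "ST",
                               offset = 0L, residue = "A", weight = 0))
  w <- extract_window("AAAAASAAAAA", 6)
  expect_equal(unname(score_features(w, zero)[1, 1]), 0)

  # single-cell matrix: weight 1 at (offset -2, P)
  one <- pssm_bank(data.frame(kinase = "K1", acceptor_class = "ST",
                              offset = -2L, residue = "P", weight = 1))
  wp <- extract_window("AAAPASAAAAA", 6)  # P at offset -2
  expect_equal(unname(score_features(wp, one)[1, 1]), 1)
  wn <- extract_window("AAAAASAAAAA", 6)
  expect_equal(unname(score_features(wn, one)[1, 1]), 0)

  # class mismatch errors
  y <- extract_window("AAAAAYAAAAA", 6)
  expect_error(score_features(y, one), "acceptor")
})

test_that("features equal the brute-force double loop on random banks", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      cells <- data.frame(
        kinase = sample(c("k1", "k2", "k3"), 30, TRUE),
        acceptor_class = "ST",
        offset = sample(-5:5, 30, TRUE),
        residue = sample(c("A", "R", "P", "E", "L"), 30, TRUE),
        weight = round(runif(30, -2, 2), 2))
      cells <- cells[!duplicated(cells[, c("kinase", "offset",
                                           "residue")]), ]
      bank <- pssm_bank(cells)
      s <- random_protein(30)
      pos <- acceptor_positions(s, "ST")
      if (!length(pos)) next
      p <- pos[1]
      w <- extract_window(s, p)
      got <- score_features(w, bank)
      for (k in bank$kinases) {
        acc <- 0
        for (off in -5:5) {
          at <- p + off
          if (at < 1 || at > nchar(s)) next
          r <- substr(s, at, at)
          hit <- cells$kinase == k & cells$offset == off &
            cells$residue == r
          if (any(hit)) acc <- acc + sum(cells$weight[hit])
        }
        expect_equal(unname(got[1, k]), acc)
      }
    }
  })
})

test_that("the shipped bank fixture equals the in-code default bank", {
  f <- system.file("extdata", "pssm_bank_v1.tsv", package = "phosevo")
  expect_true(nzchar(f))
  shipped <- read_pssm_bank(f)
  built <- default_pssm_bank()
  expect_identical(shipped$W, built$W)
  expect_identical(shipped$kinases, built$kinases)
  expect_equal(length(built$kinases), 40L)
  expect_equal(sum(built$acceptor_class == "Y"), 10L)
})

test_that("training sets cap at availability, are seed-stable and label-correct", {
  s <- shared_study()
  prot <- s$families$proteome[s$families$proteome$species == "Dmel", ]
  cat <- s$merged[s$merged$species == "Dmel" & !s$merged$ambiguous, ]
  ts <- assemble_training_sets(cat, prot, "ST", seed = 5)
  # detected < 2000 -> positives capped at availability
  n_det <- length(unique(paste(cat$protein_id, cat$position)[
    acceptor_class(cat$residue) == "ST"]))
  expect_equal(nrow(ts$positives), n_det)
  n_avail <- nrow(all_acceptor_sites(prot, "ST")) - n_det
  expect_equal(nrow(ts$negatives), min(2000L, n_avail))
  # same seed twice -> identical samples
  ts2 <- assemble_training_sets(cat, prot, "ST", seed = 5)
  expect_identical(ts, ts2)
  # membership oracle: positives are detected, negatives never detected
  det_key <- paste(cat$protein_id, cat$position)
  expect_true(all(paste(ts$positives$protein_id,
                        ts$positives$position) %in% det_key))
  expect_false(any(paste(ts$negatives$protein_id,
                         ts$negatives$position) %in% det_key))
  expect_true(all(ts$negatives$residue %in% c("S", "T")))
  expect_error(assemble_training_sets(cat[0, ], prot, "ST"), "no detected")
})

test_that("the margin classifier separates a separable toy problem exactly", {
  # two windows generating the classes: positives have P at +1
  prot <- data.frame(protein_id = c("pp", "pn"), species = "Dmel",
                     gene_id = NA,
                     sequence = c(strrep("ASPAA", 20), strrep("ASAAA", 20)),
                     stringsAsFactors = FALSE)
  bank <- pssm_bank(data.frame(kinase = "K1", acceptor_class = "ST",
                               offset = 1L, residue = "P", weight = 1))
  pos <- data.frame(species = "Dmel", protein_id = "pp",
                    position = acceptor_positions(prot$sequence[1], "ST"))
  neg <- data.frame(species = "Dmel", protein_id = "pn",
                    position = acceptor_positions(prot$sequence[2], "ST"))
  m <- train_propensity_model(pos, neg, prot, bank, class = "ST")
  sp <- predict_propensity(m, padded_windows(prot, pos), FALSE, bank)
  sn <- predict_propensity(m, padded_windows(prot, neg), FALSE, bank)
  expect_true(min(sp) > max(sn))  # training accuracy 1 at any cut between
  # determinism: identical inputs -> bitwise identical weights
  m2 <- train_propensity_model(pos, neg, prot, bank, class = "ST")
  expect_identical(m$weights, m2$weights)
  expect_identical(m$calibration, m2$calibration)
})

test_that("a single planted motif earns the largest absolute weight", {
  # a generator whose phosphosites all carry one motif out of a small
  # bank of distinct ST archetypes
  bank <- pssm_bank(data.frame(
    kinase = rep(c("ProDir", "Basoph", "Acidoph", "HydroPh"), each = 2),
    acceptor_class = "ST",
    offset = c(1L, -2L, -3L, -2L, 3L, 1L, -1L, 4L),
    residue = c("P", "P", "R", "R", "E", "E", "L", "F"),
    weight = c(2, 1, 2, 1.2, 2, 1.2, 1.6, 1.2)))
  planted <- pssm_bank(data.frame(kinase = "Basoph",
                                  acceptor_class = "ST",
                                  offset = c(-3L, -2L),
                                  residue = "R", weight = c(2, 1.2)))
  cfg <- sim_config(seed = 107, n_groups = 30, len_range = c(200L, 350L),
                    bank = planted, labile_site_rate = 0,
                    functional_site_rate = 0.2)
  fam <- simulate_families(cfg)
  catal <- simulate_detection(fam, cfg)
  prot <- fam$proteome[fam$proteome$species == "Dmel", ]
  cat_ref <- catal[catal$species == "Dmel", ]
  ts <- assemble_training_sets(cat_ref, prot, "ST", seed = 5)
  m <- train_propensity_model(ts$positives, ts$negatives, prot, bank,
                              class = "ST")
  expect_equal(names(which.max(abs(m$weights))), "Basoph")
  expect_gt(m$weights[["Basoph"]], 0)
})

test_that("propensity predictions are calibrated, pinned and reload-stable", {
  s <- shared_study()
  prot <- s$families$proteome[s$families$proteome$species == "Dmel", ]
  cat <- s$merged[s$merged$species == "Dmel" & !s$merged$ambiguous, ]
  ts <- assemble_training_sets(cat, prot, "ST", seed = 5)
  m <- train_propensity_model(ts$positives, ts$negatives, prot,
                              s$config$bank, species = "Dmel",
                              class = "ST")
  # observed sites -> exactly 1
  w <- padded_windows(prot, ts$positives[1:10, ])
  expect_identical(predict_propensity(m, w, TRUE, s$config$bank),
                   rep(1, 10))
  # bounds on many random acceptor windows
  acc <- all_acceptor_sites(prot, "ST")
  acc <- acc[seq_len(min(10000, nrow(acc))), ]
  p <- predict_propensity(m, padded_windows(prot, acc), FALSE,
                          s$config$bank)
  expect_true(all(p >= 0 & p <= 1))
  # a strong positive exemplar outranks a random negative exemplar
  p_pos <- predict_propensity(m, padded_windows(prot, ts$positives),
                              FALSE, s$config$bank)
  p_neg <- predict_propensity(m, padded_windows(prot, ts$negatives),
                              FALSE, s$config$bank)
  expect_gte(max(p_pos), max(p_neg))
  expect_gt(mean(p_pos), mean(p_neg))
  # JSON round trip preserves predictions to serialisation precision
  tmp <- withr::local_tempfile(fileext = ".json")
  save_propensity_model(m, tmp)
  m2 <- load_propensity_model(tmp)
  expect_equal(predict_propensity(m2, w, FALSE, s$config$bank),
               predict_propensity(m, w, FALSE, s$config$bank),
               tolerance = 1e-12)
  expect_equal(names(m2$weights), names(m$weights))
})

test_that("rank AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    sc <- c(rnorm(60, 1), rnorm(80))
    lab <- rep(c(TRUE, FALSE), c(60, 80))
    expect_equal(auc_score(sc, lab),
                 as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                                direction = "<"))))
  })
})
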