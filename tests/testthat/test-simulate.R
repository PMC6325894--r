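# The simulator: determinism, limiting cases and rate recovery.

test_that("identical configs give byte-identical outputs", {
  cfg <- sim_config(seed = 81, n_groups = 6, len_range = c(80L, 120L))
  a <- simulate_families(cfg)
  b <- simulate_families(cfg)
  expect_identical(a, b)
  expect_identical(simulate_detection(a, cfg), simulate_detection(b, cfg))
  expect_identical(simulate_variants(a, cfg), simulate_variants(b, cfg))
})

test_that("zero substitution makes all species identical and windows perfect", {
  cfg <- sim_config(seed = 82, n_groups = 4, len_range = c(100L, 150L),
                    branch_sub = c(Dmel = 0, Dsim = 0, Dyak = 0, Dana = 0,
                                   Dpse = 0, Dvir = 0, spine = 0),
                    retention_prob = c(Dsim = 1, Dyak = 1, Dana = 1,
                                       Dpse = 1, Dvir = 1))
  fam <- simulate_families(cfg)
  for (g in fam$groups)
    expect_equal(length(unique(g$alignment)), 1L)
  # every functional site is 100% identical across the panel
  st <- fam$truth$status
  expect_true(all(st$acceptor_retained[st$type == "functional"]))
})

test_that("boost 1 removes the functional/neutral identity contrast", {
  diffs <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 900 + s, n_groups = 12,
                      len_range = c(150L, 250L),
                      functional_conservation_boost = 1,
                      retention_prob = c(Dsim = 1, Dyak = 1, Dana = 1,
                                         Dpse = 1, Dvir = 1))
    fam <- simulate_families(cfg)
    seqs <- setNames(fam$proteome$sequence,
                     paste(fam$proteome$species, fam$proteome$protein_id,
                           sep = "|"))
    st <- fam$truth$status
    idw <- function(rows) {
      ok <- !is.na(rows$position)
      mean(vapply(which(ok), function(i) {
        rw <- extract_window(seqs[[paste("Dmel",
                                         sub("^D\\w+_", "Dmel_",
                                             rows$protein_id[i]),
                                         sep = "|")]],
                             rows$position[i])
        window_identity(rw, extract_window(
          seqs[[paste(rows$species[i], rows$protein_id[i], sep = "|")]],
          rows$position[i]))
      }, numeric(1)))
    }
    fun <- st[st$species == "Dvir" & st$type == "functional", ]
    lab <- st[st$species == "Dvir" & st$type == "labile", ]
    idw(fun) - idw(lab)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("a lone mutated branch realises its substitution probability", {
  p <- 0.3
  cfg <- sim_config(seed = 83, n_groups = 180,
                    len_range = c(500L, 700L),
                    phosphoprotein_fraction = 0,  # no protected windows
                    branch_sub = c(Dmel = 0, Dsim = 0, Dyak = 0, Dana = 0,
                                   Dpse = 0, Dvir = p, spine = 0),
                    retention_prob = c(Dsim = 1, Dyak = 1, Dana = 1,
                                       Dpse = 1, Dvir = 1))
  fam <- simulate_families(cfg)
  # with every other branch silent, Dmel equals the ancestor, so the
  # Dmel/Dvir mismatch fraction is exactly Dvir's branch realisation
  mel <- fam$proteome$sequence[fam$proteome$species == "Dmel"]
  vir <- fam$proteome$sequence[fam$proteome$species == "Dvir"]
  n_tot <- sum(nchar(mel))
  expect_gt(n_tot, 1e5)
  n_diff <- sum(vapply(seq_along(mel), function(i) {
    a <- seq_chars(mel[i]); b <- seq_chars(vir[i])
    sum(a != b)
  }, numeric(1)))
  expect_lt(abs(n_diff / n_tot - p), 0.02)
})

test_that("detection is exhaustive at s = 1, silent at s = 0, binomial between", {
  cfg1 <- sim_config(seed = 84, n_groups = 30, len_range = c(300L, 500L),
                     phosphoprotein_fraction = 1,
                     functional_site_rate = 0.15, labile_site_rate = 0,
                     detection_sensitivity = c(Dsim = 1, Dyak = 1,
                                               Dana = 1, Dpse = 1,
                                               Dvir = 1),
                     ref_source_sensitivity = c(ds1 = 1))
  fam <- simulate_families(cfg1)
  cat1 <- simulate_detection(fam, cfg1)
  truth <- fam$truth$status[fam$truth$status$true_phospho, ]
  expect_setequal(paste(cat1$species, cat1$protein_id, cat1$position),
                  paste(truth$species, truth$protein_id, truth$position))
  # peptides anchor the reported residue at the reported offset
  expect_true(all(substr(cat1$peptide, cat1$peptide_offset,
                         cat1$peptide_offset) == cat1$residue))

  cfg0 <- sim_config(seed = 84, n_groups = 30, len_range = c(300L, 500L),
                     phosphoprotein_fraction = 1,
                     functional_site_rate = 0.15, labile_site_rate = 0,
                     detection_sensitivity = c(Dsim = 0, Dyak = 0,
                                               Dana = 0, Dpse = 0,
                                               Dvir = 0),
                     ref_source_sensitivity = c(ds1 = 0))
  expect_equal(nrow(simulate_detection(simulate_families(cfg0), cfg0)), 0L)

  # intermediate s: detected fraction within exact binomial 99% bounds
  s <- 0.6
  cfg <- sim_config(seed = 85, n_groups = 150, len_range = c(400L, 600L),
                    phosphoprotein_fraction = 1,
                    functional_site_rate = 0.30, labile_site_rate = 0,
                    detection_sensitivity = c(Dsim = s, Dyak = 0,
                                              Dana = 0, Dpse = 0,
                                              Dvir = 0),
                    ref_source_sensitivity = c(ds1 = 0))
  fam <- simulate_families(cfg)
  catal <- simulate_detection(fam, cfg)
  n_true <- sum(fam$truth$status$species == "Dsim" &
                  fam$truth$status$true_phospho)
  n_det <- sum(catal$species == "Dsim")
  expect_gt(n_true, 2000)
  lo <- qbinom(0.005, n_true, s); hi <- qbinom(0.995, n_true, s)
  expect_gte(n_det, lo)
  expect_lte(n_det, hi)
})

test_that("variant placement is uniform at factor 1 and enriched at factor 2", {
  # factor 1: pooled relative positions pass a 10-bin uniformity test
  pool <- list()
  for (s in 1:4) {
    cfg <- sim_config(seed = 700 + s, n_groups = 25,
                      len_range = c(200L, 400L),
                      variant_enrichment = 1, variant_rate = 0.03)
    fam <- simulate_families(cfg)
    v <- simulate_variants(fam, cfg)
    L <- nchar(setNames(fam$proteome$sequence, fam$proteome$protein_id))
    pool[[s]] <- (v$position - 0.5) / L[v$protein_id]
  }
  u <- unlist(pool)
  expect_gt(length(u), 500)
  ct <- table(cut(u, seq(0, 1, 0.1)))
  expect_gt(chisq.test(ct)$p.value, 0.01)

  # zero rate -> empty table
  cfg0 <- sim_config(seed = 86, n_groups = 5, variant_rate = 0)
  fam0 <- simulate_families(cfg0)
  expect_equal(nrow(simulate_variants(fam0, cfg0)), 0L)

  # factor 2: realised near/far rate ratio recovers the enrichment
  cfg2 <- sim_config(seed = 87, n_groups = 220,
                     len_range = c(200L, 400L),
                     phosphoprotein_fraction = 1,
                     functional_site_rate = 0.10,
                     variant_rate = 0.04, variant_enrichment = 2,
                     retention_prob = c(Dsim = 1, Dyak = 1, Dana = 1,
                                        Dpse = 1, Dvir = 1))
  fam2 <- simulate_families(cfg2)
  v2 <- simulate_variants(fam2, cfg2)
  expect_gt(nrow(v2), 2000)
  ratio <- attr(v2, "near_rate") / attr(v2, "far_rate")
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("config validation rejects bad probabilities and unknown fields", {
  expect_error(sim_config(seed = 1, variant_rate = 1.5), "probabilities")
  expect_error(sim_config(seed = 1, variant_enrichment = 0.5), ">= 1")
  expect_error(sim_config(seed = 1, nonsense = 2), "unknown")
})

test_that("deletion mode punches recorded gaps without breaking coordinates", {
  cfg <- sim_config(seed = 88, n_groups = 8, deletion_rate = 0.02)
  fam <- simulate_families(cfg)
  has_gap <- any(grepl("-", unlist(lapply(fam$groups,
                                          function(g) g$alignment)),
                       fixed = TRUE))
  expect_true(has_gap)
  # ortholog_group construction already checks that rows ungap to the
  # proteome; spot-check a round trip through the column maps
  g <- fam$groups[[1]]
  sp <- g$members$species[1]
  L <- nchar(gsub("-", "", g$alignment[[sp]]))
  pos <- unique(c(1L, max(1L, L %/% 2), L))
  expect_equal(column_to_position(g, sp, position_to_column(g, sp, pos)),
               pos)
})
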