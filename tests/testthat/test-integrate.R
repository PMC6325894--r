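# Multi-source integration: consolidation, peptide remapping, catalog
# merging and overlap accounting.

test_that("consolidate_proteome collapses identical sequences deterministically", {
  p <- toy_proteome()
  out <- consolidate_proteome(p)
  # pA and pC share a sequence; smallest id wins
  expect_equal(nrow(out$proteome), 2L)
  expect_setequal(out$proteome$protein_id, c("pA", "pB"))
  expect_equal(out$id_map$representative_id[out$id_map$protein_id == "pC"],
               "pA")
  expect_equal(nrow(out$id_map), 3L)

  # all distinct -> identity mapping
  q <- p[1:2, ]
  out2 <- consolidate_proteome(q)
  expect_equal(out2$proteome$protein_id, out2$id_map$representative_id)
  expect_equal(nrow(out2$proteome), 2L)

  # empty input -> empty proteome
  expect_equal(nrow(consolidate_proteome(p[0, ])$proteome), 0L)

  # conflicting duplicate ids raise an error naming the id
  bad <- rbind(p, toy_proteome()[1, ])
  bad$sequence[4] <- "MMMM"
  expect_error(consolidate_proteome(bad), "pA")
})

test_that("consolidation representative count matches a brute-force string set", {
  withr::with_seed(7, {
    seqs <- replicate(12, random_protein(30))
    picks <- sample(seqs, 50, replace = TRUE)  # planted duplicates
    p <- data.frame(protein_id = sprintf("p%02d", 1:50), species = "Dmel",
                    gene_id = NA_character_, sequence = picks,
                    stringsAsFactors = FALSE)
  })
  out <- consolidate_proteome(p)
  expect_equal(nrow(out$proteome), length(unique(picks)))
  # every id maps to a representative carrying the same sequence
  rep_seq <- out$proteome$sequence[match(out$id_map$representative_id,
                                         out$proteome$protein_id)]
  expect_equal(rep_seq, p$sequence[match(out$id_map$protein_id,
                                         p$protein_id)])
})

test_that("peptide remapping recovers coordinates and flags ambiguity", {
  p <- toy_proteome()[1:2, ]
  # peptide equal to a full protein, offset k -> (protein, k)
  m <- remap_peptide_site(p$sequence[1], 4L, p)
  expect_equal(m$protein_id, "pA")
  expect_equal(m$position, 4L)
  expect_false(m$ambiguous[1])
  # absent peptide -> zero rows
  expect_equal(nrow(remap_peptide_site("WWWWW", 1L, p)), 0L)
  # duplicate sequences -> all matches, flagged ambiguous
  m2 <- remap_peptide_site("RSPAY", 2L, toy_proteome())
  expect_equal(nrow(m2), 2L)
  expect_true(all(m2$ambiguous))
  expect_equal(sort(m2$protein_id), c("pA", "pC"))
})

test_that("remapped peptides match a brute-force substring scan and round-trip", {
  withr::with_seed(11, {
    prot <- data.frame(protein_id = sprintf("p%d", 1:8), species = "Dmel",
                       gene_id = NA_character_,
                       sequence = replicate(8, random_protein(120)),
                       stringsAsFactors = FALSE)
    for (i in 1:40) {
      j <- sample(8, 1)
      len <- sample(7:15, 1)
      start <- sample(120 - len + 1, 1)
      off <- sample(len, 1)
      pep <- substr(prot$sequence[j], start, start + len - 1)
      m <- remap_peptide_site(pep, off, prot)
      # brute force: scan every start position of every sequence
      brute <- list()
      for (k in 1:8) {
        L <- nchar(prot$sequence[k])
        for (s in seq_len(L - len + 1)) {
          if (substr(prot$sequence[k], s, s + len - 1) == pep)
            brute[[length(brute) + 1]] <- c(k, s + off - 1)
        }
      }
      brute <- do.call(rbind, brute)
      expect_equal(nrow(m), nrow(brute))
      expect_setequal(paste(m$protein_id, m$position),
                      paste(prot$protein_id[brute[, 1]], brute[, 2]))
      # round trip: re-extracting the peptide at reported coordinates
      for (r in seq_len(nrow(m))) {
        s <- prot$sequence[prot$protein_id == m$protein_id[r]]
        st <- m$position[r] - off + 1
        expect_identical(substr(s, st, st + len - 1), pep)
      }
    }
  })
})

test_that("merge_catalogs unions sources per key, order independently", {
  c1 <- rbind(toy_catalog_row("Dmel", "pA", 4, "S", "ds1"),
              toy_catalog_row("Dmel", "pA", 7, "Y", "ds1"))
  c2 <- rbind(toy_catalog_row("Dmel", "pA", 4, "S", "ds2"),
              toy_catalog_row("Dmel", "pB", 6, "T", "ds2"))
  # disjoint keys -> sizes add
  m_disjoint <- merge_catalogs(list(c1[2, ], c2[2, ]))
  expect_equal(nrow(m_disjoint), 2L)
  # same key in both -> one key, two sources
  m <- merge_catalogs(list(c1, c2))
  k <- paste(m$protein_id, m$position)
  expect_equal(sort(unique(m$source[k == "pA 4"])), c("ds1", "ds2"))
  # order independence
  m_rev <- merge_catalogs(list(c2, c1))
  expect_identical(m, m_rev)
  # residue disagreement errors with the key
  c3 <- toy_catalog_row("Dmel", "pA", 4, "T", "ds3")
  expect_error(merge_catalogs(list(c1, c3)), "Dmel\\|pA\\|4")
})

test_that("merged key set equals the brute-force union on random catalogs", {
  withr::with_seed(3, {
    mk <- function(src, n) {
      data.frame(species = "Dmel",
                 protein_id = sample(c("pA", "pB"), n, TRUE),
                 position = sample(1:12, n, TRUE), residue = "S",
                 ptm_type = "phospho", source = src, source_score = NA_real_,
                 peptide = NA_character_, peptide_offset = NA_integer_,
                 stringsAsFactors = FALSE)
    }
    cats <- lapply(c("a", "b", "c"), mk, n = 25)
  })
  m <- merge_catalogs(cats)
  got <- unique(paste(m$species, m$protein_id, m$position, m$ptm_type))
  want <- unique(unlist(lapply(cats, function(x)
    paste(x$species, x$protein_id, x$position, x$ptm_type))))
  expect_setequal(got, want)
  # no duplicated (key, source) pairs survive
  expect_false(any(duplicated(paste(m$protein_id, m$position, m$source))))
})

test_that("overlap_table matches hand enumeration and per-key tallies", {
  # single source -> overlap columns all zero
  single <- toy_catalog_row("Dmel", "pA", 4, "S", "only")
  t1 <- overlap_table(single)
  expect_equal(t1$n_overlap_ge1_other[t1$source == "only"], 0L)

  # three sources sharing exactly one common key
  shared <- do.call(rbind, lapply(c("s1", "s2", "s3"), function(s)
    toy_catalog_row("Dmel", "pA", 4, "S", s)))
  priv <- rbind(toy_catalog_row("Dmel", "pA", 7, "Y", "s1"),
                toy_catalog_row("Dmel", "pB", 6, "T", "s2"))
  tt <- overlap_table(rbind(shared, priv))
  r <- tt[tt$source == "s1", ]
  expect_equal(r$n_sites, 2L)
  expect_equal(r$n_overlap_ge1_other, 1L)
  expect_equal(r$n_overlap_ge2_other, 1L)
  all_row <- tt[tt$source == "All", ]
  expect_equal(all_row$n_sites, 3L)          # distinct keys
  expect_equal(all_row$n_overlap_ge1_other, 1L)  # >= 2 sources
  expect_equal(all_row$n_overlap_ge2_other, 1L)  # >= 3 sources

  # random catalog vs a brute-force per-key source tally
  withr::with_seed(5, {
    rc <- do.call(rbind, lapply(c("x", "y", "z"), function(s)
      data.frame(species = "Dmel",
                 protein_id = sample(c("pA", "pB"), 30, TRUE),
                 position = sample(1:10, 30, TRUE), residue = "S",
                 ptm_type = "phospho", source = s, source_score = NA_real_,
                 peptide = NA_character_, peptide_offset = NA_integer_,
                 stringsAsFactors = FALSE)))
  })
  rc <- merge_catalogs(list(rc))
  tr <- overlap_table(rc)
  key <- paste(rc$protein_id, rc$position)
  tally <- tapply(rc$source, key, function(s) length(unique(s)))
  for (src in c("x", "y", "z")) {
    keys <- unique(key[rc$source == src])
    expect_equal(tr$n_sites[tr$source == src], length(keys))
    expect_equal(tr$n_overlap_ge1_other[tr$source == src],
                 sum(tally[keys] >= 2))
    expect_equal(tr$n_overlap_ge2_other[tr$source == src],
                 sum(tally[keys] >= 3))
  }
  # monotone row structure
  expect_true(all(tr$n_overlap_ge2_other <= tr$n_overlap_ge1_other))
  expect_true(all(tr$n_overlap_ge1_other <= tr$n_sites))
})

test_that("site tables and proteome FASTA round-trip through disk", {
  tmp <- withr::local_tempdir()
  cat <- rbind(toy_catalog_row("Dmel", "pA", 4, "S", "ds1",
                               peptide = "RSPAY", peptide_offset = 2),
               toy_catalog_row("Dmel", "pB", 6, "T", "ds2"))
  f <- file.path(tmp, "sites.tsv")
  write_site_table(cat, f)
  back <- read_site_table(f)
  expect_equal(back$peptide[2], NA_character_)  # '.' -> NA
  expect_equal(back$position, cat$position)
  expect_equal(back$peptide[1], "RSPAY")

  p <- toy_proteome()
  fa <- file.path(tmp, "prot.fasta")
  write_proteome_fasta(p, fa)
  back_p <- read_proteome_fasta(fa)
  expect_equal(back_p$sequence, p$sequence)
  expect_equal(back_p$species, p$species)
  expect_equal(back_p$gene_id, p$gene_id)
})
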