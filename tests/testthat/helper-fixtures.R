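# Shared fixtures, all built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

# One moderate simulated study reused across test files.
shared_study <- function() {
  if (is.null(.fixture_cache$study)) {
    cfg <- sim_config(seed = 101L, n_groups = 40L)
    fam <- simulate_families(cfg)
    catalog <- simulate_detection(fam, cfg)
    merged <- merge_catalogs(lapply(split(catalog, catalog$source),
                                    remap_catalog,
                                    proteome = fam$proteome))
    .fixture_cache$study <- list(config = cfg, families = fam,
                                 catalog = catalog, merged = merged)
  }
  .fixture_cache$study
}

shared_aligned <- function() {
  if (is.null(.fixture_cache$aligned)) {
    s <- shared_study()
    .fixture_cache$aligned <-
      do.call(rbind, c(lapply(s$families$groups,
                              select_aligned_acceptor_sites,
                              catalog = s$merged),
                       make.row.names = FALSE))
  }
  .fixture_cache$aligned
}

# Small hand-built proteome: two species, conserved toy proteins.
toy_proteome <- function() {
  data.frame(
    protein_id = c("pA", "pB", "pC"),
    species = "Dmel",
    gene_id = c("gA", "gB", "gC"),
    sequence = c("MKRSPAYLLDDE",        # S at 4, Y at 7
                 "AAAAATPPRRSK",        # T at 6, S at 11
                 "MKRSPAYLLDDE"),       # duplicate of pA
    stringsAsFactors = FALSE)
}

toy_catalog_row <- function(species, protein_id, position, residue,
                            source = "ds1", peptide = NA_character_,
                            peptide_offset = NA_integer_,
                            ptm_type = "phospho") {
  data.frame(species = species, protein_id = protein_id,
             position = as.integer(position), residue = residue,
             ptm_type = ptm_type, source = source, source_score = 42,
             peptide = peptide,
             peptide_offset = as.integer(peptide_offset),
             stringsAsFactors = FALSE)
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# A two-species, two-group hand alignment fixture with known gaps.
toy_groups <- function() {
  prot <- data.frame(
    protein_id = c("Dmel_gX", "Dvir_gX", "Dmel_gY", "Dvir_gY"),
    species = c("Dmel", "Dvir", "Dmel", "Dvir"),
    gene_id = c("gX", "gX", "gY", "gY"),
    sequence = c("MSKRT", "MKRT", "AASPAYD", "AASPAYD"),
    stringsAsFactors = FALSE)
  gX <- ortholog_group(
    "gX",
    data.frame(species = c("Dmel", "Dvir"),
               protein_id = c("Dmel_gX", "Dvir_gX"),
               stringsAsFactors = FALSE),
    c(Dmel = "MSKRT", Dvir = "M-KRT"), proteome = prot)
  gY <- ortholog_group(
    "gY",
    data.frame(species = c("Dmel", "Dvir"),
               protein_id = c("Dmel_gY", "Dvir_gY"),
               stringsAsFactors = FALSE),
    c(Dmel = "AASPAYD", Dvir = "AASPAYD"), proteome = prot)
  list(proteome = prot, groups = list(gX = gX, gY = gY))
}
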