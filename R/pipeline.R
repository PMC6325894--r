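# End-to-end orchestration: simulate -> integrate -> map -> conserve ->
# propensity -> fnr -> evostats -> disease, writing every stage's table
# plus a machine-readable run manifest (config hash, file checksums,
# per-stage record counts). Stages run in dependency order; a failing
# stage leaves the completed outputs in place and the manifest names it.

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-study pipeline
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param identity_cutoffs identity bins for the disease analysis.
#' @param enrichment_cutoff identity stratum boundary for the headline
#'   variant-enrichment test (default 0.8).
#' @return the run manifest (list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir,
                         identity_cutoffs = c(0.2, 0.5, 0.8, 1.0),
                         enrichment_cutoff = 0.8) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- config$reference_species
  comp <- config$comparator_species
  files <- character()
  counts <- list()
  stages <- character()
  env <- new.env(parent = emptyenv())

  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest <- list(status = "failed", failed_stage = name,
                       error = conditionMessage(res),
                       stages = stages, counts = counts,
                       files = manifest_files(files))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(res), call. = FALSE)
    }
    stages <<- c(stages, name)
    res
  }
  add_file <- function(path) files <<- c(files, path)
  manifest_files <- function(files) {
    lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  }

  stage("simulate", function() {
    env$study <- simulate_study(config)
    fam <- env$study$families
    for (sp in unique(fam$proteome$species)) {
      p <- file.path(out_dir, paste0("proteome_", sp, ".fasta"))
      write_proteome_fasta(fam$proteome[fam$proteome$species == sp, ],
                           p)
      add_file(p)
    }
    add_file(write_site_table(env$study$catalog,
                              file.path(out_dir, "sites_raw.tsv")))
    add_file(write_ortholog_map(fam$ortholog_map,
                                file.path(out_dir, "ortholog_map.tsv")))
    write_ortholog_groups(fam$groups, file.path(out_dir, "alignments"))
    add_file(write_tsv(fam$truth$sites,
                       file.path(out_dir, "truth_sites.tsv")))
    counts$simulate <<- list(n_groups = length(fam$groups),
                             n_proteins = nrow(fam$proteome),
                             n_raw_records = nrow(env$study$catalog))
    TRUE
  })

  stage("integrate", function() {
    fam <- env$study$families
    # consolidate per species, then remap every peptide-bearing record
    cons <- lapply(split(fam$proteome, fam$proteome$species),
                   consolidate_proteome)
    env$proteome <- do.call(rbind, c(lapply(cons, `[[`, "proteome"),
                                     make.row.names = FALSE))
    per_source <- split(env$study$catalog, env$study$catalog$source)
    remapped <- lapply(per_source, remap_catalog, proteome = env$proteome)
    env$catalog <- merge_catalogs(remapped)
    validate_catalog(env$catalog[!env$catalog$ambiguous, ], env$proteome)
    env$overlap <- overlap_table(
      env$catalog[env$catalog$species == ref, , drop = FALSE])
    add_file(write_site_table(env$catalog,
                              file.path(out_dir, "merged_catalog.tsv")))
    add_file(write_tsv(env$overlap,
                       file.path(out_dir, "overlap_table.tsv")))
    counts$integrate <<- list(n_merged_records = nrow(env$catalog),
                              n_sources =
                                length(unique(env$catalog$source)))
    TRUE
  })

  stage("map_sites", function() {
    fam <- env$study$families
    env$aligned <- do.call(rbind, c(lapply(fam$groups,
      select_aligned_acceptor_sites, catalog = env$catalog),
      make.row.names = FALSE))
    add_file(write_tsv(env$aligned,
                       file.path(out_dir, "aligned_sites.tsv")))
    counts$map_sites <<- list(
      n_aligned_sites = length(unique(paste(env$aligned$group_id,
                                            env$aligned$column))))
    TRUE
  })

  stage("conserve", function() {
    env$conservation <- site_conservation(env$aligned,
                                          env$study$families$groups,
                                          env$proteome, ref)
    add_file(write_tsv(env$conservation,
                       file.path(out_dir, "conservation.tsv")))
    counts$conserve <<- list(n_sites = nrow(env$conservation),
                             n_conserved = sum(env$conservation$conserved))
    TRUE
  })

  stage("propensity", function() {
    prot_ref <- env$proteome[env$proteome$species == ref, , drop = FALSE]
    cat_ref <- env$catalog[env$catalog$species == ref &
                             !env$catalog$ambiguous, , drop = FALSE]
    bank <- config$bank
    preds <- list()
    for (cl in c("ST", "Y")) {
      ts <- assemble_training_sets(cat_ref, prot_ref, cl,
                                   seed = config$seed + 10L)
      model <- train_propensity_model(ts$positives, ts$negatives,
                                      prot_ref, bank, species = ref,
                                      class = cl,
                                      seed = config$seed + 10L)
      mp <- file.path(out_dir, paste0("propensity_model_", cl, ".json"))
      save_propensity_model(model, mp)
      add_file(mp)
      acc <- all_acceptor_sites(prot_ref, cl)
      obs <- paste(acc$protein_id, acc$position) %in%
        paste(cat_ref$protein_id, cat_ref$position)
      acc$propensity <- predict_propensity(
        model, padded_windows(prot_ref, acc, bank$flank), obs, bank)
      acc$observed <- obs
      preds[[cl]] <- acc
    }
    env$propensity <- do.call(rbind, c(preds, make.row.names = FALSE))
    add_file(write_tsv(env$propensity,
                       file.path(out_dir, "propensity.tsv")))
    counts$propensity <<- list(n_scored = nrow(env$propensity),
                               n_observed = sum(env$propensity$observed))
    TRUE
  })

  stage("fnr", function() {
    bench <- select_benchmark_sites(env$aligned,
                                    env$study$families$groups,
                                    env$proteome,
                                    species = config$species)
    env$fnr <- estimate_fnr_all(bench)
    add_file(write_tsv(env$fnr, file.path(out_dir, "fnr.tsv")))
    counts$fnr <<- list(n_benchmark = nrow(bench))
    TRUE
  })

  stage("evostats", function() {
    fam <- env$study$families
    cat_ref <- env$catalog[env$catalog$species == ref &
                             !env$catalog$ambiguous, , drop = FALSE]
    prot_ref <- env$proteome[env$proteome$species == ref, , drop = FALSE]
    phospho <- unique(cat_ref$protein_id)
    control <- setdiff(prot_ref$protein_id, phospho)
    rows <- lapply(setdiff(config$species, ref), function(tgt) {
      cmp <- ortholog_conservation_comparison(phospho, control,
                                              fam$ortholog_map, ref, tgt)
      data.frame(level = "protein", target_species = tgt,
                 n_phospho = length(phospho), n_control = length(control),
                 proportion_phospho = cmp$proportion_phospho,
                 proportion_control = cmp$proportion_control,
                 odds_ratio = cmp$odds_ratio, p_value = cmp$p_value,
                 stringsAsFactors = FALSE)
    })
    sites <- unique(cat_ref[, c("protein_id", "position", "residue")])
    ctrl_sites <- sample_control_acceptors(sites, prot_ref,
                                           seed = config$seed + 20L)
    srows <- lapply(setdiff(config$species, ref), function(tgt) {
      cmp <- site_conservation_comparison(sites, ctrl_sites, fam$groups,
                                          env$proteome, ref, tgt)
      data.frame(level = "site", target_species = tgt,
                 n_phospho = nrow(sites), n_control = nrow(ctrl_sites),
                 proportion_phospho = cmp$proportion_phospho,
                 proportion_control = cmp$proportion_control,
                 odds_ratio = cmp$odds_ratio, p_value = cmp$p_value,
                 stringsAsFactors = FALSE)
    })
    env$evostats <- do.call(rbind, c(rows, srows,
                                     make.row.names = FALSE))
    add_file(write_tsv(env$evostats,
                       file.path(out_dir, "evostats.tsv")))
    counts$evostats <<- list(n_comparisons = nrow(env$evostats))
    TRUE
  })

  stage("disease", function() {
    fam <- env$study$families
    add_file(write_variant_table(env$study$variants,
                                 file.path(out_dir, "variants.tsv")))
    # reference sites carried to comparator coordinates with their
    # comparator window identity and acceptor status
    cons <- env$conservation
    al <- env$aligned[env$aligned$species == comp, , drop = FALSE]
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
                            "acceptor_class_changed"),
                        stringsAsFactors = FALSE)
    sites <- sites[!is.na(sites$protein_id) & !is.na(sites$position), ,
                   drop = FALSE]
    env$proximity <- proximity_by_identity(sites, env$study$variants,
                                           identity_cutoffs,
                                           config$variant_distance)
    enr <- tryCatch(enrichment_test(sites, env$study$variants,
                                    enrichment_cutoff,
                                    config$variant_distance),
                    error = function(e) NULL)
    add_file(write_tsv(env$proximity,
                       file.path(out_dir, "disease_proximity.tsv")))
    if (!is.null(enr)) {
      et <- data.frame(identity_cutoff = enr$identity_cutoff,
                       fraction_high = enr$fraction_high,
                       fraction_low = enr$fraction_low,
                       odds_ratio = enr$odds_ratio,
                       p_value = enr$p_value)
      add_file(write_tsv(et, file.path(out_dir,
                                       "disease_enrichment.tsv")))
    }
    counts$disease <<- list(n_sites = nrow(sites),
                            n_variants = nrow(env$study$variants))
    TRUE
  })

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "bank")],
                               auto_unbox = TRUE, digits = NA)
  manifest <- list(status = "complete",
                   tool = paste0("phosevo ",
                                 as.character(utils::packageVersion("phosevo"))),
                   config_hash = unname(tools::md5sum(
                     local({
                       tf <- tempfile()
                       writeLines(cfg_json, tf)
                       tf
                     }))),
                   seed = config$seed,
                   stages = stages, counts = counts,
                   files = manifest_files(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
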