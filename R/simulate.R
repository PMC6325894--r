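# Deterministic multi-species simulator. Six species evolve along a
# fixed pectinate (ladder) tree by per-site independent substitution;
# phosphoprotein families carry two planted phosphosite classes, both
# with kinase-motif context sampled from the PSSM bank:
#
#   * functional sites — substitution in the +/-5 window is reduced by a
#     multiplicative boost factor (purifying selection), and the site is
#     truly phosphorylated in every species retaining the acceptor
#     class;
#   * labile sites — motif context but no conservation boost, and each
#     species retaining the acceptor is truly phosphorylated
#     independently with the labile activity rate.
#
# Detection then thins truth per species (and per source for the
# reference species); variants land on the comparator species enriched
# near conserved functional sites. Everything is reproducible from the
# config seed, and the returned truth suffices to compute every
# downstream recovery oracle without re-simulation.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: a six-leaf
#' pectinate tree (melanogaster-like ladder) with neutral divergence
#' spanning the 0.2–0.8 window-identity range, strong purifying
#' selection (boost 0.02) on functional windows, planted motif strength
#' 2 log-odds, a four-source reference species with merged coverage
#' ~0.85 and single-source coverage 0.25–0.50 elsewhere, and 2x
#' disease-variant enrichment within 10 residues of conserved functional
#' sites. See the methods vignette for the rationale behind each value.
#'
#' @param seed integer RNG seed (mandatory; the config fully serialises
#'   the run).
#' @param n_groups number of ortholog families.
#' @param ... overrides for any default field.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed, n_groups = 60L, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cfg <- list(
    seed = as.integer(seed),
    n_groups = as.integer(n_groups),
    species = c("Dmel", "Dsim", "Dyak", "Dana", "Dpse", "Dvir"),
    reference_species = "Dmel",
    comparator_species = "Dvir",
    # per-edge substitution probabilities on the pectinate tree
    branch_sub = c(Dmel = 0.05, Dsim = 0.24, Dyak = 0.53, Dana = 0.66,
                   Dpse = 0.75, Dvir = 0.82, spine = 0.04),
    len_range = c(200L, 800L),
    aa_freq = aa_background,
    phosphoprotein_fraction = 0.6,
    functional_site_rate = 0.05,   # per ancestor acceptor
    labile_site_rate = 0.10,       # per ancestor acceptor
    labile_activity = 0.4,         # per-species activity of labile sites
    functional_conservation_boost = 0.02,  # substitution multiplier
    motif_strength = 3,            # log-odds tilt around planted sites
    detection_sensitivity = c(Dsim = 0.50, Dyak = 0.40, Dana = 0.35,
                              Dpse = 0.30, Dvir = 0.25),
    ref_source_sensitivity = c(ds1 = 0.45, ds2 = 0.40, ds3 = 0.35,
                               ds4 = 0.30),
    fp_rate = 0,                   # false-positive detections (off)
    retention_prob = c(Dsim = 0.95, Dyak = 0.92, Dana = 0.88,
                       Dpse = 0.85, Dvir = 0.80),
    phospho_retention_odds = 3,    # odds multiplier for phosphoproteins
    deletion_rate = 0,             # per-site deletion start (indel mode)
    deletion_extend = 0.7,         # geometric extension probability
    variant_rate = 0.01,           # per comparator residue
    variant_enrichment = 2,        # rate multiplier near conserved sites
    variant_distance = 10L)
  dots <- list(...)
  bad <- setdiff(names(dots), c(names(cfg), "bank"))
  if (length(bad)) stop("unknown sim_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (is.null(cfg$bank)) cfg$bank <- default_pssm_bank()
  probs <- c(cfg$branch_sub, cfg$detection_sensitivity,
             cfg$ref_source_sensitivity, cfg$retention_prob,
             cfg$phosphoprotein_fraction, cfg$functional_site_rate,
             cfg$labile_site_rate, cfg$labile_activity,
             cfg$functional_conservation_boost, cfg$fp_rate,
             cfg$deletion_rate, cfg$variant_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (cfg$variant_enrichment < 1)
    stop("variant_enrichment must be >= 1")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_groups, "groups |",
      length(x$species), "species\n")
  invisible(x)
}

# Pectinate tree edge list: (parent, child, substitution probability).
tree_edges <- function(config) {
  sp <- config$species
  bs <- config$branch_sub
  n <- length(sp)
  anc <- paste0("anc", seq_len(n - 1L))  # anc(n-1) is the root
  edges <- data.frame(parent = character(), child = character(),
                      p = numeric(), stringsAsFactors = FALSE)
  add <- function(parent, child, p)
    rbind(edges, data.frame(parent = parent, child = child, p = p))
  edges <- add(anc[1L], sp[1L], bs[[sp[1L]]])
  edges <- add(anc[1L], sp[2L], bs[[sp[2L]]])
  for (i in seq(2L, n - 1L)) {
    edges <- add(anc[i], anc[i - 1L], bs[["spine"]])
    edges <- add(anc[i], sp[i + 1L], bs[[sp[i + 1L]]])
  }
  edges
}

# Substitute positions of `ch` independently with probability `p_eff`
# (vector); replacements are drawn from the background excluding the
# current residue, so every substitution changes the sequence.
mutate_chars <- function(ch, p_eff, freq) {
  hit <- which(runif(length(ch)) < p_eff)
  if (!length(hit)) return(ch)
  new <- sample(AA20, length(hit), replace = TRUE, prob = freq)
  same <- which(new == ch[hit])
  while (length(same)) {
    new[same] <- sample(AA20, length(same), replace = TRUE, prob = freq)
    same <- same[new[same] == ch[hit][same]]
  }
  ch[hit] <- new
  ch
}

# Sample one residue per row from the background tilted by
# exp(strength * pssm-weight) at that offset.
tilted_residue <- function(weights_row, strength, freq) {
  p <- freq * exp(strength * weights_row)
  sample(AA20, 1L, prob = p / sum(p))
}

simulate_one_family <- function(gid, config) {
  bank <- config$bank
  L <- sample(seq(config$len_range[1L], config$len_range[2L]), 1L)
  anc <- sample(AA20, L, replace = TRUE, prob = config$aa_freq)
  phospho <- runif(1L) < config$phosphoprotein_fraction
  sites <- data.frame(position = integer(), type = character(),
                      anc_residue = character(), class = character(),
                      motif = character(), stringsAsFactors = FALSE)
  if (phospho) {
    acc <- which(anc %in% ACCEPTORS)
    r <- runif(length(acc))
    fun_pos <- acc[r < config$functional_site_rate]
    lab_pos <- acc[r >= config$functional_site_rate &
                     r < config$functional_site_rate +
                       config$labile_site_rate]
    pos <- c(fun_pos, lab_pos)
    if (length(pos)) {
      cls <- acceptor_class(anc[pos])
      motif <- vapply(cls, function(cl) {
        pool <- bank$kinases[bank$acceptor_class == cl]
        if (!length(pool)) return(NA_character_)  # no motif of this class
        pool[sample.int(length(pool), 1L)]
      }, character(1))
      sites <- data.frame(position = pos,
                          type = rep(c("functional", "labile"),
                                     c(length(fun_pos), length(lab_pos))),
                          anc_residue = anc[pos], class = cls,
                          motif = motif, stringsAsFactors = FALSE)
      # plant motif context in the ancestor around every planted site
      for (i in seq_len(nrow(sites))) {
        if (is.na(sites$motif[i])) next
        m <- match(sites$motif[i], bank$kinases)
        for (off in seq(-bank$flank, bank$flank)) {
          if (off == 0L) next
          p <- sites$position[i] + off
          if (p < 1L || p > L) next
          anc[p] <- tilted_residue(bank$W[off + bank$flank + 1L, , m],
                                   config$motif_strength, config$aa_freq)
        }
      }
    }
  }
  # purifying selection: substitution probability multiplier per site
  fac <- rep(1, L)
  for (p in sites$position[sites$type == "functional"]) {
    w <- max(1L, p - 5L):min(L, p + 5L)
    fac[w] <- config$functional_conservation_boost
  }
  # evolve down the tree, parents before children
  edges <- tree_edges(config)
  root <- setdiff(edges$parent, edges$child)[1L]
  seqs <- setNames(list(anc), root)
  remaining <- edges
  while (nrow(remaining)) {
    ready <- remaining$parent %in% names(seqs)
    stopifnot(any(ready))
    for (j in which(ready)) {
      seqs[[remaining$child[j]]] <-
        mutate_chars(seqs[[remaining$parent[j]]],
                     pmin(remaining$p[j] * fac, 1), config$aa_freq)
    }
    remaining <- remaining[!ready, , drop = FALSE]
  }
  # optional deletion-only indel mode: gaps punched into leaf rows, so
  # alignment columns stay ancestor coordinates (no insertions)
  rows <- lapply(config$species, function(sp) seqs[[sp]])
  names(rows) <- config$species
  if (config$deletion_rate > 0) {
    for (sp in config$species) {
      ch <- rows[[sp]]
      start <- which(runif(L) < config$deletion_rate * fac)
      for (s in start) {
        len <- 1L + stats::rgeom(1L, 1 - config$deletion_extend)
        ch[s:min(L, s + len - 1L)] <- "-"
      }
      rows[[sp]] <- ch
    }
  }
  list(gid = gid, L = L, phospho = phospho, sites = sites, rows = rows,
       fac = fac)
}

#' Simulate ortholog families
#'
#' @param config a `sim_config`.
#' @param seed RNG seed (default `config$seed`).
#' @return list with `proteome` (data.frame over retained members),
#'   `groups` (named list of `ortho_group`s), `ortholog_map`
#'   (data.frame with DIOPT-like scores >= 3 for every retained
#'   member), and `truth` (list: `proteins`, `sites`, `status`,
#'   `membership`, `config`).
#' @export
simulate_families <- function(config, seed = config$seed) {
  withr::with_seed(seed, {
    fams <- lapply(seq_len(config$n_groups), function(g)
      simulate_one_family(sprintf("g%04d", g), config))
    ref <- config$reference_species
    proteome <- list(); groups <- list(); map <- list()
    prot_truth <- list(); site_truth <- list(); status <- list()
    membership <- list()
    for (f in fams) {
      gid <- f$gid
      keep <- vapply(config$species, function(sp) {
        if (sp == ref) return(TRUE)
        p <- config$retention_prob[[sp]]
        if (f$phospho) {
          b <- config$phospho_retention_odds
          p <- p * b / (1 - p + p * b)
        }
        runif(1L) < p
      }, logical(1))
      kept <- config$species[keep]
      pid <- setNames(paste0(config$species, "_", gid), config$species)
      membership[[gid]] <- data.frame(group_id = gid,
                                      species = config$species,
                                      protein_id = unname(pid),
                                      retained = keep,
                                      stringsAsFactors = FALSE)
      aln <- vapply(kept, function(sp) paste(f$rows[[sp]], collapse = ""),
                    character(1))
      seqs <- gsub("-", "", aln, fixed = TRUE)
      proteome[[gid]] <- data.frame(protein_id = unname(pid[kept]),
                                    species = kept, gene_id = gid,
                                    sequence = unname(seqs),
                                    stringsAsFactors = FALSE)
      members <- data.frame(species = kept, protein_id = unname(pid[kept]),
                            stringsAsFactors = FALSE)
      groups[[gid]] <- ortholog_group(gid, members, aln)
      map[[gid]] <- data.frame(group_id = gid, species = kept,
                               protein_id = unname(pid[kept]),
                               ortholog_score = sample(3:15, length(kept),
                                                       replace = TRUE),
                               stringsAsFactors = FALSE)
      prot_truth[[gid]] <- data.frame(group_id = gid, gene_id = gid,
                                      phosphoprotein = f$phospho,
                                      n_functional =
                                        sum(f$sites$type == "functional"),
                                      n_labile =
                                        sum(f$sites$type == "labile"),
                                      stringsAsFactors = FALSE)
      if (nrow(f$sites)) {
        site_truth[[gid]] <- cbind(group_id = gid, f$sites)
        for (sp in kept) {
          ch <- f$rows[[sp]]
          ungapped_pos <- cumsum(ch != "-")
          res <- ch[f$sites$position]
          ok <- ifelse(f$sites$class == "ST", res %in% c("S", "T"),
                       res == "Y")
          true_ph <- ok & (f$sites$type == "functional" |
                             runif(nrow(f$sites)) < config$labile_activity)
          status[[paste(gid, sp)]] <-
            data.frame(group_id = gid, species = sp,
                       protein_id = pid[[sp]],
                       column = f$sites$position,
                       position = ifelse(res == "-", NA_integer_,
                                         ungapped_pos[f$sites$position]),
                       residue = res, type = f$sites$type,
                       acceptor_retained = ok & res != "-",
                       true_phospho = true_ph & res != "-",
                       stringsAsFactors = FALSE)
        }
      }
    }
    truth <- list(proteins = do.call(rbind, prot_truth),
                  sites = do.call(rbind, site_truth),
                  status = do.call(rbind, status),
                  membership = do.call(rbind, membership),
                  config = config)
    for (nm in c("proteins", "sites", "status", "membership"))
      rownames(truth[[nm]]) <- NULL
    proteome <- do.call(rbind, proteome)
    rownames(proteome) <- NULL
    list(proteome = proteome, groups = groups,
         ortholog_map = do.call(rbind, c(map, make.row.names = FALSE)),
         truth = truth)
  })
}

#' Simulate per-source detection of true phosphosites
#'
#' Each true site is detected independently with its species'
#' sensitivity — per source for the reference species, which carries
#' several sources — and detected records are emitted with a synthetic
#' supporting peptide (a true 7–25-mer subsequence containing the site)
#' so that peptide remapping is exercised end to end. With
#' `fp_rate > 0`, spurious records are added at never-true acceptors.
#'
#' @param families [simulate_families()] output.
#' @param config the `sim_config`.
#' @param seed RNG seed (default `config$seed + 1`).
#' @return site-catalog data.frame (all species and sources).
#' @export
simulate_detection <- function(families, config,
                               seed = config$seed + 1L) {
  st <- families$truth$status
  st <- st[st$true_phospho, , drop = FALSE]
  seqs <- setNames(families$proteome$sequence,
                   paste(families$proteome$species,
                         families$proteome$protein_id, sep = "|"))
  withr::with_seed(seed, {
    out <- list()
    emit <- function(rows, source, s) {
      det <- rows[runif(nrow(rows)) < s, , drop = FALSE]
      if (!nrow(det)) return(NULL)
      pep <- t(vapply(seq_len(nrow(det)), function(i) {
        sq <- seqs[[paste(det$species[i], det$protein_id[i], sep = "|")]]
        n <- nchar(sq)
        len <- sample(7:25, 1L)
        len <- min(len, n)
        off_lo <- max(1L, det$position[i] + len - n)
        off_hi <- min(len, det$position[i])
        off <- if (off_lo >= off_hi) off_lo else sample(off_lo:off_hi, 1L)
        start <- det$position[i] - off + 1L
        c(substr(sq, start, start + len - 1L), as.character(off))
      }, character(2)))
      data.frame(species = det$species, protein_id = det$protein_id,
                 position = det$position, residue = det$residue,
                 ptm_type = "phospho", source = source,
                 source_score = round(runif(nrow(det), 20, 100), 1),
                 peptide = pep[, 1L],
                 peptide_offset = as.integer(pep[, 2L]),
                 stringsAsFactors = FALSE)
    }
    for (sp in unique(st$species)) {
      rows <- st[st$species == sp, , drop = FALSE]
      if (sp == config$reference_species) {
        for (src in names(config$ref_source_sensitivity))
          out[[paste(sp, src)]] <-
            emit(rows, paste0(sp, "_", src),
                 config$ref_source_sensitivity[[src]])
      } else {
        out[[sp]] <- emit(rows, paste0(sp, "_ds1"),
                          config$detection_sensitivity[[sp]])
      }
    }
    if (config$fp_rate > 0) {
      true_key <- paste(st$species, st$protein_id, st$position)
      acc <- rbind(all_acceptor_sites(families$proteome, "ST"),
                   all_acceptor_sites(families$proteome, "Y"))
      acc <- acc[!paste(acc$species, acc$protein_id, acc$position) %in%
                   true_key, , drop = FALSE]
      fp <- acc[runif(nrow(acc)) < config$fp_rate, , drop = FALSE]
      if (nrow(fp)) {
        fp$ptm_type <- "phospho"
        fp$source <- paste0(fp$species, "_fp")
        fp$source_score <- round(runif(nrow(fp), 20, 100), 1)
        fp$peptide <- NA_character_
        fp$peptide_offset <- NA_integer_
        out[["fp"]] <- fp[, c("species", "protein_id", "position",
                              "residue", "ptm_type", "source",
                              "source_score", "peptide", "peptide_offset")]
      }
    }
    out <- Filter(Negate(is.null), out)
    cat <- if (length(out))
      do.call(rbind, c(out, make.row.names = FALSE)) else NULL
    if (is.null(cat))
      cat <- data.frame(species = character(), protein_id = character(),
                        position = integer(), residue = character(),
                        ptm_type = character(), source = character(),
                        source_score = numeric(), peptide = character(),
                        peptide_offset = integer())
    rownames(cat) <- NULL
    cat
  })
}

#' Simulate disease variants on the comparator species
#'
#' Variants land on each comparator protein independently per residue:
#' at the background `variant_rate` far from any conserved functional
#' site and at `variant_enrichment` times that rate within
#' `variant_distance` residues of one (a functional site whose acceptor
#' class is retained in the comparator). Realized near/far rates are
#' attached as attributes.
#'
#' @param families [simulate_families()] output.
#' @param config the `sim_config`.
#' @param seed RNG seed (default `config$seed + 2`).
#' @return variant data.frame `protein_id`, `position`, `disease_label`
#'   with attributes `near_rate`, `far_rate`.
#' @export
simulate_variants <- function(families, config,
                              seed = config$seed + 2L) {
  comp <- config$comparator_species
  prot <- families$proteome[families$proteome$species == comp, ,
                            drop = FALSE]
  st <- families$truth$status
  cons <- st[st$species == comp & st$type == "functional" &
               st$acceptor_retained, , drop = FALSE]
  withr::with_seed(seed, {
    out <- list(); n_near <- 0L; n_far <- 0L; k_near <- 0L; k_far <- 0L
    for (i in seq_len(nrow(prot))) {
      L <- nchar(prot$sequence[i])
      near <- rep(FALSE, L)
      for (p in cons$position[cons$protein_id == prot$protein_id[i]]) {
        if (is.na(p)) next
        w <- max(1L, p - config$variant_distance):
          min(L, p + config$variant_distance)
        near[w] <- TRUE
      }
      rate <- ifelse(near, pmin(1, config$variant_rate *
                                  config$variant_enrichment),
                     config$variant_rate)
      hit <- which(runif(L) < rate)
      n_near <- n_near + sum(near); n_far <- n_far + sum(!near)
      k_near <- k_near + sum(near[hit]); k_far <- k_far + sum(!near[hit])
      if (length(hit))
        out[[i]] <- data.frame(protein_id = prot$protein_id[i],
                               position = hit,
                               disease_label = "synthetic_disease",
                               stringsAsFactors = FALSE)
    }
    v <- do.call(rbind, out)
    if (is.null(v))
      v <- data.frame(protein_id = character(), position = integer(),
                      disease_label = character())
    rownames(v) <- NULL
    attr(v, "near_rate") <- if (n_near) k_near / n_near else NA_real_
    attr(v, "far_rate") <- if (n_far) k_far / n_far else NA_real_
    v
  })
}

#' Re-draw ortholog retention only (for comparison nulls)
#'
#' Re-randomises group membership at the configured retention
#' probabilities — with `phospho_odds` boosting phosphoprotein families
#' (1 = null, no effect) — without re-simulating any sequence. Used for
#' cheap null/power replicates of the protein-level conservation
#' comparison.
#'
#' @param truth `truth` element of [simulate_families()] output.
#' @param config the `sim_config`.
#' @param seed RNG seed.
#' @param phospho_odds retention odds multiplier for phosphoproteins.
#' @return ortholog-map data.frame.
#' @export
simulate_ortholog_map <- function(truth, config, seed,
                                  phospho_odds =
                                    config$phospho_retention_odds) {
  pr <- truth$proteins
  ref <- config$reference_species
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(pr)), function(i) {
      keep <- vapply(config$species, function(sp) {
        if (sp == ref) return(TRUE)
        p <- config$retention_prob[[sp]]
        if (pr$phosphoprotein[i]) {
          p <- p * phospho_odds / (1 - p + p * phospho_odds)
        }
        runif(1L) < p
      }, logical(1))
      kept <- config$species[keep]
      data.frame(group_id = pr$group_id[i], species = kept,
                 protein_id = paste0(kept, "_", pr$group_id[i]),
                 ortholog_score = sample(3:15, length(kept),
                                         replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Run the full simulation (families, detection, variants)
#'
#' @param config a `sim_config`.
#' @return list `families`, `catalog`, `variants`, `config`.
#' @export
simulate_study <- function(config) {
  families <- simulate_families(config)
  list(families = families,
       catalog = simulate_detection(families, config),
       variants = simulate_variants(families, config),
       config = config)
}
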