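# Conservation comparisons between phosphorylated and control sets with
# an exact two-sided Fisher test (probability-mass rule).

#' Exact two-sided Fisher test for a 2x2 table
#'
#' P-value by the probability-mass rule: the sum of hypergeometric
#' probabilities, at the table's fixed margins, of all tables at most as
#' probable as the observed one (with the customary 1e-7 relative
#' tolerance for floating-point ties). A table with a zero margin has no
#' alternative configurations and returns p = 1 by convention. The odds
#' ratio is the sample `(a*d)/(b*c)`, `Inf` when the denominator is 0.
#'
#' @param a,b,c,d cell counts, rows = group, columns = outcome. `a` may
#'   also be a 2x2 matrix.
#' @return list with `odds_ratio`, `p_value`, `table`.
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    tab <- a
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  }
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    p <- 1
  } else {
    k <- max(0, c1 - r2):min(r1, c1)  # support of the a-cell
    pk <- dhyper(k, r1, r2, c1)
    p_obs <- dhyper(a, r1, r2, c1)
    p <- min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
  }
  list(odds_ratio = or, p_value = p,
       table = matrix(c(a, c, b, d), 2, 2,
                      dimnames = list(group = c("g1", "g2"),
                                      outcome = c("yes", "no"))))
}

comparison_result <- function(target_species, n_yes1, n1, n_yes2, n2) {
  stopifnot(n1 > 0L, n2 > 0L)
  ft <- fisher_exact_two_sided(n_yes1, n1 - n_yes1, n_yes2, n2 - n_yes2)
  list(target_species = target_species,
       proportion_phospho = n_yes1 / n1,
       proportion_control = n_yes2 / n2,
       table = ft$table, odds_ratio = ft$odds_ratio,
       p_value = ft$p_value)
}

#' Protein-level ortholog conservation comparison
#'
#' Do phosphoproteins have an ortholog in the target species more often
#' than non-phosphoproteins? Outcome per protein: a group containing it
#' also contains a target-species member at ortholog score >=
#' `min_score`.
#'
#' @param phospho_proteins,control_proteins disjoint character vectors
#'   of reference-species protein ids (controls: proteins with no
#'   detected site of the tested PTM type).
#' @param ortholog_map data.frame `group_id, species, protein_id,
#'   ortholog_score`.
#' @param reference_species,target_species species labels.
#' @param min_score DIOPT-like score threshold (default 3).
#' @return list: `target_species`, group proportions, 2x2 `table`,
#'   `odds_ratio`, `p_value`.
#' @export
ortholog_conservation_comparison <- function(phospho_proteins,
                                             control_proteins,
                                             ortholog_map,
                                             reference_species,
                                             target_species,
                                             min_score = 3L) {
  if (!length(phospho_proteins) || !length(control_proteins))
    stop("both protein groups must be non-empty")
  if (length(intersect(phospho_proteins, control_proteins)))
    stop("phospho and control protein sets must be disjoint")
  ref <- ortholog_map[ortholog_map$species == reference_species, ,
                      drop = FALSE]
  tgt_groups <- unique(ortholog_map$group_id[
    ortholog_map$species == target_species &
      ortholog_map$ortholog_score >= min_score])
  has_orth <- function(ids) {
    g <- ref$group_id[match(ids, ref$protein_id)]
    !is.na(g) & g %in% tgt_groups
  }
  comparison_result(target_species,
                    sum(has_orth(phospho_proteins)),
                    length(phospho_proteins),
                    sum(has_orth(control_proteins)),
                    length(control_proteins))
}

#' Site-level conservation comparison
#'
#' Do phosphosites show conserved context in the target species more
#' often than control acceptors drawn from the same proteins? The
#' default conserved-site rule: the aligned target residue is a
#' phospho-acceptor and the reference-target window identity is >=
#' `identity_min`. Sites whose protein has no target ortholog, or with a
#' gap at the site, count as not conserved.
#'
#' @param phospho_sites,control_sites data.frames with `protein_id`,
#'   `position` (reference-species coordinates).
#' @param groups named list of `ortho_group`s.
#' @param proteome proteome data.frame.
#' @param reference_species,target_species species labels.
#' @param identity_min window-identity part of the conserved rule
#'   (default 0.5).
#' @param require_acceptor require the target residue to be S/T/Y
#'   (default TRUE).
#' @param flank window flank.
#' @return list as in [ortholog_conservation_comparison()].
#' @export
site_conservation_comparison <- function(phospho_sites, control_sites,
                                         groups, proteome,
                                         reference_species, target_species,
                                         identity_min = 0.5,
                                         require_acceptor = TRUE,
                                         flank = 5L) {
  if (!nrow(phospho_sites) || !nrow(control_sites))
    stop("both site sets must be non-empty")
  seqs <- setNames(proteome$sequence,
                   paste(proteome$species, proteome$protein_id, sep = "|"))
  grp_of <- site_group_index(groups, reference_species)
  conserved_in_target <- function(sites) {
    vapply(seq_len(nrow(sites)), function(i) {
      gid <- grp_of[[sites$protein_id[i]]]
      if (is.null(gid)) return(FALSE)
      g <- groups[[gid]]
      if (!target_species %in% g$members$species) return(FALSE)
      col <- position_to_column(g, reference_species, sites$position[i])
      tpos <- column_to_position(g, target_species, col)
      if (is.na(tpos)) return(FALSE)
      tpid <- g$members$protein_id[g$members$species == target_species]
      tseq <- seqs[[paste(target_species, tpid, sep = "|")]]
      tres <- substr(tseq, tpos, tpos)
      if (require_acceptor && !tres %in% ACCEPTORS) return(FALSE)
      rpid <- g$members$protein_id[g$members$species == reference_species]
      rw <- extract_window(seqs[[paste(reference_species, rpid, sep = "|")]],
                           sites$position[i], flank)
      window_identity(rw, extract_window(tseq, tpos, flank)) >= identity_min
    }, logical(1))
  }
  comparison_result(target_species,
                    sum(conserved_in_target(phospho_sites)),
                    nrow(phospho_sites),
                    sum(conserved_in_target(control_sites)),
                    nrow(control_sites))
}

# protein_id -> group_id lookup for one species (first group wins; the
# simulator emits one group per gene).
site_group_index <- function(groups, species) {
  out <- list()
  for (g in groups) {
    m <- g$members
    pid <- m$protein_id[m$species == species]
    if (length(pid) && is.null(out[[pid]])) out[[pid]] <- g$group_id
  }
  out
}

#' Sample control acceptors matched to a phosphosite set
#'
#' Controls are non-phosphorylated S/T/Y positions on the same proteins
#' as the phosphosites; by default the sample is matched to the
#' phosphosite residue-class composition (S/T/Y proportions) to avoid
#' composition confounding.
#'
#' @param phospho_sites data.frame `protein_id`, `position`, `residue`.
#' @param proteome proteome data.frame (one species).
#' @param n number of controls (default: size of the phospho set).
#' @param match_class match S/T/Y composition (default TRUE).
#' @param seed RNG seed.
#' @return data.frame `protein_id`, `position`, `residue`.
#' @export
sample_control_acceptors <- function(phospho_sites, proteome, n = NULL,
                                     match_class = TRUE, seed = 1L) {
  if (is.null(n)) n <- nrow(phospho_sites)
  prot <- proteome[proteome$protein_id %in% phospho_sites$protein_id, ,
                   drop = FALSE]
  acc <- all_acceptor_sites(prot, "ST")
  acc <- rbind(acc, all_acceptor_sites(prot, "Y"))
  taken <- paste(phospho_sites$protein_id, phospho_sites$position)
  acc <- acc[!paste(acc$protein_id, acc$position) %in% taken, , drop = FALSE]
  if (!nrow(acc)) stop("no control acceptors available")
  withr::with_seed(seed, {
    if (match_class) {
      frac <- table(factor(phospho_sites$residue, ACCEPTORS)) /
        nrow(phospho_sites)
      idx <- unlist(lapply(ACCEPTORS, function(r) {
        pool <- which(acc$residue == r)
        k <- min(round(n * frac[[r]]), length(pool))
        if (k > 0) sample(pool, k) else integer(0)
      }))
    } else {
      idx <- sample(nrow(acc), min(n, nrow(acc)))
    }
  })
  out <- acc[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}
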