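# Window extraction, 11-mer identity scoring, per-site average
# similarity, conserved-site calling and identity binning.
#
# A site window is the acceptor plus `flank` residues up- and downstream
# (default flank 5, nominal length 11). Identity is the number of
# identical positions divided by the nominal length 2*flank+1, so
# truncated or gapped positions count as mismatches and scores stay
# comparable across sites. "X" never matches anything, including "X".

#' Extract the residue window around a site
#'
#' @param sequence ungapped amino-acid string.
#' @param position 1-based site position.
#' @param flank residues on each side (default 5).
#' @return object of class `site_window` with fields `center_position`,
#'   `flank`, `residues` (clipped string), `left_truncated`,
#'   `right_truncated`.
#' @export
extract_window <- function(sequence, position, flank = 5L) {
  n <- nchar(sequence)
  if (position < 1L || position > n)
    stop("position ", position, " out of range [1, ", n, "]")
  lo <- max(1L, position - flank)
  hi <- min(n, position + flank)
  padded <- rep(NA_character_, 2L * flank + 1L)
  idx <- (lo:hi) - position + flank + 1L
  padded[idx] <- seq_chars(substr(sequence, lo, hi))
  structure(list(center_position = position, flank = flank,
                 residues = substr(sequence, lo, hi),
                 left_truncated = lo > position - flank,
                 right_truncated = hi < position + flank,
                 padded = padded),
            class = "site_window")
}

#' @export
print.site_window <- function(x, ...) {
  cat(sprintf("site_window @%d (+/-%d): %s%s%s\n", x$center_position,
              x$flank,
              if (x$left_truncated) "<" else "", x$residues,
              if (x$right_truncated) ">" else ""))
  invisible(x)
}

#' Window identity between two sites
#'
#' Fraction of identical residues over the nominal window length
#' `2*flank+1`, the two windows anchored at their centers. Positions
#' absent from either window (truncation or alignment gap) and `X`
#' residues never count as identical. Two windows identical at 10 of 11
#' positions therefore score 10/11 ~= 0.909, displayed as 0.9 at
#' one-decimal rounding.
#'
#' @param w1,w2 `site_window` objects with equal `flank`.
#' @return identity in `[0, 1]`.
#' @export
window_identity <- function(w1, w2) {
  stopifnot(inherits(w1, "site_window"), inherits(w2, "site_window"),
            w1$flank == w2$flank)
  a <- w1$padded
  b <- w2$padded
  ok <- !is.na(a) & !is.na(b) & a != "-" & b != "-" & a != "X" & b != "X"
  sum(ok & a == b) / (2L * w1$flank + 1L)
}

#' Average similarity of a site across its orthologs
#'
#' Arithmetic mean of the reference-versus-ortholog window identities.
#' An ortholog gapped at the acceptor column contributes similarity 0
#' (absence is the strongest non-conservation signal) rather than being
#' excluded; with zero orthologs the average is undefined (`NA`) and the
#' site is excluded from conserved summaries.
#'
#' @param ref_window reference `site_window`.
#' @param ortholog_windows list of `site_window` objects or `NA` for an
#'   ortholog gapped at the acceptor column.
#' @return mean similarity, or `NA_real_` with zero orthologs.
#' @export
average_similarity <- function(ref_window, ortholog_windows) {
  if (!length(ortholog_windows)) return(NA_real_)
  vals <- vapply(ortholog_windows, function(w) {
    if (!inherits(w, "site_window")) 0 else window_identity(ref_window, w)
  }, numeric(1))
  mean(vals)
}

#' Score site conservation across an ortholog group set
#'
#' For every aligned site observed in the reference species, computes the
#' reference-versus-ortholog window identity for each other species in
#' the group, the average similarity, the conserved call
#' (`average_similarity > threshold`, strict), and the acceptor-status
#' class of each ortholog.
#'
#' @param aligned_sites long aligned-site table
#'   ([select_aligned_acceptor_sites()] output, possibly row-bound over
#'   groups).
#' @param groups named list of `ortho_group`s.
#' @param proteome proteome data.frame (window source).
#' @param reference_species reference species label.
#' @param flank window flank (default 5).
#' @param threshold conserved-call threshold (default 0.5, strict `>`).
#' @param comparison `"reference"` (default; reference vs each ortholog)
#'   or `"allpairs"` (mean over all species pairs).
#' @param mode acceptor classification mode, see
#'   [classify_acceptor_status()].
#' @return data.frame, one row per reference site: `group_id`,
#'   `protein_id`, `position`, `column`, `residue`, `n_orthologs`,
#'   `sim_<species>` and `class_<species>` per non-reference species,
#'   `average_similarity`, `conserved`.
#' @export
site_conservation <- function(aligned_sites, groups, proteome,
                              reference_species, flank = 5L,
                              threshold = 0.5,
                              comparison = c("reference", "allpairs"),
                              mode = c("strict", "broad")) {
  comparison <- match.arg(comparison)
  mode <- match.arg(mode)
  seqs <- setNames(proteome$sequence,
                   paste(proteome$species, proteome$protein_id, sep = "|"))
  species_all <- sort(unique(aligned_sites$species))
  others <- setdiff(species_all, reference_species)
  ref <- aligned_sites[aligned_sites$species == reference_species &
                         aligned_sites$observed, , drop = FALSE]
  if (!nrow(ref)) {
    return(data.frame(group_id = character(), protein_id = character(),
                      position = integer(), column = integer(),
                      residue = character(), n_orthologs = integer(),
                      average_similarity = numeric(), conserved = logical()))
  }
  win_of <- function(sp, pid, pos) {
    if (is.na(pos)) return(NA)
    extract_window(seqs[[paste(sp, pid, sep = "|")]], pos, flank)
  }
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    gid <- ref$group_id[i]
    col <- ref$column[i]
    grp <- groups[[gid]]
    site <- aligned_sites[aligned_sites$group_id == gid &
                            aligned_sites$column == col, , drop = FALSE]
    rw <- win_of(reference_species, ref$protein_id[i], ref$position[i])
    sims <- setNames(rep(NA_real_, length(others)), others)
    cls <- setNames(rep(NA_character_, length(others)), others)
    wins <- list()
    for (sp in intersect(site$species, others)) {
      srow <- site[site$species == sp, , drop = FALSE]
      w <- win_of(sp, srow$protein_id, srow$position)
      wins[[sp]] <- w
      sims[[sp]] <- if (inherits(w, "site_window")) window_identity(rw, w) else 0
      cls[[sp]] <- classify_acceptor_status(ref$residue[i], srow$residue,
                                            TRUE, srow$observed, mode = mode)
    }
    present <- intersect(site$species, others)
    avg <- if (comparison == "reference") {
      if (length(present)) mean(sims[present]) else NA_real_
    } else {
      allpairs_similarity(site, wins, rw, reference_species, flank)
    }
    out <- data.frame(group_id = gid, protein_id = ref$protein_id[i],
                      position = ref$position[i], column = col,
                      residue = ref$residue[i],
                      n_orthologs = length(present),
                      stringsAsFactors = FALSE)
    for (sp in others) out[[paste0("sim_", sp)]] <- sims[[sp]]
    for (sp in others) out[[paste0("class_", sp)]] <- cls[[sp]]
    out$average_similarity <- avg
    out$conserved <- !is.na(avg) & avg > threshold
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Mean window identity over all unordered species pairs at a column
# (alternative to the default reference-vs-ortholog averaging).
allpairs_similarity <- function(site, wins, ref_window, reference_species,
                                flank) {
  wins[[reference_species]] <- ref_window
  sp <- site$species
  if (length(sp) < 2L) return(NA_real_)
  vals <- c()
  for (i in seq_along(sp)[-length(sp)]) {
    for (j in seq((i + 1L), length(sp))) {
      wi <- wins[[sp[i]]]
      wj <- wins[[sp[j]]]
      vals <- c(vals, if (inherits(wi, "site_window") &&
                            inherits(wj, "site_window"))
        window_identity(wi, wj) else 0)
    }
  }
  mean(vals)
}

#' Bin sites by identity cutoff
#'
#' A site belongs to every bin whose cutoff is <= its similarity, so the
#' bins are nested and counts are non-increasing with the cutoff.
#'
#' @param results data.frame with an `average_similarity` column (or a
#'   numeric vector of similarities).
#' @param cutoffs increasing identity cutoffs.
#' @return list with `counts` (data.frame `cutoff`, `n_sites`) and
#'   `membership` (logical matrix, sites x cutoffs).
#' @export
bin_sites_by_identity <- function(results,
                                  cutoffs = c(0.2, 0.5, 0.8, 1.0)) {
  sims <- if (is.data.frame(results)) results$average_similarity else results
  stopifnot(length(sims) > 0L)
  member <- vapply(cutoffs, function(ct) !is.na(sims) & sims >= ct,
                   logical(length(sims)))
  member <- matrix(member, nrow = length(sims),
                   dimnames = list(NULL, paste0("ge_", cutoffs)))
  list(counts = data.frame(cutoff = cutoffs, n_sites = colSums(member)),
       membership = member)
}
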