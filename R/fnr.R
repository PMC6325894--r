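# False-negative-rate estimation. Benchmark sites are aligned acceptor
# sites whose 11-mer windows are 100% identical across all species and
# that were observed phosphorylated in at least two species; a species'
# FNR is the fraction of benchmark sites its data miss.

#' Select FNR benchmark sites
#'
#' A benchmark site must have every species of the panel present and
#' ungapped at the column, all per-species windows untruncated, free of
#' `X`, and pairwise 100% identical, and must be observed in at least
#' `min_observed` species.
#'
#' @param aligned_sites long aligned-site table (over all groups).
#' @param groups named list of `ortho_group`s.
#' @param proteome proteome data.frame.
#' @param species species panel (default: all species in
#'   `aligned_sites`).
#' @param min_observed minimum observing species (default 2).
#' @param flank window flank (default 5).
#' @return data.frame, one row per benchmark site: `group_id`, `column`,
#'   `window`, `n_observed`, plus `obs_<species>` logical columns.
#' @export
select_benchmark_sites <- function(aligned_sites, groups, proteome,
                                   species = NULL, min_observed = 2L,
                                   flank = 5L) {
  if (is.null(species)) species <- sort(unique(aligned_sites$species))
  seqs <- setNames(proteome$sequence,
                   paste(proteome$species, proteome$protein_id, sep = "|"))
  key <- paste(aligned_sites$group_id, aligned_sites$column)
  rows <- lapply(split(aligned_sites, key), function(site) {
    if (!all(species %in% site$species)) return(NULL)
    site <- site[match(species, site$species), , drop = FALSE]
    if (anyNA(site$position)) return(NULL)  # gap in some species
    wins <- lapply(seq_len(nrow(site)), function(i)
      extract_window(seqs[[paste(site$species[i], site$protein_id[i],
                                 sep = "|")]],
                     site$position[i], flank))
    if (any(vapply(wins, function(w)
      w$left_truncated || w$right_truncated, logical(1)))) return(NULL)
    wstr <- vapply(wins, `[[`, character(1), "residues")
    if (any(grepl("X", wstr, fixed = TRUE))) return(NULL)
    if (length(unique(wstr)) != 1L) return(NULL)
    n_obs <- sum(site$observed)
    if (n_obs < min_observed) return(NULL)
    out <- data.frame(group_id = site$group_id[1L],
                      column = site$column[1L], window = wstr[1L],
                      n_observed = n_obs, stringsAsFactors = FALSE)
    for (i in seq_along(species))
      out[[paste0("obs_", species[i])]] <- site$observed[i]
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group_id = character(), column = integer(),
                      window = character(), n_observed = integer())
    for (sp in species) out[[paste0("obs_", sp)]] <- logical()
  }
  rownames(out) <- NULL
  out
}

# Wilson 95% score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

#' Estimate a species' false-negative rate
#'
#' `fnr = n_missed / n_benchmark`, where `n_missed` counts benchmark
#' sites whose observed flag for that species is `FALSE`; a Wilson 95%
#' score interval accompanies the point estimate.
#'
#' @param benchmark benchmark-site table from
#'   [select_benchmark_sites()].
#' @param species one species label (must have an `obs_` column).
#' @return one-row data.frame `species`, `n_benchmark`, `n_missed`,
#'   `fnr`, `ci_low`, `ci_high`.
#' @export
estimate_fnr <- function(benchmark, species) {
  col <- paste0("obs_", species)
  if (!col %in% names(benchmark)) stop("no observed flags for ", species)
  n <- nrow(benchmark)
  if (n < 1L) stop("empty benchmark set")
  miss <- sum(!benchmark[[col]])
  ci <- wilson_ci(miss, n)
  data.frame(species = species, n_benchmark = n, n_missed = miss,
             fnr = miss / n, ci_low = ci[["low"]], ci_high = ci[["high"]],
             stringsAsFactors = FALSE)
}

#' @rdname estimate_fnr
#' @param benchmark benchmark-site table.
#' @export
estimate_fnr_all <- function(benchmark) {
  species <- sub("^obs_", "", grep("^obs_", names(benchmark), value = TRUE))
  out <- do.call(rbind, lapply(species, estimate_fnr, benchmark = benchmark))
  rownames(out) <- NULL
  out
}
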