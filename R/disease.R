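# Disease-variant proximity: are conserved phosphosites closer to
# disease-related variants than weakly conserved ones?
#
# Distance is inclusive: a variant within <= `distance` residues of the
# site (the site's own position counting as distance 0) makes the site
# proximal. Sites on proteins without any annotated variant stay in the
# denominators — absence of variants is informative.

#' Flag sites proximal to a disease variant
#'
#' @param sites data.frame `protein_id`, `position` (same coordinate
#'   system as the variants).
#' @param variants data.frame `protein_id`, `position`.
#' @param distance inclusive residue distance (default 10).
#' @return logical vector, one flag per site row.
#' @export
proximal_sites <- function(sites, variants, distance = 10L) {
  vpos <- split(variants$position, variants$protein_id)
  vapply(seq_len(nrow(sites)), function(i) {
    v <- vpos[[sites$protein_id[i]]]
    !is.null(v) && any(abs(v - sites$position[i]) <= distance)
  }, logical(1))
}

#' Variant-proximity fractions by identity cutoff
#'
#' For each identity cutoff and each acceptor stratum (target residue
#' still an acceptor versus acceptor lost), the fraction of sites at
#' identity >= cutoff lying within `distance` residues of a disease
#' variant. Empty strata are omitted.
#'
#' @param sites data.frame with `protein_id`, `position` (variant
#'   coordinate system), `identity` (site window identity to the
#'   variant-bearing species) and `acceptor_conserved` (logical).
#' @param variants variant table.
#' @param cutoffs identity cutoffs (default 0.2/0.5/0.8/1.0).
#' @param distance inclusive distance (default 10).
#' @return data.frame `cutoff`, `stratum`, `n_sites`, `n_proximal`,
#'   `fraction`.
#' @export
proximity_by_identity <- function(sites, variants,
                                  cutoffs = c(0.2, 0.5, 0.8, 1.0),
                                  distance = 10L) {
  prox <- proximal_sites(sites, variants, distance)
  strata <- list(acceptor_conserved = sites$acceptor_conserved,
                 acceptor_lost = !sites$acceptor_conserved)
  rows <- list()
  for (ct in cutoffs) {
    for (sname in names(strata)) {
      keep <- strata[[sname]] & !is.na(sites$identity) &
        sites$identity >= ct
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <-
        data.frame(cutoff = ct, stratum = sname, n_sites = sum(keep),
                   n_proximal = sum(prox[keep]),
                   fraction = mean(prox[keep]),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cutoff = numeric(), stratum = character(),
                      n_sites = integer(), n_proximal = integer(),
                      fraction = numeric())
  rownames(out) <- NULL
  out
}

#' Variant-proximity enrichment test
#'
#' Compares the proximal fraction of high-identity sites (identity >=
#' `identity_cutoff`) against the below-cutoff baseline with the exact
#' two-sided Fisher test.
#'
#' @param sites data.frame with `protein_id`, `position`, `identity`.
#' @param variants variant table.
#' @param identity_cutoff stratum boundary (default 0.8).
#' @param distance inclusive distance (default 10).
#' @return list `table`, `odds_ratio`, `p_value`, per-stratum fractions.
#' @export
enrichment_test <- function(sites, variants, identity_cutoff = 0.8,
                            distance = 10L) {
  prox <- proximal_sites(sites, variants, distance)
  hi <- !is.na(sites$identity) & sites$identity >= identity_cutoff
  lo <- !is.na(sites$identity) & !hi
  if (!any(hi) || !any(lo))
    stop("both identity strata must be non-empty")
  ft <- fisher_exact_two_sided(sum(prox[hi]), sum(hi) - sum(prox[hi]),
                               sum(prox[lo]), sum(lo) - sum(prox[lo]))
  list(identity_cutoff = identity_cutoff, table = ft$table,
       odds_ratio = ft$odds_ratio, p_value = ft$p_value,
       fraction_high = mean(prox[hi]), fraction_low = mean(prox[lo]))
}

#' Read / write disease-variant tables
#'
#' TSV columns `protein_id, position, disease_label`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_variant_table <- function(path) {
  x <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "disease_label")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  x$position <- as.integer(x$position)
  x[, need]
}

#' @rdname read_variant_table
#' @param variants variant data.frame.
#' @export
write_variant_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
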