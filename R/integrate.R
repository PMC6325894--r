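# Multi-source integration: non-redundant proteomes, peptide remapping,
# catalog merging and per-source overlap accounting.
#
# Coordinates: protein positions are 1-based and inclusive throughout.

#' Read a proteome FASTA
#'
#' Description lines are parsed as `"<protein_id> gene=<gene_id>
#' species=<label>"`; the `gene=`/`species=` tags are optional and default
#' to `NA` / the `species` argument.
#'
#' @param path FASTA file.
#' @param species fallback species label when the header carries none.
#' @return data.frame with columns `protein_id`, `species`, `gene_id`,
#'   `sequence`.
#' @export
read_proteome_fasta <- function(path, species = NA_character_) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  id <- sub("\\s.*$", "", hdr)
  tag <- function(name) {
    m <- regmatches(hdr, regexpr(paste0(name, "=\\S+"), hdr))
    out <- rep(NA_character_, length(hdr))
    hit <- grepl(paste0(name, "="), hdr)
    out[hit] <- sub(paste0("^", name, "="), "", m)
    out
  }
  gene <- tag("gene")
  gene[!is.na(gene) & gene == "."] <- NA_character_
  sp <- tag("species")
  sp[is.na(sp)] <- species
  data.frame(protein_id = id, species = sp, gene_id = gene,
             sequence = toupper(as.character(aa)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a proteome FASTA
#'
#' @param proteome data.frame as returned by [read_proteome_fasta()].
#' @param path output file.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- sprintf("%s gene=%s species=%s",
                       proteome$protein_id,
                       ifelse(is.na(proteome$gene_id), ".", proteome$gene_id),
                       proteome$species)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

validate_proteome <- function(proteome) {
  stopifnot(is.data.frame(proteome),
            all(c("protein_id", "species", "sequence") %in% names(proteome)))
  if (any(nchar(proteome$sequence) < 1L))
    stop("proteome contains an empty sequence")
  if (any(grepl("-", proteome$sequence, fixed = TRUE)))
    stop("proteome sequences must be ungapped")
  dup <- duplicated(proteome[, c("species", "protein_id")])
  if (any(dup))
    stop("duplicate protein_id within a species: ",
         proteome$protein_id[dup][1L])
  invisible(proteome)
}

#' Consolidate a proteome to distinct sequences
#'
#' Collapses identical sequences to a single representative — the
#' lexicographically smallest `protein_id` — and returns the map from
#' every input id to its representative. Duplicated ids with conflicting
#' sequences are an error.
#'
#' @param proteome data.frame of `ProteinRecord`s for one species.
#' @return list with `proteome` (representatives only) and `id_map`
#'   (data.frame `protein_id`, `representative_id`).
#' @export
consolidate_proteome <- function(proteome) {
  if (nrow(proteome) == 0L) {
    return(list(proteome = proteome,
                id_map = data.frame(protein_id = character(),
                                    representative_id = character())))
  }
  if (length(unique(proteome$species)) != 1L)
    stop("consolidate_proteome() expects a single species")
  agg <- split(proteome$sequence, proteome$protein_id)
  bad <- names(agg)[vapply(agg, function(s) length(unique(s)) > 1L, logical(1))]
  if (length(bad))
    stop("conflicting sequences for duplicated protein_id: ", bad[1L])
  proteome <- proteome[!duplicated(proteome$protein_id), , drop = FALSE]
  ord <- order(proteome$protein_id)  # representative = smallest id
  proteome <- proteome[ord, , drop = FALSE]
  rep_id <- vapply(split(proteome$protein_id, proteome$sequence), min,
                   character(1))
  id_map <- data.frame(protein_id = proteome$protein_id,
                       representative_id = unname(rep_id[proteome$sequence]),
                       stringsAsFactors = FALSE)
  keep <- proteome$protein_id %in% id_map$representative_id
  list(proteome = proteome[keep, , drop = FALSE],
       id_map = id_map[order(id_map$protein_id), , drop = FALSE])
}

#' Remap a peptide-anchored site onto a proteome
#'
#' Finds every exact occurrence of `peptide` in the proteome and converts
#' the in-peptide offset of the modified residue to protein coordinates.
#' Peptides matching more than one location are returned in full and
#' flagged `ambiguous`; an unmapped peptide yields zero rows.
#'
#' @param peptide peptide string.
#' @param peptide_offset 1-based offset of the modified residue within
#'   `peptide`.
#' @param proteome proteome data.frame (typically the consolidated one).
#' @return data.frame `protein_id`, `position`, `ambiguous`.
#' @export
remap_peptide_site <- function(peptide, peptide_offset, proteome) {
  stopifnot(nchar(peptide) >= 1L,
            peptide_offset >= 1L, peptide_offset <= nchar(peptide))
  hits <- gregexpr(peptide, proteome$sequence, fixed = TRUE)
  rows <- lapply(seq_along(hits), function(i) {
    st <- as.integer(hits[[i]])
    st <- st[st > 0L]
    if (!length(st)) return(NULL)
    data.frame(protein_id = proteome$protein_id[i],
               position = st + peptide_offset - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), position = integer())
  out$ambiguous <- rep(nrow(out) > 1L, nrow(out))
  out
}

#' Remap a whole site catalog through its peptides
#'
#' Records carrying a peptide are re-anchored by exact substring search
#' against the proteome of the record's own species; records without a
#' peptide are kept as-is. Per the package default, downstream analyses
#' drop ambiguous matches unless asked otherwise.
#'
#' @param catalog site catalog data.frame.
#' @param proteome proteome data.frame.
#' @param keep_ambiguous keep multi-hit peptides (flagged) or drop them.
#' @return remapped catalog with an `ambiguous` column.
#' @export
remap_catalog <- function(catalog, proteome, keep_ambiguous = TRUE) {
  has_pep <- !is.na(catalog$peptide) & nzchar(catalog$peptide)
  plain <- catalog[!has_pep, , drop = FALSE]
  if (nrow(plain)) plain$ambiguous <- FALSE
  pep <- catalog[has_pep, , drop = FALSE]
  out <- lapply(seq_len(nrow(pep)), function(i) {
    m <- remap_peptide_site(pep$peptide[i], pep$peptide_offset[i],
                            proteome[proteome$species == pep$species[i], ,
                                     drop = FALSE])
    if (!nrow(m)) return(NULL)
    r <- pep[rep(i, nrow(m)), , drop = FALSE]
    r$protein_id <- m$protein_id
    r$position <- m$position
    r$ambiguous <- m$ambiguous
    r
  })
  out <- rbind(plain, do.call(rbind, out))
  rownames(out) <- NULL
  if (!keep_ambiguous) out <- out[!out$ambiguous, , drop = FALSE]
  out
}

validate_catalog <- function(catalog, proteome) {
  seqs <- setNames(proteome$sequence,
                   paste(proteome$species, proteome$protein_id, sep = "|"))
  key <- paste(catalog$species, catalog$protein_id, sep = "|")
  s <- seqs[key]
  if (anyNA(s))
    stop("catalog refers to unknown protein: ", key[which(is.na(s))[1L]])
  bad <- catalog$position < 1L | catalog$position > nchar(s)
  if (any(bad))
    stop("catalog position out of range for ", key[which(bad)[1L]])
  res <- substr(s, catalog$position, catalog$position)
  bad <- res != catalog$residue
  if (any(bad))
    stop("catalog residue mismatch at ",
         site_key(catalog$species, catalog$protein_id, catalog$position,
                  catalog$ptm_type)[which(bad)[1L]])
  invisible(catalog)
}

#' Merge site catalogs from multiple sources
#'
#' Records sharing a `(species, protein_id, position, ptm_type)` key are
#' kept as one key carrying the union of sources with all original
#' scores and peptides; duplicate `(key, source)` pairs collapse to one
#' row. The result is independent of input order.
#'
#' @param catalogs list of site-catalog data.frames (already remapped to
#'   one proteome release).
#' @return merged catalog data.frame, one row per `(key, source)`.
#' @export
merge_catalogs <- function(catalogs) {
  if (is.data.frame(catalogs)) catalogs <- list(catalogs)
  cat <- do.call(rbind, lapply(catalogs, as.data.frame))
  if (is.null(cat) || nrow(cat) == 0L) return(cat)
  rownames(cat) <- NULL
  key <- site_key(cat$species, cat$protein_id, cat$position, cat$ptm_type)
  res_by_key <- split(cat$residue, key)
  bad <- names(res_by_key)[vapply(res_by_key,
                                  function(r) length(unique(r)) > 1L,
                                  logical(1))]
  if (length(bad))
    stop("residue disagreement between sources at site key ", bad[1L])
  cat <- cat[!duplicated(paste(key, cat$source, sep = "@")), , drop = FALSE]
  key <- site_key(cat$species, cat$protein_id, cat$position, cat$ptm_type)
  cat <- cat[order(key, cat$source), , drop = FALSE]
  rownames(cat) <- NULL
  cat
}

#' Per-source site-overlap table
#'
#' For each source: the number of its distinct site keys, and how many of
#' those are also supported by at least one (resp. two) other source(s).
#' The `"All"` row counts distinct keys in the union supported by >= 2 and
#' >= 3 sources.
#'
#' @param catalog merged site catalog.
#' @return data.frame `source`, `n_sites`, `n_overlap_ge1_other`,
#'   `n_overlap_ge2_other`, `frac_overlap_ge1_other`,
#'   `frac_overlap_ge2_other`.
#' @export
overlap_table <- function(catalog) {
  stopifnot(nrow(catalog) > 0L)
  key <- site_key(catalog$species, catalog$protein_id, catalog$position,
                  catalog$ptm_type)
  nsrc <- vapply(split(catalog$source, key),
                 function(s) length(unique(s)), integer(1))
  sources <- sort(unique(catalog$source))
  rows <- lapply(sources, function(src) {
    k <- unique(key[catalog$source == src])
    n <- length(k)
    ge1 <- sum(nsrc[k] >= 2L)
    ge2 <- sum(nsrc[k] >= 3L)
    data.frame(source = src, n_sites = n,
               n_overlap_ge1_other = ge1, n_overlap_ge2_other = ge2,
               frac_overlap_ge1_other = if (n) ge1 / n else 0,
               frac_overlap_ge2_other = if (n) ge2 / n else 0,
               stringsAsFactors = FALSE)
  })
  all_row <- data.frame(source = "All", n_sites = length(nsrc),
                        n_overlap_ge1_other = sum(nsrc >= 2L),
                        n_overlap_ge2_other = sum(nsrc >= 3L),
                        frac_overlap_ge1_other = mean(nsrc >= 2L),
                        frac_overlap_ge2_other = mean(nsrc >= 3L),
                        stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), all_row)
  rownames(out) <- NULL
  out
}

SITE_COLS <- c("species", "protein_id", "position", "residue", "ptm_type",
               "source", "source_score", "peptide", "peptide_offset")

#' Read / write PTM site tables
#'
#' Tab-separated with header columns `species, protein_id, position,
#' residue, ptm_type, source, source_score, peptide, peptide_offset`;
#' absent fields are `"."`.
#'
#' @param path TSV file.
#' @return site-catalog data.frame.
#' @export
read_site_table <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                  na.strings = ".", stringsAsFactors = FALSE,
                  colClasses = "character")
  miss <- setdiff(SITE_COLS, names(x))
  if (length(miss))
    stop("site table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  x$position <- as.integer(x$position)
  x$source_score <- as.numeric(x$source_score)
  x$peptide_offset <- as.integer(x$peptide_offset)
  x[, SITE_COLS]
}

#' @rdname read_site_table
#' @param catalog site-catalog data.frame.
#' @export
write_site_table <- function(catalog, path) {
  out <- catalog[, intersect(SITE_COLS, names(catalog)), drop = FALSE]
  out[] <- lapply(out, function(v) {
    v <- as.character(v)
    v[is.na(v)] <- "."
    v
  })
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
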