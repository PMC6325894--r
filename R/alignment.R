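# Ortholog groups: gapped multiple alignments, position<->column maps,
# aligned acceptor-site selection, and cross-species acceptor
# classification. Alignments are consumed, never computed, here.
#
# Alignment columns and protein positions are both 1-based.

#' Construct an ortholog group
#'
#' @param group_id group label.
#' @param members data.frame with `species`, `protein_id` (one row per
#'   species; a species may appear at most once).
#' @param alignment named character vector of equal-length gapped rows
#'   (gap `-`), names = species labels, same order as `members`.
#' @param proteome optional proteome; when given, each row is checked to
#'   ungap to the member's proteome sequence.
#' @return object of class `ortho_group`.
#' @export
ortholog_group <- function(group_id, members, alignment, proteome = NULL) {
  stopifnot(nrow(members) == length(alignment),
            all(members$species == names(alignment)))
  if (anyDuplicated(members$species))
    stop("species appears more than once in group ", group_id)
  w <- unique(nchar(alignment))
  if (length(w) != 1L)
    stop("alignment rows of group ", group_id, " differ in length")
  if (!is.null(proteome)) {
    key <- paste(proteome$species, proteome$protein_id, sep = "|")
    seqs <- setNames(proteome$sequence, key)
    ung <- gsub("-", "", alignment, fixed = TRUE)
    want <- seqs[paste(members$species, members$protein_id, sep = "|")]
    if (any(is.na(want) | ung != want))
      stop("alignment row does not match proteome sequence in group ",
           group_id)
  }
  structure(list(group_id = group_id, members = members,
                 alignment = alignment, width = w),
            class = "ortho_group")
}

#' @export
print.ortho_group <- function(x, ...) {
  cat("ortho_group", x$group_id, "|", nrow(x$members), "species, width",
      x$width, "\n")
  invisible(x)
}

row_chars <- function(group, species) {
  seq_chars(group$alignment[[species]])
}

#' Map an ungapped position to its alignment column (and back)
#'
#' `position_to_column()` and `column_to_position()` are mutually inverse
#' where defined; a gap column has no position and returns `NA`.
#'
#' @param group an `ortho_group`.
#' @param species member species label.
#' @param position 1-based ungapped position(s).
#' @return integer column(s) / position(s); `NA` at gap columns.
#' @export
position_to_column <- function(group, species, position) {
  ch <- row_chars(group, species)
  cols <- which(ch != "-")
  if (any(position < 1L | position > length(cols)))
    stop("position out of range for ", species, " in group ", group$group_id)
  cols[position]
}

#' @rdname position_to_column
#' @param column 1-based alignment column(s).
#' @export
column_to_position <- function(group, species, column) {
  ch <- row_chars(group, species)
  if (any(column < 1L | column > length(ch)))
    stop("column out of range in group ", group$group_id)
  pos <- cumsum(ch != "-")
  out <- pos[column]
  out[ch[column] == "-"] <- NA_integer_
  out
}

#' Select aligned phospho-acceptor sites
#'
#' Returns the alignment columns of a group at which at least one member
#' carries an observed PTM site of the requested type, in long format:
#' one row per (column, species) with the residue, the ungapped position
#' (`NA` at gaps) and the per-species observed flag.
#'
#' @param group an `ortho_group`.
#' @param catalog site catalog already remapped to the group's proteome.
#' @param ptm_type PTM type to select (default `"phospho"`).
#' @param include_ambiguous include catalog records flagged ambiguous.
#' @return data.frame `group_id`, `column`, `species`, `protein_id`,
#'   `residue`, `position`, `observed`.
#' @export
select_aligned_acceptor_sites <- function(group, catalog,
                                          ptm_type = "phospho",
                                          include_ambiguous = FALSE) {
  cat <- catalog[catalog$ptm_type == ptm_type, , drop = FALSE]
  if (!include_ambiguous && "ambiguous" %in% names(cat))
    cat <- cat[!cat$ambiguous, , drop = FALSE]
  cols <- integer(0)
  obs_by_member <- vector("list", nrow(group$members))
  for (i in seq_len(nrow(group$members))) {
    sp <- group$members$species[i]
    pid <- group$members$protein_id[i]
    pos <- cat$position[cat$species == sp & cat$protein_id == pid]
    obs_by_member[[i]] <- pos
    if (length(pos)) cols <- c(cols, position_to_column(group, sp, pos))
  }
  cols <- sort(unique(cols))
  if (!length(cols)) {
    return(data.frame(group_id = character(), column = integer(),
                      species = character(), protein_id = character(),
                      residue = character(), position = integer(),
                      observed = logical()))
  }
  out <- lapply(seq_len(nrow(group$members)), function(i) {
    sp <- group$members$species[i]
    ch <- row_chars(group, sp)
    pos <- column_to_position(group, sp, cols)
    data.frame(group_id = group$group_id, column = cols, species = sp,
               protein_id = group$members$protein_id[i],
               residue = ch[cols], position = pos,
               observed = !is.na(pos) & pos %in% obs_by_member[[i]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$column, out$species), , drop = FALSE]
}

#' Classify a target residue against a reference phospho-acceptor
#'
#' Categories follow the cross-species acceptor-status scheme:
#' `identical_acceptor_observed_both` / `identical_acceptor` when the
#' target residue equals the reference acceptor; `acceptor_class_changed`
#' for S<->T substitutions (and, under `mode = "broad"`, any change
#' within \{S,T,Y\}); `acceptor_lost` when the acceptor chemistry is gone
#' (including Y<->S/T under the default strict mode, since tyrosine
#' kinases are mechanistically distinct); `gap` when the target is
#' gapped.
#'
#' @param ref_residue reference residue(s), must be S/T/Y.
#' @param target_residue target residue(s) or `"-"`.
#' @param ref_observed,target_observed observed-phospho flags.
#' @param mode `"strict"` (default) or `"broad"`.
#' @return character vector of categories.
#' @export
classify_acceptor_status <- function(ref_residue, target_residue,
                                     ref_observed = TRUE,
                                     target_observed = FALSE,
                                     mode = c("strict", "broad")) {
  mode <- match.arg(mode)
  if (!all(ref_residue %in% ACCEPTORS))
    stop("reference residue is not a phospho-acceptor")
  n <- max(length(ref_residue), length(target_residue))
  ref <- rep_len(ref_residue, n)
  tgt <- rep_len(target_residue, n)
  ro <- rep_len(ref_observed, n)
  to <- rep_len(target_observed, n)
  out <- character(n)
  same <- tgt == ref
  st_swap <- ref %in% c("S", "T") & tgt %in% c("S", "T") & !same
  if (mode == "broad")
    st_swap <- ref %in% ACCEPTORS & tgt %in% ACCEPTORS & !same
  out[same & ro & to] <- "identical_acceptor_observed_both"
  out[same & !(ro & to)] <- "identical_acceptor"
  out[st_swap] <- "acceptor_class_changed"
  out[!same & !st_swap] <- "acceptor_lost"
  out[tgt == "-"] <- "gap"
  out
}

#' Classify one aligned site between two species
#'
#' Convenience wrapper over [classify_acceptor_status()] for the long
#' aligned-site format of [select_aligned_acceptor_sites()].
#'
#' @param aligned_site rows of one alignment column (long format).
#' @param reference_species,target_species species labels.
#' @param mode see [classify_acceptor_status()].
#' @return single category string.
#' @export
classify_aligned_site <- function(aligned_site, reference_species,
                                  target_species,
                                  mode = c("strict", "broad")) {
  r <- aligned_site[aligned_site$species == reference_species, , drop = FALSE]
  t <- aligned_site[aligned_site$species == target_species, , drop = FALSE]
  stopifnot(nrow(r) == 1L, nrow(t) == 1L)
  classify_acceptor_status(r$residue, t$residue, r$observed, t$observed,
                           mode = match.arg(mode))
}

#' Read an ortholog map TSV
#'
#' Columns `group_id, species, protein_id, ortholog_score` (a DIOPT-like
#' integer vote count); rows below `min_score` are dropped, mirroring the
#' conventional score >= 3 input filter.
#'
#' @param path TSV file.
#' @param min_score minimum ortholog score kept (default 3).
#' @return data.frame.
#' @export
read_ortholog_map <- function(path, min_score = 3L) {
  x <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  need <- c("group_id", "species", "protein_id", "ortholog_score")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("ortholog map missing column(s): ", paste(miss, collapse = ", "))
  x[x$ortholog_score >= min_score, need, drop = FALSE]
}

#' Write an ortholog map TSV
#' @param map data.frame `group_id, species, protein_id, ortholog_score`.
#' @param path output file.
#' @export
write_ortholog_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned FASTA files into ortholog groups
#'
#' One aligned FASTA per group under `dir`, named `<group_id>.afa`, row
#' ids `"<species>|<protein_id>"`.
#'
#' @param map ortholog map data.frame (already score-filtered).
#' @param dir directory of aligned FASTA files.
#' @param proteome optional proteome for row validation.
#' @return named list of `ortho_group` objects.
#' @export
read_ortholog_groups <- function(map, dir, proteome = NULL) {
  groups <- lapply(sort(unique(map$group_id)), function(gid) {
    aa <- Biostrings::readAAStringSet(file.path(dir, paste0(gid, ".afa")))
    ids <- sub("\\s.*$", "", names(aa))
    sp <- sub("\\|.*$", "", ids)
    pid <- sub("^[^|]*\\|", "", ids)
    keep <- paste(sp, pid) %in%
      paste(map$species[map$group_id == gid], map$protein_id[map$group_id == gid])
    members <- data.frame(species = sp[keep], protein_id = pid[keep],
                          stringsAsFactors = FALSE)
    ortholog_group(gid, members,
                   setNames(toupper(as.character(aa[keep])), members$species),
                   proteome = proteome)
  })
  setNames(groups, sort(unique(map$group_id)))
}

#' Write ortholog groups as aligned FASTA files
#' @param groups named list of `ortho_group`s.
#' @param dir output directory (created if needed).
#' @export
write_ortholog_groups <- function(groups, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in groups) {
    aa <- Biostrings::AAStringSet(g$alignment)
    names(aa) <- paste(g$members$species, g$members$protein_id, sep = "|")
    Biostrings::writeXStringSet(aa, file.path(dir, paste0(g$group_id, ".afa")))
  }
  invisible(dir)
}
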