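# Kinase-motif PSSM bank: sparse log-odds matrices over window offsets
# -flank..+flank used as phosphosite features. The default bank contains
# 40 synthetic motifs spanning the classic kinase archetypes
# (proline-directed, basophilic, acidophilic, ST-other, Y-kinase); it is
# built deterministically in code and also shipped as a versioned TSV
# fixture (inst/extdata/pssm_bank_v1.tsv).

#' Construct a PSSM bank from a sparse weight table
#'
#' @param weights data.frame with columns `kinase`, `acceptor_class`
#'   (`"ST"`/`"Y"`), `offset` (-flank..flank), `residue`, `weight`
#'   (log-odds units). Cells not listed are 0.
#' @param flank window flank (default 5).
#' @return object of class `pssm_bank`: a `(2*flank+1) x 20 x n_motifs`
#'   array plus per-motif acceptor classes.
#' @export
pssm_bank <- function(weights, flank = 5L) {
  stopifnot(all(c("kinase", "acceptor_class", "offset", "residue",
                  "weight") %in% names(weights)),
            all(weights$acceptor_class %in% c("ST", "Y")),
            all(abs(weights$offset) <= flank),
            all(weights$residue %in% AA20))
  kin <- unique(weights$kinase)
  W <- array(0, dim = c(2L * flank + 1L, 20L, length(kin)),
             dimnames = list(as.character(-flank:flank), AA20, kin))
  W[cbind(weights$offset + flank + 1L,
          match(weights$residue, AA20),
          match(weights$kinase, kin))] <- weights$weight
  cls <- vapply(kin, function(k)
    unique(weights$acceptor_class[weights$kinase == k])[1L], character(1))
  structure(list(W = W, kinases = kin, acceptor_class = cls,
                 flank = flank, version = attr(weights, "version")),
            class = "pssm_bank")
}

#' @export
print.pssm_bank <- function(x, ...) {
  cat("pssm_bank:", length(x$kinases), "motifs (",
      sum(x$acceptor_class == "ST"), "ST /", sum(x$acceptor_class == "Y"),
      "Y ), flank", x$flank, "\n")
  invisible(x)
}

#' Read / write a sparse PSSM bank TSV
#'
#' Columns `kinase, acceptor_class, offset, residue, weight`.
#'
#' @param path TSV file.
#' @param flank window flank.
#' @return a `pssm_bank`.
#' @export
read_pssm_bank <- function(path, flank = 5L) {
  x <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  pssm_bank(x, flank = flank)
}

#' @rdname read_pssm_bank
#' @param bank a `pssm_bank`.
#' @export
write_pssm_bank <- function(bank, path) {
  idx <- which(bank$W != 0, arr.ind = TRUE)
  out <- data.frame(
    kinase = bank$kinases[idx[, 3L]],
    acceptor_class = unname(bank$acceptor_class[bank$kinases[idx[, 3L]]]),
    offset = idx[, 1L] - bank$flank - 1L,
    residue = AA20[idx[, 2L]],
    weight = bank$W[idx])
  out <- out[order(match(out$kinase, bank$kinases), out$offset,
                   out$residue), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Sparse cell list for the default 40-motif bank. Weights are log-odds
# units; informative cells sit at the offsets where the archetype's
# determinant residues live.
default_bank_cells <- function() {
  cell <- function(kinase, class, offset, residue, weight)
    data.frame(kinase = kinase, acceptor_class = class, offset = offset,
               residue = residue, weight = weight,
               stringsAsFactors = FALSE)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- cell(...)
  # 10 proline-directed ST motifs (CDK/MAPK-like): P at +1, variable
  # secondary determinants.
  sec_off <- c(-2L, 2L, 3L, -3L, 2L, -2L, 3L, 2L, -3L, -2L)
  sec_res <- c("P", "P", "K", "L", "R", "S", "P", "L", "P", "V")
  for (i in 1:10) {
    k <- sprintf("ProD_%02d", i)
    add(k, "ST", 1L, "P", 2.0 + 0.05 * (i - 1))
    add(k, "ST", sec_off[i], sec_res[i], 1.0)
  }
  # 10 basophilic ST motifs (PKA/PKC/CAMK-like): R/K at -3/-2.
  b1 <- rep(c("R", "K"), each = 5)
  b2_off <- c(-2L, -2L, -4L, 2L, -2L, -2L, -4L, -2L, 2L, -4L)
  b2_res <- c("R", "K", "R", "F", "L", "K", "K", "R", "L", "K")
  for (i in 1:10) {
    k <- sprintf("Baso_%02d", i)
    add(k, "ST", -3L, b1[i], 2.0 + 0.05 * (i - 1))
    add(k, "ST", b2_off[i], b2_res[i], 1.2)
  }
  # 6 acidophilic ST motifs (CK2-like): D/E downstream.
  a_res <- c("E", "D", "E", "D", "E", "D")
  for (i in 1:6) {
    k <- sprintf("Acid_%02d", i)
    add(k, "ST", 1L, a_res[i], 1.2)
    add(k, "ST", 3L, a_res[i], 2.0 + 0.05 * (i - 1))
    add(k, "ST", 2L, "E", 0.8)
  }
  # 4 other ST motifs (hydrophobic-directed / NEK-like).
  o_off <- list(c(-1L, 4L), c(1L, 4L), c(-1L, -4L), c(2L, 4L))
  o_res <- list(c("L", "F"), c("F", "L"), c("F", "M"), c("W", "L"))
  for (i in 1:4) {
    k <- sprintf("OthST_%02d", i)
    add(k, "ST", o_off[[i]][1L], o_res[[i]][1L], 1.5 + 0.05 * i)
    add(k, "ST", o_off[[i]][2L], o_res[[i]][2L], 1.2)
  }
  # 10 Y-kinase motifs (SRC/EGFR/ABL-like): acidic upstream,
  # hydrophobic downstream.
  y_up <- c("E", "D", "E", "D", "E", "E", "D", "E", "D", "E")
  y_dn <- c("I", "V", "L", "I", "F", "V", "I", "P", "L", "V")
  y_off <- c(-3L, -4L, -3L, -2L, -3L, -4L, -3L, -2L, -4L, -3L)
  for (i in 1:10) {
    k <- sprintf("TyrK_%02d", i)
    add(k, "Y", y_off[i], y_up[i], 2.0 + 0.05 * (i - 1))
    add(k, "Y", 3L, y_dn[i], 1.2)
  }
  out <- do.call(rbind, rows)
  attr(out, "version") <- "pssm_bank_v1"
  out
}

#' The default 40-motif kinase PSSM bank
#'
#' 30 ST motifs (proline-directed, basophilic, acidophilic, other) and
#' 10 Y-kinase motifs with sparse log-odds weights. Identical to the
#' shipped fixture `inst/extdata/pssm_bank_v1.tsv`.
#'
#' @param flank window flank (default 5).
#' @return a `pssm_bank` of 40 motifs.
#' @export
default_pssm_bank <- function(flank = 5L) {
  pssm_bank(default_bank_cells(), flank = flank)
}

#' Score kinase-motif features for site windows
#'
#' Feature k of a window is the sum over window offsets of motif k's
#' weight for the residue at that offset; truncated, gapped or `X`
#' positions contribute 0. Every window is scored against the whole
#' bank (all 40 motifs), whatever its acceptor class; however the window
#' center must be an acceptor present among the bank's classes.
#'
#' @param windows a `site_window`, a list of them, or a character matrix
#'   of padded windows (rows = sites, `2*flank+1` columns).
#' @param bank a `pssm_bank`.
#' @return numeric matrix, sites x motifs.
#' @export
score_features <- function(windows, bank) {
  if (inherits(windows, "site_window")) windows <- list(windows)
  if (is.list(windows)) {
    mat <- t(vapply(windows, function(w) {
      stopifnot(inherits(w, "site_window"), w$flank == bank$flank)
      w$padded
    }, character(2L * bank$flank + 1L)))
  } else mat <- windows
  center <- mat[, bank$flank + 1L]
  cls <- acceptor_class(center)
  if (anyNA(cls) || !all(cls %in% bank$acceptor_class))
    stop("window center is not a phospho-acceptor of the bank's class")
  mat[mat %in% c("-", "X")] <- NA_character_
  ridx <- matrix(match(mat, AA20), nrow = nrow(mat))
  n <- nrow(mat)
  K <- length(bank$kinases)
  F <- matrix(0, n, K, dimnames = list(NULL, bank$kinases))
  for (j in seq_len(ncol(mat))) {
    r <- ridx[, j]
    ok <- !is.na(r)
    if (!any(ok)) next
    F[ok, ] <- F[ok, ] + matrix(bank$W[j, r[ok], ], ncol = K)
  }
  F
}
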