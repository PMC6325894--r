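# Phosphorylation-propensity models: per species and per acceptor class
# (pooled S+T versus Y), a linear maximum-margin classifier over the
# 40 kinase-motif PSSM features, trained by deterministic full-batch
# subgradient descent on the regularised hinge loss and calibrated to
# [0, 1] with a two-parameter logistic (Platt) map. Sites observed by MS
# are always pinned to propensity 1.

#' Padded window matrix for a set of sites
#'
#' Extracts the `2*flank+1` window around each site of a site table and
#' returns them as a character matrix (`NA` beyond the termini),
#' suitable for [score_features()].
#'
#' @param proteome proteome data.frame.
#' @param sites data.frame with `species`, `protein_id`, `position`.
#' @param flank window flank (default 5).
#' @return character matrix, sites x (2*flank+1).
#' @export
padded_windows <- function(proteome, sites, flank = 5L) {
  seqs <- setNames(proteome$sequence,
                   paste(proteome$species, proteome$protein_id, sep = "|"))
  t(vapply(seq_len(nrow(sites)), function(i) {
    s <- seqs[[paste(sites$species[i], sites$protein_id[i], sep = "|")]]
    extract_window(s, sites$position[i], flank)$padded
  }, character(2L * flank + 1L)))
}

#' Enumerate every acceptor site of a proteome as a site table
#'
#' @param proteome proteome data.frame.
#' @param class `"ST"` or `"Y"`.
#' @return data.frame `species`, `protein_id`, `position`, `residue`.
#' @export
all_acceptor_sites <- function(proteome, class = c("ST", "Y")) {
  class <- match.arg(class)
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    pos <- acceptor_positions(proteome$sequence[i], class)
    if (!length(pos)) return(NULL)
    data.frame(species = proteome$species[i],
               protein_id = proteome$protein_id[i], position = pos,
               residue = substring(proteome$sequence[i], pos, pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(), protein_id = character(),
                      position = integer(), residue = character())
  out
}

#' Assemble propensity training sets
#'
#' Positives are windows around detected phosphosites of the requested
#' acceptor class (initial score 1); negatives are windows around
#' acceptors of the same class never detected in the catalog (initial
#' score 0). Both are sampled uniformly without replacement, capped at
#' the available count; default sample sizes are 2000 for the pooled
#' S+T class and 800 for Y.
#'
#' @param catalog site catalog (one species; `ptm_type == "phospho"`
#'   rows are used).
#' @param proteome proteome data.frame restricted to the same species.
#' @param class `"ST"` or `"Y"`.
#' @param n_samples per-class cap (default 2000 ST / 800 Y).
#' @param seed RNG seed (sampling is reproducible from it).
#' @return list with `positives` and `negatives` site data.frames.
#' @export
assemble_training_sets <- function(catalog, proteome,
                                   class = c("ST", "Y"),
                                   n_samples = NULL, seed = 1L) {
  class <- match.arg(class)
  if (is.null(n_samples)) n_samples <- if (class == "ST") 2000L else 800L
  cat <- catalog[catalog$ptm_type == "phospho", , drop = FALSE]
  if ("ambiguous" %in% names(cat)) cat <- cat[!cat$ambiguous, , drop = FALSE]
  cat <- cat[!is.na(acceptor_class(cat$residue)) &
               acceptor_class(cat$residue) == class, , drop = FALSE]
  pos_sites <- unique(cat[, c("species", "protein_id", "position",
                              "residue")])
  acc <- all_acceptor_sites(proteome, class)
  det_key <- paste(pos_sites$species, pos_sites$protein_id,
                   pos_sites$position)
  neg_sites <- acc[!paste(acc$species, acc$protein_id, acc$position) %in%
                     det_key, , drop = FALSE]
  if (!nrow(pos_sites)) stop("no detected ", class, " sites to train on")
  if (!nrow(neg_sites)) stop("no undetected ", class, " acceptors to train on")
  withr::with_seed(seed, {
    pi <- sample(nrow(pos_sites), min(n_samples, nrow(pos_sites)))
    ni <- sample(nrow(neg_sites), min(n_samples, nrow(neg_sites)))
  })
  list(positives = pos_sites[sort(pi), , drop = FALSE],
       negatives = neg_sites[sort(ni), , drop = FALSE])
}

#' Train a propensity model
#'
#' Linear maximum-margin classifier on standardised PSSM features, fit
#' by full-batch subgradient descent on the L2-regularised hinge loss
#' (Pegasos schedule: fixed `n_iter` iterations, step `1/(lambda * t)`,
#' projection onto the `1/sqrt(lambda)` ball, and the returned weights
#' are the average over the second half of the iterations, which is
#' what makes the fixed-step schedule converge). Classes are
#' cost-balanced in the loss (each class contributes weight 1/2
#' regardless of its size, the classic SVM cost-factor idiom), so an
#' abundant negative class cannot drown the positives. The bias is
#' carried as an augmented always-1 feature. A two-parameter logistic
#' calibration is fitted on the training margins with Platt's soft
#' targets. Fully deterministic given data and hyperparameters.
#'
#' @param positives,negatives site data.frames
#'   ([assemble_training_sets()] output).
#' @param proteome proteome supplying the windows.
#' @param bank `pssm_bank` feature bank.
#' @param species,class metadata stored in the model.
#' @param lambda L2 regularisation (default 1e-3).
#' @param n_iter subgradient iterations (default 500).
#' @param seed recorded in metadata (training itself is deterministic).
#' @param flank window flank.
#' @return object of class `propensity_model`.
#' @export
train_propensity_model <- function(positives, negatives, proteome, bank,
                                   species = NA_character_,
                                   class = "ST", lambda = 1e-3,
                                   n_iter = 500L, seed = NA_integer_,
                                   flank = 5L) {
  stopifnot(nrow(positives) > 0L, nrow(negatives) > 0L)
  X <- rbind(score_features(padded_windows(proteome, positives, flank), bank),
             score_features(padded_windows(proteome, negatives, flank), bank))
  y <- rep(c(1, -1), c(nrow(positives), nrow(negatives)))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (all(scl == 0))
    stop("degenerate training set: all features constant across classes")
  scl[scl == 0] <- 1
  Xs <- cbind(sweep(sweep(X, 2L, ctr), 2L, scl, "/"), bias = 1)
  w <- numeric(ncol(Xs))
  n <- nrow(Xs)
  cw <- ifelse(y > 0, n / (2 * sum(y > 0)), n / (2 * sum(y < 0)))
  radius <- 1 / sqrt(lambda)
  wsum <- numeric(ncol(Xs))
  n_avg <- 0L
  for (t in seq_len(n_iter)) {
    marg <- drop(Xs %*% w) * y
    viol <- marg < 1
    grad <- lambda * w -
      if (any(viol))
        colSums(Xs[viol, , drop = FALSE] * (y * cw)[viol]) / n else 0
    w <- w - grad / (lambda * t)
    nw <- sqrt(sum(w^2))
    if (nw > radius) w <- w * radius / nw
    if (t > n_iter / 2) {
      wsum <- wsum + w
      n_avg <- n_avg + 1L
    }
  }
  w <- wsum / n_avg
  margins <- drop(Xs %*% w)
  # Platt soft targets avoid divergence on separable data.
  npos <- sum(y > 0); nneg <- sum(y < 0)
  tgt <- ifelse(y > 0, (npos + 1) / (npos + 2), 1 / (nneg + 2))
  fit <- suppressWarnings(glm(tgt ~ margins, family = binomial()))
  calib <- unname(coef(fit))
  structure(list(species = species, acceptor_class = class,
                 kinases = bank$kinases, flank = flank,
                 center = ctr, scale = scl,
                 weights = w[-length(w)], bias = w[length(w)],
                 calibration = c(A = calib[1L], B = calib[2L]),
                 meta = list(n_pos = nrow(positives),
                             n_neg = nrow(negatives),
                             lambda = lambda, n_iter = n_iter,
                             seed = seed,
                             bank_version = bank$version)),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("propensity_model [%s/%s]: %d features, n+=%d n-=%d\n",
              x$species, x$acceptor_class, length(x$weights),
              x$meta$n_pos, x$meta$n_neg))
  invisible(x)
}

model_margin <- function(model, features) {
  Xs <- sweep(sweep(features, 2L, model$center), 2L, model$scale, "/")
  drop(Xs %*% model$weights) + model$bias
}

#' Predict phosphorylation propensity
#'
#' Calibrated score in `[0, 1]` for each window; windows flagged
#' `observed` are pinned to exactly 1 irrespective of the model output.
#'
#' @param model a `propensity_model`.
#' @param windows windows acceptable to [score_features()] (their class
#'   must match the model's).
#' @param observed logical vector (recycled): site observed by MS.
#' @param bank the `pssm_bank` used at training time.
#' @return numeric vector of propensities in `[0, 1]`.
#' @export
predict_propensity <- function(model, windows, observed = FALSE,
                               bank = default_pssm_bank(model$flank)) {
  if (!identical(bank$kinases, model$kinases))
    stop("bank does not match the model's feature order")
  F <- score_features(windows, bank)
  center <- if (is.list(windows) || inherits(windows, "site_window")) {
    if (inherits(windows, "site_window")) windows <- list(windows)
    vapply(windows, function(w) w$padded[model$flank + 1L], character(1))
  } else windows[, model$flank + 1L]
  if (!all(acceptor_class(center) == model$acceptor_class))
    stop("window acceptor class does not match the model (",
         model$acceptor_class, ")")
  p <- plogis(model$calibration[["A"]] +
                model$calibration[["B"]] * model_margin(model, F))
  p[rep_len(observed, length(p))] <- 1
  unname(p)
}

#' Save / load a propensity model as JSON
#'
#' @param model a `propensity_model`.
#' @param path JSON file.
#' @export
save_propensity_model <- function(model, path) {
  obj <- unclass(model)
  obj$calibration <- as.list(model$calibration)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_propensity_model
#' @export
load_propensity_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$format_version <- NULL
  for (f in c("center", "scale", "weights")) {
    obj[[f]] <- as.numeric(obj[[f]])
    names(obj[[f]]) <- obj$kinases
  }
  obj$calibration <- c(A = as.numeric(obj$calibration$A),
                       B = as.numeric(obj$calibration$B))
  structure(obj, class = "propensity_model")
}

#' Rank-based AUC (Mann-Whitney)
#'
#' @param scores numeric predictions.
#' @param labels logical or 0/1 truth.
#' @return area under the ROC curve.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  stopifnot(n1 > 0L, n0 > 0L)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
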