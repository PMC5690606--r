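#' Multivoxel contrast definitions
#'
#' Three contrasts are analyzed: `stimulus_vs_blank` (all Glass-pattern
#' epochs against blank epochs — basic visual responsiveness),
#' `dynamic_vs_static` (dynamic against static presentation, both structured
#' and random), and `structured_vs_random` (static structured forms against
#' static random dipoles — global form). Condition labels follow the
#' `<class>_<mode>` convention of the schedule builder.
#'
#' @param name Contrast name.
#' @return A `contrast_def`: list with `name` and a classifier of condition
#'   labels into the two classes.
#' @export
contrast_def <- function(name = c("stimulus_vs_blank", "dynamic_vs_static",
                                  "structured_vs_random")) {
  name <- match.arg(name)
  structure(list(name = name), class = "contrast_def")
}

# Split the stimulus condition labels of a session into the two classes of a
# contrast. Returns NULL when the contrast is not applicable (a class would
# be empty), which callers translate into "session dropped for this contrast".
condition_classes <- function(labels, cdef) {
  labels <- setdiff(labels, c("blank", "pinwheel_on", "pinwheel_off"))
  cls <- switch(cdef$name,
    stimulus_vs_blank = list(a = labels, b = "blank"),
    dynamic_vs_static = list(a = grep("_dynamic$", labels, value = TRUE),
                             b = grep("_static$", labels, value = TRUE)),
    structured_vs_random = list(
      a = grep("^(concentric|radial)_static$", labels, value = TRUE),
      b = grep("^random_static$", labels, value = TRUE)))
  if (length(cls$a) == 0 || length(cls$b) == 0) return(NULL)
  cls
}

#' Rank VOI voxels by pinwheel responsiveness
#'
#' Voxels are ordered by descending t-value of the pinwheel (localizer) GLM —
#' a metric independent of the Glass-pattern contrasts — keeping only voxels
#' with positive response (negative BOLD is excluded from all analyses), and
#' truncating at `truncate` voxels so pool sizes are comparable across VOIs
#' and sessions. Ties break by ascending voxel index.
#'
#' @param pinwheel_glm A `glm_result` fitted on the pinwheel run.
#' @param voi Integer indices (or logical mask) of the VOI's voxels.
#' @param truncate Maximum ranking length (default 70).
#' @return A `voxel_ranking`: list with `voxels` (global indices in rank
#'   order), `t`, `truncated_at`, and `flagged` (TRUE when no voxel
#'   responded positively).
#' @export
rank_voxels <- function(pinwheel_glm, voi, truncate = 70) {
  idx <- if (is.logical(voi)) which(voi) else as.integer(voi)
  if (length(idx) == 0) stop("empty VOI", call. = FALSE)
  tv <- pinwheel_glm$t[idx]
  pos <- tv > 0
  if (!any(pos)) {
    warning("no positively responsive voxels in VOI; session flagged")
    return(structure(list(voxels = integer(0), t = numeric(0),
                          truncated_at = truncate, flagged = TRUE),
                     class = "voxel_ranking"))
  }
  ord <- order(-tv[pos], idx[pos])
  keep <- idx[pos][ord]
  tk <- tv[pos][ord]
  if (length(keep) < truncate)
    warning(sprintf("only %d positive voxels (< %d); all retained",
                    length(keep), truncate))
  keep_n <- min(truncate, length(keep))
  structure(list(voxels = keep[seq_len(keep_n)], t = tk[seq_len(keep_n)],
                 truncated_at = truncate, flagged = FALSE),
            class = "voxel_ranking")
}

# Volumes whose acquisition start falls inside [onset, onset + duration),
# shifted by exactly one volume (the 6 s hemodynamic delay).
epoch_volumes <- function(onset, duration, tr, n_vol, delay_volumes = 1) {
  vols <- which((seq_len(n_vol) - 1) * tr >= onset &
                  (seq_len(n_vol) - 1) * tr < onset + duration)
  vols <- vols + delay_volumes
  vols[vols >= 1 & vols <= n_vol]
}

#' Assemble class-labeled multivoxel response patterns
#'
#' One pattern per schedule epoch: each ranked voxel's response is the mean
#' of the volumes inside the epoch's boxcar shifted by one volume (6 s, the
#' time to scan one volume). Epochs of the two classes are paired in temporal
#' order ("condition pairs"); unmatched epochs are dropped so every fold
#' stays balanced and chance is 0.5.
#'
#' @param run A `bold_run`.
#' @param contrast A [contrast_def()] (or its name).
#' @param ranking A [rank_voxels()] result.
#' @param max_patterns Cap on the total pattern count fed to the classifier
#'   (default 189, the largest per-session count the design produces); epochs
#'   beyond the cap are left unused so the binomial chance model stays in its
#'   calibrated regime.
#' @return A `pattern_matrix`: list with `x` (patterns x voxels), `y` (class
#'   labels `"a"`/`"b"`), `pair` (pair index), `n` (pattern count),
#'   `contrast`, or `NULL` with a message when the contrast is inapplicable
#'   to the session's condition set (session dropped for that contrast).
#' @export
assemble_patterns <- function(run, contrast, ranking, max_patterns = 189) {
  if (is.character(contrast)) contrast <- contrast_def(contrast)
  sched <- run$schedule
  n_vol <- ncol(run$data)
  labels <- unique(sched$trial_type)
  cls <- condition_classes(labels, contrast)
  if (is.null(cls)) {
    message("contrast ", contrast$name,
            " not applicable to this session's conditions; session dropped")
    return(NULL)
  }
  if (length(ranking$voxels) == 0)
    stop("empty voxel ranking", call. = FALSE)
  collapse <- function(conds) {
    ev <- which(sched$trial_type %in% conds)
    rows <- lapply(ev, function(i) {
      vols <- epoch_volumes(sched$onset[i], sched$duration[i], run$tr, n_vol)
      if (length(vols) == 0) return(NULL)
      rowMeans(run$data[ranking$voxels, vols, drop = FALSE])
    })
    do.call(rbind, Filter(Negate(is.null), rows))
  }
  xa <- collapse(cls$a)
  xb <- collapse(cls$b)
  n_pairs <- min(nrow(xa), nrow(xb), floor(max_patterns / 2))
  xa <- xa[seq_len(n_pairs), , drop = FALSE]
  xb <- xb[seq_len(n_pairs), , drop = FALSE]
  structure(list(x = rbind(xa, xb),
                 y = rep(c("a", "b"), each = n_pairs),
                 pair = rep(seq_len(n_pairs), 2),
                 n = 2 * n_pairs, contrast = contrast$name),
            class = "pattern_matrix")
}

#' Binomial chance level for classification accuracy
#'
#' The upper chance boundary is the smallest k with
#' `Binomial(n, 0.5) CDF >= 0.95`, returned as a proportion k/n; the
#' symmetric lower boundary (n - k)/n supports below-chance detection. As n
#' grows both boundaries approach 0.5.
#'
#' @param n Number of patterns (trials).
#' @return List with `upper`, `lower`, `k`, `n`.
#' @export
chance_level <- function(n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  k <- stats::qbinom(0.95, n, 0.5)
  list(upper = k / n, lower = (n - k) / n, k = k, n = n)
}

#' 8-fold cross-validated linear classification
#'
#' Condition pairs are shuffled (seeded) and dealt round-robin into
#' `n_folds` disjoint folds that cover every pattern exactly once; each fold
#' holds out whole pairs so classes stay balanced. Per fold, a linear
#' maximum-margin classifier is trained on the remaining pairs — with
#' per-voxel z-scoring fit on the training folds only — and scored on the
#' held-out patterns. The session's reported metric is the accuracy at the
#' full pool size (70 voxels by default); an accuracy-vs-pool-size trace over
#' 1..pool_size voxels is computed on request. A session is flagged
#' non-significant when the mean accuracy plus one SD does not exceed the
#' upper binomial chance boundary, or the mean falls below the lower
#' boundary (below-chance classification).
#'
#' @param patterns A `pattern_matrix` with at least `n_folds` patterns per
#'   class.
#' @param pool_size Number of top-ranked voxels to use (truncated with a
#'   warning if it exceeds the available ranking).
#' @param n_folds Number of cross-validation folds (default 8).
#' @param C Classifier regularization constant.
#' @param zscore Standardize each voxel within training folds (default TRUE).
#' @param seed Seed for the fold assignment.
#' @param trace Also compute the accuracy trace over pool sizes
#'   1..pool_size.
#' @return A `classification_result`: list with `fold_accuracies`, `mu_acc`,
#'   `sigma_acc`, `chance` (from [chance_level()]), `n`, `below_chance`
#'   (non-significance flag), `pool_size`, and `trace` (or NULL).
#' @export
crossvalidate <- function(patterns, pool_size = 70, n_folds = 8, C = 1,
                          zscore = TRUE, seed = NULL, trace = FALSE) {
  stopifnot(inherits(patterns, "pattern_matrix"))
  n_pairs <- max(patterns$pair)
  if (n_pairs < n_folds)
    stop("need at least ", n_folds, " patterns per class", call. = FALSE)
  avail <- ncol(patterns$x)
  if (pool_size > avail) {
    warning(sprintf("pool_size %d exceeds ranking length %d; truncated",
                    pool_size, avail))
    pool_size <- avail
  }
  if (!is.null(seed)) set.seed(seed)
  fold_of_pair <- sample(rep(seq_len(n_folds), length.out = n_pairs))
  fold <- fold_of_pair[patterns$pair]

  run_folds <- function(k) {
    acc <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr_i <- fold != f
      xtr <- patterns$x[tr_i, seq_len(k), drop = FALSE]
      xte <- patterns$x[!tr_i, seq_len(k), drop = FALSE]
      if (zscore) {
        mu <- colMeans(xtr)
        sd_ <- apply(xtr, 2, stats::sd)
        sd_[sd_ == 0] <- 1
        xtr <- sweep(sweep(xtr, 2, mu), 2, sd_, "/")
        xte <- sweep(sweep(xte, 2, mu), 2, sd_, "/")
      }
      m <- svm_linear(xtr, patterns$y[tr_i], C = C)
      acc[f] <- mean(predict(m, xte) == patterns$y[!tr_i])
    }
    acc
  }

  fold_acc <- run_folds(pool_size)
  tr <- NULL
  if (trace) tr <- vapply(seq_len(pool_size),
                          function(k) mean(run_folds(k)), numeric(1))
  mu <- mean(fold_acc)
  sg <- stats::sd(fold_acc)
  ch <- chance_level(patterns$n)
  flag <- (mu + sg <= ch$upper) || (mu <= ch$lower)
  structure(list(fold_accuracies = fold_acc, mu_acc = mu, sigma_acc = sg,
                 chance = ch, n = patterns$n, below_chance = flag,
                 pool_size = pool_size, trace = tr, fold = fold),
            class = "classification_result")
}
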