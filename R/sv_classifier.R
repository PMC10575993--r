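## Random-forest ensemble over the 14 pair features. Training pairs a curated
## positive set with an equal-sized uniformly sampled negative set; candidate
## pairs are scored by the fraction of trees voting SV. Missing feature values
## are imputed with the training-set median (boolean NA -> 0).

#' Forest hyperparameters
#'
#' @param n_trees number of trees (default 500).
#' @param m_try variables tried at each split (default 3).
#' @param seed RNG seed for reproducible fits.
#' @return list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500, m_try = 3, seed = 1) {
  stopifnot(n_trees >= 1, m_try >= 1, m_try <= 14)
  structure(list(n_trees = n_trees, m_try = m_try, seed = seed),
            class = "forest_config")
}

#' Assemble a labeled training set with equal negatives
#'
#' Negatives are sampled uniformly without replacement from all unordered
#' gene pairs of the universe that are not positives; deterministic given
#' `seed`.
#'
#' @param positives data.frame with `gene1`, `gene2`.
#' @param universe character vector of gene symbols.
#' @param seed integer seed.
#' @return list with `positives`, `negatives` (data.frames) of equal size.
#' @export
build_training_set <- function(positives, universe, seed = 1) {
  n_pos <- nrow(positives)
  n_all <- choose(length(universe), 2)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  pos_keys <- unique(key(positives$gene1, positives$gene2))
  n_avail <- n_all - length(pos_keys)
  if (n_avail < n_pos) {
    stop("universe too small: ", n_avail, " non-positive pairs available, ",
         n_pos, " needed")
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  negatives <- withr_seed({
    if (n_all <= 2e6) {
      cmb <- utils::combn(sort(universe), 2)
      keys <- paste(cmb[1, ], cmb[2, ], sep = "|")
      pool <- which(!(keys %in% pos_keys))
      pick <- sample(pool, n_pos)
      data.frame(gene1 = cmb[1, pick], gene2 = cmb[2, pick],
                 stringsAsFactors = FALSE)
    } else {
      seen <- character(0)
      g1 <- g2 <- character(0)
      while (length(seen) < n_pos) {
        a <- sample(universe, 1); b <- sample(universe, 1)
        if (a == b) next
        kk <- key(a, b)
        if (kk %in% pos_keys || kk %in% seen) next
        seen <- c(seen, kk)
        g1 <- c(g1, min(a, b)); g2 <- c(g2, max(a, b))
      }
      data.frame(gene1 = g1, gene2 = g2, stringsAsFactors = FALSE)
    }
  })
  list(positives = positives[, c("gene1", "gene2")], negatives = negatives)
}

impute_features <- function(x, medians = NULL) {
  x <- as.data.frame(x)
  if (is.null(medians)) {
    medians <- vapply(x, function(v) {
      m <- stats::median(v, na.rm = TRUE)
      if (is.na(m)) 0 else m
    }, numeric(1))
  }
  for (j in names(x)) {
    v <- x[[j]]
    v[is.na(v)] <- medians[[j]]
    x[[j]] <- v
  }
  list(data = x, medians = medians)
}

#' Train the SV random-forest classifier
#'
#' @param features data.frame of feature columns only (one row per pair).
#' @param labels logical or `"SV"`/`"non-SV"` vector.
#' @param cfg a [forest_config()].
#' @return list of class `sv_model` with the fitted forest, feature names,
#'   training medians for imputation, and variable importances.
#' @export
train_sv_classifier <- function(features, labels, cfg = forest_config()) {
  lab <- if (is.logical(labels)) labels else labels == "SV"
  if (length(unique(lab)) < 2) stop("training labels contain a single class")
  all_na <- vapply(features, function(v) all(is.na(v)), logical(1))
  if (any(all_na)) stop("all-NA feature column(s): ",
                        paste(names(features)[all_na], collapse = ", "))
  imp <- impute_features(features)
  y <- factor(ifelse(lab, "SV", "nonSV"), levels = c("nonSV", "SV"))
  set.seed(cfg$seed)
  forest <- randomForest::randomForest(
    x = imp$data, y = y, ntree = cfg$n_trees,
    mtry = min(cfg$m_try, ncol(imp$data)), importance = TRUE)
  structure(list(forest = forest, feature_names = names(features),
                 medians = imp$medians, config = cfg,
                 importance = randomForest::importance(forest)),
            class = "sv_model")
}

#' Score candidate pairs with a fitted SV classifier
#'
#' @param model an `sv_model`.
#' @param candidates data.frame containing (at least) the model's feature
#'   columns; extra columns are carried through.
#' @param threshold probability above which a pair is flagged candidate-SV.
#' @return input data.frame plus `sv_probability` (fraction of trees voting
#'   SV) and logical `candidate_sv`.
#' @export
predict_sv <- function(model, candidates, threshold = 0.5) {
  if (nrow(candidates) == 0) {
    candidates$sv_probability <- numeric(0)
    candidates$candidate_sv <- logical(0)
    return(candidates)
  }
  miss <- setdiff(model$feature_names, names(candidates))
  if (length(miss)) stop("candidate table missing feature(s): ",
                         paste(miss, collapse = ", "))
  x <- candidates[, model$feature_names, drop = FALSE]
  n_all_na <- sum(rowSums(!is.na(x)) == 0)
  if (n_all_na) message(n_all_na, " candidate(s) with all-NA features imputed from training medians")
  x <- impute_features(x, model$medians)$data
  prob <- stats::predict(model$forest, newdata = x, type = "prob")[, "SV"]
  candidates$sv_probability <- as.numeric(prob)
  candidates$candidate_sv <- candidates$sv_probability > threshold
  candidates
}

#' Stratified cross-validated AUC of the SV classifier
#'
#' @param features feature data.frame.
#' @param labels logical or `"SV"`/`"non-SV"` labels.
#' @param n_folds number of stratified folds.
#' @param cfg a [forest_config()]; its seed also fixes the fold assignment.
#' @return pooled out-of-fold rank AUC.
#' @export
evaluate_auc <- function(features, labels, n_folds = 5, cfg = forest_config()) {
  lab <- if (is.logical(labels)) labels else labels == "SV"
  if (min(sum(lab), sum(!lab)) < n_folds) {
    stop("too few examples per class to stratify into ", n_folds, " folds")
  }
  set.seed(cfg$seed)
  fold <- integer(length(lab))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(lab == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  prob <- rep(NA_real_, length(lab))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    model <- train_sv_classifier(features[tr, , drop = FALSE], lab[tr], cfg)
    scored <- predict_sv(model, features[!tr, , drop = FALSE])
    prob[!tr] <- scored$sv_probability
  }
  rank_auc(prob, lab)
}
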