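# Feature construction, evaluation metrics, stratified k-fold
# cross-validation, and a randomized decision-tree ensemble discriminator.

#' Default property scales used as classifier features
#'
#' Hydrophobicity (published retention-time coefficients), isoelectric point
#' (textbook values) and the synthetic stand-in long-range non-bonded energy
#' scale bundled with the package.
#'
#' @return List of three complete [property_scale()] objects.
#' @export
default_feature_scales <- function() {
  lapply(c("mant_hydrophobicity", "isoelectric_point",
           "longrange_energy_synthetic"), get_property_scale)
}

#' Build classifier feature vectors
#'
#' The default (`mode = "full"`) vector has 15 entries per peptide: the
#' position-specific energies under the amyloid matrix (`phi_amy_p1..p6`,
#' kcal/mol), the same under the non-amyloid matrix (`phi_non_p1..p6`), and
#' three property totals. `mode = "energies"` keeps only the 12 energies;
#' `mode = "delta"` uses the 6 per-position energy differentials
#' (`dphi_p1..p6`); `mode = "delta_total"` reduces to the single summed
#' differential (`delta_phi_total`), the scalar on which the sign
#' discriminator operates.
#'
#' @param sequence Character vector of hexapeptides.
#' @inheritParams score_peptide
#' @param scales List of complete [property_scale()] objects appended as
#'   totals (`prop_<name>` columns); defaults to
#'   [default_feature_scales()]. Ignored unless `mode = "full"`.
#' @param mode Feature set, see above.
#' @return Numeric matrix, one row per peptide, with stable column names.
#' @export
#' @examples
#' build_features("STVIIE", mode = "energies")
build_features <- function(sequence, amy = amyloid_potentials(),
                           non = nonamyloid_potentials(),
                           scales = default_feature_scales(),
                           mode = c("full", "energies", "delta",
                                    "delta_total")) {
  mode <- match.arg(mode)
  assert_sequences(sequence)
  idx <- residue_index_matrix(sequence)
  n <- length(sequence)
  cell <- function(pot) matrix(unclass(pot)[cbind(as.vector(idx),
                                                  rep(seq_len(6L), each = n))],
                               nrow = n)
  ea <- cell(amy)
  en <- cell(non)
  colnames(ea) <- paste0("phi_amy_p", 1:6)
  colnames(en) <- paste0("phi_non_p", 1:6)
  if (mode %in% c("delta", "delta_total")) {
    d <- ea - en
    colnames(d) <- paste0("dphi_p", 1:6)
    if (mode == "delta_total")
      d <- matrix(rowSums(d), ncol = 1,
                  dimnames = list(NULL, "delta_phi_total"))
    return(d)
  }
  feats <- cbind(ea, en)
  if (mode == "full") {
    if (inherits(scales, "property_scale")) scales <- list(scales)
    props <- vapply(scales, function(sc) total_property(sequence, sc),
                    numeric(n))
    if (n == 1) props <- matrix(props, nrow = 1)
    colnames(props) <- paste0("prop_",
                              vapply(scales, `[[`, "", "name"))
    feats <- cbind(feats, props)
  }
  feats
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, with amyloid as the
#' positive class. A requested metric whose denominator is zero is an
#' error, not a silent 0; restrict `metrics` to compute a defined subset
#' (e.g. sensitivity on a positive-only dataset).
#'
#' @param counts A [confusion_counts()] object (or list with `tp`, `fp`,
#'   `tn`, `fn`).
#' @param metrics Which metrics to compute.
#' @return List with the requested subset of `sensitivity`, `specificity`,
#'   `accuracy`; class `discrimination_metrics`.
#' @export
#' @examples
#' compute_metrics(confusion_counts(tp = 123, fp = 0, tn = 0, fn = 16),
#'                 metrics = "sensitivity")
compute_metrics <- function(counts, metrics = c("sensitivity",
                                                "specificity", "accuracy")) {
  if (!inherits(counts, "confusion_counts"))
    counts <- confusion_counts(counts$tp, counts$fp, counts$tn, counts$fn)
  metrics <- match.arg(metrics, several.ok = TRUE)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  out <- list()
  if ("sensitivity" %in% metrics) {
    if (tp + fn == 0) stop("sensitivity undefined: no positive records",
                           call. = FALSE)
    out$sensitivity <- tp / (tp + fn)
  }
  if ("specificity" %in% metrics) {
    if (tn + fp == 0) stop("specificity undefined: no negative records",
                           call. = FALSE)
    out$specificity <- tn / (tn + fp)
  }
  if ("accuracy" %in% metrics) {
    if (tp + tn + fp + fn == 0) stop("accuracy undefined: no records",
                                     call. = FALSE)
    out$accuracy <- (tp + tn) / (tp + tn + fp + fn)
  }
  structure(out, class = "discrimination_metrics")
}

#' @export
print.discrimination_metrics <- function(x, ...) {
  cat(paste(sprintf("%s %.3f", names(x), unlist(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Assign cross-validation folds
#'
#' Random fold assignment, by default stratified so that every fold
#' preserves the class ratio to within one record per class.
#'
#' @param labels Factor or character vector of record labels.
#' @param n_folds Number of folds (>= 2, <= number of records; with
#'   stratification, <= size of the smallest class).
#' @param seed Optional integer seed making the assignment reproducible.
#' @param stratified Stratify folds by label.
#' @return Integer vector of fold ids in `1..n_folds`, one per record.
#' @export
make_folds <- function(labels, n_folds, seed = NULL, stratified = TRUE) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n_folds < 2 || n_folds > n)
    stop("n_folds must be between 2 and the number of records",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      ii <- which(labels == cl)
      if (n_folds > length(ii))
        stop(sprintf("n_folds (%d) exceeds size of class '%s' (%d)",
                     n_folds, cl, length(ii)), call. = FALSE)
      folds[ii] <- sample(rep_len(seq_len(n_folds), length(ii)))
    }
  } else {
    folds <- sample(rep_len(seq_len(n_folds), n))
  }
  folds
}

#' Train a randomized decision-tree ensemble
#'
#' Bagged ensemble of randomized decision trees (random forest): 100
#' unpruned trees by default, each split drawn from a random subset of
#' `floor(sqrt(p))` features, majority-vote prediction. Deterministic for a
#' fixed seed.
#'
#' @param x Numeric feature matrix (rows = peptides).
#' @param y Class labels (two levels required).
#' @param ntree Number of trees.
#' @param mtry Features tried per split; default `floor(sqrt(ncol(x)))`.
#' @param nodesize Minimum terminal-node size; values above the
#'   randomForest default of 1 regularize the trees, which helps when the
#'   true class boundary is a smooth threshold on a few features.
#' @param seed Optional integer seed.
#' @return A fitted `randomForest` object.
#' @export
train_ensemble <- function(x, y, ntree = 100, mtry = NULL, nodesize = 1,
                           seed = NULL) {
  y <- factor(as.character(y))
  if (nlevels(y) < 2)
    stop("training data must contain both classes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  randomForest::randomForest(x = as.matrix(x), y = y, ntree = ntree,
                             mtry = mtry %||% max(1L, floor(sqrt(ncol(x)))),
                             nodesize = nodesize)
}

#' Cross-validated evaluation of the ensemble discriminator
#'
#' Builds feature vectors for every labeled peptide, assigns stratified
#' folds, trains the ensemble on each set of `n_folds - 1` folds and
#' predicts the held-out fold, then pools the confusion counts over all
#' folds (every record is tested exactly once) and reports
#' sensitivity/specificity/accuracy.
#'
#' @param ds A [peptide_dataset()] with both classes and no unlabeled
#'   records.
#' @inheritParams build_features
#' @param n_folds Number of folds (5, 10 and 20 are the conventional
#'   choices; any value >= 2 compatible with the class sizes is allowed).
#' @param seed Integer seed controlling fold assignment and tree
#'   randomness.
#' @param stratified Stratify folds by class.
#' @param ntree,mtry,nodesize Ensemble size, per-split feature draw and
#'   minimum terminal-node size, as in [train_ensemble()].
#' @return List with `metrics`, pooled `counts`, `per_fold` (data frame of
#'   per-fold counts) and the fold assignment `folds`.
#' @export
cross_validate <- function(ds, amy = amyloid_potentials(),
                           non = nonamyloid_potentials(),
                           scales = default_feature_scales(),
                           mode = c("full", "energies", "delta",
                                    "delta_total"),
                           n_folds = 10, seed = NULL, stratified = TRUE,
                           ntree = 100, mtry = NULL, nodesize = 1) {
  stopifnot(inherits(ds, "peptide_dataset"))
  mode <- match.arg(mode)
  if (any(ds$label == "unlabeled"))
    stop("dataset contains unlabeled records", call. = FALSE)
  y <- factor(as.character(ds$label), levels = c("amyloid", "non_amyloid"))
  if (any(table(y) == 0))
    stop("dataset must contain both classes", call. = FALSE)
  x <- build_features(ds$sequence, amy, non, scales, mode)
  folds <- make_folds(y, n_folds, seed = seed, stratified = stratified)
  per_fold <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    test <- folds == k
    fit <- train_ensemble(x[!test, , drop = FALSE], y[!test], ntree = ntree,
                          mtry = mtry, nodesize = nodesize,
                          seed = if (!is.null(seed)) seed + k else NULL)
    pred <- stats::predict(fit, x[test, , drop = FALSE])
    truth <- y[test]
    per_fold[[k]] <- data.frame(
      fold = k,
      tp = sum(truth == "amyloid" & pred == "amyloid"),
      fp = sum(truth == "non_amyloid" & pred == "amyloid"),
      tn = sum(truth == "non_amyloid" & pred == "non_amyloid"),
      fn = sum(truth == "amyloid" & pred == "non_amyloid"))
  }
  per_fold <- do.call(rbind, per_fold)
  pooled <- confusion_counts(tp = sum(per_fold$tp), fp = sum(per_fold$fp),
                             tn = sum(per_fold$tn), fn = sum(per_fold$fn))
  list(metrics = compute_metrics(pooled), counts = pooled,
       per_fold = per_fold, folds = folds)
}
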