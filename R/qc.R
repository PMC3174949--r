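#' Label replicate spots via regression bands
#'
#' Training labels for the reliability classifier are derived from
#' replicate agreement: for a spot in subarray a, a simple linear
#' regression of subarray a's log2 intensities on each other subarray's
#' values (over all shared peptides) is fitted, and the spot is labeled
#' unreliable if it falls outside the `level` regression band in either
#' partner regression. By default the band is the prediction band for a
#' new observation (`fit +/- t * s * sqrt(1 + 1/n + (x - xbar)^2 / Sxx)`);
#' the narrower mean-response confidence band is available via
#' `band = "confidence"` but flags far more spots at realistic n.
#'
#' @param replicates numeric matrix, one row per peptide, one column
#'   per subarray (>= 3 columns), of log2 intensities; rownames are
#'   peptide ids.
#' @param level band coverage level, default 0.95.
#' @param band `"prediction"` (default) or `"confidence"`.
#' @return Data frame with one row per (peptide, subarray) spot:
#'   `peptide_id`, `subarray`, `label` (`"reliable"`/`"unreliable"`),
#'   `probability_reliable` (0 or 1) and `source = "training-band"`.
#' @export
band_label <- function(replicates, level = 0.95,
                       band = c("prediction", "confidence")) {
  band <- match.arg(band)
  replicates <- as.matrix(replicates)
  ns <- ncol(replicates)
  if (ns < 3L) stop("need >= 3 subarray replicates for band labeling",
                    call. = FALSE)
  complete <- stats::complete.cases(replicates)
  if (sum(complete) < 10L) {
    stop("need >= 10 shared peptides per regression", call. = FALSE)
  }
  ids <- rownames(replicates)
  if (is.null(ids)) ids <- sprintf("peptide_%d", seq_len(nrow(replicates)))

  unreliable <- matrix(FALSE, nrow(replicates), ns)
  for (a in seq_len(ns)) {
    for (b in setdiff(seq_len(ns), a)) {
      x <- replicates[complete, b]
      y <- replicates[complete, a]
      if (stats::sd(x) == 0) {
        stop(sprintf("zero-variance predictor: subarray %d vs %d", a, b),
             call. = FALSE)
      }
      fit <- stats::lm(y ~ x)
      n <- length(x)
      s <- stats::sigma(fit)
      xbar <- mean(x)
      sxx <- sum((x - xbar)^2)
      pred <- stats::coef(fit)[1L] + stats::coef(fit)[2L] * x
      lever <- 1 / n + (x - xbar)^2 / sxx
      if (band == "prediction") lever <- lever + 1
      half <- stats::qt(1 - (1 - level) / 2, df = n - 2L) * s * sqrt(lever)
      # guard against an (essentially) perfect fit: residuals at machine
      # precision are agreement, not outliers
      slack <- 1e-8 * max(abs(y), 1)
      out <- abs(y - pred) > pmax(half, slack)
      unreliable[complete, a] <- unreliable[complete, a] | out
    }
  }
  res <- data.frame(
    peptide_id = rep(ids, ns),
    subarray = rep(seq_len(ns), each = nrow(replicates)),
    label = ifelse(as.vector(unreliable), "unreliable", "reliable"),
    probability_reliable = as.numeric(!as.vector(unreliable)),
    source = "training-band",
    stringsAsFactors = FALSE)
  # spots with a missing replicate value cannot be band-labeled
  res[!is.na(as.vector(replicates)), , drop = FALSE]
}

#' Balance reliability classes by downsampling
#'
#' Randomly downsamples the majority class, without replacement, to the
#' minority class size; deterministic under `seed`.
#'
#' @param labels character or factor vector with two classes.
#' @param seed integer RNG seed.
#' @return Sorted integer indices of the balanced training set.
#' @export
balance_classes <- function(labels, seed = 1L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L || any(table(labels) == 0L)) {
    stop("need two non-empty classes to balance", call. = FALSE)
  }
  idx <- split(seq_along(labels), labels)
  n_min <- min(lengths(idx))
  out <- local_seed(seed, {
    unlist(lapply(idx, function(i) {
      if (length(i) > n_min) sort(sample(i, n_min)) else i
    }), use.names = FALSE)
  })
  sort(out)
}

# evaluate expr with a temporary RNG state seeded by `seed`
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Train the random-forest reliability classifier
#'
#' Fits a random forest on per-spot quantification features (all
#' numeric result-file columns plus the scatterlight scan columns; the
#' peptide sequence and identifiers are never features). Constant
#' columns are dropped and missing values are median-imputed; the
#' imputation medians and the feature list are stored so prediction
#' applies the identical preprocessing. Defaults: 500 trees, mtry =
#' floor(sqrt(p)).
#'
#' @param features data frame or matrix of spot features (rows already
#'   balanced, e.g. via [balance_classes()]).
#' @param labels character vector, `"reliable"`/`"unreliable"`, one per
#'   row of `features`.
#' @param ntree number of trees.
#' @param seed integer RNG seed for the forest.
#' @return A `reliability_classifier` with the fitted forest, the
#'   ordered feature list, imputation medians and training metadata
#'   (class counts, ntree, seed, out-of-bag error).
#' @export
train_reliability_classifier <- function(features, labels, ntree = 500L,
                                         seed = 1L) {
  features <- as.data.frame(features)
  if (nrow(features) < 20L) {
    stop("need >= 20 training spots, got ", nrow(features), call. = FALSE)
  }
  stopifnot(length(labels) == nrow(features))
  numeric_cols <- names(features)[vapply(features, is.numeric, logical(1L))]
  dropped_nonnum <- setdiff(names(features), numeric_cols)
  if (length(dropped_nonnum)) {
    message("dropping non-numeric feature(s): ",
            paste(dropped_nonnum, collapse = ", "))
  }
  x <- features[numeric_cols]
  medians <- vapply(x, function(v) stats::median(v, na.rm = TRUE), numeric(1L))
  for (col in numeric_cols) {
    miss <- is.na(x[[col]])
    if (any(miss)) x[[col]][miss] <- medians[[col]]
  }
  keep <- vapply(x, function(v) stats::sd(v) > 0, logical(1L))
  x <- x[keep]
  medians <- medians[keep]
  if (ncol(x) == 0L) stop("no informative (non-constant) features",
                          call. = FALSE)
  y <- factor(labels, levels = c("reliable", "unreliable"))
  forest <- local_seed(seed, {
    randomForest::randomForest(x = x, y = y, ntree = ntree,
                               mtry = max(1L, floor(sqrt(ncol(x)))))
  })
  oob <- unname(forest$err.rate[ntree, "OOB"])
  structure(list(forest = forest, feature_names = names(x),
                 medians = medians,
                 metadata = list(ntree = ntree, seed = seed,
                                 class_counts = as.list(table(y)),
                                 oob_error = oob)),
            class = "reliability_classifier")
}

#' @export
print.reliability_classifier <- function(x, ...) {
  cat(sprintf(
    "reliability_classifier: %d trees on %d features, OOB error %.3f\n",
    x$metadata$ntree, length(x$feature_names), x$metadata$oob_error))
  invisible(x)
}

#' Predict spot reliability
#'
#' Applies a trained [train_reliability_classifier()] forest. The input
#' must provide every training feature (missing columns are an error,
#' not silently imputed); missing values within a provided column are
#' imputed with the training medians.
#'
#' @param classifier a `reliability_classifier`.
#' @param features data frame of spot features.
#' @return Data frame with `probability_reliable`, `label` and
#'   `source = "predicted"`.
#' @export
predict_reliability <- function(classifier, features) {
  stopifnot(inherits(classifier, "reliability_classifier"))
  features <- as.data.frame(features)
  missing <- setdiff(classifier$feature_names, names(features))
  if (length(missing)) {
    stop("feature(s) required by the classifier are missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- features[classifier$feature_names]
  for (col in names(x)) {
    miss <- is.na(x[[col]])
    if (any(miss)) x[[col]][miss] <- classifier$medians[[col]]
  }
  prob <- stats::predict(classifier$forest, newdata = x, type = "prob")
  p_rel <- prob[, "reliable"]
  data.frame(probability_reliable = unname(p_rel),
             label = ifelse(p_rel >= 0.5, "reliable", "unreliable"),
             source = "predicted", stringsAsFactors = FALSE)
}

#' Persist / restore a reliability classifier
#'
#' The classifier is stored with its feature list and a format version
#' so that prediction refuses silently mismatched inputs.
#'
#' @param classifier a `reliability_classifier`.
#' @param path file path.
#' @return `path` (save) or the restored classifier (load).
#' @export
save_reliability_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "reliability_classifier"))
  obj <- classifier
  obj$format_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_reliability_classifier
#' @export
load_reliability_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "reliability_classifier")) {
    stop("file does not contain a reliability classifier", call. = FALSE)
  }
  obj
}

#' Aggregate replicate spots into one peptide value
#'
#' Replicates labeled unreliable are discarded; the rest are averaged
#' with weights equal to their probability of being reliable. If every
#' replicate is unreliable (or absent) the peptide is excluded. With
#' quality control disabled all weights are 1 and this is the plain
#' mean over the available replicates.
#'
#' @param values numeric replicate values (NA = absent replicate).
#' @param reliable logical per replicate; default all reliable.
#' @param weights per-replicate probability of being reliable; default 1.
#' @return A list with `value` (weighted mean, `NA` when excluded) and
#'   `excluded` (logical).
#' @export
aggregate_replicates <- function(values, reliable = NULL, weights = NULL) {
  if (is.null(reliable)) reliable <- rep(TRUE, length(values))
  if (is.null(weights)) weights <- rep(1, length(values))
  if (any(weights < 0, na.rm = TRUE)) {
    stop("negative reliability weight", call. = FALSE)
  }
  keep <- reliable & !is.na(values) & !is.na(weights) & weights > 0
  if (!any(keep)) return(list(value = NA_real_, excluded = TRUE))
  list(value = sum(values[keep] * weights[keep]) / sum(weights[keep]),
       excluded = FALSE)
}
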