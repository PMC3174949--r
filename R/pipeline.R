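#' Normalize one slide
#'
#' Applies the per-slide preprocessing: binary-log transform of the raw
#' intensities, address resolution against the layout, control-peptide
#' effects-model fit and correction of all spots.
#'
#' @param table a `spot_table` (incubation scan, possibly joined with a
#'   scatterlight scan via [join_scans()]).
#' @param layout the slide's `array_layout`.
#' @param annotation control annotation data frame (`peptide_id`,
#'   `class`); peptides not listed are treated as experimental.
#' @param floor log-transform floor, see [log2_transform()].
#' @param exclude_flagged drop spots with a negative GenePix flag
#'   (treated as absent replicates) before any analysis; by default
#'   they are retained and left to the quality-control stage.
#' @return A list with `spots` (data frame: addresses, `id`, `class`,
#'   `flag`, `log_intensity`, `normalized`, plus the table's feature
#'   columns) and `model` (the fitted `effects_model`).
#' @export
normalize_slide <- function(table, layout, annotation, floor = 1,
                            exclude_flagged = FALSE) {
  stopifnot(inherits(table, "spot_table"), inherits(layout, "array_layout"))
  sp <- table$spots
  addr <- resolve_address(layout, sp$block, sp$row, sp$column)
  cls <- annotation$class[match(sp$id, annotation$peptide_id)]
  cls[is.na(cls)] <- "experimental"
  spots <- cbind(
    data.frame(block = sp$block, row = sp$row, column = sp$column,
               id = sp$id, class = cls, flag = sp$flag,
               log_intensity = log2_transform(sp$intensity, floor = floor),
               stringsAsFactors = FALSE),
    addr)
  for (f in table$feature_names) spots[[f]] <- sp[[f]]
  if (exclude_flagged) spots <- spots[spots$flag >= 0L, , drop = FALSE]
  ctrl <- spots[spots$class != "experimental", , drop = FALSE]
  model <- fit_effects_model(ctrl, layout = layout)
  spots <- correct_effects(spots, model)
  list(spots = spots, model = model)
}

#' Per-peptide replicate matrix
#'
#' Arranges a per-spot column of a normalized slide as a peptides x
#' subarrays matrix, one replicate per subarray; absent replicates are
#' `NA`.
#'
#' @param spots normalized spot data frame from [normalize_slide()].
#' @param layout the `array_layout`.
#' @param column which spot column to spread (default `"normalized"`).
#' @return Numeric matrix with peptide ids as rownames and one column
#'   per subarray.
#' @export
peptide_matrix <- function(spots, layout, column = "normalized") {
  ids <- sort(unique(spots$id))
  m <- matrix(NA_real_, nrow = length(ids), ncol = layout$n_subarrays,
              dimnames = list(ids, NULL))
  m[cbind(match(spots$id, ids), spots$subarray)] <- spots[[column]]
  m
}

#' Aggregate a replicate matrix into per-peptide values
#'
#' Applies [aggregate_replicates()] row-wise, with optional per-spot
#' reliability labels/probabilities from the quality-control stage.
#'
#' @param m replicate matrix from [peptide_matrix()].
#' @param reliable optional logical matrix (same shape): replicate kept?
#' @param weights optional numeric matrix of reliability probabilities.
#' @return A list with `values` (named numeric vector; `NA` where the
#'   peptide is excluded) and `excluded` (named logical vector:
#'   all replicates unreliable/absent).
#' @export
aggregate_matrix <- function(m, reliable = NULL, weights = NULL) {
  n <- nrow(m)
  values <- stats::setNames(rep(NA_real_, n), rownames(m))
  excluded <- stats::setNames(rep(FALSE, n), rownames(m))
  for (i in seq_len(n)) {
    r <- aggregate_replicates(m[i, ],
                              reliable = if (!is.null(reliable)) reliable[i, ],
                              weights = if (!is.null(weights)) weights[i, ])
    values[i] <- r$value
    excluded[i] <- r$excluded
  }
  list(values = values, excluded = excluded)
}

#' Detect secondary-antibody binding peptides on an empty slide
#'
#' Peptides that react directly with the dye-coupled secondary antibody
#' confound the specific signal and must be excluded. On a slide
#' incubated with diluent only (no sample), any reactivity is
#' secondary binding; a two-component Gaussian mixture is fitted to the
#' per-peptide normalized intensities, initialized from the negative
#' controls (no reaction expected) and the secondary-antibody controls
#' (reaction expected), and every peptide whose noise-component
#' exceedance probability is below `alpha` is excluded from the sample
#' slides of the same print batch.
#'
#' @param values named per-peptide aggregated normalized intensities of
#'   the empty slide.
#' @param annotation control annotation data frame.
#' @param alpha exceedance cutoff, default 0.05.
#' @param ... passed to [em_fit()].
#' @return A list with `excluded` (character vector of experimental
#'   peptide ids), `fit` (the `mixture_fit`), and `p_hat` (named vector
#'   over all fitted peptides).
#' @export
detect_secondary_binders <- function(values, annotation, alpha = 0.05, ...) {
  cls <- annotation$class[match(names(values), annotation$peptide_id)]
  cls[is.na(cls)] <- "experimental"
  neg <- values[cls == "negative" & !is.na(values)]
  sec <- values[cls == "secondary_antibody" & !is.na(values)]
  if (length(neg) < 2L || length(sec) < 2L) {
    stop("empty slide lacks negative and/or secondary-antibody controls ",
         "needed to initialize the mixture", call. = FALSE)
  }
  init <- init_from_controls(neg, sec)
  fitted_vals <- values[!is.na(values)]
  fit <- em_fit(fitted_vals, init, ...)
  exc <- exceedance_prob(fitted_vals, fit, alpha = alpha)
  p_hat <- stats::setNames(exc$p_hat, names(fitted_vals))
  is_exp <- cls[match(names(fitted_vals), names(values))] == "experimental"
  excluded <- names(fitted_vals)[is_exp & exc$exceeds]
  list(excluded = excluded, fit = fit, p_hat = p_hat, alpha = alpha)
}

#' Call reactive peptides on a sample slide
#'
#' Separates signal-carrying peptides from noise with a two-component
#' Gaussian mixture on the per-peptide normalized intensities,
#' initialized from the positive controls (reaction expected) and the
#' negative controls (no reaction expected). Peptides in the exclusion
#' set (secondary binders) are removed before fitting and carry no
#' call. A peptide is called reactive when the probability that a
#' noise-component draw is at least as large as its intensity is
#' strictly below `alpha`.
#'
#' @param values named per-peptide aggregated normalized intensities
#'   (`NA` = all replicates unreliable).
#' @param annotation control annotation data frame.
#' @param exclusions character vector of peptide ids excluded as
#'   secondary binders.
#' @param alpha exceedance cutoff, default 0.05.
#' @param ... passed to [em_fit()].
#' @return A `call_table` data frame with one row per peptide:
#'   `peptide_id`, `class`, `normalized_intensity`, `secondary_binder`,
#'   `p_hat`, `reactive`, `excluded_reason` (`NA`, `"secondary_binder"`
#'   or `"all_replicates_unreliable"`); the fitted mixture and the
#'   cutoff are attached as attributes `fit` and `alpha`.
#' @export
call_signals <- function(values, annotation, exclusions = character(0),
                         alpha = 0.05, ...) {
  cls <- annotation$class[match(names(values), annotation$peptide_id)]
  cls[is.na(cls)] <- "experimental"
  pos <- values[cls == "positive" & !is.na(values)]
  neg <- values[cls == "negative" & !is.na(values)]
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("sample slide lacks positive and/or negative controls ",
         "needed to initialize the mixture", call. = FALSE)
  }
  excluded_sec <- names(values) %in% exclusions
  excluded_na <- is.na(values) & !excluded_sec
  fit_mask <- !excluded_sec & !is.na(values)
  init <- init_from_controls(neg, pos)
  fit <- em_fit(values[fit_mask], init, ...)
  exc <- exceedance_prob(values[fit_mask], fit, alpha = alpha)

  out <- data.frame(
    peptide_id = names(values), class = cls,
    normalized_intensity = unname(values),
    secondary_binder = excluded_sec,
    p_hat = NA_real_, reactive = NA,
    excluded_reason = NA_character_,
    stringsAsFactors = FALSE)
  out$p_hat[fit_mask] <- exc$p_hat
  out$reactive[fit_mask] <- exc$exceeds
  out$excluded_reason[excluded_sec] <- "secondary_binder"
  out$excluded_reason[excluded_na] <- "all_replicates_unreliable"
  attr(out, "fit") <- fit
  attr(out, "alpha") <- alpha
  class(out) <- c("call_table", "data.frame")
  out
}

#' Evaluate calls against a truth assignment
#'
#' Tabulates the confusion matrix of reactive calls against expected
#' reactivity, and computes sensitivity = tp/(tp+fn),
#' specificity = tn/(tn+fp) and accuracy = (tp+tn)/(tp+tn+fp+fn).
#' Expected-nonreactive peptides called reactive are false positives;
#' expected-reactive peptides without a reactive call are false
#' negatives. Peptides excluded upstream (secondary binders, all
#' replicates unreliable) are by default removed from the denominators;
#' with `count_excluded_as_negative = TRUE` they are treated as
#' non-reactive calls instead.
#'
#' @param calls a `call_table`, subset to the evaluated peptides.
#' @param truth named character vector mapping every evaluated peptide
#'   to `"expected_reactive"` or `"expected_nonreactive"`.
#' @param count_excluded_as_negative see above.
#' @return An `evaluation_result` list: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `n_excluded`.
#' @export
evaluate_calls <- function(calls, truth, count_excluded_as_negative = FALSE) {
  extra <- setdiff(calls$peptide_id, names(truth))
  if (length(extra)) {
    stop("peptide(s) in calls but not in truth: ",
         paste(utils::head(extra, 10L), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(names(truth), calls$peptide_id)
  if (length(missing)) {
    stop("truth peptide(s) absent from calls: ",
         paste(utils::head(missing, 10L), collapse = ", "), call. = FALSE)
  }
  tr <- truth[calls$peptide_id]
  stopifnot(all(tr %in% c("expected_reactive", "expected_nonreactive")))
  excluded <- !is.na(calls$excluded_reason)
  reactive <- calls$reactive
  if (count_excluded_as_negative) {
    reactive[excluded] <- FALSE
    excluded <- rep(FALSE, length(excluded))
  }
  keep <- !excluded
  tp <- sum(keep & tr == "expected_reactive" & reactive)
  fn <- sum(keep & tr == "expected_reactive" & !reactive)
  fp <- sum(keep & tr == "expected_nonreactive" & reactive)
  tn <- sum(keep & tr == "expected_nonreactive" & !reactive)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn)
               else NA_real_,
    n_excluded = sum(!keep)), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "tp=%d fp=%d tn=%d fn=%d | sensitivity=%.3f specificity=%.3f accuracy=%.3f\n",
    x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Bootstrap confidence interval for an evaluation metric
#'
#' Resamples the peptide intensities of each truth class with
#' replacement, recomputes the reactive calls against the fixed fitted
#' cutoff and the requested metric, and returns the percentile interval
#' over `B` replicates. Deterministic under `seed`.
#'
#' @param values_by_class list with elements `expected_reactive` and
#'   `expected_nonreactive`: the normalized intensities of the
#'   evaluated peptides of each class.
#' @param call_fun function mapping a numeric vector of intensities to
#'   a logical vector of reactive calls (typically exceedance against
#'   the slide's fitted mixture cutoff).
#' @param metric `"sensitivity"`, `"specificity"` or `"accuracy"`.
#' @param B number of bootstrap replicates (default 1000).
#' @param level interval coverage (default 0.95).
#' @param seed integer RNG seed.
#' @return A list with `lower`, `upper`, `level`, `B` and the
#'   bootstrap `replicates`.
#' @export
bootstrap_ci <- function(values_by_class, call_fun,
                         metric = c("sensitivity", "specificity", "accuracy"),
                         B = 1000L, level = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  if (B < 2L) stop("B must be >= 2", call. = FALSE)
  pos <- values_by_class$expected_reactive
  neg <- values_by_class$expected_nonreactive
  if (!length(pos) || !length(neg)) {
    stop("both truth classes must be non-empty", call. = FALSE)
  }
  stat <- function(p, n) {
    cp <- call_fun(p); cn <- call_fun(n)
    switch(metric,
           sensitivity = mean(cp),
           specificity = mean(!cn),
           accuracy = (sum(cp) + sum(!cn)) / (length(cp) + length(cn)))
  }
  reps <- local_seed(seed, {
    vapply(seq_len(B), function(b) {
      stat(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    }, numeric(1L))
  })
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(lower = qs[1L], upper = qs[2L], level = level, B = B,
       estimate = stat(pos, neg), replicates = reps)
}

#' Run the full analysis pipeline
#'
#' Executes the workflow on a slide set: read GPR files, log2
#' transform, control-peptide effects correction, optional
#' random-forest spot quality control, replicate aggregation,
#' secondary-binder exclusion from each print batch's empty slide,
#' probabilistic signal calling on the sample slides, and (when a truth
#' assignment is supplied) evaluation with bootstrap confidence
#' intervals.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{manifest}{data frame or CSV path with columns `array_id`,
#'       `gpr_path`, `scatterlight_path` (optional), `role`
#'       (`"empty"`/`"sample"`), `print_batch`, `spike_in_level`.}
#'     \item{annotation}{control annotation data frame or CSV path.}
#'     \item{layout}{an `array_layout`, or (in YAML configs) a list of
#'       [array_layout()] arguments (default: the standard
#'       3 x 16 x 20 x 20 geometry).}
#'     \item{intensity_column, scatterlight_column}{GPR column names
#'       (defaults `"F635 Mean"`, `"F532 Mean"`).}
#'     \item{alpha_secondary, alpha_signal}{exceedance cutoffs
#'       (default 0.05 each).}
#'     \item{qc}{list: `enabled` (default FALSE), and `classifier` (a
#'       `reliability_classifier`) or `classifier_path`.}
#'     \item{exclude_flagged}{drop GenePix-flagged spots up front
#'       (default FALSE).}
#'     \item{truth}{optional named vector (or data frame `peptide_id`,
#'       `truth`) of `"expected_reactive"`/`"expected_nonreactive"`.}
#'     \item{bootstrap}{list `B`, `level`, `seed` (default 1000, 0.95, 1).}
#'     \item{count_excluded_as_negative}{evaluation policy, default FALSE.}
#'     \item{out_dir}{optional directory for TSV/JSON outputs.}
#'   }
#' @return A result bundle: per-slide normalized data and ANOVA tables,
#'   per-batch exclusion sets, a `call_table` per sample slide,
#'   evaluation results with bootstrap intervals when truth was given,
#'   and a run log.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  layout <- cfg$layout
  if (is.null(layout)) {
    layout <- array_layout()
  } else if (!inherits(layout, "array_layout")) {
    # YAML configs specify the geometry as plain fields
    layout <- do.call(array_layout, layout)
  }
  manifest <- cfg$manifest
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("array_id", "gpr_path", "role", "print_batch") %in%
                  names(manifest)))
  annotation <- cfg$annotation
  if (is.character(annotation)) annotation <- read_control_annotation(annotation)
  intensity_column <- cfg$intensity_column %||% "F635 Mean"
  sl_column <- cfg$scatterlight_column %||% "F532 Mean"
  alpha_secondary <- cfg$alpha_secondary %||% 0.05
  alpha_signal <- cfg$alpha_signal %||% 0.05
  exclude_flagged <- isTRUE(cfg$exclude_flagged)
  qc_enabled <- isTRUE(cfg$qc$enabled)
  classifier <- NULL
  if (qc_enabled) {
    classifier <- cfg$qc$classifier
    if (is.null(classifier) && !is.null(cfg$qc$classifier_path)) {
      classifier <- load_reliability_classifier(cfg$qc$classifier_path)
    }
    if (is.null(classifier)) {
      stop("qc enabled but no classifier supplied", call. = FALSE)
    }
  }
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  slides <- vector("list", nrow(manifest))
  names(slides) <- manifest$array_id
  for (i in seq_len(nrow(manifest))) {
    aid <- manifest$array_id[i]
    note("reading slide %s (%s)", aid, manifest$role[i])
    tab <- read_gpr(manifest$gpr_path[i], intensity_column = intensity_column)
    has_sl <- "scatterlight_path" %in% names(manifest) &&
      !is.na(manifest$scatterlight_path[i]) &&
      nzchar(manifest$scatterlight_path[i])
    if (has_sl) {
      sl <- read_gpr(manifest$scatterlight_path[i],
                     intensity_column = sl_column)
      tab <- join_scans(tab, sl)
    }
    norm <- normalize_slide(tab, layout, annotation,
                            exclude_flagged = exclude_flagged)
    m <- peptide_matrix(norm$spots, layout)
    reliable <- weights <- NULL
    if (qc_enabled) {
      feats <- norm$spots[intersect(classifier$feature_names,
                                    names(norm$spots))]
      pred <- predict_reliability(classifier, feats)
      rel_spot <- pred$label == "reliable"
      note("slide %s: %.1f%% of spots marked unreliable", aid,
           100 * mean(!rel_spot))
      reliable <- matrix(TRUE, nrow(m), ncol(m),
                         dimnames = dimnames(m))
      weights <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
      idx <- cbind(match(norm$spots$id, rownames(m)), norm$spots$subarray)
      reliable[idx] <- rel_spot
      weights[idx] <- pred$probability_reliable
    }
    agg <- aggregate_matrix(m, reliable = reliable, weights = weights)
    slides[[i]] <- list(array_id = aid, role = manifest$role[i],
                        print_batch = manifest$print_batch[i],
                        spike_in_level = manifest$spike_in_level[i],
                        model = norm$model, values = agg$values,
                        excluded_unreliable = names(agg$values)[agg$excluded])
  }

  # secondary-binder exclusion, one set per print batch (from its empty slide)
  batches <- unique(manifest$print_batch)
  exclusions <- stats::setNames(vector("list", length(batches)),
                                as.character(batches))
  for (b in batches) {
    empty_i <- which(manifest$print_batch == b & manifest$role == "empty")
    if (!length(empty_i)) {
      warning("print batch ", b, ": no empty slide in manifest; ",
              "secondary-binder exclusion skipped (increased risk of ",
              "false positives)")
      note("batch %s: no empty slide, exclusion skipped", b)
      exclusions[[as.character(b)]] <- list(excluded = character(0),
                                            fit = NULL)
      next
    }
    det <- detect_secondary_binders(slides[[empty_i[1L]]]$values, annotation,
                                    alpha = alpha_secondary)
    note("batch %s: %d peptide(s) excluded as secondary binders", b,
         length(det$excluded))
    exclusions[[as.character(b)]] <- det
  }

  truth <- cfg$truth
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$truth, truth$peptide_id)
  }
  bs <- cfg$bootstrap
  bs_B <- bs$B %||% 1000L
  bs_level <- bs$level %||% 0.95
  bs_seed <- bs$seed %||% 1L

  calls <- list(); evaluations <- list()
  for (i in which(manifest$role == "sample")) {
    aid <- manifest$array_id[i]
    excl <- exclusions[[as.character(manifest$print_batch[i])]]$excluded
    ct <- call_signals(slides[[i]]$values, annotation, exclusions = excl,
                       alpha = alpha_signal)
    note("slide %s: %d reactive peptide(s) called", aid,
         sum(ct$reactive, na.rm = TRUE))
    calls[[aid]] <- ct
    if (!is.null(truth)) {
      sub <- ct[ct$peptide_id %in% names(truth), , drop = FALSE]
      ev <- evaluate_calls(sub, truth[sub$peptide_id],
                           count_excluded_as_negative =
                             isTRUE(cfg$count_excluded_as_negative))
      fit <- attr(ct, "fit")
      cutoff <- fit$mu1 + stats::qnorm(1 - alpha_signal) * sqrt(fit$var1)
      call_fun <- function(v) v > cutoff
      kept <- sub[is.na(sub$excluded_reason), , drop = FALSE]
      vbc <- split(kept$normalized_intensity, truth[kept$peptide_id])
      cis <- lapply(
        stats::setNames(c("sensitivity", "specificity", "accuracy"),
                        c("sensitivity", "specificity", "accuracy")),
        function(mt) {
          ci <- bootstrap_ci(vbc, call_fun, metric = mt, B = bs_B,
                             level = bs_level, seed = bs_seed)
          ci$replicates <- NULL
          ci
        })
      evaluations[[aid]] <- list(metrics = ev, ci = cis)
    }
  }

  bundle <- list(slides = slides, exclusions = exclusions, calls = calls,
                 evaluations = evaluations,
                 params = list(intensity_column = intensity_column,
                               scatterlight_column = sl_column,
                               alpha_secondary = alpha_secondary,
                               alpha_signal = alpha_signal,
                               qc_enabled = qc_enabled,
                               exclude_flagged = exclude_flagged,
                               bootstrap = list(B = bs_B, level = bs_level,
                                                seed = bs_seed)),
                 log = log_lines)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline result bundle to disk
#'
#' Emits, under `dir`: one call-table TSV per sample slide, one ANOVA
#' TSV per slide, the per-batch exclusion sets, mixture-fit summaries
#' and evaluation results as JSON, and the run log.
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (aid in names(bundle$slides)) {
    write_anova_tsv(bundle$slides[[aid]]$model,
                    file.path(dir, paste0("anova_", aid, ".tsv")))
  }
  for (aid in names(bundle$calls)) {
    ct <- bundle$calls[[aid]]
    utils::write.table(as.data.frame(ct),
                       file.path(dir, paste0("calls_", aid, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  mix <- lapply(bundle$calls, function(ct) {
    f <- attr(ct, "fit")
    list(mu1 = f$mu1, var1 = f$var1, mu2 = f$mu2, var2 = f$var2,
         pi1 = f$pi1, pi2 = f$pi2, converged = f$converged,
         iterations = length(f$loglik_trace) - 1L)
  })
  exc <- lapply(bundle$exclusions, function(e) e$excluded)
  jsonlite::write_json(list(mixtures = mix, exclusions = exc),
                       file.path(dir, "mixtures.json"), auto_unbox = TRUE,
                       digits = NA)
  if (length(bundle$evaluations)) {
    jsonlite::write_json(bundle$evaluations,
                         file.path(dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}
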