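#' Variance-stabilizing binary log transform
#'
#' Raw fluorescence intensities are strongly heteroscedastic (variance
#' grows with the mean); a binary logarithm stabilizes the variance so
#' that a constant-variance linear model applies. Intensities below
#' `floor` are floored before the log, so 0 maps to `log2(floor)`
#' (0 with the default floor of one count).
#'
#' @param raw_intensity non-negative numeric vector of raw counts.
#' @param floor lowest count substituted before the log; default 1.
#' @return `log2(pmax(raw_intensity, floor))`.
#' @export
log2_transform <- function(raw_intensity, floor = 1) {
  if (any(raw_intensity < 0, na.rm = TRUE)) {
    stop("raw intensities must be >= 0", call. = FALSE)
  }
  stopifnot(floor > 0)
  log2(pmax(raw_intensity, floor))
}

#' Fit the control-peptide effects model
#'
#' Fits, by least squares on control spots only, the additive model of
#' log2 intensity on the categorical factors peptide, (array,) subarray,
#' needle, global row and global column — no interactions. Restricting
#' the fit to dedicated control peptides, which are printed with many
#' repeats for every needle and subarray, avoids confounding the
#' systematic effects with genuine peptide reactivity. The peptide
#' effect is fitted (it absorbs the differences between control
#' sequences) but is never applied when correcting: experimental
#' peptides have no estimable peptide effect.
#'
#' Rank deficiency (e.g. subarray and block-row contrasts are linear
#' combinations of row contrasts) is resolved by dropping
#' later-entering aliased columns, in the fitting order
#' peptide, array, subarray, needle, row, column; dropped coefficients
#' are recorded in `aliased_terms`. All retained non-peptide effects
#' are re-expressed as deviations from their own level mean
#' (sum-to-zero), so correction preserves the overall intensity scale.
#'
#' @param controls data frame of control spots with columns
#'   `log_intensity`, `id` (peptide), `subarray`, `needle`,
#'   `global_row`, `global_col`, and optionally `array_id` (an array
#'   effect is fitted when more than one array is present).
#' @param layout optional `array_layout`; when given, every needle and
#'   subarray of the layout must be represented among the controls.
#' @return An `effects_model`: centered per-level effect vectors for
#'   each factor, `intercept`, `residual_variance`, `aliased_terms`,
#'   the sequential `anova` table (data frame with columns `term`,
#'   `df`, `sumsq`, `meansq`, `statistic`, `p.value`) and the
#'   underlying `lm` fit.
#' @export
fit_effects_model <- function(controls, layout = NULL) {
  req <- c("log_intensity", "id", "subarray", "needle", "global_row",
           "global_col")
  if (!all(req %in% names(controls))) {
    stop("controls must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(layout)) {
    missing_needle <- setdiff(seq_len(layout$blocks_per_subarray),
                              unique(controls$needle))
    if (length(missing_needle)) {
      stop("no control spots for needle ",
           paste(missing_needle, collapse = ", "), call. = FALSE)
    }
    missing_sub <- setdiff(seq_len(layout$n_subarrays),
                           unique(controls$subarray))
    if (length(missing_sub)) {
      stop("no control spots for subarray ",
           paste(missing_sub, collapse = ", "), call. = FALSE)
    }
  }
  tab_n <- table(controls$needle)
  tab_s <- table(controls$subarray)
  if (any(tab_n < 2L) || any(tab_s < 2L)) {
    lev <- c(sprintf("needle %s", names(tab_n)[tab_n < 2L]),
             sprintf("subarray %s", names(tab_s)[tab_s < 2L]))
    stop("fewer than 2 control observations for ",
         paste(lev, collapse = ", "), call. = FALSE)
  }

  d <- data.frame(
    y = controls$log_intensity,
    peptide = factor(controls$id),
    subarray = factor(controls$subarray),
    needle = factor(controls$needle),
    row = factor(controls$global_row),
    col = factor(controls$global_col))
  multi_array <- "array_id" %in% names(controls) &&
    length(unique(controls$array_id)) > 1L
  if (multi_array) d$array <- factor(controls$array_id)

  form <- if (multi_array) {
    y ~ peptide + array + subarray + needle + row + col
  } else {
    y ~ peptide + subarray + needle + row + col
  }
  fit <- stats::lm(form, data = d)

  cf <- stats::coef(fit)
  aliased <- names(cf)[is.na(cf)]

  # per-factor centered effect vectors (baseline level = 0, aliased = 0,
  # then sum-to-zero over the levels seen in the data)
  effect_vector <- function(fac_name) {
    lev <- levels(d[[fac_name]])
    e <- stats::setNames(rep(0, length(lev)), lev)
    nm <- paste0(fac_name, lev)
    hit <- nm %in% names(cf)
    vals <- cf[nm[hit]]
    vals[is.na(vals)] <- 0
    e[lev[hit]] <- vals
    e - mean(e)
  }
  facs <- c(if (multi_array) "array", "subarray", "needle", "row", "col")
  effects <- lapply(stats::setNames(facs, facs), effect_vector)
  peptide_eff <- effect_vector("peptide")

  a <- stats::anova(fit)
  anova_tab <- data.frame(
    term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
    meansq = a$`Mean Sq`, statistic = a$`F value`,
    p.value = a$`Pr(>F)`, stringsAsFactors = FALSE)
  rownames(anova_tab) <- NULL

  structure(list(effects = effects, peptide_effects = peptide_eff,
                 intercept = unname(cf[["(Intercept)"]]),
                 residual_variance = stats::sigma(fit)^2,
                 aliased_terms = aliased, anova = anova_tab,
                 multi_array = multi_array, fit = fit),
            class = "effects_model")
}

#' @export
print.effects_model <- function(x, ...) {
  cat("effects_model fitted on control spots\n")
  cat(sprintf("  residual variance: %.4g; %d aliased coefficient(s)\n",
              x$residual_variance, length(x$aliased_terms)))
  print(x$anova, digits = 4)
  invisible(x)
}

#' Correct spot intensities for systematic array effects
#'
#' Subtracts the fitted (centered) array, subarray, needle, row and
#' column effects from every spot's log2 intensity — controls and
#' experimental peptides alike. The peptide effect is never subtracted:
#' it is not estimable for non-control peptides and carries the signal
#' of interest. Spots at levels whose coefficients were aliased during
#' fitting are corrected with the retained effects only.
#'
#' @param spots data frame with columns `log_intensity`, `subarray`,
#'   `needle`, `global_row`, `global_col` (and `array_id` for
#'   multi-array models).
#' @param model an `effects_model`.
#' @return `spots` with an added `normalized` column.
#' @export
correct_effects <- function(spots, model) {
  stopifnot(inherits(model, "effects_model"))
  cols <- c(array = "array_id", subarray = "subarray", needle = "needle",
            row = "global_row", col = "global_col")
  adj <- rep(0, nrow(spots))
  for (fac in names(model$effects)) {
    lev <- as.character(spots[[cols[[fac]]]])
    e <- model$effects[[fac]]
    unknown <- setdiff(unique(lev), names(e))
    if (length(unknown)) {
      stop(sprintf("level(s) %s of factor '%s' absent from fitted model",
                   paste(unknown, collapse = ", "), fac), call. = FALSE)
    }
    adj <- adj + unname(e[lev])
  }
  spots$normalized <- spots$log_intensity - adj
  spots
}

#' Fraction of non-peptide variance explained by systematic effects
#'
#' From the sequential (Type I) ANOVA with the peptide term fitted
#' first: the sum of squares of all systematic terms (array, subarray,
#' needle, row, column) divided by the systematic plus residual sum of
#' squares. This is the share of the variation left after accounting
#' for peptide identity that the model attributes to removable array
#' effects.
#'
#' @param model an `effects_model`.
#' @return A fraction in \[0, 1\].
#' @export
variance_reduction <- function(model) {
  stopifnot(inherits(model, "effects_model"))
  a <- model$anova
  sys <- a$term %in% c("array", "subarray", "needle", "row", "col")
  ss_sys <- sum(a$sumsq[sys])
  ss_res <- a$sumsq[a$term == "Residuals"]
  if (ss_sys + ss_res == 0) return(1)
  ss_sys / (ss_sys + ss_res)
}

#' Export an ANOVA summary as TSV
#'
#' Writes the sequential ANOVA table of a fitted effects model with
#' columns Term, Df, SumSq, MeanSq, F, p.
#'
#' @param model an `effects_model`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_anova_tsv <- function(model, path) {
  stopifnot(inherits(model, "effects_model"))
  a <- model$anova
  out <- data.frame(Term = a$term, Df = a$df, SumSq = a$sumsq,
                    MeanSq = a$meansq, F = a$statistic, p = a$p.value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
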