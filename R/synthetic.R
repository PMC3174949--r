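#' Parameters for the synthetic experiment generator
#'
#' The generator produces slide sets with the additive log2-scale
#' structure the pipeline assumes: per-spot log2 intensity =
#' intercept + array + subarray + needle + row + column + peptide
#' effects + Gaussian noise, exponentiated to the raw scale (so raw
#' intensities are heteroscedastic, with larger variance at higher
#' means). The default design mirrors the six-slide study layout: two
#' print batches, each with one empty slide (diluent only), one
#' low-concentration and one high-concentration spike-in slide.
#'
#' All effect scales are in log2 units. Row/column systematic effects
#' are smooth spatial gradients (signal declining with position) plus
#' small per-level jitter. Positive controls react on plasma slides,
#' secondary-antibody controls and secondary-binder peptides react on
#' every slide including empty ones, spike-target peptides react on
#' sample slides at the slide's concentration level. A fraction of
#' spots are artifacts: large independent intensity perturbations with
#' correlated aberrant scatterlight features.
#'
#' @param layout an `array_layout`.
#' @param seed integer RNG seed; the whole experiment is deterministic
#'   given the seed.
#' @param intercept baseline log2 intensity.
#' @param peptide_sd sd of experimental peptide baseline effects.
#' @param noise_sd residual (spot-level) noise sd.
#' @param needle_sd,subarray_sd,array_sd effect scales per factor.
#' @param row_amplitude,col_amplitude spatial gradient amplitudes.
#' @param row_jitter,col_jitter per-level jitter sds on the gradients.
#' @param pos_control_effect,sec_control_effect control reactivities.
#' @param n_reactive number of spike-target experimental peptides
#'   (default 222, i.e. 666 spots per slide).
#' @param n_nonreactive number of expected-nonreactive truth peptides
#'   (default 171, i.e. 513 spots per slide).
#' @param signal_high,signal_low spike effects at the two
#'   concentration levels.
#' @param n_secondary_binders,binder_effect secondary-binder planting.
#' @param artifact_fraction,artifact_magnitude artifact spot fraction
#'   per slide and magnitude (in units of `noise_sd`, random sign).
#' @param batch_shift extra array offset applied to print batch 2.
#' @param batch2_artifact_fraction artifact fraction for batch 2.
#' @return A `generator_params` list.
#' @export
generator_params <- function(layout = array_layout(), seed = 1L,
                             intercept = 9, peptide_sd = 0.5,
                             noise_sd = 0.3, needle_sd = 0.15,
                             subarray_sd = 0.1, array_sd = 0.15,
                             row_amplitude = 0.5, col_amplitude = 0.4,
                             row_jitter = 0.4, col_jitter = 0.4,
                             pos_control_effect = 4,
                             sec_control_effect = 4,
                             n_reactive = 222L, n_nonreactive = 171L,
                             signal_high = 3, signal_low = 1.3,
                             n_secondary_binders = 50L, binder_effect = 3,
                             artifact_fraction = 0.01,
                             artifact_magnitude = 4,
                             batch_shift = 0.3,
                             batch2_artifact_fraction = 0.02) {
  p <- list(layout = layout, seed = as.integer(seed), intercept = intercept,
            peptide_sd = peptide_sd, noise_sd = noise_sd,
            needle_sd = needle_sd, subarray_sd = subarray_sd,
            array_sd = array_sd, row_amplitude = row_amplitude,
            col_amplitude = col_amplitude, row_jitter = row_jitter,
            col_jitter = col_jitter,
            pos_control_effect = pos_control_effect,
            sec_control_effect = sec_control_effect,
            n_reactive = as.integer(n_reactive),
            n_nonreactive = as.integer(n_nonreactive),
            signal_high = signal_high, signal_low = signal_low,
            n_secondary_binders = as.integer(n_secondary_binders),
            binder_effect = binder_effect,
            artifact_fraction = artifact_fraction,
            artifact_magnitude = artifact_magnitude,
            batch_shift = batch_shift,
            batch2_artifact_fraction = batch2_artifact_fraction)
  sds <- c(p$peptide_sd, p$noise_sd, p$needle_sd, p$subarray_sd, p$array_sd,
           p$row_jitter, p$col_jitter)
  if (any(sds < 0) || p$artifact_fraction < 0 || p$artifact_fraction > 1 ||
      p$batch2_artifact_fraction < 0 || p$batch2_artifact_fraction > 1) {
    stop("invalid generator parameters: sds must be >= 0 and fractions in [0,1]",
         call. = FALSE)
  }
  structure(p, class = "generator_params")
}

#' Generate a synthetic slide experiment with known ground truth
#'
#' Builds the six-slide design (2 print batches x \{empty, low-spike,
#' high-spike\}), see [generator_params()] for the generative model.
#' Returns in-memory incubation and scatterlight `spot_table`s per
#' slide plus the truth tables; with `dir` set, additionally writes
#' GPR files, the slide manifest CSV, the control annotation CSV and
#' the truth tables as TSV. Byte-identical output under the same seed.
#'
#' @param params a `generator_params`.
#' @param dir optional output directory.
#' @return A list with `slides` (per slide: `array_id`, `role`,
#'   `print_batch`, `spike_in_level`, `incubation`, `scatterlight`),
#'   `manifest` (data frame; paths filled when `dir` is given),
#'   `annotation`, `truth` (list: `peptides` data frame with
#'   `peptide_id`, `class`, `is_reactive`, `is_secondary_binder`,
#'   `truth`; `spots` data frame of artifact flags per slide;
#'   `effects` the injected per-level factor effects), `design` and
#'   `params`.
#' @export
generate_experiment <- function(params = generator_params(), dir = NULL) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  lay <- p$layout
  dl <- default_layout(lay)
  design <- dl$design
  ann <- dl$annotation
  ns <- nrow(design)
  rows_total <- lay$n_subarrays * lay$grid_rows * lay$rows_per_block
  cols_total <- lay$grid_cols * lay$cols_per_block

  slide_plan <- data.frame(
    array_id = sprintf("array%d", 1:6),
    print_batch = rep(1:2, each = 3L),
    role = rep(c("empty", "sample", "sample"), 2L),
    spike_in_level = rep(c(NA, "low", "high"), 2L),
    stringsAsFactors = FALSE)

  exp_ids <- ann$peptide_id[ann$class == "experimental"]
  out <- local_seed(p$seed, {
    # peptide truth: contiguous tiling block of spike targets, a disjoint
    # contiguous block of expected-nonreactive peptides, random binders
    reactive_ids <- exp_ids[seq_len(p$n_reactive)]
    nonreactive_ids <- exp_ids[p$n_reactive + seq_len(p$n_nonreactive)]
    binder_pool <- setdiff(exp_ids, c(reactive_ids, nonreactive_ids))
    binder_ids <- sort(sample(binder_pool, p$n_secondary_binders))

    peptide_eff <- stats::setNames(stats::rnorm(length(exp_ids), 0,
                                                p$peptide_sd), exp_ids)
    ctrl_ids <- ann$peptide_id[ann$class != "experimental"]
    ctrl_eff <- stats::setNames(stats::rnorm(length(ctrl_ids), 0,
                                             p$peptide_sd / 2), ctrl_ids)
    pep_eff <- c(peptide_eff, ctrl_eff)

    # printing effects, shared within a print batch
    needle_eff <- lapply(1:2, function(b)
      stats::rnorm(lay$blocks_per_subarray, 0, p$needle_sd))
    subarray_eff <- lapply(1:2, function(b)
      stats::rnorm(lay$n_subarrays, 0, p$subarray_sd))

    slides <- vector("list", nrow(slide_plan))
    spot_truth <- vector("list", nrow(slide_plan))
    effects_truth <- vector("list", nrow(slide_plan))
    for (k in seq_len(nrow(slide_plan))) {
      b <- slide_plan$print_batch[k]
      role <- slide_plan$role[k]
      level <- slide_plan$spike_in_level[k]
      array_off <- stats::rnorm(1, 0, p$array_sd) +
        if (b == 2L) p$batch_shift else 0
      # incubation gradients: smooth decline with position + jitter
      row_eff <- p$row_amplitude *
        (0.5 - (seq_len(rows_total) - 1) / max(1, rows_total - 1)) +
        stats::rnorm(rows_total, 0, p$row_jitter)
      col_eff <- p$col_amplitude *
        (0.5 - (seq_len(cols_total) - 1) / max(1, cols_total - 1)) +
        stats::rnorm(cols_total, 0, p$col_jitter)

      cls <- design$class
      id <- design$id
      react <- numeric(ns)
      react[cls == "secondary_antibody"] <- p$sec_control_effect
      react[id %in% binder_ids] <- p$binder_effect
      if (role == "sample") {
        react[cls == "positive"] <- react[cls == "positive"] +
          p$pos_control_effect
        spike <- if (identical(level, "high")) p$signal_high else p$signal_low
        react[id %in% reactive_ids] <- react[id %in% reactive_ids] + spike
      }

      frac <- if (b == 2L) p$batch2_artifact_fraction else p$artifact_fraction
      is_artifact <- stats::runif(ns) < frac
      art_delta <- ifelse(stats::runif(ns) < 0.5, -1, 1) *
        p$artifact_magnitude * p$noise_sd

      logint <- p$intercept + array_off +
        subarray_eff[[b]][design$subarray] + needle_eff[[b]][design$needle] +
        row_eff[design$global_row] + col_eff[design$global_col] +
        pep_eff[id] + react +
        stats::rnorm(ns, 0, p$noise_sd) +
        ifelse(is_artifact, art_delta, 0)

      inc_spots <- data.frame(
        block = design$block, row = design$row, column = design$column,
        id = id, sequence = NA_character_,
        intensity = 2^logint, flag = 0L, stringsAsFactors = FALSE)
      inc_spots[["F635 SD"]] <- stats::rnorm(ns, 200, 20) *
        ifelse(is_artifact, 8, 1)
      inc_spots[["B635 Median"]] <- stats::rnorm(ns, 90, 5)
      inc <- new_spot_table(
        inc_spots, feature_names = c("F635 SD", "B635 Median"),
        channel = "635",
        header = c(Type = "GenePix Results 3",
                   Wavelengths = "635",
                   Settings = sprintf("synthetic seed=%d slide=%s", p$seed,
                                      slide_plan$array_id[k])),
        intensity_column = "F635 Mean")

      sl_spots <- data.frame(
        block = design$block, row = design$row, column = design$column,
        id = id, sequence = NA_character_,
        intensity = 2^(8 + stats::rnorm(ns, 0, 0.2)), flag = 0L,
        stringsAsFactors = FALSE)
      sl_spots[["Dia."]] <- stats::rnorm(ns, 100, 5) +
        ifelse(is_artifact, stats::rnorm(ns, 0, 30), 0)
      sl_spots[["Pixel SD"]] <- stats::rnorm(ns, 50, 10) *
        ifelse(is_artifact, 10, 1)
      sl_spots[["Circularity"]] <- stats::rnorm(ns, 0.9, 0.02) -
        ifelse(is_artifact, 0.3, 0)
      sl <- new_spot_table(
        sl_spots, feature_names = c("Dia.", "Pixel SD", "Circularity"),
        channel = "532",
        header = c(Type = "GenePix Results 3", Wavelengths = "532"),
        intensity_column = "F532 Mean")

      slides[[k]] <- c(as.list(slide_plan[k, ]),
                       list(incubation = inc, scatterlight = sl))
      spot_truth[[k]] <- data.frame(
        array_id = slide_plan$array_id[k],
        block = design$block, row = design$row, column = design$column,
        id = id, is_artifact = is_artifact, stringsAsFactors = FALSE)
      effects_truth[[k]] <- list(array = array_off,
                                 subarray = subarray_eff[[b]],
                                 needle = needle_eff[[b]],
                                 row = row_eff, col = col_eff)
    }

    peptides <- data.frame(
      peptide_id = ann$peptide_id, class = ann$class,
      is_reactive = ann$peptide_id %in% reactive_ids,
      is_secondary_binder = ann$peptide_id %in% binder_ids,
      stringsAsFactors = FALSE)
    peptides$truth <- NA_character_
    peptides$truth[peptides$is_reactive] <- "expected_reactive"
    peptides$truth[peptides$peptide_id %in% nonreactive_ids] <-
      "expected_nonreactive"

    list(slides = slides, spot_truth = do.call(rbind, spot_truth),
         peptides = peptides, effects = effects_truth)
  })

  manifest <- slide_plan
  manifest$gpr_path <- NA_character_
  manifest$scatterlight_path <- NA_character_

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(out$slides)) {
      aid <- slide_plan$array_id[k]
      gp <- file.path(dir, paste0(aid, ".gpr"))
      sp <- file.path(dir, paste0(aid, "_scatterlight.gpr"))
      write_gpr(out$slides[[k]]$incubation, gp)
      write_gpr(out$slides[[k]]$scatterlight, sp)
      manifest$gpr_path[k] <- gp
      manifest$scatterlight_path[k] <- sp
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(ann, file.path(dir, "control_annotation.csv"),
                     row.names = FALSE)
    utils::write.table(out$peptides, file.path(dir, "truth_peptides.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$spot_truth, file.path(dir, "truth_spots.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(slides = out$slides, manifest = manifest, annotation = ann,
       truth = list(peptides = out$peptides, spots = out$spot_truth,
                    effects = out$effects),
       design = design, layout = lay, params = p)
}

#' Oracle confusion matrix from generator truth
#'
#' Tabulates a call table directly against the generator's truth flags,
#' independently of [evaluate_calls()] (which it cross-checks): spike
#' targets are the positives, expected-nonreactive truth peptides the
#' negatives; peptides excluded upstream are dropped.
#'
#' @param calls a `call_table`.
#' @param truth the `truth$peptides` data frame of
#'   [generate_experiment()].
#' @return A list `tp`, `fp`, `tn`, `fn`.
#' @export
truth_metrics <- function(calls, truth) {
  known <- truth[!is.na(truth$truth), , drop = FALSE]
  missing <- setdiff(known$peptide_id, calls$peptide_id)
  if (length(missing)) {
    stop("truth peptide(s) absent from calls: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  sub <- calls[match(known$peptide_id, calls$peptide_id), , drop = FALSE]
  keep <- is.na(sub$excluded_reason)
  pos <- known$is_reactive
  list(tp = sum(keep & pos & sub$reactive %in% TRUE),
       fn = sum(keep & pos & !(sub$reactive %in% TRUE)),
       fp = sum(keep & !pos & sub$reactive %in% TRUE),
       tn = sum(keep & !pos & !(sub$reactive %in% TRUE)))
}
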