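test_that("generator parameters are validated", {
  expect_error(generator_params(noise_sd = -1), "invalid")
  expect_error(generator_params(artifact_fraction = 1.5), "invalid")
  expect_error(generator_params(batch2_artifact_fraction = -0.1), "invalid")
  p <- small_params(seed = 9)
  expect_s3_class(p, "generator_params")
  expect_identical(p$seed, 9L)
})

test_that("the experiment is deterministic in the seed", {
  e1 <- generate_experiment(small_params(seed = 17))
  e2 <- generate_experiment(small_params(seed = 17))
  e3 <- generate_experiment(small_params(seed = 18))
  expect_identical(e1$slides[[4]]$incubation$spots$intensity,
                   e2$slides[[4]]$incubation$spots$intensity)
  expect_identical(e1$truth$peptides, e2$truth$peptides)
  expect_false(identical(e1$slides[[4]]$incubation$spots$intensity,
                         e3$slides[[4]]$incubation$spots$intensity))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_experiment(small_params(seed = 17)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("the slide plan mirrors the two-batch six-slide design", {
  ex <- small_experiment()
  man <- ex$manifest
  expect_equal(nrow(man), 6L)
  expect_equal(man$print_batch, rep(1:2, each = 3L))
  expect_equal(table(man$role)[["empty"]], 2L)
  expect_equal(table(man$role)[["sample"]], 4L)
  expect_setequal(man$spike_in_level[man$role == "sample"],
                  c("low", "high"))
  # each slide has matched incubation and scatterlight scans
  for (s in ex$slides) {
    expect_s3_class(s$incubation, "spot_table")
    expect_s3_class(s$scatterlight, "spot_table")
    expect_equal(nrow(s$incubation$spots), n_spots(ex$layout))
    expect_equal(s$incubation$channel, "635")
    expect_equal(s$scatterlight$channel, "532")
  }
})

test_that("truth tables are internally consistent", {
  ex <- small_experiment()
  tp <- ex$truth$peptides
  p <- ex$params
  expect_equal(sum(tp$is_reactive), p$n_reactive)
  expect_equal(sum(tp$truth %in% "expected_nonreactive"), p$n_nonreactive)
  expect_equal(sum(tp$is_secondary_binder), p$n_secondary_binders)
  # planted classes are disjoint: binders are never truth peptides,
  # controls are never reactive or binders
  expect_false(any(tp$is_secondary_binder & !is.na(tp$truth)))
  expect_true(all(tp$class[tp$is_reactive] == "experimental"))
  expect_true(all(tp$class[tp$is_secondary_binder] == "experimental"))
  # spot truth covers every spot of every slide
  expect_equal(nrow(ex$truth$spots), 6L * n_spots(ex$layout))
  expect_setequal(unique(ex$truth$spots$array_id), ex$manifest$array_id)
})

test_that("spike targets are silent on empty slides and scale with level", {
  ex <- small_experiment()
  tp <- ex$truth$peptides
  reactive <- tp$peptide_id[tp$is_reactive]
  nonreactive <- tp$peptide_id[tp$truth %in% "expected_nonreactive"]
  mean_gap <- function(k) {
    v <- log2(ex$slides[[k]]$incubation$spots$intensity)
    id <- ex$slides[[k]]$incubation$spots$id
    mean(v[id %in% reactive]) - mean(v[id %in% nonreactive])
  }
  gap_empty <- mean_gap(1)
  gap_low <- mean_gap(2)
  gap_high <- mean_gap(3)
  p <- ex$params
  expect_lt(abs(gap_empty), 0.3)
  expect_equal(gap_low - gap_empty, p$signal_low, tolerance = 0.3)
  expect_equal(gap_high - gap_empty, p$signal_high, tolerance = 0.3)
  # secondary binders react on the empty slide too
  binders <- tp$peptide_id[tp$is_secondary_binder]
  v <- log2(ex$slides[[1]]$incubation$spots$intensity)
  id <- ex$slides[[1]]$incubation$spots$id
  expect_equal(mean(v[id %in% binders]) - mean(v[id %in% nonreactive]),
               p$binder_effect, tolerance = 0.4)
  # positive controls only react on sample slides
  pos <- tp$peptide_id[tp$class == "positive"]
  neg <- tp$peptide_id[tp$class == "negative"]
  v3 <- log2(ex$slides[[3]]$incubation$spots$intensity)
  id3 <- ex$slides[[3]]$incubation$spots$id
  expect_lt(mean(v[id %in% pos]) - mean(v[id %in% neg]), 1.5)
  expect_gt(mean(v3[id3 %in% pos]) - mean(v3[id3 %in% neg]), 2.5)
})

test_that("artifact fractions and feature signatures match the parameters", {
  ex <- generate_experiment(small_params(seed = 23, artifact_fraction = 0.05,
                                         batch2_artifact_fraction = 0.10))
  st <- ex$truth$spots
  frac <- tapply(st$is_artifact, st$array_id, mean)
  expect_lt(abs(mean(frac[c("array1", "array2", "array3")]) - 0.05), 0.015)
  expect_lt(abs(mean(frac[c("array4", "array5", "array6")]) - 0.10), 0.02)
  # artifacts have inflated scatterlight pixel noise
  sl <- ex$slides[[1]]$scatterlight$spots
  art <- st$is_artifact[st$array_id == "array1"]
  expect_gt(mean(sl[["Pixel SD"]][art]), 3 * mean(sl[["Pixel SD"]][!art]))
  expect_lt(mean(sl[["Circularity"]][art]),
            mean(sl[["Circularity"]][!art]))
  # zero fraction possible
  ex0 <- generate_experiment(small_params(seed = 23, artifact_fraction = 0,
                                          batch2_artifact_fraction = 0))
  expect_false(any(ex0$truth$spots$is_artifact))
})

test_that("raw intensities are heteroscedastic, log intensities are not", {
  ex <- small_experiment()
  sp <- ex$slides[[1]]$incubation$spots
  exp_only <- sp[grepl("^PEP", sp$id), ]
  per_pep_raw <- tapply(exp_only$intensity, exp_only$id,
                        function(v) c(mean(v), stats::sd(v)))
  m <- do.call(rbind, per_pep_raw)
  high <- m[, 1] > stats::median(m[, 1])
  # replicate sd grows with the mean on the raw scale
  expect_gt(mean(m[high, 2]), 1.5 * mean(m[!high, 2]))
})

test_that("print-batch effects are shared within, not across, batches", {
  ex <- small_experiment()
  eff <- ex$truth$effects
  expect_identical(eff[[1]]$needle, eff[[2]]$needle)
  expect_identical(eff[[1]]$needle, eff[[3]]$needle)
  expect_identical(eff[[4]]$needle, eff[[6]]$needle)
  expect_false(identical(eff[[1]]$needle, eff[[4]]$needle))
  # per-slide effects differ even within a batch
  expect_false(identical(eff[[1]]$row, eff[[2]]$row))
  expect_false(identical(eff[[1]]$array, eff[[2]]$array))
})

test_that("writing to a directory produces loadable, identical files", {
  dir <- withr::local_tempdir()
  ex <- generate_experiment(small_params(seed = 29), dir = dir)
  expect_setequal(
    list.files(dir),
    c(sprintf("array%d.gpr", 1:6),
      sprintf("array%d_scatterlight.gpr", 1:6),
      "manifest.csv", "control_annotation.csv",
      "truth_peptides.tsv", "truth_spots.tsv"))
  back <- read_gpr(file.path(dir, "array2.gpr"))
  expect_identical(back$spots$intensity,
                   ex$slides[[2]]$incubation$spots$intensity)
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  expect_true(all(file.exists(man$gpr_path)))
  expect_true(all(file.exists(man$scatterlight_path)))
  ann <- read_control_annotation(file.path(dir, "control_annotation.csv"))
  expect_identical(ann, ex$annotation, ignore_attr = TRUE)
  tp <- utils::read.delim(file.path(dir, "truth_peptides.tsv"),
                          stringsAsFactors = FALSE)
  expect_equal(sum(tp$is_reactive), ex$params$n_reactive)
})

test_that("truth_metrics refuses calls missing truth peptides", {
  ex <- small_experiment()
  v <- fixture("values_high1", slide_values(ex, 3)$values)
  calls <- call_signals(v, ex$annotation)
  expect_error(truth_metrics(calls[-(1:50), ], ex$truth$peptides),
               "absent from calls")
})
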