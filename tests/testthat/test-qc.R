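# closed-form prediction band, evaluated directly as the oracle
band_oracle <- function(x, y, x0, y0, level = 0.95) {
  fit <- lm(y ~ x)
  n <- length(x)
  s <- sigma(fit)
  half <- qt(1 - (1 - level) / 2, n - 2) * s *
    sqrt(1 + 1 / n + (x0 - mean(x))^2 / sum((x - mean(x))^2))
  abs(y0 - (coef(fit)[1] + coef(fit)[2] * x0)) > half
}

test_that("band labeling flags a single grossly perturbed spot", {
  set.seed(31)
  base <- rnorm(60, 10, 1)
  m <- cbind(base + rnorm(60, 0, 0.05), base + rnorm(60, 0, 0.05),
             base + rnorm(60, 0, 0.05))
  rownames(m) <- sprintf("p%02d", 1:60)
  m[7, 2] <- m[7, 2] + 10
  lab <- band_label(m)
  # the perturbed spot is flagged; a 95% band also flags roughly 5% of
  # clean spots per partner regression, never a large fraction
  expect_equal(lab$label[lab$peptide_id == "p07" & lab$subarray == 2],
               "unreliable")
  expect_lte(mean(lab$label == "unreliable"), 0.2)
  # oracle agreement for the perturbed spot, regression of 2 on 1
  expect_true(band_oracle(m[, 1], m[, 2], m[7, 1], m[7, 2]))
  expect_equal(unique(lab$probability_reliable[lab$label == "unreliable"]), 0)
})

test_that("exactly collinear replicates are all reliable; level is monotone", {
  base <- seq(5, 15, length.out = 40)
  m <- cbind(base, base, base)
  rownames(m) <- sprintf("p%02d", 1:40)
  lab <- band_label(m, level = 0.95)
  expect_true(all(lab$label == "reliable"))
  # near level 1 everything is reliable; near level 0 everything with
  # nonzero residual is unreliable
  set.seed(32)
  m2 <- m + matrix(rnorm(120, 0, 0.3), ncol = 3)
  lab_hi <- band_label(m2, level = 0.999999)
  lab_lo <- band_label(m2, level = 1e-6)
  expect_true(all(lab_hi$label == "reliable"))
  expect_true(mean(lab_lo$label == "unreliable") > 0.99)
  n_mid <- sum(band_label(m2, level = 0.5)$label == "unreliable")
  n_95 <- sum(band_label(m2, level = 0.95)$label == "unreliable")
  expect_gte(n_mid, n_95)
})

test_that("band labeling validates its inputs", {
  m <- matrix(rnorm(30), ncol = 3)
  rownames(m) <- sprintf("p%d", 1:10)
  expect_error(band_label(m[, 1:2]), ">= 3 subarray")
  m2 <- matrix(rnorm(15), ncol = 3)
  expect_error(band_label(m2), ">= 10 shared")
  m[, 1] <- 5
  expect_error(band_label(m), "zero-variance")
})

test_that("class balancing downsamples the majority deterministically", {
  labels <- c(rep("reliable", 100), rep("unreliable", 10))
  idx <- balance_classes(labels, seed = 5)
  expect_length(idx, 20L)
  expect_equal(sum(labels[idx] == "reliable"), 10L)
  expect_equal(sum(labels[idx] == "unreliable"), 10L)
  expect_identical(idx, balance_classes(labels, seed = 5))
  # already balanced input is untouched
  expect_identical(balance_classes(rep(c("a", "b"), each = 10), seed = 1),
                   1:20)
  expect_error(balance_classes(rep("reliable", 5), seed = 1), "two non-empty")
})

test_that("classifier separates synthetic artifact features", {
  set.seed(41)
  n <- 400L
  art <- rep(c(FALSE, TRUE), each = n / 2)
  feats <- data.frame(
    intensity = rnorm(n, 10, 1),
    pixel_sd = rnorm(n, 50, 10) * ifelse(art, 10, 1),
    diameter = rnorm(n, 100, 5))
  labels <- ifelse(art, "unreliable", "reliable")
  train <- sample(n, n / 2)
  clf <- train_reliability_classifier(feats[train, ], labels[train], seed = 6)
  pred <- predict_reliability(clf, feats[-train, ])
  expect_gte(mean(pred$label == labels[-train]), 0.95)
  # determinism: same data + seed -> identical predictions
  clf2 <- train_reliability_classifier(feats[train, ], labels[train], seed = 6)
  pred2 <- predict_reliability(clf2, feats[-train, ])
  expect_identical(pred$probability_reliable, pred2$probability_reliable)
  # random labels -> chance-level held-out accuracy
  set.seed(42)
  rnd <- sample(labels)
  clf_null <- train_reliability_classifier(feats[train, ], rnd[train],
                                           seed = 6)
  pred_null <- predict_reliability(clf_null, feats[-train, ])
  acc_null <- mean(pred_null$label == rnd[-train])
  expect_gte(acc_null, 0.35)
  expect_lte(acc_null, 0.65)
})

test_that("classifier refuses tiny samples and missing features", {
  feats <- data.frame(a = rnorm(30), b = rnorm(30))
  labels <- rep(c("reliable", "unreliable"), 15)
  expect_error(train_reliability_classifier(feats[1:10, ], labels[1:10]),
               ">= 20")
  clf <- train_reliability_classifier(feats, labels, ntree = 50, seed = 1)
  expect_error(predict_reliability(clf, feats["a"]), "missing")
})

test_that("replicate aggregation weights by reliability", {
  r <- aggregate_replicates(c(10, 12), reliable = c(TRUE, TRUE),
                            weights = c(0.5, 1.0))
  expect_equal(r$value, (0.5 * 10 + 1.0 * 12) / 1.5)
  expect_false(r$excluded)
  # all unreliable -> excluded
  r2 <- aggregate_replicates(c(10, 12, 14), reliable = rep(FALSE, 3))
  expect_true(r2$excluded)
  expect_true(is.na(r2$value))
  # equal weights = plain mean; result within replicate range
  set.seed(51)
  for (i in 1:20) {
    v <- rnorm(3, 10, 2)
    w <- runif(3, 0.1, 1)
    keep <- sample(c(TRUE, FALSE), 3, replace = TRUE, prob = c(0.8, 0.2))
    if (!any(keep)) next
    r3 <- aggregate_replicates(v, reliable = keep, weights = w)
    expect_gte(r3$value, min(v[keep]) - 1e-12)
    expect_lte(r3$value, max(v[keep]) + 1e-12)
  }
  expect_equal(aggregate_replicates(c(1, 2, 6), weights = c(1, 1, 1))$value,
               3)
  expect_error(aggregate_replicates(c(1, 2), weights = c(-1, 1)), "negative")
})

test_that("qc flags injected artifacts on held-out synthetic slides", {
  lay <- small_layout()
  exH <- generate_experiment(small_params(seed = 61, artifact_fraction = 0.05,
                                          batch2_artifact_fraction = 0.05))
  train_one <- function(k) {
    tab <- join_scans(exH$slides[[k]]$incubation, exH$slides[[k]]$scatterlight)
    norm <- normalize_slide(tab, lay, exH$annotation)
    m <- peptide_matrix(norm$spots, lay)
    lab <- band_label(m)
    idx <- match(paste(norm$spots$id, norm$spots$subarray),
                 paste(lab$peptide_id, lab$subarray))
    feat_cols <- setdiff(names(norm$spots),
                         c("block", "row", "column", "id", "class",
                           "subarray", "needle", "global_row", "global_col",
                           "normalized"))
    list(feats = norm$spots[!is.na(idx), feat_cols],
         labels = lab$label[idx[!is.na(idx)]])
  }
  tr <- lapply(c(2, 3, 5, 6), train_one)
  feats <- do.call(rbind, lapply(tr, `[[`, "feats"))
  labels <- unlist(lapply(tr, `[[`, "labels"))
  bi <- balance_classes(labels, seed = 62)
  clf <- train_reliability_classifier(feats[bi, ], labels[bi], seed = 62)

  exN <- generate_experiment(small_params(seed = 63, artifact_fraction = 0.05))
  tabN <- join_scans(exN$slides[[3]]$incubation, exN$slides[[3]]$scatterlight)
  normN <- normalize_slide(tabN, lay, exN$annotation)
  pred <- predict_reliability(clf, normN$spots)
  tn <- exN$truth$spots[exN$truth$spots$array_id == "array3", ]
  is_art <- tn$is_artifact[match(paste(normN$spots$block, normN$spots$row,
                                       normN$spots$column),
                                 paste(tn$block, tn$row, tn$column))]
  expect_gte(mean(pred$label[is_art] == "unreliable"), 0.80)

  # qc-weighted aggregation lands closer to the artifact-free oracle
  # (aggregation over the truly clean replicates) than plain averaging
  m <- peptide_matrix(normN$spots, lay)
  idx <- cbind(match(normN$spots$id, rownames(m)), normN$spots$subarray)
  art_m <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  art_m[idx] <- is_art
  rel <- matrix(TRUE, nrow(m), ncol(m), dimnames = dimnames(m))
  w <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
  rel[idx] <- pred$label == "reliable"
  w[idx] <- pred$probability_reliable
  v_oracle <- aggregate_matrix(m, reliable = !art_m)$values
  v_no <- aggregate_matrix(m)$values
  v_qc <- aggregate_matrix(m, reliable = rel, weights = w)$values
  sel <- rowSums(art_m) > 0 & rowSums(art_m) < ncol(m) &
    !is.na(v_qc) & !is.na(v_oracle)
  expect_gte(sum(sel), 20L)
  expect_lt(mean(abs(v_qc - v_oracle)[sel]),
            mean(abs(v_no - v_oracle)[sel]))

  # persistence round trip preserves behaviour
  f <- withr::local_tempfile(fileext = ".rds")
  save_reliability_classifier(clf, f)
  clf_back <- load_reliability_classifier(f)
  pred_back <- predict_reliability(clf_back, normN$spots)
  expect_identical(pred$probability_reliable, pred_back$probability_reliable)
})
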