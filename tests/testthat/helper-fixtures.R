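# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# reduced geometry for fast tests: 3 subarrays x 4 blocks (2x2) x 10x20
# spots = 2400 spots, same 10% control budget structure as the default
small_layout <- function() {
  array_layout(n_subarrays = 3L, grid_rows = 2L, grid_cols = 2L,
               rows_per_block = 10L, cols_per_block = 20L)
}

small_params <- function(seed = 1L, ...) {
  generator_params(layout = small_layout(), seed = seed,
                   n_reactive = 60L, n_nonreactive = 40L,
                   n_secondary_binders = 20L, ...)
}

small_experiment <- function() {
  fixture("small_experiment", generate_experiment(small_params(seed = 101L)))
}

full_experiment <- function() {
  fixture("full_experiment", generate_experiment(generator_params(seed = 101L)))
}

# minimal hand-written GPR text: 3 spots, one extra numeric column
tiny_gpr_text <- function() {
  c("ATF\t1.0",
    "2\t7",
    "\"Type=GenePix Results 3\"",
    "\"Wavelengths=635\"",
    paste(c("\"Block\"", "\"Row\"", "\"Column\"", "\"ID\"", "\"Flags\"",
            "\"F635 Mean\"", "\"F635 SD\""), collapse = "\t"),
    "1\t1\t1\tpepA\t0\t1024\t10.5",
    "1\t1\t2\tpepB\t-100\t2000\t20.5",
    "1\t2\t1\tpepC\t0\t0\t30.5")
}

# normalized slide + per-peptide values for one slide of an experiment
slide_values <- function(ex, k, qc = FALSE, classifier = NULL) {
  tab <- if (qc) join_scans(ex$slides[[k]]$incubation,
                            ex$slides[[k]]$scatterlight)
         else ex$slides[[k]]$incubation
  norm <- normalize_slide(tab, ex$layout, ex$annotation)
  m <- peptide_matrix(norm$spots, ex$layout)
  reliable <- weights <- NULL
  if (qc && !is.null(classifier)) {
    pred <- predict_reliability(classifier, norm$spots)
    reliable <- matrix(TRUE, nrow(m), ncol(m), dimnames = dimnames(m))
    weights <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
    idx <- cbind(match(norm$spots$id, rownames(m)), norm$spots$subarray)
    reliable[idx] <- pred$label == "reliable"
    weights[idx] <- pred$probability_reliable
  }
  agg <- aggregate_matrix(m, reliable = reliable, weights = weights)
  list(norm = norm, values = agg$values, excluded = agg$excluded)
}

truth_vector <- function(ex) {
  tp <- ex$truth$peptides
  stats::setNames(tp$truth, tp$peptide_id)[!is.na(tp$truth)]
}
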