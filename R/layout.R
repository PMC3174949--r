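#' Array geometry
#'
#' A slide carries `n_subarrays` identical copies of the peptide set,
#' printed consecutively and stacked vertically; each subarray holds
#' `blocks_per_subarray` blocks arranged in a `grid_rows` x `grid_cols`
#' pattern, each block printed by a single print needle and holding
#' `rows_per_block` x `cols_per_block` spots. The default geometry
#' (3 subarrays, 16 blocks as 4x4, 20x20 spots) gives 19200 spots per
#' slide.
#'
#' @param n_subarrays number of subarray replicates per slide.
#' @param grid_rows,grid_cols block grid dimensions within a subarray.
#' @param rows_per_block,cols_per_block spot grid dimensions per block.
#' @return An `array_layout` object.
#' @export
array_layout <- function(n_subarrays = 3L, grid_rows = 4L, grid_cols = 4L,
                         rows_per_block = 20L, cols_per_block = 20L) {
  stopifnot(n_subarrays >= 1L, grid_rows >= 1L, grid_cols >= 1L,
            rows_per_block >= 1L, cols_per_block >= 1L)
  structure(list(n_subarrays = as.integer(n_subarrays),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 blocks_per_subarray = as.integer(grid_rows * grid_cols),
                 rows_per_block = as.integer(rows_per_block),
                 cols_per_block = as.integer(cols_per_block)),
            class = "array_layout")
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf(
    "array_layout: %d subarrays x %d blocks (%dx%d) x %dx%d spots = %d spots\n",
    x$n_subarrays, x$blocks_per_subarray, x$grid_rows, x$grid_cols,
    x$rows_per_block, x$cols_per_block, n_spots(x)))
  invisible(x)
}

#' Total number of spots on a slide
#' @param layout an `array_layout`.
#' @return Integer spot count.
#' @export
n_spots <- function(layout) {
  layout$n_subarrays * layout$blocks_per_subarray *
    layout$rows_per_block * layout$cols_per_block
}

#' Resolve a GPR block/row/column address to physical coordinates
#'
#' GPR files number blocks 1..48 in row-major order across the whole
#' slide. This maps each (block, row-in-block, column-in-block) triple
#' to the physical position used by the normalization model: the
#' subarray it belongs to, the print needle (position of the block
#' within its subarray's grid — corresponding blocks across subarrays
#' share the needle), and the global row and column across the slide.
#' Subarrays are stacked vertically, so with the default layout the
#' global row runs 1..240 and the global column 1..80.
#'
#' The mapping is a bijection: vectorized over the inputs.
#'
#' @param layout an `array_layout`.
#' @param block_id,row_in_block,col_in_block 1-based GPR coordinates.
#' @param array_id slide identifier carried through (optional).
#' @return A data frame with columns `subarray`, `needle`, `global_row`,
#'   `global_col` (and `array_id` if supplied).
#' @export
resolve_address <- function(layout, block_id, row_in_block, col_in_block,
                            array_id = NULL) {
  stopifnot(inherits(layout, "array_layout"))
  block_id <- as.integer(block_id)
  row_in_block <- as.integer(row_in_block)
  col_in_block <- as.integer(col_in_block)
  bps <- layout$blocks_per_subarray
  if (any(block_id < 1L | block_id > layout$n_subarrays * bps)) {
    stop("block_id out of range 1..", layout$n_subarrays * bps, call. = FALSE)
  }
  if (any(row_in_block < 1L | row_in_block > layout$rows_per_block)) {
    stop("row_in_block out of range 1..", layout$rows_per_block, call. = FALSE)
  }
  if (any(col_in_block < 1L | col_in_block > layout$cols_per_block)) {
    stop("col_in_block out of range 1..", layout$cols_per_block, call. = FALSE)
  }
  subarray <- (block_id - 1L) %/% bps + 1L
  needle <- (block_id - 1L) %% bps + 1L
  grid_row <- (needle - 1L) %/% layout$grid_cols + 1L
  grid_col <- (needle - 1L) %% layout$grid_cols + 1L
  rows_per_subarray <- layout$grid_rows * layout$rows_per_block
  global_row <- (subarray - 1L) * rows_per_subarray +
    (grid_row - 1L) * layout$rows_per_block + row_in_block
  global_col <- (grid_col - 1L) * layout$cols_per_block + col_in_block
  out <- data.frame(subarray = subarray, needle = needle,
                    global_row = global_row, global_col = global_col)
  if (!is.null(array_id)) out$array_id <- array_id
  out
}

#' Replicate values of one peptide across subarrays
#'
#' Each peptide is spotted once per subarray at the same within-subarray
#' position, so a slide yields one replicate per subarray. Missing
#' replicates (e.g. excluded spots) are reported as `NA`, never silently
#' dropped.
#'
#' @param peptide_id peptide identifier.
#' @param table a `spot_table` covering one slide.
#' @param layout the slide's `array_layout`.
#' @param values which per-spot value to return (a column of
#'   `table$spots`, default the intensity).
#' @return Numeric vector of length `layout$n_subarrays`, ordered by
#'   subarray, `NA` where a replicate is absent.
#' @export
replicates_of <- function(peptide_id, table, layout, values = "intensity") {
  stopifnot(inherits(table, "spot_table"), inherits(layout, "array_layout"))
  sp <- table$spots
  hit <- sp$id == peptide_id
  if (!any(hit)) stop("peptide '", peptide_id, "' absent from all subarrays",
                      call. = FALSE)
  addr <- resolve_address(layout, sp$block[hit], sp$row[hit], sp$column[hit])
  out <- rep(NA_real_, layout$n_subarrays)
  out[addr$subarray] <- sp[[values]][hit]
  out
}

#' Default slide design: geometry plus control annotation
#'
#' Builds the standard slide: 3 subarrays of 16 blocks (4x4 needles) of
#' 20x20 spots, 19200 spots in total. 10% of spots are dedicated
#' controls — 5% positive (strong specific reaction expected), 2.5%
#' secondary-antibody (react with the labelled detection antibody), 1%
#' negative and 1.5% process controls — placed deterministically so
#' that every block (hence every needle and subarray) carries repeats
#' of every control class, spread over all block rows and columns.
#' Controls use 13 distinct control peptide identities; the remaining
#' spots hold 5760 experimental peptides, each spotted once per
#' subarray (triplicates).
#'
#' @param layout an `array_layout`; defaults to the standard geometry.
#' @return A list with `layout`, `design` (data frame: `block`, `row`,
#'   `column`, `id`, `class`, plus resolved `subarray`, `needle`,
#'   `global_row`, `global_col`) and `annotation` (data frame
#'   `peptide_id`, `class` — one row per distinct peptide).
#' @export
default_layout <- function(layout = array_layout()) {
  stopifnot(inherits(layout, "array_layout"))
  spots_per_block <- layout$rows_per_block * layout$cols_per_block
  n_blocks <- layout$n_subarrays * layout$blocks_per_subarray
  # control budget: 10% of spots, split 5/2.5/1/1.5 over the classes;
  # with defaults this is 40 controls per block (20/10/4/6)
  per_block <- round(spots_per_block * c(positive = 0.05,
                                         secondary_antibody = 0.025,
                                         negative = 0.01,
                                         process = 0.015))
  n_ctrl_block <- sum(per_block)

  # control peptide identities: 13 distinct sequences over the classes
  ctrl_ids <- list(
    positive = sprintf("CTRL_POS_%02d", 1:5),
    secondary_antibody = sprintf("CTRL_SEC_%02d", 1:3),
    negative = sprintf("CTRL_NEG_%02d", 1:2),
    process = sprintf("CTRL_PRC_%02d", 1:3))

  # within-block control positions: two per row, at columns k*(r-1)+1 and
  # k*(r-1)+2 (wrapping) with stride k = cols/rows. For the default square
  # block (k = 1) adjacent rows share a column, so rows and columns form
  # one connected chain and row/column contrasts stay estimable instead
  # of aliasing in disconnected pairs; in every case all block columns
  # carry controls.
  rows <- rep(seq_len(layout$rows_per_block), each = 2L)
  stride <- max(1L, layout$cols_per_block %/% layout$rows_per_block)
  base <- stride * (seq_len(layout$rows_per_block) - 1L)
  cols <- as.vector(rbind(base %% layout$cols_per_block + 1L,
                          (base + 1L) %% layout$cols_per_block + 1L))
  if (length(setdiff(seq_len(layout$cols_per_block), cols))) {
    stop("control placement cannot cover all block columns for this ",
         "geometry; use cols_per_block <= 2 * rows_per_block", call. = FALSE)
  }
  stopifnot(length(rows) == n_ctrl_block)
  ctrl_class <- rep(names(per_block), per_block)
  ctrl_id_cycle <- unlist(lapply(names(per_block), function(cl) {
    ids <- ctrl_ids[[cl]]
    ids[((seq_len(per_block[[cl]]) - 1L) %% length(ids)) + 1L]
  }))

  # one subarray's worth of experimental peptide slots
  n_exp_per_subarray <- layout$blocks_per_subarray *
    (spots_per_block - n_ctrl_block)
  exp_ids <- sprintf("PEP_%05d", seq_len(n_exp_per_subarray))

  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    needle <- (b - 1L) %% layout$blocks_per_subarray + 1L
    grid <- expand.grid(column = seq_len(layout$cols_per_block),
                        row = seq_len(layout$rows_per_block))
    grid <- grid[, c("row", "column")]
    is_ctrl <- rep(FALSE, spots_per_block)
    ctrl_pos <- match(paste(rows, cols), paste(grid$row, grid$column))
    is_ctrl[ctrl_pos] <- TRUE
    id <- character(spots_per_block)
    class <- rep("experimental", spots_per_block)
    # rotate the class/identity cycle per needle so no control class is
    # confined to the same block rows on every needle (identical across
    # subarrays, so triplicates stay aligned)
    rot <- ((seq_len(n_ctrl_block) - 1L + (needle - 1L) * 7L) %%
              n_ctrl_block) + 1L
    id[ctrl_pos] <- ctrl_id_cycle[rot]
    class[ctrl_pos] <- ctrl_class[rot]
    n_exp_block <- spots_per_block - n_ctrl_block
    exp_offset <- (needle - 1L) * n_exp_block
    id[!is_ctrl] <- exp_ids[exp_offset + seq_len(n_exp_block)]
    blocks[[b]] <- data.frame(block = b, row = grid$row, column = grid$column,
                              id = id, class = class,
                              stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, blocks)
  design <- cbind(design,
                  resolve_address(layout, design$block, design$row,
                                  design$column))
  ann <- unique(design[, c("id", "class")])
  ann <- ann[order(ann$id), ]
  names(ann) <- c("peptide_id", "class")
  rownames(ann) <- NULL
  list(layout = layout, design = design, annotation = ann)
}

#' Read a control annotation file
#'
#' Two-column CSV mapping `peptide_id` to a control class in
#' \{positive, secondary_antibody, negative, process, experimental\};
#' peptides absent from the file default to class `experimental`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `peptide_id`, `class`.
#' @export
read_control_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("peptide_id", "class") %in% names(ann))) {
    stop("control annotation needs columns peptide_id, class", call. = FALSE)
  }
  ok <- c("positive", "secondary_antibody", "negative", "process",
          "experimental")
  bad <- setdiff(unique(ann$class), ok)
  if (length(bad)) stop("unknown control class(es): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$peptide_id)) {
    stop("duplicated peptide_id in control annotation", call. = FALSE)
  }
  ann[, c("peptide_id", "class")]
}
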