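# shared builders for synthetic inputs used across the test files

disc_mask <- function(H, W, centre, radius) {
  outer(seq_len(H), seq_len(W), function(r, c)
    (r - centre[1])^2 + (c - centre[2])^2 <= radius^2)
}

# a small stack with discs of constant, known per-channel intensity
disc_stack <- function(H = 64, W = 64, discs = list(), n_channels = 3,
                       background = 0) {
  cube <- array(background, dim = c(H, W, n_channels))
  for (d in discs) {
    m <- disc_mask(H, W, d$centre, d$radius)
    for (c in seq_len(n_channels))
      cube[, , c][m] <- d$values[c]
  }
  hyper_stack(cube, channel_table(n_channels))
}

two_group_scene <- function(seed, n_cells = 24, identical_groups = FALSE) {
  profiles <- if (identical_groups)
    list(A = list(mean = c(1, 0.5, 0.25), sd = 0.05),
         B = list(mean = c(1, 0.5, 0.25), sd = 0.05))
  else
    list(A = list(mean = c(1, 0.4, 0.2), sd = 0.05),
         B = list(mean = c(0.2, 0.4, 1), sd = 0.05))
  synth_scene(seed = seed, image_size = c(128, 128), n_cells = n_cells,
              cell_radius_px = c(4.5, 6.5),
              group_abundance_profiles = profiles)
}

# full pipeline for one seed: returns the split-sample 1-D projection
# test p-value (train on alternate cells, test on the rest)
pipeline_pvalue <- function(seed, identical_groups = FALSE) {
  r <- render_scene(two_group_scene(seed, identical_groups =
                                      identical_groups))
  st <- denoise_stack(subtract_background(r$stack))
  seg <- segment_cells(st)
  f <- suppressMessages(extract_features(st, seg))
  gt <- r$labels[cbind(round(seg$cells$centroid_row),
                       round(seg$cells$centroid_col))]
  gi <- gt[match(f$cell_id, seg$cells$cell_id)]
  g <- ifelse(gi > 0, r$cells$group[pmax(gi, 1L)], NA)
  ok <- !is.na(g)
  f <- f[ok, ]; g <- g[ok]
  split <- seq_along(g) %% 2 == 0
  if (min(table(g[split])) < 2 || min(table(g[!split])) < 1) return(NA_real_)
  d <- discriminate_1d(dplyr::select(f, -cell_id), g, split = split)
  d$p_value
}

expect_no_na <- function(x) testthat::expect_false(anyNA(x))
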