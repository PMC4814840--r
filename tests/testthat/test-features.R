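test_that("mean intensity and band ratio match loop oracles", {
  cell <- cbind(c(2, 4), c(10, 10), c(1, 3))
  expect_equal(mean_channel_intensity(cell, 1), 3)
  expect_equal(mean_channel_intensity(cell, 2), 10)
  set.seed(1)
  rc <- matrix(runif(15, 0, 9), 5, 3)
  for (j in 1:3) {
    s <- 0; for (i in 1:5) s <- s + rc[i, j]
    expect_equal(mean_channel_intensity(rc, j), s / 5)
  }
  expect_equal(band_ratio(rc, 2, 2), 1, tolerance = 1e-6)
  con <- cbind(rep(10, 4), rep(2, 4))
  expect_equal(band_ratio(con, 1, 2, epsilon = 1e-12), 5)
  expect_error(mean_channel_intensity(rc, 9), "range")
})

test_that("the 360/460 ratio resolves to the nearest excitation channels", {
  ch <- channel_table(18)
  reg <- feature_registry("default18", channels = ch)
  p <- reg$params[[match("ratio_360_460", reg$name)]]
  expect_equal(ch$ex_center_nm[p$num_channel],
               ch$ex_center_nm[which.min(abs(ch$ex_center_nm - 360))])
  expect_equal(ch$ex_center_nm[p$den_channel],
               ch$ex_center_nm[which.min(abs(ch$ex_center_nm - 460))])
  expect_lt(abs(ch$ex_center_nm[p$num_channel] - 360), 5)
  expect_lt(abs(ch$ex_center_nm[p$den_channel] - 460), 5)
})

test_that("PCA score statistics match direct moment formulas", {
  expect_equal(pca_abundance_stat(cbind(c(-1, 0, 1)), 1, "mean"), 0)
  expect_equal(pca_abundance_stat(cbind(c(-1, 0, 1)), 1, "variance"), 1)
  expect_error(pca_abundance_stat(cbind(rep(2, 5)), 1, "skewness"),
               "undefined")
  set.seed(2)
  x <- rnorm(40)
  sc <- cbind(x, x^2)
  m <- mean(x); m2 <- mean((x - m)^2)
  expect_equal(pca_abundance_stat(sc, 1, "mean"), m)
  expect_equal(pca_abundance_stat(sc, 1, "variance"), sum((x - m)^2) / 39)
  expect_equal(pca_abundance_stat(sc, 1, "skewness"),
               mean((x - m)^3) / m2^1.5)
  expect_equal(pca_abundance_stat(sc, 1, "kurtosis"),
               mean((x - m)^4) / m2^2)
})

test_that("channel correlation is Pearson with a zero-variance sentinel", {
  set.seed(3)
  a <- runif(20); b <- runif(20)
  cell <- cbind(a, b, a, -a + 2)
  expect_equal(channel_correlation(cell, 1, 3), 1)
  expect_equal(channel_correlation(cell, 1, 4), -1)
  expect_equal(channel_correlation(cell, 1, 2), cor(a, b))
  cell0 <- cbind(a, rep(5, 20))
  expect_true(is.nan(channel_correlation(cell0, 1, 2)))
})

test_that("spectral variation is the mean angle to the mean spectrum", {
  # same shape at different brightness: zero variation
  shape <- c(3, 2, 1)
  cell <- rbind(shape, 2 * shape, 10 * shape)
  expect_equal(spectral_variation(cell), 0, tolerance = 1e-12)
  # two orthogonal halves: every pixel sits pi/4 from the mean
  cell2 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(spectral_variation(cell2), pi / 4, tolerance = 1e-12)
  set.seed(4)
  rc <- matrix(runif(18, 0.1, 2), 6, 3)
  m <- colMeans(rc)
  oracle <- mean(sapply(1:6, function(i)
    acos(sum(rc[i, ] * m) / sqrt(sum(rc[i, ]^2) * sum(m^2)))))
  expect_equal(spectral_variation(rc), oracle, tolerance = 1e-10)
})

test_that("GLCM texture matches a brute-force co-occurrence oracle", {
  expect_equal(texture_feature(matrix(7, 4, 4), metric = "glcm_contrast"), 0)
  expect_equal(texture_feature(matrix(7, 4, 4), metric = "glcm_energy"), 1)
  # checkerboard: every horizontal neighbour pair differs by one level
  cb <- outer(1:6, 1:6, function(r, c) (r + c) %% 2)
  P <- specell:::glcm_matrix(matrix(ifelse(cb == 1, 2L, 1L), 6), c(0, 1), 2)
  expect_equal(sum(P[1, 2] + P[2, 1]) / sum(P), 1)   # all pairs unequal
  set.seed(5)
  img <- matrix(runif(49), 7, 7)
  msk <- matrix(TRUE, 7, 7); msk[1, 1] <- FALSE
  for (metric in c("glcm_contrast", "glcm_homogeneity", "glcm_energy")) {
    got <- texture_feature(img, msk, metric, levels = 4, distance_px = 1)
    # brute force: enumerate pairs per orientation
    q <- matrix(NA_integer_, 7, 7)
    rng <- range(img[msk])
    q[msk] <- pmin(as.integer((img[msk] - rng[1]) / diff(rng) * 4) + 1L, 4L)
    oracle <- mean(sapply(list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1)),
                          function(off) {
      P <- matrix(0, 4, 4)
      for (r in 1:7) for (c in 1:7) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 >= 1 && r2 <= 7 && c2 >= 1 && c2 <= 7 &&
            !is.na(q[r, c]) && !is.na(q[r2, c2])) {
          P[q[r, c], q[r2, c2]] <- P[q[r, c], q[r2, c2]] + 1
          P[q[r2, c2], q[r, c]] <- P[q[r2, c2], q[r, c]] + 1
        }
      }
      P <- P / sum(P)
      i <- row(P); j <- col(P)
      switch(metric, glcm_contrast = sum(P * (i - j)^2),
             glcm_homogeneity = sum(P / (1 + abs(i - j))),
             glcm_energy = sum(P^2))
    }))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("morphology features behave on canonical shapes", {
  lab <- matrix(0L, 20, 20)
  lab[6:15, 6:15] <- 1L                     # 10x10 square
  seg <- structure(list(labels = lab, n_cells = 1L,
                        cells = tibble::tibble(cell_id = 1L)),
                   class = "segmentation")
  m <- morphology_features(seg, 1)
  expect_equal(m$area_px, 100)
  expect_equal(m$perimeter_px, 40)
  expect_equal(m$solidity, 1)
  lab1 <- matrix(0L, 5, 5); lab1[3, 3] <- 1L
  seg1 <- structure(list(labels = lab1, n_cells = 1L), class = "segmentation")
  expect_equal(morphology_features(seg1, 1)$area_px, 1)
  disc <- matrix(0L, 32, 32)
  disc[disc_mask(32, 32, c(16, 16), 10)] <- 1L
  segd <- structure(list(labels = disc, n_cells = 1L), class = "segmentation")
  md <- morphology_features(segd, 1)
  expect_lt(md$eccentricity, 0.2)
  expect_gt(md$solidity, 0.9)
  expect_error(morphology_features(seg, 7), "unknown")
})

test_that("extract_features reproduces hand-computed values on known cells", {
  st <- disc_stack(64, 64, discs = list(
    list(centre = c(20, 20), radius = 6, values = c(40, 10, 5)),
    list(centre = c(45, 45), radius = 6, values = c(8, 16, 32))))
  # ground-truth segmentation: isolates the feature arithmetic from the
  # thresholding pipeline
  lab <- matrix(0L, 64, 64)
  lab[disc_mask(64, 64, c(20, 20), 6)] <- 1L
  lab[disc_mask(64, 64, c(45, 45), 6)] <- 2L
  seg <- structure(list(
    labels = lab, n_cells = 2L, min_area_px = 1L,
    channel_weights = rep(1, 3),
    cells = tibble::tibble(cell_id = 1:2, area = c(sum(lab == 1),
                                                   sum(lab == 2)),
                           centroid_row = c(20, 45),
                           centroid_col = c(20, 45),
                           border_touching = c(FALSE, FALSE))),
    class = "segmentation")
  reg <- dplyr::bind_rows(
    tibble::tibble(name = "mean_c1", family = "mean_intensity",
                   params = list(list(channel = 1L))),
    tibble::tibble(name = "ratio_c1_c3", family = "band_ratio",
                   params = list(list(num_channel = 1L,
                                      den_channel = 3L))),
    tibble::tibble(name = "area", family = "morphology",
                   params = list(list(property = "area_px"))))
  f <- suppressMessages(extract_features(st, seg, reg))
  expect_equal(names(f), c("cell_id", "mean_c1", "ratio_c1_c3", "area"))
  expect_equal(nrow(f), 2)
  expect_equal(f$mean_c1, c(40, 8), tolerance = 1e-6)
  expect_equal(f$ratio_c1_c3, c(8, 0.25), tolerance = 1e-4)
})

test_that("similarity_stat features use the shipped reference spectra", {
  refs <- read_reference_spectra(
    system.file("extdata", "reference_spectra_synthetic.csv",
                package = "specell"))
  expect_equal(refs$name, c("nadh_like", "fad_like"))
  expect_true(all(abs(sapply(refs$values, sum) - 1) < 1e-6))
  st <- disc_stack(48, 48, n_channels = 18, discs = list(
    list(centre = c(24, 24), radius = 8,
         values = refs$values[[1]] * 500)))
  seg <- segment_cells(st, min_area_px = 20)
  reg <- tibble::tibble(name = "sam_to_nadh", family = "similarity_stat",
                        params = list(list(reference_name = "nadh_like",
                                           metric = "sam_angle",
                                           statistic = "mean")))
  f <- suppressMessages(extract_features(st, seg, reg, refs = refs))
  expect_equal(f$sam_to_nadh, 0, tolerance = 1e-8)
  expect_error(suppressMessages(extract_features(st, seg, reg)),
               "reference")
})

test_that("every taxonomy family is covered by the default registry", {
  reg <- feature_registry("default18")
  core <- c("mean_intensity", "band_ratio", "pca_stat",
            "channel_correlation", "spectral_variation", "texture",
            "morphology")
  expect_true(all(core %in% reg$family))
  # similarity_stat is available through the registry schema
  expect_silent(validate_registry(
    tibble::tibble(name = "s", family = "similarity_stat",
                   params = list(list(reference_name = "nadh_like")))))
  expect_error(validate_registry(
    tibble::tibble(name = "x", family = "nonsense", params = list(list()))),
    "unknown")
})

test_that("registry YAML round-trips", {
  reg <- feature_registry("default18")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_feature_registry(reg, path)
  back <- read_feature_registry(path)
  expect_equal(back$name, reg$name)
  expect_equal(back$family, reg$family)
  expect_equal(back$params[[3]]$num_channel, reg$params[[3]]$num_channel)
})

test_that("global intensity rescaling leaves shape features unchanged", {
  r <- render_scene(synth_scene(seed = 12, image_size = c(128, 128),
                                n_cells = 4))
  st <- r$stack
  st2 <- hyper_stack(st$data * 3.7, st$channels)
  seg <- segment_cells(st)       # same segmentation for both
  reg <- feature_registry("default18", channels = st$channels)
  reg <- reg[reg$family %in% c("mean_intensity", "band_ratio",
                               "channel_correlation",
                               "spectral_variation", "morphology"), ]
  f1 <- suppressMessages(extract_features(st, seg, reg))
  f2 <- suppressMessages(extract_features(st2, seg, reg))
  for (nm in names(f1)[-1]) {
    if (startsWith(nm, "mean_"))
      expect_equal(f2[[nm]], 3.7 * f1[[nm]], tolerance = 1e-9)
    else
      expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6)
  }
})

test_that("empty segmentations give an empty but valid feature table", {
  st <- hyper_stack(array(0, dim = c(32, 32, 3)), channel_table(3))
  seg <- segment_cells(st)
  f <- suppressMessages(
    extract_features(st, seg, feature_registry("minimal",
                                               channels = st$channels)))
  expect_equal(nrow(f), 0)
  expect_true("cell_id" %in% names(f))
})
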