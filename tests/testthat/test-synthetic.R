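test_that("default grid covers both analysed regions with 838 points", {
  g <- default_grid()
  expect_length(g, 838)
  expect_true(all(diff(g) < 0))                 # strictly descending
  expect_equal(max(g), 2973)
  expect_equal(min(g), 1050)
  # no points in the gap between the regions
  expect_equal(sum(g < 2700 & g > 1583), 0)
  expect_equal(count_in_region(g, c(1583, 1050)) +
                 count_in_region(g, c(2973, 2700)), 838)
  # per-segment spacing within 1e-3 of the nominal 806/836 cm^-1
  lower <- g[g <= 1583]
  upper <- g[g >= 2700]
  expect_equal(-diff(lower)[1], 806 / 836, tolerance = 1e-3)
  expect_equal(-diff(upper)[1], 806 / 836, tolerance = 1e-3)
  expect_lt(max(abs(diff(diff(lower)))), 1e-9)  # uniform within segment
})

test_that("make_grid honours explicit spacing", {
  g <- make_grid(list(c(1500, 1050)), 2.0)
  expect_length(g, 226)                          # (1500-1050)/2 + 1
  expect_equal(g[1] - g[2], 2.0)
})

test_that("clinical generator recovers the reference means under truncation", {
  cfg <- generator_config(n_mets = 1000, n_nomets = 1000, seed = 11)
  tab <- generate_clinical(cfg)
  mets <- tab[tab$label == "MetS", ]
  nomets <- tab[tab$label == "noMetS", ]
  expect_equal(mean(mets$TGL), 242, tolerance = 10 / 242)
  expect_equal(mean(nomets$TGL), 109, tolerance = 10 / 109)
  expect_equal(mean(mets$GLU), 114, tolerance = 8 / 114)
  expect_equal(mean(nomets$HDL), 55, tolerance = 8 / 55)
  # truncation bounds respected for every parameter and class
  rng <- default_clinical_ranges()
  for (cl in c("MetS", "noMetS")) {
    sub <- tab[tab$label == cl, ]
    for (p in c("TGL", "HDL", "SP", "DP", "GLU")) {
      r <- rng[rng$class == cl & rng$param == p, ]
      expect_true(all(sub[[p]] >= r$min & sub[[p]] <= r$max),
                  label = paste(cl, p, "within [min, max]"))
    }
  }
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_mets = 8, n_nomets = 12, seed = 99)
  d1 <- make_dataset(cfg)
  d2 <- make_dataset(cfg)
  expect_identical(d1$clinical, d2$clinical)
  expect_identical(d1$spectra$absorbance, d2$spectra$absorbance)
  d3 <- make_dataset(generator_config(n_mets = 8, n_nomets = 12, seed = 100))
  expect_false(identical(d1$spectra$absorbance, d3$spectra$absorbance))
})

test_that("a noiseless single band is an exact Gaussian profile", {
  bl <- data.frame(center = 1300, width = 10, base = 0.4, link = "none",
                   sign = 1, strength = 0, informative = FALSE)
  cfg <- generator_config(n_mets = 1, n_nomets = 0, seed = 5,
                          band_library = bl, noise_sd = 0,
                          baseline_offset_sd = 0, baseline_slope_sd = 0,
                          scatter_sd = 0, n_replicates = 1)
  ds <- make_dataset(cfg)
  g <- cfg$grid
  profile <- 0.4 * exp(-(g - 1300)^2 / (2 * 10^2))
  expect_equal(unname(ds$spectra$absorbance[1, ]), profile,
               tolerance = 1e-12)
  # amplitude recoverable by least squares to machine precision
  basis <- exp(-(g - 1300)^2 / (2 * 10^2))
  amp <- sum(basis * ds$spectra$absorbance[1, ]) / sum(basis^2)
  expect_equal(amp, 0.4, tolerance = 1e-12)
})

test_that("TGL-linked band absorbance is higher in the MetS group", {
  cfg <- generator_config(n_mets = 100, n_nomets = 100, seed = 21,
                          n_replicates = 1)
  ds <- make_dataset(cfg)
  j <- which.min(abs(ds$spectra$wavenumbers - 2948.94))
  a <- ds$spectra$absorbance[ds$clinical$label == "MetS", j]
  b <- ds$spectra$absorbance[ds$clinical$label == "noMetS", j]
  tt <- t.test(a, b, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("band centers outside the grid are skipped with a warning", {
  bl <- rbind(default_band_library(),
              data.frame(center = 3500, width = 5, base = 0.1, link = "none",
                         sign = 1, strength = 0, informative = FALSE))
  cfg <- generator_config(n_mets = 2, n_nomets = 2, seed = 3,
                          band_library = bl, n_replicates = 1)
  expect_warning(make_dataset(cfg), "3500")
})

test_that("dataset assembly matches the study design", {
  ds <- make_dataset(seed = 1)
  expect_equal(nrow(ds$clinical), 105)          # 19 + 86
  expect_equal(sum(ds$clinical$label == "MetS"), 19)
  expect_equal(sum(ds$clinical$label == "noMetS"), 86)
  expect_equal(nrow(ds$spectra$absorbance), 315)  # triplicates
  expect_equal(length(unique(ds$spectra$replicate_of)), 105)
  # informative flags are exactly the grid points nearest each linked center
  expect_equal(sum(ds$truth$informative), 10)
  flagged <- ds$config$grid[ds$truth$informative]
  expect_true(all(vapply(ds$truth$centers, function(cc)
    min(abs(flagged - cc)), numeric(1)) <= 806 / 836 / 2 + 1e-9))
  expect_identical(unname(ds$truth$class), ds$clinical$label)
})

test_that("a single-class dataset carries only neutral-band truth", {
  cfg <- generator_config(n_mets = 0, n_nomets = 12, seed = 2,
                          n_replicates = 1)
  ds <- make_dataset(cfg)
  expect_equal(unique(ds$clinical$label), "noMetS")
  expect_equal(nrow(ds$clinical), 12)
})

test_that("stronger links raise the Fisher weight of the linked wavenumber", {
  weight_at <- function(effect) {
    cfg <- generator_config(n_mets = 150, n_nomets = 150, seed = 31,
                            effect_size = effect, n_replicates = 1,
                            scatter_sd = 0, baseline_offset_sd = 0,
                            baseline_slope_sd = 0)
    ds <- make_dataset(cfg)
    j <- which.min(abs(ds$spectra$wavenumbers - 1133.09))
    fisher_weight(ds$spectra$absorbance[, j], ds$clinical$label)
  }
  w <- vapply(c(0, 2, 4, 8), weight_at, numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("a null generator yields chance-level downstream classification", {
  bl <- default_band_library()
  bl$strength <- 0                      # all clinical->band links removed
  cfg <- generator_config(n_mets = 25, n_nomets = 55, seed = 17,
                          band_library = bl, effect_size = 0,
                          n_replicates = 1)
  ds <- make_dataset(cfg)
  spec <- apply_plan(ds$spectra, preprocess_plan(
    steps = c("savgol", "snv", "restrict")))
  X <- mean_center(spec$absorbance)$X
  lab <- ds$clinical$label
  # selection nested inside the CV loop so the held-out sample never
  # influences which wavenumbers are picked
  pred <- vapply(seq_len(nrow(X)), function(i) {
    sel <- run_select(X[-i, ], lab[-i], k_max = 5)
    fit <- suppressWarnings(fit_lda(X[-i, sel$selected, drop = FALSE],
                                    lab[-i]))
    predict(fit, X[i, sel$selected])
  }, character(1))
  acc <- mean(pred == lab)
  # majority rate 55/80 = 0.6875; binomial 99.9% envelope around chance
  expect_lt(acc, 55 / 80 + 3.3 * sqrt(0.6875 * 0.3125 / 80))
})
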