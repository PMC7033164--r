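# Synthetic factorial generator: grid construction, response surfaces,
# replicate noise, dataset round trips.

test_that("factorial grid is the full Cartesian product in nested order", {
  cfg <- generator_config()
  grid <- build_factorial_grid(cfg)
  expect_equal(nrow(grid), 6 * 4 * 13)           # 312 combinations
  expect_equal(nrow(dplyr::distinct(grid)), 312)
  # tem outermost, co2 middle, par innermost
  expect_equal(grid$par[1:13], cfg$par_levels)
  expect_equal(grid$tem, rep(cfg$temp_levels, each = 4 * 13))
  expect_equal(grid$co2[1:(4 * 13)], rep(cfg$co2_levels, each = 13))

  tiny <- generator_config(temp_levels = 20, co2_levels = 400, par_levels = 100)
  expect_equal(nrow(build_factorial_grid(tiny)), 1)
  custom <- generator_config(temp_levels = c(18, 24),
                             co2_levels = c(300, 600, 900),
                             par_levels = c(100, 200, 300, 400))
  expect_equal(nrow(build_factorial_grid(custom)), 24)
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(temp_levels = numeric(0)),
               class = "psobp_config_error")
  expect_error(generator_config(par_levels = c(100, 100, 200)),
               class = "psobp_config_error")
  expect_error(generator_config(replicates = 0), class = "psobp_config_error")
  expect_error(generator_config(noise_cv = -0.1), class = "psobp_config_error")
})

test_that("Pn surface has the expected dark, saturation and peak behaviour", {
  p <- pn_surface_params()
  expect_equal(pn_surface(18, 600, 0, p), -p$r_d)   # darkness: respiration only
  # CO2 saturation: the Michaelis-Menten factor approaches 1
  no_co2_limit <- p$alpha * 500 * (1 - p$beta * 500) / (1 + p$gamma * 500) *
    exp(-((18 - p$t_opt) / p$t_sigma)^2) - p$r_d
  expect_equal(pn_surface(18, 1e9, 500, p), no_co2_limit, tolerance = 1e-6)
  expect_error(pn_surface(18, 600, -5, p), class = "psobp_domain_error")
})

test_that("light saturation point at 18 degC / 600 umol mol-1 is near 990", {
  # independent oracle: dense 1-unit grid search over the light axis
  par_grid <- 0:1500
  pn <- pn_surface(18, 600, par_grid, pn_surface_params())
  argmax <- par_grid[which.max(pn)]
  expect_gte(argmax, 900)
  expect_lte(argmax, 1100)
})

test_that("noise-free Pn rises on [0,300] and does not rise on [1100,1500]", {
  p <- pn_surface_params()
  low <- pn_surface(18, 600, 0:300, p)
  expect_true(all(diff(low) > 0))
  high <- pn_surface(18, 600, 1100:1500, p)
  expect_true(all(diff(high) <= 0))
})

test_that("fluorescence surfaces satisfy their construction identities", {
  f <- fluor_surface_params()
  grid <- build_factorial_grid(generator_config())
  fl <- fluorescence_surface(grid$tem, grid$co2, grid$par, f)
  # ETR identity: absorptance x PSII fraction = 0.42 for the defaults
  expect_equal(fl$etr / (fl$phips2 * grid$par), rep(0.42, nrow(grid)),
               tolerance = 1e-12)
  expect_true(all(fl$qp > 0 & fl$qp <= 1))
  expect_true(all(fl$phips2 <= fl$fvpfmp & fl$fvpfmp <= 1))
  expect_true(all(fl$npq >= 0))
  # NPQ declines beyond the photodamage threshold
  npq_at <- function(par) fluorescence_surface(18, 600, par, f)$npq
  expect_lt(npq_at(1500), npq_at(f$i_damage))
  # vanishing light: no electron transport, no quenching
  near0 <- fluorescence_surface(18, 600, 1e-6, f)
  expect_lt(near0$etr, 1e-6)
  expect_lt(near0$npq, 1e-6)
  expect_error(fluorescence_surface(18, 600, 0, f),
               class = "psobp_domain_error")
})

test_that("generated datasets have the right size and reproducibility", {
  d <- generate_dataset(generator_config(seed = 42))
  expect_equal(nrow(d), 936)
  expect_true(all(d$valid_fluor))

  d2 <- generate_dataset(generator_config(seed = 42))
  expect_identical(as.data.frame(d), as.data.frame(d2))
  d3 <- generate_dataset(generator_config(seed = 43))
  expect_false(identical(d$pn, d3$pn))
})

test_that("record count equals grid size x replicates for custom designs", {
  for (reps in c(1, 4)) {
    cfg <- generator_config(temp_levels = c(18, 24), co2_levels = c(300, 600),
                            par_levels = c(100, 500, 1000), replicates = reps)
    expect_equal(nrow(generate_dataset(cfg)), 2 * 2 * 3 * reps)
  }
})

test_that("zero noise gives identical replicates; par = 0 marks fluorescence invalid", {
  cfg <- generator_config(par_levels = c(0, 100, 1000), replicates = 3,
                          noise_cv = 0, seed = 5)
  d <- generate_dataset(cfg)
  grp <- dplyr::summarise(
    dplyr::group_by(d, tem, co2, par),
    spread = max(pn) - min(pn), .groups = "drop")
  expect_true(all(grp$spread == 0))
  dark <- d[d$par == 0, ]
  expect_true(all(!dark$valid_fluor))
  expect_true(all(is.na(dark$etr)))
  expect_true(all(d$valid_fluor[d$par > 0]))
})

test_that("physical invariants hold after noise and clipping across seeds", {
  for (s in 1:4) {
    d <- generate_dataset(generator_config(seed = s, noise_cv = 0.1))
    lit <- d[d$valid_fluor, ]
    expect_true(all(lit$qp >= 0 & lit$qp <= 1))
    expect_true(all(lit$phips2 >= 0 & lit$phips2 <= lit$fvpfmp))
    expect_true(all(lit$fvpfmp <= 1))
    expect_true(all(lit$etr >= 0))
    expect_true(all(lit$npq >= 0))
    expect_true(all(lit$qn >= 0 & lit$qn <= 1))
  }
})

test_that("datasets round-trip through the annotated CSV format", {
  d <- generate_dataset(generator_config(
    temp_levels = c(18, 24), co2_levels = 600, par_levels = c(100, 900),
    replicates = 1, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- read_dataset(path)
  for (col in setdiff(names(d), "valid_fluor")) {
    expect_equal(d2[[col]], d[[col]], tolerance = 1e-13, label = col)
  }
  expect_identical(d2$valid_fluor, d$valid_fluor)
  # metadata (seed, config) survives the round trip
  meta <- attr(d2, "meta")
  expect_equal(meta$seed, 9)
  expect_equal(meta$config$par_levels, c(100, 900))

  d3 <- generate_dataset(generator_config(seed = 1))
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d3, path3)
  body <- readr::read_lines(path3)
  expect_equal(sum(!startsWith(body, "#")) - 1, 936)  # header + 936 data rows
})

test_that("malformed dataset files raise schema errors naming the problem", {
  d <- generate_dataset(generator_config(
    temp_levels = 18, co2_levels = 600, par_levels = c(100, 900),
    replicates = 1, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)

  lines <- readr::read_lines(path)
  hdr_i <- which(!startsWith(lines, "#"))[1]
  # drop the npq column
  drop_col <- function(ln) {
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    paste(parts[-10], collapse = ",")
  }
  mut <- lines
  mut[hdr_i:length(mut)] <- vapply(mut[hdr_i:length(mut)], drop_col, "")
  path_bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_lines(mut, path_bad)
  expect_error(read_dataset(path_bad), "npq", class = "psobp_schema_error")

  # corrupt a numeric cell
  mut2 <- lines
  parts <- strsplit(mut2[hdr_i + 1], ",", fixed = TRUE)[[1]]
  parts[5] <- "oops"
  mut2[hdr_i + 1] <- paste(parts, collapse = ",")
  path_bad2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_lines(mut2, path_bad2)
  expect_error(read_dataset(path_bad2), "pn", class = "psobp_schema_error")
})
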