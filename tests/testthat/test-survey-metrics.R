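test_that("count calibration multiplies by species-method factors", {
  cal <- data.frame(species_code = c("PARROT", "CHUB"),
                    method = c("belt", "belt"),
                    factor = c(1, 2))
  tab <- tiny_allometric(cal)
  obs <- data.frame(species_code = c("PARROT", "CHUB", "TANG"),
                    count = c(5, 3, 4), method = "belt",
                    total_length_cm = 20)
  expect_warning(out <- calibrate_counts(obs, tab), "TANG")
  expect_equal(out$count, c(5, 6, 4))  # factor 1, factor 2, missing pair -> 1

  cal_bad <- data.frame(species_code = "PARROT", method = "belt", factor = -1)
  expect_error(allometric_table(tiny_species(), cal_bad), "negative")
})

test_that("biomass density follows the allometric power law", {
  tab <- allometric_table(data.frame(
    species_code = c("UNIT", "PARROT"), a = c(1, 0.0135), b = c(1, 3.05),
    functional_group = c("other", "scraper"), herbivore = c(FALSE, TRUE)))
  obs1 <- data.frame(species_code = "UNIT", count = 1, total_length_cm = 10)
  expect_equal(compute_biomass(obs1, tab, 1), 10)
  expect_equal(compute_biomass(transform(obs1, count = 0), tab, 1), 0)

  # oracle: direct high-precision evaluation of count * a * TL^b / area
  obs2 <- data.frame(species_code = "PARROT", count = 2, total_length_cm = 20)
  oracle <- 2 * 0.0135 * exp(3.05 * log(20)) / 125
  expect_equal(compute_biomass(obs2, tab, 125), oracle, tolerance = 1e-12)

  expect_error(compute_biomass(
    data.frame(species_code = "NOPE", count = 1, total_length_cm = 5), tab, 1),
    "missing parameter")
  expect_error(compute_biomass(obs1, tab, 0), "survey_area")
})

test_that("biomass is homogeneous of degree 1 in count and calibration factor", {
  tab <- tiny_allometric(data.frame(species_code = "PARROT", method = "belt",
                                    factor = 3))
  obs <- data.frame(species_code = "PARROT", count = c(2, 7),
                    total_length_cm = c(15, 33), method = "belt")
  b1 <- compute_biomass(obs, tab, 100)
  obs2 <- transform(obs, count = count * 5)
  expect_equal(compute_biomass(obs2, tab, 100), 5 * b1)
  expect_equal(compute_biomass(calibrate_counts(obs, tab), tab, 100), 3 * b1)
})

test_that("schooling truncation flags at 99.9% and truncates to the 99% quantile", {
  # constant counts: nothing to do
  flat <- data.frame(species_code = rep("TANG", 50), count = 5)
  res <- truncate_schooling(flat)
  expect_equal(res$observations$count, flat$count)
  expect_equal(nrow(res$report), 0L)

  # one wild outlier among 1..999
  obs <- data.frame(species_code = c(rep("TANG", 999), "TANG"),
                    count = c(1:999, 1e6))
  res <- truncate_schooling(obs)
  q99 <- oracle_q7(obs$count, 0.99)
  expect_equal(nrow(res$report), sum(obs$count > q99))
  expect_equal(max(res$observations$count), q99)
  expect_true(all(res$observations$count <= obs$count))

  # flagged species that is not a herbivore: untouched when a table is given
  sp <- tiny_species()
  obs_j <- data.frame(species_code = c(rep("TANG", 900), rep("JACK", 99), "JACK"),
                      count = c(rep(3, 900), rep(5, 99), 1e5))
  res_j <- truncate_schooling(obs_j, species_table = sp)
  expect_identical(res_j$observations, obs_j)
  expect_equal(nrow(res_j$report), 0L)

  expect_error(truncate_schooling(flat[0, ]), "empty")
})

test_that("schooling truncation is idempotent on realistic tables", {
  set.seed(8)
  obs <- data.frame(
    species_code = sample(c("TANG", "CHUB", "PARROT"), 2000, TRUE),
    count = c(rpois(1990, 8) + 1, rep(5000, 10)))
  r1 <- truncate_schooling(obs)
  r2 <- truncate_schooling(r1$observations)
  expect_equal(r2$observations$count, r1$observations$count)
  expect_true(all(r1$observations$count <= obs$count))
})

test_that("domain filter keeps hard bottom, 0-30 m, 2004-2014 and is idempotent", {
  tr <- data.frame(
    hardbottom = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    depth_m = c(10, 35, 15, 10, 30, 0),
    year = c(2010, 2010, 2016, 2010, 2004, 2014),
    x = 1:6)
  out <- filter_domain(tr)
  expect_equal(out$x, c(1, 5, 6))  # 35 m, 2016, soft bottom all excluded
  expect_identical(filter_domain(out), out)
  expect_error(filter_domain(data.frame(depth_m = 1)), "schema error")
})

test_that("replicate aggregation averages transects within keys", {
  tr <- data.frame(source_dataset = "a", latitude = 20, longitude = -156,
                   depth_m = 10, year = 2010, biomass = c(10, 20))
  out <- aggregate_replicates(tr)
  expect_equal(nrow(out), 1L)
  expect_equal(out$biomass, 15)
  expect_equal(out$n_transects, 2L)

  # distinct keys preserved
  tr2 <- transform(tr, latitude = c(20, 21))
  expect_equal(nrow(aggregate_replicates(tr2)), 2L)
})

test_that("aggregation matches a brute-force group-and-average oracle", {
  set.seed(5)
  n <- 50
  tr <- data.frame(
    source_dataset = sample(c("a", "b"), n, TRUE),
    latitude = sample(c(20.1, 20.2, 20.3), n, TRUE),
    longitude = -156, depth_m = sample(c(5, 10), n, TRUE),
    year = sample(2008:2010, n, TRUE),
    biomass = rgamma(n, 2, 0.1), cover = runif(n, 0, 100))
  out <- aggregate_replicates(tr)
  key <- paste(tr$source_dataset, tr$latitude, tr$longitude, tr$depth_m, tr$year)
  for (k in unique(key)) {
    rows <- key == k
    i <- which(out$source_dataset == tr$source_dataset[rows][1] &
                 out$latitude == tr$latitude[rows][1] &
                 out$depth_m == tr$depth_m[rows][1] &
                 out$year == tr$year[rows][1])
    expect_equal(out$biomass[i], mean(tr$biomass[rows]))
    expect_equal(out$cover[i], mean(tr$cover[rows]))
  }
  # totaling then aggregating equals aggregating then totaling (mean linearity)
  tr$total <- tr$biomass + tr$cover
  out2 <- aggregate_replicates(tr)
  expect_equal(out2$total, out2$biomass + out2$cover)
})

test_that("site subsampling keeps only the chosen year at the site", {
  reps <- data.frame(site = c("kahekili", "kahekili", "other"),
                     year = c(2012, 2014, 2012), x = 1:3)
  out <- subsample_site(reps, "kahekili", 2014)
  expect_equal(out$x, c(2, 3))
  # no replicates at the site: identity
  expect_identical(subsample_site(reps, "elsewhere", 2014), reps)
  # keep_year absent at site: site removed entirely, with a warning
  expect_warning(out2 <- subsample_site(reps, "kahekili", 2013), "removed")
  expect_equal(out2$x, 3)
  # radius rule
  reps2 <- data.frame(longitude = c(-156.68, -156.68, -155.0),
                      latitude = c(20.94, 20.94, 19.5),
                      year = c(2012, 2014, 2012), x = 1:3)
  out3 <- subsample_site(reps2, "kahekili", 2014,
                         center = c(-156.68, 20.94), radius_km = 2.5)
  expect_equal(out3$x, c(2, 3))
})

test_that("sparse moku are dropped at the five-replicate rule", {
  reps <- data.frame(moku_id = rep(c("a", "b"), c(4, 5)))
  out <- drop_sparse_moku(reps)
  expect_equal(unique(out$moku_id), "b")   # 4 removed, exactly 5 retained
  expect_equal(nrow(out), 5L)
  expect_identical(drop_sparse_moku(reps, min_n = 1), reps)
  expect_warning(out2 <- drop_sparse_moku(reps, min_n = 10), "all moku")
  expect_equal(nrow(out2), 0L)
})

test_that("functional groups map parrotfish/chub/surgeonfish correctly", {
  tab <- tiny_allometric()
  expect_equal(assign_functional_groups(c("PARROT", "CHUB", "TANG", "JACK"), tab),
               c("scraper", "browser", "grazer", "other"))
  expect_error(assign_functional_groups("GHOST", tab), "missing parameter")
})

test_that("benthic condition log-ratio behaves per its contract", {
  expect_equal(benthic_condition(20, 10, 30), 0)          # delta cancels
  expect_equal(benthic_condition(0, 0, 0), 0)             # delta / delta
  expect_equal(benthic_condition(40, 10, 5, delta = 0.1), # scalar oracle
               log(50.1 / 5.1), tolerance = 1e-12)
  # antisymmetric under swapping calcified and macroalgal cover
  expect_equal(benthic_condition(30, 10, 15), -benthic_condition(15, 0, 40))
  expect_error(benthic_condition(101, 0, 10), "invalid argument")
  expect_error(benthic_condition(10, 0, -1), "invalid argument")
})
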