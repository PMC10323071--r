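test_that("lattice adjacency is symmetric, self-edge free and connected", {
  city <- tiny_city()
  adj <- city$adjacency
  expect_true(all(adj$area_i != adj$area_j))
  # rook lattice 4x4 has 2*4*3 = 24 undirected edges
  expect_identical(nrow(adj), 24L)
  # connectivity by flood fill
  nb <- split(c(adj$area_j, adj$area_i), c(adj$area_i, adj$area_j))
  seen <- city$areas[1]
  repeat {
    grow <- setdiff(unique(unlist(nb[seen])), seen)
    if (!length(grow)) break
    seen <- c(seen, grow)
  }
  expect_setequal(seen, city$areas)
})

test_that("regenerating with the same seed is identical, different seed is not", {
  a <- tiny_city(seed = 3)
  b <- tiny_city(seed = 3)
  expect_identical(a, b)
  c <- tiny_city(seed = 4)
  expect_false(identical(a$deaths$deaths, c$deaths$deaths))
})

test_that("death counts are nonnegative integers and conserved across strata", {
  city <- tiny_city()
  expect_true(all(city$deaths$deaths >= 0))
  expect_identical(city$deaths$deaths, as.integer(city$deaths$deaths))
  by_sex <- tapply(city$deaths$deaths, city$deaths$sex, sum)
  expect_identical(sum(city$deaths$deaths), sum(by_sex))
  # every (area, age, sex) stratum appears exactly once
  expect_false(anyDuplicated(city$deaths[c("area", "age", "sex")]) > 0)
})

test_that("ses_effect = 0 with no offset noise gives identical true LE everywhere", {
  city <- tiny_city(seed = 5, ses_effect = 0, offset_noise_sd = 0)
  for (s in c("F", "M")) {
    expect_equal(max(city$true_le[[s]][, "e0"]) -
                   min(city$true_le[[s]][, "e0"]), 0)
    lt <- make_life_table(exp(city$schedules[[s]]$log_rate))
    expect_equal(unname(city$true_le[[s]][1, "e0"]), lt$ex[1])
  }
})

test_that("higher latent SES means higher true life expectancy at birth", {
  city <- simulate_city(n_areas = 64, n_units = 8, seed = 2,
                        ses_effect = 0.15)
  for (s in c("F", "M")) {
    rho <- cor(city$latent_ses, city$true_le[[s]][, "e0"],
               method = "spearman")
    expect_gt(rho, 0.5)
  }
})

test_that("observed SES variables are oriented and calibrated plausibly", {
  city <- simulate_city(n_areas = 100, n_units = 10, seed = 7)
  ses <- city$ses
  # disadvantage-oriented variables correlate negatively with latent SES
  expect_lt(cor(city$latent_ses, ses$unemployment), -0.5)
  expect_lt(cor(city$latent_ses, ses$overcrowding), -0.5)
  expect_gt(cor(city$latent_ses, ses$high_school), 0.5)
  expect_true(all(ses$unemployment > 2.5 & ses$unemployment < 6.5))
  expect_true(all(ses$overcrowding >= 0 & ses$overcrowding < 3.5))
  expect_true(all(ses$high_school > 45 & ses$high_school < 95))
})

test_that("pooled death rates match the standard schedule when offsets vanish", {
  city <- simulate_city(n_areas = 36, n_units = 6, seed = 9,
                        ses_effect = 0, offset_noise_sd = 0,
                        mean_pop = 30000)
  for (s in c("F", "M")) {
    d <- city$deaths[city$deaths$sex == s, ]
    e <- city$exposure_true[city$exposure_true$sex == s, ]
    O <- tapply(d$deaths, d$age, sum)
    E <- tapply(e$count * exp(city$schedules[[s]]$log_rate[e$age + 1L]),
                e$age, sum)
    keep <- E >= 5
    chi2 <- sum((O[keep] - E[keep])^2 / E[keep])
    # chi-square goodness of fit, generous alpha for a fixed seed
    expect_lt(chi2, qchisq(0.999, df = sum(keep)))
  }
})

test_that("incompatible lattice dimensions and bad sizes are rejected", {
  expect_error(simulate_city(n_areas = 12, n_units = 3, dims = c(5, 5)),
               "incompatible")
  expect_error(simulate_city(n_areas = 3), ">= 4")
  expect_error(simulate_city(n_areas = 9, n_units = 20), "exceed")
})

test_that("grouping into bands conserves totals and matches accumulation", {
  pop <- expand.grid(unit = "U1", age = 0:9, sex = "F",
                     stringsAsFactors = FALSE)
  pop$count <- 1
  g <- group_population(pop, width = 5)
  expect_equal(g$count, c(5, 5))
  expect_equal(g$band_lower, c(0L, 5L))
  expect_equal(sum(g$count), sum(pop$count))

  set.seed(42)
  pop2 <- expand.grid(unit = c("U1", "U2"), age = 0:103, sex = c("F", "M"),
                      stringsAsFactors = FALSE)
  pop2$count <- rpois(nrow(pop2), 50)
  g2 <- group_population(pop2, width = 5)
  expect_equal(sum(g2$count), sum(pop2$count))
  # brute-force accumulation oracle for one stratum
  for (u in c("U1", "U2")) for (s in c("F", "M")) {
    d <- pop2[pop2$unit == u & pop2$sex == s, ]
    manual <- vapply(seq(0, 100, by = 5), function(lo) {
      hi <- if (lo == 100) Inf else lo + 4
      sum(d$count[d$age >= lo & d$age <= hi])
    }, numeric(1))
    got <- g2[g2$unit == u & g2$sex == s, ]
    expect_equal(got$count[order(got$band_lower)], manual)
  }
  # open band label is open-ended
  expect_true("100+" %in% g2$age_band)
})
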