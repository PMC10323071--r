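test_that("decile scores step from 0 to 1 in ninths", {
  x <- 1:100
  s <- decile_score(x)
  expect_equal(sort(unique(s)), (0:9) / 9)
  expect_equal(as.vector(table(s)), rep(10L, 10))
  expect_true(all(diff(s[order(x)]) >= 0))
  # first decile scores 0, second decile scores 1/9
  expect_equal(s[5], 0)
  expect_equal(s[15], 1 / 9)
  expect_error(decile_score(rep(1, 20)), "identical")
  expect_error(decile_score(1:5), "10 areas")
})

test_that("ties share the lower decile", {
  x <- c(rep(1, 15), 2:86)   # 100 values, mass of ties at the bottom
  s <- decile_score(x)
  expect_true(all(s[1:15] == 0))
})

test_that("composite z standardizes, reverses and averages", {
  set.seed(2)
  ses <- data.frame(area = sprintf("A%02d", 1:20),
                    water_access = runif(20, 90, 100),
                    overcrowding = runif(20, 0, 3),
                    school_attendance = runif(20, 85, 99),
                    high_school = runif(20, 50, 90),
                    unemployment = runif(20, 3, 6))
  z <- composite_z(ses)
  # brute-force oracle
  zc <- function(v) (v - mean(v)) / sd(v)
  want <- (zc(ses$water_access) - zc(ses$overcrowding) +
             zc(ses$school_attendance) + zc(ses$high_school) -
             zc(ses$unemployment)) / 5
  expect_equal(z, want)
  expect_equal(mean(z), 0, tolerance = 1e-12)

  # two areas give symmetric scores
  z2 <- composite_z(ses[1:2, ])
  expect_equal(z2[1], -z2[2])

  # perfectly aligned rankings give perfect rank correlation
  ses3 <- data.frame(area = 1:12, water_access = 1:12,
                     overcrowding = 12:1, school_attendance = 1:12,
                     high_school = 1:12, unemployment = 12:1)
  z3 <- composite_z(ses3)
  expect_equal(cor(z3, 1:12, method = "spearman"), 1)

  ses$unemployment <- 4
  expect_error(composite_z(ses), "unemployment")
})

test_that("gap statistics reproduce differences, shifts and scalings", {
  le <- c(80, 81, 79, 82, 80.5)
  g <- gap_stats(le)
  q <- quantile(le, c(0.1, 0.9), type = 7, names = FALSE)
  expect_equal(unname(g["p90_p10"]), q[2] - q[1])
  expect_equal(unname(g["range"]), 3)
  expect_equal(gap_stats(le + 5), g)                      # translation invariant
  expect_equal(unname(gap_stats(3 * le)), unname(3 * g)) # linear in scale
  expect_equal(unname(gap_stats(rep(80, 4))), c(0, 0))
})

test_that("per-draw SII matches exact lines and the lm oracle", {
  score <- decile_score(1:50)
  le <- 70 + 5 * score
  fit <- sii_per_draw(le, score)
  expect_equal(unname(fit["coef"]), 5)
  expect_equal(unname(fit["se"]), 0)

  set.seed(3)
  le2 <- 70 + 3 * score + rnorm(50, sd = 0.8)
  fit2 <- sii_per_draw(le2, score)
  ref <- summary(lm(le2 ~ score))$coefficients["score", ]
  expect_equal(unname(fit2["coef"]), unname(ref["Estimate"]))
  expect_equal(unname(fit2["se"]), unname(ref["Std. Error"]))
  expect_error(sii_per_draw(le2, rep(0.5, 50)), "constant")
})

test_that("randomly permuted scores give slope zero on average", {
  set.seed(6)
  score <- decile_score(1:40)
  le <- rnorm(40, 75, 2)
  slopes <- replicate(1000, sii_per_draw(le, sample(score))["coef"])
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(1000))
})

test_that("Rubin pooling matches hand arithmetic and ignores draw order", {
  p <- rubin_pool(c(2.5, 2.5, 2.5), c(0.4, 0.4, 0.4))
  expect_equal(p$coef, 2.5)
  expect_equal(p$between_var, 0)
  expect_equal(p$total_var, 0.16)

  p2 <- rubin_pool(c(1, 3), c(0, 0))
  expect_equal(p2$coef, 2)
  expect_equal(p2$between_var, 2)      # sample variance of {1,3}
  expect_equal(p2$total_var, 3)        # (1 + 1/2) * 2
  expect_equal(p2$ci_low, 2 - qnorm(0.975) * sqrt(3))

  set.seed(8)
  cf <- rnorm(50); se <- runif(50, 0.1, 0.3)
  o <- sample(50)
  expect_equal(rubin_pool(cf, se), rubin_pool(cf[o], se[o]))
  expect_error(rubin_pool(1, 0.1), "at least 2")

  # Barnard-Rubin interval is wider than the normal one for small m
  pn <- rubin_pool(c(1, 2, 3), c(0.2, 0.2, 0.2))
  pt <- rubin_pool(c(1, 2, 3), c(0.2, 0.2, 0.2), df_adjust = TRUE)
  expect_gt(pt$ci_high - pt$ci_low, pn$ci_high - pn$ci_low)
})

test_that("pooled SII recovers the orientation of every SES variable", {
  set.seed(15)
  n <- 60
  z <- sort(rnorm(n))
  ses <- cbind(data.frame(area = sprintf("A%03d", 1:n)),
               saele:::ses_from_latent(z, noise_sd = 0.15))
  # LE draws: truth rises in z, draw noise on top
  truth <- 76 + 2.5 * z
  draws <- do.call(rbind, lapply(1:40, function(d)
    data.frame(draw = d, area = ses$area, sex = "M", age = 0L,
               le = truth + rnorm(n, sd = 0.4))))
  out <- sii_analysis(draws, ses)
  pos <- c("water_access", "school_attendance", "high_school", "composite_z")
  neg <- c("overcrowding", "unemployment")
  expect_true(all(out$coef[out$variable %in% pos] > 0))
  expect_true(all(out$coef[out$variable %in% neg] < 0))
  expect_true(all(out$ci_low <= out$coef & out$coef <= out$ci_high))
})
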