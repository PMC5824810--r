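obs <- function(cond, counts) {
  # counts: named vector over morphology levels
  data.frame(condition = cond,
             morphology = rep(names(counts), counts))
}

test_that("morphology fractions reproduce the printed count arithmetic", {
  tab <- morphology_fractions(obs("Q3_1nM", c(outward_tubules = 22, spherical = 99)))
  row <- tab[tab$morphology == "outward_tubules", ]
  expect_equal(row$fraction, 22 / 121)
  expect_equal(round(100 * row$fraction), 18)

  tab2 <- morphology_fractions(obs("Q3_0.5nM", c(outward_tubules = 154, spherical = 31)))
  f2 <- tab2$fraction[tab2$morphology == "outward_tubules"]
  expect_equal(round(100 * f2, 1), 83.2)
  expect_gt(f2, 0.8)

  # the H3 tallies: 100 spherical, 20 burst, 14 flaccid of 134
  tab3 <- morphology_fractions(obs("H3", c(spherical = 100, burst = 20, flaccid = 14)))
  expect_equal(round(100 * tab3$fraction[tab3$morphology == "spherical"]), 75)
  expect_equal(round(100 * tab3$fraction[tab3$morphology == "burst"]), 15)
  expect_equal(tab3$n[1], 134)                 # burst GUVs stay in n
})

test_that("fractions sum to one and Wilson CIs behave", {
  set.seed(7)
  levs <- morphology_levels()
  d <- data.frame(condition = sample(c("A", "B"), 200, TRUE),
                  morphology = sample(levs, 200, TRUE))
  tab <- morphology_fractions(d)
  sums <- tapply(tab$fraction, tab$condition, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  counts <- tapply(tab$count, tab$condition, sum)
  expect_equal(unname(counts), unname(table(d$condition))[order(names(table(d$condition)))],
               ignore_attr = TRUE)
  expect_true(all(tab$ci_lower <= tab$fraction + 1e-12))
  expect_true(all(tab$ci_upper >= tab$fraction - 1e-12))
  # zero count still has a positive upper bound
  z <- morphology_fractions(obs("C", c(spherical = 50)))
  zrow <- z[z$morphology == "outward_tubules", ]
  expect_equal(zrow$fraction, 0)
  expect_gt(zrow$ci_upper, 0)
  # CI width shrinks with n
  w_small <- diff(wilson_interval(10, 20))
  w_big <- diff(wilson_interval(100, 200))
  expect_lt(w_big, w_small)
  expect_error(morphology_fractions(data.frame(condition = "A", morphology = "weird")),
               "unknown morphology")
})

test_that("threshold density interpolates monotone response curves", {
  res <- threshold_density(c(30, 50, 90), c(0.1, 0.3, 0.85), 0.8)
  expect_true(res$reached)
  expect_equal(res$density_per_um2, 50 + 0.5 * 40 / 0.55, tolerance = 1e-9)
  # target 0 -> smallest density
  expect_equal(threshold_density(c(30, 50, 90), c(0.1, 0.3, 0.85), 0)$density_per_um2, 30)
  # never reached
  nr <- threshold_density(c(30, 50, 90), c(0.1, 0.3, 0.5), 0.8)
  expect_false(nr$reached)
  expect_true(is.na(nr$density_per_um2))
  expect_equal(nr$max_fraction, 0.5)
  # non-monotone input is isotonized first
  res2 <- threshold_density(c(10, 30, 50, 90), c(0.1, 0.35, 0.25, 0.85), 0.5)
  expect_true(res2$reached)
  expect_true(res2$density_per_um2 > 30 && res2$density_per_um2 < 90)
  # monotone in target fraction
  targets <- c(0.2, 0.4, 0.6, 0.8)
  ths <- vapply(targets, function(t)
    threshold_density(c(30, 50, 90), c(0.1, 0.3, 0.85), t)$density_per_um2,
    numeric(1))
  expect_true(all(diff(ths) >= 0))
})

test_that("tube diameter summary matches mean/sd with ddof = 1", {
  x <- c(200, 210, 250)
  s <- summarize_tube_diameters(x, 170)
  expect_equal(s$mean_nm, 220)
  expect_equal(s$sd_nm, sd(x))
  expect_equal(s$ratio, 220 / 170)
  same <- summarize_tube_diameters(c(100, 100, 100), 100)
  expect_equal(same$sd_nm, 0)
  expect_equal(same$ratio, 1)
  # sampling-distribution bound on synthetic cross-sections
  d <- gen_tube_sections(simulation_config(seed = 3))
  s2 <- summarize_tube_diameters(d, 170)
  expect_equal(s2$n, 35)
  expect_lt(abs(s2$mean_nm - 220), 3 * 70 / sqrt(35))
})
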