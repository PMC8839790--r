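# HMF statistics: assumptions, ANOVA, Tukey / Games-Howell, letters, stars.

test_that("assumption checks flag constructed heteroscedasticity", {
  set.seed(31)
  x <- rnorm(30)
  groups <- rep(c("a", "b", "c"), each = 10)
  a <- check_assumptions(x, groups)
  expect_true(all(a$normality_p > 0.001))
  expect_gt(a$levene_p, 0.05)
  # one near-constant group among dispersed ones breaks homogeneity
  x2 <- c(rnorm(10, sd = 3), rnorm(10, sd = 3), rnorm(10, sd = 0.01))
  expect_lt(check_assumptions(x2, groups)$levene_p, 0.05)
  # groups of n = 2 are rejected
  expect_error(check_assumptions(rnorm(4), c("a", "a", "b", "b")), "n < 3")
})

test_that("two-way ANOVA finds the generator's effects and a null generator none", {
  d <- generate_design()
  h <- generate_hmf(d, default_synth_params(1))
  for (ty in c("sunflower", "acacia")) {
    eff <- two_way_anova(h[h$honey_type == ty, ])
    expect_identical(eff$effect, c("temperature", "time", "interaction"))
    expect_true(all(eff$p < 0.05))
  }
  # dose-free generator: each effect non-significant in >= 90% of seeds
  pmat <- vapply(1:20, function(seed) {
    p0 <- default_synth_params(seed)
    p0$hmf_rate <- 0
    h0 <- generate_hmf(d, p0)
    two_way_anova(h0[h0$honey_type == "sunflower", ])$p
  }, numeric(3))
  expect_gte(mean(pmat > 0.05), 0.9)
  # a pure temperature main effect leaves no interaction signal
  set.seed(77)
  d_sun <- d[d$honey_type == "sunflower" & d$temperature_C != "CONTROL", ]
  h_pure <- data.frame(
    d_sun,
    hmf_mg_kg = as.numeric(d_sun$temperature_C) + rnorm(nrow(d_sun), 0, 0.1))
  eff_pure <- two_way_anova(h_pure)
  Ft <- eff_pure$F[eff_pure$effect == "temperature"]
  Fi <- eff_pure$F[eff_pure$effect == "interaction"]
  expect_gt(Ft / Fi, 1e3)
  expect_gt(eff_pure$p[eff_pure$effect == "interaction"], 0.05)
})

test_that("Games-Howell from summaries equals Games-Howell from matching raw data", {
  summ <- data.frame(group = c("g1", "g2", "g3"),
                     mean = c(10, 12.5, 30),
                     sd = c(1.2, 0.4, 5),
                     n = c(3, 3, 3))
  ph_sum <- posthoc(summ, homogeneous = FALSE)
  raw <- do.call(rbind, lapply(1:3, function(i)
    data.frame(g = summ$group[i],
               v = raw_matching_summary(summ$mean[i], summ$sd[i],
                                        summ$n[i]))))
  ph_raw <- posthoc(values = raw$v, groups = raw$g, homogeneous = FALSE)
  expect_equal(ph_sum$statistic, ph_raw$statistic, tolerance = 1e-9)
  expect_equal(ph_sum$p, ph_raw$p, tolerance = 1e-9)
  # identical cells compare with p = 1
  same <- data.frame(group = c("x", "y"), mean = 5, sd = 1, n = 3)
  expect_equal(posthoc(same, homogeneous = FALSE)$p, 1, tolerance = 1e-9)
  expect_error(posthoc(data.frame(group = "x", mean = 1, sd = 0, n = 3)),
               ">= 2 groups")
  expect_error(posthoc(data.frame(group = c("x", "y"), mean = 1, sd = 0,
                                  n = c(1, 3))), "n < 2")
})

test_that("Tukey converges to Games-Howell on equal-variance balanced fixtures", {
  summ <- data.frame(group = c("g1", "g2", "g3", "g4"),
                     mean = c(10, 11, 13, 16),
                     sd = rep(2, 4), n = rep(200, 4))
  pt <- posthoc(summ, homogeneous = TRUE)
  pg <- posthoc(summ, homogeneous = FALSE)
  expect_lt(max(abs(pt$p - pg$p)), 1e-3)
})

test_that("published HMF summaries reproduce the study's letter separations", {
  ref <- hmf_reference_summary()
  sun <- ref[ref$honey_type == "sunflower", ]
  # 40C column: no time interval differs (all letters 'a')
  col40 <- sun[sun$temperature_C == "40", ]
  ph40 <- posthoc(data.frame(group = paste0(col40$time_min, "min"),
                             mean = col40$mean, sd = col40$sd, n = col40$n),
                  homogeneous = FALSE)
  expect_false(any(ph40$significant))
  lt40 <- letter_display(ph40, paste0(c(60, 120, 180, 240), "min"))
  expect_true(all(lt40 == "a"))
  # 100C column: 60 min separates from 120/180/240 min
  col100 <- sun[sun$temperature_C == "100", ]
  ph100 <- posthoc(data.frame(group = paste0(col100$time_min, "min"),
                              mean = col100$mean, sd = col100$sd,
                              n = col100$n),
                   homogeneous = FALSE)
  sig60 <- ph100[ph100$group_a == "60min" | ph100$group_b == "60min", ]
  expect_true(all(sig60$significant))
  # 100C x 240 min vs 60 min matches the published a-vs-d separation
  pair <- ph100[(ph100$group_a == "60min" & ph100$group_b == "240min") |
                  (ph100$group_a == "240min" & ph100$group_b == "60min"), ]
  expect_true(pair$significant)
  # within-row capital letters: the 240 min row separates 80C and 100C from
  # the 40/60C pair
  row240 <- sun[sun$time_min == 240, ]
  ph_row <- posthoc(data.frame(group = paste0(row240$temperature_C, "C"),
                               mean = row240$mean, sd = row240$sd,
                               n = row240$n),
                    homogeneous = FALSE)
  lt <- letter_display(ph_row, c("40C", "60C", "80C", "100C"),
                       letters_pool = LETTERS)
  expect_equal(unname(lt[c("40C", "60C")]), c("A", "A"))
  expect_equal(unname(lt["80C"]), "B")
  expect_equal(unname(lt["100C"]), "C")
})

test_that("compact letter display handles all-distinct, none, and chains", {
  mk <- function(sig_pairs, groups = as.character(1:4)) {
    pr <- t(combn(groups, 2))
    data.frame(group_a = pr[, 1], group_b = pr[, 2],
               statistic = 1, df = 10,
               p = ifelse(paste(pr[, 1], pr[, 2]) %in% sig_pairs, 0.01, 0.5),
               significant = paste(pr[, 1], pr[, 2]) %in% sig_pairs)
  }
  all_pairs <- paste(t(combn(1:4, 2))[, 1], t(combn(1:4, 2))[, 2])
  expect_equal(unname(letter_display(mk(all_pairs), as.character(1:4))),
               c("a", "b", "c", "d"))
  expect_equal(unname(letter_display(mk(character(0)), as.character(1:4))),
               rep("a", 4))
  # chain where only the extremes differ -> {a, ab, ab, b}
  expect_equal(unname(letter_display(mk("1 4"), as.character(1:4))),
               c("a", "ab", "ab", "b"))
})

test_that("control stars follow the generator's kinetics", {
  d <- generate_design()
  h <- generate_hmf(d, default_synth_params(1))
  for (ty in c("sunflower", "acacia")) {
    st <- control_comparison(h[h$honey_type == ty, ])
    expect_equal(nrow(st), 16L)
    # all 100C cells star; 80C cells from 120 min star; 40C never stars
    expect_true(all(st$star[st$temperature_C == "100"]))
    expect_true(all(st$star[st$temperature_C == "80" & st$time_min >= 120]))
    expect_false(any(st$star[st$temperature_C == "40"]))
  }
  # a dose-free generator stars (almost) nothing
  clean <- 0L
  for (seed in 1:10) {
    p0 <- default_synth_params(seed)
    p0$hmf_rate <- 0
    h0 <- generate_hmf(d, p0)
    st0 <- control_comparison(h0[h0$honey_type == "sunflower", ])
    if (!any(st0$star)) clean <- clean + 1L
  }
  expect_gte(clean, 9L)
  # control vs itself never stars: a flat table stars nothing
  flat <- h[h$honey_type == "sunflower", ]
  flat$hmf_mg_kg <- 10
  st_flat <- control_comparison(flat)
  expect_false(any(st_flat$star))
})
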