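SIX_EXCLUDED <- c("CHSP", "TRES", "REVI", "LEFL", "CEDW", "ALFL")

test_that("fixture screening reproduces the exclusion arithmetic", {
  rec <- expand_fixture_records(seed = 1)
  scr <- screen_records(rec, min_n = 9, exclusion = SIX_EXCLUDED)
  expect_equal(scr$retained_records, 192)
  expect_length(scr$retained_species, 15)
  expect_setequal(names(scr$excluded_species), SIX_EXCLUDED)
})

test_that("screening filters age, exclusions and small samples in order", {
  rec <- toy_records(c("AA", "BB", "CC"), c(9, 8, 10),
                     d2hf = rnorm(27, -140, 5))
  scr <- screen_records(rec, min_n = 9)
  expect_equal(scr$retained_records, 19)       # middle species dropped
  expect_setequal(scr$retained_species, c("AA", "CC"))
  expect_match(scr$excluded_species$BB, "min_n")

  # identity filter
  all_in <- screen_records(rec, min_n = 1)
  expect_equal(all_in$retained_records, nrow(rec))

  # age filter precedes the count rule
  rec2 <- rec
  rec2$age[rec2$species == "CC"][1:2] <- "SY"
  scr2 <- screen_records(rec2, min_n = 9)
  expect_equal(scr2$dropped_age, 2)
  expect_setequal(scr2$retained_species, "AA")

  # idempotence: screening its own output changes nothing
  twice <- screen_records(scr$records, min_n = 9)
  expect_equal(twice$records, scr$records)
  expect_equal(twice$retained_records, scr$retained_records)

  expect_error(screen_records(rec, min_n = 99), "empty")
})

test_that("non-local molt flagging uses a strict upper bound", {
  mns <- data.frame(species = c("X", "Y", "Z"),
                    mean_d2hf = c(-51, -120, -110))
  expect_equal(flag_nonlocal_molt(mns, band = c(-Inf, -110)), "X")
  # mean exactly at the bound is not flagged
  expect_false("Z" %in% flag_nonlocal_molt(mns, band = c(-Inf, -110)))
  expect_length(flag_nonlocal_molt(data.frame(species = "Q",
                                              mean_d2hf = -140)), 0)

  # the synthetic fixture means reproduce exactly the six excluded species
  flagged <- flag_nonlocal_molt(fixture_species_means())
  expect_setequal(flagged, SIX_EXCLUDED)
})

test_that("screened fixture species means sit in the printed local range", {
  rec <- expand_fixture_records(means = fixture_species_means(), seed = 4)
  scr <- screen_records(rec, min_n = 9, exclusion = SIX_EXCLUDED)
  ps <- scr$per_species
  expect_equal(nrow(ps), 15)
  expect_true(all(ps$mean_d2hf > -175 & ps$mean_d2hf < -115))
})

test_that("two-way ANOVA matches a hand-computed sums-of-squares oracle", {
  # balanced 2 x 2 cell-means design: SS decomposition by hand
  set.seed(21)
  cells <- expand.grid(species = c("A", "B"), year = c(2011, 2013))
  mu <- c(0, 0, 0, 10)
  rec <- do.call(rbind, lapply(1:4, function(i)
    data.frame(species = cells$species[i], year = cells$year[i],
               d2hf = rnorm(5, mu[i], 1))))
  tab <- year_species_anova(rec)

  ybar <- mean(rec$d2hf)
  ym <- tapply(rec$d2hf, list(rec$species, rec$year), mean)
  ss_a <- 10 * sum((rowMeans(ym) - ybar)^2)            # species
  ss_b <- 10 * sum((colMeans(ym) - ybar)^2)            # year
  ss_int <- 5 * sum((ym - outer(rowMeans(ym), colMeans(ym), "+") + ybar)^2)
  ss_e <- sum((rec$d2hf - ym[cbind(as.character(rec$species),
                                   as.character(rec$year))])^2)
  f_int <- (ss_int / 1) / (ss_e / 16)
  got <- tab[tab$effect == "year:species", ]
  expect_equal(got$F, f_int, tolerance = 1e-8)
  expect_equal(got$sum_sq, ss_int, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$effect == "species"], ss_a, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$effect == "year"], ss_b, tolerance = 1e-8)

  # F statistics unchanged by adding a constant to every observation
  rec2 <- rec; rec2$d2hf <- rec2$d2hf - 143
  expect_equal(year_species_anova(rec2)$F, tab$F, tolerance = 1e-10)

  # full-model row: cells - 1 numerator df
  expect_equal(tab$df[tab$effect == "Full model (cell means)"], 3)
})

test_that("ANOVA rejects malformed designs and null data give null F", {
  rec <- toy_records(c("A", "B"), 6, d2hf = rnorm(12))
  expect_error(year_species_anova(rec), "2 year")
  rec$year <- rep(c(2011, 2013), 6)
  rec$year[rec$species == "B" & rec$year == 2011] <- 2013
  expect_error(year_species_anova(rec), "B")

  # all cell means equal: interaction p is uniform, rarely small
  set.seed(17)
  ps <- replicate(40, {
    r <- data.frame(species = rep(c("A", "B"), each = 10),
                    year = rep(c(2011, 2013), 10),
                    d2hf = rnorm(20))
    tab <- year_species_anova(r)
    tab$p[tab$effect == "year:species"]
  })
  expect_gt(mean(ps > 0.5), 0.3)
  expect_gt(min(ps), 1e-4)
})

test_that("the four-species year experiment is detected at the observed offsets", {
  # per-species shifts between years matching the observed directions
  # (+4, +9, +12, -6 per mil), n = 15/cell, sd = 8 per mil; the detection
  # rate must match the closed-form noncentral-F power of this design
  offsets <- c(-6, 4, 9, 12); n_cell <- 15; sdev <- 8
  ncp <- n_cell * sum((offsets - mean(offsets))^2) / (2 * sdev^2)
  df1 <- 3; df2 <- 4 * 2 * n_cell - 8
  power_001 <- pf(qf(1 - 0.001, df1, df2), df1, df2, ncp = ncp,
                  lower.tail = FALSE)             # 0.762 at this design
  power_05 <- pf(qf(1 - 0.05, df1, df2), df1, df2, ncp = ncp,
                 lower.tail = FALSE)              # 0.981 at this design
  hits001 <- 0L; hits05 <- 0L
  R <- 200
  for (r in seq_len(R)) {
    dat <- simulate_year_dataset(c("OVEN", "SWTH", "AMRE", "YRWA"),
                                 n_per_cell = n_cell,
                                 means = c(-144, -127, -140, -137),
                                 offsets = offsets, sd = sdev,
                                 seed = 3000 + r)
    tab <- year_species_anova(dat)
    p_int <- tab$p[tab$effect == "year:species"]
    hits001 <- hits001 + (p_int < 0.001)
    hits05 <- hits05 + (p_int < 0.05)
  }
  mc <- sqrt(power_001 * (1 - power_001) / R)
  expect_lt(abs(hits001 / R - power_001), 4 * mc)
  expect_gte(hits05 / R, power_05 - 4 * sqrt(power_05 * (1 - power_05) / R))
})

test_that("transfer-function bands are linear in the precipitation value", {
  tf <- list(list(label = "ground", intercept = -20, slope = 1, resid_sd = 10))
  band <- predict_feather_band(-120, tf)
  expect_equal(band$fit, -140)
  expect_equal(c(band$lower, band$upper), c(-150, -130))

  # slope 0: band independent of the input
  tf0 <- list(list(label = "flat", intercept = -140, slope = 0, resid_sd = 5))
  expect_equal(predict_feather_band(-80, tf0)$fit,
               predict_feather_band(-160, tf0)$fit)

  # two functions evaluated side by side
  tf2 <- data.frame(label = c("ground", "nonground"),
                    intercept = c(-20, -25), slope = c(1, 0.95),
                    resid_sd = c(14, 15))
  out <- predict_feather_band(-120, tf2)
  expect_equal(nrow(out), 2)

  expect_error(predict_feather_band(-120, list(list(label = "x"))), "intercept")
  expect_error(predict_feather_band(-120, list()), "no transfer")

  # interval membership: observed ground-forager mean against its band
  expect_equal(classify_local_molt(-143, c(-160, -130)),
               "consistent with local molt")
  expect_equal(classify_local_molt(-100, c(-160, -130)),
               "outside predicted band")
})
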