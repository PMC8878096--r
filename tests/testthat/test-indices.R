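test_that("germination percentage matches worked values", {
  expect_equal(gp(1, 30), 100 / 30, tolerance = 1e-12)   # prints as 3.33
  expect_equal(round(gp(1, 30), 2), 3.33)
  expect_equal(round(gp(23, 30), 2), 76.67)
  expect_equal(round(gp(14, 30), 2), 46.67)
  expect_equal(gp(0, 10), 0)
  expect_error(gp(1, 0), "positive")
})

test_that("MGT, MGR and their reciprocity", {
  expect_equal(mgt(c(1, 2), c(2, 3)), 1.6)  # (2*1 + 3*2)/5
  expect_equal(mgt(1, 10), 1)
  expect_equal(mgt(7, 1), 7)
  expect_true(is.na(mgt(numeric(0), numeric(0))))
  expect_equal(mgr(1.6), 0.625)
  for (d in list(c(1, 3, 5), c(2, 2, 9))) {
    m <- mgt(d, c(1, 4, 2))
    expect_equal(m * mgr(m), 1)
  }
})

test_that("GRI sums daily percentages over day numbers", {
  expect_equal(gri(1, 50), 50)
  expect_equal(gri(c(1, 2), c(10, 20)), 20)
  expect_equal(gri(numeric(0), numeric(0)), 0)
})

test_that("GI applies descending integer weights", {
  expect_equal(gi(1, 10, test_length = 10), 100)
  expect_equal(gi(c(1, 2), c(2, 3), test_length = 10), 2 * 10 + 3 * 9)
  expect_equal(gi(10, 4, test_length = 10), 4)   # last-day weight is 1
  # bound: GI <= test_length x total seeds
  expect_lte(gi(c(1, 3), c(5, 5), test_length = 10), 10 * 10)
})

test_that("CVG attains 100 only for all-first-day germination", {
  expect_equal(cvg(1, 10), 100)
  expect_equal(cvg(c(1, 2), c(1, 1)), 100 * 2 / 3)
  expect_equal(cvg(4, 1), 25)
  expect_true(is.na(cvg(numeric(0), numeric(0))))
  expect_lt(cvg(c(1, 5), c(9, 1)), 100)
})

test_that("GE telescopes cumulative increments over day numbers", {
  expect_equal(ge(c(1, 2), c(5, 8)), 5 / 1 + 3 / 2)
  expect_equal(ge(1, 7), 7)
  expect_equal(ge(numeric(0), numeric(0)), 0)
})

test_that("Timson index sums carried-forward cumulative percentages", {
  expect_equal(tgi(1, 100, period = 5), 500)
  expect_equal(tgi(3, 50, period = 4), 100)   # 0 + 0 + 50 + 50
  expect_equal(tgi(numeric(0), numeric(0), period = 5), 0)
  # bound 100 x period
  expect_lte(tgi(c(1, 2), c(40, 90), period = 6), 600)
})

test_that("vigour indices and root:shoot ratio", {
  expect_equal(svi1(10, 50), 500)
  expect_equal(svi1(3, 0), 0)
  expect_equal(svi1(1, 100), 100)
  expect_equal(svi2(2, 50), 100)
  expect_equal(svi2(0, 80), 0)
  expect_equal(rsr(0.2, 0.4), 0.5)
  expect_equal(rsr(0.3, 0.3), 1)
  expect_error(rsr(0.2, 0), "positive")
})

test_that("T50 interpolates the cumulative count at half the final count", {
  expect_equal(t50(c(1, 2, 3), c(1, 4, 6), final_count = 10), 2.5)
  expect_equal(t50(c(1, 2, 3), c(2, 5, 10)), 2)  # N/2 = 5 hit exactly
  expect_true(is.na(t50(c(1, 2), c(0, 0), final_count = 0)))
})

test_that("dish indices agree with a hand-computed schedule", {
  # dish of 10: 2 germinate day 1, 3 on day 2 (observed at 24/48 h)
  rec <- dish_records(20, 0, 1, c(24, 48, 72), c(2, 5, 5))
  idx <- dishIndices(rec, test_length = 3)
  expect_equal(idx[["GP"]], 50)
  expect_equal(idx[["MGT"]], 1.6)
  expect_equal(idx[["GRI"]], 20 / 1 + 30 / 2)
  expect_equal(idx[["GI"]], 2 * 3 + 3 * 2)
  expect_equal(idx[["CVG"]], 100 * 5 / (2 * 1 + 3 * 2))
  expect_equal(idx[["GE"]], 2 / 1 + 3 / 2)
  expect_equal(idx[["TGI"]], 20 + 50 + 50)
  expect_equal(idx[["MGR"]], 1 / 1.6)
  expect_equal(idx[["T50"]], 1 + (2.5 - 2) * (2 - 1) / (5 - 2))
  expect_true(is.na(idx[["SVI_I"]]))
  # with seedling data the vigour indices fill in
  sdl <- data.frame(temperature_C = 20, psi_MPa = 0, replicate = 1,
                    seedling_id = 1:3, length_cm = c(8, 10, 12),
                    dry_weight_mg = c(1.8, 2, 2.2), root_dry_mg = 0.7,
                    shoot_dry_mg = 1.4)
  idx2 <- dishIndices(rec, sdl, test_length = 3)
  expect_equal(idx2[["SVI_I"]], 10 * 50)
  expect_equal(idx2[["SVI_II"]], 2 * 50)
  expect_equal(idx2[["RSR"]], 0.5)
})

test_that("index table aggregates replicate means and SEs stably", {
  rec <- rbind(dish_records(20, 0, 1, c(24, 48), c(2, 5)),
               dish_records(20, 0, 2, c(24, 48), c(4, 7)),
               dish_records(20, -0.5, 1, c(24, 48), c(1, 3)))
  tab <- indexTable(rec)
  gp_row <- tab[tab$index == "GP" & tab$psi_MPa == 0, ]
  expect_equal(gp_row$mean, mean(c(50, 70)))
  expect_equal(gp_row$se, sd(c(50, 70)) / sqrt(2))
  # single replicate -> SE 0
  gp_single <- tab[tab$index == "GP" & tab$psi_MPa == -0.5, ]
  expect_equal(gp_single$se, 0)
  expect_equal(gp_single$n, 1)
  # permuting dish order leaves the table unchanged
  tab2 <- indexTable(rec[sample(nrow(rec)), ])
  expect_equal(tab, tab2)
})

test_that("pooled-schedule indices are invariant to how dishes are split", {
  # same pooled counts as one dish of 20 or two dishes of 10
  one <- dish_records(20, 0, 1, c(24, 48, 72), c(4, 10, 14), sown = 20)
  twoA <- dish_records(20, 0, 1, c(24, 48, 72), c(3, 6, 8), sown = 10)
  twoB <- dish_records(20, 0, 2, c(24, 48, 72), c(1, 4, 6), sown = 10)
  pooled_two <- twoA
  pooled_two$cum_germinated <- twoA$cum_germinated + twoB$cum_germinated
  pooled_two$seeds_sown <- 20
  expect_equal(dishIndices(one, test_length = 3),
               dishIndices(pooled_two, test_length = 3))
  # equal-sized dishes: treatment-mean GP matches the pooled GP
  tab <- indexTable(rbind(twoA, twoB))
  expect_equal(tab[tab$index == "GP", "mean"], 100 * 14 / 20)
})
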