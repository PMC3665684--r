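test_that("binned tables expand to the published rejection counts", {
  cases <- list(
    # offer, n, rate, expected rejections
    list(0.2, 5L, 0.60, 3L),
    list(0.4, 8L, 0.13, 1L),   # 8 x 0.13 = 1.04 rounds to 1
    list(0.4, 14L, 0.14, 2L),  # 14 x 0.14 = 1.96 rounds to 2
    list(0.1, 3L, 0.67, 2L)
  )
  for (cs in cases) {
    d <- ug_expand_binned(data.frame(offer = cs[[1]], n = cs[[2]],
                                     rejection_rate = cs[[3]]))
    expect_equal(nrow(d), cs[[2]])
    expect_equal(sum(d$accepted == 0), cs[[4]])
    expect_true(all(d$offer == cs[[1]]))
  }
  # zero-count rows emit nothing
  d0 <- ug_expand_binned(data.frame(offer = c(0.3, 0.5),
                                    n = c(0L, 2L),
                                    rejection_rate = c(0.5, 0)))
  expect_equal(nrow(d0), 2)
  expect_true(all(d0$offer == 0.5))
  # ambiguous rate x n stops rather than guesses
  expect_error(
    ug_expand_binned(data.frame(offer = 0.2, n = 2L, rejection_rate = 0.25)),
    "ambiguous")
  # aggregate validation fails loudly
  expect_error(
    ug_expand_binned(data.frame(offer = 0.5, n = 4L, rejection_rate = 0),
                     expected_n = 5), "expected")
  expect_error(
    ug_expand_binned(data.frame(offer = 0.5, n = 4L, rejection_rate = 0.25),
                     expected_rejection_rate = 0.50), "rejection rate")
})

test_that("every fixture conserves the published group aggregates", {
  published <- list(
    all_resettled = c(n = 86, rate = 0.07),
    all_traditional = c(n = 31, rate = 0.10),
    mupfurudzi_all = c(n = 64, rate = 0.09),
    mutanda_resettled = c(n = 9, rate = 0.00),
    mutanda_traditional = c(n = 10, rate = 0.10),
    sengezi_resettled = c(n = 25, rate = 0.04),
    sengezi_traditional = c(n = 9, rate = 0.11),
    pooled_all = c(n = 117, rate = 0.08),
    mutanda_all = c(n = 19, rate = 0.05),
    sengezi_all = c(n = 34, rate = 0.06))
  expect_setequal(ug_fixture_names(), names(published))
  for (g in names(published)) {
    d <- ug_fixture(g)
    expect_equal(nrow(d), unname(published[[g]]["n"]))
    expect_equal(round(mean(d$accepted == 0), 2),
                 unname(published[[g]]["rate"]))
  }
  expect_error(ug_fixture("nowhere"), "available")
})

test_that("specific fixtures reconstruct the printed plays", {
  res <- ug_fixture("all_resettled")
  expect_equal(sum(res$accepted == 0), 6)
  mut <- ug_fixture("mutanda_resettled")
  expect_equal(as.numeric(table(mut$offer)), c(2, 7))
  expect_equal(sort(unique(mut$offer)), c(0.4, 0.5))
  expect_true(all(mut$accepted == 1))
  sen <- ug_fixture("sengezi_resettled")
  expect_equal(sum(sen$accepted == 0), 1)
  expect_equal(sen$offer[sen$accepted == 0], 0.2)
  # pooled fixture is the concatenation of the two status groups
  pool <- ug_fixture("pooled_all")
  both <- rbind(ug_fixture("all_resettled"), ug_fixture("all_traditional"))
  expect_equal(nrow(pool), 117)
  expect_equal(pool[c("area", "status", "offer", "accepted")],
               both[c("area", "status", "offer", "accepted")],
               ignore_attr = TRUE)
})

test_that("observation CSV round-trips and rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  for (g in c("all_resettled", "mutanda_traditional")) {
    d <- ug_fixture(g)
    ug_write_observations(d, tmp)
    d2 <- ug_read_observations(tmp)
    expect_equal(as.data.frame(d2), as.data.frame(d))
  }
  writeLines(c("pair_id,area,status,offer,accepted",
               "p1,all,all,0.5,1",
               "p2,all,all,0.55,1"), tmp)
  expect_error(ug_read_observations(tmp), "line\\(s\\): 3")
  writeLines("pair_id,area,status,offer,accepted", tmp)
  expect_equal(nrow(ug_read_observations(tmp)), 0)
  writeLines(c("pair_id,offer", "p1,0.5"), tmp)
  expect_error(ug_read_observations(tmp), "header")
})

test_that("descriptive summaries reproduce the published table", {
  d_all <- ug_descriptives(ug_fixture("pooled_all"))
  expect_equal(round(d_all$mean_offer, 2), 0.44)
  expect_equal(round(d_all$sd_offer, 2), 0.11)
  expect_equal(round(d_all$rejection_rate, 2), 0.08)
  expect_equal(d_all$n_below_half, 38)
  expect_equal(round(d_all$rejection_rate_below_half, 2), 0.24)
  expect_equal(d_all$n_below_03, 13)
  expect_equal(round(d_all$rejection_rate_below_03, 2), 0.46)
  expect_equal(d_all$modal_offer, 0.5)

  d_res <- ug_descriptives(ug_fixture("all_resettled"))
  expect_equal(round(d_res$mean_offer, 2), 0.45)
  expect_equal(round(d_res$rejection_rate, 2), 0.07)

  one <- ug_observations(0.5, 1)
  d1 <- ug_descriptives(one)
  expect_equal(d1$mean_offer, 0.5)
  expect_equal(d1$sd_offer, 0)
  expect_equal(d1$rejection_rate, 0)
  expect_error(ug_descriptives(ug_observations(numeric(0), integer(0))),
               "empty")
})

test_that("observation constructor validates offers and acceptance", {
  expect_error(ug_observations(0.55, 1), "grid")
  expect_error(ug_observations(0.5, 2), "0/1")
  d <- ug_observations(c(0.5, 0.2), c(TRUE, FALSE))
  expect_equal(d$accepted, c(1L, 0L))
})
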