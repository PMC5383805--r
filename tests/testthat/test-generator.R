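test_that("expected counts follow the step-plus-decay rate model", {
  cfg <- tiny_config(mult = 1, baseline = 50)
  mu <- expected_counts(cfg)
  expect_true(all(mu$expected[mu$category == "gun_type"] == 50))
  # spike day multiplies that day only
  cfg2 <- tiny_config(mult = 1, baseline = 100,
                      spikes = data.frame(day = -6, category = "gun_type",
                                          multiplier = 3))
  mu2 <- expected_counts(cfg2)
  g <- mu2[mu2$category == "gun_type", ]
  expect_equal(g$expected[g$day == -6], 300)
  expect_true(all(g$expected[g$day != -6 & g$day < 0] == 100))
  # halflife decay: 1 + (5 - 1) * 2^(-1) = 3 at event_day + halflife
  cfg3 <- tiny_config(mult = 5, halflife = 3, baseline = 100)
  mu3 <- expected_counts(cfg3)
  g3 <- mu3[mu3$category == "gun_type", ]
  expect_equal(g3$expected[g3$day == 3], 300)
  expect_equal(g3$expected[g3$day == 0], 500)
  expect_true(all(g3$expected[g3$day < 0] == 100))
  # control is event-agnostic by construction
  expect_true(all(mu3$expected[mu3$category == "control"] == 25))
})

test_that("same seed reproduces the log byte for byte, new seeds vary", {
  cfg <- tiny_config(seed = 7)
  expect_identical(generate_log(cfg), generate_log(cfg))
  expect_identical(generate_log(cfg, seed = 99), generate_log(cfg, seed = 99))
  expect_false(identical(generate_log(cfg), generate_log(cfg, seed = 99)))
  # the caller's RNG stream is not consumed
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_log(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated records satisfy the record invariants", {
  cfg <- tiny_config(seed = 8)
  log <- generate_log(cfg)
  expect_true(all(log$day >= -14 & log$day <= 13))
  expect_true(all(!is.na(extract_domain(log$clicked_url))))
  # every query classifies back into its generating category
  cl <- classify_log(log)
  expect_true(all(!is.na(cl$category)))
  expect_setequal(unique(cl$category), c("gun_type", "shooting", "control"))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(tiny_profile(-1), "baseline_rate")
  expect_error(tiny_profile(1, multiplier = -2), "event_multiplier")
  expect_error(tiny_profile(1, halflife = 0), "decay_halflife_days")
  expect_error(category_profile(1, 1, 1, "q", c(a = 0.5, b = 0.6)),
               "domain_weights")
  expect_error(category_profile(1, 1, 1, character(0), c(a = 1)),
               "query_templates")
  expect_error(tiny_config(window = 0), "window_days")
  expect_error(tiny_config(spikes = data.frame(day = 1, category = "nope",
                                               multiplier = 2)),
               "unknown categories")
})

test_that("Monte-Carlo means match the analytic expectations cellwise", {
  cfg <- tiny_config(mult = 2, halflife = 3, baseline = 20, control_baseline = 15,
                     spikes = data.frame(day = -6, category = "gun_type",
                                         multiplier = 2))
  mu <- expected_counts(cfg)
  nsim <- 200
  acc <- matrix(0, nrow(mu), nsim)
  for (s in seq_len(nsim)) {
    log <- generate_log(cfg, seed = 1000 + s)
    cl_cat <- classify_query(log$query)
    key <- paste(cl_cat, log$day)
    tab <- table(key)
    acc[, s] <- as.integer(tab[match(paste(mu$category, mu$day), names(tab))])
  }
  acc[is.na(acc)] <- 0
  mc_mean <- rowMeans(acc)
  se <- sqrt(mu$expected / nsim)
  expect_true(all(abs(mc_mean - mu$expected) <= 3 * se + 1e-9))
})

test_that("control counts do not depend on other categories' multipliers", {
  totals <- function(mult, seeds) {
    vapply(seeds, function(s) {
      log <- generate_log(tiny_config(mult = mult, baseline = 40), seed = s)
      sum(classify_query(log$query) == "control")
    }, 0)
  }
  a <- totals(1, 1:25)
  b <- totals(10, 101:125)
  expect_gt(wilcox.test(a, b, exact = FALSE)$p.value, 0.01)
})

test_that("generator configuration round-trips through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "window_days: 7",
    "event_day: 0",
    "seed: 5",
    "categories:",
    "  gun_type:",
    "    baseline_rate: 50",
    "    event_multiplier: 2",
    "    decay_halflife_days: .inf",
    "    query_templates: [buy handgun online]",
    "    domain_weights: {gundepot.com: 0.6, wikipedia.org: 0.4}",
    "control:",
    "  baseline_rate: 20",
    "  query_templates: [bicycle shop near me]",
    "  domain_weights: {bikebarn.com: 1.0}",
    "spikes:",
    "  - {day: -3, category: gun_type, multiplier: 2}"), p)
  cfg <- read_generator_config(p)
  expect_s3_class(cfg, "qp_generator_config")
  expect_identical(cfg$window_days, 7L)
  expect_identical(cfg$categories$gun_type$decay_halflife_days, Inf)
  expect_identical(generate_log(cfg), generate_log(cfg))
  mu <- expected_counts(cfg)
  expect_equal(mu$expected[mu$category == "gun_type" & mu$day == -3], 100)
  expect_error(read_generator_config("no/such.yaml"), "not found")
})
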