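test_that("window assignment uses half-open 14-day windows around the event", {
  w <- event_window()
  expect_identical(assign_window(c(-15, -14, -1, 0, 13, 14), w),
                   c("excluded", "before", "before", "after", "after",
                     "excluded"))
  w5 <- event_window(event_day = 10, window_days = 5)
  expect_identical(assign_window(c(4, 5, 9, 10, 14, 15), w5),
                   c("excluded", "before", "before", "after", "after",
                     "excluded"))
})

test_that("percent-change arithmetic matches hand calculations", {
  expect_equal(delta_percent(1345833, 2019526), 50.06)
  expect_equal(delta_percent(51678, 596555), 1054.37)
  expect_equal(delta_percent(308603, 281927), -8.64)
  expect_equal(delta_percent(7, 7), 0)
  expect_true(is.na(delta_percent(0, 5)))
  expect_equal(cumulative_percent(965795, 3365359), 28.70)
  expect_equal(cumulative_percent(c(965795, 595689), 3365359)[2], 46.40)
  expect_equal(cumulative_percent(42, 42), 100)
  expect_equal(category_share(3370523, 5653588), 59.62)
  expect_equal(category_share(45848, 66581), 68.86)
  expect_equal(category_share(9, 9), 100)
})

test_that("reported percents round half away from zero", {
  expect_equal(delta_percent(1000, 1001.25), 0.13)  # base round() would give 0.12
  expect_equal(delta_percent(1000, 998.75), -0.13)
})

test_that("cross-tabs reproduce a brute-force recount of the raw records", {
  w <- event_window()
  cl <- classify_log(generate_log(tiny_config(seed = 41, baseline = 60)))
  for (cat in c("gun_type", "shooting", "control")) {
    ct <- build_crosstab(cl, cat, w, top_k = 2)
    tot <- brute_counts(cl, cat, w)
    expect_identical(ct$before_n[ct$class_label == "total"], tot[["before"]])
    expect_identical(ct$after_n[ct$class_label == "total"], tot[["after"]])
    for (lab in setdiff(ct$class_label, c("total", "all other classes"))) {
      bc <- brute_counts(cl, cat, w, label = lab)
      expect_identical(ct$before_n[ct$class_label == lab], bc[["before"]])
      expect_identical(ct$after_n[ct$class_label == lab], bc[["after"]])
    }
    # conservation: named rows plus residual equal the total row
    body <- ct[ct$class_label != "total", ]
    expect_equal(sum(body$n), ct$n[ct$class_label == "total"])
    # cumulative share is nondecreasing and ends at 100
    expect_true(all(diff(ct$cumulative_pct) >= 0))
    expect_equal(ct$cumulative_pct[nrow(ct)], 100)
    # row percents split each row's n
    expect_true(all(abs(ct$before_pct + ct$after_pct - 100) <= 0.01))
  }
})

test_that("degenerate splits are handled without errors", {
  cl <- classify_log(generate_log(tiny_config(seed = 42)))
  after_only <- cl[cl$day >= 0, ]
  ct <- build_crosstab(after_only, "gun_type", event_window())
  expect_true(all(ct$before_pct == 0))
  expect_true(all(is.na(ct$delta_pct)))
  empty <- build_crosstab(cl, "no_such_category", event_window())
  expect_identical(nrow(empty), 1L)
  expect_identical(empty$n, 0L)
})

test_that("advocacy tables agree with direct recounts and shares", {
  w <- event_window()
  cfg <- tiny_config(seed = 43, baseline = 80)
  cfg$categories$gun_type$domain_weights <-
    c("rifleassociation.org" = 0.4, "stopgunviolence.org" = 0.3,
      "wikipedia.org" = 0.3)
  cl <- classify_log(generate_log(cfg))
  adv <- advocacy_crosstab(cl, w)
  g <- adv[adv$group == "gun_type", ]
  side <- assign_window(cl$day, w)
  for (view in c("gun_rights", "gun_control")) {
    keep <- cl$category == "gun_type" & !is.na(cl$advocacy) &
      cl$advocacy == view & side != "excluded"
    expect_identical(g$before_n[g$advocacy == view], sum(keep & side == "before"))
    expect_identical(g$after_n[g$advocacy == view], sum(keep & side == "after"))
  }
  expect_equal(sum(g$n[g$advocacy != "total"]), g$n[g$advocacy == "total"])
  expect_equal(g$share_pct[g$advocacy == "total"], 100)
})

test_that("advocacy reconstruction from printed shares follows the integer rule", {
  shares <- data.frame(group = "laws", advocacy = c("gun_control", "x"),
                       n = c(1179, 1000), before_pct = c(11.62, 50))
  out <- advocacy_from_shares(shares)
  expect_identical(out$before_n, c(137, 500))
  expect_identical(out$after_n, c(1042, 500))
  expect_equal(out$delta_pct, c(660.58, 0))
})

test_that("control contrast reports target minus control percent change", {
  counts <- data.frame(class_label = c("a", "b"), before_n = c(100, 50),
                       after_n = c(200, 60))
  target <- crosstab_from_counts(counts, group = "guns")
  identical_ct <- crosstab_from_counts(counts, group = "bicycle")
  same <- control_contrast(target, identical_ct)
  expect_true(all(same$contrast_points == 0))
  expect_false(any(same$event_attributable))
  ctl <- crosstab_from_counts(
    data.frame(class_label = "a", before_n = 80, after_n = 72),
    group = "bicycle")
  expect_warning(ct <- control_contrast(target, ctl), "total row")
  expect_equal(ct$contrast_points[ct$class_label == "a"], 100 - (-10))
  # class "b" missing from control: contrasted against control total
  expect_equal(ct$control_delta_pct[ct$class_label == "b"], -10)
})

test_that("tidy and glance expose the table as plain tibbles", {
  cl <- classify_log(generate_log(tiny_config(seed = 44)))
  ct <- build_crosstab(cl, "gun_type", event_window())
  td <- tidy(ct)
  expect_false("total" %in% td$class_label)
  expect_identical(td$group[1], "gun_type")
  gl <- glance(ct)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n, ct$n[ct$class_label == "total"])
})
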