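# Small generator configurations used across tests. Baselines are kept low
# so sampled logs stay in the hundreds of records.

tiny_profile <- function(baseline, multiplier = 1, halflife = Inf,
                         templates = "buy handgun online",
                         weights = c("gundepot.com" = 0.6, "wikipedia.org" = 0.4)) {
  category_profile(
    baseline_rate = baseline, event_multiplier = multiplier,
    decay_halflife_days = halflife,
    query_templates = templates, domain_weights = weights
  )
}

tiny_config <- function(mult = 2, halflife = Inf, baseline = 30,
                        control_baseline = 25, window = 14, spikes = NULL,
                        seed = 1) {
  generator_config(
    categories = list(
      gun_type = tiny_profile(baseline, mult, halflife),
      shooting = tiny_profile(
        baseline / 2, mult, halflife,
        templates = c("school shooting coverage", "shooting range hours"),
        weights = c("eveningnews.com" = 0.7, "gazette.com" = 0.3))
    ),
    control = tiny_profile(
      control_baseline,
      templates = c("bicycle shop near me", "buy bike online"),
      weights = c("bikebarn.com" = 0.5, "wikipedia.org" = 0.5)),
    window_days = window, spikes = spikes, seed = seed
  )
}

# Brute-force before/after recount straight off the raw records, using only
# base subsetting -- the oracle the cross-tab machinery is checked against.
brute_counts <- function(classified, category, window, label = NULL) {
  side <- assign_window(classified$day, window)
  keep <- !is.na(classified$category) & classified$category == category &
    side != "excluded"
  if (!is.null(label)) keep <- keep & classified$class_label %in% label
  c(before = sum(keep & side == "before"), after = sum(keep & side == "after"))
}
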