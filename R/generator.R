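#' Define one query-category profile for the synthetic generator
#'
#' @param baseline_rate Expected queries/day before the event (Poisson mean).
#' @param event_multiplier Dimensionless factor `>= 0`; the daily rate is
#'   multiplied by `1 + (event_multiplier - 1) * 2^(-(d - event_day)/halflife)`
#'   from the event day on, i.e. a step whose excess decays geometrically
#'   back toward baseline. `Inf` halflife keeps the full step.
#' @param decay_halflife_days Positive halflife (days) of the excess
#'   multiplier; may be `Inf`.
#' @param query_templates Character vector of raw query strings emitted for
#'   this category; each template should embed one of the category's
#'   taxonomy keywords so generated records classify back to the category.
#' @param domain_weights Named numeric vector of probabilities over
#'   registry domains for the clicked URL; must sum to 1.
#' @return A list of class `qp_profile`.
#' @export
category_profile <- function(baseline_rate, event_multiplier = 1,
                             decay_halflife_days = Inf,
                             query_templates, domain_weights) {
  if (!is.numeric(baseline_rate) || length(baseline_rate) != 1 || baseline_rate < 0) {
    qp_config_abort("`baseline_rate` must be a single number >= 0")
  }
  if (!is.numeric(event_multiplier) || length(event_multiplier) != 1 ||
      event_multiplier < 0) {
    qp_config_abort("`event_multiplier` must be a single number >= 0")
  }
  if (!is.numeric(decay_halflife_days) || length(decay_halflife_days) != 1 ||
      is.na(decay_halflife_days) || decay_halflife_days <= 0) {
    qp_config_abort("`decay_halflife_days` must be > 0 (Inf allowed)")
  }
  query_templates <- as.character(query_templates)
  if (length(query_templates) == 0) {
    qp_config_abort("`query_templates` must be nonempty")
  }
  if (length(domain_weights) == 0 || is.null(names(domain_weights)) ||
      any(!nzchar(names(domain_weights)))) {
    qp_config_abort("`domain_weights` must be a named numeric vector")
  }
  if (any(domain_weights < 0) || abs(sum(domain_weights) - 1) > 1e-9) {
    qp_config_abort("`domain_weights` must be >= 0 and sum to 1")
  }
  structure(
    list(baseline_rate = baseline_rate,
         event_multiplier = event_multiplier,
         decay_halflife_days = decay_halflife_days,
         query_templates = query_templates,
         domain_weights = domain_weights),
    class = "qp_profile"
  )
}

#' Configure the synthetic search-log generator
#'
#' Full stochastic specification of a synthetic log: per-category Poisson
#' baselines with a step-plus-geometric-decay event effect starting at
#' `event_day`, optional isolated spikes on single (day, category) pairs,
#' and an event-agnostic control profile whose event multiplier is fixed
#' at 1. One seed governs all randomness through a single generator stream.
#'
#' @param categories Named list of [category_profile()] objects.
#' @param control A [category_profile()] for the control topic; its
#'   `event_multiplier` is forced to 1.
#' @param window_days Window half-length `W >= 1`; days run from `-W` to
#'   `W - 1` relative to the event (the event day opens the after window).
#' @param event_day Integer day index of the event (default 0).
#' @param spikes Data frame with columns `day, category, multiplier`:
#'   multiplicative bumps applied to single days (e.g. pre-event news spikes).
#' @param seed Integer seed; identical seed means byte-identical output.
#' @param control_name Name used for the control category (default "control").
#' @return A list of class `qp_generator_config`.
#' @seealso [generate_log()], [expected_counts()], [default_generator_config()]
#' @export
generator_config <- function(categories, control = NULL, window_days = 14,
                             event_day = 0, spikes = NULL, seed = 42,
                             control_name = "control") {
  if (!is.list(categories) || length(categories) == 0 ||
      is.null(names(categories)) || any(!nzchar(names(categories)))) {
    qp_config_abort("`categories` must be a named list of category_profile objects")
  }
  ok <- purrr::map_lgl(categories, inherits, "qp_profile")
  if (!all(ok)) qp_config_abort("`categories` entries must be category_profile objects")
  if (!is.null(control)) {
    stopifnot(inherits(control, "qp_profile"))
    control$event_multiplier <- 1 # the control is event-agnostic by definition
    if (control_name %in% names(categories)) {
      qp_config_abort("`control_name` clashes with a category name")
    }
  }
  if (!is.numeric(window_days) || length(window_days) != 1 || window_days < 1) {
    qp_config_abort("`window_days` must be >= 1")
  }
  spikes <- if (is.null(spikes)) {
    tibble(day = integer(0), category = character(0), multiplier = numeric(0))
  } else {
    as_tibble(spikes)
  }
  if (!all(c("day", "category", "multiplier") %in% names(spikes))) {
    qp_config_abort("`spikes` needs columns day, category, multiplier")
  }
  all_names <- c(names(categories), if (!is.null(control)) control_name)
  bad <- setdiff(spikes$category, all_names)
  if (length(bad)) {
    qp_config_abort(paste0("spikes reference unknown categories: ",
                           paste(bad, collapse = ", ")))
  }
  if (any(spikes$multiplier < 0)) qp_config_abort("spike multipliers must be >= 0")
  structure(
    list(categories = categories, control = control,
         control_name = control_name,
         window_days = as.integer(window_days),
         event_day = as.integer(event_day),
         spikes = spikes, seed = as.integer(seed)),
    class = "qp_generator_config"
  )
}

config_profiles <- function(config) {
  p <- config$categories
  if (!is.null(config$control)) p[[config$control_name]] <- config$control
  p
}

config_days <- function(config) {
  seq(config$event_day - config$window_days,
      config$event_day + config$window_days - 1L)
}

#' Analytic expected counts of the generator
#'
#' Deterministic per-(category, day) Poisson means implied by a generator
#' configuration: baseline times the event step-decay multiplier times any
#' spike multiplier. This is the closed-form oracle against which sampled
#' logs can be checked.
#'
#' @param config A `qp_generator_config`.
#' @return A tibble `category, day, expected`.
#' @export
expected_counts <- function(config) {
  stopifnot(inherits(config, "qp_generator_config"))
  days <- config_days(config)
  profiles <- config_profiles(config)
  out <- purrr::imap_dfr(profiles, function(p, nm) {
    rel <- days - config$event_day
    m <- ifelse(rel < 0, 1,
                1 + (p$event_multiplier - 1) * 2^(-(rel / p$decay_halflife_days)))
    tibble(category = nm, day = days, expected = p$baseline_rate * m)
  })
  if (nrow(config$spikes)) {
    sp <- config$spikes
    key <- paste(out$category, out$day)
    idx <- match(key, paste(sp$category, sp$day))
    out$expected <- out$expected * ifelse(is.na(idx), 1, sp$multiplier[idx])
  }
  out
}

#' Generate a synthetic search log
#'
#' Draws per-(category, day) record counts as Poisson variates with the
#' means given by [expected_counts()], then samples each record's query
#' from the category's templates and its clicked URL from the category's
#' domain weights (URLs are emitted as `https://www.<domain>/`). All
#' randomness flows through one seeded stream scoped to this call, so the
#' same configuration and seed reproduce the log byte for byte and the
#' caller's RNG state is left untouched.
#'
#' @param config A `qp_generator_config`.
#' @param seed Optional integer overriding `config$seed`.
#' @return A tibble `day, query, clicked_url`, ordered by category then day.
#' @export
generate_log <- function(config, seed = NULL) {
  stopifnot(inherits(config, "qp_generator_config"))
  mu <- expected_counts(config)
  withr::with_seed(seed %||% config$seed, {
    n <- rpois(nrow(mu), mu$expected)
    profiles <- config_profiles(config)
    recs <- purrr::map_dfr(split(seq_len(nrow(mu)), mu$category)[unique(mu$category)],
      function(rows) {
        p <- profiles[[mu$category[rows[1]]]]
        total <- sum(n[rows])
        tibble(
          day = rep(mu$day[rows], n[rows]),
          query = sample(p$query_templates, total, replace = TRUE),
          clicked_url = paste0(
            "https://www.",
            sample(names(p$domain_weights), total, replace = TRUE,
                   prob = p$domain_weights),
            "/")
        )
      })
    recs
  })
}

#' Default study-shaped generator configuration
#'
#' A scaled-down configuration that emulates the qualitative structure of
#' firearm-related search traffic around a mass-shooting event: four
#' firearm categories whose volumes share out roughly 60/22/17/1 percent
#' (gun type / shooting / ammunition / law related), a step increase at the
#' event day whose size mirrors each category's observed relative change,
#' a 2.5-day excess halflife so traffic is back near baseline roughly ten
#' days after the event, pre-event news spikes at days -6 and -11 on the
#' firearm categories, and a flat bicycle control. Domains are drawn from
#' the bundled synthetic registry and every query template embeds one of
#' its category's taxonomy keywords.
#'
#' @param baseline_scale Multiplier applied to all baseline rates (default
#'   1 gives ~1,100 firearm records/day before the event).
#' @param seed Integer seed stored in the configuration.
#' @return A `qp_generator_config`.
#' @export
default_generator_config <- function(baseline_scale = 1, seed = 42) {
  spikes <- tidyr::expand_grid(
    day = c(-6L, -11L),
    category = c("gun_type", "shooting", "ammunition", "law_related")
  )
  spikes$multiplier <- 1.5
  generator_config(
    categories = list(
      gun_type = category_profile(
        baseline_rate = 600 * baseline_scale,
        event_multiplier = 2.7, decay_halflife_days = 2.5,
        query_templates = c("remington shotgun for sale", "buy handgun online",
                            "best rifle scope", "pistol price comparison",
                            "revolver cleaning kit", "firearm safety class",
                            "gun show this weekend"),
        domain_weights = c("gundepot.com" = 0.35, "eveningnews.com" = 0.15,
                           "wikipedia.org" = 0.15, "gunsafetycourse.com" = 0.10,
                           "rifleassociation.org" = 0.05, "screenbuzz.com" = 0.02,
                           "firearms-bureau.gov" = 0.03, "randomblog.net" = 0.10,
                           "firearmlaw.edu" = 0.05)),
      shooting = category_profile(
        baseline_rate = 225 * baseline_scale,
        event_multiplier = 12.6, decay_halflife_days = 2.5,
        query_templates = c("shooting in connecticut news",
                            "school shooting coverage",
                            "shooting range near me"),
        domain_weights = c("eveningnews.com" = 0.45, "gazette.com" = 0.20,
                           "wikipedia.org" = 0.12, "screenbuzz.com" = 0.08,
                           "stopgunviolence.org" = 0.05, "randomblog.net" = 0.10)),
      ammunition = category_profile(
        baseline_rate = 170 * baseline_scale,
        event_multiplier = 6.4, decay_halflife_days = 2.5,
        query_templates = c("cheap ammo online", "9mm ammunition bulk",
                            "bullets for sale", "rimfire ammo review"),
        domain_weights = c("ammoexchange.com" = 0.50, "gundepot.com" = 0.15,
                           "wikipedia.org" = 0.10, "eveningnews.com" = 0.08,
                           "randomblog.net" = 0.12, "rifleassociation.org" = 0.05)),
      law_related = category_profile(
        baseline_rate = 10 * baseline_scale,
        event_multiplier = 19.5, decay_halflife_days = 2.5,
        query_templates = c("second amendment rights", "brady act summary",
                            "second amendment history",
                            "brady act background check"),
        domain_weights = c("wikipedia.org" = 0.25, "constitutioncenter.org" = 0.20,
                           "firearmlaw.edu" = 0.12, "eveningnews.com" = 0.10,
                           "rifleassociation.org" = 0.08,
                           "stopgunviolence.org" = 0.10,
                           "ceasefirecoalition.org" = 0.05,
                           "firearms-bureau.gov" = 0.05, "randomblog.net" = 0.05))
    ),
    control = category_profile(
      baseline_rate = 105 * baseline_scale,
      event_multiplier = 1, decay_halflife_days = Inf,
      query_templates = c("bicycle shop near me", "buy bike online",
                          "cycling gear sale", "bicycle repair guide"),
      domain_weights = c("bikebarn.com" = 0.40, "cyclingweekly.co.uk" = 0.15,
                         "wikipedia.org" = 0.15, "eveningnews.com" = 0.05,
                         "randomblog.net" = 0.25)),
    window_days = 14, event_day = 0, spikes = spikes, seed = seed
  )
}

#' Read a generator configuration from YAML or JSON
#'
#' Expected layout: top-level `window_days`, `event_day`, `seed`, a
#' `categories` mapping of name to profile fields (`baseline_rate`,
#' `event_multiplier`, `decay_halflife_days`, `query_templates`,
#' `domain_weights`), an optional `control` profile (same fields, its
#' multiplier is forced to 1) and an optional `spikes` list of
#' `{day, category, multiplier}` records. `.inf` (YAML) encodes an
#' undecaying step.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `qp_generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) qp_config_abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$categories)) qp_config_abort("config needs a `categories` mapping")
  as_profile <- function(p) {
    category_profile(
      baseline_rate = p$baseline_rate,
      event_multiplier = p$event_multiplier %||% 1,
      decay_halflife_days = p$decay_halflife_days %||% Inf,
      query_templates = unlist(p$query_templates),
      domain_weights = unlist(p$domain_weights))
  }
  spikes <- if (!is.null(raw$spikes)) {
    purrr::map_dfr(raw$spikes, as_tibble)
  }
  generator_config(
    categories = purrr::map(raw$categories, as_profile),
    control = if (!is.null(raw$control)) as_profile(raw$control),
    window_days = raw$window_days %||% 14,
    event_day = raw$event_day %||% 0,
    spikes = spikes,
    seed = raw$seed %||% 42,
    control_name = raw$control_name %||% "control")
}
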