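# Seeded synthetic-data generator.
#
# Emulates the statistical structure the analysis assumes, not any real
# recordings: two song groups with (by default) disjoint phrase catalogues,
# one recorded only at the western edge (Elephant Island) in 2013 and one
# throughout the area in all years; strong within-group-year repertoire
# sharing (singers converge on a few shared song variants, so some pairs
# share 100%); catalogue turnover of at least 50% between the 2011-2013 and
# 2017-2018 eras; song presence peaking in May (austral autumn) with the
# southernmost station producing social calls only; a sinusoidal sea-ice
# cycle with retrievable closed form; and separable Gaussian unit-feature
# clusters. Every artifact is a pure function of (config, seed).

DEFAULT_STATIONS <- data.frame(
  id = c("G1", "G2", "G3", "G4", "G5", "W13", "W9", "W6"),
  latitude = c(-59.0, -61.0, -63.0, -64.5, -66.5, -61.0, -64.0, -63.5),
  longitude = c(0, 0, 0, 0, 0, -55.5, -45.0, -50.0),
  stringsAsFactors = FALSE)

#' Synthetic-study configuration
#'
#' Defaults state the emulated world: two groups with disjoint catalogues;
#' the widespread group sings at the Greenwich-meridian and central Weddell
#' stations in all years, the western group only at the Elephant Island
#' station in 2013; 50% catalogue turnover between eras; May song peak;
#' a seasonal ice cycle crossing the 15% edge twice a year.
#'
#' @param seed Integer seed (mandatory).
#' @param n_groups Number of song groups (default 2).
#' @param catalog_sizes Phrase types per group catalogue (recycled;
#'   default `c(12, 8)` — a richer widespread catalogue, a small exclusive
#'   western one).
#' @param group_overlap Fraction of the smaller catalogue shared between
#'   groups (default 0, disjoint).
#' @param years Study years (default 2011-2013 and 2017-2018).
#' @param era_drift Fraction of a group's catalogue replaced between the
#'   2011-2013 and 2017-2018 eras (default 0.5).
#' @param singers_per_group_year Singers per group per active year
#'   (default 4).
#' @param songs_per_singer Songs per singer (default 6).
#' @param theme_len_range Range of theme-sequence lengths (default 2-7,
#'   the bulk of printed set-median lengths).
#' @param repertoire_core_frac Fraction of the catalogue every singer of a
#'   group-year carries (default 0.5).
#' @param repertoire_variants Number of shared song variants per group-year
#'   from which singers draw repertoires (default 3; with more singers than
#'   variants some pairs share repertoires 100%).
#' @param stations Station table (`id`, `latitude`, `longitude`).
#' @param group_stations List of station-id vectors, one per group.
#' @param group_years List of active years per group.
#' @param season_peak_month Month of maximal song activity (default 5, May).
#' @param ice_mean,ice_amplitude,ice_phase,ice_noise_sd Sea-ice cycle:
#'   concentration = clip(mean + amplitude * cos(2*pi*(doy - phase)/365.25)
#'   + noise, 0, 100); phase 260 puts the maximum in mid-September and the
#'   late-February minimum below the 15% edge.
#' @param feature_classes,feature_exemplars,n_features,feature_separation
#'   Unit-feature generator: classes (default 21, echoing ~436 exemplars at
#'   >= 20 per type), exemplars per class (20), features (44) and class-mean
#'   spread in within-class standard deviations (6).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_groups = 2L,
                         catalog_sizes = c(12L, 8L),
                         group_overlap = 0,
                         years = c(2011:2013, 2017:2018),
                         era_drift = 0.5,
                         singers_per_group_year = 4L,
                         songs_per_singer = 6L,
                         theme_len_range = c(2L, 7L),
                         repertoire_core_frac = 0.5,
                         repertoire_variants = 3L,
                         stations = DEFAULT_STATIONS,
                         group_stations = NULL,
                         group_years = NULL,
                         season_peak_month = 5L,
                         ice_mean = 50, ice_amplitude = 45,
                         ice_phase = 260, ice_noise_sd = 3,
                         feature_classes = 21L, feature_exemplars = 20L,
                         n_features = 44L, feature_separation = 6) {
  if (missing(seed)) stop("synth_config requires a seed")
  catalog_sizes <- rep_len(as.integer(catalog_sizes), n_groups)
  if (group_overlap < 0 || group_overlap > 1)
    stop("group_overlap must be in [0, 1]")
  if (era_drift < 0 || era_drift > 1) stop("era_drift must be in [0, 1]")
  if (any(catalog_sizes < 2L)) stop("catalogues need at least 2 phrase types")
  if (round(group_overlap * min(catalog_sizes)) > min(catalog_sizes))
    stop("infeasible group overlap")
  if (repertoire_core_frac <= 0 || repertoire_core_frac > 1)
    stop("repertoire_core_frac must be in (0, 1]")
  core <- round(repertoire_core_frac * catalog_sizes)
  if (any(core < 2L))
    stop("infeasible core fraction: every singer needs >= 2 core phrase types")
  if (is.null(group_stations))
    group_stations <- if (n_groups == 2L)
      list(c("G1", "G2", "G3", "G4", "W6", "W9"), "W13")
    else rep_len(list(stations$id), n_groups)
  if (is.null(group_years))
    group_years <- if (n_groups == 2L)
      list(years, intersect(2013L, years)) else rep_len(list(years), n_groups)
  if (n_groups == 2L && !length(group_years[[2L]]))
    group_years[[2L]] <- years[1L]
  stopifnot(all(unlist(group_stations) %in% stations$id),
            singers_per_group_year >= 1L, songs_per_singer >= 1L,
            theme_len_range[1] >= 1L, diff(theme_len_range) >= 0,
            repertoire_variants >= 1L)
  structure(list(seed = as.integer(seed), n_groups = as.integer(n_groups),
                 catalog_sizes = catalog_sizes, group_overlap = group_overlap,
                 years = as.integer(years), era_drift = era_drift,
                 singers_per_group_year = as.integer(singers_per_group_year),
                 songs_per_singer = as.integer(songs_per_singer),
                 theme_len_range = as.integer(theme_len_range),
                 repertoire_core_frac = repertoire_core_frac,
                 repertoire_variants = as.integer(repertoire_variants),
                 stations = stations, group_stations = group_stations,
                 group_years = group_years,
                 season_peak_month = as.integer(season_peak_month),
                 ice_mean = ice_mean, ice_amplitude = ice_amplitude,
                 ice_phase = ice_phase, ice_noise_sd = ice_noise_sd,
                 feature_classes = as.integer(feature_classes),
                 feature_exemplars = as.integer(feature_exemplars),
                 n_features = as.integer(n_features),
                 feature_separation = feature_separation),
            class = "synth_config")
}

# sequential phrase-type code factory: A -> Aa..Ad, B -> Ba..Bd, ...
code_factory <- function() {
  counter <- 0L
  function(n) {
    idx <- counter + seq_len(n)
    counter <<- counter + n
    if (max(idx) > 26L * 4L) stop("phrase-code space exhausted")
    paste0(LETTERS[(idx - 1L) %/% 4L + 1L], letters[(idx - 1L) %% 4L + 1L])
  }
}

era_of_year <- function(year) ifelse(year <= 2013L, "2011-2013", "2017-2018")

# safe single draw (sample() would treat a scalar as 1:x)
pick1 <- function(x) x[sample.int(length(x), 1L)]

# build per-group, per-era phrase catalogues honouring overlap and drift
build_catalogues <- function(config) {
  mint <- code_factory()
  eras <- unique(era_of_year(unlist(config$group_years)))
  n_shared <- round(config$group_overlap * min(config$catalog_sizes))
  cats <- list()
  for (era in eras) {
    shared <- if (n_shared > 0L) mint(n_shared) else character(0)
    for (g in seq_len(config$n_groups)) {
      s <- config$catalog_sizes[g]
      key <- paste(g, era, sep = "/")
      prev_key <- paste(g, "2011-2013", sep = "/")
      if (era == "2017-2018" && !is.null(cats[[prev_key]])) {
        # replacement types go in the core positions (the front); only old
        # *tail* types survive, so era-1 cores vanish and cross-era
        # repertoire sharing stays at or below 1 - era_drift
        n_new <- round(config$era_drift * s)
        old_tail <- rev(setdiff(cats[[prev_key]], shared))
        kept <- old_tail[seq_len(min(length(old_tail),
                                     s - n_new - length(shared)))]
        cats[[key]] <- c(shared, mint(n_new), kept)
      } else {
        cats[[key]] <- c(shared, mint(s - n_shared))
      }
    }
  }
  cats
}

# unit template for a phrase type: first unit fixed by the uppercase letter,
# 0-2 following units drawn from the same group's call-type pool
phrase_templates <- function(codes) {
  out <- lapply(codes, function(code) {
    first_ct <- paste0("CT", match(substr(code, 1, 1), LETTERS))
    extra <- sample(0:2, 1L)
    others <- if (extra > 0L)
      paste0("CT", sample(26L + seq_len(20L), extra)) else character(0)
    phrase_type(code, c(first_ct, others))
  })
  names(out) <- codes
  out
}

#' Generate synthetic singers with songs, phrases and units
#'
#' @param config A [synth_config()].
#' @return List with `singers` (each: `id`, `station`, `date`, `latitude`,
#'   `longitude`, `group`, `repertoire`, `songs`, `sessions`), `catalogues`
#'   (per group/era), `phrase_types`, `truth` (named group vector) and
#'   `config`.
#' @export
generate_song_groups <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cats <- build_catalogues(config)
  ptypes <- phrase_templates(sort(unique(unlist(cats))))
  singers <- list()
  for (g in seq_len(config$n_groups)) {
    stns <- config$group_stations[[g]]
    for (year in config$group_years[[g]]) {
      cat_gy <- cats[[paste(g, era_of_year(year), sep = "/")]]
      n_core <- round(config$repertoire_core_frac * length(cat_gy))
      core <- cat_gy[seq_len(max(2L, n_core))]
      extra_pool <- setdiff(cat_gy, core)
      variants <- lapply(seq_len(config$repertoire_variants), function(i) {
        extra <- extra_pool[stats::runif(length(extra_pool)) < 0.5]
        sort(c(core, extra))
      })
      season <- seq(as.Date(sprintf("%d-03-01", year)),
                    as.Date(sprintf("%d-06-30", year)), by = "day")
      slots <- expand.grid(station = stns, date = season,
                           stringsAsFactors = FALSE)
      slots <- slots[sample.int(nrow(slots), config$singers_per_group_year), ]
      for (si in seq_len(nrow(slots))) {
        rep_i <- variants[[pick1(seq_along(variants))]]
        sg <- build_singer(slots$station[si], slots$date[si], g, rep_i,
                           ptypes, config)
        singers[[sg$id]] <- sg
      }
    }
  }
  singers <- singers[order(names(singers))]
  truth <- vapply(singers, `[[`, integer(1), "group")
  list(singers = singers, catalogues = cats, phrase_types = ptypes,
       truth = truth, config = config)
}

build_singer <- function(stn, date, group, repertoire, ptypes, config) {
  st <- config$stations[config$stations$id == stn, ]
  songs <- list()
  sessions <- list()
  t_cursor <- 0
  sess_units <- NULL
  id <- format_singer_id(stn, date)
  songs_per_session <- 3L
  for (k in seq_len(config$songs_per_singer)) {
    len <- pick1(seq(config$theme_len_range[1], config$theme_len_range[2]))
    toks <- character(len)
    toks[1] <- pick1(repertoire)
    if (len > 1L) for (i in seq(2L, len))
      toks[i] <- pick1(setdiff(repertoire, toks[i - 1L]))
    built <- build_song_units(toks, ptypes, t_cursor)
    song <- song_sequence(built$units, built$phrases, singer = id)
    songs[[k]] <- song
    sess_units <- rbind(sess_units, built$units)
    t_cursor <- built$t_end +
      if (k %% songs_per_session == 0L) stats::runif(1, 90, 600)
      else stats::runif(1, 5, 30)
    if (k %% songs_per_session == 0L || k == config$songs_per_singer) {
      sessions[[length(sessions) + 1L]] <- sess_units
      sess_units <- NULL
    }
  }
  list(id = id, station = stn, date = date,
       latitude = st$latitude, longitude = st$longitude, group = group,
       repertoire = repertoire, songs = songs, sessions = sessions)
}

# expand a theme-token sequence into phrases and timed units
build_song_units <- function(tokens, ptypes, t0) {
  t <- t0
  phrase_rows <- list()
  unit_rows <- list()
  pid <- 0L
  for (tok in tokens) {
    pt <- ptypes[[tok]]
    n_rep <- sample(1:4, 1L)                 # phrases in this theme
    for (r in seq_len(n_rep)) {
      pid <- pid + 1L
      reps <- sample(1:3, length(pt$unit_template), replace = TRUE)
      uts <- expand_phrase(pt, reps)
      durs <- stats::runif(length(uts), 0.5, 2.5)
      gaps <- stats::runif(length(uts), 0.1, 0.5)
      starts <- t + cumsum(gaps) + cumsum(c(0, durs[-length(durs)]))
      t <- starts[length(starts)] + durs[length(durs)]
      unit_rows[[pid]] <- data.frame(
        start = starts, duration = durs, unit_type = uts,
        snr = round(stats::runif(length(uts), 10.5, 25), 1),
        phrase_code = tok, phrase_id = pid, stringsAsFactors = FALSE)
      phrase_rows[[pid]] <- data.frame(
        phrase_id = pid, code = tok, reps = paste(reps, collapse = ","),
        stringsAsFactors = FALSE)
      t <- t + stats::runif(1, 1, 5)         # inter-phrase gap
    }
  }
  list(units = do.call(rbind, unit_rows),
       phrases = do.call(rbind, phrase_rows), t_end = t)
}

#' Generate a synthetic classified hour table
#'
#' Hour categories are drawn with month-dependent probabilities peaking at
#' `season_peak_month`; the southernmost station emits social calls only.
#'
#' @param config A [synth_config()].
#' @param hours_per_day Even-hour slots per day (default 12).
#' @return `data.frame` with `station`, `hour_start_iso`, `category`.
#' @export
generate_hour_table <- function(config, hours_per_day = 12L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  south <- config$stations$id[which.min(config$stations$latitude)]
  rows <- list()
  for (year in config$years) {
    days <- seq(as.Date(sprintf("%d-01-01", year)),
                as.Date(sprintf("%d-12-31", year)), by = "day")
    mon <- as.integer(format(days, "%m"))
    w <- exp(-((mon - config$season_peak_month)^2) / 2)
    for (stn in config$stations$id) {
      p1 <- if (stn == south) rep(0, length(days)) else 0.45 * w
      p2 <- if (stn == south) rep(0, length(days)) else 0.15 * w
      ps <- rep(0.15, length(days))
      for (h in seq(0L, by = 2L, length.out = hours_per_day)) {
        u <- stats::runif(length(days))
        cat_day <- ifelse(u < p1, "HWS1",
                   ifelse(u < p1 + p2, "HWS2",
                   ifelse(u < p1 + p2 + ps, "SOCIAL", "ABSENT")))
        rows[[length(rows) + 1L]] <- data.frame(
          station = stn,
          hour_start_iso = format(as.POSIXct(days, tz = "UTC") + h * 3600,
                                  "%Y-%m-%dT%H:%M:%S"),
          category = cat_day, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$station, out$hour_start_iso), ]
}

#' Closed-form noise-free sea-ice concentration
#'
#' @param config A [synth_config()].
#' @param dates `Date` vector.
#' @return Concentration in % (clipped to `[0, 100]`).
#' @export
ice_closed_form <- function(config, dates) {
  doy <- as.numeric(format(as.Date(dates), "%j"))
  raw <- config$ice_mean + config$ice_amplitude *
    cos(2 * pi * (doy - config$ice_phase) / 365.25)
  pmin(100, pmax(0, raw))
}

#' Generate a synthetic sea-ice grid
#'
#' A small cluster of grid cells around each station; per cell-day the
#' closed-form seasonal cycle plus Gaussian noise, clipped to `[0, 100]`.
#'
#' @param config A [synth_config()].
#' @param years Years to cover (default `config$years`).
#' @param cells_per_station Cells in the mini-grid (default 5).
#' @return Long-format `data.frame` (`date`, `lat`, `lon`, `sic_percent`).
#' @export
generate_ice <- function(config, years = config$years,
                         cells_per_station = 5L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  dates <- do.call(c, lapply(years, function(y)
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)),
        by = "day")))
  base <- ice_closed_form(config, dates)
  rows <- list()
  for (i in seq_len(nrow(config$stations))) {
    st <- config$stations[i, ]
    dlat <- stats::runif(cells_per_station, -0.15, 0.15)
    dlon <- stats::runif(cells_per_station, -0.3, 0.3)
    for (k in seq_len(cells_per_station)) {
      noise <- if (config$ice_noise_sd > 0)
        stats::rnorm(length(dates), 0, config$ice_noise_sd) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        date = dates, lat = st$latitude + dlat[k],
        lon = st$longitude + dlon[k],
        sic_percent = pmin(100, pmax(0, base + noise)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic unit-feature table
#'
#' Gaussian clusters: class means have per-feature offsets drawn from
#' N(0, separation^2) (in units of the within-class standard deviation,
#' which is 1); exemplars scatter N(mean, 1).
#'
#' @param config A [synth_config()].
#' @param separation Overrides `config$feature_separation` if given.
#' @return `data.frame` with `n_features` numeric columns `f1..fp` and a
#'   `label` column (`CT1`, `CT2`, ...).
#' @export
generate_unit_features <- function(config, separation = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 3L)
  if (is.null(separation)) separation <- config$feature_separation
  k <- config$feature_classes; m <- config$feature_exemplars
  p <- config$n_features
  mu <- matrix(stats::rnorm(k * p, 0, separation), k, p)
  X <- mu[rep(seq_len(k), each = m), ] + matrix(stats::rnorm(k * m * p), k * m, p)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(p))
  df$label <- rep(paste0("CT", seq_len(k)), each = m)
  df
}

#' Materialize a complete synthetic toy study on disk
#'
#' Writes one selection table per singer, the hour table, the ice grid and
#' the unit-feature table, plus a JSON manifest echoing the config.
#'
#' @param sim Result of [generate_song_groups()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(sim, dir) {
  dir.create(file.path(dir, "selections"), recursive = TRUE,
             showWarnings = FALSE)
  cfg <- sim$config
  for (sg in sim$singers) {
    units <- do.call(rbind, lapply(sg$sessions, identity))
    fn <- paste0(gsub("[ /]", "-", sg$id), ".txt")
    write_selection_table(units, file.path(dir, "selections", fn))
  }
  utils::write.csv(generate_hour_table(cfg), file.path(dir, "hours.csv"),
                   row.names = FALSE)
  utils::write.csv(generate_ice(cfg), file.path(dir, "ice.csv"),
                   row.names = FALSE)
  utils::write.csv(generate_unit_features(cfg),
                   file.path(dir, "unit_features.csv"), row.names = FALSE)
  manifest <- unclass(cfg)
  manifest$stations <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
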