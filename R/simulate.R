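#' Latent traits of a simulated fish
#'
#' Ground-truth state of one simulated animal. `metabolic_trait` and
#' `boldness_trait` live on a standard-normal scale; in a cohort they are
#' drawn jointly with correlation `rho_true`, which is the planted
#' metabolism-boldness association that the downstream analysis tries to
#' recover.
#'
#' @param fish_id Identifier.
#' @param metabolic_trait,boldness_trait Latent traits, standard-normal
#'   scale.
#' @param mass Body mass in g, > 0.
#' @param strain,sex,feed_state Group labels.
#' @return An object of class `latent_traits`.
#' @export
latent_traits <- function(fish_id, metabolic_trait = 0, boldness_trait = 0,
                          mass = 0.8, strain = "TU", sex = "female",
                          feed_state = "fed") {
  check_finite_scalar(metabolic_trait, "metabolic_trait")
  check_finite_scalar(boldness_trait, "boldness_trait")
  check_finite_scalar(mass, "mass", 0, strict_min = TRUE)
  structure(
    list(fish_id = as.character(fish_id),
         metabolic_trait = metabolic_trait,
         boldness_trait = boldness_trait,
         mass = mass, strain = strain, sex = sex, feed_state = feed_state),
    class = "latent_traits"
  )
}

#' Trajectory simulation parameters
#'
#' Controls the movement model: a persistent (autocorrelated) random walk
#' whose vertical coordinate mean-reverts toward a preferred height, gated
#' by a two-state moving/frozen Markov chain, with reflecting tank walls.
#' Boldness enters through exactly two channels: the preferred height
#' fraction (shifted on the logit scale by `boldness_height_slope` per
#' trait SD) and the speed scale (multiplied by
#' `exp(boldness_speed_slope * trait)`), so that bottom distance and
#' percent explored are its direct behavioral readouts.
#'
#' @param frame_interval Frame spacing in s. The default 1/30 s is a plain
#'   assumption about the camera rate; it is not derived from data.
#' @param duration Trial length in s (default 360, a 6-min trial).
#' @param speed_scale Stationary per-axis swim-velocity s.d., mm/s, at
#'   boldness 0.
#' @param velocity_persistence AR(1) coefficient of the velocity process,
#'   in \[0, 1).
#' @param depth_attraction_strength Mean-reversion rate toward the
#'   preferred height, 1/s.
#' @param preferred_height_fraction Preferred height as a fraction of tank
#'   height, in \[0, 1\], at boldness 0.
#' @param immobility_onset_rate,immobility_offset_rate Rates (1/s) of the
#'   moving->frozen and frozen->moving transitions.
#' @param boldness_height_slope Logit-scale shift of the preferred height
#'   fraction per boldness SD.
#' @param boldness_speed_slope Log-scale speed multiplier per boldness SD.
#' @param rng_seed Integer seed, or NULL to draw from the ambient RNG
#'   stream.
#' @return An object of class `trajectory_sim_params`.
#' @export
trajectory_sim_params <- function(frame_interval = 1 / 30, duration = 360,
                                  speed_scale = 25,
                                  velocity_persistence = 0.9,
                                  depth_attraction_strength = 1.0,
                                  preferred_height_fraction = 0.35,
                                  immobility_onset_rate = 0.05,
                                  immobility_offset_rate = 0.5,
                                  boldness_height_slope = 0.8,
                                  boldness_speed_slope = 0.25,
                                  rng_seed = NULL) {
  check_finite_scalar(frame_interval, "frame_interval", 0, strict_min = TRUE)
  check_finite_scalar(duration, "duration", 0, strict_min = TRUE)
  check_finite_scalar(speed_scale, "speed_scale", 0)
  check_finite_scalar(velocity_persistence, "velocity_persistence", 0)
  if (velocity_persistence >= 1)
    stop_field("velocity_persistence", "must be < 1")
  check_finite_scalar(depth_attraction_strength,
                      "depth_attraction_strength", 0)
  check_finite_scalar(preferred_height_fraction,
                      "preferred_height_fraction", 0, 1)
  check_finite_scalar(immobility_onset_rate, "immobility_onset_rate", 0)
  check_finite_scalar(immobility_offset_rate, "immobility_offset_rate", 0)
  check_finite_scalar(boldness_height_slope, "boldness_height_slope")
  check_finite_scalar(boldness_speed_slope, "boldness_speed_slope")
  if (round(duration / frame_interval) < 2)
    stop_field("duration", "must span at least 2 frames")
  structure(
    list(frame_interval = frame_interval, duration = duration,
         speed_scale = speed_scale,
         velocity_persistence = velocity_persistence,
         depth_attraction_strength = depth_attraction_strength,
         preferred_height_fraction = preferred_height_fraction,
         immobility_onset_rate = immobility_onset_rate,
         immobility_offset_rate = immobility_offset_rate,
         boldness_height_slope = boldness_height_slope,
         boldness_speed_slope = boldness_speed_slope,
         rng_seed = rng_seed),
    class = "trajectory_sim_params"
  )
}

# boldness -> effective preferred height fraction (logit shift, monotone)
effective_height_fraction <- function(params, boldness) {
  pf <- params$preferred_height_fraction
  if (pf <= 0 || pf >= 1) return(pf)
  plogis(qlogis(pf) + params$boldness_height_slope * boldness)
}

# boldness -> effective speed scale (log-linear, monotone)
effective_speed <- function(params, boldness) {
  params$speed_scale * exp(params$boldness_speed_slope * boldness)
}

#' Simulate a novel-tank swim trajectory
#'
#' Runs the movement model of [trajectory_sim_params()] for one fish.
#' Bolder fish swim higher in the tank and faster; the frozen state of the
#' Markov chain produces immobility bouts. Every position is inside the
#' tank (reflecting walls) and the same `rng_seed` reproduces the
#' trajectory bit-for-bit.
#'
#' @param params A [trajectory_sim_params()].
#' @param geometry A [tank_geometry()].
#' @param traits A [latent_traits()].
#' @return A [trajectory3d()].
#' @examples
#' tr <- simulate_trajectory(
#'   trajectory_sim_params(duration = 10, rng_seed = 1),
#'   tank_geometry(), latent_traits("f1", boldness_trait = 1))
#' mean(tr$positions[, 3])
#' @export
simulate_trajectory <- function(params, geometry = tank_geometry(),
                                traits = latent_traits("fish")) {
  stopifnot(inherits(params, "trajectory_sim_params"),
            inherits(geometry, "tank_geometry"),
            inherits(traits, "latent_traits"))
  dt <- params$frame_interval
  nf <- as.integer(round(params$duration / dt))
  ext <- geometry_extents(geometry)
  zstar <- effective_height_fraction(params, traits$boldness_trait) * ext[3]
  speed_cm <- effective_speed(params, traits$boldness_trait) / 10  # mm->cm
  p_freeze <- 1 - exp(-params$immobility_onset_rate * dt)
  p_unfreeze <- 1 - exp(-params$immobility_offset_rate * dt)
  pos <- with_seed(params$rng_seed,
    sim_path_cpp(nf, dt,
                 ext[1] / 2, ext[2] / 2, ext[3] / 2,
                 ext[1], ext[2], ext[3],
                 speed_cm, params$velocity_persistence,
                 params$depth_attraction_strength, zstar,
                 p_freeze, p_unfreeze))
  trajectory3d(times = (seq_len(nf) - 1L) * dt,
               x = pos[, 1], y = pos[, 2], z = pos[, 3],
               geometry = geometry, fish_id = traits$fish_id)
}

#' Respirometry simulation parameters
#'
#' Controls the closed-chamber session generator. A session records
#' dissolved O2 (mg/l) in the fish tank and a parallel blank tank at trial
#' start and end. The fish-tank drop is the fish's true consumption plus
#' the blank drift; the blank-tank drop is the drift alone, so blank
#' correction recovers consumption exactly when `measurement_noise_sd = 0`.
#'
#' @param baseline_o2 Dissolved O2 at trial start, mg/l (air-saturated
#'   facility water at 27.5 C sits near 7.9).
#' @param rmr_per_gram Consumption scale: mg O2/l per g^`mass_exponent`
#'   per trial for a fish with metabolic trait 0.
#' @param blank_drift O2 change in the fish-free tank over the trial,
#'   mg/l (degassing/temperature drift).
#' @param measurement_noise_sd S.d. of the meter error applied to every
#'   individual reading, mg/l.
#' @param duration Trial length, min (default 30).
#' @param tank_volume Chamber volume, ml (default 500); carried in the
#'   record, not used in concentration-based consumption.
#' @param metabolic_trait_sd Log-scale spread of consumption per unit
#'   metabolic trait: the trait multiplies consumption by
#'   `exp(metabolic_trait_sd * trait)`.
#' @param rng_seed Integer seed or NULL.
#' @return An object of class `respirometry_sim_params`.
#' @export
respirometry_sim_params <- function(baseline_o2 = 7.9, rmr_per_gram = 1.75,
                                    blank_drift = 0.1,
                                    measurement_noise_sd = 0.12,
                                    duration = 30, tank_volume = 500,
                                    metabolic_trait_sd = 0.25,
                                    rng_seed = NULL) {
  check_finite_scalar(baseline_o2, "baseline_o2", 0, strict_min = TRUE)
  check_finite_scalar(rmr_per_gram, "rmr_per_gram", 0)
  check_finite_scalar(blank_drift, "blank_drift")
  check_finite_scalar(measurement_noise_sd, "measurement_noise_sd", 0)
  check_finite_scalar(duration, "duration", 0, strict_min = TRUE)
  check_finite_scalar(tank_volume, "tank_volume", 0, strict_min = TRUE)
  check_finite_scalar(metabolic_trait_sd, "metabolic_trait_sd", 0)
  structure(
    list(baseline_o2 = baseline_o2, rmr_per_gram = rmr_per_gram,
         blank_drift = blank_drift,
         measurement_noise_sd = measurement_noise_sd,
         duration = duration, tank_volume = tank_volume,
         metabolic_trait_sd = metabolic_trait_sd, rng_seed = rng_seed),
    class = "respirometry_sim_params"
  )
}

# deterministic part of a fish's per-trial O2 consumption (mg/l)
true_consumption <- function(params, traits, mass_exponent = 0.8,
                             fasting_rmr_multiplier = 1) {
  fast <- if (identical(traits$feed_state, "unfed"))
    fasting_rmr_multiplier else 1
  params$rmr_per_gram * traits$mass^mass_exponent *
    exp(params$metabolic_trait_sd * traits$metabolic_trait) * fast
}

#' Simulate one closed-chamber respirometry session
#'
#' @param params A [respirometry_sim_params()].
#' @param traits A [latent_traits()]; mass and metabolic trait set the true
#'   consumption, and `feed_state == "unfed"` scales it by
#'   `fasting_rmr_multiplier`.
#' @param session_day Integer day label.
#' @param mass_exponent Allometric exponent of consumption on mass.
#' @param fasting_rmr_multiplier Multiplier in (0, 1\] applied to unfed
#'   fish.
#' @return One-row data frame with columns `fish_id, session_day,
#'   o2_fish_t1, o2_fish_t2, o2_blank_t1, o2_blank_t2, duration_min,
#'   mass_g, valid`. `valid` is FALSE when a reading ran below zero
#'   (anoxia: the configured drop exceeds the available oxygen).
#' @examples
#' simulate_respirometry(
#'   respirometry_sim_params(measurement_noise_sd = 0, rng_seed = 1),
#'   latent_traits("f1", mass = 0.8))
#' @export
simulate_respirometry <- function(params, traits, session_day = 1L,
                                  mass_exponent = 0.8,
                                  fasting_rmr_multiplier = 1) {
  stopifnot(inherits(params, "respirometry_sim_params"),
            inherits(traits, "latent_traits"))
  check_finite_scalar(mass_exponent, "mass_exponent")
  check_finite_scalar(fasting_rmr_multiplier, "fasting_rmr_multiplier",
                      0, 1, strict_min = TRUE)
  consumption <- true_consumption(params, traits, mass_exponent,
                                  fasting_rmr_multiplier)
  e <- with_seed(params$rng_seed,
                 rnorm(4, 0, params$measurement_noise_sd))
  b <- params$baseline_o2
  rec <- data.frame(
    fish_id = traits$fish_id, session_day = as.integer(session_day),
    o2_fish_t1 = b + e[1],
    o2_fish_t2 = b - consumption - params$blank_drift + e[2],
    o2_blank_t1 = b + e[3],
    o2_blank_t2 = b - params$blank_drift + e[4],
    duration_min = params$duration, mass_g = traits$mass,
    stringsAsFactors = FALSE
  )
  rec$valid <- rec$o2_fish_t2 >= 0 & rec$o2_blank_t2 >= 0
  rec
}

#' Cohort configuration
#'
#' Defines a simulated study: the factorial sex-by-strain design, the
#' planted metabolism-boldness correlation `rho_true`, the fasting design,
#' mass distributions, and the per-fish simulators. Defaults mirror a
#' two-strain (TU, WIK), two-sex design at about 30 fish per cell with two
#' consecutive respirometry days.
#'
#' @param strains,sexes Factor levels of the design.
#' @param n_per_cell Fish per sex-by-strain cell (>= 2).
#' @param rho_true Planted correlation between the metabolic and boldness
#'   latent traits, in \[-1, 1\].
#' @param fasting One of `"none"`, `"crossover"` (each fish measured fed
#'   and unfed on respirometry days 2 days apart), or `"between"`
#'   (fish assigned to fed/unfed groups; the behavioral design).
#' @param fasting_rmr_multiplier Multiplier in (0, 1\] applied to the true
#'   consumption of unfed fish.
#' @param n_days Respirometry sessions per fish (2 enables repeatability).
#' @param mass_median_female,mass_median_male Median mass in g of the
#'   per-sex log-normal mass distributions.
#' @param mass_sdlog Log-scale s.d. of mass.
#' @param mass_exponent Allometric exponent of consumption on mass.
#' @param traj_params A [trajectory_sim_params()] (per-fish seeds are
#'   derived from the cohort seed).
#' @param resp_params A [respirometry_sim_params()].
#' @param include_trajectories Set FALSE to generate latent traits and
#'   respirometry only (fast, for calibration studies).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(strains = c("TU", "WIK"),
                          sexes = c("female", "male"),
                          n_per_cell = 30, rho_true = 0,
                          fasting = c("none", "crossover", "between"),
                          fasting_rmr_multiplier = 0.8,
                          n_days = 2,
                          mass_median_female = 0.9,
                          mass_median_male = 0.6,
                          mass_sdlog = 0.2,
                          mass_exponent = 0.8,
                          traj_params = trajectory_sim_params(),
                          resp_params = respirometry_sim_params(),
                          include_trajectories = TRUE) {
  fasting <- match.arg(fasting)
  if (length(strains) < 1 || length(sexes) < 1)
    stop("strains and sexes must each have at least one level",
         call. = FALSE)
  check_finite_scalar(n_per_cell, "n_per_cell", 2)
  check_finite_scalar(rho_true, "rho_true", -1, 1)
  check_finite_scalar(fasting_rmr_multiplier, "fasting_rmr_multiplier",
                      0, 1, strict_min = TRUE)
  check_finite_scalar(n_days, "n_days", 1)
  check_finite_scalar(mass_median_female, "mass_median_female", 0,
                      strict_min = TRUE)
  check_finite_scalar(mass_median_male, "mass_median_male", 0,
                      strict_min = TRUE)
  check_finite_scalar(mass_sdlog, "mass_sdlog", 0)
  stopifnot(inherits(traj_params, "trajectory_sim_params"),
            inherits(resp_params, "respirometry_sim_params"))
  structure(
    list(strains = strains, sexes = sexes,
         n_per_cell = as.integer(n_per_cell), rho_true = rho_true,
         fasting = fasting,
         fasting_rmr_multiplier = fasting_rmr_multiplier,
         n_days = as.integer(n_days),
         mass_median_female = mass_median_female,
         mass_median_male = mass_median_male,
         mass_sdlog = mass_sdlog, mass_exponent = mass_exponent,
         traj_params = traj_params, resp_params = resp_params,
         include_trajectories = isTRUE(include_trajectories)),
    class = "cohort_config"
  )
}

# bivariate standard-normal draw at correlation rho (exactly collinear at
# |rho| = 1)
draw_latent_pair <- function(n, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * rnorm(n)
  cbind(metabolic_trait = z1, boldness_trait = z2)
}

#' Generate a simulated cohort with known ground truth
#'
#' Draws latent traits per fish — (metabolic, boldness) bivariate standard
#' normal at correlation `rho_true`, log-normal mass per sex — then
#' simulates one novel-tank trajectory per fish and `n_days` respirometry
#' sessions, and records the full ground truth for recovery tests.
#' Regenerating with the same `(config, seed)` is bit-identical.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed (mandatory).
#' @return An object of class `cohort`: a list with `metadata` (one row
#'   per fish: fish_id, strain, sex, feed_state, mass_g, session_day),
#'   `trajectories` (named list of [trajectory3d()], or NULL),
#'   `respirometry` (records as in [simulate_respirometry()], with
#'   `feed_state` per session), and `ground_truth` (per-fish latent
#'   traits, `rho_true`, `fasting_rmr_multiplier`, `mass_exponent`,
#'   `seed`).
#' @examples
#' co <- generate_cohort(
#'   cohort_config(n_per_cell = 3, include_trajectories = FALSE), seed = 1)
#' head(co$metadata)
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed) || is.null(seed))
    stop("a master seed is mandatory", call. = FALSE)
  if (config$n_per_cell < 2)
    stop("n_per_cell must be >= 2", call. = FALSE)
  cells <- expand.grid(strain = config$strains, sex = config$sexes,
                       stringsAsFactors = FALSE)
  n_cell <- config$n_per_cell
  n_fish <- nrow(cells) * n_cell

  with_seed(seed, {
    traits_tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      lat <- draw_latent_pair(n_cell, config$rho_true)
      med <- if (cells$sex[i] == "male") config$mass_median_male
             else config$mass_median_female
      data.frame(
        fish_id = sprintf("%s_%s_%02d", cells$strain[i],
                          substr(cells$sex[i], 1, 1), seq_len(n_cell)),
        strain = cells$strain[i], sex = cells$sex[i],
        metabolic_trait = lat[, 1], boldness_trait = lat[, 2],
        mass_g = rlnorm(n_cell, meanlog = log(med),
                        sdlog = config$mass_sdlog),
        stringsAsFactors = FALSE
      )
    }))
    # feed-state assignment
    traits_tab$feed_state <- "fed"
    if (config$fasting == "between") {
      # alternate within cell: balanced fed/unfed groups
      traits_tab$feed_state <-
        ifelse(seq_len(n_fish) %% 2 == 0, "unfed", "fed")
    }
    fish_seeds <- sample.int(.Machine$integer.max - 1L, n_fish * 2L)
  })

  traj_seeds <- fish_seeds[seq_len(n_fish)]
  resp_seeds <- fish_seeds[n_fish + seq_len(n_fish)]

  make_traits <- function(i, feed_state = traits_tab$feed_state[i]) {
    latent_traits(traits_tab$fish_id[i],
                  metabolic_trait = traits_tab$metabolic_trait[i],
                  boldness_trait = traits_tab$boldness_trait[i],
                  mass = traits_tab$mass_g[i],
                  strain = traits_tab$strain[i], sex = traits_tab$sex[i],
                  feed_state = feed_state)
  }

  trajectories <- NULL
  if (config$include_trajectories) {
    trajectories <- lapply(seq_len(n_fish), function(i) {
      p <- config$traj_params
      p$rng_seed <- traj_seeds[i]
      simulate_trajectory(p, tank_geometry(), make_traits(i))
    })
    names(trajectories) <- traits_tab$fish_id
  }

  # respirometry sessions
  resp <- do.call(rbind, lapply(seq_len(n_fish), function(i) {
    day_seeds <- derive_seeds(resp_seeds[i], config$n_days)
    do.call(rbind, lapply(seq_len(config$n_days), function(d) {
      feed <- traits_tab$feed_state[i]
      if (config$fasting == "crossover") {
        # fed on one day, unfed on the other, alternating start by fish
        first_unfed <- i %% 2 == 0
        feed <- if ((d == 1) == first_unfed) "unfed" else "fed"
      }
      p <- config$resp_params
      p$rng_seed <- day_seeds[d]
      rec <- simulate_respirometry(
        p, make_traits(i, feed), session_day = d,
        mass_exponent = config$mass_exponent,
        fasting_rmr_multiplier = config$fasting_rmr_multiplier)
      rec$feed_state <- feed
      rec
    }))
  }))
  rownames(resp) <- NULL

  ground_truth <- list(
    traits = traits_tab, rho_true = config$rho_true,
    fasting = config$fasting,
    fasting_rmr_multiplier = config$fasting_rmr_multiplier,
    mass_exponent = config$mass_exponent, seed = seed
  )
  metadata <- traits_tab[, c("fish_id", "strain", "sex", "feed_state",
                             "mass_g")]
  metadata$session_day <- 1L
  structure(list(metadata = metadata, trajectories = trajectories,
                 respirometry = resp, ground_truth = ground_truth,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d fish (%d strains x %d sexes), %d respirometry day(s)%s\n",
    nrow(x$metadata), length(x$config$strains), length(x$config$sexes),
    x$config$n_days,
    if (is.null(x$trajectories)) ", no trajectories" else ""))
  cat(sprintf("  planted rho_true = %.2f, fasting design = %s\n",
              x$ground_truth$rho_true, x$ground_truth$fasting))
  invisible(x)
}

#' Write / read a cohort to a directory of plain-text files
#'
#' Writes `metadata.csv`, `respirometry.csv`, `ground_truth.json` and one
#' `trajectories/<fish_id>.csv` per fish (columns `time_s, x_cm, y_cm,
#' z_cm`). `read_cohort()` reads the same layout back; ground truth is
#' optional on read (real data have none).
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; `read_cohort()` returns a `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(cohort$respirometry, file.path(dir, "respirometry.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(cohort$trajectories)) {
    tdir <- file.path(dir, "trajectories")
    dir.create(tdir, showWarnings = FALSE)
    for (tr in cohort$trajectories)
      write_trajectory_csv(tr, file.path(tdir, paste0(tr$fish_id, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param geometry Tank geometry used to validate trajectories on read.
#' @export
read_cohort <- function(dir, geometry = tank_geometry()) {
  metadata <- read.csv(file.path(dir, "metadata.csv"),
                       stringsAsFactors = FALSE)
  resp <- read.csv(file.path(dir, "respirometry.csv"),
                   stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path))
    jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  tdir <- file.path(dir, "trajectories")
  trajectories <- NULL
  if (dir.exists(tdir)) {
    files <- list.files(tdir, pattern = "\\.csv$", full.names = TRUE)
    trajectories <- lapply(files, read_trajectory_csv, geometry = geometry)
    names(trajectories) <- vapply(trajectories, `[[`, "", "fish_id")
  }
  structure(list(metadata = metadata, trajectories = trajectories,
                 respirometry = resp, ground_truth = ground_truth,
                 config = NULL),
            class = "cohort")
}
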