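#' Simulation configuration for synthetic dyad datasets
#'
#' Bundles every knob of the synthetic-data generator: the imaging geometry
#' (regions, runs, volumes, trimming), the dyad-level shared-signal range,
#' and the generative model for the behavioral outcomes. Defaults follow the
#' study design the package targets: 268 functional parcels, four ~10-minute
#' runs (320 volumes at a 2 s TR, 21 initial volumes trimmed, video ending at
#' volume 300), eight confederates shared across participants, and additive
#' standardized effects of neural similarity and trait empathy on the
#' communication-game distance with perceived quality driven almost entirely
#' by perceived similarity.
#'
#' @param n_dyads number of participant-confederate pairs.
#' @param n_confederates number of distinct confederates (default 8);
#'   participants are assigned round-robin, and each confederate carries a
#'   fixed offset so the "confederate" covariate explains real variance.
#' @param n_regions number of atlas parcels (default 268).
#' @param n_runs runs per subject (default 4).
#' @param volumes_per_run volumes acquired per run (default 320).
#' @param trim_volumes initial volumes discarded per run (default 21).
#' @param video_end_volume last volume of stimulus per run; later volumes are
#'   discarded (default 300). May be a scalar or one value per run.
#' @param tr repetition time in seconds, used only to report minutes of data
#'   (default 2).
#' @param isc_range length-2 range in `[0, 1)` from which each dyad's
#'   shared-signal fraction is drawn uniformly.
#' @param effect_sizes named numeric vector of standardized coefficients for
#'   the communicative-success generative model; names must be predictor
#'   columns (or `whole_brain` for neural similarity).
#' @param quality_effects same, for the perceived-quality latent variable.
#' @param noise_sd residual SD (standardized units) of the game-distance model.
#' @param quality_noise_sd residual SD of the quality latent.
#' @param perceived_coupling standardized coupling between true neural
#'   similarity and the perceived-similarity item; near zero by default,
#'   since perceived and neural similarity are modelled as distinct signals.
#' @param confederate_sd SD of the per-confederate offset (standardized units).
#' @param distance_baseline mean game distance on the 0-100 scale.
#' @param distance_scale points of game distance per standardized unit; the
#'   Bayes-factor analyses are scale-invariant, so this only makes the
#'   simulated 0-100 values realistic.
#' @param ar_phi AR(1) coefficient of the simulated BOLD series.
#' @param dropout_prob per-run probability that a participant's run is flagged
#'   bad (e.g. sleep) and removed.
#' @param seed master seed; every stage derives its own sub-stream from it.
#' @return a `simulation_config` list, validated.
#' @export
simulation_config <- function(n_dyads = 60,
                              n_confederates = 8,
                              n_regions = 268,
                              n_runs = 4,
                              volumes_per_run = 320,
                              trim_volumes = 21,
                              video_end_volume = 300,
                              tr = 2,
                              isc_range = c(0.01, 0.3),
                              effect_sizes = c(whole_brain = 0.5, iri = 0.5),
                              quality_effects = c(perceived_similarity = 0.7,
                                                  mrms = 0.15),
                              noise_sd = 1,
                              quality_noise_sd = 0.7,
                              perceived_coupling = 0,
                              confederate_sd = 0.5,
                              distance_baseline = 30,
                              distance_scale = 10,
                              ar_phi = 0.4,
                              dropout_prob = 0.05,
                              seed = 1L) {
  cfg <- list(n_dyads = as.integer(n_dyads),
              n_confederates = as.integer(n_confederates),
              n_regions = as.integer(n_regions),
              n_runs = as.integer(n_runs),
              volumes_per_run = as.integer(volumes_per_run),
              trim_volumes = as.integer(trim_volumes),
              video_end_volume = as.integer(video_end_volume),
              tr = as.numeric(tr),
              isc_range = as.numeric(isc_range),
              effect_sizes = effect_sizes,
              quality_effects = quality_effects,
              noise_sd = as.numeric(noise_sd),
              quality_noise_sd = as.numeric(quality_noise_sd),
              perceived_coupling = as.numeric(perceived_coupling),
              confederate_sd = as.numeric(confederate_sd),
              distance_baseline = as.numeric(distance_baseline),
              distance_scale = as.numeric(distance_scale),
              ar_phi = as.numeric(ar_phi),
              dropout_prob = as.numeric(dropout_prob),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_dyads >= 1, cfg$n_confederates >= 1, cfg$n_regions >= 1,
            cfg$n_runs >= 1, cfg$volumes_per_run >= 1, cfg$trim_volumes >= 0,
            cfg$noise_sd >= 0, cfg$quality_noise_sd >= 0)
  if (cfg$n_confederates > cfg$n_dyads)
    stop("n_confederates (", cfg$n_confederates,
         ") must not exceed n_dyads (", cfg$n_dyads, ")")
  if (length(cfg$isc_range) != 2L || cfg$isc_range[1] > cfg$isc_range[2] ||
      any(cfg$isc_range < 0) || any(cfg$isc_range >= 1))
    stop("isc_range must be an ordered pair inside [0, 1)")
  if (any(cfg$video_end_volume <= cfg$trim_volumes))
    stop("video_end_volume (", paste(cfg$video_end_volume, collapse = ","),
         ") must exceed trim_volumes (", cfg$trim_volumes, ")")
  if (any(cfg$video_end_volume > cfg$volumes_per_run))
    stop("video_end_volume must be <= volumes_per_run")
  if (cfg$dropout_prob < 0 || cfg$dropout_prob > 1)
    stop("dropout_prob must lie in [0, 1]")
  invisible(cfg)
}

#' Simulate one dyad's paired BOLD parcel timecourses and motion traces
#'
#' Both partners share a latent stimulus-driven component in every region;
#' the participant's signal is `sqrt(dyad_isc) * shared +
#' sqrt(1 - dyad_isc) * idiosyncratic`, and the confederate gets the same
#' shared component mixed with an independent idiosyncratic part, so the
#' expected region-wise Pearson correlation between partners equals
#' `dyad_isc`. All components are stationary unit-variance AR(1) series.
#' Framewise-displacement traces are nonnegative with occasional spikes and
#' are independent between partners.
#'
#' @param config a [simulation_config()].
#' @param dyad_isc shared-signal fraction in `[0, 1)`.
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return list with elements `participant`, `confederate` (each a list of
#'   per-run volumes x regions matrices) and `fd` (list with per-run
#'   nonnegative FD vectors for `participant` and `confederate`).
#' @export
simulate_bold_pair <- function(config, dyad_isc, seed) {
  if (!is.numeric(dyad_isc) || length(dyad_isc) != 1L || is.na(dyad_isc) ||
      dyad_isc < 0 || dyad_isc >= 1)
    stop("dyad_isc must be a single value in [0, 1); got ", format(dyad_isc))
  nv <- config$volumes_per_run
  k  <- config$n_regions
  phi <- config$ar_phi
  with_seed(seed, {
    part <- conf <- vector("list", config$n_runs)
    fd_p <- fd_c <- vector("list", config$n_runs)
    w_sh <- sqrt(dyad_isc)
    w_id <- sqrt(1 - dyad_isc)
    for (r in seq_len(config$n_runs)) {
      shared <- ar1_matrix(nv, k, phi)
      part[[r]] <- w_sh * shared + w_id * ar1_matrix(nv, k, phi)
      conf[[r]] <- w_sh * shared + w_id * ar1_matrix(nv, k, phi)
      fd_p[[r]] <- simulate_fd_trace(nv)
      fd_c[[r]] <- simulate_fd_trace(nv)
    }
    list(participant = part, confederate = conf,
         fd = list(participant = fd_p, confederate = fd_c))
  })
}

# low-motion baseline with sparse spikes, as in typical FD traces
simulate_fd_trace <- function(nv, base_mean = 0.12, base_sd = 0.04,
                              spike_prob = 0.03, spike_scale = 0.5) {
  base <- abs(stats::rnorm(nv, base_mean, base_sd))
  spikes <- stats::rbinom(nv, 1L, spike_prob) * stats::rexp(nv, 1 / spike_scale)
  base + spikes
}

#' Simulate trait questionnaires for participants and confederates
#'
#' Draws plausible totals for the trait measures (IRI, mind-reading
#' motivation, emotion-recognition accuracy, empathic accuracy) and
#' item-level Likert responses for the personality mini-markers (40 items,
#' 1-9) and avocation interests (20 items, 1-5), from which item-level
#' partner similarity can be scored. Confederate item responses are fixed
#' per confederate, as each confederate answers once.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `participants` (data frame of ids and trait totals),
#'   `participant_items`, `confederate_items` (lists with `big_five` and
#'   `avocation` response matrices, rows = subjects).
#' @export
simulate_traits <- function(config, seed) {
  n <- config$n_dyads
  m <- config$n_confederates
  with_seed(seed, {
    participants <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      iri  = pmin(pmax(round(stats::rnorm(n, 65, 12)), 0), 112),
      mrms = pmin(pmax(round(stats::rnorm(n, 55, 10)), 13), 91),
      cerf = pmin(pmax(round(stats::rnorm(n, 75, 8)), 0), 100),
      empathic_accuracy = pmin(pmax(stats::rnorm(n, 0.5, 0.15), -1), 1)
    )
    likert <- function(nsub, nitem, lo, hi)
      matrix(pmin(pmax(round(stats::rnorm(nsub * nitem,
                                          (lo + hi) / 2, (hi - lo) / 4)),
                       lo), hi),
             nrow = nsub)
    list(participants = participants,
         participant_items = list(big_five = likert(n, 40L, 1L, 9L),
                                  avocation = likert(n, 20L, 1L, 5L)),
         confederate_items = list(big_five = likert(m, 40L, 1L, 9L),
                                  avocation = likert(m, 20L, 1L, 5L)))
  })
}

#' Simulate interaction outcomes from traits and dyad similarity
#'
#' Generates the two interaction-success outcomes from a linear model in
#' standardized predictors. Game distance is
#' `baseline - scale * (sum_k beta_k z_k) + scale * (confederate offset +
#' noise)`, clipped to `[0, 100]` (larger coefficients therefore mean
#' *smaller* distance, i.e. more success). The perceived-similarity item is
#' an ordinal 1-5 rating only weakly coupled (default: uncoupled) to neural
#' similarity, and perceived quality is a 3-15 composite discretized from a
#' latent driven by perceived similarity plus a small mind-reading-motivation
#' term.
#'
#' @param traits data frame with `participant_id` and the predictor columns
#'   named in `config$effect_sizes` / `config$quality_effects` (except
#'   `whole_brain` and `perceived_similarity`, which are supplied or
#'   generated here).
#' @param similarity per-dyad scalar neural similarity (one per row of
#'   `traits`), used both as the `whole_brain` predictor and as the coupling
#'   source for perceived similarity.
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param confederate_id optional character vector assigning each participant
#'   a confederate; defaults to round-robin over `config$n_confederates`.
#' @return an outcome table: one row per participant with
#'   `communicative_distance`, `communicative_success` (= minus distance),
#'   `perceived_quality`, `perceived_similarity`, `whole_brain`, all trait
#'   columns and `confederate_id`.
#' @export
simulate_outcomes <- function(traits, similarity, config, seed,
                              confederate_id = NULL) {
  n <- nrow(traits)
  stopifnot(length(similarity) == n)
  if (is.null(confederate_id)) {
    confederate_id <- sprintf("C%02d",
                              ((seq_len(n) - 1L) %% config$n_confederates) + 1L)
  }
  tab <- traits
  tab$whole_brain <- as.numeric(similarity)
  tab$confederate_id <- confederate_id

  known <- c(names(tab), "perceived_similarity")
  for (nm in list(config$effect_sizes, config$quality_effects)) {
    bad <- setdiff(names(nm), known)
    if (length(bad))
      stop("unknown predictor key(s) in effect sizes: ",
           paste(bad, collapse = ", "))
  }

  with_seed(seed, {
    confs <- sort(unique(confederate_id))
    offsets <- stats::setNames(stats::rnorm(length(confs),
                                            sd = config$confederate_sd), confs)

    # perceived similarity: ordinal 1-5, weakly coupled to neural similarity
    lat_ps <- config$perceived_coupling * zscore(tab$whole_brain) +
      stats::rnorm(n)
    lat_sd <- stats::sd(lat_ps)
    if (!is.finite(lat_sd) || lat_sd == 0) lat_sd <- 1
    tab$perceived_similarity <-
      as.integer(cut(lat_ps, breaks = stats::qnorm(seq(0, 1, length.out = 6),
                                                   sd = lat_sd),
                     labels = FALSE, include.lowest = TRUE))

    lin <- rep(0, n)
    for (nm in names(config$effect_sizes))
      lin <- lin + config$effect_sizes[[nm]] * zscore(tab[[nm]])
    dist <- config$distance_baseline -
      config$distance_scale * lin +
      config$distance_scale * offsets[confederate_id] +
      config$distance_scale * stats::rnorm(n, sd = config$noise_sd)
    tab$communicative_distance <- pmin(pmax(dist, 0), 100)
    tab$communicative_success <- -tab$communicative_distance

    latq <- rep(0, n)
    for (nm in names(config$quality_effects))
      latq <- latq + config$quality_effects[[nm]] * zscore(tab[[nm]])
    latq <- latq + offsets[confederate_id] +
      stats::rnorm(n, sd = config$quality_noise_sd)
    tab$perceived_quality <- as.integer(pmin(pmax(round(9 + 2.5 * latq), 3L),
                                             15L))
    tab
  })
}

#' Simulate a complete dyad dataset (imaging + behavior)
#'
#' Runs every generator stage off one master seed: dyad manifest with
#' scanner-group pairing and run dropouts, paired BOLD parcel timecourses and
#' FD traces (optional), questionnaire traits and item responses, item-level
#' partner similarities, interaction outcomes, and trial-level communication
#' game data consistent with the generated distances.
#'
#' @param config a [simulation_config()].
#' @param include_bold simulate the imaging component (set `FALSE` for
#'   behavior-only studies; much faster).
#' @return list with `config`, `manifest`, `dyad_isc` (true shared-signal
#'   fractions), `bold` (per-dyad output of [simulate_bold_pair()], or NULL),
#'   `traits`, `outcomes`, `trials`.
#' @export
simulate_dyad_dataset <- function(config, include_bold = TRUE) {
  validate_simulation_config(config)
  n <- config$n_dyads
  pid <- sprintf("P%03d", seq_len(n))
  cid <- sprintf("C%02d", ((seq_len(n) - 1L) %% config$n_confederates) + 1L)
  # confederates split across scanner systems; partners always share a system
  conf_group <- ifelse(seq_len(config$n_confederates) <=
                         ceiling(config$n_confederates / 2), "trio", "prisma")
  scanner_group <- conf_group[((seq_len(n) - 1L) %% config$n_confederates) + 1L]

  dyad_isc <- with_seed(derive_seed(config$seed, "isc"),
                        stats::runif(n, config$isc_range[1],
                                     config$isc_range[2]))

  bad_runs <- with_seed(derive_seed(config$seed, "dropout"), {
    lapply(seq_len(n), function(i) {
      which(stats::rbinom(config$n_runs, 1L, config$dropout_prob) == 1L)
    })
  })
  names(bad_runs) <- pid

  manifest <- data.frame(participant_id = pid, confederate_id = cid,
                         scanner_group = scanner_group,
                         retained_runs = vapply(seq_len(n), function(i)
                           paste(seq_len(config$n_runs), collapse = ";"), ""),
                         excluded = FALSE, exclusion_reason = "",
                         stringsAsFactors = FALSE)
  manifest <- apply_run_exclusions(manifest, bad_runs, config = config)

  traits <- simulate_traits(config, derive_seed(config$seed, "traits"))
  tr <- traits$participants
  conf_idx <- match(cid, sprintf("C%02d", seq_len(config$n_confederates)))
  tr$big_five_sim <- vapply(seq_len(n), function(i)
    item_similarity(traits$participant_items$big_five[i, ],
                    traits$confederate_items$big_five[conf_idx[i], ]),
    numeric(1))
  tr$avocation_sim <- vapply(seq_len(n), function(i)
    item_similarity(traits$participant_items$avocation[i, ],
                    traits$confederate_items$avocation[conf_idx[i], ]),
    numeric(1))

  outcomes <- simulate_outcomes(tr, dyad_isc, config,
                                derive_seed(config$seed, "outcomes"),
                                confederate_id = cid)
  outcomes$scanner_group <- scanner_group

  trials <- simulate_trials(outcomes$communicative_distance, pid,
                            derive_seed(config$seed, "trials"))
  # the trial realization quantizes distance to multiples of 1/15;
  # keep the outcome table consistent with its own trial-level data
  realized <- vapply(split(trials, trials$participant_id), function(d)
    mean(abs(d$guess[d$role == "guesser"] - d$bullseye[d$role == "guesser"])),
    numeric(1))
  outcomes$communicative_distance <- as.numeric(realized[pid])
  outcomes$communicative_success <- -outcomes$communicative_distance

  bold <- NULL
  if (include_bold) {
    bold <- lapply(seq_len(n), function(i)
      simulate_bold_pair(config, dyad_isc[i],
                         derive_seed(config$seed, "bold", pid[i])))
    names(bold) <- pid
  }

  structure(list(config = config, manifest = manifest, dyad_isc = dyad_isc,
                 bold = bold, traits = traits, outcomes = outcomes,
                 trials = trials),
            class = "dyad_dataset")
}

#' Generate trial-level communication-game data realizing given distances
#'
#' Emits 30 trials per participant (15 as guesser, 15 as clue giver, roles
#' alternating in blocks) whose guesser-trial mean absolute error equals the
#' requested distance up to 1/15-point quantization; clue-giver trials carry
#' the confederate's guesses and are ignored by scoring.
#'
#' @param distance numeric vector of target mean distances (0-100).
#' @param participant_id character vector of ids, same length.
#' @param seed integer seed.
#' @param n_guess guesser trials per participant (default 15).
#' @return long data frame: `participant_id`, `trial_index`, `role`,
#'   `bullseye`, `guess`.
#' @export
simulate_trials <- function(distance, participant_id, seed, n_guess = 15L) {
  stopifnot(length(distance) == length(participant_id))
  with_seed(seed, {
    out <- lapply(seq_along(distance), function(i) {
      d <- min(max(distance[i], 0), 100)
      base <- floor(d)
      n_hi <- round((d - base) * n_guess)
      err <- base + as.integer(seq_len(n_guess) <= n_hi)
      err <- sample(pmin(err, 100L))
      # bullseyes are placed so that at least one guess direction stays
      # inside [0, 100] for the trial's error magnitude
      g_bull <- vapply(err, function(e) {
        pool <- if (e <= 50L) 0:100 else c(0:(100L - e), e:100L)
        pool[sample.int(length(pool), 1L)]
      }, integer(1))
      sgn <- ifelse(stats::runif(n_guess) < 0.5, -1L, 1L)
      guess <- g_bull + sgn * err
      flip <- guess < 0 | guess > 100
      guess[flip] <- g_bull[flip] - sgn[flip] * err[flip]
      c_bull <- sample(0:100, n_guess, replace = TRUE)
      conf_guess <- pmin(pmax(c_bull + round(stats::rnorm(n_guess, 0, 12)),
                              0), 100)
      data.frame(participant_id = participant_id[i],
                 trial_index = seq_len(2L * n_guess),
                 role = rep(c("guesser", "clue_giver"), each = n_guess),
                 bullseye = c(g_bull, c_bull),
                 guess = c(guess, conf_guess),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Write a synthetic dyad dataset to disk as a fixture tree
#'
#' Emits, under `out_dir`: per-subject-per-run 4D NIfTI parcel "images" plus
#' a matching 3D integer label atlas (each parcel is a small block of voxels
#' all carrying the region timecourse, so parcel extraction reproduces the
#' generating means exactly), fMRIprep-dialect confounds TSVs with a
#' `framewise_displacement` column, behavioral CSVs (traits, trials,
#' outcomes), the dyad manifest CSV and the simulation config as JSON.
#'
#' @param dataset a [simulate_dyad_dataset()] result with `bold` included.
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param voxels_per_parcel voxels per atlas parcel (default 3).
#' @return (invisibly) a character vector of written files.
#' @export
write_fixture <- function(dataset, out_dir, overwrite = FALSE,
                          voxels_per_parcel = 3L) {
  if (is.null(dataset) || is.null(dataset$outcomes) ||
      nrow(dataset$outcomes) == 0L)
    stop("dataset is empty; nothing to write")
  if (is.null(dataset$bold))
    stop("dataset has no BOLD component; rerun simulate_dyad_dataset with ",
         "include_bold = TRUE")
  if (dir.exists(out_dir) && length(list.files(out_dir, all.files = TRUE,
                                               no.. = TRUE)) > 0L &&
      !overwrite)
    stop("output directory ", out_dir,
         " exists and is not empty; use overwrite = TRUE")
  dir.create(file.path(out_dir, "bold"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "confounds"), showWarnings = FALSE)
  cfg <- dataset$config
  k <- cfg$n_regions
  v <- as.integer(voxels_per_parcel)
  written <- character(0)

  atlas <- array(0L, dim = c(k, v, 1L))
  for (j in seq_len(v)) atlas[, j, 1L] <- seq_len(k)
  atlas_file <- file.path(out_dir, "atlas.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(atlas), atlas_file)
  written <- c(written, atlas_file)

  write_run <- function(mat, fd, subject, run) {
    nt <- nrow(mat)
    arr <- array(0, dim = c(k, v, 1L, nt))
    tm <- t(mat)                      # regions x time
    for (j in seq_len(v)) arr[, j, 1L, ] <- tm
    bf <- file.path(out_dir, "bold",
                    sprintf("sub-%s_run-%d_bold.nii.gz", subject, run))
    RNifti::writeNifti(RNifti::asNifti(arr), bf)
    cf <- file.path(out_dir, "confounds",
                    sprintf("sub-%s_run-%d_confounds.tsv", subject, run))
    utils::write.table(data.frame(framewise_displacement = fd),
                       cf, sep = "\t", row.names = FALSE, quote = FALSE)
    c(bf, cf)
  }

  for (i in seq_len(nrow(dataset$manifest))) {
    pid <- dataset$manifest$participant_id[i]
    cid <- dataset$manifest$confederate_id[i]
    pair <- dataset$bold[[pid]]
    for (r in seq_len(cfg$n_runs)) {
      written <- c(written,
                   write_run(pair$participant[[r]], pair$fd$participant[[r]],
                             pid, r),
                   write_run(pair$confederate[[r]], pair$fd$confederate[[r]],
                             paste0(cid, "x", pid), r))
    }
  }

  wcsv <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    f
  }
  written <- c(written,
               wcsv(dataset$manifest, "manifest.csv"),
               wcsv(dataset$traits$participants, "traits.csv"),
               wcsv(dataset$trials, "trials.csv"),
               wcsv(dataset$outcomes, "outcomes.csv"))
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_file, auto_unbox = TRUE, digits = NA)
  invisible(c(written, cfg_file))
}
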