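test_that("simulation config enforces its invariants", {
  expect_error(simulation_config(isc_range = c(0.5, 0.2)), "isc_range")
  expect_error(simulation_config(isc_range = c(0, 1)), "isc_range")
  expect_error(simulation_config(video_end_volume = 10, trim_volumes = 21),
               "video_end_volume")
  expect_error(simulation_config(n_dyads = 4, n_confederates = 8),
               "n_confederates")
  expect_error(simulation_config(dropout_prob = 1.2), "dropout_prob")
})

test_that("simulate_bold_pair rejects out-of-range shared-signal fractions", {
  cfg <- simulation_config(n_dyads = 2, n_confederates = 1, n_regions = 3,
                           n_runs = 1, volumes_per_run = 50,
                           video_end_volume = 40)
  expect_error(simulate_bold_pair(cfg, -0.1, 1), "dyad_isc")
  expect_error(simulate_bold_pair(cfg, 1.0, 1), "dyad_isc")
})

test_that("identical seed and config give bit-identical BOLD output", {
  cfg <- simulation_config(n_dyads = 2, n_confederates = 1, n_regions = 4,
                           n_runs = 2, volumes_per_run = 80,
                           video_end_volume = 70)
  a <- simulate_bold_pair(cfg, 0.3, seed = 99)
  b <- simulate_bold_pair(cfg, 0.3, seed = 99)
  expect_identical(a, b)
  c <- simulate_bold_pair(cfg, 0.3, seed = 100)
  expect_false(identical(a$participant[[1]], c$participant[[1]]))
})

test_that("partner correlation tracks the configured shared-signal fraction", {
  nt <- 2000L
  cfg0 <- simulation_config(n_dyads = 2, n_confederates = 1, n_regions = 20,
                            n_runs = 1, volumes_per_run = nt,
                            video_end_volume = nt, trim_volumes = 0)
  pair <- simulate_bold_pair(cfg0, 0, seed = 5)
  r0 <- diag(cor(pair$participant[[1]], pair$confederate[[1]]))
  expect_lt(abs(mean(r0)), 3 / sqrt(nt))

  nt <- 10000L
  cfg99 <- simulation_config(n_dyads = 2, n_confederates = 1, n_regions = 5,
                             n_runs = 1, volumes_per_run = nt,
                             video_end_volume = nt, trim_volumes = 0)
  pair <- simulate_bold_pair(cfg99, 0.99, seed = 6)
  r99 <- diag(cor(pair$participant[[1]], pair$confederate[[1]]))
  expect_true(all(abs(r99 - 0.99) < 0.02))
})

test_that("FD traces are nonnegative", {
  cfg <- simulation_config(n_dyads = 2, n_confederates = 1, n_regions = 2,
                           n_runs = 3, volumes_per_run = 100,
                           video_end_volume = 90)
  pair <- simulate_bold_pair(cfg, 0.2, seed = 2)
  expect_true(all(unlist(pair$fd) >= 0))
})

test_that("zero effects and zero noise give identical outcomes within confederate", {
  cfg <- simulation_config(n_dyads = 24, n_confederates = 4,
                           effect_sizes = numeric(0),
                           quality_effects = numeric(0),
                           noise_sd = 0, quality_noise_sd = 0)
  traits <- simulate_traits(cfg, 1)$participants
  tab <- simulate_outcomes(traits, runif(24), cfg, seed = 3)
  for (cid in unique(tab$confederate_id)) {
    sub <- tab[tab$confederate_id == cid, ]
    expect_equal(length(unique(sub$communicative_distance)), 1L)
    expect_equal(length(unique(sub$perceived_quality)), 1L)
  }
})

test_that("a positive similarity effect induces a negative similarity-distance correlation", {
  cfg <- simulation_config(n_dyads = 1000, n_confederates = 8,
                           effect_sizes = c(whole_brain = 0.5),
                           quality_effects = c(perceived_similarity = 0.7))
  traits <- simulate_traits(cfg, 2)$participants
  sim <- runif(1000)
  tab <- simulate_outcomes(traits, sim, cfg, seed = 4)
  expect_lt(cor(sim, tab$communicative_distance), 0)
})

test_that("unknown predictor keys in effect sizes are rejected", {
  cfg <- simulation_config(n_dyads = 10, n_confederates = 2,
                           effect_sizes = c(not_a_column = 0.5))
  traits <- simulate_traits(cfg, 1)$participants
  expect_error(simulate_outcomes(traits, runif(10), cfg, seed = 1),
               "unknown predictor")
})

test_that("outcomes respect their ranges and the generator is reproducible", {
  cfg <- simulation_config(n_dyads = 200, n_confederates = 8,
                           distance_baseline = 5, distance_scale = 40)
  traits <- simulate_traits(cfg, 7)$participants
  sim <- runif(200)
  a <- simulate_outcomes(traits, sim, cfg, seed = 8)
  b <- simulate_outcomes(traits, sim, cfg, seed = 8)
  expect_identical(a, b)
  expect_true(all(a$communicative_distance >= 0 &
                    a$communicative_distance <= 100))
  expect_true(all(a$perceived_quality >= 3 & a$perceived_quality <= 15))
  expect_true(all(a$perceived_similarity %in% 1:5))
})

test_that("dataset-level exclusion bookkeeping follows the >2 bad runs rule", {
  cfg <- simulation_config(n_dyads = 40, n_confederates = 4, n_regions = 2,
                           n_runs = 4, volumes_per_run = 30,
                           video_end_volume = 28, trim_volumes = 2,
                           dropout_prob = 0.4, seed = 21)
  ds <- simulate_dyad_dataset(cfg, include_bold = FALSE)
  man <- ds$manifest
  n_retained <- lengths(strsplit(man$retained_runs, ";"))
  expect_identical(man$excluded, n_retained < cfg$n_runs - 2L)
  expect_identical(man$n_runs_used, n_retained)
})

test_that("trial realizations reproduce the outcome table's distances", {
  cfg <- simulation_config(n_dyads = 12, n_confederates = 3, seed = 31)
  ds <- simulate_dyad_dataset(cfg, include_bold = FALSE)
  for (i in seq_len(nrow(ds$outcomes))) {
    tr <- ds$trials[ds$trials$participant_id ==
                      ds$outcomes$participant_id[i], ]
    sc <- score_game(tr)
    expect_equal(sc$communicative_distance,
                 ds$outcomes$communicative_distance[i])
  }
  expect_true(all(ds$trials$guess >= 0 & ds$trials$guess <= 100))
  expect_true(all(ds$trials$bullseye >= 0 & ds$trials$bullseye <= 100))
})

test_that("write_fixture emits a complete, round-trippable tree", {
  cfg <- tiny_imaging_config()
  ds <- simulate_dyad_dataset(cfg)
  out <- file.path(tempdir(), "fixture-tree")
  unlink(out, recursive = TRUE)
  write_fixture(ds, out)

  bold_files <- list.files(file.path(out, "bold"))
  # 2 dyads x 2 subjects (participant + confederate) x 2 runs
  expect_length(bold_files, 8L)
  expect_length(list.files(file.path(out, "confounds")), 8L)
  expect_true(file.exists(file.path(out, "atlas.nii.gz")))
  expect_true(file.exists(file.path(out, "manifest.csv")))

  # read-back: parcel extraction on the written atlas reproduces the
  # generating region means
  atlas <- RNifti::readNifti(file.path(out, "atlas.nii.gz"))
  pid <- ds$manifest$participant_id[1]
  bold <- RNifti::readNifti(file.path(out, "bold",
                                      sprintf("sub-%s_run-1_bold.nii.gz", pid)))
  tc <- extract_parcel_timecourses(bold, atlas)
  expect_equal(dim(tc), dim(ds$bold[[pid]]$participant[[1]]))
  expect_equal(as.numeric(tc), as.numeric(ds$bold[[pid]]$participant[[1]]),
               tolerance = 1e-6)

  cf <- read.delim(file.path(out, "confounds",
                             sprintf("sub-%s_run-1_confounds.tsv", pid)))
  expect_equal(cf$framewise_displacement, ds$bold[[pid]]$fd$participant[[1]],
               tolerance = 1e-12)

  # refuses to clobber a non-empty directory unless told to
  expect_error(write_fixture(ds, out), "not empty")
  expect_silent(write_fixture(ds, out, overwrite = TRUE))
})

test_that("write_fixture rejects empty or incomplete datasets without partial writes", {
  out <- file.path(tempdir(), "fixture-empty")
  unlink(out, recursive = TRUE)
  expect_error(write_fixture(list(), out), "empty")
  cfg <- tiny_imaging_config()
  ds <- simulate_dyad_dataset(cfg, include_bold = FALSE)
  expect_error(write_fixture(ds, out), "BOLD")
  expect_false(dir.exists(out))
})
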