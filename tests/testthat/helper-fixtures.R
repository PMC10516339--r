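# shared generators for the test suite; everything is built in code at test
# time, keyed off explicit seeds

# a design with an exact target R^2: project a draft outcome onto the column
# space of X and recombine fitted and residual parts with the right weights
design_with_r2 <- function(n, p, R2, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(p))
  y0 <- rnorm(n)
  fit <- lm(y0 ~ ., data = cbind(y0 = y0, df))
  f <- fitted(fit) - mean(fitted(fit))
  r <- resid(fit)
  y <- if (R2 == 0) r / sqrt(sum(r^2))
       else sqrt(R2) * f / sqrt(sum(f^2)) + sqrt(1 - R2) * r / sqrt(sum(r^2))
  df$y <- y
  design_spec(df, "y", paste0("x", seq_len(p)))
}

# a random regression instance with genuine signal, for oracle-equivalence
# checks
random_instance <- function(n, p, seed, beta_scale = 0.4) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(df) <- paste0("x", seq_len(p))
  beta <- rnorm(p, sd = beta_scale)
  df$y <- as.matrix(df) %*% beta + rnorm(n)
  design_spec(df, "y", paste0("x", seq_len(p)))
}

# outcome table for pipeline tests: traits plus nuisance imaging covariates,
# outcomes generated by the package's own generator under `config`
make_outcome_table <- function(config, seed) {
  traits <- simulate_traits(config, derive_seed_t(seed, "traits"))$participants
  n <- nrow(traits)
  set.seed(derive_seed_t(seed, "nuisance"))
  similarity <- runif(n, config$isc_range[1], config$isc_range[2])
  tab <- simulate_outcomes(traits, similarity, config,
                           derive_seed_t(seed, "outcomes"))
  tab$n_runs_used <- sample(2:4, n, replace = TRUE)
  tab$fd_similarity <- runif(n, -0.2, 0.4)
  tab
}

derive_seed_t <- function(master, label) dyadisc:::derive_seed(master, label)

# data with configurable main effects and interaction between two
# continuous measures, confederate offsets included
make_interaction_data <- function(n, b_a, b_b, b_ab, seed,
                                  n_confederates = 8, noise_sd = 1) {
  set.seed(seed)
  conf <- sprintf("C%02d", ((seq_len(n) - 1L) %% n_confederates) + 1L)
  offs <- setNames(rnorm(n_confederates, sd = 0.5),
                   sprintf("C%02d", seq_len(n_confederates)))
  a <- rnorm(n); b <- rnorm(n)
  za <- as.numeric(scale(a)); zb <- as.numeric(scale(b))
  y <- b_a * za + b_b * zb + b_ab * za * zb + offs[conf] +
    rnorm(n, sd = noise_sd)
  data.frame(y = y, A = a, B = b, confederate_id = conf,
             stringsAsFactors = FALSE)
}

# tiny imaging fixture config used by the write/extract round-trip tests
tiny_imaging_config <- function(seed = 11) {
  simulation_config(n_dyads = 2, n_confederates = 2, n_regions = 10,
                    n_runs = 2, volumes_per_run = 60, video_end_volume = 50,
                    trim_volumes = 21, dropout_prob = 0, seed = seed)
}
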