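# Shared fixtures and independent oracles used across the suite.

# Coerce a plain data frame of feature columns + behaviour into the
# feature_matrix shape the modelling functions expect.
as_feature_matrix <- function(df) {
  class(df) <- c("feature_matrix", "data.frame")
  df
}

# Naive per-sample loop implementation of the fourteen movement metrics,
# written directly from their defining sums; the vectorized implementation
# must agree with this.
naive_features <- function(m) {
  T_n <- nrow(m)
  x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
  ax <- ay <- az <- 0
  for (t in 1:T_n) {
    ax <- ax + x[t]; ay <- ay + y[t]; az <- az + z[t]
  }
  ax <- ax / T_n; ay <- ay / T_n; az <- az / T_n
  mv <- 0
  for (i in 1:(T_n - 1))
    mv <- mv + abs(x[i + 1] - x[i]) + abs(y[i + 1] - y[i]) + abs(z[i + 1] - z[i])
  mv <- mv / T_n
  sma <- 0
  for (t in 1:T_n) sma <- sma + abs(x[t]) + abs(y[t]) + abs(z[t])
  sma <- sma / T_n
  ai <- 0
  for (t in 1:T_n) ai <- ai + sqrt(x[t]^2 + y[t]^2 + z[t]^2)
  ai <- ai / T_n
  ent <- 0
  for (t in 1:T_n) {
    arg <- 1 + x[t] + y[t] + z[t]
    if (arg != 0) ent <- ent + arg * log(abs(arg))
  }
  ent <- ent / T_n
  en <- 0
  for (t in 1:T_n) en <- en + (x[t]^2 + y[t]^2 + z[t]^2)^2
  en <- en / T_n
  c(Ax = ax, Ay = ay, Az = az, MV = mv, SMA = sma, AI = ai,
    Entropy = ent, Energy = en,
    MaxX = max(x), MaxY = max(y), MaxZ = max(z),
    MinX = min(x), MinY = min(y), MinZ = min(z))
}

# Two-class design with one perfectly separating feature among pure noise,
# named after the canonical feature columns so ranking code runs unchanged.
planted_design <- function(n = 200, seed = 1, duplicate_planted = FALSE) {
  set.seed(seed)
  y <- rep(c("sound_walking", "lame_walking"), each = n / 2)
  planted <- ifelse(y == "lame_walking", runif(n, 2, 3), runif(n, 0, 1))
  noise <- matrix(rnorm(n * 13), n, 13)
  df <- as.data.frame(cbind(planted, noise))
  names(df) <- feature_names()
  if (duplicate_planted) {
    df$MaxX <- df$Ax  # second identical copy of the planted column
  }
  df$behaviour <- y
  as_feature_matrix(df)
}

# Random labelled Gaussian feature matrix with K classes over `feats`.
gaussian_classes <- function(n_per = 20, feats = c("Ax", "MV"), K = 3,
                             sep = 3, seed = 1,
                             classes = c("sound_grazing", "sound_walking",
                                         "lame_walking")[1:K]) {
  set.seed(seed)
  d <- length(feats)
  rows <- lapply(seq_len(K), function(k) {
    m <- matrix(rnorm(n_per * d, mean = sep * k), n_per, d)
    df <- as.data.frame(m)
    names(df) <- feats
    df$behaviour <- classes[k]
    df
  })
  as_feature_matrix(do.call(rbind, rows))
}

# Brute-force class-conditional Gaussian density evaluation (explicit solve
# and determinant), independent of predict_qda's Cholesky path.
oracle_qda_posterior <- function(model, v) {
  dens <- vapply(model$classes, function(k) {
    S <- model$cov[[k]]
    d <- length(v)
    diffv <- as.numeric(v) - model$mean[[k]]
    (2 * pi)^(-d / 2) * det(S)^(-1 / 2) *
      exp(-0.5 * as.numeric(t(diffv) %*% solve(S) %*% diffv))
  }, numeric(1))
  w <- model$prior * dens
  w / sum(w)
}

# A small balanced synthetic study segmented into epochs, cached per
# (epochs-per-class, seed, lame-grazing-overlap) so acceptance and unit
# tests can share work.
balanced_epochs <- local({
  cache <- list()
  function(per_class = 110, seed = 42, overlap_lame_grazing = FALSE) {
    key <- paste(per_class, seed, overlap_lame_grazing)
    if (!is.null(cache[[key]])) return(cache[[key]])
    counts <- setNames(rep(as.integer(per_class), 6),
                       c("sound_grazing", "sound_standing", "sound_walking",
                         "sound_lying", "lame_walking", "lame_grazing"))
    params <- list()
    if (overlap_lame_grazing) {
      sg <- default_behaviour_params("sound_grazing")
      params$lame_grazing <- behaviour_params(
        "lame_grazing", sg$gravity_orientation, sg$osc_freq_hz,
        sg$osc_amp, sg$asymmetry, sg$noise_sd)
    }
    cfg <- study_config(animals = 5, epoch_counts = counts,
                        deployments = "ear", seed = seed, params = params)
    eps <- study_epochs(generate_study(cfg), "ear")
    cache[[key]] <<- eps
    eps
  }
})
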