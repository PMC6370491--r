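# Shared fixtures, built lazily once per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# 100-node atlas used by the signal-structure and cohort tests
fix_atlas100 <- function() {
  fixture("atlas100", function() generate_atlas(100L, 8L, 3L, seed = 2L))
}

fix_atlas_small <- function() {
  fixture("atlas_small", function() generate_atlas(20L, 3L, 2L, seed = 5L))
}

# light model: small nuisance pools, used where pool size is irrelevant
fix_light_model <- function(...) {
  artifact_model(n_pool = 50L, n_csf = 8L, n_wm = 10L, ...)
}

fix_subject <- function() {
  fixture("subject_small", function() {
    coh <- generate_cohort(3L, fix_atlas_small(), artifact_model(),
                           n_frames = 120L, tr = 3, seed = 7L)
    coh$subjects[[1L]]
  })
}

fix_cohort_small <- function() {
  fixture("cohort_small", function() {
    generate_cohort(12L, fix_atlas_small(), fix_light_model(),
                    n_frames = 120L, tr = 3, seed = 9L)
  })
}

# random tiny multilayer instance with positive total weight
rand_multilayer <- function(n_max = 5L, t_max = 2L) {
  repeat {
    n <- sample(2:n_max, 1L)
    t_l <- sample(seq_len(t_max), 1L)
    layers <- lapply(seq_len(t_l), function(l) {
      a <- matrix(runif(n * n), n, n)
      a <- (a + t(a)) / 2
      a[a < 0.4] <- 0
      diag(a) <- 0
      a
    })
    if (sum(vapply(layers, sum, 0)) > 0) {
      return(suppressWarnings(
        multilayer_network(layers, omega = runif(1, 0, 2))))
    }
  }
}

# build a connectivity stack directly from prescribed z matrices
stack_from_z <- function(z_list, negative_policy = "zero") {
  t_l <- length(z_list)
  n <- nrow(z_list[[1L]])
  z <- array(0, dim = c(t_l, n, n))
  for (w in seq_len(t_l)) z[w, , ] <- z_list[[w]]
  structure(list(z = z, negative_policy = negative_policy,
                 scheme = NULL), class = "dfc_stack")
}

# two series with an exact target Pearson correlation
series_with_cor <- function(n, rho, seed = 1L) {
  set.seed(seed)
  x <- rnorm(n)
  y0 <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  y0 <- residuals(lm(y0 ~ x))
  y0 <- y0 / sd(y0)
  y <- rho * x + sqrt(1 - rho^2) * y0
  cbind(x, y)
}
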