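# helper: long observations from a label matrix restricted to given molecules
obs_of <- function(Y) labels_to_observations(Y)

test_that("MOGP with B = I and fixed noise reproduces independent single-task GPs", {
  sp <- synthetic_spec(n_molecules = 25, feature_length = 64,
                       label_missingness = c(0.1, 0.3, 0.3, 0.2), seed = 21)
  d <- generate_synthetic_dataset(sp)
  Y <- d$observations
  mo <- mogp_fit(d$features, obs_of(Y), L = diag(4), fix_L = TRUE,
                 sigma_y2 = 0.15)
  xs <- tiny_features(5, d = 64, seed = 22)
  for (t in 1:4) {
    ix <- which(!is.na(Y[, t]))
    st <- gp_fit(d$features[ix, ], Y[ix, t], sigma_f2 = 1, sigma_y2 = 0.15)
    expect_equal(predict(mo, xs, task = t)$mean, predict(st, xs)$mean,
                 tolerance = 1e-6)
  }
})

test_that("MOGP on a single observed task matches the single-task fit", {
  sp <- synthetic_spec(n_molecules = 40, feature_length = 128,
                       label_missingness = c(0, 1, 1, 1), seed = 5)
  d <- generate_synthetic_dataset(sp)
  y <- d$observations[, 1]
  g <- gp_fit(d$features, y, n_restarts = 3, seed = 1)
  m <- mogp_fit(d$features, obs_of(d$observations), n_restarts = 3, seed = 1)
  expect_equal(predict(m, d$features, task = "E_PI_PI")$mean,
               predict(g, d$features)$mean, tolerance = 0.05)
})

test_that("MOGP posterior matches a brute-force joint-Gaussian conditional on a toy set", {
  # 6 observations over 3 molecules and 3 tasks, fixed hyperparameters
  x <- tiny_features(4, d = 16, seed = 31)
  L <- diag(4); L[2, 1] <- 0.6; L[2, 2] <- 0.8; L[3, 1] <- -0.3; L[3, 3] <- 1.2
  sy2 <- 0.05
  obs <- data.frame(molecule = c(1, 1, 2, 2, 3, 3),
                    task = c("E_PI_PI", "E_N_PI", "E_PI_PI", "Z_PI_PI",
                             "E_N_PI", "Z_PI_PI"),
                    value = c(450, 330, 460, 365, 335, 350))
  fit <- mogp_fit(x, obs, L = L, fix_L = TRUE, sigma_y2 = sy2)
  for (t_star in c("E_PI_PI", "E_N_PI", "Z_PI_PI")) {
    got <- predict(fit, x[4, , drop = FALSE], task = t_star)
    # oracle: dense joint covariance over (train obs, test point) from the
    # scalar ICM kernel, conditioned by solve(); same standardisation and jitter
    ti <- match(obs$task, azogp_tasks())
    ts <- match(t_star, azogp_tasks())
    mns <- tapply(obs$value, ti, mean)[as.character(ti)]
    sds <- tapply(obs$value, ti, sd)[as.character(ti)]
    z <- (obs$value - mns) / sds
    n <- nrow(obs)
    Ktr <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      Ktr[i, j] <- icm_covariance(x[obs$molecule[i], ], x[obs$molecule[j], ],
                                  ti[i], ti[j], L)
    }
    Ktr <- Ktr + diag(sy2, n)
    Ktr <- Ktr + diag(oracle_jitter(Ktr), n)
    ks <- sapply(1:n, function(i) {
      icm_covariance(x[4, ], x[obs$molecule[i], ], ts, ti[i], L)
    })
    m_t <- mean(obs$value[ti == ts]); s_t <- sd(obs$value[ti == ts])
    mu <- drop(ks %*% solve(Ktr, z)) * s_t + m_t
    v <- (icm_covariance(x[4, ], x[4, ], ts, ts, L) -
            drop(ks %*% solve(Ktr, ks))) * s_t^2
    expect_equal(got$mean, mu, tolerance = 1e-8)
    expect_equal(got$var, v, tolerance = 1e-6)
  }
})

test_that("a task uncorrelated with the rest is unaffected by their data", {
  x <- tiny_features(12, d = 32, seed = 41)
  set.seed(41)
  Y <- matrix(NA_real_, 12, 4, dimnames = list(NULL, azogp_tasks()))
  Y[, 1] <- 420 + rnorm(12, sd = 20)
  Y[1:8, 2] <- 340 + rnorm(8, sd = 15)
  Y[1:8, 3] <- 330 + rnorm(8, sd = 15)
  # task 1 independent; tasks 2-4 mutually correlated
  L <- diag(4); L[3, 2] <- 0.9; L[4, 2] <- 0.5
  joint <- mogp_fit(x, obs_of(Y), L = L, fix_L = TRUE, sigma_y2 = 0.1)
  alone <- mogp_fit(x, obs_of(cbind(Y[, 1], NA, NA, NA)), L = L, fix_L = TRUE,
                    sigma_y2 = 0.1)
  xs <- tiny_features(3, d = 32, seed = 42)
  expect_equal(predict(joint, xs, task = 1)$mean,
               predict(alone, xs, task = 1)$mean, tolerance = 1e-8)
})

test_that("MOGP interpolates an observed (molecule, task) pair as noise vanishes", {
  x <- tiny_features(6, d = 32, seed = 51)
  set.seed(51)
  Y <- matrix(NA_real_, 6, 4, dimnames = list(NULL, azogp_tasks()))
  Y[, 1] <- 430 + rnorm(6, 20); Y[, 3] <- 350 + rnorm(6, 15)
  fit <- mogp_fit(x, obs_of(Y), L = diag(4), fix_L = TRUE, sigma_y2 = 0)
  p <- predict(fit, x, task = 3)
  expect_equal(p$mean, Y[, 3], tolerance = 0.05)
})

test_that("MOGP input contracts are enforced", {
  x <- tiny_features(5, d = 16, seed = 61)
  obs <- data.frame(molecule = 1:4, task = "E_PI_PI", value = c(1, 2, 3, 4))
  expect_error(mogp_fit(x, obs[1, , drop = FALSE]), "at least 2")
  expect_error(mogp_fit(x, transform(obs, molecule = c(1, 2, 3, 99))),
               "out of range")
  expect_error(mogp_fit(x, transform(obs, value = rep(5, 4))), "zero variance")
  fit <- mogp_fit(x, obs, L = diag(4), fix_L = TRUE, sigma_y2 = 0.1)
  expect_error(predict(fit, x, task = "NOT_A_TASK"))
  expect_error(predict(fit, x, task = "Z_N_PI"), "no training observations")
})
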