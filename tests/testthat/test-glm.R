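# Design construction and OLS fitting: HRF, boxcar convolution, modulators,
# RT regressor, drift basis, physiological regressors, motion summaries,
# confound assembly, PPI terms, and the per-ROI GLM driver.

ft100 <- frame_times(100, 1.38)

test_that("double-gamma HRF has the canonical shape", {
  h <- double_gamma_hrf()
  expect_equal(h$values[1], 0)
  expect_equal(max(h$values), 1)
  # gamma(shape 6, scale 1) has mode 5: argmax within 1 s of the delay
  expect_lte(abs(h$t[which.max(h$values)] - 6), 1)
  expect_lt(min(h$values), 0)                       # undershoot exists
  expect_error(double_gamma_hrf(peak_delay_s = -1), "positive")
})

test_that("task regressors are linear in events and identifiable", {
  hrf <- double_gamma_hrf()
  e1 <- data.frame(onset_s = 10, duration_s = 2, regressor = "a")
  e2 <- data.frame(onset_s = 14, duration_s = 2, regressor = "a")
  x1 <- build_task_regressors(e1, hrf, ft100)
  x2 <- build_task_regressors(e2, hrf, ft100)
  x12 <- build_task_regressors(rbind(e1, e2), hrf, ft100)
  expect_equal(as.vector(x12), as.vector(x1 + x2), tolerance = 1e-10)
  # zero-noise series built from the column recovers the amplitude exactly
  X <- cbind(x1, intercept = 1)
  y <- X %*% c(0.37, 5)
  fit <- fit_ols(X, as.vector(y))
  expect_equal(unname(fit$beta["a"]), 0.37, tolerance = 1e-10)
  expect_error(build_task_regressors(
    data.frame(onset_s = 1e5, duration_s = 2, regressor = "a"), hrf, ft100),
    "beyond run end")
})

test_that("parametric modulator is z-scored with the main effect retained", {
  hrf <- double_gamma_hrf()
  ev <- data.frame(onset_s = c(10, 40, 70), duration_s = 2)
  expect_error(add_parametric_modulator(ev, c(5, 5, 5), hrf, ft100),
               "zero variance")
  vals <- c(20, 50, 95)
  z <- (vals - mean(vals)) / sd(vals)
  expect_equal(sum(z), 0, tolerance = 1e-12)
  col <- add_parametric_modulator(ev, vals, hrf, ft100)
  # column equals the z-amplitude-weighted sum of single-event columns
  singles <- sapply(1:3, function(i) build_task_regressors(
    data.frame(onset_s = ev$onset_s[i], duration_s = 2, regressor = "e"),
    hrf, ft100))
  expect_equal(as.vector(col), as.vector(singles %*% z), tolerance = 1e-10)
})

test_that("RT regressor area grows with RT and flags missing RTs", {
  hrf <- double_gamma_hrf()
  short <- build_rt_regressor(data.frame(onset_s = 10, rt_s = 0.4), hrf,
                              ft100)
  long <- build_rt_regressor(data.frame(onset_s = 10, rt_s = 1.2), hrf,
                             ft100)
  expect_gt(sum(long), sum(short))
  expect_warning(build_rt_regressor(
    data.frame(onset_s = c(10, 30), rt_s = c(0.5, NA)), hrf, ft100),
    "omitted")
})

test_that("RT-amplitude coupling yields positive fitted RT betas", {
  hrf <- double_gamma_hrf()
  signs <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    onsets <- seq(8, 120, by = 14)
    rts <- runif(length(onsets), 0.3, 1.5)
    rt_col <- build_rt_regressor(data.frame(onset_s = onsets, rt_s = rts),
                                 hrf, ft100)
    item_col <- build_task_regressors(
      data.frame(onset_s = onsets, duration_s = 2, regressor = "item"),
      hrf, ft100)
    y <- 0.5 * rt_col + 0.3 * item_col + rnorm(100, 0, 0.2)
    fit <- fit_ols(cbind(item_col, rt_col, intercept = 1), as.vector(y))
    signs <- signs + (fit$beta["rt_duration"] > 0)
  }
  expect_gte(signs, 15L)  # sign test at 20 seeds
})

test_that("DCT basis is orthogonal and removes a pure drift", {
  X <- dct_basis(120)
  expect_equal(ncol(X), 12L)
  G <- crossprod(X)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-10)
  expect_error(dct_basis(10, 12), "smaller")
  # regressing out the basis removes a first-component drift exactly
  drift <- X[, 1] * 3.2
  res <- drift - X %*% qr.coef(qr(X), drift)
  expect_lt(max(abs(res)), 1e-10)
})

test_that("RETROICOR block has 18 bounded columns with zero phase at peaks", {
  ph <- make_physio(180, seed = 3)
  ft <- frame_times(120, 1.38)
  R <- retroicor_regressors(ph, ft)
  expect_equal(ncol(R), 18L)
  expect_true(all(R >= -1 & R <= 1))
  # noise-free periodic cardiac trace: phase at each peak is 0 (mod 2pi)
  ph0 <- make_physio(60, 60, jitter = 0, seed = 1)
  pks <- which(diff(sign(diff(ph0$cardiac))) < 0) + 1L
  pks <- pks[ph0$cardiac[pks] >= mean(range(ph0$cardiac))]
  phase <- aasroi:::cardiac_phase(ph0, ph0$time_s[pks])
  expect_lt(max(abs(sin(phase))), 1e-6)
  expect_error(retroicor_regressors(ph, frame_times(1000, 1.38)), "cover")
})

test_that("framewise displacement follows the 50 mm sphere convention", {
  m <- matrix(0, nrow = 5, ncol = 6)
  expect_equal(framewise_displacement(m), rep(0, 5))
  m[3, 1] <- 1                           # 1 mm x-translation step
  fd <- framewise_displacement(m)
  expect_equal(fd[3], 1)
  expect_equal(fd[4], 1)                 # stepping back counts again
  m2 <- matrix(0, nrow = 3, ncol = 6)
  m2[2, 4] <- 0.01                       # 0.01 rad rotation step
  expect_equal(framewise_displacement(m2)[2], 0.5)
})

test_that("DVARS matches the difference-image RMS", {
  y <- array(7, dim = c(4, 4, 2, 5))
  expect_equal(dvars(y), rep(0, 5))
  y2 <- y
  y2[, , , 3] <- y2[, , , 3] + 2        # constant difference image of 2
  expect_equal(dvars(y2)[3], 2)
  expect_equal(dvars(y2)[4], 2)
  set.seed(5)
  sigma <- 3
  yn <- array(rnorm(100 * 100 * 1 * 2, 0, sigma), dim = c(100, 100, 1, 2))
  expect_lt(abs(dvars(yn)[2] - sigma * sqrt(2)) / (sigma * sqrt(2)), 0.05)
})

test_that("confound block assembles 39 named columns, ventricle centered", {
  nt <- 120L
  ph <- make_physio(180, seed = 6)
  ft <- frame_times(nt, 1.38)
  motion <- matrix(rnorm(nt * 6, 0, 0.01), ncol = 6)
  X <- assemble_confounds(motion, framewise_displacement(motion),
                          rep(0.5, nt), dct_basis(nt),
                          retroicor_regressors(ph, ft),
                          rnorm(nt, 300, 4))
  expect_equal(ncol(X), 39L)   # 6 + 1 + 1 + 12 + 18 + 1
  expect_lt(abs(mean(X[, "ventricle"])), 1e-12)
  # swapping the physio block for same-width components conserves the count
  X2 <- assemble_confounds(motion, framewise_displacement(motion),
                           rep(0.5, nt), dct_basis(nt),
                           matrix(rnorm(nt * 18), ncol = 18),
                           rnorm(nt, 300, 4))
  expect_equal(ncol(X2), 39L)
  expect_error(assemble_confounds(motion[-1, ], rep(0, nt), rep(0, nt),
                                  dct_basis(nt),
                                  matrix(0, nt, 18), rep(1, nt)),
               "mismatch")
})

test_that("PPI columns are products of demeaned seed and centered terms", {
  set.seed(8)
  n <- 80
  cond <- rep(c(1, 0), each = 40)
  mem <- rep(c(0, 1), 40)
  # zero seed -> zero interactions
  z <- ppi_columns(rep(5, n), cond, mem)
  expect_equal(max(abs(z[, "ppi_condition"])), 0)
  expect_warning(ppi_columns(rnorm(n), rep(1, n), mem), "constant")
  # forward-model recovery: target = 0.5 * seed x condition + noise
  seed_ts <- rnorm(n)
  P <- ppi_columns(seed_ts, cond, mem)
  y <- 0.5 * P[, "ppi_condition"] + rnorm(n, 0, 0.1)
  fit <- fit_ols(cbind(P, intercept = 1), y)
  expect_lt(abs(fit$beta["ppi_condition"] - 0.5),
            3 * fit$se["ppi_condition"])
})

test_that("PPI beta has nominal type-I error under independence", {
  set.seed(123)
  n <- 60
  cond <- rep(c(1, 0), each = n / 2)
  mem <- rep(c(0, 1), n / 2)
  rejections <- 0L
  n_sim <- 400L
  for (i in seq_len(n_sim)) {
    P <- ppi_columns(rnorm(n), cond, mem)
    y <- rnorm(n)
    fit <- fit_ols(cbind(P, intercept = 1), y)
    t_ <- fit$beta["ppi_condition"] / fit$se["ppi_condition"]
    p <- 2 * pt(-abs(t_), fit$dof)
    rejections <- rejections + (p < 0.05)
  }
  ci <- binom.test(rejections, n_sim, 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})

test_that("OLS matches hand-solved normal equations and edge cases", {
  # 3-column toy with integer entries, solved by hand via (X'X)^-1 X'y
  X <- cbind(a = c(1, 0, 1, 2), b = c(0, 1, 1, 0), c = c(1, 1, 0, 1))
  y <- c(3, 1, 2, 5)
  beta_hand <- solve(crossprod(X), crossprod(X, y))
  fit <- fit_ols(X, y)
  expect_equal(unname(fit$beta), as.vector(beta_hand), tolerance = 1e-10)
  # exact recovery without noise
  b_star <- c(0.3, -1.2, 2.5)
  fit2 <- fit_ols(X, as.vector(X %*% b_star))
  expect_equal(unname(fit2$beta), b_star, tolerance = 1e-10)
  # y orthogonal to all columns -> beta 0
  ns <- qr.Q(qr(X), complete = TRUE)[, 4]   # orthogonal complement of col(X)
  fit3 <- fit_ols(X, ns)
  expect_equal(max(abs(fit3$beta)), 0, tolerance = 1e-10)
  # rank deficiency warns
  Xd <- cbind(X, d = X[, "a"])
  expect_warning(fit_ols(Xd, y), "rank deficient")
})

test_that("per-ROI GLM driver books one row per cell and excludes bad runs", {
  cfg <- tiny_config()
  ds <- make_dataset(cfg)
  fr <- fit_roi_glms(ds)
  b <- fr$betas
  expect_true(all(c("participant", "run", "roi", "regressor", "beta") %in%
                  names(b)))
  # one row per (participant, run, roi, non-confound regressor)
  expect_equal(anyDuplicated(b[, c("participant", "run", "roi",
                                   "regressor")]), 0L)
  expect_equal(sort(unique(b$roi)),
               sort(setdiff(names(ds$masks), "fourth_ventricle")))
  # force a run over the misclassification threshold
  ds2 <- ds
  i <- ds2$participants[[1]]$behavior$run_index == 0
  ds2$participants[[1]]$behavior$item_response_correct[i] <- FALSE
  ds2$participants[[1]]$behavior$remembered[i] <- FALSE
  fr2 <- fit_roi_glms(ds2)
  expect_false(any(fr2$betas$participant == 1 & fr2$betas$run == 0))
  expect_true(!is.null(fr2$exclusions))
})

test_that("zero-noise forward model is recovered exactly through the GLM", {
  cfg <- tiny_config(noise_sd_psc = 0, drift_amp_psc = 0,
                     physio_amp_psc = 0)
  hrf <- double_gamma_hrf()
  ft <- frame_times(cfg$n_vols_per_run, cfg$tr_s)
  ev <- data.frame(onset_s = c(15, 55, 95), duration_s = 2,
                   regressor = "item")
  X <- build_task_regressors(ev, hrf, ft)
  masks <- list(item_roi = point_mask(cfg$grid_shape, c(8, 8, 6)))
  out <- make_bold(cfg, masks, list(frame_times = ft, X = X),
                   list(item_roi = list(item = 0.42)), seed = 2)
  raw <- extract_weighted_ts(out$bold, masks$item_roi)
  # normalizing by the true baseline inverts the forward model exactly;
  # empirical-mean PSC adds a multiplicative bias of ~mean(signal)/100
  series <- 100 * raw$values / cfg$baseline - 100
  fit <- fit_ols(cbind(X, intercept = 1), series)
  expect_equal(unname(fit$beta["item"]), 0.42, tolerance = 1e-8)
  psc_fit <- fit_ols(cbind(X, intercept = 1), percent_signal_change(raw))
  expect_lt(abs(psc_fit$beta["item"] - 0.42) / 0.42, 0.005)
})

test_that("an injected SN contrast is recovered within 3 SE", {
  # binary (weight-1) SN mask so extraction composes to the identity
  cfg <- tiny_config(noise_sd_psc = 1.0, drift_amp_psc = 0,
                     physio_amp_psc = 0, n_vols_per_run = 400L)
  hrf <- double_gamma_hrf()
  ft <- frame_times(cfg$n_vols_per_run, cfg$tr_s)
  set.seed(77)
  onsets <- seq(10, max(ft) - 20, by = 12)
  cond <- rep(c("reward", "neutral"), length.out = length(onsets))
  ev <- data.frame(onset_s = onsets, duration_s = 2, regressor = cond)
  X <- build_task_regressors(ev, hrf, ft)
  d <- array(0, dim = cfg$grid_shape); d[10:12, 10:12, 5:7] <- 1
  masks <- list(SN = prob_mask(d, cfg$voxel_size_mm, "SN"))
  out <- make_bold(cfg, masks, list(frame_times = ft, X = X),
                   list(SN = list(reward = 0.2)), seed = 3)
  series <- percent_signal_change(extract_weighted_ts(out$bold, masks$SN))
  fit <- fit_ols(cbind(X, intercept = 1), series)
  contrast <- fit$beta["reward"] - fit$beta["neutral"]
  se <- sqrt(fit$se["reward"]^2 + fit$se["neutral"]^2)
  expect_lt(abs(contrast - 0.2), 3 * se)
})

test_that("a DCT drift leaves task betas untouched when modeled", {
  hrf <- double_gamma_hrf()
  ev <- data.frame(onset_s = c(12, 50, 90), duration_s = 2,
                   regressor = "item")
  Xt <- build_task_regressors(ev, hrf, ft100)
  D <- dct_basis(100)
  X <- cbind(Xt, intercept = 1, D)
  set.seed(12)
  y0 <- as.vector(Xt * 0.4) + rnorm(100, 0, 0.3)
  y1 <- y0 + D[, 2] * 5            # add a pure DCT-component drift
  b0 <- fit_ols(X, y0)$beta["item"]
  b1 <- fit_ols(X, y1)$beta["item"]
  expect_lt(abs(b0 - b1), 1e-6)
})
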