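# Shared fixtures: a tiny grid configuration that keeps module tests fast
# while exercising every pipeline path.

tiny_roi_spec <- function() {
  rs <- default_roi_spec()
  rs$cx <- c(8, 8, 4, 12, 4, 12, 4, 12, 8, 4, 12)
  rs$cy <- c(8, 5, 4, 4, 12, 12, 8, 8, 12, 8, 4)
  rs$cz <- c(6, 6, 3, 3, 3, 3, 9, 9, 9, 6, 9)
  rs$radius_mm <- rep(3, 11)
  rs
}

tiny_config <- function(...) {
  args <- list(grid_shape = c(16L, 16L, 12L), roi_spec = tiny_roi_spec(),
               n_vols_per_run = 100L, n_runs = 1L, n_participants = 2L,
               trials_per_run = 6L, seed = 11L)
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}

# A single-voxel, weight-1 mask: extraction is the identity on that voxel,
# so GLM fits recover injected betas exactly.
point_mask <- function(grid_shape, at, voxel_size_mm = c(1.5, 1.5, 1.5),
                       name = "point") {
  d <- array(0, dim = grid_shape)
  d[at[1], at[2], at[3]] <- 1
  prob_mask(d, voxel_size_mm, name)
}

# Constant-image wrapper for segmentation tests.
as_image <- function(data, voxel_size_mm = c(1, 1, 1)) {
  list(data = data, voxel_size_mm = voxel_size_mm)
}

# Simulate a beta table for one ROI directly from the group-level mixed
# model (participant random intercept + fixed condition/memory effects).
sim_beta_rows <- function(n_part = 8, n_runs = 2, cond_eff = 0.2,
                          mem_eff = 0, intercept_sd = 0.1, resid_sd = 0.1,
                          roi = "SN", seed = 1) {
  set.seed(seed)
  rows <- expand.grid(participant = seq_len(n_part),
                      run = seq_len(n_runs) - 1L,
                      regressor = c("reward_remembered", "reward_forgotten",
                                    "neutral_remembered",
                                    "neutral_forgotten"),
                      stringsAsFactors = FALSE)
  u <- rnorm(n_part, 0, intercept_sd)
  cond <- grepl("^reward_", rows$regressor)
  mem <- grepl("_remembered$", rows$regressor)
  rows$roi <- roi
  rows$beta <- u[rows$participant] + cond_eff * cond + mem_eff * mem +
    rnorm(nrow(rows), 0, resid_sd)
  rows
}
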