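# Named simulation scenarios: the fixed study conditions used by the analysis
# drivers, the validation suite and the acceptance script. Each returns a
# sim_config; sizes are chosen to resolve the quantity under study on a
# single CPU (rationale in the methods vignette).

#' Preset simulation scenarios
#'
#' @param name scenario name:
#'   * `event_recovery` — 20 isolated planted release events on a
#'     128 x 128 px field, 2,000 frames, noise-free field (event recall /
#'     precision / localization).
#'   * `colocation` — bouts of release with co-located delayed reuptake
#'     (spatial/temporal release:reuptake correlation directions).
#'   * `glm_recovery` — 25 cells, 9,000 frames, planted beta_local = 0.3 and
#'     beta_globalCa = 0.5, no shared drive (end-to-end coefficient
#'     recovery through the rendered movie).
#'   * `regime_split` — interaction coupling gated to the field's coherent
#'     state (high- vs low-synchrony fit contrast).
#'   * `radius_sweep` — phasic coupling integrated over a 25 um disk, small
#'     plumes, no shared drive (spatial-scale recovery of the coupling
#'     profile).
#'   * `drug_saline` / `drug_desipramine` — matched pair for the
#'     reuptake-blockade contrast.
#'   * `synchrony_events` — saline-like field for event/synchrony coupling
#'     checks.
#' @param seed RNG seed forwarded to the config
#' @return a [sim_config()]
#' @export
scenario_config <- function(name, seed = 1L) {
  switch(
    name,
    event_recovery = {
      set.seed(seed)
      n_ev <- 20L
      # grid of events, visited in a stride order so that temporally adjacent
      # events land far apart in space (isolated under the 5 s smoothing)
      gx <- rep(seq(22, 106, length.out = 5), 4)
      gy <- rep(seq(22, 106, length.out = 4), each = 5)
      ord <- (seq_len(n_ev) * 7L) %% n_ev + 1L
      sim_config(
        fov_px = c(128L, 128L), duration_s = 2000 / 15, n_cells = 4,
        planted_events = data.frame(
          kind = rep(c("release", "release", "reuptake"),
                     length.out = n_ev),
          onset_s = seq(8, 2000 / 15 - 14, length.out = n_ev),
          x_px = gx[ord] + stats::runif(n_ev, -2, 2),
          y_px = gy[ord] + stats::runif(n_ev, -2, 2)),
        global_drive_amp = 0, noise_sd = 0, bleedthrough_frac = 0,
        seed = seed)
    },
    colocation = sim_config(
      fov_px = c(64L, 64L), duration_s = 300, n_cells = 4,
      n_varicosities = 10, release_rate_hz = 0.03, colocation_p = 0.8,
      reuptake_rate_hz = 0.002, reuptake_amp = 0.8, reuptake_delay_s = 10,
      reuptake_tau_s = 2, burst_period_s = 40, burst_duty = 0.3,
      global_drive_amp = 0.15, noise_sd = 0, seed = seed),
    glm_recovery = sim_config(
      fov_px = c(96L, 96L), duration_s = 600, n_cells = 25,
      n_varicosities = 24, release_rate_hz = 0.01, global_drive_amp = 0,
      diffusion_sigma_um = 8, reuptake_tau_s = 4.5,
      beta_local = 0.3, beta_globalCa = 0.5, cell_noise_sd = 0.8,
      noise_sd = 0.1, bleedthrough_frac = 0.1, seed = seed),
    regime_split = sim_config(
      fov_px = c(96L, 96L), duration_s = 600, n_cells = 9,
      n_varicosities = 24, release_rate_hz = 0.012, global_drive_amp = 0.5,
      beta_local = 0.25, beta_globalCa = 0.3, beta_interaction = 0.45,
      cell_noise_sd = 0.6, noise_sd = 0.1, seed = seed),
    radius_sweep = sim_config(
      fov_px = c(128L, 128L), duration_s = 300, n_cells = 4,
      n_varicosities = 24, release_rate_hz = 0.015, global_drive_amp = 0,
      diffusion_sigma_um = 6, beta_local = 0.4, beta_globalCa = 0.3,
      cell_noise_sd = 0.6, local_radius_um = 25, noise_sd = 0.1,
      seed = seed),
    drug_saline = sim_config(
      fov_px = c(96L, 96L), duration_s = 300, n_cells = 9,
      n_varicosities = 24, release_rate_hz = 0.012, global_drive_amp = 0.4,
      beta_local = 0.3, beta_globalCa = 0.4, cell_noise_sd = 0.7,
      noise_sd = 0.1, condition = "saline", seed = seed),
    drug_desipramine = sim_config(
      fov_px = c(96L, 96L), duration_s = 300, n_cells = 9,
      n_varicosities = 24, release_rate_hz = 0.012, global_drive_amp = 0.4,
      beta_local = 0.3, beta_globalCa = 0.4, cell_noise_sd = 0.7,
      noise_sd = 0.1, condition = "desipramine", seed = seed),
    synchrony_events = sim_config(
      fov_px = c(96L, 96L), duration_s = 300, n_cells = 9,
      n_varicosities = 16, release_rate_hz = 0.015, global_drive_amp = 0.5,
      noise_sd = 0.1, seed = seed),
    stop("scenario_config: unknown scenario `", name, "`")
  )
}
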