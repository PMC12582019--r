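#' Study condition presets for the G4_IX / Zuo1 system
#'
#' Fixed parameter sets describing the experimental regimes analyzed
#' throughout the package: the ionic and protein conditions under which the
#' 32-nt chromosome-IX G-quadruplex (G4_IX) was measured, and the reported
#' headline quantities for each. These drive the synthetic-data generators in
#' recovery tests and in the acceptance script.
#'
#' Population components give per-molecule apparent-FRET mixtures
#' (means/sds/weights); the compacted state is broader (sd 0.07) than the
#' folded state (sd 0.05), typical of smFRET histograms. Kinetic presets are
#' full [two_state_model()] parameter sets at 0.3 s frames, 300 frames.
#'
#' @return A nested list with elements `fret_populations` (regimes
#'   `potassium_1mM`, `potassium_high`, `refolded_25mM`, `zuo1_25mM`),
#'   `fret_kinetics` (`no_protein`, `with_protein`), `cd_kinetics`,
#'   `melting` and `binding`.
#' @export
#' @examples
#' p <- g4ix_conditions()
#' p$fret_kinetics$no_protein$k_lh
g4ix_conditions <- function() {
  list(
    fret_populations = list(
      # 1 mM K+: single compacted population
      potassium_1mM = list(means = 0.41, sds = 0.05, weights = 1),
      # K+ above 25 mM: folded state at 0.85 appears (weight at 25 mM maintained)
      potassium_high = list(means = c(0.49, 0.85), sds = c(0.07, 0.05),
                            weights = c(0.59, 0.41)),
      # 25 mM K+ after in-situ refolding: 7% folded
      refolded_25mM = list(means = c(0.49, 0.81), sds = c(0.07, 0.05),
                           weights = c(0.93, 0.07)),
      # 25 mM K+ plus 25 uM Zuo1 C-terminal domain: 63% folded
      zuo1_25mM = list(means = c(0.49, 0.81), sds = c(0.07, 0.05),
                       weights = c(0.37, 0.63))
    ),
    fret_kinetics = list(
      no_protein = list(k_lh = 0.011, k_hl = 0.050),
      with_protein = list(k_lh = 0.021, k_hl = 0.036),
      e_low = 0.49, e_high = 0.81,
      sigma_e = 0.06, frame_interval = 0.3, n_frames = 300
    ),
    cd_kinetics = list(
      # five protein equivalents, 295 nm: single fast phase
      five_equivalents = list(k_per_min = 9.7, amplitude = 1,
                              t_max_min = 1, dt_min = 0.1 / 60)
    ),
    melting = list(
      dna_only_tm = 41.2, with_protein_tm = 52.8, width = 4,
      t_range = c(25, 95), step = 0.5
    ),
    binding = list(
      kd_potassium_uM = 4.9, kd_sodium_uM = 85,
      dna_total_uM = 0.02, top_conc_uM = 200, n_points = 16,
      dilution_factor = 2
    )
  )
}
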