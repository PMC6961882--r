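# Scenario presets: cohort-level regimes (subject group x lighting
# condition x canal) with stimulus statistics, VOR gains, and first/second
# saccade frequency / amplitude / latency / latency-SD parameters taken
# from the published cohort summaries this package models.
#
# Per-trial amplitude SDs are not recoverable from cohort tables (which
# report SEMs of marginal means); presets use a CV of 0.25.  The latency
# SD, by contrast, IS reported directly: "clustering" is the SD of onset
# latency, so each preset's latency spread equals its clustering value.

# stimulus: canal x condition -> (Vp mean, sd, D mean, sd, bounce mean, sd)
.stim_tbl <- list(
  lateral_light = c(204, 45.6, 154, 16.2, 33, 16.6),
  lateral_dark = c(205, 44.8, 163, 16.4, 31, 15.8),
  anterior_light = c(174, 38.8, 157, 24.8, 21, 15.1),
  anterior_dark = c(174, 35.9, 159, 21.5, 22, 13.8),
  posterior_light = c(167, 38.2, 152, 26.2, 22, 17.6),
  posterior_dark = c(163, 37.5, 157, 23.4, 22, 16.0))

# VOR gain (light-condition means; lighting shifts gain by <= ~0.08 and is
# neglected in the presets): group -> c(lateral, anterior, posterior)
.gain_tbl <- list(
  normal = c(0.93, 0.81, 0.74),
  uvd_contra = c(0.87, 0.84, 0.73),
  uvd_ipsi = c(0.36, 0.47, 0.25),
  bvl = c(0.16, 0.31, 0.15),
  bvd = c(-0.02, 0.00, -0.01))

# Saccade cells: freq1(%), amp1(deg), lat1(ms), clu1(ms),
#                freq2(%), amp2(deg), lat2(ms), clu2(ms)
# per group_condition, columns lateral/anterior/posterior.
.sacc_tbl <- list(
  normal_light = rbind(l = c(46.9, 1.4, 232, 77, 6.9, 1.2, 379, 55),
                       a = c(15.3, 1.6, 264, 81, 1.5, 1.3, 383, 59),
                       p = c(26.1, 2.1, 248, 82, 2.9, 1.9, 376, 60)),
  normal_dark = rbind(l = c(22.4, 2.1, 332, 102, 2.4, 2.4, 327, 74),
                      a = c(3.1, 2.3, 315, 106, 0.3, 1.9, 439, 78),
                      p = c(15.5, 3.2, 266, 107, 1.5, 2.5, 373, 79)),
  uvd_contra_light = rbind(l = c(82, 2.0, 224, 83, 27.5, 1.6, 379, 67),
                           a = c(29.2, 1.7, 312, 87, 3.3, 1.6, 421, 71),
                           p = c(52.9, 2.9, 228, 88, 8.6, 1.6, 376, 72)),
  uvd_contra_dark = rbind(l = c(34.8, 2.5, 311, 84, 4.3, 2.5, 332, 55),
                          a = c(8.8, 2.0, 349, 88, 0.8, 2.0, 379, 59),
                          p = c(19.9, 3.0, 276, 89, 2.0, 2.5, 336, 60)),
  uvd_ipsi_light = rbind(l = c(98.3, 6.2, 177, 54, 83.2, 4.0, 225, 62),
                         a = c(88.4, 3.1, 203, 58, 38.9, 2.8, 276, 66),
                         p = c(93.4, 4.7, 162, 59, 54, 3.5, 306, 67)),
  uvd_ipsi_dark = rbind(l = c(92, 5.5, 196, 92, 49, 4.0, 298, 88),
                        a = c(43.1, 3.1, 252, 96, 6, 2.9, 348, 93),
                        p = c(64, 3.8, 223, 96, 12.9, 3.2, 328, 94)),
  bvl_light = rbind(l = c(96.6, 7.0, 168, 51, 70.5, 4.5, 274, 66),
                    a = c(83.8, 4.0, 187, 55, 30.2, 2.5, 276, 70),
                    p = c(84.9, 5.9, 184, 56, 31.9, 3.0, 300, 71)),
  bvl_dark = rbind(l = c(62.3, 3.8, 240, 102, 12.1, 3.2, 354, 78),
                   a = c(26.3, 2.1, 287, 106, 2.9, 2.0, 407, 82),
                   p = c(39.6, 2.4, 227, 107, 5.2, 2.3, 346, 83)),
  bvd_light = rbind(l = c(100, 7.3, 165, 17, 96, 2.3, 362, 69),
                    a = c(98, 6.6, 190, 51, 64, 1.5, 424, 72),
                    p = c(100, 6.7, 205, 60, 65, 0.6, 414, 39)),
  bvd_dark = rbind(l = c(90, 3.1, 168, 66, 28, 1.7, 472, 69),
                   a = c(42, 1.1, 236, 104, 4, 0.6, 547, 70),
                   p = c(80, 1.2, 281, 96, 18, 0.7, 477, 122)))

#' Scenario preset catalogue
#'
#' Named [synth_config()]s reproducing the study regimes: every
#' combination of subject group (`normal`, `uvd_contra`, `uvd_ipsi`,
#' `bvl`, `bvd`), lighting condition (`light`, `dark`), and canal
#' (`lateral`, `anterior`, `posterior`), as `"<group>_<condition>_<canal>"`
#' (e.g. `"bvl_light_lateral"`).  Each preset carries the cohort's
#' stimulus envelope, mean VOR gain, and first/second saccade
#' frequency/amplitude/latency parameters, with the reported latency
#' "clustering" (SD of onset latency) as the per-trial latency spread.
#'
#' @param name preset name; `NULL` returns the whole catalogue.
#' @param n_trials,seed,noise_sd_dps overrides applied to the returned
#'   config(s).
#' @return a `synth_config` (if `name` given) or named list of all
#'   presets.
#' @examples
#' names(scenario_presets())
#' scenario_presets("normal_light_lateral")$vor_gain
#' @export
scenario_presets <- function(name = NULL, n_trials = 100, seed = NULL,
                             noise_sd_dps = 3) {
  canals <- c(l = "lateral", a = "anterior", p = "posterior")
  out <- list()
  for (gc in names(.sacc_tbl)) {
    grp <- sub("_(light|dark)$", "", gc)
    cond <- sub("^.*_", "", gc)
    for (ck in names(canals)) {
      canal <- canals[[ck]]
      st <- .stim_tbl[[paste(canal, cond, sep = "_")]]
      sc <- .sacc_tbl[[gc]][ck, ]
      gm <- .gain_tbl[[grp]][match(canal, canals)]
      gain_sd <- if (grp == "bvd") 0.03 else 0.05
      preset <- synth_config(
        n_trials = n_trials, seed = seed,
        stimulus = list(peak_velocity = st[1:2], duration_ms = st[3:4],
                        bounce_pct = st[5:6], direction = "alternate"),
        vor_gain = c(gm, gain_sd),
        saccades = list(
          list(probability = sc[1] / 100, amplitude = c(sc[2], 0.25 * sc[2]),
               sigma_ms = c(12, 2), latency_ms = c(sc[3], sc[4])),
          list(probability = sc[5] / 100, amplitude = c(sc[6], 0.25 * sc[6]),
               sigma_ms = c(12, 2), latency_ms = c(sc[7], sc[8]))),
        noise_sd_dps = noise_sd_dps,
        canal = canal, condition = cond, group = grp,
        description = sprintf(
          "%s group, %s canal, %s condition: cohort-level stimulus, gain and first/second saccade statistics",
          grp, canal, cond))
      out[[paste(grp, cond, canal, sep = "_")]] <- preset
    }
  }
  if (is.null(name)) return(out)
  if (!name %in% names(out))
    vorsac_stop("vorsac_lookup_error",
                sprintf("unknown preset '%s'; see names(scenario_presets())", name))
  out[[name]]
}
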