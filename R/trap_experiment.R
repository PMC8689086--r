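#' Synthetic trap-plate experiment at the study scale
#'
#' Convenience wrapper used by the calibrated-recovery analyses: generates
#' the three trap-chamber conditions (0, 16 and 39 microspheres per trap on
#' average, with the study's trap counts), measures each cell's Voronoi
#' area and simulates area-coupled copper responses, returning the pooled
#' per-cell table.
#'
#' @param seed integer seed.
#' @param n_traps trap counts per condition (default 59, 58, 62).
#' @param sphere_means,sphere_sds truncated-normal sphere-count parameters
#'   per condition.
#' @param preset exposure preset (default `"cellasic_area"`).
#' @return data frame: `cell_id`, `condition` (mean spheres), `n_spheres`,
#'   `area_um2`, `percent_increase`.
#' @export
simulate_trap_experiment <- function(seed,
                                     n_traps = c(59, 58, 62),
                                     sphere_means = c(0, 16, 39),
                                     sphere_sds = c(0, 5, 8),
                                     preset = "cellasic_area") {
  tabs <- lapply(seq_along(n_traps), function(ci) {
    traps <- generate_trap_chamber(n_traps[ci], sphere_means[ci],
                                   sphere_sds[ci],
                                   seed = stage_seed(seed, paste0("cond", ci)))
    data.frame(condition = sphere_means[ci],
               n_spheres = vapply(traps, function(s) s$meta$n_spheres,
                                  integer(1)),
               area_um2 = vapply(traps, function(s)
                 spatial_metrics(s)$area_um2[1], numeric(1)))
  })
  cells <- do.call(rbind, tabs)
  cells$cell_id <- seq_len(nrow(cells))
  resp <- simulate_structured(cells[, c("cell_id", "area_um2")], preset,
                              seed = stage_seed(seed, "simulate"))
  cbind(cells[, c("cell_id", "condition", "n_spheres", "area_um2")],
        percent_increase = resp$percent_increase)
}
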