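#' Physical parameters of the perfused device
#'
#' Container for the fluid and device constants used by the flow model and
#' the advection-diffusion scale analysis. Defaults are the operating point
#' of the soil-micromodel experiments: YNB medium approximated as water
#' (viscosity 1e-3 Pa s, density 1000 kg/m^3), a 2 ul/h feed
#' (5.56e-13 m^3/s), a 32-um-high channel of 0.974 mm effective cross-
#' section width, and a Cu(II) diffusion coefficient of 7e-10 m^2/s.
#'
#' @param mu dynamic viscosity, Pa s.
#' @param rho density, kg/m^3.
#' @param Phi volumetric flow rate, m^3/s.
#' @param h channel (structure) height, m.
#' @param width_w effective channel cross-section width, m.
#' @param D solute diffusion coefficient, m^2/s.
#' @return an object of class `strucell_params`.
#' @export
physical_params <- function(mu = 1e-3, rho = 1000, Phi = 5.56e-13,
                            h = 32e-6, width_w = 0.974e-3, D = 7e-10) {
  p <- list(mu = mu, rho = rho, Phi = Phi, h = h, width_w = width_w, D = D)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                  logical(1))))
    stop("all physical parameters must be strictly positive scalars")
  structure(p, class = "strucell_params")
}

#' Convert a flow rate in microlitres per hour to m^3/s
#'
#' @param ul_per_h flow rate in ul/h.
#' @return flow rate in m^3/s (2 ul/h is 5.56e-13 m^3/s).
#' @export
ul_per_h_to_m3s <- function(ul_per_h) ul_per_h * 1e-9 / 3600

#' Mean inlet speed from the flow rate and channel cross-section
#'
#' `v0 = Phi / (h * width_w)`; with the default parameters this is
#' 1.78e-5 m/s.
#'
#' @param params a [physical_params()] object.
#' @return inlet speed in m/s.
#' @export
inlet_speed <- function(params) {
  stopifnot(inherits(params, "strucell_params"))
  params$Phi / (params$h * params$width_w)
}

#' Reynolds-number estimate for the device
#'
#' Single-pore worst case `Re ~ rho * Phi / (mu * h)`; about 1e-2 with the
#' default parameters, so inertia is negligible and Stokes flow applies.
#'
#' @param params a [physical_params()] object.
#' @return dimensionless Reynolds estimate.
#' @export
reynolds_estimate <- function(params) {
  stopifnot(inherits(params, "strucell_params"))
  params$rho * params$Phi / (params$mu * params$h)
}

#' Nearest power of ten of a positive number
#'
#' @param x positive scalar.
#' @return `10^round(log10(x))`.
#' @export
nearest_power_of_ten <- function(x) {
  stopifnot(x > 0)
  10^round(log10(x))
}

#' Advection-diffusion crossover length
#'
#' In a uniform flow of speed `v`, diffusion dominates solute delivery at
#' distances below about `D / v`; solute flux towards a cell scales with the
#' average flow speed within this radius of the cell.
#'
#' @param D diffusion coefficient, m^2/s.
#' @param v flow speed, m/s (must be positive).
#' @return crossover length in m.
#' @export
diffusion_radius <- function(D, v) {
  stopifnot(is.numeric(D), D >= 0)
  if (v <= 0) stop("reference speed v must be positive")
  D / v
}

#' Solve the depth-averaged flow model on a scene
#'
#' Solves the interpolated thick/thin-limit momentum equation
#' `grad p = mu lap(vbar) - (12 mu / h^2) vbar` with `div vbar = 0` on the
#' open pixels of the scene, using a staggered-grid finite-difference
#' discretisation and a geometric multigrid solver with coupled Vanka
#' smoothing. Boundary conditions: no slip on obstacles and side walls, a
#' uniform normal speed `v0` (zero tangential) on the open pixels of the top
#' (inlet) edge, and zero gauge pressure with a zero-gradient outflow
#' condition on the bottom (outlet) edge. Cells never perturb the flow; only
#' the obstacle mask does.
#'
#' @param scene a validated scene with flow from top to bottom.
#' @param params a [physical_params()] object.
#' @param v0 inlet speed, m/s; default [inlet_speed()] of `params`.
#' @param tol convergence tolerance on the maximum continuity residual (in
#'   units of `v0` per pixel) and, scaled by the drag coefficient, on the
#'   momentum residual.
#' @param max_cycles maximum multigrid V-cycles.
#' @param nu_pre,nu_post smoothing sweeps per cycle.
#' @param omega Vanka damping factor.
#' @param quiet suppress per-cycle residual reporting.
#' @return an object of class `strucell_flowfield` with cell-centred
#'   velocity components `vbar_x`, `vbar_y` (m/s; exactly zero on solid
#'   pixels), `speed`, gauge `pressure` (Pa, `NA` on solid), the staggered
#'   face velocities (`u_face`, `v_face`, in units of `v0`), and solver
#'   diagnostics (`cycles`, `res_mom`, `res_cont`).
#' @export
solve_flow <- function(scene, params = physical_params(), v0 = NULL,
                       tol = 1e-10, max_cycles = 400, nu_pre = 2,
                       nu_post = 2, omega = 0.7, quiet = TRUE) {
  validate_scene(scene)
  stopifnot(inherits(params, "strucell_params"))
  if (scene$inlet_edge != "top" || scene$outlet_edge != "bottom")
    stop("solve_flow expects flow from the top edge to the bottom edge")
  if (is.null(v0)) v0 <- inlet_speed(params)
  dx <- scene$pixel_size * 1e-6
  h <- scene$height_um * 1e-6
  drag <- 12 * (dx / h)^2
  # open components with no path between inlet and outlet carry no flow and
  # have no well-defined pressure; exclude them from the linear system
  lab <- .label4_cpp(!scene$mask)
  good <- intersect(unique(lab[1, ]), unique(lab[nrow(lab), ]))
  good <- setdiff(good, 0L)
  if (length(good) == 0L) stop("no-flow error: inlet and outlet disconnected")
  solver_solid <- scene$mask | !matrix(lab %in% good, nrow(lab), ncol(lab))
  sol <- solve_masked(solver_solid, drag, tol, max_cycles, nu_pre, nu_post,
                      omega, quiet)
  if (!sol$converged)
    stop(sprintf(paste0("solver error: no convergence after %d cycles ",
                        "(momentum residual %.3e, continuity residual %.3e)"),
                 sol$cycles, sol$res_mom, sol$res_cont))
  ny <- nrow(scene$mask); nx <- ncol(scene$mask)
  vbar_x <- (sol$u_face[, 1:nx] + sol$u_face[, 2:(nx + 1)]) / 2 * v0
  vbar_y <- (sol$v_face[1:ny, ] + sol$v_face[2:(ny + 1), ]) / 2 * v0
  vbar_x[scene$mask] <- 0
  vbar_y[scene$mask] <- 0
  structure(list(
    vbar_x = vbar_x, vbar_y = vbar_y,
    speed = sqrt(vbar_x^2 + vbar_y^2),
    pressure = sol$p * params$mu * v0 / dx,
    u_face = sol$u_face, v_face = sol$v_face,
    v0 = v0, pixel_size = scene$pixel_size, height_um = scene$height_um,
    mask = scene$mask, params = params,
    diagnostics = list(cycles = sol$cycles, res_mom = sol$res_mom,
                       res_cont = sol$res_cont, n_levels = sol$n_levels,
                       drag_c = drag)),
    class = "strucell_flowfield")
}

#' @export
print.strucell_flowfield <- function(x, ...) {
  cat(sprintf(
    "<strucell_flowfield> %d x %d px, v0 = %.3g m/s, peak speed %.3g m/s\n",
    nrow(x$speed), ncol(x$speed), x$v0, max(x$speed)))
  cat(sprintf("  %d V-cycles, residuals: momentum %.2e, continuity %.2e\n",
              x$diagnostics$cycles, x$diagnostics$res_mom,
              x$diagnostics$res_cont))
  invisible(x)
}

# Nested-iteration driver: on large rasters, solve first on a 2x coarsened
# mask (any-child-fluid) and prolong that state as the initial guess. The
# fine Krylov solve then only has to remove the coarsening error.
solve_masked <- function(solid, drag, tol, max_cycles, nu_pre, nu_post,
                         omega, quiet, nested_threshold = 1200) {
  ny <- nrow(solid); nx <- ncol(solid)
  init <- list(u = NULL, v = NULL, p = NULL)
  if (min(ny, nx) > nested_threshold) {
    coarse <- coarsen_mask(solid)
    # solve the coarse problem to (at most) the prolongation-error floor:
    # tighter than that buys nothing for an initial guess
    sub <- solve_masked(coarse, drag * 4, max(tol, 1e-4),
                        max_cycles, nu_pre, nu_post, omega, quiet)
    ui <- pmin(pmax(ceiling((seq_len(nx + 1) - 0.5) / 2), 1), ncol(sub$u_face))
    uj <- pmin(ceiling(seq_len(ny) / 2), nrow(sub$u_face))
    vi <- pmin(ceiling(seq_len(nx) / 2), ncol(sub$v_face))
    vj <- pmin(pmax(ceiling((seq_len(ny + 1) - 0.5) / 2), 1), nrow(sub$v_face))
    p0 <- sub$p
    p0[is.na(p0)] <- 0
    init <- list(u = sub$u_face[uj, ui, drop = FALSE],
                 v = sub$v_face[vj, vi, drop = FALSE],
                 p = 0.5 * p0[uj, vi, drop = FALSE])
  }
  .solve_flow_cpp(solid, drag, tol, as.integer(max_cycles),
                  as.integer(nu_pre), as.integer(nu_post), omega, quiet,
                  25L, 1L, init$u, init$v, init$p)
}

# 2x any-child-fluid coarsening of a solid mask
coarsen_mask <- function(solid) {
  ny <- nrow(solid); nx <- ncol(solid)
  nyc <- ceiling(ny / 2); nxc <- ceiling(nx / 2)
  pad <- matrix(TRUE, 2 * nyc, 2 * nxc)
  pad[seq_len(ny), seq_len(nx)] <- solid
  # fluid if any child fluid -> solid only if all children solid
  o <- pad[seq(1, 2 * nyc, 2), , drop = FALSE] &
       pad[seq(2, 2 * nyc, 2), , drop = FALSE]
  o[, seq(1, 2 * nxc, 2), drop = FALSE] &
    o[, seq(2, 2 * nxc, 2), drop = FALSE]
}

#' Volumetric flux through a transverse cross-section
#'
#' Integrates the normal (streamwise) face velocities across a full
#' transverse station of the raster: `Q = h * sum(vbar_n * dx)`. For a
#' converged solution this is identical at every station (discrete mass
#' conservation) and equals the imposed inlet flux.
#'
#' @param field a [solve_flow()] result.
#' @param station face row index, 1 (inlet face) to `ny + 1` (outlet face).
#' @return flux in m^3/s.
#' @export
cross_section_flux <- function(field, station) {
  stopifnot(inherits(field, "strucell_flowfield"))
  if (station < 1 || station > nrow(field$v_face))
    stop("station outside the raster")
  dx <- field$pixel_size * 1e-6
  h <- field$height_um * 1e-6
  h * sum(field$v_face[station, ] * field$v0 * dx)
}

#' Mean flow speed in a neighbourhood of a cell
#'
#' Mean of the depth-averaged speed over the open pixels whose centres lie
#' within `radius_um` of the cell centre. The default radius is the
#' advection-diffusion crossover length D/v for Cu(II) at the typical pore
#' speed 1e-4 m/s, i.e. 7 um: solute flux towards a cell tracks the average
#' flow in such a neighbourhood rather than the speed at the (no-slip,
#' near-wall) cell position itself.
#'
#' @param field a [solve_flow()] result.
#' @param site either a cell id present in `scene$cells` passed as a row of
#'   that table, or a `c(row, col)` pixel position.
#' @param radius_um neighbourhood radius in micrometres.
#' @return mean speed in m/s.
#' @export
neighbourhood_mean_speed <- function(field, site, radius_um = 7) {
  stopifnot(inherits(field, "strucell_flowfield"), radius_um > 0)
  if (is.data.frame(site)) site <- c(site$row[1], site$col[1])
  r_px <- radius_um / field$pixel_size
  px <- disc_pixels(site[1], site[2], r_px, nrow(field$mask),
                    ncol(field$mask))
  open <- !field$mask[px]
  if (!any(open)) stop("no open pixels within the neighbourhood radius")
  mean(field$speed[px[open, , drop = FALSE]])
}

#' Export a flow field as images and tables
#'
#' Writes the speed and pressure rasters as 32-bit float TIFFs, a greyscale
#' PNG render of speed (lighter shades = faster flow, solid pixels black),
#' and, when cells are supplied, a CSV of per-cell neighbourhood speeds.
#'
#' @param field a [solve_flow()] result.
#' @param dir output directory.
#' @param cells optional cell table (`id`, `row`, `col`).
#' @param radius_um neighbourhood radius for the per-cell table.
#' @return `dir`, invisibly.
#' @export
export_flow <- function(field, dir, cells = NULL, radius_um = 7) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(field$speed / max(field$speed, 1e-300),
                  file.path(dir, "speed.tiff"), bits.per.sample = 32)
  prast <- field$pressure
  prast[is.na(prast)] <- 0
  tiff::writeTIFF(prast / max(abs(prast), 1e-300),
                  file.path(dir, "pressure.tiff"), bits.per.sample = 32)
  png::writePNG(render_speed(field), file.path(dir, "speed.png"))
  if (!is.null(cells) && nrow(cells)) {
    spd <- vapply(seq_len(nrow(cells)), function(k)
      neighbourhood_mean_speed(field, c(cells$row[k], cells$col[k]),
                               radius_um), numeric(1))
    write.csv(data.frame(cell_id = cells$id, nbhd_speed_m_s = spd),
              file.path(dir, "cell_speeds.csv"), row.names = FALSE)
  }
  invisible(dir)
}

# greyscale speed render in [0,1]: open pixels scaled by speed (lighter =
# faster), solid pixels black
render_speed <- function(field) {
  sp <- field$speed
  mx <- max(sp)
  img <- if (mx > 0) 0.15 + 0.85 * sp / mx else matrix(0.15, nrow(sp), ncol(sp))
  img[field$mask] <- 0
  img
}
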