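# Scenario discovery: which test characteristics drive cost-effectiveness,
# and a low-dimensional "map" of net monetary benefit. The random forest
# ranks the five design variables by mean decrease in Gini; the three most
# important (cost, advanced-adenoma sensitivity, interval) span a smoothed
# NMB surface fitted by locally weighted regression, conditioned on the
# best-case CRC sensitivity, with iso-NMB contours including the colonoscopy
# reference level.

DISCOVERY_PREDICTORS <- c("cost", "aa_sens", "interval", "model", "crc_sens")

#' Rank scenario characteristics by random-forest Gini importance
#'
#' Trains a seeded random-forest classifier on the scenario table's binary
#' cost-effectiveness label using the five design variables (test cost,
#' advanced-adenoma sensitivity, screening interval, natural-history model,
#' CRC sensitivity) and returns the variables ranked by mean decrease in
#' Gini impurity. `interval` and `model` are treated as categorical.
#'
#' @param scenario_table result of [evaluate_scenarios()] (or any data frame
#'   with the predictor columns and the label column).
#' @param label name of the binary label column (default `cost_effective`).
#' @param predictors predictor column names.
#' @param ntree,mtry,min_node forest hyperparameters (see [gini_forest()]).
#' @param seed integer seed.
#' @return a data.frame of class `importance_ranking` with columns
#'   `variable`, `importance`, `rank` (descending importance), and the
#'   fitted forest as attribute `"forest"`.
#' @export
rank_importance <- function(scenario_table, label = "cost_effective",
                            predictors = intersect(DISCOVERY_PREDICTORS,
                                                   names(scenario_table)),
                            ntree = 500L, mtry = NULL, min_node = 5L,
                            seed = 1L) {
  if (!label %in% names(scenario_table))
    stop("rank_importance: label column '", label, "' not found")
  y <- scenario_table[[label]]
  if (length(unique(y)) < 2L)
    stop("rank_importance: label '", label,
         "' has a single class; importance is undefined on a degenerate label")
  df <- scenario_table[predictors]
  for (nm in intersect(c("interval", "model"), names(df)))
    df[[nm]] <- factor(df[[nm]])
  fit <- gini_forest(df, y, ntree = ntree, mtry = mtry, min_node = min_node,
                     seed = seed)
  imp <- sort(fit$importance, decreasing = TRUE)
  out <- data.frame(variable = names(imp), importance = unname(imp),
                    rank = seq_along(imp))
  attr(out, "forest") <- fit
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Smoothed net-monetary-benefit surface over the top test characteristics
#'
#' Fits a locally weighted regression (tricube weights, degree 1,
#' configurable span) of NMB on test cost and advanced-adenoma sensitivity,
#' separately within each screening-interval panel, after conditioning the
#' table on one CRC sensitivity level and averaging NMB across model
#' replicates. The fit is evaluated on an evenly spaced grid of about
#' `grid_n` points split equally across the interval panels.
#'
#' @param scenario_table result of [evaluate_scenarios()].
#' @param vars the three surface variables; the first two must be numeric
#'   axes (cost, aa_sens), the third the panel variable (interval).
#' @param grid_n total number of grid points across panels (default 10000).
#' @param conditioning named list of column = value filters applied first
#'   (default `list(crc_sens = 0.92)`).
#' @param span LOESS span.
#' @return a list of class `nmb_surface`: `grid` (data.frame `interval`,
#'   `cost`, `aa_sens`, `nmb_smooth`), axis grids per panel, the
#'   conditioning used, and the fitted panel models.
#' @export
fit_nmb_surface <- function(scenario_table,
                            vars = c("cost", "aa_sens", "interval"),
                            grid_n = 10000L,
                            conditioning = list(crc_sens = 0.92),
                            span = 0.5) {
  stopifnot(length(vars) == 3L, all(vars %in% names(scenario_table)))
  tab <- scenario_table
  for (nm in names(conditioning)) {
    tab <- tab[tab[[nm]] == conditioning[[nm]], , drop = FALSE]
    if (!nrow(tab))
      stop("fit_nmb_surface: conditioning on ", nm, " = ", conditioning[[nm]],
           " leaves no scenarios")
  }
  xv <- vars[1L]; yv <- vars[2L]; pv <- vars[3L]
  # average NMB across model replicates at identical design points
  agg <- stats::aggregate(tab["nmb"], tab[c(xv, yv, pv)], mean)
  panels <- sort(unique(agg[[pv]]))
  m <- round(sqrt(grid_n / length(panels)))
  if (m^2 * length(panels) != grid_n)
    warning(sprintf("fit_nmb_surface: %d points are not an integer lattice over %d panels; using %d x %d per panel (%d total)",
                    grid_n, length(panels), m, m, m^2 * length(panels)))
  fits <- list(); grids <- list(); out <- list()
  for (pl in panels) {
    sub <- agg[agg[[pv]] == pl, , drop = FALSE]
    fml <- stats::as.formula(paste("nmb ~", xv, "+", yv))
    fit <- stats::loess(fml, data = sub, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    gx <- seq(min(sub[[xv]]), max(sub[[xv]]), length.out = m)
    gy <- seq(min(sub[[yv]]), max(sub[[yv]]), length.out = m)
    gg <- expand.grid(gx, gy, KEEP.OUT.ATTRS = FALSE)
    names(gg) <- c(xv, yv)
    z <- stats::predict(fit, newdata = gg)
    if (any(!is.finite(z)))
      stop("fit_nmb_surface: non-finite smoothed values on the grid")
    df <- data.frame(pl, gg[[xv]], gg[[yv]], z)
    names(df) <- c(pv, xv, yv, "nmb_smooth")
    out[[as.character(pl)]] <- df
    fits[[as.character(pl)]] <- fit
    grids[[as.character(pl)]] <- list(x = gx, y = gy)
  }
  structure(list(grid = do.call(rbind, c(out, list(make.row.names = FALSE))),
                 vars = vars, panel_grids = grids, conditioning = conditioning,
                 span = span, fits = fits),
            class = "nmb_surface")
}

#' Iso-NMB contour lines of a smoothed surface
#'
#' Marching-squares contours within each interval panel at the requested
#' NMB levels (for instance the colonoscopy net monetary benefit, which
#' partitions each panel into noninferior and inferior regions). Levels
#' outside the surface range yield no polylines.
#'
#' @param surface an `nmb_surface` from [fit_nmb_surface()].
#' @param levels numeric NMB levels (USD), sorted internally.
#' @return a list of class `contour_set`: one element per panel, each a list
#'   of polylines with `level`, `x` (cost), `y` (aa_sens).
#' @export
extract_contours <- function(surface, levels) {
  stopifnot(inherits(surface, "nmb_surface"), is.numeric(levels))
  levels <- sort(levels)
  pv <- surface$vars[3L]; xv <- surface$vars[1L]; yv <- surface$vars[2L]
  out <- list()
  for (pl in names(surface$panel_grids)) {
    g <- surface$panel_grids[[pl]]
    sub <- surface$grid[surface$grid[[pv]] == as.numeric(pl), , drop = FALSE]
    z <- matrix(sub$nmb_smooth, nrow = length(g$x), ncol = length(g$y))
    cl <- grDevices::contourLines(g$x, g$y, z, levels = levels)
    out[[pl]] <- cl
  }
  structure(out, levels = levels, vars = surface$vars, class = "contour_set")
}

#' Interpolate a smoothed surface at arbitrary points
#'
#' Bilinear interpolation on the surface grid; used to verify that contour
#' polylines lie on their level within grid tolerance.
#'
#' @param surface an `nmb_surface`.
#' @param panel panel value (interval).
#' @param x,y coordinates (cost, aa_sens).
#' @return interpolated NMB values.
#' @export
interp_surface <- function(surface, panel, x, y) {
  g <- surface$panel_grids[[as.character(panel)]]
  pv <- surface$vars[3L]
  sub <- surface$grid[surface$grid[[pv]] == panel, , drop = FALSE]
  z <- matrix(sub$nmb_smooth, nrow = length(g$x), ncol = length(g$y))
  ix <- findInterval(x, g$x, rightmost.closed = TRUE)
  iy <- findInterval(y, g$y, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(g$x) - 1L)
  iy <- pmin(pmax(iy, 1L), length(g$y) - 1L)
  tx <- (x - g$x[ix]) / (g$x[ix + 1L] - g$x[ix])
  ty <- (y - g$y[iy]) / (g$y[iy + 1L] - g$y[iy])
  z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    z[cbind(ix + 1L, iy)] * tx * (1 - ty) +
    z[cbind(ix, iy + 1L)] * (1 - tx) * ty +
    z[cbind(ix + 1L, iy + 1L)] * tx * ty
}
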