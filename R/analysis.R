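# Post-processing: radial profiles against the signed distance to the tumor
# edge, distance-to-vessel profiles with exponential fits, region-wise
# exposure summaries, and the region-integrated fluid/flow aggregates.

#' Radial profile of a field against the tumor level set
#'
#' Sorts grid values into contiguous theta bins (shells around the invasive
#' edge), averages within each run, then reports ensemble mean and standard
#' deviation across runs.  Empty bins are marked missing, not zero.
#'
#' @param fields list of field arrays (one per run); @param thetas list of
#'   level sets (one per run); @param bin_width um (default 100); @param
#'   range optional c(lo, hi) of theta.
#' @return data.frame(theta, mean, sd, n_runs) of class `radial_profile`.
#' @export
theta_profile <- function(fields, thetas, bin_width = 100, range = NULL) {
  if (!is.list(fields)) { fields <- list(fields); thetas <- list(thetas) }
  if (is.null(range))
    range <- range(unlist(lapply(thetas, range)))
  breaks <- seq(floor(range[1] / bin_width) * bin_width,
                ceiling(range[2] / bin_width) * bin_width, by = bin_width)
  centers <- head(breaks, -1) + bin_width / 2
  per_run <- sapply(seq_along(fields), function(m) {
    bin <- cut(as.vector(thetas[[m]]), breaks, include.lowest = TRUE)
    v <- tapply(as.vector(fields[[m]]), bin, mean)
    as.numeric(v)
  })
  per_run <- matrix(per_run, nrow = length(centers))
  out <- data.frame(
    theta = centers,
    mean = rowMeans(per_run, na.rm = TRUE),
    sd = apply(per_run, 1, function(x) if (sum(!is.na(x)) > 1) sd(x, na.rm = TRUE) else 0),
    n_runs = rowSums(!is.na(per_run)))
  out$mean[out$n_runs == 0] <- NA_real_
  class(out) <- c("radial_profile", class(out))
  out
}

#' Signed distance from the vascularized region
#'
#' Thresholds the vessel volume fraction and returns the signed distance from
#' the captured region (negative inside), via the geometric redistancing
#' machinery.
#' @param grid grid; @param phiv vessel volume fraction; @param threshold
#'   capture threshold (default 0.001).
#' @return distance array (um).
#' @export
vessel_distance_field <- function(grid, phiv, threshold = 0.001) {
  if (!any(phiv > threshold)) stop("no vessel voxels above threshold")
  ls <- array(ifelse(phiv > threshold, -grid$h, grid$h), dim = grid$dims)
  redistance_levelset(grid, ls)
}

#' Distance-to-vessel profile with exponential fit
#'
#' Bins a field against the distance from the vascularized region and fits
#' `A exp(-d / l)` over the positive-distance range by nonlinear least
#' squares.
#'
#' @param grid grid; @param field array; @param phiv vessel volume fraction;
#'   @param threshold vessel capture threshold; @param bin_width um.
#' @return list(profile = data.frame(d, mean, n), fit = list(A, l, l_se,
#'   ok)); `ok = FALSE` flags a degenerate fit (e.g. uniform field).
#' @export
distance_to_vessel_profile <- function(grid, field, phiv, threshold = 0.001,
                                       bin_width = 30) {
  dfield <- vessel_distance_field(grid, phiv, threshold)
  breaks <- seq(floor(min(dfield) / bin_width) * bin_width,
                ceiling(max(dfield) / bin_width) * bin_width, by = bin_width)
  bin <- cut(as.vector(dfield), breaks, include.lowest = TRUE)
  mean_v <- tapply(as.vector(field), bin, mean)
  n_v <- tapply(as.vector(field), bin, length)
  centers <- head(breaks, -1) + bin_width / 2
  prof <- data.frame(d = centers, mean = as.numeric(mean_v),
                     n = as.numeric(ifelse(is.na(n_v), 0, n_v)))
  pos <- prof[prof$d > 0 & !is.na(prof$mean) & prof$mean > 0, ]
  fit <- list(A = NA_real_, l = NA_real_, l_se = NA_real_, ok = FALSE)
  if (nrow(pos) >= 3 && diff(range(pos$mean)) > 1e-12 * max(pos$mean)) {
    lmfit <- lm(log(mean) ~ d, data = pos)
    l0 <- -1 / coef(lmfit)[2]
    if (is.finite(l0) && l0 > 0) {
      nl <- tryCatch(nls(mean ~ A * exp(-d / l), data = pos,
                         start = list(A = exp(coef(lmfit)[1]), l = l0)),
                     error = function(e) NULL)
      if (!is.null(nl)) {
        sm <- summary(nl)$coefficients
        fit <- list(A = sm["A", 1], l = sm["l", 1], l_se = sm["l", 2],
                    ok = TRUE)
      } else {
        # nls cannot converge on (near-)zero-residual data; the log-linear
        # fit is then exact (lm warns about the perfect fit, expectedly)
        sl <- suppressWarnings(summary(lmfit))$coefficients
        fit <- list(A = exp(coef(lmfit)[1]), l = unname(l0),
                    l_se = unname(sl[2, 2] / coef(lmfit)[2]^2), ok = TRUE)
      }
    }
  }
  list(profile = prof, fit = fit)
}

#' Region-wise exposure summaries
#'
#' Means and spatial standard deviations of exposure maps over the viable
#' tumor (T), the boundary shell (B, `|theta| < shell`) and the interior (I,
#' `theta < -shell`), per run, then aggregated over the ensemble.
#'
#' @param maps list per run of list(icmax, icauc); @param thetas list of level
#'   sets; @param viable list of logical arrays of viable tumor cells
#'   (`phiT` present and not necrotic); @param shell half-width of the
#'   boundary shell, um.
#' @return data.frame with region, metric, mean, sd (spatial, ensemble
#'   averaged), ens_sd (ensemble deviation of the mean).
#' @export
region_summaries <- function(maps, thetas, viable, shell = 100) {
  if (!is.null(maps$icmax)) {   # single run passed directly
    maps <- list(maps); thetas <- list(thetas); viable <- list(viable)
  }
  rows <- list()
  for (metric in c("icmax", "icauc")) {
    for (region in c("T", "B", "I")) {
      ms <- sds <- numeric(0)
      for (m in seq_along(maps)) {
        th <- thetas[[m]]
        mask <- switch(region,
          "T" = viable[[m]] & th < 0,
          "B" = viable[[m]] & abs(th) < shell,
          "I" = viable[[m]] & th < -shell)
        if (!any(mask)) stop("empty region ", region)
        vals <- maps[[m]][[metric]][mask]
        ms <- c(ms, mean(vals)); sds <- c(sds, sd(vals))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, metric = metric, mean = mean(ms),
        sd = mean(sds), ens_sd = if (length(ms) > 1) sd(ms) else 0)
    }
  }
  do.call(rbind, rows)
}

#' Region-integrated fluid and flow aggregates
#'
#' Tumor volume and fraction, blood inflow across the tumor boundary, and the
#' interstitial influx/uptake integrals per region, plus the extravasation
#' fraction `r_Gamma`.
#'
#' @param net network with flow; @param state continuum state; @param grid
#'   grid; @param iff `iff_solution`.
#' @return one-row data.frame.
#' @export
table3_aggregates <- function(net, state, grid, iff) {
  V <- cell_volume(grid)
  tumor <- state$theta < 0
  src <- iff$sources
  ex <- extravasation_ratio(net, state, grid, src)
  data.frame(
    tumor_volume = sum(tumor) * V,
    tumor_volume_fraction = mean(tumor),
    blood_inflow = ex$inflow,
    if_influx_tumor = sum(src$Qin_v[tumor]) * V,
    if_uptake_tumor = sum((src$Qout_v + src$Qout_L)[tumor]) * V,
    if_influx_normal = sum(src$Qin_v[!tumor]) * V,
    if_uptake_normal = sum((src$Qout_v + src$Qout_L)[!tumor]) * V,
    r_gamma = ex$r_gamma)
}
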