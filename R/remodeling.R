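# Stochastic vascular remodeling during tumor growth: sprout initiation and
# migration (angiogenesis), wall degeneration, vessel dilation
# (circumferential growth), collapse of degenerate low-shear vessels, and the
# master growth loop with operator splitting over the 1 h network step.

# growth-factor value and gradient direction at lattice sites
.site_field <- function(net, grid, field, sites) {
  pos <- site_position(net$lat, sites)
  interp_field(grid, field, data.frame(x = pos[, 1], y = pos[, 2],
                                       z = pos[, 3]))
}

# distance (bonds) to the nearest branch point (node with degree >= 3)
.branch_distance <- function(net, deg) {
  nid <- net$nodes$id
  gr <- igraph::make_empty_graph(n = length(nid), directed = FALSE)
  segs <- net$segments
  if (nrow(segs))
    gr <- igraph::add_edges(gr, rbind(match(segs$n1, nid), match(segs$n2, nid)))
  br <- which(deg >= 3)
  if (!length(br)) return(setNames(rep(Inf, length(nid)), nid))
  dm <- igraph::distances(gr, v = seq_along(nid), to = br)
  setNames(apply(dm, 1, min), nid)
}

#' Update tumor membership and residence clocks of vessels
#'
#' A vessel is "within the tumor" if at least one endpoint has `theta < 0`;
#' the time-in-tumor clock advances by `dt` (h) for those segments.
#' @param net network; @param grid grid; @param theta level set; @param dt h.
#' @return network.
#' @export
update_tumor_flags <- function(net, grid, theta, dt = 1) {
  if (!nrow(net$segments)) return(net)
  th1 <- .site_field(net, grid, theta, node_site(net, net$segments$n1))
  th2 <- .site_field(net, grid, theta, node_site(net, net$segments$n2))
  inside <- th1 < 0 | th2 < 0
  net$segments$tumor <- inside
  net$segments$t_tumor <- ifelse(inside, net$segments$t_tumor + dt, 0)
  net
}

#' Sprout initiation
#'
#' Vessel-occupied lattice sites are visited in random order; at a site a new
#' single-bond sprout segment is attached with probability `sprout_rate * dt`
#' provided the growth factor there is non-zero, the distance to the next
#' branch point exceeds the minimum separation, and the site's time in the
#' tumor is below the maximum.  The new segment follows the neighboring free
#' lattice edge of maximal growth-factor gradient (ties broken uniformly).
#' Initiation from sprouts emulates tip splitting.
#'
#' @param net network; @param grid grid; @param g growth-factor field; @param
#'   params parameters; @param dt step h.
#' @return network with new sprout segments (age 0).
#' @export
sprout_initiation <- function(net, grid, g, params = default_parameters(),
                              dt = 1) {
  rp <- params$remodel
  p_init <- min(1, rp$sprout_rate * dt)
  deg <- node_degree(net)
  bdist <- .branch_distance(net, deg) * net$lat$spacing
  cand <- net$nodes$id
  if (!length(cand)) return(net)
  cand <- cand[sample.int(length(cand))]
  occ_bond <- occupied_bonds(net); occ_site <- occupied_sites(net)
  for (id in cand) {
    rows <- which(net$segments$n1 == id | net$segments$n2 == id)
    if (!length(rows)) next
    if (min(net$segments$t_tumor[rows]) >= rp$sprout_tumor_time_max) next
    if (bdist[as.character(id)] <= rp$sprout_min_separation) next
    site <- as.integer(node_site(net, id))
    gval <- .site_field(net, grid, g, matrix(site, 1))
    if (gval <= 0) next
    if (runif(1) >= p_init) next
    nbs <- site_neighbors(net$lat, site)
    free <- apply(nbs, 1, function(s)
      is.null(occ_bond[[bond_key(site, s)]]) && is.null(occ_site[[site_key(s)]]))
    nbs <- nbs[free, , drop = FALSE]
    if (!nrow(nbs)) next
    gn <- .site_field(net, grid, g, nbs)
    grad <- gn - gval
    best <- which(grad == max(grad))
    pickd <- best[sample.int(length(best), 1L)]
    res <- net_add_segment(net, site, nbs[pickd, ], r = rp$r_sprout,
                           sprout = TRUE, check_occupancy = FALSE)
    net <- res$net
    assign(bond_key(site, nbs[pickd, ]), res$id, envir = occ_bond)
    assign(site_key(nbs[pickd, ]), -1L, envir = occ_site)
  }
  net
}

#' Sprout migration
#'
#' Sprout tips extend by one lattice edge in the sprout direction with
#' probability `speed * dt / spacing`.  A tip fusing with a vessel such that a
#' conducting arterio-venous path arises loses the sprout tag; fusion with
#' another sprout keeps it; sprouts older than the maximum life lose the tag
#' without fusing.  Sprouts never dilate, degenerate or collapse.
#'
#' @param net network; @param params parameters; @param dt h; @param flow
#'   optional current flow solution used to detect conduction after fusion.
#' @return network.
#' @export
sprout_migration <- function(net, params = default_parameters(), dt = 1) {
  rp <- params$remodel
  p_ext <- min(1, rp$sprout_extension_speed * dt / net$lat$spacing)
  srows <- which(net$segments$sprout)
  net$segments$tau_s[srows] <- net$segments$tau_s[srows] + dt
  deg <- node_degree(net)
  for (m in srows[sample.int(length(srows))]) {
    s <- net$segments[m, ]
    if (!s$sprout) next
    # tip: endpoint of the sprout with degree 1
    tip <- if (deg[as.character(s$n1)] == 1) s$n1
           else if (deg[as.character(s$n2)] == 1) s$n2 else NA
    if (!is.na(tip) && runif(1) < p_ext) {
      tail_id <- if (tip == s$n1) s$n2 else s$n1
      tsite <- as.integer(node_site(net, tip))
      dsite <- tsite - as.integer(node_site(net, tail_id)) # direction
      dsite <- dsite %/% max(1L, s$nbonds)
      target <- tsite + dsite
      occ_bond <- occupied_bonds(net); occ_site <- occupied_sites(net)
      if (site_valid(net$lat, matrix(target, 1)) &&
          is.null(occ_bond[[bond_key(tsite, target)]])) {
        hit <- occ_site[[site_key(target)]]
        res <- tryCatch(net_add_segment(net, tsite, target, r = s$r,
                                        sprout = TRUE,
                                        check_occupancy = FALSE),
                        error = function(e) NULL)
        if (!is.null(res)) {
          net <- res$net
          nr <- nrow(net$segments)
          net$segments$tau_s[nr] <- s$tau_s
          if (!is.null(hit) && hit > 0) {
            # fused with an existing vessel: conducting if flow appears
            sol <- tryCatch(solve_nodal_pressures(net, params),
                            error = function(e) NULL)
            if (!is.null(sol)) {
              net <- sol$net
              chain <- .sprout_chain(net, nr)
              if (all(net$segments$perfused[chain]))
                net$segments$sprout[chain] <- FALSE
            }
          }
        }
      }
      deg <- node_degree(net)
    }
  }
  # expire old sprouts
  old <- net$segments$sprout & net$segments$tau_s >= rp$sprout_max_life
  net$segments$sprout[old] <- FALSE
  net
}

# all sprout-tagged segments connected to segment row m through sprout nodes
.sprout_chain <- function(net, row) {
  segs <- net$segments
  sel <- which(segs$sprout | seq_len(nrow(segs)) == row)
  nid <- unique(c(segs$n1[sel], segs$n2[sel]))
  gr <- igraph::make_empty_graph(n = length(nid), directed = FALSE)
  gr <- igraph::add_edges(gr, rbind(match(segs$n1[sel], nid),
                                    match(segs$n2[sel], nid)))
  comp <- igraph::components(gr)$membership
  target <- comp[match(segs$n1[row], nid)]
  keep <- sel[comp[match(segs$n1[sel], nid)] == target |
              comp[match(segs$n2[sel], nid)] == target]
  keep
}

#' Wall degeneration
#'
#' The wall maturity of tumor vessels decreases at the degradation rate until
#' zero; normal vessels and sprouts are unaffected.
#' @param net network (tumor flags current); @param params parameters; @param
#'   dt h.
#' @return network.
#' @export
degrade_walls <- function(net, params = default_parameters(), dt = 1) {
  sel <- net$segments$tumor & !net$segments$sprout
  net$segments$w[sel] <- pmax(0, net$segments$w[sel] -
                                params$remodel$w_degrade_rate * dt)
  net
}

#' Vessel dilation (circumferential growth)
#'
#' Tumor vessels below the maximum radius whose average growth factor is
#' non-zero and whose time in the tumor exceeds the switch delay increase
#' their radius at the dilation rate.  Sprouts are excluded.
#' @param net network; @param grid grid; @param g growth factor; @param
#'   params parameters; @param dt h.
#' @return network.
#' @export
dilate_vessels <- function(net, grid, g, params = default_parameters(),
                           dt = 1) {
  rp <- params$remodel
  if (!nrow(net$segments)) return(net)
  g1 <- .site_field(net, grid, g, node_site(net, net$segments$n1))
  g2 <- .site_field(net, grid, g, node_site(net, net$segments$n2))
  gavg <- (g1 + g2) / 2
  sel <- !net$segments$sprout & net$segments$r < rp$r_max & gavg > 0 &
    net$segments$t_tumor > rp$switch_delay
  net$segments$r[sel] <- pmin(rp$r_max,
                              net$segments$r[sel] + rp$dilation_rate * dt)
  net
}

#' Stochastic vessel collapse
#'
#' Degenerate vessels (wall maturity at/below the collapse threshold) with
#' wall shear stress below the critical value are removed with probability
#' `dt / t_unstable` per step.  Sprouts are excluded.  Branches disconnected
#' by a removal become unperfused at the next flow solve.
#' @param net network with current shear stresses; @param params parameters;
#'   @param dt h.
#' @return network.
#' @export
maybe_collapse <- function(net, params = default_parameters(), dt = 1) {
  rp <- params$remodel
  p <- min(1, dt / rp$t_unstable)
  segs <- net$segments
  eligible <- !segs$sprout & segs$w <= rp$w_collapse &
    !is.na(segs$f) & segs$f < rp$f_collapse
  if (!any(eligible)) return(net)
  u <- runif(nrow(segs))
  doomed <- segs$id[eligible & u < p]
  if (length(doomed)) net <- net_remove_segments(net, doomed)
  net
}

#' Drop connected components that contain no root node
#'
#' Collapse events can split the graph; fragments without a pressure boundary
#' cannot carry flow and are removed (they no longer exchange anything).
#' @param net network.
#' @return network.
#' @export
drop_rootless_components <- function(net) {
  if (!nrow(net$segments)) return(net)
  nid <- net$nodes$id
  gr <- igraph::make_empty_graph(n = length(nid), directed = FALSE)
  gr <- igraph::add_edges(gr, rbind(match(net$segments$n1, nid),
                                    match(net$segments$n2, nid)))
  comp <- igraph::components(gr)$membership
  rooted <- unique(comp[net$nodes$bc != "none"])
  bad_nodes <- nid[!(comp %in% rooted)]
  if (length(bad_nodes)) {
    bad_segs <- net$segments$id[net$segments$n1 %in% bad_nodes |
                                net$segments$n2 %in% bad_nodes]
    net <- net_remove_segments(net, bad_segs)
    net$nodes <- net$nodes[!(net$nodes$id %in% bad_nodes), , drop = FALSE]
  }
  net
}

#' One master growth step (1 h)
#'
#' Applies, in fixed order: flow solve, sprout initiation, sprout migration,
#' wall degeneration, dilation, collapse, then continuum sub-stepping of the
#' volume fractions and level set with refreshed oxygen and growth factor.
#'
#' @param sim list with `net`, `state` (continuum), `grid`, `params`, `seed`,
#'   `t` (h); create with [init_growth_sim()].
#' @return updated sim.
#' @export
growth_step <- function(sim) {
  params <- sim$params
  grid <- sim$grid
  dt_h <- params$remodel$dt
  master <- derive_seed(sim$seed, paste0("step", sim$t))
  # flow
  sim$net <- drop_rootless_components(sim$net)
  sol <- solve_nodal_pressures(sim$net, params)
  sim$net <- sol$net
  # fields
  ox <- with_stream(master, "oxygen",
                    oxygen_field(grid, sim$net, sim$state, params,
                                 seed = derive_seed(master, "o2")))
  cfield <- ox$c
  g <- growth_factor_field(grid, gf_source_mask(sim$state, cfield, params),
                           params)
  sim$net <- update_tumor_flags(sim$net, grid, sim$state$theta, dt_h)
  sim$net <- with_stream(master, "sprout",
                         sprout_initiation(sim$net, grid, g, params, dt_h))
  sim$net <- with_stream(master, "migrate",
                         sprout_migration(sim$net, params, dt_h))
  sim$net <- degrade_walls(sim$net, params, dt_h)
  sim$net <- dilate_vessels(sim$net, grid, g, params, dt_h)
  sim$net <- drop_rootless_components(sim$net)
  sol <- solve_nodal_pressures(sim$net, params)
  sim$net <- sol$net
  sim$net <- with_stream(master, "collapse",
                         maybe_collapse(sim$net, params, dt_h))
  sim$net <- drop_rootless_components(sim$net)
  sol <- solve_nodal_pressures(sim$net, params)
  sim$net <- sol$net
  # continuum sub-steps over the hour
  phi <- phase_closure(sim$state)$phi
  p_solid <- solid_pressure(phi, 1, params$tissue$phi_relaxed)
  v <- cell_velocity(grid, p_solid, params$tissue$mobility_E)
  vmax <- max(abs(unlist(v[c("ux", "uy", "uz")])), 1e-12)
  # cell motion acts as porous-medium diffusion with D ~ mobility*E*phi;
  # the parabolic bound governs stability of the explicit update
  dt_par <- params$numerics$cfl * grid$h^2 /
    (4 * params$tissue$mobility_E * max(phi, 0.1))
  dt_sub <- min(params$numerics$cfl * grid$h / vmax, dt_par, 3600)
  nsub <- ceiling(3600 * dt_h / dt_sub)
  dt_sub <- 3600 * dt_h / nsub
  for (ss in seq_len(nsub)) {
    # refresh the pressure-driven velocity so compression feeds back within
    # the hour (frozen velocity lets the front overshoot the packing density)
    phi <- phase_closure(sim$state)$phi
    p_solid <- solid_pressure(phi, 1, params$tissue$phi_relaxed)
    v <- cell_velocity(grid, p_solid, params$tissue$mobility_E)
    sim$state <- advance_phases(sim$state, cfield, v, dt_sub, params)
    sim$state$theta <- advect_levelset(grid, sim$state$theta, v, dt_sub)
  }
  sim$state$theta <- redistance_levelset(grid, sim$state$theta)
  sim$oxygen <- cfield
  sim$gf <- g
  sim$t <- sim$t + dt_h
  sim
}

#' Initialize a growth simulation
#' @param net initial network (with flow solution); @param grid grid; @param
#'   tumor_radius um; @param params parameters; @param seed master seed.
#' @return sim list for [growth_step()].
#' @export
init_growth_sim <- function(net, grid, tumor_radius = 250,
                            params = default_parameters(), seed = 1L) {
  theta <- levelset_sphere(grid, tumor_radius)
  state <- continuum_state(grid, theta, params)
  list(net = net, state = state, grid = grid, params = params, seed = seed,
       t = 0)
}
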