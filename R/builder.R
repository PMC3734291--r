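# Hierarchical arteriovenous network construction: alternating root placement
# on the lattice boundary, staged stochastic tree growth with single/Y
# structural elements, temporary capillarization between opposing terminals,
# Murray radii, shear-stress-driven terminal remodeling to a capillary-count
# plateau, and the outer up-scaling loop.

tree_label <- function(net) {
  # per-node tree membership by connectivity over non-capillary segments
  segs <- net$segments[!net$segments$cap, , drop = FALSE]
  nid <- net$nodes$id
  gr <- igraph::make_empty_graph(n = length(nid), directed = FALSE)
  if (nrow(segs))
    gr <- igraph::add_edges(gr, rbind(match(segs$n1, nid), match(segs$n2, nid)))
  comp <- igraph::components(gr)$membership
  setNames(comp, nid)
}

node_kind <- function(net) {
  # "arterial"/"venous"/"none" per node, inherited from the root of its tree
  lab <- tree_label(net)
  kind <- setNames(rep("none", nrow(net$nodes)), net$nodes$id)
  for (b in c("arterial-root", "venous-root")) {
    roots <- net$nodes$id[net$nodes$bc == b]
    kk <- sub("-root", "", b)
    kind[lab %in% lab[as.character(roots)]] <- kk
  }
  kind
}

node_degree <- function(net) {
  tab <- table(factor(c(net$segments$n1, net$segments$n2),
                      levels = net$nodes$id))
  setNames(as.integer(tab), net$nodes$id)
}

terminal_nodes <- function(net) {
  # leaves of the trees: degree-1 nodes over non-capillary segments, not roots
  segs <- net$segments[!net$segments$cap, , drop = FALSE]
  tab <- table(factor(c(segs$n1, segs$n2), levels = net$nodes$id))
  ids <- net$nodes$id[tab == 1 & net$nodes$bc == "none"]
  ids
}

#' Place alternating arterial/venous tree roots on the lattice boundary
#'
#' Roots are put on boundary sites in perimeter-traversal order, evenly spaced,
#' with types alternating arterial, venous, arterial, ...  The traversal start
#' is drawn with the supplied RNG stream so different seeds give different
#' placements while a fixed seed reproduces exactly.
#'
#' @param lat lattice; @param n_roots even number of roots (>= 2);
#' @param seed integer seed for the placement stream.
#' @return `vessel_network` with tagged root nodes (pressures assigned later,
#'   once root radii are known).
#' @export
place_roots <- function(lat, n_roots = 6L, seed = 1L) {
  b <- boundary_sites(lat)
  if (!nrow(b)) stop("lattice has no boundary sites")
  if (n_roots < 2L || n_roots > nrow(b)) stop("invalid number of roots")
  rng <- local({ set.seed(seed); sample.int(nrow(b), 1L) })
  ord <- ((seq_len(nrow(b)) + rng - 2L) %% nrow(b)) + 1L
  pick <- ord[round(seq(1, nrow(b), length.out = n_roots + 1L))[-(n_roots + 1L)]]
  net <- vessel_network(lat)
  for (m in seq_along(pick)) {
    bc <- if (m %% 2L == 1L) "arterial-root" else "venous-root"
    net <- net_add_node(net, b[pick[m], ], bc = bc)$net
  }
  net
}

# append one structural element (single bond or Y aggregate) at node `leaf`;
# returns list(net, grown)
.append_element <- function(net, leaf, occ_bond, occ_site, p_single, r_term) {
  site <- as.integer(node_site(net, leaf))
  nbs <- site_neighbors(net$lat, site)
  free <- apply(nbs, 1, function(s)
    is.null(occ_bond[[bond_key(site, s)]]) && is.null(occ_site[[site_key(s)]]))
  nbs <- nbs[free, , drop = FALSE]
  if (!nrow(nbs)) return(list(net = net, grown = FALSE))
  mark <- function(a, b) {
    assign(bond_key(a, b), TRUE, envir = occ_bond)
    assign(site_key(b), -1L, envir = occ_site)
  }
  single <- runif(1) < p_single || nrow(nbs) < 3
  first <- nbs[sample.int(nrow(nbs), 1L), ]
  res <- net_add_segment(net, site, first, r = r_term,
                         check_occupancy = FALSE)
  net <- res$net
  mark(site, first)
  if (!single) {
    # Y element: two further bonds from the new stem end
    stem <- as.integer(first)
    nb2 <- site_neighbors(net$lat, stem)
    ok <- apply(nb2, 1, function(s)
      is.null(occ_bond[[bond_key(stem, s)]]) &&
        is.null(occ_site[[site_key(s)]]))
    nb2 <- nb2[ok, , drop = FALSE]
    if (nrow(nb2) >= 2) {
      ch <- nb2[sample.int(nrow(nb2), 2L), , drop = FALSE]
      for (m in 1:2) {
        net <- net_add_segment(net, stem, ch[m, ], r = r_term,
                               check_occupancy = FALSE)$net
        mark(stem, ch[m, ])
      }
    }
  }
  list(net = net, grown = TRUE)
}

#' Grow vascular trees by stochastic appending of structural elements
#'
#' Starting from the placed roots (or the terminals promoted to roots after an
#' up-scaling step), single vessels or Y-shaped three-vessel aggregates are
#' appended to randomly chosen current leaves on free, unoccupied lattice
#' bonds, until no legal attachment remains.  Trees stay cycle-free because
#' target sites must be unoccupied.
#'
#' @param net network with roots; @param params parameters; @param seed RNG
#'   seed for the growth stream; @param max_steps safety cap.
#' @return grown network.
#' @export
grow_trees <- function(net, params = default_parameters(), seed = 1L,
                       max_steps = 100000L) {
  set.seed(seed)
  pb <- params$builder
  deg <- node_degree(net)
  frontier <- unique(c(net$nodes$id[net$nodes$bc != "none" & deg[as.character(net$nodes$id)] == 0],
                       terminal_nodes(net)))
  steps <- 0L
  occ_bond <- occupied_bonds(net); occ_site <- occupied_sites(net)
  while (length(frontier) && steps < max_steps) {
    steps <- steps + 1L
    pickm <- sample.int(length(frontier), 1L)
    leaf <- frontier[pickm]
    res <- .append_element(net, leaf, occ_bond, occ_site, pb$p_single,
                           pb$r_arterial_terminal)
    net <- res$net
    if (res$grown) {
      frontier <- unique(c(frontier[-pickm], terminal_nodes(net)))
    } else {
      frontier <- frontier[-pickm]                   # fully blocked leaf
    }
  }
  net
}

#' Temporarily insert capillaries between opposing terminals
#'
#' For every arterial terminal with a venous terminal on a neighboring lattice
#' site reachable over a free bond, a capillary segment of radius
#' `r_capillary` is inserted (flagged `cap`).  Terminals of equal type are
#' never connected.
#'
#' @param net network; @param params parameters.
#' @return network with capillaries.
#' @export
insert_capillaries <- function(net, params = default_parameters()) {
  kind <- node_kind(net)
  term <- terminal_nodes(net)
  if (!length(term)) return(net)
  aterm <- term[kind[as.character(term)] == "arterial"]
  vterm <- term[kind[as.character(term)] == "venous"]
  if (!length(aterm) || !length(vterm)) return(net)
  vsites <- new.env(hash = TRUE, parent = emptyenv())
  for (id in vterm) assign(site_key(node_site(net, id)), id, envir = vsites)
  occ <- occupied_bonds(net)
  osite <- occupied_sites(net)
  rcap <- params$builder$r_capillary
  addcap <- function(net, a, b) {
    net <- net_add_segment(net, a, b, r = rcap, cap = TRUE,
                           check_occupancy = FALSE)$net
    assign(bond_key(a, b), TRUE, envir = occ)
    assign(site_key(b), -1L, envir = osite)
    net
  }
  for (id in aterm) {
    site <- as.integer(node_site(net, id))
    nbs <- site_neighbors(net$lat, site)
    done <- FALSE
    # direct bond to a venous terminal
    for (m in seq_len(nrow(nbs))) {
      vid <- vsites[[site_key(nbs[m, ])]]
      if (is.null(vid)) next
      if (!is.null(occ[[bond_key(site, nbs[m, ])]])) next
      net <- addcap(net, site, nbs[m, ])
      done <- TRUE
      break
    }
    if (done) next
    # two-bond path through one free intermediate site
    for (m in seq_len(nrow(nbs))) {
      mid <- nbs[m, ]
      if (!is.null(osite[[site_key(mid)]])) next
      if (!is.null(occ[[bond_key(site, mid)]])) next
      nb2 <- site_neighbors(net$lat, mid)
      for (m2 in seq_len(nrow(nb2))) {
        vid <- vsites[[site_key(nb2[m2, ])]]
        if (is.null(vid)) next
        if (!is.null(occ[[bond_key(mid, nb2[m2, ])]])) next
        net <- addcap(net, site, mid)
        net <- addcap(net, mid, nb2[m2, ])
        done <- TRUE
        break
      }
      if (done) break
    }
  }
  net
}

#' Assign radii by Murray's law
#'
#' Leaves get the terminal radii (arterial/venous), capillaries keep
#' `r_capillary`, and every parent radius satisfies
#' `r_parent^alpha = sum(r_child^alpha)` on a postorder sweep from the leaves
#' to the roots of each tree.
#'
#' @param net network (trees + optional capillaries); @param params parameters.
#' @return network with radii set.
#' @export
assign_murray_radii <- function(net, params = default_parameters()) {
  alpha <- params$builder$murray_alpha
  kind <- node_kind(net)
  segs <- net$segments
  tree <- which(!segs$cap)
  if (!length(tree)) return(net)
  roots <- net$nodes$id[net$nodes$bc != "none"]
  # orient trees away from roots by BFS
  nid <- net$nodes$id
  inc <- lapply(seq_along(nid), function(x) integer(0))
  names(inc) <- as.character(nid)
  for (m in tree) {
    inc[[as.character(segs$n1[m])]] <- c(inc[[as.character(segs$n1[m])]], m)
    inc[[as.character(segs$n2[m])]] <- c(inc[[as.character(segs$n2[m])]], m)
  }
  r_new <- segs$r
  parent_of <- rep(NA_integer_, nrow(segs))   # child segment rows per segment
  order_rows <- integer(0)
  visited_nodes <- new.env(hash = TRUE, parent = emptyenv())
  for (rt in roots) {
    queue <- rt
    assign(as.character(rt), TRUE, envir = visited_nodes)
    while (length(queue)) {
      nd <- queue[1]; queue <- queue[-1]
      for (m in inc[[as.character(nd)]]) {
        other <- if (segs$n1[m] == nd) segs$n2[m] else segs$n1[m]
        if (!is.null(visited_nodes[[as.character(other)]])) {
          if (is.na(parent_of[m])) parent_of[m] <- -1L  # cycle within tree
          next
        }
        assign(as.character(other), TRUE, envir = visited_nodes)
        parent_of[m] <- nd                    # node closer to root
        order_rows <- c(order_rows, m)
        queue <- c(queue, other)
      }
    }
  }
  if (any(parent_of[tree] == -1L, na.rm = TRUE))
    stop("cycle encountered within a tree")
  # postorder: reverse BFS order; child radii known before parent
  for (m in rev(order_rows)) {
    far <- if (segs$n1[m] == parent_of[m]) segs$n2[m] else segs$n1[m]
    child_rows <- setdiff(inc[[as.character(far)]], m)
    if (!length(child_rows)) {
      k <- kind[as.character(far)]
      r_new[m] <- if (identical(k, "venous")) params$builder$r_venous_terminal
                  else params$builder$r_arterial_terminal
    } else {
      r_new[m] <- sum(r_new[child_rows]^alpha)^(1 / alpha)
    }
  }
  net$segments$r <- r_new
  net$segments$w <- normal_wall_thickness(net$segments$r)
  net
}

# prescribe root pressures from the radius of the attached segment
.set_root_pressures <- function(net) {
  for (b in c("arterial-root", "venous-root")) {
    ids <- net$nodes$id[net$nodes$bc == b]
    for (id in ids) {
      rows <- which(net$segments$n1 == id | net$segments$n2 == id)
      if (!length(rows)) { net$nodes$press[net$nodes$id == id] <- NA; next }
      r <- max(net$segments$r[rows])
      net$nodes$press[net$nodes$id == id] <-
        root_pressure(r, sub("-root", "", b))
    }
  }
  # root nodes that never grew a tree do not constrain the solve
  dangling <- net$nodes$bc != "none" & is.na(net$nodes$press)
  net$nodes$bc[dangling] <- "none"
  net
}

# one flow solve on the capillarized network; silently returns NULL on failure
.try_flow <- function(net, params) {
  net2 <- assign_murray_radii(net, params)
  net2 <- .set_root_pressures(net2)
  used <- unique(c(net2$segments$n1, net2$segments$n2))
  net2$nodes <- net2$nodes[net2$nodes$id %in% used, , drop = FALSE]
  out <- tryCatch(solve_nodal_pressures(net2, params), error = function(e) NULL)
  out
}

#' Shear-stress-driven growth/shrinkage of terminal branches
#'
#' Iterative remodeling stage: flow is solved on the capillarized network and
#' terminals are stochastically removed or extended with probabilities
#' monotone in the rank of their wall shear stress among all terminals (high
#' shear grows, low shear shrinks; probabilities bounded away from 0 and 1).
#' Capillaries are re-inserted after every sweep.  Iteration stops when the
#' moving average of the capillary count changes by less than
#' `plateau_tol` over `plateau_window` sweeps.
#'
#' @param net capillarized network; @param params parameters; @param seed RNG
#'   seed.
#' @return list(net, capillary_history).
#' @export
shear_remodel <- function(net, params = default_parameters(), seed = 1L) {
  set.seed(seed)
  pb <- params$builder
  hist <- integer(0)
  for (sweep in seq_len(pb$max_remodel_sweeps)) {
    net <- net_remove_segments(net, net$segments$id[net$segments$cap])
    net <- insert_capillaries(net, params)
    flow <- .try_flow(net, params)
    hist <- c(hist, sum(net$segments$cap))
    if (!is.null(flow)) {
      fnet <- flow$net
      # map shear back to the working net by segment id
      fmap <- setNames(fnet$segments$f, fnet$segments$id)
      term <- terminal_nodes(net)
      if (length(term)) {
        # removal: low-shear terminal segments are pruned
        fterm <- vapply(term, function(id) {
          rows <- which(net$segments$n1 == id | net$segments$n2 == id)
          rows <- rows[!net$segments$cap[rows]]
          if (!length(rows)) return(0)
          f <- fmap[as.character(net$segments$id[rows])]
          max(c(f, 0), na.rm = TRUE)
        }, numeric(1))
        p_grow <- shear_growth_probability(fterm)
        removed <- 0L
        for (m in sample(seq_along(term))) {
          id <- term[m]
          if (runif(1) < (1 - p_grow[m])) {
            rows <- which((net$segments$n1 == id | net$segments$n2 == id) &
                          !net$segments$cap)
            if (length(rows) == 1) {
              net <- net_remove_segments(net, net$segments$id[rows])
              removed <- removed + 1L
            }
          }
        }
        # attachment: new side branches sprout at nodes of high-shear
        # (perfused) segments, filling space near flowing paths
        tree_rows <- which(!net$segments$cap)
        if (length(tree_rows)) {
          fseg <- fmap[as.character(net$segments$id[tree_rows])]
          fseg[is.na(fseg)] <- 0
          w <- rank(fseg, ties.method = "average")
          n_att <- length(term)
          pickrows <- tree_rows[sample.int(length(tree_rows), n_att,
                                           replace = TRUE, prob = w)]
          occ_bond <- occupied_bonds(net); occ_site <- occupied_sites(net)
          for (rw in pickrows) {
            if (rw > nrow(net$segments)) next
            nd <- if (runif(1) < 0.5) net$segments$n1[rw] else net$segments$n2[rw]
            if (net$nodes$bc[match(nd, net$nodes$id)] != "none") next
            net <- .append_element(net, nd, occ_bond, occ_site, 1,
                                   pb$r_arterial_terminal)$net
          }
        }
      }
    }
    if (length(hist) >= 2 * pb$plateau_window) {
      a <- mean(tail(hist, pb$plateau_window))
      b <- mean(head(tail(hist, 2 * pb$plateau_window), pb$plateau_window))
      if (abs(a - b) <= pb$plateau_tol * max(1, b)) break
    }
  }
  net <- net_remove_segments(net, net$segments$id[net$segments$cap])
  net <- insert_capillaries(net, params)
  list(net = net, capillary_history = hist)
}

#' Monotone map from terminal shear stress to growth probability
#'
#' Probabilities proportional to the rank of the shear stress within the
#' terminal population, rescaled into [0.1, 0.9]: equal stresses give equal
#' probabilities; zero-flow terminals get the minimum (maximal removal
#' probability).
#' @param f vector of terminal wall shear stresses (kPa).
#' @return growth probabilities in [0.1, 0.9].
#' @export
shear_growth_probability <- function(f) {
  if (!length(f)) return(numeric(0))
  if (length(unique(f)) == 1) return(rep(0.5, length(f)))
  rk <- rank(f, ties.method = "average")
  0.1 + 0.8 * (rk - 1) / (length(f) - 1)
}

#' Construct the hierarchical arteriovenous initial network
#'
#' Full pipeline: root placement, stochastic tree growth, capillarization +
#' Murray radii + shear remodeling to a capillary plateau, then `upscale_steps`
#' rounds of lattice subdivision (previous terminals become new roots) with
#' renewed growth and remodeling.  Finally unperfused branches are pruned so
#' that every remaining capillary lies on an arterio-venous path.
#'
#' @param params parameters ([default_parameters()]); @param seed master seed.
#' @return list(net, flow, capillary_history).
#' @export
construct_initial_network <- function(params = default_parameters(),
                                      seed = 1L) {
  lat <- build_lattice(params$lattice$extent, params$lattice$spacing,
                       params$lattice$kind)
  net <- place_roots(lat, params$builder$n_roots,
                     seed = derive_seed(seed, "roots"))
  net <- grow_trees(net, params, seed = derive_seed(seed, "grow0"))
  net <- insert_capillaries(net, params)
  res <- shear_remodel(net, params, seed = derive_seed(seed, "remodel0"))
  net <- res$net
  hist <- res$capillary_history
  if (params$builder$upscale_steps > 0)
    for (u in seq_len(params$builder$upscale_steps)) {
      net <- net_remove_segments(net, net$segments$id[net$segments$cap])
      net <- subdivide_network(net)
      net <- grow_trees(net, params, seed = derive_seed(seed, paste0("grow", u)))
      net <- insert_capillaries(net, params)
      res <- shear_remodel(net, params, seed = derive_seed(seed, paste0("remodel", u)))
      net <- res$net
      hist <- c(hist, res$capillary_history)
    }
  net <- assign_murray_radii(net, params)
  net <- .set_root_pressures(net)
  flow <- solve_nodal_pressures(net, params)
  net <- flow$net
  net <- prune_unperfused(net, params)
  # pruning changes the tree topology, so the Murray radii are re-derived on
  # the final graph (re-derivation is then idempotent)
  net <- assign_murray_radii(net, params)
  net <- .set_root_pressures(net)
  flow <- solve_nodal_pressures(net, params)
  list(net = flow$net, flow = flow, capillary_history = hist)
}

#' Remove unperfused branches
#'
#' Iteratively deletes segments carrying (numerically) zero flow that are not
#' needed for connectivity of perfused paths, then drops orphaned nodes.
#' @param net network with a current flow solution; @param params parameters.
#' @return pruned network.
#' @export
prune_unperfused <- function(net, params = default_parameters()) {
  repeat {
    dead <- net$segments$id[!net$segments$perfused]
    if (!length(dead)) break
    net <- net_remove_segments(net, dead)
    if (!nrow(net$segments)) break
    sol <- tryCatch(solve_nodal_pressures(net, params), error = function(e) NULL)
    if (is.null(sol)) break
    net <- sol$net
  }
  net
}
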