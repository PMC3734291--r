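test_that("roots alternate arterial/venous along the boundary traversal", {
  lat <- build_lattice(c(10, 10, 1), 80, "tri")
  net <- place_roots(lat, 4L, seed = 3)
  expect_equal(net$nodes$bc,
               c("arterial-root", "venous-root", "arterial-root", "venous-root"))
  # deterministic placement under a fixed seed
  net2 <- place_roots(lat, 4L, seed = 3)
  expect_equal(net$nodes[, c("i", "j", "k")], net2$nodes[, c("i", "j", "k")])
  net3 <- place_roots(lat, 4L, seed = 99)
  expect_false(identical(net$nodes$i, net3$nodes$i))
  expect_error(place_roots(lat, 1L), "roots")
})

test_that("tree growth stays cycle-free and never overlaps occupied bonds", {
  p <- test_params()
  lat <- build_lattice(c(10, 10, 1), 80, "tri")
  net <- place_roots(lat, 6L, seed = 3)
  net <- grow_trees(net, p, seed = 4)
  expect_true(validate_network(net))   # rejects duplicate bond occupancy
  # cycle-free: edges = nodes - number of trees
  nid <- net$nodes$id
  gr <- igraph::graph_from_edgelist(
    cbind(match(net$segments$n1, nid), match(net$segments$n2, nid)),
    directed = FALSE)
  expect_equal(igraph::gsize(gr),
               igraph::vcount(gr) - igraph::components(gr)$no)
})

test_that("capillaries join only opposing terminals at the capillary radius", {
  p <- test_params()
  lat <- build_lattice(c(10, 10, 1), 80, "tri")
  net <- place_roots(lat, 6L, seed = 3)
  net <- grow_trees(net, p, seed = 4)
  net <- insert_capillaries(net, p)
  caps <- net$segments[net$segments$cap, ]
  expect_true(all(caps$r == p$builder$r_capillary))
  # no capillary connects two same-type trees
  kind <- tumorperf:::node_kind(net)
  if (nrow(caps)) {
    k1 <- kind[as.character(caps$n1)]
    k2 <- kind[as.character(caps$n2)]
    expect_false(any(k1 == "arterial" & k2 == "arterial"))
    expect_false(any(k1 == "venous" & k2 == "venous"))
  }
  # two adjacent same-type terminals never get a capillary
  small <- vessel_network(lat)
  small <- net_add_node(small, c(0L, 0L, 0L), "arterial-root")$net
  small <- net_add_node(small, c(0L, 4L, 0L), "arterial-root")$net
  small <- net_add_segment(small, c(0L, 0L, 0L), c(1L, 0L, 0L), r = 4)$net
  small <- net_add_segment(small, c(0L, 4L, 0L), c(1L, 4L, 0L), r = 4)$net
  small2 <- insert_capillaries(small, p)
  expect_equal(sum(small2$segments$cap), 0)
})

test_that("Murray's law radii: two equal children, single child, monotonicity", {
  p <- test_params()
  lat <- build_lattice(c(8, 8, 1), 80, "tri")
  # hand-built Y tree: root - stem - two children with terminal radius 4
  p$builder$r_arterial_terminal <- 4
  net <- vessel_network(lat)
  net <- net_add_node(net, c(0L, 2L, 0L), "arterial-root")$net
  net <- net_add_segment(net, c(0L, 2L, 0L), c(1L, 2L, 0L), r = 1)$net
  net <- net_add_segment(net, c(1L, 2L, 0L), c(2L, 1L, 0L), r = 1)$net
  net <- net_add_segment(net, c(1L, 2L, 0L), c(1L, 3L, 0L), r = 1)$net
  net <- assign_murray_radii(net, p)
  expect_equal(net$segments$r[2], 4)
  expect_equal(net$segments$r[3], 4)
  expect_equal(net$segments$r[1], 4 * 2^(1 / 3), tolerance = 1e-12)
  # single child: parent radius equals child radius
  net1 <- vessel_network(lat)
  net1 <- net_add_node(net1, c(0L, 2L, 0L), "arterial-root")$net
  net1 <- net_add_segment(net1, c(0L, 2L, 0L), c(1L, 2L, 0L), r = 1)$net
  net1 <- net_add_segment(net1, c(1L, 2L, 0L), c(2L, 2L, 0L), r = 1)$net
  net1 <- assign_murray_radii(net1, p)
  expect_equal(net1$segments$r[1], net1$segments$r[2])
  # on a grown tree, radii never decrease from terminals toward the root,
  # and re-deriving radii reproduces the stored values exactly
  res <- test_network()
  net2 <- assign_murray_radii(res$net, test_params())
  expect_equal(net2$segments$r, res$net$segments$r, tolerance = 1e-12)
  alpha <- test_params()$builder$murray_alpha
  deg <- tumorperf:::node_degree(net2)
  segs <- net2$segments[!net2$segments$cap, ]
  for (nd in net2$nodes$id[deg >= 3]) {
    inc <- segs[segs$n1 == nd | segs$n2 == nd, ]
    if (nrow(inc) < 3) next
    rmax <- max(inc$r)
    expect_gte(rmax^alpha + 1e-9, sum(inc$r[inc$r < rmax - 1e-12]^alpha))
  }
})

test_that("shear-to-growth probability map is monotone and bounded", {
  expect_equal(shear_growth_probability(c(1, 1, 1)), rep(0.5, 3))
  p <- shear_growth_probability(c(0, 0.2, 0.5, 0.9))
  expect_equal(p[1], 0.1)            # zero-flow terminal: maximal removal
  expect_equal(p[4], 0.9)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0.1 - 1e-12 & p <= 0.9 + 1e-12))
})

test_that("remodeling reaches a capillary-count plateau on a 2D fixture", {
  res <- test_network()
  hist <- res$capillary_history
  p <- test_params()
  expect_lt(length(hist), p$builder$max_remodel_sweeps * (1 + p$builder$upscale_steps))
  w <- p$builder$plateau_window
  a <- mean(tail(hist, w))
  b <- mean(head(tail(hist, 2 * w), w))
  expect_lte(abs(a - b), p$builder$plateau_tol * max(1, b))
})

test_that("constructed network is fully perfused with surviving roots < placed", {
  res <- test_network()
  net <- res$net
  expect_true(all(net$segments$perfused))
  expect_true(all(net$segments$q > 0))
  # every capillary lies on an arterio-venous path (it carries flow and the
  # graph only conducts between an arterial and a venous root)
  expect_true(all(net$segments$q[net$segments$cap] > 0))
  expect_lt(sum(net$nodes$bc != "none"), test_params()$builder$n_roots + 1)
  # determinism under a fixed seed
  res2 <- construct_initial_network(test_params(), seed = 7)
  expect_equal(res2$net$segments$id, net$segments$id)
  expect_equal(res2$net$segments$r, net$segments$r)
})

test_that("zero up-scaling steps reduce to single-stage construction", {
  p <- test_params()
  p$builder$upscale_steps <- 0L
  res <- construct_initial_network(p, seed = 11)
  expect_true(nrow(res$net$segments) > 0)
  expect_true(all(res$net$segments$perfused))
})

test_that("vascular density of the healthy network is spatially homogeneous", {
  res <- test_network()
  net <- res$net
  # total vessel length per quadrant of the lattice bounding box
  mid <- colMeans(site_position(net$lat, cbind(net$nodes$i, net$nodes$j,
                                               net$nodes$k)))
  lens <- numeric(4)
  for (m in seq_len(nrow(net$segments))) {
    s <- net$segments[m, ]
    pm <- (site_position(net$lat, node_site(net, s$n1)) +
           site_position(net$lat, node_site(net, s$n2))) / 2
    q <- 1 + (pm[1] > mid[1]) + 2 * (pm[2] > mid[2])
    lens[q] <- lens[q] + s$nbonds * net$lat$spacing
  }
  # each quadrant holds a comparable share of the total vessel length
  # (uniform would be 25%; tree branches are spatially correlated, so a
  # plain chi-square on bonds would overstate the evidence)
  share <- lens / sum(lens)
  expect_true(all(share > 0.10 & share < 0.45))
})
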