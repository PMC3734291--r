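# Shared cached fixtures: building networks and solving frozen-tumor states is
# the expensive part of the suite, so each is computed once per run.

.tp_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.tp_cache[[name]])) assign(name, force(expr), envir = .tp_cache)
  .tp_cache[[name]]
}

test_params <- function() {
  p <- default_parameters(desk = TRUE)
  p$builder$max_remodel_sweeps <- 60L
  p$builder$plateau_window <- 15L
  p
}

test_network <- function() cached("net", {
  construct_initial_network(test_params(), seed = 7)
})

frozen_fixture <- function() cached("frozen", {
  make_fixture("frozen-spherical-tumor", size = 40, seed = 1,
               params = test_params())
})

frozen_iff <- function() cached("frozen_iff", {
  fx <- frozen_fixture()
  assemble_and_solve_ifp(fx$net, fx$state, fx$grid, test_params(), seed = 3)
})

single_vessel_fixture <- function() cached("single", {
  make_fixture("single-vessel-block", size = 24, seed = 1,
               params = test_params())
})

# tiny two-root chain network for hand-solvable flow problems
chain_network <- function(n = 2, r = 5, spacing = 100, p_in = 10, p_out = 2) {
  lat <- build_lattice(c(n + 2L, 3L, 1L), spacing, "tri")
  net <- vessel_network(lat)
  net <- net_add_node(net, c(0L, 0L, 0L), "arterial-root", p_in)$net
  net <- net_add_node(net, c(n, 0L, 0L), "venous-root", p_out)$net
  for (m in seq_len(n))
    net <- net_add_segment(net, c(m - 1L, 0L, 0L), c(m, 0L, 0L), r = r)$net
  net
}
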