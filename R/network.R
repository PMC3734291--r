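# Vessel network data model: nodes at lattice sites, segments on lattice bonds.
# Segments may span several collinear bonds (straight multi-bond vessels); the
# builder and remodeling rules only create single-bond segments, and
# subdivision inserts explicit degree-2 midpoint nodes.

#' Create an empty vessel network on a lattice
#'
#' Nodes carry the lattice index, a blood pressure and a boundary-condition tag
#' (`"none"`, `"arterial-root"`, `"venous-root"`).  Segments carry radius `r`
#' (um), wall maturity `w` (um), hematocrit, flow `q` (um^3/s), wall shear `f`
#' (kPa) and the sprout/tumor/perfused/capillary flags plus sprout age and
#' time-in-tumor clocks (h).
#'
#' @param lat a `vessel_lattice`.
#' @return an object of class `vessel_network`.
#' @export
vessel_network <- function(lat) {
  structure(list(
    lat = lat,
    nodes = data.frame(id = integer(), i = integer(), j = integer(),
                       k = integer(), bc = character(), press = numeric(),
                       stringsAsFactors = FALSE),
    segments = data.frame(id = integer(), n1 = integer(), n2 = integer(),
                          nbonds = integer(), r = numeric(), w = numeric(),
                          hema = numeric(), q = numeric(), f = numeric(),
                          sprout = logical(), tumor = logical(),
                          perfused = logical(), cap = logical(),
                          tau_s = numeric(), t_tumor = numeric(),
                          stringsAsFactors = FALSE),
    next_node = 1L, next_seg = 1L), class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network: %d nodes, %d segments on %s lattice>\n",
              nrow(x$nodes), nrow(x$segments), x$lat$kind))
  invisible(x)
}

#' Add a node at a lattice site (or return the existing node id)
#' @param net network; @param site integer triple; @param bc boundary tag;
#' @param press prescribed pressure (kPa) for root nodes.
#' @return list(net, id).
#' @export
net_add_node <- function(net, site, bc = "none", press = NA_real_) {
  site <- as.integer(site)
  if (!site_valid(net$lat, matrix(site, 1))) stop("site not on lattice: ",
                                                  site_key(site))
  hit <- which(net$nodes$i == site[1] & net$nodes$j == site[2] &
               net$nodes$k == site[3])
  if (length(hit)) {
    if (bc != "none") {
      net$nodes$bc[hit] <- bc
      net$nodes$press[hit] <- press
    }
    return(list(net = net, id = net$nodes$id[hit]))
  }
  id <- net$next_node
  net$nodes <- rbind(net$nodes, data.frame(
    id = id, i = site[1], j = site[2], k = site[3], bc = bc, press = press,
    stringsAsFactors = FALSE))
  net$next_node <- id + 1L
  list(net = net, id = id)
}

node_site <- function(net, id) {
  r <- net$nodes[match(id, net$nodes$id), ]
  cbind(r$i, r$j, r$k)
}

# ordered chain of lattice sites a segment passes through (collinear multi-bond)
seg_sites <- function(net, sid) {
  s <- net$segments[match(sid, net$segments$id), ]
  a <- as.integer(node_site(net, s$n1))
  b <- as.integer(node_site(net, s$n2))
  nb <- s$nbonds
  step <- (b - a) / nb
  if (any(step != round(step))) stop("segment ", sid, " not on lattice bonds")
  t(sapply(0:nb, function(m) a + as.integer(round(step * m))))
}

#' Add a straight segment between two lattice sites
#'
#' The sites must be joined by a whole number of collinear lattice bonds; the
#' direction must be a lattice bond direction.  Duplicate occupancy of a bond
#' is rejected.
#'
#' @param net network; @param s1,s2 integer site triples; @param r radius um;
#' @param w wall maturity um (default: normal wall thickness for `r`);
#' @param hema hematocrit; @param sprout,tumor,cap flags; @param check_occupancy
#'   set FALSE when the caller maintains the occupancy map itself (fast path
#'   used by the builder and remodeling loops).
#' @return list(net, id).
#' @export
net_add_segment <- function(net, s1, s2, r, w = NULL, hema = 0.45,
                            sprout = FALSE, tumor = FALSE, cap = FALSE,
                            check_occupancy = TRUE) {
  if (r <= 0) stop("segment radius must be > 0")
  s1 <- as.integer(s1); s2 <- as.integer(s2)
  d <- s2 - s1
  # direction must be a multiple of one neighbor offset
  off <- net$lat$offsets
  nb <- NA_integer_
  for (m in seq_len(nrow(off))) {
    o <- off[m, ]
    nz <- which(o != 0L)[1]
    if (d[nz] != 0L && d[nz] %% o[nz] == 0L) {
      mult <- d[nz] %/% o[nz]
      if (mult > 0L && all(d == o * mult)) { nb <- mult; break }
    }
  }
  if (is.na(nb)) stop("sites are not joined by collinear lattice bonds")
  sites <- t(sapply(0:nb, function(m) s1 + (d %/% nb) * m))
  if (check_occupancy) {
    occ <- occupied_bonds(net)
    for (m in seq_len(nb)) {
      key <- bond_key(sites[m, ], sites[m + 1, ])
      if (!is.null(occ[[key]])) stop("bond already occupied: ", key)
    }
  }
  a <- net_add_node(net, s1); net <- a$net
  b <- net_add_node(net, s2); net <- b$net
  if (is.null(w)) w <- normal_wall_thickness(r)
  id <- net$next_seg
  net$segments <- rbind(net$segments, data.frame(
    id = id, n1 = a$id, n2 = b$id, nbonds = nb, r = r, w = w, hema = hema,
    q = NA_real_, f = NA_real_, sprout = sprout, tumor = tumor,
    perfused = FALSE, cap = cap, tau_s = if (sprout) 0 else NA_real_,
    t_tumor = 0, stringsAsFactors = FALSE))
  net$next_seg <- id + 1L
  list(net = net, id = id)
}

#' Remove segments (and orphaned interior nodes)
#' @param net network; @param sids segment ids.
#' @return network.
#' @export
net_remove_segments <- function(net, sids) {
  net$segments <- net$segments[!(net$segments$id %in% sids), , drop = FALSE]
  used <- unique(c(net$segments$n1, net$segments$n2))
  keep <- net$nodes$id %in% used | net$nodes$bc != "none"
  net$nodes <- net$nodes[keep, , drop = FALSE]
  net
}

# environment mapping occupied bond keys -> segment id, and site keys -> node id
occupied_bonds <- function(net) {
  e <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(net$segments))
    for (sid in net$segments$id) {
      sites <- seg_sites(net, sid)
      for (m in seq_len(nrow(sites) - 1))
        assign(bond_key(sites[m, ], sites[m + 1, ]), sid, envir = e)
    }
  e
}

occupied_sites <- function(net) {
  e <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(net$nodes))
    for (m in seq_len(nrow(net$nodes)))
      assign(site_key(c(net$nodes$i[m], net$nodes$j[m], net$nodes$k[m])),
             net$nodes$id[m], envir = e)
  if (nrow(net$segments))
    for (sid in net$segments$id) {
      sites <- seg_sites(net, sid)
      for (m in seq_len(nrow(sites)))
        if (is.null(e[[site_key(sites[m, ])]]))
          assign(site_key(sites[m, ]), -1L, envir = e)   # interior chain site
    }
  e
}

#' Segment length and unit direction
#' @param net network; @param sid segment id.
#' @return list(length um, direction unit 3-vector).
#' @export
segment_geometry <- function(net, sid) {
  s <- net$segments[match(sid, net$segments$id), ]
  if (is.na(s$id)) stop("no such segment: ", sid)
  p1 <- site_position(net$lat, node_site(net, s$n1))
  p2 <- site_position(net$lat, node_site(net, s$n2))
  d <- as.numeric(p2 - p1)
  len <- sqrt(sum(d^2))
  if (len == 0) stop("zero-length segment")
  list(length = s$nbonds * net$lat$spacing, direction = d / len)
}

#' Validate network referential and geometric integrity
#'
#' Checks that every segment endpoint refers to an existing node, endpoints lie
#' on lattice sites, multi-bond segments are collinear chains of bonds, no bond
#' carries two segments, and radii/wall values are in range.
#' @param net network.
#' @return TRUE invisibly; stops on violation.
#' @export
validate_network <- function(net) {
  segs <- net$segments
  if (nrow(segs)) {
    if (!all(segs$n1 %in% net$nodes$id) || !all(segs$n2 %in% net$nodes$id))
      stop("segment endpoint refers to a missing node")
    if (any(segs$r <= 0)) stop("non-positive radius")
    if (any(segs$w < 0)) stop("negative wall maturity")
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (sid in segs$id) {
      sites <- seg_sites(net, sid)       # errors if off-lattice / non-collinear
      if (!all(site_valid(net$lat, sites))) stop("segment leaves the lattice")
      for (m in seq_len(nrow(sites) - 1)) {
        key <- bond_key(sites[m, ], sites[m + 1, ])
        if (!is.null(seen[[key]])) stop("duplicate segment on bond ", key)
        assign(key, sid, envir = seen)
      }
    }
  }
  nd <- net$nodes
  if (nrow(nd) && !all(site_valid(net$lat, cbind(nd$i, nd$j, nd$k))))
    stop("node off lattice")
  invisible(TRUE)
}

#' Subdivide a network onto a refined lattice
#'
#' Halves the lattice spacing (doubling the site count per axis) so that every
#' old segment occupies two bonds, inserts an explicit midpoint node per old
#' bond, then resets the spacing to its former value: the spatial extent and all
#' segment lengths are effectively doubled.
#'
#' @param net network.
#' @return the subdivided network (with `$lat` replaced).
#' @export
subdivide_network <- function(net) {
  old <- net
  lat2 <- build_lattice(old$lat$extent * 2L, old$lat$spacing, old$lat$kind,
                        old$lat$origin)
  new <- vessel_network(lat2)
  idmap <- integer(0)
  if (nrow(old$nodes))
    for (m in seq_len(nrow(old$nodes))) {
      a <- net_add_node(new, 2L * c(old$nodes$i[m], old$nodes$j[m],
                                    old$nodes$k[m]),
                        bc = old$nodes$bc[m], press = old$nodes$press[m])
      new <- a$net
      idmap[as.character(old$nodes$id[m])] <- a$id
    }
  if (nrow(old$segments))
    for (m in seq_len(nrow(old$segments))) {
      s <- old$segments[m, ]
      sites <- 2L * seg_sites(old, s$id)   # per-bond chain, now 2 bonds apart
      for (b in seq_len(nrow(sites) - 1)) {
        mid <- (sites[b, ] + sites[b + 1, ]) %/% 2L
        for (half in list(rbind(sites[b, ], mid), rbind(mid, sites[b + 1, ]))) {
          r <- net_add_segment(new, half[1, ], half[2, ], r = s$r, w = s$w,
                               hema = s$hema, sprout = s$sprout,
                               tumor = s$tumor, cap = s$cap,
                               check_occupancy = FALSE)
          new <- r$net
          rr <- nrow(new$segments)
          new$segments$tau_s[rr] <- s$tau_s
          new$segments$t_tumor[rr] <- s$t_tumor
        }
      }
    }
  new
}

#' Contract pass-through (degree-2, non-root) nodes
#'
#' Merges pairs of collinear segments meeting at a degree-2 node into one
#' multi-bond segment; the topological inverse of [subdivide_network()].
#' @param net network.
#' @return network with pass-through nodes removed.
#' @export
contract_passthrough_nodes <- function(net) {
  repeat {
    deg <- table(factor(c(net$segments$n1, net$segments$n2),
                        levels = net$nodes$id))
    cand <- net$nodes$id[deg == 2 & net$nodes$bc == "none"]
    merged <- FALSE
    for (nid in cand) {
      sids <- net$segments$id[net$segments$n1 == nid | net$segments$n2 == nid]
      if (length(sids) != 2) next
      s1 <- net$segments[match(sids[1], net$segments$id), ]
      s2 <- net$segments[match(sids[2], net$segments$id), ]
      e1 <- setdiff(c(s1$n1, s1$n2), nid)
      e2 <- setdiff(c(s2$n1, s2$n2), nid)
      if (length(e1) != 1 || length(e2) != 1 || e1 == e2) next
      a <- as.integer(node_site(net, e1)); b <- as.integer(node_site(net, e2))
      m <- as.integer(node_site(net, nid))
      d1 <- (m - a) / s1$nbonds; d2 <- (b - m) / s2$nbonds
      if (!all(d1 == d2)) next                      # not collinear
      net$segments <- net$segments[!(net$segments$id %in% sids), , drop = FALSE]
      net$nodes <- net$nodes[net$nodes$id != nid, , drop = FALSE]
      row <- s1
      row$n1 <- e1; row$n2 <- e2; row$nbonds <- s1$nbonds + s2$nbonds
      net$segments <- rbind(net$segments, row)
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  net
}

#' Total vessel length of a network (um)
#' @param net network.
#' @export
total_vessel_length <- function(net) {
  if (!nrow(net$segments)) return(0)
  sum(net$segments$nbonds) * net$lat$spacing
}

#' Write / read a vessel network as a pair of CSV tables
#'
#' `<path>_nodes.csv` holds id, lattice index, boundary tag and pressure;
#' `<path>_segments.csv` the segment table.  Lattice metadata is stored as
#' comment-style columns in the node file header row.
#' @param net network; @param path file prefix.
#' @export
write_network_csv <- function(net, path) {
  nd <- net$nodes
  nd$lat_kind <- net$lat$kind
  nd$lat_spacing <- net$lat$spacing
  nd$lat_ex1 <- net$lat$extent[1]; nd$lat_ex2 <- net$lat$extent[2]
  nd$lat_ex3 <- net$lat$extent[3]
  write.csv(nd, paste0(path, "_nodes.csv"), row.names = FALSE)
  write.csv(net$segments, paste0(path, "_segments.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  nd <- read.csv(paste0(path, "_nodes.csv"), stringsAsFactors = FALSE)
  sg <- read.csv(paste0(path, "_segments.csv"), stringsAsFactors = FALSE)
  lat <- build_lattice(c(nd$lat_ex1[1], nd$lat_ex2[1], nd$lat_ex3[1]),
                       nd$lat_spacing[1], nd$lat_kind[1])
  net <- vessel_network(lat)
  net$nodes <- nd[, c("id", "i", "j", "k", "bc", "press")]
  net$segments <- sg
  net$next_node <- max(0L, nd$id) + 1L
  net$next_seg <- if (nrow(sg)) max(sg$id) + 1L else 1L
  net
}
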