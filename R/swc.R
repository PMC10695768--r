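#' Read and write SWC neuron morphologies
#'
#' Standard 7-column whitespace-separated SWC: `id`, `type`, `x`, `y`, `z`
#' (um), `radius` (um), `parent` (-1 for the root). The reader checks the
#' structural invariants: a single root, every parent defined before its
#' child (which also rules out cycles), and numeric coordinates. The root is
#' taken to be the soma.
#'
#' @param path SWC file path.
#' @param tree A neurite tree tibble with the seven SWC columns.
#' @return `read_swc()` returns an `msb_neurite` tibble with the seven SWC
#'   columns plus `path_dist`, the arc length to the soma along the tree.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    abort("Empty SWC file.", class = "msbnet_input_error")
  }
  fields <- utils::read.table(text = lines, col.names = c(
    "id", "type", "x", "y", "z", "radius", "parent"))
  as_neurite_tree(tibble::as_tibble(fields))
}

#' @rdname read_swc
#' @export
write_swc <- function(tree, path) {
  df <- as.data.frame(tree)[c("id", "type", "x", "y", "z", "radius",
                              "parent")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC exported by msbnet", con)
  utils::write.table(format(df, trim = TRUE, digits = 15, scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a neurite tree and compute soma path distances
#'
#' @param tbl Tibble with SWC columns.
#' @return An `msb_neurite` tibble with a `path_dist` column (um).
#' @export
as_neurite_tree <- function(tbl) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(tbl))) {
    abort("A neurite tree needs the 7 SWC columns.",
          class = "msbnet_input_error")
  }
  roots <- which(tbl$parent == -1)
  if (length(roots) != 1L) {
    abort("A neurite tree must have exactly one root (parent = -1).",
          class = "msbnet_input_error")
  }
  pos <- match(tbl$parent, tbl$id)
  bad <- which(tbl$parent != -1 & (is.na(pos) | pos >= seq_len(nrow(tbl))))
  if (length(bad)) {
    abort("Every parent must be defined before its child.",
          class = "msbnet_input_error")
  }
  # edge length to parent, accumulated root-to-node
  seg <- rep(0, nrow(tbl))
  nz <- which(tbl$parent != -1)
  seg[nz] <- sqrt((tbl$x[nz] - tbl$x[pos[nz]])^2 +
                  (tbl$y[nz] - tbl$y[pos[nz]])^2 +
                  (tbl$z[nz] - tbl$z[pos[nz]])^2)
  pd <- rep(0, nrow(tbl))
  for (i in nz) pd[i] <- pd[pos[i]] + seg[i]
  tbl$path_dist <- pd
  structure(tbl, class = c("msb_neurite", class(tibble::tibble())))
}

# Decompose a tree into unbranched segments: maximal chains whose interior
# nodes have exactly one child. A segment starts at the root or at a child
# of a branch point and runs to the next branch point or leaf. Returns the
# tree with a `segment` column (the root keeps segment 0: it anchors all
# primary segments and belongs to none of them).
segment_tree <- function(tree) {
  n <- nrow(tree)
  pos <- match(tree$parent, tree$id)
  n_children <- tabulate(pos[!is.na(pos)], nbins = n)
  is_branch <- n_children > 1
  root <- which(tree$parent == -1)
  segment <- integer(n)
  seg_id <- 0L
  for (i in seq_len(n)) {
    if (i == root) next
    p <- pos[i]
    if (p == root || is_branch[p]) {
      seg_id <- seg_id + 1L
      segment[i] <- seg_id
      j <- i
      while (n_children[j] == 1L) {
        j <- which(pos == j)
        segment[j] <- seg_id
      }
    }
  }
  tree$segment <- segment
  tree
}

#' Resample a neurite tree at constant node spacing
#'
#' Re-samples every unbranched segment at constant arc-length spacing
#' (default 0.5 um), preserving branch-point and tip positions so the tree
#' topology is unchanged. Node positions between original nodes are linear
#' interpolations of the trace.
#'
#' @param tree An `msb_neurite`.
#' @param spacing Node spacing, um (default 0.5).
#' @return An `msb_neurite` with `segment` and `path_dist` columns.
#' @export
resample_neurite <- function(tree, spacing = 0.5) {
  if (spacing <= 0) {
    abort("`spacing` must be positive.", class = "msbnet_input_error")
  }
  tree <- segment_tree(as_neurite_tree(tibble::as_tibble(tree)))
  pos <- match(tree$parent, tree$id)
  root <- which(tree$parent == -1)
  segs <- split(seq_len(nrow(tree))[tree$segment > 0],
                tree$segment[tree$segment > 0])

  new_id <- 0L
  rows <- list()
  add_node <- function(type, xyz, radius, parent, path_dist, segment) {
    new_id <<- new_id + 1L
    rows[[new_id]] <<- tibble::tibble(
      id = new_id, type = type, x = xyz[1], y = xyz[2], z = xyz[3],
      radius = radius, parent = parent, path_dist = path_dist,
      segment = segment)
    new_id
  }
  add_node(tree$type[root], c(tree$x[root], tree$y[root], tree$z[root]),
           tree$radius[root], -1L, 0, 0L)
  # map old node id -> new node id for segment anchors (root & branch ends)
  anchor_map <- stats::setNames(1L, tree$id[root])

  for (s in segs) {
    s <- s[order(match(tree$parent[s], tree$id))]  # parent-before-child order
    start_old <- tree$parent[s[1]]
    anchor_new <- anchor_map[[as.character(start_old)]]
    anchor_row <- rows[[anchor_new]]
    poly <- rbind(c(anchor_row$x, anchor_row$y, anchor_row$z),
                  cbind(tree$x[s], tree$y[s], tree$z[s]))
    dl <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                        poly[-nrow(poly), , drop = FALSE])^2))
    cum <- c(0, cumsum(dl))
    L <- cum[length(cum)]
    arcs <- seq(spacing, L, by = spacing)
    if (length(arcs) == 0 || L - arcs[length(arcs)] > spacing / 2) {
      arcs <- c(arcs, L)   # keep the tip/branch point
    } else {
      arcs[length(arcs)] <- L
    }
    parent <- anchor_new
    base_pd <- anchor_row$path_dist
    for (aa in arcs) {
      k <- findInterval(aa, cum, rightmost.closed = TRUE)
      k <- min(max(k, 1L), length(dl))
      w <- if (dl[k] > 0) (aa - cum[k]) / dl[k] else 0
      xyz <- poly[k, ] + w * (poly[k + 1, ] - poly[k, ])
      parent <- add_node(tree$type[s[1]], xyz, tree$radius[s[1]], parent,
                         base_pd + aa, tree$segment[s[1]])
    }
    anchor_map[[as.character(tree$id[s[length(s)]])]] <- parent
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("msb_neurite", class(tibble::tibble())))
}

#' Dendrite self-proximity along the arbor
#'
#' Quantifies how often separate branches of the same dendritic tree come
#' close enough to contribute spines to a shared presynaptic bouton. The
#' tree is resampled at constant `node_spacing` (default 0.5 um); for every
#' node the analysis counts the distinct *other* unbranched branches having
#' at least one node within the 3D Euclidean `threshold` (default 5 um).
#' Nodes whose along-tree path distance to the query node is below
#' `path_exclusion` are ignored, so sibling segments immediately adjacent to
#' a shared branch point do not register as spurious contacts. Nodes are
#' then ordered by path distance to the soma and split into `n_bins`
#' equal-count bins; the per-bin mean count is returned.
#'
#' @param tree An `msb_neurite` (see [read_swc()], [generate_neurite_tree()]).
#' @param node_spacing Resampling spacing, um (default 0.5).
#' @param threshold Euclidean proximity threshold, um (default 5).
#' @param n_bins Number of equal-count soma-distance bins (default 10).
#' @param path_exclusion Minimum along-tree path distance for a node pair to
#'   count, um (default 5).
#' @return An `msb_proximity` tibble: `bin`, `n_nodes`, `mean_soma_distance`
#'   (um), `mean_count`. Fewer than `n_bins` rows (with a warning) if the
#'   tree has fewer nodes than bins.
#' @export
dendrite_self_proximity <- function(tree, node_spacing = 0.5, threshold = 5,
                                    n_bins = 10,
                                    path_exclusion = 5) {
  rt <- resample_neurite(tree, node_spacing)
  n <- nrow(rt)
  xyz <- as.matrix(rt[c("x", "y", "z")])
  eu <- as.matrix(stats::dist(xyz))
  g <- igraph::graph_from_edgelist(
    cbind(rt$parent[rt$parent != -1], rt$id[rt$parent != -1]),
    directed = FALSE)
  edge_ends <- igraph::ends(g, igraph::E(g))
  igraph::E(g)$weight <- sqrt(rowSums(
    (xyz[edge_ends[, 1], , drop = FALSE] -
     xyz[edge_ends[, 2], , drop = FALSE])^2))
  pd <- igraph::distances(g)
  seg <- rt$segment
  counts <- integer(n)
  for (i in seq_len(n)) {
    js <- which(eu[i, ] <= threshold & seg != seg[i] & seg > 0 &
                pd[i, ] >= path_exclusion)
    counts[i] <- length(unique(seg[js]))
  }
  keep <- seg > 0   # drop the soma anchor itself
  df <- tibble::tibble(soma_distance = rt$path_dist[keep],
                       count = counts[keep])
  if (nrow(df) < n_bins) {
    warn(sprintf("Tree has %d nodes < %d bins; returning fewer bins.",
                 nrow(df), n_bins))
    n_bins <- max(1L, nrow(df))
  }
  df <- dplyr::arrange(df, .data$soma_distance)
  df$bin <- dplyr::ntile(seq_len(nrow(df)), n_bins)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$bin),
    n_nodes = dplyr::n(),
    mean_soma_distance = mean(.data$soma_distance),
    mean_count = mean(.data$count),
    .groups = "drop")
  structure(out, class = c("msb_proximity", class(tibble::tibble())))
}

#' Plot per-bin dendrite self-proximity
#'
#' @param object An `msb_proximity` tibble.
#' @param ... Unused.
#' @return A ggplot of mean nearby-branch count against soma distance.
#' @export
autoplot.msb_proximity <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$mean_soma_distance,
                               y = .data$mean_count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance to soma (µm)",
                  y = "mean nearby separate branches") +
    ggplot2::theme_minimal()
}
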