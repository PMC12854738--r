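## Superbasin analysis and disconnectivity trees.
##
## Two minima belong to the same superbasin at threshold E iff a path
## connects them whose transition states all lie at or below E. A
## disconnectivity tree evaluates the superbasin partition on a descending
## grid of thresholds; leaves are minima attached at their own energies and
## branches merge at the lowest grid level admitting a connecting path.

#' Superbasin partition at an energy threshold
#'
#' @param net A `ktn` object. For free-energy analysis pass the
#'   [quotient_ktn()] of a grouped network.
#' @param E Threshold energy (kcal/mol).
#' @return Integer vector of basin labels, one per minimum (labels are the
#'   smallest member id of each basin); `NA` for minima with `V > E`.
#' @export
superbasin_partition <- function(net, E) {
  stopifnot(inherits(net, "ktn"))
  n <- n_minima(net)
  keep_min <- net$minima$V <= E
  ets <- .edge_ts(net)
  ets <- ets[ets$V <= E, , drop = FALSE]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(ets)) g <- igraph::add_edges(g, rbind(ets$min1, ets$min2))
  comp <- igraph::components(g)$membership
  ## label each basin by its smallest member id, NA out the excluded minima
  lab <- stats::ave(seq_len(n), comp, FUN = min)
  lab[!keep_min] <- NA_integer_
  as.integer(lab)
}

#' Build a disconnectivity tree
#'
#' @param net A `ktn` object (potential energies), or a [quotient_ktn()]
#'   for a free-energy tree.
#' @param dE Level spacing in kcal/mol (> 0).
#' @param E_max Top threshold; defaults to the highest transition-state (or
#'   minimum) energy plus one `dE`.
#' @return A `disconnectivity_tree`: list with `levels` (descending
#'   thresholds), `nodes` (data.frame `id`, `level`, `energy`, `parent`),
#'   `membership` (minima x levels matrix of node ids), `leaf_node` (node id
#'   at which each minimum attaches) and the source `ktn`.
#' @export
build_tree <- function(net, dE, E_max = NULL) {
  stopifnot(inherits(net, "ktn"))
  if (dE <= 0) stop("dE must be positive")
  if (n_minima(net) == 0L) stop("empty KTN")
  top_guess <- max(c(net$minima$V, net$ts$V))
  if (is.null(E_max)) E_max <- top_guess + dE
  if (E_max < min(net$minima$V))
    stop("E_max lies below the global minimum; empty tree")
  levels <- seq(E_max, min(net$minima$V) - dE, by = -dE)
  n <- n_minima(net)
  nl <- length(levels)
  part <- vapply(levels, function(E) superbasin_partition(net, E),
                 integer(n))
  part <- matrix(part, nrow = n)
  ## assign node ids: one node per (level, basin label) with any member
  nodes <- data.frame(id = integer(0), level = integer(0),
                      energy = numeric(0), parent = integer(0))
  membership <- matrix(NA_integer_, n, nl)
  node_key <- new.env(parent = emptyenv())
  next_id <- 0L
  for (li in seq_len(nl)) {
    labs <- unique(part[!is.na(part[, li]), li])
    for (lb in sort(labs)) {
      next_id <- next_id + 1L
      assign(paste(li, lb), next_id, envir = node_key)
      members <- which(!is.na(part[, li]) & part[, li] == lb)
      membership[members, li] <- next_id
      parent <- if (li == 1L) NA_integer_ else {
        ## containing cell one level up: any member present there
        up <- membership[members, li - 1L]
        up <- up[!is.na(up)][1]
        if (is.na(up)) NA_integer_ else up
      }
      nodes <- rbind(nodes, data.frame(id = next_id, level = li,
                                       energy = levels[li], parent = parent))
    }
  }
  leaf_node <- vapply(seq_len(n), function(i) {
    present <- which(!is.na(membership[i, ]))
    if (!length(present)) NA_integer_ else membership[i, max(present)]
  }, integer(1))
  structure(list(levels = levels, nodes = nodes, membership = membership,
                 leaf_node = leaf_node, ktn = net),
            class = "disconnectivity_tree")
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  cat(sprintf("<disconnectivity_tree> %d minima, %d levels [%.4g .. %.4g], %d nodes\n",
              nrow(x$membership), length(x$levels), max(x$levels),
              min(x$levels), nrow(x$nodes)))
  invisible(x)
}

#' Merge level of two leaves
#'
#' The lowest level threshold at which two minima share a superbasin node.
#'
#' @param tree A `disconnectivity_tree`.
#' @param i,j Minimum ids.
#' @return The threshold energy (kcal/mol), or `NA` if they never merge
#'   within the tree's levels.
#' @export
merge_level <- function(tree, i, j) {
  same <- which(!is.na(tree$membership[i, ]) &
                tree$membership[i, ] == tree$membership[j, ])
  if (!length(same)) return(NA_real_)
  tree$levels[max(same)]
}

#' Colour a disconnectivity tree by a per-minimum order parameter
#'
#' Leaves carry their own value; an internal node carries the
#' occupation-weighted mean over its member minima (weights from the
#' harmonic equilibrium occupations at `temperature`, or uniform when the
#' tree was built on a quotient network without vibrational data).
#'
#' @param tree A `disconnectivity_tree`.
#' @param values Numeric vector, one value per minimum.
#' @param temperature Temperature for the occupation weights (K).
#' @return The tree with a `node_values` column added to `nodes` and a
#'   `leaf_values` element.
#' @export
color_tree <- function(tree, values, temperature = 310.15) {
  n <- nrow(tree$membership)
  if (length(values) != n || anyNA(values))
    stop("need one non-missing value per minimum; missing for: ",
         paste(which(is.na(values[seq_len(n)])), collapse = ", "))
  w <- equilibrium_occupations(tree$ktn, temperature)$p
  nv <- vapply(tree$nodes$id, function(id) {
    members <- which(apply(tree$membership == id, 1, any, na.rm = TRUE))
    sum(w[members] * values[members]) / sum(w[members])
  }, numeric(1))
  tree$nodes$node_value <- nv
  tree$leaf_values <- values
  tree
}

#' Select a funnel by anchor minimum and cutting level
#'
#' Returns the members of the anchor's superbasin at the given threshold:
#' the programmatic equivalent of cutting a disconnectivity graph at a key
#' branch.
#'
#' @param tree A `disconnectivity_tree` (or a `ktn`, in which case the
#'   partition is evaluated directly at `level`).
#' @param anchor Minimum id inside the funnel.
#' @param level Threshold energy (kcal/mol).
#' @return Integer vector of member minimum ids.
#' @export
select_funnel <- function(tree, anchor, level) {
  net <- if (inherits(tree, "disconnectivity_tree")) tree$ktn else tree
  if (inherits(tree, "disconnectivity_tree") && level > max(tree$levels))
    stop("level lies above the top of the tree")
  part <- superbasin_partition(net, level)
  if (is.na(part[anchor]))
    stop("anchor minimum lies above the cutting level")
  which(!is.na(part) & part == part[anchor])
}

#' Deterministic leaf layout for plotting
#'
#' Recursive-midpoint x positions: leaves are placed in depth-first order
#' under their merge hierarchy and internal nodes at the midpoint of their
#' children. Rendering itself is left to the host environment.
#'
#' @param tree A `disconnectivity_tree`.
#' @return data.frame with `id`, `level`, `energy`, `parent`, `x` and
#'   `is_leaf`.
#' @export
tree_layout <- function(tree) {
  nodes <- tree$nodes
  kids <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  leaf_of <- tree$leaf_node
  x <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  counter <- new.env(parent = emptyenv()); counter$next_x <- 0
  assign_x <- function(id) {
    ch <- kids[[as.character(id)]]
    if (is.null(ch) || !length(ch)) {
      counter$next_x <- counter$next_x + 1
      x[as.character(id)] <<- counter$next_x
    } else {
      for (c_ in sort(ch)) assign_x(c_)
      x[as.character(id)] <<- mean(x[as.character(sort(ch))])
    }
  }
  roots <- nodes$id[is.na(nodes$parent)]
  for (r in sort(roots)) assign_x(r)
  out <- nodes
  out$x <- unname(x[as.character(nodes$id)])
  out$is_leaf <- nodes$id %in% leaf_of
  out
}

#' Export a disconnectivity tree as JSON
#'
#' @param tree A `disconnectivity_tree`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON export")
  payload <- list(levels = tree$levels, nodes = tree_layout(tree),
                  leaf_node = tree$leaf_node,
                  minima_V = tree$ktn$minima$V)
  js <- jsonlite::toJSON(payload, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
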