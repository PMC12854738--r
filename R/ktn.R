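## Data model and plain-text I/O for stationary-point databases.
##
## A kinetic transition network (KTN) is a graph whose nodes are local minima
## of a potential energy surface and whose edges are transition states
## (Hessian-index-1 saddle points) connecting them. Minima and transition
## states each carry a potential energy V (kcal/mol), the log-product of
## their real vibrational frequencies (kappa for minima, kappa - 1 for
## transition states, frequencies in s^-1) and a point-group order.

#' Construct a kinetic transition network
#'
#' @param minima data.frame with columns `V`, `logProd`, `pgOrder` and
#'   optionally `coordsRef` (path to a PDB structure for the minimum).
#'   Row order defines the 1-based minimum ids.
#' @param ts data.frame with columns `V`, `logProd`, `pgOrder`, `min1`,
#'   `min2`; may be empty. Row order defines the 1-based transition-state
#'   ids. `min1 == min2` flags a degenerate rearrangement: such transition
#'   states are retained but excluded from graph edges and rates.
#' @param kappa Number of vibrational degrees of freedom per minimum
#'   (identical across the network). May be `NA` if unknown; heat-capacity
#'   curves then refuse to run.
#' @return An object of class `ktn`.
#' @export
ktn <- function(minima = NULL, ts = NULL, kappa = NA_real_) {
  minima <- .as_min_table(minima)
  ts <- .as_ts_table(ts)
  net <- structure(list(minima = minima, ts = ts, kappa = kappa),
                   class = "ktn")
  .check_ts_refs(net)
  net
}

.as_min_table <- function(minima) {
  if (is.null(minima) || nrow(as.data.frame(minima)) == 0L) {
    return(data.frame(id = integer(0), V = numeric(0), logProd = numeric(0),
                      pgOrder = numeric(0), coordsRef = character(0),
                      stringsAsFactors = FALSE))
  }
  minima <- as.data.frame(minima)
  need <- c("V", "logProd", "pgOrder")
  if (!all(need %in% names(minima)))
    stop("minima table needs columns: ", paste(need, collapse = ", "))
  if (is.null(minima$coordsRef)) minima$coordsRef <- NA_character_
  minima$id <- seq_len(nrow(minima))
  if (any(minima$pgOrder < 1)) stop("pgOrder must be >= 1")
  if (any(!is.finite(minima$logProd))) stop("logProd must be finite")
  minima[, c("id", "V", "logProd", "pgOrder", "coordsRef")]
}

.as_ts_table <- function(ts) {
  if (is.null(ts) || nrow(as.data.frame(ts)) == 0L) {
    return(data.frame(id = integer(0), V = numeric(0), logProd = numeric(0),
                      pgOrder = numeric(0), min1 = integer(0),
                      min2 = integer(0)))
  }
  ts <- as.data.frame(ts)
  need <- c("V", "logProd", "pgOrder", "min1", "min2")
  if (!all(need %in% names(ts)))
    stop("ts table needs columns: ", paste(need, collapse = ", "))
  ts$id <- seq_len(nrow(ts))
  if (any(ts$pgOrder < 1)) stop("pgOrder must be >= 1")
  ts[, c("id", "V", "logProd", "pgOrder", "min1", "min2")]
}

.check_ts_refs <- function(net) {
  n <- nrow(net$minima)
  bad <- which(net$ts$min1 < 1 | net$ts$min1 > n |
               net$ts$min2 < 1 | net$ts$min2 > n)
  if (length(bad))
    stop("transition state(s) reference nonexistent minima at line(s): ",
         paste(bad, collapse = ", "))
  invisible(net)
}

#' @export
print.ktn <- function(x, ...) {
  cat(sprintf("<ktn> %d minima, %d transition states (kappa = %s)\n",
              nrow(x$minima), nrow(x$ts),
              ifelse(is.na(x$kappa), "unset", format(x$kappa))))
  if (nrow(x$minima)) {
    cat(sprintf("  V range: [%.6g, %.6g] kcal/mol\n",
                min(x$minima$V), max(x$minima$V)))
  }
  invisible(x)
}

#' Number of minima / transition states in a KTN
#' @param net A `ktn` object.
#' @return Integer count.
#' @export
n_minima <- function(net) nrow(net$minima)

#' @rdname n_minima
#' @export
n_ts <- function(net) nrow(net$ts)

## non-degenerate transition states (the ones that form graph edges)
.edge_ts <- function(net) net$ts[net$ts$min1 != net$ts$min2, , drop = FALSE]

#' Undirected igraph view of a KTN
#'
#' Degenerate-rearrangement transition states (`min1 == min2`) are excluded.
#' Edges carry the transition-state id in attribute `ts_id` and its energy in
#' `V`.
#'
#' @param net A `ktn` object.
#' @return An `igraph` graph with `n_minima(net)` vertices.
#' @export
ktn_graph <- function(net) {
  ets <- .edge_ts(net)
  g <- igraph::make_empty_graph(n = n_minima(net), directed = FALSE)
  if (nrow(ets)) {
    g <- igraph::add_edges(g, rbind(ets$min1, ets$min2))
    igraph::E(g)$ts_id <- ets$id
    igraph::E(g)$V <- ets$V
  }
  g
}

#' Read a stationary-point database
#'
#' Reads the plain-text dialect used for minima/transition-state tables:
#' whitespace-separated numeric columns, one stationary point per line, ids
#' given by 1-based line numbers. The minima file has columns
#' `V logProd pgOrder` and the transition-state file
#' `V logProd pgOrder min1 min2`; up to three trailing columns (moments of
#' inertia in the common convention) are read and ignored.
#'
#' @param min_file,ts_file Paths to the minima and transition-state tables.
#' @param kappa Optional vibrational degrees-of-freedom count to attach.
#' @return A `ktn` object.
#' @export
read_stationary_points <- function(min_file, ts_file, kappa = NA_real_) {
  for (f in c(min_file, ts_file))
    if (!file.exists(f)) stop("file not found: ", f)
  minima <- .read_sp_table(min_file, min_cols = 3,
                           cols = c("V", "logProd", "pgOrder"))
  ts <- .read_sp_table(ts_file, min_cols = 5,
                       cols = c("V", "logProd", "pgOrder", "min1", "min2"))
  if (nrow(ts)) {
    ts$min1 <- as.integer(ts$min1)
    ts$min2 <- as.integer(ts$min2)
  }
  ktn(minima, ts, kappa = kappa)
}

.read_sp_table <- function(path, min_cols, cols) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < min_cols)
  vals <- suppressWarnings(lapply(fields, function(f) as.numeric(f)))
  bad <- sort(union(bad, which(vapply(vals, function(v)
    any(is.na(v[seq_len(min(length(v), min_cols))])), logical(1)))))
  if (length(bad))
    stop("malformed line(s) in ", path, ": ", paste(bad, collapse = ", "))
  out <- as.data.frame(do.call(rbind, lapply(vals, function(v)
    v[seq_len(min_cols)])))
  names(out) <- cols
  out
}

#' Write a stationary-point database
#'
#' Inverse of [read_stationary_points()]: numeric columns are written with 17
#' significant digits so that a read-back reproduces the network exactly.
#'
#' @param net A `ktn` object.
#' @param min_file,ts_file Output paths.
#' @return Invisibly, `net`.
#' @export
write_stationary_points <- function(net, min_file, ts_file) {
  stopifnot(inherits(net, "ktn"))
  fmt <- function(df, cols) {
    if (!nrow(df)) return(character(0))
    apply(df[, cols, drop = FALSE], 1L, function(r)
      paste(sprintf("%.17g", as.numeric(r)), collapse = " "))
  }
  writeLines(fmt(net$minima, c("V", "logProd", "pgOrder")), min_file)
  writeLines(fmt(net$ts, c("V", "logProd", "pgOrder", "min1", "min2")),
             ts_file)
  invisible(net)
}

#' Validate a KTN against the saddle-point invariants
#'
#' A true transition state must lie at or above both minima it connects.
#' Violating transition states are discarded, clamped to the higher minimum
#' energy, or reported as an error, depending on `policy`.
#'
#' @param net A `ktn` object.
#' @param policy One of `"discard"`, `"clamp"`, `"error"`.
#' @return The validated `ktn`, with attribute `"report"`: a list with the
#'   number of offending transition states (`n_below`), their ids
#'   (`offenders`) and the `action` taken.
#' @export
validate_ktn <- function(net, policy = c("discard", "clamp", "error")) {
  policy <- match.arg(policy)
  stopifnot(inherits(net, "ktn"))
  .check_ts_refs(net)
  ts <- net$ts
  if (nrow(ts)) {
    vmax <- pmax(net$minima$V[ts$min1], net$minima$V[ts$min2])
    low <- which(ts$V < vmax)
  } else low <- integer(0)
  if (length(low) && policy == "error")
    stop("transition state(s) below a connected minimum: ",
         paste(ts$id[low], collapse = ", "))
  if (length(low)) {
    if (policy == "discard") {
      ts <- ts[-low, , drop = FALSE]
    } else {
      ts$V[low] <- vmax[low]
    }
    ts$id <- seq_len(nrow(ts))
  }
  out <- ktn(net$minima[, c("V", "logProd", "pgOrder", "coordsRef")], ts,
             kappa = net$kappa)
  attr(out, "report") <- list(n_below = length(low),
                              offenders = if (length(low)) net$ts$id[low]
                                          else integer(0),
                              action = policy)
  out
}

#' Dot-bracket string from a base-pair list
#'
#' Utility only: dot-bracket notation is ambiguous for wobbling registers and
#' is never used for classification inside the package.
#'
#' @param pairs data.frame with columns `i`, `j` (1-based residue indices).
#' @param n Sequence length.
#' @return A character scalar of length-`n` dots and brackets.
#' @export
dot_bracket <- function(pairs, n) {
  s <- rep(".", n)
  if (nrow(pairs)) {
    s[pairs$i] <- "("
    s[pairs$j] <- ")"
  }
  paste(s, collapse = "")
}
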