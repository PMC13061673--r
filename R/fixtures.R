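#' Sample a random initial condition
#'
#' Initial phases are uniform on `[0, 2*pi)`; initial couplings are uniform on
#' `[-1, 1]` with zero diagonal (`coupling_mode = "uniform"`), or uniform on
#' `[1 - delta, 1]` (`"near_plus_one"`), the configuration that produces a
#' long fully-synchronized transient before metastable switching sets in.
#'
#' @param n Number of oscillators.
#' @param seed RNG seed; same seed, same draw.
#' @param coupling_mode `"uniform"` or `"near_plus_one"`.
#' @param delta Width of the near-one band (default 0.01).
#' @return A [kuramoto_state()] at `t = 0` with a `seed` attribute.
#' @examples
#' init <- sample_initial_condition(10, seed = 42)
#' range(init$k)
#' @export
sample_initial_condition <- function(n, seed,
                                     coupling_mode = c("uniform", "near_plus_one"),
                                     delta = 0.01) {
  coupling_mode <- match.arg(coupling_mode)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  set.seed(seed)
  theta <- stats::runif(n, 0, 2 * pi)
  k <- if (coupling_mode == "uniform") {
    matrix(stats::runif(n * n, -1, 1), n, n)
  } else {
    matrix(stats::runif(n * n, 1 - delta, 1), n, n)
  }
  diag(k) <- 0
  st <- kuramoto_state(theta, k, t = 0)
  attr(st, "seed") <- seed
  st
}

#' Generate a connected Erdos-Renyi graph
#'
#' Edges are drawn independently with probability `mean_degree / (n - 1)` and
#' the sample is rejected until connected, which keeps the degree distribution
#' of the conditioned ensemble clean (no spanning-tree augmentation).
#'
#' @param n Number of nodes.
#' @param mean_degree Target average degree in `[1, n - 1]`;
#'   `mean_degree = n - 1` returns the complete graph deterministically.
#' @param seed RNG seed.
#' @param max_tries Resampling budget before giving up (default 1000).
#' @return Symmetric 0/1 adjacency matrix with zero diagonal and attributes
#'   `realized_mean_degree` and `tries`.
#' @examples
#' a <- generate_connected_graph(10, 5, seed = 1)
#' attr(a, "realized_mean_degree")
#' @export
generate_connected_graph <- function(n, mean_degree, seed, max_tries = 1000L) {
  if (mean_degree < 1 || mean_degree > n - 1) {
    stop("`mean_degree` must be in [1, n - 1]", call. = FALSE)
  }
  p <- mean_degree / (n - 1)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    a <- matrix(0, n, n)
    up <- upper.tri(a)
    a[up] <- as.numeric(stats::runif(sum(up)) < p)
    a <- a + t(a)
    if (graph_is_connected(a)) {
      attr(a, "realized_mean_degree") <- mean(rowSums(a))
      attr(a, "tries") <- try
      return(a)
    }
  }
  stop("could not sample a connected graph in ", max_tries,
       " tries; increase `mean_degree` or `max_tries`", call. = FALSE)
}

#' Write / read an undirected edge list
#'
#' Plain whitespace-delimited text, one edge per line, 1-based node ids.
#'
#' @param adjacency Symmetric 0/1 adjacency matrix.
#' @param path File path.
#' @return `write_edge_list()` returns `path` invisibly; `read_edge_list()`
#'   the adjacency matrix.
#' @export
write_edge_list <- function(adjacency, path) {
  idx <- which(upper.tri(adjacency) & adjacency == 1, arr.ind = TRUE)
  lines <- c(paste("#", nrow(adjacency), "nodes"),
             sprintf("%d %d", idx[, 1], idx[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' @param n_nodes Number of nodes; if `NULL`, taken from the header comment or
#'   the largest id seen.
#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  pairs <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.integer))
  if (is.null(n_nodes)) {
    n_nodes <- if (length(header) > 0) {
      as.integer(strsplit(trimws(sub("#", "", header[1])), "\\s+")[[1]][1])
    } else {
      max(pairs)
    }
  }
  a <- matrix(0, n_nodes, n_nodes)
  a[pairs] <- 1
  a[pairs[, c(2, 1), drop = FALSE]] <- 1
  diag(a) <- 0
  a
}
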