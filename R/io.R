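#' Read and write graphs as plain-text edge lists
#'
#' One `"i j"` pair per line with 0-based node indices, preceded by a
#' header comment `# n <nodes>` so isolated trailing nodes survive the
#' round trip. GraphML output is available through
#' [igraph::write_graph()] on the returned graph objects.
#'
#' @param g An [igraph::igraph] graph.
#' @param path File path.
#' @return `write_edgelist` returns `path` invisibly; `read_edgelist`
#'   returns an [igraph::igraph] graph.
#' @export
write_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n %d", igraph::vcount(g)), con)
  writeLines(sprintf("%d %d", el[, 1L], el[, 2L]), con)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  n <- NA_integer_
  if (length(header) > 0L) {
    m <- regmatches(header[1L], regexec("# *n +(\\d+)", header[1L]))[[1L]]
    if (length(m) == 2L) n <- as.integer(m[2L])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  el <- if (length(body) > 0L) {
    do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer)) + 1L
  } else matrix(integer(0), 0L, 2L)
  if (is.na(n)) n <- if (nrow(el) > 0L) max(el) else 0L
  igraph::graph_from_edgelist(el, directed = FALSE) |>
    igraph::add_vertices(max(0L, n - max(el, 0L)))
}

#' Export a weighted adjacency matrix as dense CSV
#'
#' @param a A weight matrix.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(a, path) {
  utils::write.table(as.matrix(a), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a trajectory in long format
#'
#' Writes one row per (step, agent) with columns
#' `step`, `agent`, `mu`, `sigma2`.
#'
#' @param traj An `opinion_trajectory`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "opinion_trajectory"))
  n <- traj$n_agents
  steps <- nrow(traj$mu)
  df <- data.frame(
    step = rep(seq_len(steps) - 1L, each = n),
    agent = rep(seq_len(n), times = steps),
    mu = as.vector(t(traj$mu)),
    sigma2 = as.vector(t(traj$sigma2))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
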