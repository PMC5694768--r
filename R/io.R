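#' Read a network from an edge-list file
#'
#' Reads a whitespace/tab-separated edge list (`i j [w]`, `#` comments
#' allowed), symmetrizes it, drops self-loops, collapses duplicate edges and
#' keeps only the largest connected component (with a warning when smaller
#' components are discarded). External node ids may be arbitrary integers;
#' they are remapped to consecutive internal ids `1..n` and the original ids
#' are kept in the `node_ids` attribute and used again on output.
#'
#' For duplicate rows carrying a weight the first occurrence wins.
#'
#' @param path Path to the edge-list file.
#' @return A tibble with columns `from`, `to` (internal 1-based ids) and
#'   `weight` when the file has a third column; attribute `node_ids` maps
#'   internal id `k` to the original id `node_ids[k]`.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("1 2", "2 3", "3 1"), f)
#' read_edgelist(f)
read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) abort("Empty edge list.")
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 2 | nf > 3)) {
    abort(sprintf("Unparsable row at line %d: expected `i j [w]`.",
                  line_no[which(nf < 2 | nf > 3)[1]]))
  }
  from <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
  to <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  if (anyNA(from) || anyNA(to)) {
    abort(sprintf("Unparsable node id at line %d.",
                  line_no[which(is.na(from) | is.na(to))[1]]))
  }
  weighted <- all(nf == 3)
  w <- if (weighted) as.numeric(vapply(parts, `[[`, "", 3)) else NULL
  if (weighted && anyNA(w)) {
    abort(sprintf("Unparsable weight at line %d.", line_no[which(is.na(w))[1]]))
  }

  ids <- sort(unique(c(from, to)))
  fi <- match(from, ids)
  ti <- match(to, ids)
  lo <- pmin(fi, ti)
  hi <- pmax(fi, ti)
  ok <- lo != hi           # drop self-loops
  lo <- lo[ok]; hi <- hi[ok]
  if (weighted) w <- w[ok]
  dup <- duplicated(cbind(lo, hi))
  lo <- lo[!dup]; hi <- hi[!dup]
  if (weighted) w <- w[!dup]
  if (length(lo) == 0) abort("Edge list contains no usable edges.")

  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::add_edges(g, rbind(lo, hi))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    giant <- which.max(comp$csize)
    warn(sprintf(
      "Graph has %d components; keeping the largest (%d of %d nodes).",
      comp$no, max(comp$csize), length(ids)))
    keep_v <- comp$membership == giant
    remap <- cumsum(keep_v)
    keep_e <- keep_v[lo] & keep_v[hi]
    lo <- remap[lo[keep_e]]; hi <- remap[hi[keep_e]]
    if (weighted) w <- w[keep_e]
    ids <- ids[keep_v]
  }
  out <- tibble::tibble(from = as.integer(lo), to = as.integer(hi))
  if (weighted) out$weight <- w
  attr(out, "node_ids") <- ids
  out
}

#' Write a network to an edge-list file
#'
#' Writes `i j [w]` rows, tab-separated, at full precision. Internal ids are
#' translated back through the table's `node_ids` attribute when present.
#'
#' @param edges Edge table (`from`, `to`, optional `weight`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(edges, path) {
  edges <- as_edge_tbl(edges)
  ids <- attr(edges, "node_ids") %||% seq_len(n_nodes(edges))
  cols <- list(ids[edges$from], ids[edges$to])
  if ("weight" %in% names(edges)) {
    cols <- c(cols, list(formatC(edges$weight, format = "g", digits = 17)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read / write hyperbolic coordinate tables
#'
#' Coordinate tables are tab-separated with a header: `node`, `r`, `theta`
#' and optionally `phi` (3D polar angle).
#'
#' @param path File path.
#' @return `read_coords()`: a tibble with columns `node`, `r`, `theta`
#'   (and `phi` if present).
#' @export
read_coords <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  cols <- intersect(c("node", "r", "theta", "phi"), names(df))
  if (!all(c("node", "r", "theta") %in% cols)) {
    abort("Coordinate file must have columns `node`, `r`, `theta`.")
  }
  tibble::as_tibble(df[cols])
}

#' @rdname read_coords
#' @param coords Coordinate table (`node`, `r`, `theta`, optional `phi`).
#' @export
write_coords <- function(coords, path) {
  stopifnot(all(c("node", "r", "theta") %in% names(coords)))
  cols <- intersect(c("node", "r", "theta", "phi"), names(coords))
  utils::write.table(format(as.data.frame(coords)[cols], digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Deterministic toy networks
#'
#' Small named fixtures used in examples and tests: `"path:n"`, `"cycle:n"`,
#' `"star:n"` (hub plus `n` leaves), `"complete:n"`, `"barbell:n"` (two
#' complete graphs of size `n` joined by one edge), `"grid:rxc"`, and
#' `"pso:N<n>m<m>T<t>seed<s>"` for a fixed-seed PSO network.
#'
#' @param name Fixture name, e.g. `"cycle:4"` or `"pso:N100m4T0seed1"`.
#' @return An edge tibble (`from`, `to`); for PSO fixtures a [generate_pso()]
#'   object.
#' @export
#' @examples
#' toy_fixtures("star:5")
toy_fixtures <- function(name) {
  if (grepl("^pso:", name)) {
    m <- regmatches(name, regexec("^pso:N(\\d+)m(\\d+)T([0-9.]+)seed(\\d+)$", name))[[1]]
    if (length(m) == 0) abort("PSO fixture name must look like 'pso:N100m4T0seed1'.")
    return(generate_pso(n = as.integer(m[2]), m = as.integer(m[3]),
                        temp = as.numeric(m[4]), seed = as.integer(m[5])))
  }
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) abort("Fixture name must look like 'kind:size'.")
  kind <- parts[1]
  el <- switch(kind,
    path = {
      n <- as.integer(parts[2])
      cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    },
    cycle = {
      n <- as.integer(parts[2])
      cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L))
    },
    star = {
      n <- as.integer(parts[2])
      cbind(rep(1L, n), seq_len(n) + 1L)
    },
    complete = {
      n <- as.integer(parts[2])
      t(utils::combn(n, 2))
    },
    barbell = {
      n <- as.integer(parts[2])
      k1 <- t(utils::combn(n, 2))
      k2 <- t(utils::combn(n, 2)) + n
      rbind(k1, k2, c(n, n + 1L))
    },
    grid = {
      dims <- as.integer(strsplit(parts[2], "x", fixed = TRUE)[[1]])
      r <- dims[1]; cc <- dims[2]
      id <- function(i, j) (i - 1L) * cc + j
      horiz <- do.call(rbind, lapply(seq_len(r), function(i)
        cbind(id(i, seq_len(cc - 1)), id(i, seq_len(cc - 1) + 1L))))
      vert <- do.call(rbind, lapply(seq_len(r - 1), function(i)
        cbind(id(i, seq_len(cc)), id(i + 1L, seq_len(cc)))))
      rbind(horiz, vert)
    },
    abort(sprintf("Unknown fixture kind '%s'.", kind))
  )
  tibble::tibble(from = as.integer(el[, 1]), to = as.integer(el[, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
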