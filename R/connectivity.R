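#' Region-mean time series from a 4D series
#'
#' The acquisition-wise mean over each region's voxels (the standard
#' parcellation step before connectivity analysis). Regions with no
#' in-mask voxels are reported in a warning and filled with `NA`.
#'
#' @param series a [bold_series()].
#' @param atlas an [atlas_volume()].
#' @param table a [region_table()] fixing the row order.
#' @return Numeric matrix, regions x acquisitions, rownames = region ids.
#' @export
region_timeseries <- function(series, atlas, table) {
  check_shapes(series, atlas)
  d <- dim(series$data)
  lab <- as.vector(atlas$labels)
  x <- matrix(series$data, prod(d[1:3]), d[4])
  ids <- table$region_id
  out <- matrix(NA_real_, length(ids), d[4],
                dimnames = list(as.character(ids), NULL))
  keep <- lab > 0L
  f <- factor(lab[keep], levels = ids)
  counts <- tabulate(f, nbins = length(ids))
  sums <- rowsum(x[keep, , drop = FALSE], f)
  nonzero <- counts > 0L
  out[nonzero, ] <- sums[nonzero, , drop = FALSE] / counts[nonzero]
  if (any(!nonzero))
    warning("regions with no in-mask voxels (rows set to NA): ",
            paste(ids[!nonzero], collapse = ", "))
  out
}

#' Pearson connectivity matrix of region time series
#'
#' @param ts regions x acquisitions matrix (from [region_timeseries()]).
#' @param group group label carried on the result.
#' @return A `conn_matrix`: list with `r` (symmetric, unit diagonal),
#'   `level = "subject"`, `group`.
#' @export
corr_matrix <- function(ts, group = NA) {
  if (ncol(ts) < 3L) stop("need at least 3 time points")
  if (anyNA(ts)) stop("missing region rows; drop or repair them first")
  v <- apply(ts, 1L, sd)
  if (any(v == 0))
    stop("zero-variance region(s): correlation undefined for region ",
         paste(rownames(ts)[v == 0], collapse = ", "))
  r <- cor(t(ts))
  diag(r) <- 1
  structure(list(r = r, level = "subject", group = group),
            class = "conn_matrix")
}

#' Group-level connectivity matrix by Fisher-z averaging
#'
#' Subject correlation matrices are Fisher z-transformed, averaged, and
#' transformed back — the variance-stabilised way to combine correlation
#' estimates across subjects.
#'
#' @param mats list of subject `conn_matrix` objects over the same regions.
#' @param group group label for the result.
#' @return A `conn_matrix` with `level = "group"`.
#' @export
group_matrix <- function(mats, group = NA) {
  stopifnot(length(mats) >= 1L,
            all(vapply(mats, inherits, TRUE, "conn_matrix")))
  dims <- vapply(mats, function(m) nrow(m$r), 0L)
  if (length(unique(dims)) != 1L)
    stop("subject matrices cover different region universes")
  zs <- lapply(mats, function(m) atanh(pmin(pmax(m$r, -1 + 1e-12), 1 - 1e-12)))
  z <- Reduce(`+`, zs) / length(zs)
  r <- tanh(z)
  diag(r) <- 1
  dimnames(r) <- dimnames(mats[[1]]$r)
  structure(list(r = r, level = "group", group = group),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("Connectivity matrix (%s level%s): %d regions, mean |r| = %.3f\n",
              x$level, if (is.na(x$group)) "" else paste0(", group ", x$group),
              nrow(x$r), mean(abs(off))))
  invisible(x)
}

#' Threshold a connectivity matrix into an undirected graph
#'
#' Edges connect region pairs whose absolute correlation reaches the
#' cutoff (absolute values, undirected, unweighted — Gephi-style degree
#' centrality). No self-edges.
#'
#' @param conn a `conn_matrix`.
#' @param cutoff absolute-correlation threshold in `(0, 1)` (default 0.3).
#' @return A `conn_graph`: list with logical `adjacency`, `cutoff`,
#'   integer `degrees` (named by region), `group`.
#' @export
threshold_graph <- function(conn, cutoff = 0.3) {
  stopifnot(inherits(conn, "conn_matrix"))
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  adj <- abs(conn$r) >= cutoff
  diag(adj) <- FALSE
  structure(list(adjacency = adj, cutoff = cutoff,
                 degrees = rowSums(adj), group = conn$group),
            class = "conn_graph")
}

#' @export
print.conn_graph <- function(x, ...) {
  cat(sprintf("Connectivity graph (|r| >= %g%s): %d nodes, %d edges, mean degree %.1f\n",
              x$cutoff, if (is.na(x$group)) "" else paste0(", group ", x$group),
              nrow(x$adjacency), sum(x$adjacency) / 2, mean(x$degrees)))
  invisible(x)
}

#' Compare node degrees between two graphs within subregions
#'
#' For each requested subregion (macro-region name or system tag), a
#' paired two-sided Wilcoxon signed-rank test over the member nodes'
#' degrees in graph B versus graph A, with the direction of the median
#' difference. Subregions with fewer than 2 member nodes are skipped with
#' a warning. When every member's degree is identical in both graphs the
#' difference is exactly zero and p = 1.
#'
#' @param graph_a,graph_b `conn_graph` objects over the same region
#'   universe (e.g. vehicle and treatment group graphs).
#' @param table a [region_table()].
#' @param subregions character vector of macro-region names and/or system
#'   tags.
#' @return Data frame `subregion n_nodes median_diff p direction`, where
#'   `direction` uses the graphs' group labels (B vs A).
#' @export
compare_degree <- function(graph_a, graph_b, table, subregions) {
  stopifnot(inherits(graph_a, "conn_graph"), inherits(graph_b, "conn_graph"))
  if (!all(dim(graph_a$adjacency) == dim(graph_b$adjacency)))
    stop("graphs cover different region universes")
  la <- if (is.na(graph_a$group)) "A" else as.character(graph_a$group)
  lb <- if (is.na(graph_b$group)) "B" else as.character(graph_b$group)
  ids_all <- table$region_id
  rows <- lapply(subregions, function(tag) {
    ids <- regions_with_tag(table, tag)
    if (length(ids) < 2L) {
      warning("subregion '", tag, "' has fewer than 2 member nodes; skipped")
      return(NULL)
    }
    idx <- match(ids, ids_all)
    da <- graph_a$degrees[idx]; db <- graph_b$degrees[idx]
    diffs <- db - da
    p <- if (all(diffs == 0)) 1 else
      suppressWarnings(wilcox.test(db, da, paired = TRUE, exact = FALSE)$p.value)
    md <- median(diffs)
    direction <- if (md < 0) sprintf("%s < %s", lb, la)
                 else if (md > 0) sprintf("%s > %s", lb, la)
                 else "none"
    data.frame(subregion = tag, n_nodes = length(ids), median_diff = md,
               p = p, direction = direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(subregion = character(0), n_nodes = integer(0),
                                      median_diff = numeric(0), p = numeric(0),
                                      direction = character(0))
  rownames(out) <- NULL
  out
}

#' Composite-node coupling analysis
#'
#' Combines a member set (e.g. every ARAS region) into one composite node
#' whose time series is the mean of the member region series, per subject.
#' The composite's coupling to each non-member region is the group-level
#' Fisher-z mean of the per-subject correlations. A region is classified
#' `hyper` if its coupling in group B exceeds group A by at least `margin`
#' (in z space), `hypo` for the opposite, `unchanged` otherwise.
#'
#' @param ts_a,ts_b lists of subject region-time-series matrices (from
#'   [region_timeseries()]) for groups A and B.
#' @param table a [region_table()].
#' @param members integer vector of member region ids (nonempty, strictly
#'   inside the region universe).
#' @param margin classification margin in Fisher-z units (default 0.1).
#' @param groups labels for the two groups (A, B).
#' @return A `composite_node_report` data frame: `region_id name z_a z_b
#'   dz class`, with the member set as attribute `members`.
#' @export
composite_node <- function(ts_a, ts_b, table, members, margin = 0.1,
                           groups = c("A", "B")) {
  members <- as.integer(members)
  if (!length(members)) stop("member set is empty")
  ids <- table$region_id
  if (!all(members %in% ids)) stop("member ids outside the region universe")
  others <- setdiff(ids, members)
  if (!length(others)) stop("members exhaust the region universe; nothing to classify")
  couple_z <- function(ts_list) {
    zs <- vapply(ts_list, function(ts) {
      comp <- colMeans(ts[as.character(members), , drop = FALSE])
      r <- as.vector(cor(comp, t(ts[as.character(others), , drop = FALSE])))
      atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    }, numeric(length(others)))
    rowMeans(matrix(zs, nrow = length(others)))
  }
  z_a <- couple_z(ts_a); z_b <- couple_z(ts_b)
  dz <- z_b - z_a
  cls <- ifelse(dz >= margin, "hyper", ifelse(dz <= -margin, "hypo", "unchanged"))
  out <- data.frame(region_id = others, name = table$name[match(others, ids)],
                    z_a = z_a, z_b = z_b, dz = dz, class = cls,
                    stringsAsFactors = FALSE)
  names(out)[3:4] <- paste0("z_", make.names(groups))
  structure(out, class = c("composite_node_report", "data.frame"),
            members = members, margin = margin, groups = groups)
}

#' @export
print.composite_node_report <- function(x, ...) {
  tab <- base::table(factor(x$class, levels = c("hyper", "hypo", "unchanged")))
  cat(sprintf("Composite-node report (%d members, margin %g): %d hyper, %d hypo, %d unchanged\n",
              length(attr(x, "members")), attr(x, "margin"),
              tab[["hyper"]], tab[["hypo"]], tab[["unchanged"]]))
  invisible(x)
}

#' Export a connectivity matrix / graph
#'
#' `write_conn_matrix` writes a square CSV with region-id header;
#' `write_graph_edges` an edge-list CSV; `write_graphml` a GraphML file
#' (via igraph) with degree as a node attribute.
#'
#' @param conn a `conn_matrix`.
#' @param graph a `conn_graph`.
#' @param path output path.
#' @export
write_conn_matrix <- function(conn, path) {
  df <- as.data.frame(conn$r)
  names(df) <- colnames(conn$r)
  utils::write.csv(cbind(region_id = rownames(conn$r), df), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_conn_matrix
#' @export
write_graph_edges <- function(graph, path) {
  adj <- graph$adjacency
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(adj)))
  df <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]])
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_conn_matrix
#' @export
write_graphml <- function(graph, path) {
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency * 1,
                                           mode = "undirected", diag = FALSE)
  igraph::V(g)$degree <- graph$degrees
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
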