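# Directed-tree river network: construction, validation, topological order,
# Strahler orders, and upstream accumulation.

#' Build a river network from reach and pond records
#'
#' Validates the reach table, resolves downstream links, detects cycles,
#' drops reaches with no path to an outlet within the record set (isolated
#' components, e.g. clipped at a study boundary), computes a topological
#' order and, when absent, Strahler stream orders. Pond segment records are
#' attached to their host reaches.
#'
#' @param reaches data.frame with columns `reach_id`, `downstream_id`
#'   (`NA`/`""` marks an outlet), `length_m`, `slope`, `q_m3d` (mean annual
#'   discharge), and optionally `velocity_md`, `order` (Strahler),
#'   `inc_area_m2`, `inc_load_kgyr`, `geometry` (WKT LINESTRING). A missing
#'   geometry defaults to a straight segment of the reach's length in a
#'   per-reach local frame.
#' @param ponds optional data.frame of pond segments with columns `pond_id`,
#'   `segment_id`, `reach_id`, `polygon` (WKT POLYGON) and optionally
#'   `area_m2`, `depth_m`. Area, perimeter and centroid are derived from the
#'   polygon; an explicit `area_m2` overrides the polygon area (NHD tables
#'   carry both).
#' @return An object of class `river_network`: a list with `reaches`
#'   (augmented data.frame), `ponds` (augmented data.frame or NULL),
#'   `topo_order` (indices, every reach before its downstream reach) and
#'   `excluded` (reach ids dropped as isolated).
#' @export
river_network <- function(reaches, ponds = NULL) {
  reaches <- as.data.frame(reaches, stringsAsFactors = FALSE)
  req <- c("reach_id", "downstream_id", "length_m", "slope", "q_m3d")
  miss <- setdiff(req, names(reaches))
  if (length(miss))
    stop("reach table missing columns: ", paste(miss, collapse = ", "))
  reaches$reach_id <- as.character(reaches$reach_id)
  reaches$downstream_id <- as.character(reaches$downstream_id)
  reaches$downstream_id[reaches$downstream_id %in% c("", "NA")] <- NA_character_
  if (anyDuplicated(reaches$reach_id))
    stop("duplicate reach_id: ",
         paste(unique(reaches$reach_id[duplicated(reaches$reach_id)]),
               collapse = ", "))
  if (any(reaches$length_m < 0, na.rm = TRUE)) stop("negative reach length")

  n <- nrow(reaches)
  ds <- match(reaches$downstream_id, reaches$reach_id)  # NA = outlet or dangling

  # classify every reach by following downstream pointers: reaches whose
  # chain ends at NA downstream_id reach an outlet; chains hitting an id
  # absent from the table are isolated; revisiting a reach is a cycle.
  status <- integer(n)  # 0 unknown, 1 ok, 2 isolated
  for (i in seq_len(n)) {
    if (status[i] != 0L) next
    path <- integer(0)
    onpath <- logical(n)
    j <- i
    repeat {
      if (status[j] != 0L) { res <- status[j]; break }
      if (onpath[j]) {
        cyc <- reaches$reach_id[path[which(path == j)[1]:length(path)]]
        stop("cycle detected among reaches: ", paste(cyc, collapse = " -> "))
      }
      onpath[j] <- TRUE
      path <- c(path, j)
      if (is.na(reaches$downstream_id[j])) { res <- 1L; break }
      nxt <- ds[j]
      if (is.na(nxt)) { res <- 2L; break }
      j <- nxt
    }
    status[path] <- res
  }
  excluded <- reaches$reach_id[status == 2L]
  if (length(excluded)) {
    message("excluding ", length(excluded),
            " isolated reach(es) with no path to an outlet")
    reaches <- reaches[status == 1L, , drop = FALSE]
    rownames(reaches) <- NULL
    n <- nrow(reaches)
    ds <- match(reaches$downstream_id, reaches$reach_id)
  }
  if (n == 0L) stop("no reaches remain after exclusions")

  # hops to outlet; parents have strictly larger values than their child,
  # so ordering by decreasing distance puts every parent first
  dist <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(dist[i])) next
    path <- integer(0); j <- i
    while (is.na(dist[j]) && !is.na(ds[j])) { path <- c(path, j); j <- ds[j] }
    base <- if (is.na(ds[j])) { dist[j] <- 0L; 0L } else dist[j]
    if (length(path))
      dist[path] <- base + rev(seq_along(path))
  }
  topo <- order(dist, decreasing = TRUE)

  if (is.null(reaches$inc_area_m2)) reaches$inc_area_m2 <- 0
  if (is.null(reaches$inc_load_kgyr)) reaches$inc_load_kgyr <- 0
  if (is.null(reaches$order) || all(is.na(reaches$order))) {
    reaches$order <- strahler_order(ds, topo)
  }

  net <- structure(list(reaches = reaches, ponds = NULL,
                        downstream = ds, topo_order = topo,
                        excluded = excluded),
                   class = "river_network")
  if (!is.null(ponds) && nrow(as.data.frame(ponds)) > 0L)
    net <- attach_ponds(net, ponds)
  net
}

# Standard Strahler rule over the upstream-merge tree: headwaters are order 1;
# a reach takes the max upstream order, +1 when two or more attain that max.
strahler_order <- function(ds, topo) {
  n <- length(ds)
  ord <- rep(1L, n)
  max_in <- rep(0L, n)   # max order among parents seen so far
  n_max <- rep(0L, n)    # how many parents attain it
  for (i in topo) {
    if (max_in[i] > 0L)
      ord[i] <- max_in[i] + (n_max[i] >= 2L)
    j <- ds[i]
    if (!is.na(j)) {
      if (ord[i] > max_in[j]) { max_in[j] <- ord[i]; n_max[j] <- 1L }
      else if (ord[i] == max_in[j]) n_max[j] <- n_max[j] + 1L
    }
  }
  ord
}

attach_ponds <- function(net, ponds) {
  ponds <- as.data.frame(ponds, stringsAsFactors = FALSE)
  req <- c("pond_id", "segment_id", "reach_id", "polygon")
  miss <- setdiff(req, names(ponds))
  if (length(miss))
    stop("pond table missing columns: ", paste(miss, collapse = ", "))
  ponds$pond_id <- as.character(ponds$pond_id)
  ponds$segment_id <- as.character(ponds$segment_id)
  ponds$reach_id <- as.character(ponds$reach_id)
  if (anyDuplicated(ponds$segment_id))
    stop("duplicate pond segment_id")
  ridx <- match(ponds$reach_id, net$reaches$reach_id)
  if (anyNA(ridx))
    stop("pond segment references missing reach: ",
         paste(ponds$reach_id[is.na(ridx)], collapse = ", "))
  if (anyDuplicated(ridx))
    stop("more than one pond segment on a reach: ",
         paste(ponds$reach_id[duplicated(ridx)], collapse = ", "))

  props <- lapply(ponds$polygon, function(w) polygon_properties(wkt_polygon(w)))
  ponds$poly_area_m2 <- vapply(props, `[[`, numeric(1), "area")
  ponds$perimeter_m <- vapply(props, `[[`, numeric(1), "perimeter")
  ponds$centroid_x <- vapply(props, function(p) p$centroid[1], numeric(1))
  ponds$centroid_y <- vapply(props, function(p) p$centroid[2], numeric(1))
  if (is.null(ponds$area_m2) || all(is.na(ponds$area_m2)))
    ponds$area_m2 <- ponds$poly_area_m2
  if (any(ponds$area_m2 <= 0)) stop("pond segment with non-positive area")
  ponds$reach_index <- ridx

  net$reaches$pond_segment_id <- NA_character_
  net$reaches$pond_segment_id[ridx] <- ponds$segment_id
  net$ponds <- ponds
  net
}

#' @export
print.river_network <- function(x, ...) {
  n <- nrow(x$reaches)
  np <- if (is.null(x$ponds)) 0L else length(unique(x$ponds$pond_id))
  ns <- if (is.null(x$ponds)) 0L else nrow(x$ponds)
  cat("River network: ", n, " reaches (",
      sum(is.na(x$reaches$downstream_id)), " outlet(s), max Strahler order ",
      max(x$reaches$order), "),\n  ", np, " ponded water(s) in ", ns,
      " segment(s)", sep = "")
  if (length(x$excluded))
    cat(";", length(x$excluded), "isolated reach(es) excluded")
  cat("\n")
  invisible(x)
}

#' Accumulate a per-reach field over all upstream reaches
#'
#' For every reach returns its own value plus the sum over its full upstream
#' set, i.e. the additive accumulation used for drainage area, pond surface
#' area and no-decay loads. Junction sums use Kahan compensation so results
#' are independent of sibling ordering to machine precision.
#'
#' @param net a `river_network`.
#' @param field numeric vector: either named by `reach_id` or positional in
#'   reach-table order; or the name of a reach-table column.
#' @return numeric vector named by `reach_id`.
#' @export
accumulate_upstream <- function(net, field) {
  r <- net$reaches
  if (is.character(field) && length(field) == 1L) {
    if (!field %in% names(r)) stop("no reach column '", field, "'")
    x <- r[[field]]
  } else if (!is.null(names(field))) {
    x <- field[r$reach_id]
    if (anyNA(names(x)) || anyNA(match(r$reach_id, names(field))))
      stop("field missing values for some reaches")
  } else {
    if (length(field) != nrow(r)) stop("field length != number of reaches")
    x <- field
  }
  if (anyNA(x)) stop("field contains NA")
  acc <- as.numeric(x)
  comp <- numeric(length(acc))  # Kahan compensation per target reach
  ds <- net$downstream
  for (i in net$topo_order) {
    j <- ds[i]
    if (!is.na(j)) {
      y <- acc[i] - comp[j]
      t <- acc[j] + y
      comp[j] <- (t - acc[j]) - y
      acc[j] <- t
    }
  }
  names(acc) <- r$reach_id
  acc
}

#' Enumerate the upstream reach set of every reach
#'
#' Returns, for each reach, the indices of all reaches draining through it
#' (itself included). Quadratic; intended for oracles and small networks.
#'
#' @param net a `river_network`.
#' @return list of integer index vectors, named by `reach_id`.
#' @export
upstream_sets <- function(net) {
  n <- nrow(net$reaches)
  sets <- lapply(seq_len(n), function(i) i)
  ds <- net$downstream
  for (i in net$topo_order) {
    j <- ds[i]
    if (!is.na(j)) sets[[j]] <- c(sets[[j]], sets[[i]])
  }
  names(sets) <- net$reaches$reach_id
  sets
}

#' Read a network from the reaches/ponds CSV interchange format
#'
#' @param reaches_csv path to the reach table.
#' @param ponds_csv optional path to the pond-segment table.
#' @return a `river_network`.
#' @export
read_network_csv <- function(reaches_csv, ponds_csv = NULL) {
  rd <- utils::read.csv(reaches_csv, stringsAsFactors = FALSE)
  pd <- NULL
  if (!is.null(ponds_csv) && file.exists(ponds_csv)) {
    pd <- utils::read.csv(ponds_csv, stringsAsFactors = FALSE)
    if (nrow(pd) == 0L) pd <- NULL
  }
  river_network(rd, pd)
}

#' Write a network to the CSV interchange format
#' @param net a `river_network`.
#' @param reaches_csv,ponds_csv output paths; ponds written only when present.
#' @return invisibly, the paths written.
#' @export
write_network_csv <- function(net, reaches_csv, ponds_csv = NULL) {
  keep <- c("reach_id", "downstream_id", "length_m", "slope", "q_m3d",
            "velocity_md", "order", "inc_area_m2", "inc_load_kgyr",
            "pond_segment_id", "geometry")
  r <- net$reaches[, intersect(keep, names(net$reaches)), drop = FALSE]
  utils::write.csv(r, reaches_csv, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  paths <- reaches_csv
  if (!is.null(net$ponds) && !is.null(ponds_csv)) {
    keep_p <- c("pond_id", "segment_id", "reach_id", "area_m2", "depth_m",
                "polygon")
    p <- net$ponds[, intersect(keep_p, names(net$ponds)), drop = FALSE]
    utils::write.csv(p, ponds_csv, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, ponds_csv)
  }
  invisible(paths)
}

# polyline geometry of one reach; default straight local segment (0,0)-(L,0)
reach_polyline <- function(net, i) {
  g <- net$reaches$geometry
  if (!is.null(g) && !is.na(g[i]) && nzchar(g[i])) wkt_linestring(g[i])
  else rbind(c(0, 0), c(net$reaches$length_m[i], 0))
}
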