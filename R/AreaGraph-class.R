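#' AreaGraph: symmetric area adjacency with connected components
#'
#' An undirected, loop-free neighbor structure over a fixed set of areas.
#' This is the neighborhood graph of the intrinsic conditional
#' autoregressive (ICAR) prior: two areas are neighbors when they share a
#' border, plus any extra edges (e.g. regular sea routes between islands)
#' added with [addEdges()].
#'
#' @slot areaIds character vector of unique area identifiers, storage order.
#' @slot adj list of integer vectors; `adj[[i]]` holds sorted indices of the
#'   neighbors of area `i`.
#' @slot componentLabels integer vector of connected-component labels,
#'   contiguous from 1.
#'
#' @seealso [readNeighborList()], [addEdges()], [validateGraph()],
#'   [aggregateAreas()], [icarPrecision()]
#' @export
setClass("AreaGraph",
  representation(
    areaIds = "character",
    adj = "list",
    componentLabels = "integer"
  )
)

setValidity("AreaGraph", function(object) {
  n <- length(object@areaIds)
  msg <- character()
  if (anyDuplicated(object@areaIds)) {
    msg <- c(msg, "area ids must be unique")
  }
  if (length(object@adj) != n) {
    msg <- c(msg, "adjacency list length must equal number of areas")
  }
  if (length(object@componentLabels) != n) {
    msg <- c(msg, "componentLabels length must equal number of areas")
  }
  if (length(msg)) return(msg)
  for (i in seq_len(n)) {
    nb <- object@adj[[i]]
    if (any(nb < 1L | nb > n)) {
      return(sprintf("neighbor index out of range for area '%s'",
                     object@areaIds[i]))
    }
    if (any(nb == i)) {
      return(sprintf("self-loop at area '%s'", object@areaIds[i]))
    }
    if (anyDuplicated(nb)) {
      return(sprintf("duplicated neighbor for area '%s'", object@areaIds[i]))
    }
    for (j in nb) {
      if (!(i %in% object@adj[[j]])) {
        return(sprintf("asymmetric adjacency between '%s' and '%s'",
                       object@areaIds[i], object@areaIds[j]))
      }
    }
  }
  lab <- .componentsFromAdj(object@adj, n)
  if (!identical(unname(lab), unname(object@componentLabels))) {
    return("componentLabels inconsistent with adjacency reachability")
  }
  TRUE
})

## canonical component labelling via igraph, relabelled to first-appearance order
.componentsFromAdj <- function(adj, n) {
  if (n == 0L) return(integer(0))
  edges <- .edgeMatrix(adj)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  as.integer(match(memb, unique(memb)))
}

## unordered edge pairs (i < j), one row per edge
.edgeMatrix <- function(adj) {
  n <- length(adj)
  from <- rep.int(seq_len(n), lengths(adj))
  to <- unlist(adj, use.names = FALSE)
  if (!length(from)) return(matrix(integer(0), ncol = 2))
  keep <- from < to
  cbind(from[keep], to[keep])
}

#' Construct an AreaGraph from an edge list
#'
#' @param areaIds character vector of unique area identifiers.
#' @param edges two-column matrix or data.frame of area ids (or a
#'   zero-row object for an edgeless graph). Edges are undirected; duplicates
#'   and both orientations collapse to one edge.
#' @return An [AreaGraph-class].
#' @examples
#' g <- AreaGraph(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")))
#' degrees(g)
#' @export
AreaGraph <- function(areaIds, edges = NULL) {
  areaIds <- as.character(areaIds)
  n <- length(areaIds)
  adj <- rep(list(integer(0)), n)
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    a <- match(as.character(edges[, 1]), areaIds)
    b <- match(as.character(edges[, 2]), areaIds)
    if (anyNA(a) || anyNA(b)) {
      bad <- unique(c(edges[is.na(a), 1], edges[is.na(b), 2]))
      stop("unknown area id(s) in edge list: ", paste(bad, collapse = ", "))
    }
    if (any(a == b)) stop("self-loop edges are not allowed")
    for (k in seq_along(a)) {
      adj[[a[k]]] <- c(adj[[a[k]]], b[k])
      adj[[b[k]]] <- c(adj[[b[k]]], a[k])
    }
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  new("AreaGraph",
    areaIds = areaIds, adj = adj,
    componentLabels = .componentsFromAdj(adj, n)
  )
}

#' @describeIn AreaGraph-class number of areas
#' @param x an AreaGraph
#' @export
setMethod("length", "AreaGraph", function(x) length(x@areaIds))

#' @rdname areaIds
#' @export
setMethod("areaIds", "AreaGraph", function(x) x@areaIds)

#' @rdname adjacencyList
#' @export
setMethod("adjacencyList", "AreaGraph", function(x) {
  setNames(x@adj, x@areaIds)
})

#' @rdname degrees
#' @export
setMethod("degrees", "AreaGraph", function(x) {
  setNames(lengths(x@adj), x@areaIds)
})

#' @rdname componentLabels
#' @export
setMethod("componentLabels", "AreaGraph", function(x) {
  setNames(x@componentLabels, x@areaIds)
})

#' @rdname nComponents
#' @export
setMethod("nComponents", "AreaGraph", function(x) {
  if (length(x@componentLabels) == 0L) 0L else max(x@componentLabels)
})

setMethod("show", "AreaGraph", function(object) {
  n <- length(object@areaIds)
  ne <- sum(lengths(object@adj)) / 2
  cat(sprintf(
    "AreaGraph with %d areas, %d edges, %d connected component(s)\n",
    n, ne, nComponents(object)
  ))
  if (n > 0) {
    d <- lengths(object@adj)
    cat(sprintf("  degree range: %d-%d; isolated areas: %d\n",
                min(d), max(d), sum(d == 0L)))
  }
})

#' Sparse adjacency and degree matrices
#'
#' @param graph an [AreaGraph-class].
#' @return `adjacencyMatrix`: symmetric sparse 0/1 matrix `W`.
#' @export
adjacencyMatrix <- function(graph) {
  stopifnot(is(graph, "AreaGraph"))
  n <- length(graph)
  e <- .edgeMatrix(graph@adj)
  Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]), x = 1,
    dims = c(n, n), dimnames = list(graph@areaIds, graph@areaIds)
  )
}

#' Read a GAL-dialect neighbor list
#'
#' Parses the simple neighbor-list dialect: a header line giving the area
#' count, then for each area two lines — `<area id> <neighbor count>` and
#' the neighbor ids. Ids are literal strings matched exactly against the
#' declared area records (1-based ordinal indexing is not interpreted), so
#' the file joins unambiguously with CSV tables keyed by the same ids.
#'
#' Asymmetric entries (`a` lists `b` but not vice versa) are symmetrized by
#' union with a warning; the neighbor relation is inherently symmetric.
#'
#' @param path path to the neighbor-list file.
#' @return An [AreaGraph-class].
#' @export
readNeighborList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty neighbor-list file: ", path)
  header <- strsplit(lines[[1]], "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[length(header)]))
  if (is.na(n)) stop("cannot parse area count from header line: ", lines[[1]])
  ids <- character(n)
  rawNbrs <- vector("list", n)
  cursor <- 2L
  for (k in seq_len(n)) {
    if (cursor > length(lines)) stop("truncated neighbor-list file: ", path)
    rec <- strsplit(lines[[cursor]], "\\s+")[[1]]
    if (length(rec) != 2L) {
      stop("malformed area record at line ", cursor, ": '", lines[[cursor]], "'")
    }
    ids[k] <- rec[1]
    cnt <- suppressWarnings(as.integer(rec[2]))
    if (is.na(cnt) || cnt < 0L) {
      stop("bad neighbor count at line ", cursor, ": '", lines[[cursor]], "'")
    }
    cursor <- cursor + 1L
    if (cnt > 0L) {
      nb <- strsplit(lines[[cursor]], "\\s+")[[1]]
      if (length(nb) != cnt) {
        stop("expected ", cnt, " neighbor ids at line ", cursor,
             ", found ", length(nb))
      }
      rawNbrs[[k]] <- nb
      cursor <- cursor + 1L
    } else {
      rawNbrs[[k]] <- character(0)
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate area id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  adj <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- match(rawNbrs[[k]], ids)
    if (anyNA(idx)) {
      stop("unknown neighbor id(s) for area '", ids[k], "': ",
           paste(rawNbrs[[k]][is.na(idx)], collapse = ", "))
    }
    if (any(idx == k)) stop("self-loop listed for area '", ids[k], "'")
    adj[[k]] <- sort(unique(idx))
  }
  asym <- FALSE
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      if (!(i %in% adj[[j]])) {
        asym <- TRUE
        adj[[j]] <- sort(c(adj[[j]], i))
      }
    }
  }
  if (asym) {
    warning("asymmetric neighbor entries in '", path,
            "' were symmetrized by union")
  }
  new("AreaGraph",
    areaIds = ids, adj = adj,
    componentLabels = .componentsFromAdj(adj, n)
  )
}

#' Write an AreaGraph as a GAL-dialect neighbor list
#'
#' @param graph an [AreaGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNeighborList <- function(graph, path) {
  stopifnot(is(graph, "AreaGraph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(graph)), con)
  for (i in seq_len(length(graph))) {
    nb <- graph@adj[[i]]
    writeLines(paste(graph@areaIds[i], length(nb)), con)
    if (length(nb)) writeLines(paste(graph@areaIds[nb], collapse = " "), con)
  }
  invisible(path)
}

#' Add extra neighbor edges (e.g. sea routes)
#'
#' Island areas that share no land border are connected to the mainland by
#' regular-sea-route edges so that every area has at least one neighbor.
#'
#' @param graph an [AreaGraph-class].
#' @param extra two-column matrix or data.frame of area-id pairs
#'   (columns `area_a`, `area_b` when named), or a path to such a CSV.
#' @return A new [AreaGraph-class] whose edge set is the union; connected
#'   components are recomputed. Adding an existing edge is a no-op.
#' @export
addEdges <- function(graph, extra) {
  stopifnot(is(graph, "AreaGraph"))
  if (is.character(extra) && length(extra) == 1L) {
    extra <- read.csv(extra, colClasses = "character")
  }
  extra <- as.matrix(as.data.frame(extra))
  if (NROW(extra) == 0L) return(graph)
  a <- match(as.character(extra[, 1]), graph@areaIds)
  b <- match(as.character(extra[, 2]), graph@areaIds)
  if (anyNA(a) || anyNA(b)) {
    bad <- unique(c(extra[is.na(a), 1], extra[is.na(b), 2]))
    stop("edge endpoint(s) not in graph: ", paste(bad, collapse = ", "))
  }
  if (any(a == b)) stop("self-loop edges are not allowed")
  adj <- graph@adj
  for (k in seq_along(a)) {
    adj[[a[k]]] <- sort(unique(c(adj[[a[k]]], b[k])))
    adj[[b[k]]] <- sort(unique(c(adj[[b[k]]], a[k])))
  }
  new("AreaGraph",
    areaIds = graph@areaIds, adj = adj,
    componentLabels = .componentsFromAdj(adj, length(graph))
  )
}

#' Validate an area graph and report its structure
#'
#' @param graph an [AreaGraph-class].
#' @return A list with `nAreas`, `nEdges`, `nComponents`, `isolated`
#'   (character vector of degree-zero area ids), `degreeDistribution`
#'   (table of degrees). Isolated areas trigger a warning: under the ICAR
#'   prior each forms its own component with its effect pinned to zero by
#'   the sum-to-zero constraint.
#' @export
validateGraph <- function(graph) {
  stopifnot(is(graph, "AreaGraph"))
  d <- lengths(graph@adj)
  isolated <- graph@areaIds[d == 0L]
  if (length(isolated)) {
    warning(length(isolated), " isolated area(s): ",
            paste(head(isolated, 5), collapse = ", "),
            if (length(isolated) > 5) ", ..." else "")
  }
  list(
    nAreas = length(graph),
    nEdges = sum(d) / 2,
    nComponents = nComponents(graph),
    isolated = isolated,
    degreeDistribution = table(degree = d)
  )
}

#' Aggregate areas (municipality mergers)
#'
#' Collapses groups of areas into single aggregated units: the merged unit's
#' neighbor set is the union of the members' neighbors minus internal edges,
#' and rows of any additive tables are summed within groups. Used where an
#' administrative unit was subdivided during the study period and its parts
#' must be re-joined.
#'
#' @param graph an [AreaGraph-class].
#' @param mergeMap named character vector or two-column data.frame
#'   (`area_id`, `group_id`) mapping a subset of areas to aggregated-unit
#'   ids; areas not listed are kept as-is. Group ids must not collide with
#'   retained area ids.
#' @param additiveTables optional list of matrices/data.frames with one row
#'   per area (rownames = area ids) whose rows are summed within groups.
#' @return A list with `graph` (the aggregated [AreaGraph-class]) and
#'   `tables` (the merged additive tables, same order as supplied).
#' @export
aggregateAreas <- function(graph, mergeMap, additiveTables = list()) {
  stopifnot(is(graph, "AreaGraph"))
  if (is.data.frame(mergeMap)) {
    mergeMap <- setNames(as.character(mergeMap[[2]]),
                         as.character(mergeMap[[1]]))
  }
  unknown <- setdiff(names(mergeMap), graph@areaIds)
  if (length(unknown)) {
    stop("mergeMap refers to unknown area(s): ",
         paste(unknown, collapse = ", "))
  }
  newOf <- setNames(graph@areaIds, graph@areaIds)
  newOf[names(mergeMap)] <- mergeMap
  newIds <- unique(unname(newOf))
  idx <- match(newOf, newIds)           # old index -> new index
  n2 <- length(newIds)
  adj2 <- rep(list(integer(0)), n2)
  e <- .edgeMatrix(graph@adj)
  if (nrow(e)) {
    a <- idx[e[, 1]]; b <- idx[e[, 2]]
    keep <- a != b                       # drop internal (would-be self) loops
    a <- a[keep]; b <- b[keep]
    for (k in seq_along(a)) {
      adj2[[a[k]]] <- c(adj2[[a[k]]], b[k])
      adj2[[b[k]]] <- c(adj2[[b[k]]], a[k])
    }
    adj2 <- lapply(adj2, function(x) sort(unique(x)))
  }
  g2 <- new("AreaGraph",
    areaIds = newIds, adj = adj2,
    componentLabels = .componentsFromAdj(adj2, n2)
  )
  tables2 <- lapply(additiveTables, function(tab) {
    m <- as.matrix(tab)
    if (is.null(rownames(m)) || !all(graph@areaIds %in% rownames(m))) {
      stop("additive table must have rownames covering all area ids")
    }
    m <- m[graph@areaIds, , drop = FALSE]
    out <- rowsum(m, group = idx)
    rownames(out) <- newIds[as.integer(rownames(out))]
    out[newIds, , drop = FALSE]
  })
  list(graph = g2, tables = tables2)
}

#' Read a merge map CSV
#'
#' @param path CSV with columns `area_id,group_id`.
#' @return Named character vector suitable for [aggregateAreas()].
#' @export
readMergeMap <- function(path) {
  df <- read.csv(path, colClasses = "character")
  stopifnot(all(c("area_id", "group_id") %in% names(df)))
  setNames(df$group_id, df$area_id)
}
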