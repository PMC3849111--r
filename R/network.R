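# Network data model: an extended tree of branches (cable segments) and typed
# nodes (terminal_closed, terminal_open, branch_point, soma, gap_junction).
# Gap junctions are nodes with exactly four incident segment ends, partitioned
# into two same-dendrite pairs (m-, m+) and (n-, n+).

NODE_KINDS <- c("terminal_closed", "terminal_open", "branch_point", "soma",
                "gap_junction")

#' Point location on a branch
#'
#' Positions are measured from the proximal end of the branch, in um.  The
#' branch may be addressed either by its final (segment) id or by the id of an
#' original branch that was split by a gap junction, in which case
#' [locate()] resolves the coordinate onto the proper segment.
#'
#' @param branch branch or segment id (character).
#' @param x_um distance from the proximal end (um, >= 0).
#' @return An object of class `point_location`.
#' @export
point_location <- function(branch, x_um) {
  stopifnot(is.character(branch), length(branch) == 1L,
            is.numeric(x_um), length(x_um) == 1L, is.finite(x_um), x_um >= 0)
  structure(list(branch = branch, x = x_um), class = "point_location")
}

#' @export
print.point_location <- function(x, ...) {
  cat(sprintf("<location> x = %g um on branch '%s'\n", x$x, x$branch))
  invisible(x)
}

.new_node <- function(id, kind, soma = NULL, R_GJ = NULL, gj = NULL) {
  list(id = id, kind = kind, soma = soma, R_GJ = R_GJ, gj = gj,
       incident = data.frame(branch = character(), end = character(),
                             stringsAsFactors = FALSE))
}

# assemble + validate a network from completed branch/node structures
.assemble_network <- function(branches, params_by_branch, nodes, segmap = NULL) {
  stopifnot(is.data.frame(branches))
  if (anyDuplicated(branches$id)) {
    stop("duplicate branch id: ",
         paste(unique(branches$id[duplicated(branches$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(branches$length) & !is.infinite(branches$length)) ||
      any(branches$length <= 0)) {
    bad <- branches$id[!(branches$length > 0)]
    stop("branch length must be > 0 (branch ", paste(bad, collapse = ", "), ")",
         call. = FALSE)
  }

  # group identical parameter sets into gamma-classes
  keys <- vapply(params_by_branch, .params_key, character(1))
  uk <- unique(keys)
  param_class <- match(keys, uk)
  params <- params_by_branch[match(uk, keys)]

  branches$param_class <- param_class

  # attach incidence
  for (i in seq_len(nrow(branches))) {
    b <- branches[i, ]
    pn <- b$prox_node
    if (is.na(pn) || is.null(nodes[[pn]])) {
      stop(sprintf("branch '%s': proximal node '%s' is not declared", b$id, pn),
           call. = FALSE)
    }
    nodes[[pn]]$incident <- rbind(nodes[[pn]]$incident,
                                  data.frame(branch = b$id, end = "prox",
                                             stringsAsFactors = FALSE))
    if (is.infinite(b$length)) {
      if (!is.na(b$dist_node)) {
        stop(sprintf("branch '%s' is semi-infinite and must not have a distal node",
                     b$id), call. = FALSE)
      }
    } else {
      dn <- b$dist_node
      if (is.na(dn) || is.null(nodes[[dn]])) {
        stop(sprintf("branch '%s': distal node '%s' is not declared", b$id, dn),
             call. = FALSE)
      }
      nodes[[dn]]$incident <- rbind(nodes[[dn]]$incident,
                                    data.frame(branch = b$id, end = "dist",
                                               stringsAsFactors = FALSE))
    }
  }

  net <- structure(list(branches = branches, params = params, nodes = nodes,
                        cells = unique(branches$cell), segmap = segmap),
                   class = "dendro_network")
  .validate_network(net)
  net
}

.validate_network <- function(net) {
  for (nd in net$nodes) {
    deg <- nrow(nd$incident)
    if (!nd$kind %in% NODE_KINDS) {
      stop(sprintf("node '%s': unknown kind '%s'", nd$id, nd$kind), call. = FALSE)
    }
    if (nd$kind %in% c("terminal_closed", "terminal_open") && deg != 1L) {
      stop(sprintf("node '%s': a terminal must have exactly 1 incident branch end (has %d)",
                   nd$id, deg), call. = FALSE)
    }
    if (nd$kind == "branch_point" && deg < 2L) {
      stop(sprintf("node '%s': a branch point needs >= 2 incident branch ends (has %d)",
                   nd$id, deg), call. = FALSE)
    }
    if (nd$kind == "soma") {
      if (deg < 1L) stop(sprintf("node '%s': soma needs >= 1 dendrite", nd$id),
                         call. = FALSE)
      if (!inherits(nd$soma, "soma_params")) {
        stop(sprintf("node '%s': soma node without soma_params", nd$id), call. = FALSE)
      }
    }
    if (nd$kind == "gap_junction") {
      if (deg != 4L) {
        stop(sprintf("node '%s': a gap junction must have exactly 4 incident branch ends (has %d)",
                     nd$id, deg), call. = FALSE)
      }
      if (is.null(nd$R_GJ) || !is.finite(nd$R_GJ) || nd$R_GJ <= 0) {
        stop(sprintf("node '%s': R_GJ must be > 0", nd$id), call. = FALSE)
      }
      pm <- nd$gj$m; pn <- nd$gj$n
      if (length(pm) != 2L || length(pn) != 2L ||
          !setequal(c(pm, pn), nd$incident$branch) || anyDuplicated(c(pm, pn))) {
        stop(sprintf("node '%s': gap-junction pairing must partition the 4 incident ends into two same-dendrite pairs",
                     nd$id), call. = FALSE)
      }
      cls <- function(b) net$branches$param_class[match(b, net$branches$id)]
      if (cls(pm[1]) != cls(pm[2]) || cls(pn[1]) != cls(pn[2])) {
        stop(sprintf("node '%s': the two segments of each gap-junction dendrite pair must share electrical parameters",
                     nd$id), call. = FALSE)
      }
      cellof <- function(b) net$branches$cell[match(b, net$branches$id)]
      if (cellof(pm[1]) != cellof(pm[2]) || cellof(pn[1]) != cellof(pn[2])) {
        stop(sprintf("node '%s': gap-junction pair segments must belong to one cell each",
                     nd$id), call. = FALSE)
      }
    }
  }

  # every branch end accounted for exactly once
  ends <- do.call(rbind, lapply(net$nodes, function(nd) nd$incident))
  expected <- sum(ifelse(is.infinite(net$branches$length), 1L, 2L))
  if (nrow(ends) != expected || anyDuplicated(ends)) {
    stop("every branch end must attach to exactly one node", call. = FALSE)
  }

  # connectivity over the whole extended tree
  g <- .network_graph(net, drop_gj = FALSE)
  if (igraph::components(g)$no != 1L) {
    stop("network is not connected", call. = FALSE)
  }

  # removing gap-junction nodes must decompose the structure into the cells
  comp <- .cell_components(net)
  ncell <- length(net$cells)
  if (length(unique(comp$component)) != ncell) {
    stop(sprintf("network does not decompose into %d cells when gap junctions are removed",
                 ncell), call. = FALSE)
  }
  bad <- stats::aggregate(component ~ cell, data = comp, FUN = function(x) length(unique(x)))
  if (any(bad$component != 1L)) {
    stop("branches labelled as one cell are not mutually connected without gap junctions",
         call. = FALSE)
  }
  invisible(net)
}

# igraph over branches (vertices = branch ids), joined where they share a node.
# With drop_gj the cross-cell coupling of each gap junction is removed but the
# same-dendrite pairs stay joined: the host cable is physically continuous
# through the gap-junction point.
.network_graph <- function(net, drop_gj = TRUE) {
  edges <- character(0)
  for (nd in net$nodes) {
    if (drop_gj && nd$kind == "gap_junction") {
      edges <- c(edges, nd$gj$m, nd$gj$n)
      next
    }
    bs <- nd$incident$branch
    if (length(bs) >= 2L) {
      for (i in seq_len(length(bs) - 1L)) {
        edges <- c(edges, bs[i], bs[i + 1L])
      }
    }
  }
  igraph::make_graph(edges = edges,
                     isolates = setdiff(net$branches$id, edges),
                     directed = FALSE)
}

.cell_components <- function(net) {
  g <- .network_graph(net, drop_gj = TRUE)
  memb <- igraph::components(g)$membership
  data.frame(branch = names(memb),
             component = as.integer(memb),
             cell = net$branches$cell[match(names(memb), net$branches$id)],
             stringsAsFactors = FALSE)
}

#' @export
print.dendro_network <- function(x, ...) {
  kinds <- table(vapply(x$nodes, `[[`, character(1), "kind"))
  cat(sprintf("<dendro_network> %d cells, %d branches (%d semi-infinite), %d nodes\n",
              length(x$cells), nrow(x$branches),
              sum(is.infinite(x$branches$length)), length(x$nodes)))
  cat("  nodes:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# configuration-driven construction

.mp_from_spec <- function(b, where) {
  get0n <- function(k) if (!is.null(b[[k]])) b[[k]] else NULL
  a <- if (!is.null(b$diameter_um)) b$diameter_um else b$a_um
  if (is.null(a)) stop(sprintf("%s: missing diameter_um", where), call. = FALSE)
  tryCatch(
    membrane_params(a_um = a,
                    C_uF_cm2 = if (is.null(b$C_uF_cm2)) 1 else b$C_uF_cm2,
                    Ra_Ohm_cm = if (is.null(b$Ra_Ohm_cm)) 100 else b$Ra_Ohm_cm,
                    R_Ohm_cm2 = get0n("R_Ohm_cm2"), tau_ms = get0n("tau_ms"),
                    r_Ohm_cm2 = get0n("r_Ohm_cm2"), L_H_cm2 = get0n("L_H_cm2")),
    error = function(e) stop(sprintf("%s: %s", where, conditionMessage(e)),
                             call. = FALSE))
}

.sp_from_spec <- function(s, where) {
  tryCatch(
    soma_params(as_um = s$as_um,
                Cs_uF_cm2 = if (is.null(s$Cs_uF_cm2)) 1 else s$Cs_uF_cm2,
                Rs_Ohm_cm2 = if (is.null(s$Rs_Ohm_cm2)) 2000 else s$Rs_Ohm_cm2,
                rs_Ohm_cm2 = s$rs_Ohm_cm2, Ls_H_cm2 = s$Ls_H_cm2),
    error = function(e) stop(sprintf("%s: %s", where, conditionMessage(e)),
                             call. = FALSE))
}

.num_or_inf <- function(x) {
  if (is.character(x) && tolower(x) %in% c("inf", "infinite")) return(Inf)
  as.numeric(x)
}

#' Build and validate a network from a configuration
#'
#' Two configuration forms are accepted.
#'
#' **Cell form** (`config$cells`, optional `config$gap_junctions`): each cell
#' is a rooted tree.  A cell is a list with `id`, optional `soma` (arguments
#' of [soma_params()]), `branches` (each with `id`, `length_um` — a number or
#' `"inf"` for a semi-infinite branch —, `parent` — `"root"` or the id of
#' another branch of the cell, attaching at that branch's distal end — and the
#' electrical constants of [membrane_params()] with `diameter_um` for the
#' diameter), optional `terminals` (named map branch id -> `"closed"` or
#' `"open"`; default closed) and optional `root` (`"closed"`/`"open"`, the
#' proximal boundary when the cell has no soma and a single root branch).
#' Branch ids are namespaced internally as `"<cell>.<branch>"`.  Each gap
#' junction is a list with `R_MOhm` and `site_1`/`site_2`, each
#' `list(cell=, branch=, x_um=)` with `x_um` strictly inside the branch; the
#' branch is split at that point into segments `"<id>_p"` (proximal side) and
#' `"<id>_d"` (distal side), and [locate()] resolves coordinates given on the
#' original branch.
#'
#' **Node form** (`config$branches` + `config$nodes`): the explicit extended
#' tree.  Each branch: `id`, `cell`, `length_um` (or `"inf"`), `prox_node`,
#' `dist_node` (absent for semi-infinite branches) and electrical constants as
#' above.  Each node: `id`, `kind` (one of terminal_closed, terminal_open,
#' branch_point, soma, gap_junction), plus `soma` parameters for somata and
#' `R_MOhm`, `pair_m`, `pair_n` (two-element character vectors of segment ids)
#' for gap junctions.
#'
#' @param config a nested list (e.g. parsed from YAML/JSON, see
#'   [read_network()]).
#' @return A validated `dendro_network` object.
#' @seealso [two_cell_network()], [two_soma_network()], [network_to_config()]
#' @export
build_network <- function(config) {
  if (!is.null(config$branches) && !is.null(config$nodes)) {
    return(.build_node_form(config))
  }
  if (is.null(config$cells)) {
    stop("config must contain either 'cells' or 'branches' + 'nodes'", call. = FALSE)
  }
  .build_cell_form(config)
}

.build_node_form <- function(config) {
  nodes <- list()
  for (n in config$nodes) {
    if (is.null(n$id) || is.null(n$kind)) {
      stop("node form: every node needs 'id' and 'kind'", call. = FALSE)
    }
    soma <- if (identical(n$kind, "soma")) .sp_from_spec(n$soma, sprintf("node '%s'", n$id))
    gj <- NULL
    if (identical(n$kind, "gap_junction")) {
      gj <- list(m = as.character(unlist(n$pair_m)),
                 n = as.character(unlist(n$pair_n)))
    }
    nodes[[n$id]] <- .new_node(n$id, n$kind, soma = soma,
                               R_GJ = n$R_MOhm, gj = gj)
  }
  rows <- list()
  mps <- list()
  for (b in config$branches) {
    if (is.null(b$id) || is.null(b$cell)) {
      stop("node form: every branch needs 'id' and 'cell'", call. = FALSE)
    }
    len <- .num_or_inf(b$length_um)
    rows[[length(rows) + 1L]] <-
      data.frame(id = b$id, cell = b$cell, length = len,
                 prox_node = b$prox_node,
                 dist_node = if (is.null(b$dist_node)) NA_character_ else b$dist_node,
                 stringsAsFactors = FALSE)
    mps[[length(rows)]] <- .mp_from_spec(b, sprintf("branch '%s'", b$id))
  }
  .assemble_network(do.call(rbind, rows), mps, nodes)
}

.build_cell_form <- function(config) {
  rows <- list(); mps <- list(); nodes <- list()
  segmap <- list()

  add_branch <- function(id, cell, len, prox, dist, mp) {
    rows[[length(rows) + 1L]] <<-
      data.frame(id = id, cell = cell, length = len, prox_node = prox,
                 dist_node = if (is.null(dist)) NA_character_ else dist,
                 stringsAsFactors = FALSE)
    mps[[length(rows)]] <<- mp
  }

  for (cell in config$cells) {
    cid <- cell$id
    if (is.null(cid)) stop("every cell needs an 'id'", call. = FALSE)
    bids <- vapply(cell$branches, `[[`, character(1), "id")
    if (anyDuplicated(bids)) {
      stop(sprintf("cell '%s': duplicate branch ids", cid), call. = FALSE)
    }
    parents <- vapply(cell$branches, function(b)
      if (is.null(b$parent)) "root" else b$parent, character(1))
    kids <- split(bids, parents)

    nroot <- length(kids[["root"]])
    if (nroot < 1L) stop(sprintf("cell '%s': no root branch", cid), call. = FALSE)
    root_id <- paste0(cid, if (!is.null(cell$soma)) ".soma" else ".root")
    if (!is.null(cell$soma)) {
      nodes[[root_id]] <- .new_node(root_id, "soma",
                                    soma = .sp_from_spec(cell$soma,
                                                         sprintf("cell '%s' soma", cid)))
    } else if (nroot >= 2L) {
      nodes[[root_id]] <- .new_node(root_id, "branch_point")
    } else {
      kind <- if (identical(cell$root, "open")) "terminal_open" else "terminal_closed"
      nodes[[root_id]] <- .new_node(root_id, kind)
    }

    for (b in cell$branches) {
      bid <- paste0(cid, ".", b$id)
      len <- .num_or_inf(b$length_um)
      parent <- if (is.null(b$parent)) "root" else b$parent
      prox <- if (parent == "root") root_id else paste0(cid, ".", parent, ".end")
      if (parent != "root" && !parent %in% bids) {
        stop(sprintf("cell '%s': branch '%s' has unknown parent '%s'",
                     cid, b$id, parent), call. = FALSE)
      }
      mp <- .mp_from_spec(b, sprintf("cell '%s' branch '%s'", cid, b$id))
      nkids <- length(kids[[b$id]])
      if (is.infinite(len)) {
        if (nkids > 0L) {
          stop(sprintf("cell '%s': semi-infinite branch '%s' cannot have children",
                       cid, b$id), call. = FALSE)
        }
        add_branch(bid, cid, Inf, prox, NULL, mp)
      } else {
        dn <- paste0(bid, ".end")
        if (nkids > 0L) {
          nodes[[dn]] <- .new_node(dn, "branch_point")
        } else {
          tk <- cell$terminals[[b$id]]
          kind <- if (identical(tk, "open")) "terminal_open" else "terminal_closed"
          nodes[[dn]] <- .new_node(dn, kind)
        }
        add_branch(bid, cid, len, prox, dn, mp)
      }
      segmap[[bid]] <- data.frame(orig = bid, seg = bid, start = 0, length = len,
                                  stringsAsFactors = FALSE)
    }
  }

  branches <- do.call(rbind, rows)

  # gap junctions: split host branches at interior points
  gjs <- config$gap_junctions
  for (k in seq_along(gjs)) {
    gj <- gjs[[k]]
    gid <- if (!is.null(gj$id)) gj$id else paste0("gj", k)
    nodes[[gid]] <- .new_node(gid, "gap_junction", R_GJ = gj$R_MOhm)
    pairs <- list()
    for (sk in c("site_1", "site_2")) {
      site <- gj[[sk]]
      if (is.null(site)) stop(sprintf("gap junction '%s': missing %s", gid, sk),
                              call. = FALSE)
      orig <- paste0(site$cell, ".", site$branch)
      sm <- segmap[[orig]]
      if (is.null(sm)) {
        stop(sprintf("gap junction '%s': unknown branch '%s' in cell '%s'",
                     gid, site$branch, site$cell), call. = FALSE)
      }
      x <- site$x_um
      i <- findInterval(x, sm$start, rightmost.closed = FALSE)
      if (i < 1L || x <= sm$start[i] || x >= sm$start[i] + sm$length[i]) {
        stop(sprintf("gap junction '%s': x_um = %g must lie strictly inside branch '%s'",
                     gid, x, orig), call. = FALSE)
      }
      seg <- sm$seg[i]
      j <- match(seg, branches$id)
      off <- x - sm$start[i]
      pid <- paste0(seg, "_p"); did <- paste0(seg, "_d")
      newrows <- branches[c(j, j), ]
      newrows$id <- c(pid, did)
      newrows$length <- c(off, branches$length[j] - off)
      newrows$dist_node <- c(gid, branches$dist_node[j])
      newrows$prox_node <- c(branches$prox_node[j], gid)
      branches <- rbind(branches[-j, ], newrows)
      mp <- mps[[j]]
      mps <- c(mps[-j], list(mp, mp))
      sm <- rbind(sm[-i, , drop = FALSE],
                  data.frame(orig = orig, seg = c(pid, did),
                             start = c(sm$start[i], x),
                             length = c(off, newrows$length[2]),
                             stringsAsFactors = FALSE))
      segmap[[orig]] <- sm[order(sm$start), , drop = FALSE]
      pairs[[sk]] <- c(pid, did)
    }
    nodes[[gid]]$gj <- list(m = pairs$site_1, n = pairs$site_2)
  }

  .assemble_network(branches, mps, nodes,
                    segmap = do.call(rbind, c(segmap, list(make.row.names = FALSE))))
}

# ---------------------------------------------------------------------------
# location resolution

#' Resolve a point location on a network
#'
#' Accepts coordinates on a final segment or on an original branch that was
#' split by gap junctions, and returns the canonical `(segment, offset)` pair.
#' A coordinate falling exactly on a gap-junction point is assigned to the
#' proximal segment (its distal end), which by continuity of the response
#' across the node is equivalent to the distal-segment convention.
#'
#' @param net a `dendro_network`.
#' @param loc a [point_location()].
#' @return A `point_location` on a final segment, with attribute `node` set to
#'   the node id when the point coincides with a node.
#' @export
locate <- function(net, loc) {
  stopifnot(inherits(net, "dendro_network"), inherits(loc, "point_location"))
  id <- loc$branch; x <- loc$x
  j <- match(id, net$branches$id)
  if (is.na(j) && !is.null(net$segmap) && id %in% net$segmap$orig &&
      !id %in% net$segmap$seg) {
    sm <- net$segmap[net$segmap$orig == id, , drop = FALSE]
    sm <- sm[order(sm$start), , drop = FALSE]
    total <- sm$start[nrow(sm)] + sm$length[nrow(sm)]
    if (x > total) {
      stop(sprintf("x = %g um is beyond branch '%s' (length %g um)", x, id, total),
           call. = FALSE)
    }
    i <- max(which(sm$start < x | (sm$start == 0 & x == 0)))
    id <- sm$seg[i]; x <- x - sm$start[i]
    j <- match(id, net$branches$id)
  }
  if (is.na(j)) stop(sprintf("unknown branch '%s'", loc$branch), call. = FALSE)
  len <- net$branches$length[j]
  if (x > len) {
    stop(sprintf("x = %g um is beyond branch '%s' (length %g um)", x, id, len),
         call. = FALSE)
  }
  out <- point_location(id, x)
  if (x == 0) {
    attr(out, "node") <- net$branches$prox_node[j]
  } else if (is.finite(len) && x == len) {
    attr(out, "node") <- net$branches$dist_node[j]
  }
  out
}

# ---------------------------------------------------------------------------
# convenience constructors

#' Two infinite cables coupled by a gap junction
#'
#' Builds the four-segment network of two unbranched cells, each an infinite
#' dendritic cable, joined by a single gap junction: segments `m_minus`,
#' `m_plus` (cell m) and `n_minus`, `n_plus` (cell n), all semi-infinite with
#' their proximal ends at the gap-junction node `gj`.  Coordinates on every
#' segment are distances from the gap junction.
#'
#' @param params_m,params_n [membrane_params()] for the two cells (identical
#'   cells if `params_n` is omitted).
#' @param R_GJ gap-junction resistance (MOhm).
#' @return A `dendro_network`.
#' @export
two_cell_network <- function(params_m, R_GJ, params_n = params_m) {
  branches <- data.frame(
    id = c("m_minus", "m_plus", "n_minus", "n_plus"),
    cell = c("m", "m", "n", "n"),
    length = Inf, prox_node = "gj", dist_node = NA_character_,
    stringsAsFactors = FALSE)
  nodes <- list(gj = .new_node("gj", "gap_junction", R_GJ = R_GJ,
                               gj = list(m = c("m_minus", "m_plus"),
                                         n = c("n_minus", "n_plus"))))
  .assemble_network(branches, list(params_m, params_m, params_n, params_n), nodes)
}

#' Two soma-and-dendrites cells coupled by a dendro-dendritic gap junction
#'
#' Each cell is a lumped soma with `N` semi-infinite dendrites; one dendrite
#' of each cell hosts the gap junction at distance `L_GJ` from the soma.
#' Segment ids: `"<cell>.d1_p"` (soma to gap junction, length `L_GJ`),
#' `"<cell>.d1_d"` (gap junction outward, semi-infinite), `"<cell>.d2"` ...
#' `"<cell>.d<N>"`.  Coordinates on the host dendrite may be given on the
#' original branch `"<cell>.d1"` (distance from the soma) and resolved with
#' [locate()].
#'
#' @param params dendritic [membrane_params()] (identical cells).
#' @param soma [soma_params()].
#' @param N number of dendrites per soma.
#' @param L_GJ distance of the gap junction from each soma (um).
#' @param R_GJ gap-junction resistance (MOhm).
#' @return A `dendro_network`.
#' @export
two_soma_network <- function(params, soma, N = 4, L_GJ, R_GJ) {
  stopifnot(N >= 1, L_GJ > 0)
  rows <- list(); mps <- list(); nodes <- list(); segmap <- list()
  for (cid in c("c1", "c2")) {
    sid <- paste0(cid, ".soma")
    nodes[[sid]] <- .new_node(sid, "soma", soma = soma)
    host_p <- paste0(cid, ".d1_p"); host_d <- paste0(cid, ".d1_d")
    rows[[length(rows) + 1L]] <- data.frame(
      id = host_p, cell = cid, length = L_GJ, prox_node = sid, dist_node = "gj",
      stringsAsFactors = FALSE)
    mps[[length(rows)]] <- params
    rows[[length(rows) + 1L]] <- data.frame(
      id = host_d, cell = cid, length = Inf, prox_node = "gj",
      dist_node = NA_character_, stringsAsFactors = FALSE)
    mps[[length(rows)]] <- params
    segmap[[paste0(cid, ".d1")]] <- data.frame(
      orig = paste0(cid, ".d1"), seg = c(host_p, host_d),
      start = c(0, L_GJ), length = c(L_GJ, Inf), stringsAsFactors = FALSE)
    if (N > 1) {
      for (k in 2:N) {
        bid <- paste0(cid, ".d", k)
        rows[[length(rows) + 1L]] <- data.frame(
          id = bid, cell = cid, length = Inf, prox_node = sid,
          dist_node = NA_character_, stringsAsFactors = FALSE)
        mps[[length(rows)]] <- params
        segmap[[bid]] <- data.frame(orig = bid, seg = bid, start = 0,
                                    length = Inf, stringsAsFactors = FALSE)
      }
    }
  }
  nodes[["gj"]] <- .new_node("gj", "gap_junction", R_GJ = R_GJ,
                             gj = list(m = c("c1.d1_p", "c1.d1_d"),
                                       n = c("c2.d1_p", "c2.d1_d")))
  .assemble_network(do.call(rbind, rows), mps, nodes,
                    segmap = do.call(rbind, c(segmap, list(make.row.names = FALSE))))
}

# ---------------------------------------------------------------------------
# serialisation

#' Serialise a network to a configuration list
#'
#' Produces the explicit node-form configuration (see [build_network()]);
#' `build_network(network_to_config(net))` reproduces the network.
#'
#' @param net a `dendro_network`.
#' @return A nested list with `branches` and `nodes`.
#' @export
network_to_config <- function(net) {
  stopifnot(inherits(net, "dendro_network"))
  branches <- lapply(seq_len(nrow(net$branches)), function(i) {
    b <- net$branches[i, ]
    q <- net$params[[b$param_class]]$quoted
    out <- list(id = b$id, cell = b$cell,
                length_um = if (is.infinite(b$length)) "inf" else b$length,
                prox_node = b$prox_node)
    if (!is.na(b$dist_node)) out$dist_node <- b$dist_node
    c(out, list(diameter_um = q$a_um, C_uF_cm2 = q$C_uF_cm2,
                Ra_Ohm_cm = q$Ra_Ohm_cm, R_Ohm_cm2 = q$R_Ohm_cm2),
      if (!is.null(q$r_Ohm_cm2)) list(r_Ohm_cm2 = q$r_Ohm_cm2,
                                      L_H_cm2 = q$L_H_cm2))
  })
  nodes <- lapply(net$nodes, function(nd) {
    out <- list(id = nd$id, kind = nd$kind)
    if (nd$kind == "soma") {
      q <- nd$soma$quoted
      out$soma <- c(list(as_um = q$as_um, Cs_uF_cm2 = q$Cs_uF_cm2,
                         Rs_Ohm_cm2 = q$Rs_Ohm_cm2),
                    if (!is.null(q$rs_Ohm_cm2)) list(rs_Ohm_cm2 = q$rs_Ohm_cm2,
                                                     Ls_H_cm2 = q$Ls_H_cm2))
    }
    if (nd$kind == "gap_junction") {
      out$R_MOhm <- nd$R_GJ
      out$pair_m <- as.list(nd$gj$m)
      out$pair_n <- as.list(nd$gj$n)
    }
    out
  })
  list(branches = branches, nodes = unname(nodes))
}

#' Read or write a network configuration file
#'
#' YAML (`.yml`/`.yaml`) and JSON (`.json`) are supported; the format is
#' inferred from the file extension.
#'
#' @param path file path.
#' @return `read_network`: a validated `dendro_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("network file '%s' does not exist", path), call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  build_network(cfg)
}

#' @rdname read_network
#' @param net a `dendro_network`.
#' @export
write_network <- function(net, path) {
  cfg <- network_to_config(net)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
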