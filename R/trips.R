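# Sum-over-trips engine: exhaustive enumeration of trips between two point
# locations on the extended tree, and assembly of the Laplace-domain Green's
# function
#   Ghat_ij(x, y, omega) =
#     1/(cpl_j D_j gamma_j) * sum_trips A_trip(omega) exp(-L_trip(omega)) / 2,
# where L_trip is the trip's physical length per branch scaled by that
# branch's gamma_k(omega), and A_trip is the product of node factors picked up
# along the way.  Trips are enumerated once by *physical* length (the set is
# omega-independent); the cutoff is raised adaptively until the tail of the
# expansion is below tolerance at every requested omega.

# node-to-node distance matrix over finite branches, in traversal-cost units
# (cost = physical length times the per-class weight; unit weights give
# physical distances)
.node_distances <- function(net, w) {
  ids <- names(net$nodes)
  fin <- net$branches[is.finite(net$branches$length), , drop = FALSE]
  g <- igraph::make_graph(edges = rbind(fin$prox_node, fin$dist_node),
                          isolates = setdiff(ids, c(fin$prox_node, fin$dist_node)),
                          directed = FALSE)
  d <- igraph::distances(g, weights = fin$length * w[fin$param_class])
  d[ids, ids, drop = FALSE]
}

# cheapest cost from every node to the point y
.dist_to_point <- function(net, y, w, ndist = NULL) {
  if (is.null(ndist)) ndist <- .node_distances(net, w)
  j <- match(y$branch, net$branches$id)
  b <- net$branches[j, ]
  wy <- w[b$param_class]
  d <- ndist[, b$prox_node] + y$x * wy
  if (!is.na(b$dist_node)) {
    d <- pmin(d, ndist[, b$dist_node] + (b$length - y$x) * wy)
  }
  names(d) <- rownames(ndist)
  d
}


#' Enumerate all trips between two locations up to a length cutoff
#'
#' Performs an exhaustive search for trips (paths along the extended tree that
#' change direction only at nodes) from `x` to `y` with total physical length
#' at most `cutoff`.  Trips never enter a semi-infinite branch that does not
#' host `y` (such a trip could not return), and the degenerate `x == y`
#' zero-length trip counts once.  Each trip records the ordered node events it
#' picks up and its traversed length per branch parameter class.
#'
#' @param net a `dendro_network`.
#' @param x,y [point_location()]s (resolved with [locate()]).
#' @param cutoff maximum total trip length: physical (um) by default, or in
#'   weighted units when `weights` are given.
#' @param weights optional per-parameter-class traversal weights (1/um);
#'   lengths are multiplied by them for the cutoff and the ordering (used by
#'   [greens_laplace()] to truncate in electrotonic rather than physical
#'   units).  Default: unit weights, i.e. physical length.
#' @param max_trips hard bound on the enumeration size; exceeding it marks
#'   the expansion as capped (attribute `capped`).
#' @return A `trip_expansion` object with trips sorted by ascending
#'   (weighted) length.
#' @seealso [greens_laplace()], [trip_coefficient()], [scaled_trip_length()]
#' @export
enumerate_trips <- function(net, x, y, cutoff, weights = NULL,
                            max_trips = 1e6) {
  x <- locate(net, x); y <- locate(net, y)
  br <- net$branches
  bi <- function(id) match(id, br$id)
  xj <- bi(x$branch); yj <- bi(y$branch)
  w <- if (is.null(weights)) rep(1, length(net$params)) else weights
  stopifnot(length(w) == length(net$params), all(w > 0))

  ndist <- .node_distances(net, w)
  dmin <- .dist_to_point(net, y, w, ndist)

  shortest <- .shortest_trip_length(net, x, y, w, dmin)
  if (cutoff < shortest) {
    stop(sprintf("cutoff %g is below the shortest trip length %g",
                 cutoff, shortest), call. = FALSE)
  }

  nclass <- length(net$params)
  reg_keys <- character(0)     # factor registry
  reg_rows <- list()
  reg_index <- function(type, node, inb, outb) {
    key <- paste(type, node, inb, outb, sep = "|")
    i <- match(key, reg_keys)
    if (is.na(i)) {
      reg_keys[[length(reg_keys) + 1L]] <<- key
      reg_rows[[length(reg_keys)]] <<- list(type = type, node = node,
                                            inb = inb, outb = outb, key = key)
      i <- length(reg_keys)
    }
    i
  }

  # continuation factor at a node, entering along `inb`, leaving along `outb`
  node_factor <- function(nd, inb, outb) {
    switch(nd$kind,
      terminal_closed = reg_index("term_closed", nd$id, inb, outb),
      terminal_open = reg_index("term_open", nd$id, inb, outb),
      branch_point = reg_index("branch", nd$id, inb, outb),
      soma = reg_index("soma", nd$id, inb, outb),
      gap_junction = {
        side_in <- if (inb %in% nd$gj$m) "m" else "n"
        side_out <- if (outb %in% nd$gj$m) "m" else "n"
        type <- if (side_in != side_out) "gj_cross"
                else if (inb == outb) "gj_reflect"
                else "gj_pass"
        reg_index(type, nd$id, inb, outb)
      })
  }

  # Precompiled continuation table: a state is (node, in-branch); for each
  # state, the admissible out-branches with their factor index, traversal
  # length/class, optional termination at y and optional successor state.
  # This keeps the depth-first search free of string handling.
  node_ids <- names(net$nodes)
  state_key <- character(0)
  state_of <- function(node_id, inb) {
    key <- paste(node_id, inb, sep = "\r")
    i <- match(key, state_key)
    if (is.na(i)) {
      state_key[[length(state_key) + 1L]] <<- key
      i <- length(state_key)
    }
    i
  }
  # enumerate all states up front
  for (nid in node_ids) {
    for (b in net$nodes[[nid]]$incident$branch) state_of(nid, b)
  }
  n_state <- length(state_key)
  cont <- vector("list", n_state)
  for (s in seq_len(n_state)) {
    parts <- strsplit(state_key[s], "\r", fixed = TRUE)[[1]]
    nid <- parts[1]; inb <- parts[2]
    nd <- net$nodes[[nid]]
    outs <- if (nd$kind %in% c("terminal_closed", "terminal_open")) inb
            else nd$incident$branch
    fidx <- integer(0); term_len <- numeric(0); far_state <- integer(0)
    far_len <- numeric(0); far_min <- numeric(0); ocl <- integer(0)
    for (outb in outs) {
      oj <- bi(outb)
      enters_prox <- identical(br$prox_node[oj], nid)
      tl <- NA_real_
      if (oj == yj) {
        tl <- if (enters_prox) y$x else br$length[oj] - y$x
      }
      fs <- NA_integer_; fl <- NA_real_; fm <- NA_real_
      if (is.finite(br$length[oj])) {
        far <- if (enters_prox) br$dist_node[oj] else br$prox_node[oj]
        if (!is.na(far)) {
          fs <- state_of(far, outb)
          fl <- br$length[oj]
          fm <- dmin[[far]]
        }
      }
      if (is.na(tl) && is.na(fs)) next # dead end (semi-infinite, no y)
      fidx <- c(fidx, node_factor(nd, inb, outb))
      term_len <- c(term_len, ifelse(is.na(tl), -1, tl))
      far_state <- c(far_state, ifelse(is.na(fs), 0L, fs))
      far_len <- c(far_len, ifelse(is.na(fl), 0, fl))
      far_min <- c(far_min, ifelse(is.na(fm), 0, fm))
      ocl <- c(ocl, br$param_class[oj])
    }
    wk <- w[ocl]
    cont[[s]] <- list(fidx = as.integer(fidx),
                      term_cost = as.numeric(ifelse(term_len < 0, -1,
                                                    term_len * wk)),
                      term_len = as.numeric(pmax(term_len, 0)),
                      far_state = as.integer(far_state),
                      far_cost = as.numeric(far_len * wk),
                      far_len = as.numeric(far_len),
                      far_min = as.numeric(far_min), ocl = as.integer(ocl))
  }

  # departures from x toward each end node of its branch (id 1: proximal
  # end, id 2: distal end; the direct trip carries id 0)
  starts <- list()
  wx <- w[br$param_class[xj]]
  ends <- list(list(node = br$prox_node[xj], d0 = x$x, id = 1L),
               list(node = br$dist_node[xj], d0 = br$length[xj] - x$x, id = 2L))
  for (e in ends) {
    if (is.na(e$node)) next
    if (e$d0 * wx + dmin[[e$node]] > cutoff) next
    starts[[length(starts) + 1L]] <-
      list(state = state_of(e$node, x$branch), d0_cost = e$d0 * wx, d0 = e$d0,
           cl = br$param_class[xj], id = e$id)
  }

  # Is the expansion finite?  Trips are unbounded iff the live continuation
  # graph (states reachable from the departures, following finite-branch
  # successors) contains a cycle.  On e.g. the pure two-infinite-cable
  # network it is acyclic and the finitely many trips are the exact series.
  reach <- unique(vapply(starts, `[[`, integer(1), "state"))
  succ <- lapply(cont, function(co) unique(co$far_state[co$far_state > 0L]))
  frontier <- reach
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(succ[frontier])), reach)
    reach <- c(reach, nxt)
    frontier <- nxt
  }
  # Longest elementary reverberation period among the live states: for each
  # state, the cheapest cycle returning to it (Floyd-Warshall on the
  # continuation graph).  Each reverberation family contributes shells at
  # this spacing, so tail windows must be at least this wide.
  nr <- length(reach)
  dmat <- matrix(Inf, nr, nr)
  idx_of <- integer(n_state); idx_of[reach] <- seq_len(nr)
  for (si in seq_len(nr)) {
    co <- cont[[reach[si]]]
    live <- which(co$far_state > 0L & idx_of[pmax(co$far_state, 1L)] > 0L)
    for (k in live) {
      ti <- idx_of[co$far_state[k]]
      dmat[si, ti] <- min(dmat[si, ti], co$far_cost[k])
    }
  }
  adj <- dmat
  for (k in seq_len(nr)) {
    dmat <- pmin(dmat, outer(dmat[, k], dmat[k, ], `+`))
  }
  cyc <- diag(dmat) # cheapest cycle through each state (Inf if none)
  max_cycle <- if (any(is.finite(cyc))) max(cyc[is.finite(cyc)]) else 0

  finite_expansion <- TRUE
  color <- integer(n_state) # 0 unseen, 1 on stack, 2 done
  for (s0 in reach) {
    if (color[s0] != 0L) next
    stack <- list(list(s = s0, i = 1L))
    color[s0] <- 1L
    while (length(stack) && finite_expansion) {
      top <- stack[[length(stack)]]
      kids <- succ[[top$s]]
      if (top$i > length(kids)) {
        color[top$s] <- 2L
        stack[[length(stack)]] <- NULL
      } else {
        stack[[length(stack)]]$i <- top$i + 1L
        k <- kids[top$i]
        if (color[k] == 1L) finite_expansion <- FALSE
        else if (color[k] == 0L) {
          color[k] <- 1L
          stack[[length(stack) + 1L]] <- list(s = k, i = 1L)
        }
      }
    }
    if (!finite_expansion) break
  }

  res <- enum_trips_cpp(cont, starts, cutoff, nclass, max(length(reg_keys), 1L),
                        direct_cost = if (xj == yj) abs(x$x - y$x) * wx else -1,
                        direct_len = if (xj == yj) abs(x$x - y$x) else -1,
                        direct_class = if (xj == yj) br$param_class[xj] else 0L,
                        max_trips = as.integer(max_trips))
  ntr <- length(res$costs)
  if (ntr == 0L && !res$capped) {
    stop("no trips found within the cutoff (empty expansion)", call. = FALSE)
  }

  ord <- order(res$costs)
  nfac <- length(reg_keys)
  Fcount <- res$Fcount[ord, , drop = FALSE]
  Lmat <- res$Lmat[ord, , drop = FALSE]
  fac_list <- split_ragged(res$fac_concat, res$fac_n)[ord]

  registry <- if (nfac) {
    do.call(rbind, lapply(reg_rows, function(r)
      data.frame(type = r$type, node = r$node, inb = r$inb, outb = r$outb,
                 key = r$key, stringsAsFactors = FALSE)))
  } else {
    data.frame(type = character(), node = character(), inb = character(),
               outb = character(), key = character(), stringsAsFactors = FALSE)
  }

  structure(list(
    net = net, x = x, y = y, cutoff = cutoff, weights = w,
    costs = res$costs[ord],
    lengths = rowSums(Lmat),
    factors = fac_list,
    Fcount = Fcount, Lmat = Lmat, registry = registry,
    start = res$start[ord], xj = xj,
    yj = yj, shortest = shortest, capped = isTRUE(res$capped),
    finite = finite_expansion, max_cycle = max_cycle
  ), class = "trip_expansion")
}

# re-evaluate a converged expansion for a source point moved along the same
# branch: only each trip's first leg changes, by +/- the offset difference
# depending on the departure direction (the direct trip, if any, by the
# difference of |x - y|)
.greens_shifted <- function(expansion, omega, new_x) {
  old_x <- expansion$x$x
  br <- expansion$net$branches
  len <- br$length[expansion$xj]
  stopifnot(new_x >= 0, new_x <= len)
  d <- new_x - old_x
  Lshift <- numeric(n_trips(expansion))
  Lshift[expansion$start == 1L] <- d
  Lshift[expansion$start == 2L] <- -d
  if (any(expansion$start == 0L)) {
    yx <- expansion$y$x
    Lshift[expansion$start == 0L] <- abs(new_x - yx) - abs(old_x - yx)
  }
  .eval_expansion(expansion, omega, Lshift = Lshift)
}

# split a concatenated integer vector into a list by per-element counts
split_ragged <- function(concat, counts) {
  if (!length(counts)) return(list())
  idx <- rep.int(seq_along(counts), counts)
  out <- vector("list", length(counts))
  if (length(concat)) {
    filled <- split(concat, idx)
    out[as.integer(names(filled))] <- filled
  }
  empty <- which(counts == 0L)
  for (i in empty) out[[i]] <- integer(0)
  out
}

.shortest_trip_length <- function(net, x, y, w, dmin) {
  br <- net$branches
  xj <- match(x$branch, br$id)
  wx <- w[br$param_class[xj]]
  best <- if (x$branch == y$branch) abs(x$x - y$x) * wx else Inf
  pn <- br$prox_node[xj]
  if (!is.na(pn)) best <- min(best, x$x * wx + dmin[[pn]])
  dn <- br$dist_node[xj]
  if (!is.na(dn)) best <- min(best, (br$length[xj] - x$x) * wx + dmin[[dn]])
  best
}

#' @export
print.trip_expansion <- function(x, ...) {
  cat(sprintf("<trip_expansion> %d trips, lengths %.4g .. %.4g um (cutoff %.4g)\n",
              length(x$lengths), min(x$lengths), max(x$lengths), x$cutoff))
  cat(sprintf("  from x = %g um on '%s' to y = %g um on '%s'; %d node-factor types\n",
              x$x$x, x$x$branch, x$y$x, x$y$branch, nrow(x$registry)))
  invisible(x)
}

#' Number of trips in an expansion
#' @param expansion a `trip_expansion`.
#' @return Integer.
#' @export
n_trips <- function(expansion) length(expansion$lengths)

# complex factor values (nfac x nomega) for the expansion's registry
.factor_values <- function(expansion, omega) {
  net <- expansion$net
  reg <- expansion$registry
  nf <- nrow(reg)
  out <- matrix(0 + 0i, nrow = nf, ncol = length(omega))
  if (!nf) return(out)
  # memoised per-node quantities
  zcache <- new.env(parent = emptyenv())
  zb <- function(id) {
    v <- get0(id, envir = zcache)
    if (is.null(v)) {
      v <- z_branch(.branch_params(net, id), omega)
      assign(id, v, envir = zcache)
    }
    v
  }
  gjcache <- new.env(parent = emptyenv())
  gjp <- function(node) {
    v <- get0(node, envir = gjcache)
    if (is.null(v)) {
      v <- p_gj_pair(net, node, omega)
      assign(node, v, envir = gjcache)
    }
    v
  }
  for (i in seq_len(nf)) {
    r <- reg[i, ]
    out[i, ] <- switch(r$type,
      term_closed = rep(1 + 0i, length(omega)),
      term_open = rep(-1 + 0i, length(omega)),
      branch = {
        ids <- .incident_branches(net, r$node)
        ztot <- Reduce(`+`, lapply(ids, zb))
        p <- zb(r$outb) / ztot
        2 * p - (r$inb == r$outb)
      },
      soma = {
        ids <- .incident_branches(net, r$node)
        ztot <- Reduce(`+`, lapply(ids, zb)) +
          gamma_soma(net$nodes[[r$node]]$soma, omega)
        p <- zb(r$outb) / ztot
        2 * p - (r$inb == r$outb)
      },
      gj_cross = {
        nd <- net$nodes[[r$node]]
        pp <- gjp(r$node)
        if (r$outb %in% nd$gj$m) pp$p_m else pp$p_n
      },
      gj_pass = {
        nd <- net$nodes[[r$node]]
        pp <- gjp(r$node)
        if (r$inb %in% nd$gj$m) 1 - pp$p_n else 1 - pp$p_m
      },
      gj_reflect = {
        nd <- net$nodes[[r$node]]
        pp <- gjp(r$node)
        if (r$inb %in% nd$gj$m) -pp$p_n else -pp$p_m
      },
      stop(sprintf("internal error: unknown event type '%s'", r$type)))
  }
  out
}

# gamma per parameter class (nclass x nomega)
.gamma_by_class <- function(net, omega) {
  m <- vapply(net$params, function(p) gamma_branch(p, omega),
              complex(length(omega)))
  matrix(m, nrow = length(omega), ncol = length(net$params)) |> t()
}

#' Trip coefficient A_trip(omega)
#'
#' The product of node factors (2p, 2p - 1, +/-1, p_GJ, 1 - p_GJ, -p_GJ)
#' picked up by one trip of an expansion.
#'
#' @param expansion a `trip_expansion`.
#' @param i trip index (trips are sorted by ascending length).
#' @param omega complex vector (1/ms).
#' @return Complex vector.
#' @export
trip_coefficient <- function(expansion, i, omega) {
  stopifnot(i >= 1, i <= n_trips(expansion))
  omega <- as.complex(omega)
  fv <- .factor_values(expansion, omega)
  idx <- expansion$factors[[i]]
  out <- rep(1 + 0i, length(omega))
  for (f in idx) out <- out * fv[f, ]
  out
}

#' Scaled trip length
#'
#' Sum over traversed pieces of `gamma_k(omega)` times the physical length on
#' branch k (so for a homogeneous network it is `gamma(omega)` times the
#' physical trip length).
#'
#' @inheritParams trip_coefficient
#' @return Complex vector (dimensionless).
#' @export
scaled_trip_length <- function(expansion, i, omega) {
  stopifnot(i >= 1, i <= n_trips(expansion))
  gam <- .gamma_by_class(expansion$net, as.complex(omega))
  as.vector(expansion$Lmat[i, , drop = FALSE] %*% gam)
}

# evaluate the expansion, optionally only its first `ntr` trips; `Lshift`
# (per trip, um) is added to the traversed length on the x-branch's class,
# which re-targets the expansion to a shifted source point on the same branch
.eval_expansion <- function(expansion, omega, ntr = NULL, prefactor = TRUE,
                            Lshift = NULL, window_from = NULL) {
  omega <- as.complex(omega)
  net <- expansion$net
  if (is.null(ntr)) ntr <- n_trips(expansion)
  fv <- .factor_values(expansion, omega)          # nfac x nom
  gam <- .gamma_by_class(net, omega)              # nclass x nom
  Fc <- expansion$Fcount[seq_len(ntr), , drop = FALSE]
  Lm <- expansion$Lmat[seq_len(ntr), , drop = FALSE]
  if (!is.null(Lshift)) {
    cx <- net$branches$param_class[expansion$xj]
    Lm[, cx] <- Lm[, cx] + Lshift[seq_len(ntr)]
  }

  nom <- length(omega)
  out <- complex(nom)
  yb <- .branch_params(net, expansion$y$branch)
  gj <- gamma_branch(yb, omega)
  pref <- 1 / (yb$D * gj)
  if (prefactor) pref <- pref / yb$cpl

  if (!is.null(window_from)) {
    w1_abs <- numeric(nom)
    w2_abs <- numeric(nom)
    n1 <- window_from[1]
    n2 <- window_from[2]
  }

  # product of factors via exp of summed logs; zero factors handled separately
  for (w in seq_len(nom)) {
    f <- fv[, w]
    zero <- which(f == 0)
    lf <- f
    lf[zero] <- 1 # placeholder, masked below
    lf <- log(lf)
    coef <- exp(as.vector(Fc %*% lf))
    if (length(zero)) {
      dead <- rowSums(Fc[, zero, drop = FALSE]) > 0
      coef[dead] <- 0
    }
    amp <- exp(-as.vector(Lm %*% gam[, w])) / 2
    terms <- coef * amp
    out[w] <- pref[w] * sum(terms)
    if (!is.null(window_from)) {
      # modulus sums over the two outermost windows, immune to cancellation
      w1_abs[w] <- if (n1 < ntr) {
        abs(pref[w]) * sum(Mod(terms[(n1 + 1L):ntr]))
      } else 0
      w2_abs[w] <- if (n2 < n1) {
        abs(pref[w]) * sum(Mod(terms[(n2 + 1L):n1]))
      } else 0
    }
  }
  if (!is.null(window_from)) {
    attr(out, "w1_abs") <- w1_abs
    attr(out, "w2_abs") <- w2_abs
  }
  out
}

#' Laplace-domain Green's function by sum-over-trips
#'
#' Assembles `Ghat(x, y, omega)` on an arbitrary network by adaptive trip
#' enumeration: the physical-length cutoff is raised until the contribution of
#' the outermost length shell falls below `tol` relative to the running sum at
#' every requested `omega`.  The returned values are in MOhm/ms: convolving
#' with a current in nA gives mV.
#'
#' @param net a `dendro_network`.
#' @param x,y [point_location()]s: response at `x`, impulse injected at `y`.
#' @param omega complex vector of Laplace arguments; every value must satisfy
#'   `Re gamma_k(omega) > 0` on all branches (true in particular for
#'   `Re(omega) >= 0`).
#' @param tol relative truncation tolerance of the trip series.
#' @param scale optional absolute magnitude floor for the truncation test:
#'   the tail must fall below `tol * max(|Ghat|, scale)`.  Useful when the
#'   response itself nearly vanishes (e.g. next to an open terminal, where
#'   image trips cancel) and plain relative accuracy would be ill-conditioned.
#' @param state optional environment used to cache the enumeration between
#'   calls (see [greens_function()]).
#' @param max_iter maximum number of cutoff enlargements before a convergence
#'   error is raised.
#' @return Complex vector of `Ghat` values, with attributes `n_trips` and
#'   `tail_estimate`.
#' @examples
#' mp <- membrane_params(a_um = 2, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5)
#' net <- two_cell_network(mp, R_GJ = 100)
#' greens_laplace(net, point_location("m_minus", 10),
#'                point_location("m_minus", 100), omega = 1 + 2i)
#' @export
greens_laplace <- function(net, x, y, omega, tol = 1e-8, scale = 0,
                           state = NULL, max_iter = 20L) {
  stopifnot(tol > 0)
  omega <- as.complex(omega)
  gam <- .gamma_by_class(net, omega)
  if (min(Re(gam)) <= 0) {
    stop("Re gamma(omega) must be positive on every branch for the trip series to converge",
         call. = FALSE)
  }
  x <- locate(net, x); y <- locate(net, y)
  # Per-class electrotonic weights from the requested omega themselves: the
  # slowest decay rate of each class over this omega set.  This makes the
  # traversal cost a true per-trip decay bound, so that cost ordering ranks
  # amplitude bounds consistently across classes (classes can decay at very
  # different rates at complex omega, and a frequency-independent weight
  # would let the cutoff exclude trips that still matter).
  w <- pmax(apply(matrix(Re(gam), nrow = nrow(gam)), 1, min), 1e-12)

  exp0 <- NULL
  if (!is.null(state) && !is.null(state$expansion) &&
      identical(state$key, list(x, y)) &&
      length(state$weights) == length(w) &&
      isTRUE(max(abs(state$weights - w) / w) < 1e-12)) {
    exp0 <- state$expansion
  }
  # The cutoff lives in electrotonic (decay) units: each branch's length is
  # weighted by its slowest decay rate, so a cutoff increment of 1 shrinks
  # the guaranteed envelope of the omitted trips by a factor e.  Start from
  # a modest depth and extend adaptively: node factors shrink each shell
  # further, so a worst-case depth sized from the tolerance alone would
  # grossly overshoot, and the enumeration cost is exponential in the depth.
  shell <- 2
  add <- if (is.null(exp0)) max(12, log(1 / tol) + 5) / 3.5
         else exp0$cutoff - exp0$shortest
  tail_est <- Inf
  add_cap <- Inf # depth at which the enumeration-size bound was hit

  for (it in seq_len(max_iter)) {
    if (is.null(exp0)) {
      exp0 <- enumerate_trips(net, x, y,
                              cutoff = .initial_cutoff(net, x, y, w) + add,
                              weights = w)
    }
    if (exp0$finite && is.finite(exp0$cutoff)) {
      # acyclic continuation graph: grab the whole (finite, exact) trip set
      exp0 <- enumerate_trips(net, x, y, cutoff = Inf, weights = w)
    }
    if (exp0$capped) {
      # enumeration exceeded the size bound: retry shallower and do not
      # grow back to the capped depth again
      add_cap <- min(add_cap, add)
      add <- add * 0.6
      if (add < shell) {
        stop("trip enumeration exceeds the size bound even at minimal depth",
             call. = FALSE)
      }
      exp0 <- enumerate_trips(net, x, y, cutoff = exp0$shortest + add,
                              weights = w)
      next
    }
    # Window width adapted to the observed shell structure: trips cluster at
    # discrete lengths, and a fixed-width window falling into an inter-shell
    # gap would report an empty (hence falsely converged) tail.  Each window
    # must span at least one full shell gap.
    # The window must span the longest reverberation period: shells from
    # different families (different cells, the soma loop, a terminal loop)
    # interleave at very different spacings and decay rates, and a window
    # narrower than a family's period can fall between that family's shells
    # and miss the slowest-decaying component.
    width <- max(shell, 1.1 * exp0$max_cycle + 0.5)
    n1 <- sum(exp0$costs <= exp0$cutoff - width)
    n2 <- sum(exp0$costs <= exp0$cutoff - 2 * width)
    full <- .eval_expansion(exp0, omega,
                            window_from = c(max(n1, 0L), max(n2, 0L)))
    if (exp0$finite) {
      # acyclic continuation graph: the enumerated trips are the whole
      # (exact) series once the cutoff exceeds every trip, which the
      # adaptive loop guarantees on the first pass that finds them all
      tail_est <- 0
    } else if (n1 > 0 && n2 > 0) {
      denom <- pmax(abs(full), scale, .Machine$double.xmin)
      # Remainder estimate by geometric extrapolation of the two outermost
      # windows' modulus sums (immune to cancellation inside a window, and
      # aware of slowly decaying shells: node factors |2p| may exceed one,
      # so a single window is not a valid remainder proxy).  An *empty* top
      # window carries no information on an infinite expansion — the next
      # shell may sit just beyond the cutoff — so it forces deeper search.
      w1 <- attr(full, "w1_abs")
      w2 <- attr(full, "w2_abs")
      if (max(w1) == 0) {
        tail_est <- Inf
      } else {
        # geometric extrapolation is sound here because both windows span at
        # least one full period of every reverberation family
        q <- ifelse(w2 > 0, pmin(w1 / w2, 0.9), 0.5)
        tail_est <- max(w1 * q / (1 - q) / denom)
        if (any(w2 > 0 & w1 / w2 >= 1)) tail_est <- Inf # shells not decaying
      }
    } else {
      tail_est <- Inf
    }
    attr(full, "w1_abs") <- NULL
    attr(full, "w2_abs") <- NULL
    if (tail_est < tol) {
      if (!is.null(state)) {
        state$expansion <- exp0; state$key <- list(x, y); state$weights <- w
      }
      attr(full, "n_trips") <- n_trips(exp0)
      attr(full, "tail_estimate") <- tail_est
      return(full)
    }
    # gentle growth (the enumeration cost is exponential in the cutoff),
    # but jump straight to a depth that fits two full windows when the
    # current one cannot even hold them
    target <- max(add * 1.3, if (is.finite(tail_est)) 0 else 2.2 * width)
    new_add <- min(target, 0.92 * add_cap)
    if (new_add <= add * (1 + 1e-9)) break # size bound reached: no progress
    add <- new_add
    exp0 <- enumerate_trips(net, x, y, cutoff = exp0$shortest + add,
                            weights = w)
  }
  stop(sprintf("trip series did not converge below tol = %g after %d cutoff enlargements (remainder estimate %g)",
               tol, max_iter, tail_est), call. = FALSE)
}

.initial_cutoff <- function(net, x, y, w) {
  ndist <- .node_distances(net, w)
  dmin <- .dist_to_point(net, y, w, ndist)
  .shortest_trip_length(net, locate(net, x), locate(net, y), w, dmin)
}

#' Green's function as a reusable Laplace-domain function
#'
#' Returns a function `f(omega)` evaluating `Ghat(x, y, omega)`; the trip
#' enumeration is cached between calls (and silently enlarged when a new
#' `omega` set needs a longer cutoff), which makes the closure suitable for
#' inverse-transform quadratures and frequency sweeps.
#'
#' @inheritParams greens_laplace
#' @return A function of a complex vector `omega`.
#' @export
greens_function <- function(net, x, y, tol = 1e-8) {
  state <- new.env(parent = emptyenv())
  function(omega) greens_laplace(net, x, y, omega, tol = tol, state = state)
}
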