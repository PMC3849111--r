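# Minimal SWC morphology import: standard 7-column SWC (id, type, x, y, z,
# radius, parent), coordinates and radii in um.  The soma samples (type 1)
# are collapsed to a single lumped node; dendritic samples are cut into
# unbranched cable sections between branch points, each converted to one
# branch with its path length and length-weighted mean diameter.  Electrical
# constants are supplied separately (SWC carries geometry only).

#' Import a single-cell morphology from an SWC file
#'
#' @param path SWC file path.
#' @param cell_id id of the resulting cell.
#' @param electrical named list of [membrane_params()] arguments except the
#'   diameter (e.g. `list(C_uF_cm2 = 1, Ra_Ohm_cm = 100, tau_ms = 2)`),
#'   applied to every branch; branch diameters come from the morphology.
#' @param soma [soma_params()] arguments except `as_um` (taken as twice the
#'   mean soma-sample radius), or `NULL` to use defaults.
#' @param dendrite_types SWC type codes treated as dendrite (default 3:4,
#'   basal and apical).
#' @return A cell configuration list suitable for the `cells` entry of
#'   [build_network()].
#' @export
read_swc <- function(path, cell_id = "cell1",
                     electrical = list(C_uF_cm2 = 1, Ra_Ohm_cm = 100,
                                       tau_ms = 2),
                     soma = list(Cs_uF_cm2 = 1, Rs_Ohm_cm2 = 2000),
                     dendrite_types = 3:4) {
  if (!file.exists(path)) {
    stop(sprintf("SWC file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sw <- utils::read.table(text = lines, col.names = c("id", "type", "x", "y",
                                                      "z", "radius", "parent"))
  if (!any(sw$type == 1)) stop("SWC file has no soma sample (type 1)", call. = FALSE)
  keep <- sw$type == 1 | sw$type %in% dendrite_types
  sw <- sw[keep, ]
  soma_ids <- sw$id[sw$type == 1]
  dend <- sw[sw$type %in% dendrite_types, ]
  if (!nrow(dend)) stop("SWC file has no dendrite samples", call. = FALSE)
  idx <- function(i) match(i, sw$id)
  seglen <- function(i, j) {
    a <- sw[idx(i), c("x", "y", "z")]; b <- sw[idx(j), c("x", "y", "z")]
    sqrt(sum((a - b)^2))
  }
  children <- split(sw$id, factor(sw$parent, levels = sw$id))
  n_children <- vapply(children, length, integer(1))[as.character(dend$id)]
  n_children[is.na(n_children)] <- 0L

  # a section starts at a dendrite sample whose parent is the soma or a
  # multi-child dendrite sample, and runs to the next breakpoint
  is_break <- n_children >= 2L
  names(is_break) <- as.character(dend$id)
  starts <- dend$id[dend$parent %in% soma_ids]
  if (!length(starts)) stop("SWC dendrites do not attach to the soma", call. = FALSE)

  branches <- list()
  # map from SWC breakpoint sample to the branch id ending there
  branch_at <- character(0)
  queue <- starts
  bnum <- 0L
  while (length(queue)) {
    s <- queue[1]; queue <- queue[-1]
    bnum <- bnum + 1L
    parent_sample <- sw$parent[idx(s)]
    len <- seglen(parent_sample, s)
    dia <- 2 * sw$radius[idx(s)] * len
    cur <- s
    repeat {
      kids <- children[[as.character(cur)]]
      kids <- kids[!is.na(kids)]
      if (length(kids) != 1L) break
      len1 <- seglen(cur, kids)
      len <- len + len1
      dia <- dia + 2 * sw$radius[idx(kids)] * len1
      cur <- kids
    }
    parent_branch <- if (parent_sample %in% soma_ids) "root"
                     else branch_at[[as.character(parent_sample)]]
    bid <- paste0("b", bnum)
    branch_at[[as.character(cur)]] <- bid
    branches[[bnum]] <- c(list(id = bid, length_um = len,
                               parent = parent_branch,
                               diameter_um = max(dia / len, 1e-3)),
                          electrical)
    kids <- children[[as.character(cur)]]
    kids <- kids[!is.na(kids)]
    if (length(kids) >= 2L) queue <- c(queue, kids)
  }

  as_um <- 2 * mean(sw$radius[sw$type == 1])
  list(id = cell_id,
       soma = c(list(as_um = as_um), soma),
       branches = branches,
       terminals = list())
}
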