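# Differential connectivity and rewiring between two condition-specific
# networks. SFH (subfertile) is the reference condition: a node "gains"
# connectivity when it is relatively more connected in SFH than in FH.

# accept a group_network or a plain edge data.frame; return list(edges, nodes)
as_net <- function(net) {
  if (inherits(net, "group_network"))
    return(list(edges = net$edges, nodes = net$nodes$node_id))
  stopifnot(is.data.frame(net), all(c("node_a", "node_b") %in% names(net)))
  list(edges = net, nodes = unique(c(net$node_a, net$node_b)))
}

node_degrees <- function(edges, universe) {
  d <- setNames(integer(length(universe)), universe)
  if (nrow(edges)) {
    t1 <- table(factor(edges$node_a, levels = universe))
    t2 <- table(factor(edges$node_b, levels = universe))
    d <- as.integer(t1 + t2)
    names(d) <- universe
  }
  d
}

#' Differential connectivity between two group networks
#'
#' Standardized connectivity K of a node is its degree divided by the
#' maximum degree within that group's network; the differential
#' connectivity is `DK = K_SFH - K_FH`. DK values are z-scored over the
#' union node universe (a node absent from one network has degree 0
#' there); |z| >= `z_crit` is called significant, with direction gain
#' (DK > 0) or loss (DK < 0) relative to the SFH reference.
#'
#' @param net_fh,net_sfh `group_network` objects or edge `data.frame`s
#'   (columns `node_a`, `node_b`).
#' @param z_crit Two-sided z threshold (default 1.96, the standard-normal
#'   critical value at p = 0.05).
#' @return `data.frame` with columns `node_id`, `degree_fh`, `degree_sfh`,
#'   `k_fh`, `k_sfh`, `dk`, `z`, `significant`, `direction`.
#' @export
differential_connectivity <- function(net_fh, net_sfh, z_crit = 1.96) {
  fh <- as_net(net_fh); sfh <- as_net(net_sfh)
  if (!nrow(fh$edges) || !nrow(sfh$edges))
    abort("both networks must have at least one edge")
  universe <- sort(unique(c(fh$nodes, sfh$nodes)))
  d_fh <- node_degrees(fh$edges, universe)
  d_sfh <- node_degrees(sfh$edges, universe)
  if (max(d_fh) == 0 || max(d_sfh) == 0)
    abort("a network has maximum degree 0")
  k_fh <- d_fh / max(d_fh)
  k_sfh <- d_sfh / max(d_sfh)
  dk <- k_sfh - k_fh
  s <- sd(dk)
  if (is.na(s) || s == 0) {
    warning("sd(dk) is 0; all z set to 0")
    z <- rep(0, length(dk))
  } else {
    z <- (dk - mean(dk)) / s
  }
  significant <- abs(z) >= z_crit
  direction <- rep("none", length(dk))
  direction[significant & dk > 0] <- "gain"
  direction[significant & dk < 0] <- "loss"
  data.frame(node_id = universe, degree_fh = d_fh, degree_sfh = d_sfh,
             k_fh = k_fh, k_sfh = k_sfh, dk = dk, z = z,
             significant = significant,
             direction = factor(direction, levels = c("gain", "loss", "none")),
             row.names = NULL)
}

#' DyNet-style node rewiring score
#'
#' For each node of the union universe, the two group networks give two
#' weight vectors over the node's union neighbor set (edge correlation if
#' the edge exists in that group, 0 otherwise). The rewiring score Dn is
#' the mean Euclidean distance of the two vectors from their centroid —
#' zero iff the weighted neighborhoods are identical — and the
#' degree-corrected score divides by the union degree.
#'
#' @param net_fh,net_sfh `group_network` objects or edge `data.frame`s
#'   with columns `node_a`, `node_b`, `r`.
#' @return `data.frame` with columns `node_id`, `dn`, `union_degree`
#'   (floored at 1), `dn_degree_corrected`, `isolated`.
#' @export
dyn_rewiring <- function(net_fh, net_sfh) {
  fh <- as_net(net_fh); sfh <- as_net(net_sfh)
  stopifnot("r" %in% names(fh$edges), "r" %in% names(sfh$edges))
  universe <- sort(unique(c(fh$nodes, sfh$nodes)))

  adj <- function(edges) {
    w <- list()
    for (i in seq_len(nrow(edges))) {
      a <- edges$node_a[i]; b <- edges$node_b[i]; r <- edges$r[i]
      w[[a]] <- c(w[[a]], setNames(r, b))
      w[[b]] <- c(w[[b]], setNames(r, a))
    }
    w
  }
  w_fh <- adj(fh$edges); w_sfh <- adj(sfh$edges)

  out <- lapply(universe, function(node) {
    nb <- union(names(w_fh[[node]]), names(w_sfh[[node]]))
    deg <- length(nb)
    if (deg == 0)
      return(data.frame(node_id = node, dn = 0, union_degree = 1L,
                        dn_degree_corrected = 0, isolated = TRUE))
    v_fh <- setNames(numeric(deg), nb); v_sfh <- v_fh
    v_fh[names(w_fh[[node]])] <- w_fh[[node]]
    v_sfh[names(w_sfh[[node]])] <- w_sfh[[node]]
    # distance of each state from the two-state centroid = half the gap
    dn <- sqrt(sum((v_fh - v_sfh)^2)) / 2
    data.frame(node_id = node, dn = dn, union_degree = deg,
               dn_degree_corrected = dn / deg, isolated = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Central reference network (union with provenance)
#'
#' Merges the two group networks into one table, labelling every edge and
#' node as `FH-only`, `SFH-only`, or `shared`.
#'
#' @param net_fh,net_sfh `group_network` objects or edge `data.frame`s.
#' @return List with `edges` (`node_a`, `node_b`, `provenance`, `r_fh`,
#'   `r_sfh`) and `nodes` (`node_id`, `provenance`).
#' @export
central_reference <- function(net_fh, net_sfh) {
  fh <- as_net(net_fh); sfh <- as_net(net_sfh)
  key <- function(e) paste(e$node_a, e$node_b, sep = "\r")
  k_fh <- key(fh$edges); k_sfh <- key(sfh$edges)
  all_keys <- sort(unique(c(k_fh, k_sfh)))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  in_fh <- all_keys %in% k_fh; in_sfh <- all_keys %in% k_sfh
  prov <- ifelse(in_fh & in_sfh, "shared", ifelse(in_fh, "FH-only", "SFH-only"))
  r_of <- function(e, keys) {
    if ("r" %in% names(e)) setNames(e$r, key(e))[keys] else rep(NA_real_, length(keys))
  }
  edges <- data.frame(node_a = vapply(parts, `[`, "", 1),
                      node_b = vapply(parts, `[`, "", 2),
                      provenance = prov,
                      r_fh = unname(r_of(fh$edges, all_keys)),
                      r_sfh = unname(r_of(sfh$edges, all_keys)))
  nodes_all <- sort(unique(c(fh$nodes, sfh$nodes)))
  np <- ifelse(nodes_all %in% fh$nodes & nodes_all %in% sfh$nodes, "shared",
               ifelse(nodes_all %in% fh$nodes, "FH-only", "SFH-only"))
  list(edges = edges, nodes = data.frame(node_id = nodes_all, provenance = np))
}
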