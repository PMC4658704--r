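#' Statistical-parsimony connection limit
#'
#' Largest number of observed differences `j` that can be accepted as a
#' non-homoplastic (single-hit) path at the given confidence. The estimate
#' uses a per-step multiple-hit model: the per-site expected number of
#' substitutions `d` is the Jukes-Cantor correction of the candidate distance
#' `j/L`; a differing site carries superimposed change with probability
#' `q = P(>= 2 hits | >= 1 hit)` under Poisson(d) hits, and
#' `P_parsimony(j) = (1 - q)^j`. The limit is the largest `j` (up to `3L`)
#' with `P_parsimony(j) >= confidence`; it is monotone non-decreasing in `L`.
#'
#' @param L alignment length in sites (>= 1).
#' @param confidence connection confidence in (0, 1); 0.95 is the
#'   conventional statistical-parsimony limit.
#' @return Integer number of mutational steps (>= 1).
#' @examples
#' connection_limit(352)
#' @export
connection_limit <- function(L, confidence = 0.95) {
  assert_scalar_num(L, "L", lower = 1)
  if (confidence <= 0 || confidence >= 1) abort("`confidence` must be in (0, 1)")
  jmax <- 3L * as.integer(L)
  best <- 1L
  for (j in seq_len(jmax)) {
    p_hat <- j / L
    if (p_hat >= 0.75) break  # JC correction undefined: saturated
    d <- -0.75 * log(1 - 4 * p_hat / 3)
    q <- (1 - exp(-d) - d * exp(-d)) / (1 - exp(-d))
    if ((1 - q)^j >= confidence) best <- j else break
  }
  best
}

#' Build a statistical-parsimony haplotype network
#'
#' TCS-style agglomerative construction on haplotype representatives:
#' haplotype pairs are processed in order of increasing raw difference
#' (ties broken by joint haplotype frequency, highest first, then by
#' lexicographic ids, for determinism); a pair in different components is
#' joined when its difference is within the connection limit, inserting
#' `difference - 1` inferred intermediate nodes (count 0). Pairs beyond the
#' limit stay unconnected, so the network may have several components.
#'
#' @param ht haplotype table from [collapse_haplotypes()].
#' @param d raw-difference distance matrix on the haplotype representatives
#'   (computed from [haplotype_alignment()] when omitted).
#' @param limit connection limit in steps (default: [connection_limit()] at
#'   0.95 for the alignment length).
#' @return An object of class `haplotype_network`: list with tibbles `nodes`
#'   (`node, count, is_inferred, component`) and `edges` (`node_a, node_b`),
#'   plus the limit used.
#' @export
build_network <- function(ht, d = NULL, limit = NULL) {
  if (nrow(ht) == 0) abort("empty haplotype table")
  if (is.null(d)) {
    d <- pairwise_distance(haplotype_alignment(ht), "raw_differences")
  }
  if (!identical(attr(d, "model"), "raw_differences")) {
    abort("`d` must be a raw_differences distance matrix")
  }
  hap_ids <- ht$haplotype
  counts <- setNames(ht$count, hap_ids)
  if (is.null(limit)) {
    L <- nchar(ht$sequence[1])
    limit <- connection_limit(L)
  }
  if (limit < 1) abort("`limit` must be >= 1")

  nodes <- tibble(node = hap_ids, count = as.integer(counts),
                  is_inferred = FALSE)
  edges <- tibble(node_a = character(), node_b = character())

  if (nrow(ht) > 1) {
    prs <- t(combn(hap_ids, 2))
    pair_tbl <- tibble(
      a = prs[, 1], b = prs[, 2],
      diff = d[prs],
      freq = counts[prs[, 1]] + counts[prs[, 2]]
    ) %>%
      arrange(.data$diff, dplyr::desc(.data$freq), .data$a, .data$b)

    # union-find over sampled haplotypes
    parent <- setNames(seq_along(hap_ids), hap_ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }

    n_inferred <- 0L
    for (row in seq_len(nrow(pair_tbl))) {
      dd <- pair_tbl$diff[row]
      if (dd > limit) break
      ra <- find(match(pair_tbl$a[row], hap_ids))
      rb <- find(match(pair_tbl$b[row], hap_ids))
      if (ra == rb) next
      parent[ra] <- rb
      steps <- max(1L, as.integer(round(dd)))
      chain <- pair_tbl$a[row]
      if (steps > 1) {
        mids <- sprintf("m%03d", n_inferred + seq_len(steps - 1L))
        n_inferred <- n_inferred + steps - 1L
        chain <- c(chain, mids)
        nodes <- dplyr::bind_rows(
          nodes, tibble(node = mids, count = 0L, is_inferred = TRUE))
      }
      chain <- c(chain, pair_tbl$b[row])
      edges <- dplyr::bind_rows(
        edges, tibble(node_a = head(chain, -1), node_b = tail(chain, -1)))
    }
  }

  nodes$component <- network_components(nodes$node, edges)
  structure(list(nodes = nodes, edges = edges, connection_limit = limit),
            class = "haplotype_network")
}

# connected-component labels via repeated label propagation (tiny graphs)
network_components <- function(node_ids, edges) {
  comp <- setNames(seq_along(node_ids), node_ids)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- edges$node_a[e]; b <- edges$node_b[e]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  as.integer(factor(comp, levels = unique(comp)))
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "<haplotype_network> %d haplotypes + %d inferred nodes, %d edges, %d component(s), limit %d steps\n",
    sum(!x$nodes$is_inferred), sum(x$nodes$is_inferred), nrow(x$edges),
    max(x$nodes$component), x$connection_limit))
  invisible(x)
}

#' Star-likeness of a haplotype network
#'
#' Degree of the most-connected node divided by the number of edges in its
#' component: 1 for a perfect star (one hub touching every edge), smaller for
#' elongated topologies. Star-like networks are the classic signature of
#' recent population expansion.
#'
#' @param net a `haplotype_network`.
#' @return A value in `[0, 1]` (0 when the network has no edges).
#' @export
star_score <- function(net) {
  if (nrow(net$nodes) == 0) abort("empty network")
  if (nrow(net$edges) == 0) return(0)
  deg <- table(c(net$edges$node_a, net$edges$node_b))
  hub <- names(deg)[which.max(deg)]
  hub_comp <- net$nodes$component[match(hub, net$nodes$node)]
  in_comp <- net$nodes$node[net$nodes$component == hub_comp]
  comp_edges <- sum(net$edges$node_a %in% in_comp)
  as.numeric(max(deg)) / comp_edges
}

#' Node degrees of a haplotype network
#' @param net a `haplotype_network`.
#' @return Tibble `node, degree`.
#' @export
network_degrees <- function(net) {
  deg <- table(factor(c(net$edges$node_a, net$edges$node_b),
                      levels = net$nodes$node))
  tibble(node = names(deg), degree = as.integer(deg))
}

#' Write a haplotype network to CSV files
#' @param net a `haplotype_network`.
#' @param edges_path,nodes_path output CSV paths.
#' @export
write_network <- function(net, edges_path, nodes_path) {
  write.csv(net$edges, edges_path, row.names = FALSE)
  write.csv(net$nodes, nodes_path, row.names = FALSE)
  invisible(net)
}
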