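# Haplotype collapsing, minimum-spanning networks on Hamming distances
# and within/between-lineage mutational step summaries.

#' Collapse an alignment into unique haplotypes
#'
#' Under the strict policy (default) every column containing a gap or
#' `N` anywhere in the alignment is removed before collapsing, so step
#' counts are comparable across all pairs; `pairwise` keeps all columns
#' (distances then ignore uncalled positions pair by pair).
#'
#' @param aln A `sequence_alignment`.
#' @param site_mask_policy `"strict"` or `"pairwise"`.
#' @return A `haplotype_set`: `haplotypes` (named masked sequences
#'   `H1..`), `frequency`, `assignment` (sample -> haplotype id),
#'   `masked_length`, and `membership` (haplotype x sample-site counts
#'   when the alignment carries a `lineage`/site attribute).
#' @export
unique_haplotypes <- function(aln, site_mask_policy = c("strict",
                                                        "pairwise")) {
  site_mask_policy <- match.arg(site_mask_policy)
  if (!length(aln)) stop_pondmix("empty alignment")
  m <- alignment_matrix(aln)
  if (site_mask_policy == "strict") {
    keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    if (!any(keep)) stop_pondmix("all columns masked (gap/N everywhere)")
    m <- m[, keep, drop = FALSE]
  }
  seqs <- apply(m, 1, paste, collapse = "")
  uniq <- unique(seqs)
  hap_id <- paste0("H", seq_along(uniq))
  assignment <- setNames(hap_id[match(seqs, uniq)], names(aln))
  freq <- table(factor(assignment, levels = hap_id))
  membership <- NULL
  lin <- attr(aln, "lineage")
  if (!is.null(lin)) {
    membership <- table(haplotype = assignment, label = lin[names(aln)])
  }
  structure(list(haplotypes = setNames(uniq, hap_id),
                 frequency = as.integer(freq),
                 assignment = assignment,
                 masked_length = ncol(m),
                 membership = membership,
                 policy = site_mask_policy),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes from %d sequences (%d usable columns, %s masking)\n",
              length(x$haplotypes), length(x$assignment),
              x$masked_length, x$policy))
  invisible(x)
}

# Hamming distance matrix between haplotype strings (pairwise-deletion
# of uncalled positions when the set was built with policy "pairwise")
haplotype_distances <- function(hs) {
  seqs <- hs$haplotypes
  n <- length(seqs)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  called <- mat %in% c("A", "C", "G", "T")
  dim(called) <- dim(mat)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- called[i, ] & called[j, ]
    d[i, j] <- d[j, i] <- sum(mat[i, comp] != mat[j, comp])
  }
  d
}

# Kruskal MST on a distance matrix; returns edge data.frame(from, to, w)
kruskal_mst <- function(d) {
  n <- nrow(d)
  if (n < 2) return(data.frame(from = integer(), to = integer(),
                               w = numeric()))
  edges <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[edges])
  edges <- edges[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  out <- list()
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) {
      parent[a] <- b
      out[[length(out) + 1]] <- c(edges[e, 1], edges[e, 2],
                                  d[edges[e, 1], edges[e, 2]])
      if (length(out) == n - 1) break
    }
  }
  m <- do.call(rbind, out)
  data.frame(from = m[, 1], to = m[, 2], w = m[, 3])
}

# bottleneck (max edge weight) along the MST path between every pair
mst_bottleneck <- function(mst_edges, n) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(mst_edges))) {
    a <- mst_edges$from[e]; b <- mst_edges$to[e]; w <- mst_edges$w[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  bott <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    # DFS carrying the max edge weight seen
    bott[s, s] <- 0
    stack <- list(c(s, 0))
    visited <- rep(FALSE, n); visited[s] <- TRUE
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- top[1]; wmax <- top[2]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (!visited[u]) {
          visited[u] <- TRUE
          bott[s, u] <- max(wmax, nb[r, 2])
          stack[[length(stack) + 1]] <- c(u, bott[s, u])
        }
      }
    }
  }
  bott
}

#' Build a minimum-spanning haplotype network
#'
#' All edges of a minimum spanning tree on the Hamming distances, plus
#' every tie-equivalent edge (an edge whose weight equals the bottleneck
#' weight of the MST path between its endpoints), giving the classical
#' minimum-spanning network.  Edges longer than `max_steps` are then
#' removed; the resulting connected components are reported.
#'
#' @param hs A [unique_haplotypes()] result.
#' @param max_steps Step limit (default `Inf`: fully connected network).
#' @return A `haplotype_network`: `nodes` (haplotype ids with
#'   frequencies), `edges` (`from`, `to`, `steps`, `in_mst`),
#'   `component` (node -> component id), `distances`.
#' @export
build_network <- function(hs, max_steps = Inf) {
  d <- haplotype_distances(hs)
  n <- nrow(d)
  ids <- rownames(d)
  if (n == 1) {
    return(structure(list(nodes = data.frame(haplotype = ids,
                                             frequency = hs$frequency),
                          edges = data.frame(from = character(),
                                             to = character(),
                                             steps = numeric(),
                                             in_mst = logical()),
                          component = setNames(1L, ids), distances = d),
                     class = "haplotype_network"))
  }
  mst <- kruskal_mst(d)
  bott <- mst_bottleneck(mst, n)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  keep <- d[pairs] <= bott[pairs] + 1e-9 # MSN: weight equals bottleneck
  edges <- data.frame(from = ids[pairs[keep, 1]],
                      to = ids[pairs[keep, 2]],
                      steps = d[pairs][keep], stringsAsFactors = FALSE)
  in_mst <- paste(pmin(mst$from, mst$to), pmax(mst$from, mst$to))
  edges$in_mst <- paste(pmin(pairs[keep, 1], pairs[keep, 2]),
                        pmax(pairs[keep, 1], pairs[keep, 2])) %in% in_mst
  edges <- edges[edges$steps <= max_steps, ]
  # connected components after the step-limit filter
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(edges))) {
    a <- find(match(edges$from[e], ids)); b <- find(match(edges$to[e], ids))
    if (a != b) parent[a] <- b
  }
  comp_root <- vapply(seq_len(n), find, 0L)
  component <- setNames(match(comp_root, unique(comp_root)), ids)
  structure(list(nodes = data.frame(haplotype = ids,
                                    frequency = hs$frequency,
                                    stringsAsFactors = FALSE),
                 edges = edges, component = component, distances = d),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d nodes, %d edges, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), max(x$component)))
  invisible(x)
}

#' Mutational step summaries within and between lineages
#'
#' For every lineage pair, the minimum inter-lineage Hamming distance;
#' for every lineage, the maximum intra-lineage distance — the step
#' counts conventionally reported for haplotype networks.
#'
#' @param hs A [unique_haplotypes()] result.
#' @param lineages Haplotype -> lineage label (named vector); defaults
#'   to the majority lineage per haplotype from the set's membership
#'   table.  Every haplotype must be labelled.
#' @return List of two data.frames: `between` (`lineage1`, `lineage2`,
#'   `min_steps`) and `within` (`lineage`, `n_haplotypes`, `max_steps`).
#' @export
lineage_step_summary <- function(hs, lineages = NULL) {
  if (is.null(lineages)) {
    if (is.null(hs$membership))
      stop_pondmix("no lineage labels available")
    lineages <- apply(hs$membership, 1, function(r)
      colnames(hs$membership)[which.max(r)])
  }
  ids <- names(hs$haplotypes)
  if (!all(ids %in% names(lineages)))
    stop_pondmix("unlabelled haplotype(s): ",
                 paste(setdiff(ids, names(lineages)), collapse = ", "))
  lin <- lineages[ids]
  d <- haplotype_distances(hs)
  lev <- unique(lin)
  within <- do.call(rbind, lapply(lev, function(g) {
    wh <- which(lin == g)
    mx <- if (length(wh) > 1) max(d[wh, wh]) else 0
    data.frame(lineage = g, n_haplotypes = length(wh), max_steps = mx,
               stringsAsFactors = FALSE)
  }))
  between <- NULL
  if (length(lev) > 1) {
    cmb <- combn(lev, 2)
    between <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      w1 <- which(lin == cmb[1, i]); w2 <- which(lin == cmb[2, i])
      data.frame(lineage1 = cmb[1, i], lineage2 = cmb[2, i],
                 min_steps = min(d[w1, w2, drop = FALSE]),
                 stringsAsFactors = FALSE)
    }))
  }
  list(between = between, within = within)
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param net A `haplotype_network`.
#' @param path Base path: `<path>.tsv` and `<path>.graphml` are written.
#' @return The two paths, invisibly.
#' @export
write_network <- function(net, path) {
  tsv <- paste0(path, ".tsv")
  write.table(net$edges, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  gml <- paste0(path, ".graphml")
  con <- file(gml, "w"); on.exit(close(con))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
               '<key id="w" for="edge" attr.name="steps" attr.type="int"/>',
               '<key id="f" for="node" attr.name="frequency" attr.type="int"/>',
               '<graph edgedefault="undirected">'), con)
  for (i in seq_len(nrow(net$nodes)))
    writeLines(sprintf('<node id="%s"><data key="f">%d</data></node>',
                       net$nodes$haplotype[i], net$nodes$frequency[i]),
               con)
  for (i in seq_len(nrow(net$edges)))
    writeLines(sprintf('<edge source="%s" target="%s"><data key="w">%d</data></edge>',
                       net$edges$from[i], net$edges$to[i],
                       as.integer(net$edges$steps[i])), con)
  writeLines(c("</graph>", "</graphml>"), con)
  invisible(c(tsv, gml))
}
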