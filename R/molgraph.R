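## Molecular-graph helpers on top of the OpenBabel-backed SMILES parser.
## A molecule is held as its heavy-atom graph: element per atom plus a
## bond table (from, to, order).  Rings are detected as non-bridge edges.

parse_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  if (anyDuplicated(ids))
    stop("duplicate ligand ids", call. = FALSE)
  sdfs <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    smi <- stats::setNames(smiles[i], ids[i])
    sdfs[[i]] <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smi)),
      error = function(e)
        stop("unparseable SMILES for '", ids[i], "': ", smiles[[i]],
             call. = FALSE))
  }
  sdfset <- Reduce(function(a, b) c(a, b), sdfs)
  ChemmineR::cid(sdfset) <- ids
  sdfset
}

mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bonds <- data.frame(from = integer(0), to = integer(0),
                        order = integer(0))
  } else {
    bonds <- data.frame(from = as.integer(bb[, 1L]),
                        to = as.integer(bb[, 2L]),
                        order = as.integer(bb[, 3L]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds))
    g <- igraph::add_edges(g, rbind(bonds$from, bonds$to))
  ring_edge <- rep(FALSE, nrow(bonds))
  if (nrow(bonds)) {
    br <- igraph::bridges(g)
    ring_edge[-br] <- TRUE
    if (!length(br)) ring_edge[] <- TRUE
  }
  ring_atom <- rep(FALSE, n)
  if (any(ring_edge))
    ring_atom[unique(c(bonds$from[ring_edge], bonds$to[ring_edge]))] <- TRUE
  list(elements = elements, bonds = bonds, graph = g,
       ring_edge = ring_edge, ring_atom = ring_atom)
}

## number of smallest-set rings = cyclomatic number of the whole graph
count_rings <- function(mg) {
  comps <- igraph::components(mg$graph)$no
  nrow(mg$bonds) - length(mg$elements) + comps
}

## largest fused ring system, measured in rings: cyclomatic number of the
## largest connected component of the ring-bond subgraph
max_fused_ring_system <- function(mg) {
  if (!any(mg$ring_edge)) return(0L)
  rg <- igraph::subgraph_from_edges(
    mg$graph, which(mg$ring_edge), delete.vertices = TRUE)
  memb <- igraph::components(rg)$membership
  sizes <- vapply(split(seq_along(memb), memb), function(v) {
    sub <- igraph::induced_subgraph(rg, v)
    igraph::ecount(sub) - igraph::vcount(sub) + 1L
  }, numeric(1))
  as.integer(max(sizes))
}

## longest run of consecutive acyclic sp3 carbons (no double/triple bond,
## not in a ring); the induced subgraph is a forest, so the longest path
## is a tree diameter
longest_sp3_chain <- function(mg) {
  order_sum <- rep(0L, length(mg$elements))
  if (nrow(mg$bonds)) {
    mx <- tapply(c(mg$bonds$order, mg$bonds$order),
                 c(mg$bonds$from, mg$bonds$to), max)
    order_sum[as.integer(names(mx))] <- as.integer(mx)
  }
  chain <- mg$elements == "C" & !mg$ring_atom & order_sum <= 1L
  if (!any(chain)) return(0L)
  sub <- igraph::induced_subgraph(mg$graph, which(chain))
  d <- igraph::distances(sub)
  d[!is.finite(d)] <- 0
  as.integer(max(d) + 1L)
}
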