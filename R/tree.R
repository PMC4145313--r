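## Reference tree handling: newick I/O with jplace-style {edge number}
## annotations, midpoint rooting, root-to-tip branch lengths and per-phylum
## baseline medians.  The tree is stored as an ape "phylo" plus an integer
## edge number per edge row, so placement files can be joined unambiguously.

new_ref_tree <- function(phylo, edge_num, rooted) {
  stopifnot(inherits(phylo, "phylo"), length(edge_num) == nrow(phylo$edge))
  if (anyDuplicated(edge_num)) stop("edge numbers must be unique")
  structure(list(phylo = phylo, edge_num = as.integer(edge_num),
                 rooted = isTRUE(rooted)),
            class = "ref_tree")
}

#' @export
print.ref_tree <- function(x, ...) {
  cat(sprintf("<ref_tree> %d tips, %d edges, %s\n",
              length(x$phylo$tip.label), nrow(x$phylo$edge),
              if (x$rooted) "rooted" else "unrooted"))
  invisible(x)
}

## Move jplace "{n}" edge annotations (which follow the branch length) into
## node labels so that ape can parse the string; returns the cleaned text.
## The sentinel survives in tip/node labels as "@@<n>".
stash_edge_numbers <- function(txt) {
  # internal nodes: ")label:len{n}"
  txt <- gsub("(\\))([^:,()\\{\\};]*):([^,()\\{\\};]+)\\{([0-9]+)\\}",
              "\\1\\2@@\\4:\\3", txt, perl = TRUE)
  # tips: "label:len{n}"
  txt <- gsub("([^:,()\\{\\};]+):([^,()\\{\\};]+)\\{([0-9]+)\\}",
              "\\1@@\\3:\\2", txt, perl = TRUE)
  # a root annotation like "){n};" carries no edge: drop leftovers
  gsub("\\{[0-9]+\\}", "", txt)
}

#' Read a newick reference tree
#'
#' Parses a newick string or file, optionally carrying jplace-style edge
#' numbers in curly braces after the branch lengths (`"A:0.1{0}"`). When
#' the input has no edge numbers, deterministic 0-based post-order numbers
#' are assigned.
#'
#' @param x newick text or path to a newick file.
#' @return a `ref_tree`: ape phylo + `edge_num` aligned with `phylo$edge`
#'   rows + rooted flag (as reported by [ape::is.rooted()]).
#' @export
read_newick <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else paste(x, collapse = "")
  if (!grepl(";\\s*$", txt)) txt <- paste0(txt, ";")
  has_nums <- grepl("\\{[0-9]+\\}", txt)
  if (has_nums) txt <- stash_edge_numbers(txt)
  phylo <- tryCatch(ape::read.tree(text = txt),
                    error = function(e) NULL)
  if (is.null(phylo))
    stop("malformed newick: ape failed to parse near ",
         substr(txt, 1L, 60L))
  if (is.null(phylo$edge.length) || anyNA(phylo$edge.length))
    stop("missing branch length on at least one edge; ",
         "all non-root edges must carry lengths")
  if (any(phylo$edge.length < 0))
    stop("negative branch length encountered")
  if (anyDuplicated(sub("@@[0-9]+$", "", phylo$tip.label)))
    stop("tip labels must be unique")

  if (has_nums) {
    n_tip <- length(phylo$tip.label)
    labs <- c(phylo$tip.label,
              if (is.null(phylo$node.label)) rep("", phylo$Nnode)
              else phylo$node.label)
    num_of_node <- suppressWarnings(
      as.integer(sub("^.*@@([0-9]+)$", "\\1", labs)))
    num_of_node[!grepl("@@[0-9]+$", labs)] <- NA_integer_
    phylo$tip.label <- sub("@@[0-9]+$", "", phylo$tip.label)
    if (!is.null(phylo$node.label)) {
      phylo$node.label <- sub("@@[0-9]+$", "", phylo$node.label)
      if (all(phylo$node.label == "")) phylo$node.label <- NULL
    }
    edge_num <- num_of_node[phylo$edge[, 2L]]
    if (anyNA(edge_num))
      stop("edge-number annotations present but incomplete: every edge ",
           "must carry a {number}")
  } else {
    edge_num <- postorder_edge_numbers(phylo)
  }
  new_ref_tree(phylo, edge_num, ape::is.rooted(phylo))
}

## 0-based edge numbers in post-order edge traversal (deterministic).
postorder_edge_numbers <- function(phylo) {
  po <- ape::reorder.phylo(phylo, "postorder")
  key <- paste(phylo$edge[, 1L], phylo$edge[, 2L])
  pkey <- paste(po$edge[, 1L], po$edge[, 2L])
  match(key, pkey) - 1L
}

#' Write a reference tree as newick
#'
#' @param rt a `ref_tree`.
#' @param file optional path; when `NULL` the newick string is returned.
#' @param edge_numbers embed jplace-style `{n}` annotations.
#' @return newick string (invisibly when written to file).
#' @export
write_newick <- function(rt, file = NULL, edge_numbers = FALSE) {
  phylo <- rt$phylo
  if (edge_numbers) {
    n_tip <- length(phylo$tip.label)
    n_all <- n_tip + phylo$Nnode
    num_of_node <- rep(NA_integer_, n_all)
    num_of_node[phylo$edge[, 2L]] <- rt$edge_num
    sentinel <- function(id, lab) {
      if (is.na(num_of_node[id])) lab else paste0(lab, "@@", num_of_node[id])
    }
    phylo$tip.label <- vapply(seq_len(n_tip), function(i)
      sentinel(i, phylo$tip.label[i]), character(1))
    nl <- if (is.null(phylo$node.label)) rep("", phylo$Nnode) else phylo$node.label
    phylo$node.label <- vapply(seq_len(phylo$Nnode), function(i)
      sentinel(n_tip + i, nl[i]), character(1))
    txt <- ape::write.tree(phylo, digits = 12)
    txt <- gsub("@@([0-9]+):([^,()\\{\\};]+)", ":\\2{\\1}", txt, perl = TRUE)
  } else {
    txt <- ape::write.tree(phylo, digits = 12)
  }
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Total branch length of a tree
#' @param rt a `ref_tree`.
#' @return sum of all edge lengths.
#' @export
total_tree_length <- function(rt) sum(rt$phylo$edge.length)

## ---- midpoint rooting -----------------------------------------------------

## Build a rooted phylo from an undirected edge list.  `edges` is a 3-column
## matrix (a, b, length); `root` the vertex id to orient away from; `labels`
## tip labels indexed by original tip id; `n_tip` number of tips.  Vertex ids
## may exceed n_tip + n_node when a synthetic root vertex was inserted.
orient_tree <- function(edges, root, n_tip, labels) {
  n_vert <- max(edges[, 1:2], root)
  adj <- vector("list", n_vert)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]; w <- edges[k, 3L]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  ## iterative DFS, children visited in ascending vertex id for determinism
  parent <- rep(NA_integer_, n_vert)
  order_v <- integer(0)
  stack <- root
  visited <- rep(FALSE, n_vert)
  visited[root] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_v <- c(order_v, v)
    nb <- adj[[v]]
    if (is.null(nb)) next
    nxt <- nb[!visited[nb[, 1L]], , drop = FALSE]
    if (nrow(nxt)) {
      nxt <- nxt[order(nxt[, 1L], decreasing = TRUE), , drop = FALSE]
      for (r in seq_len(nrow(nxt))) {
        visited[nxt[r, 1L]] <- TRUE
        parent[nxt[r, 1L]] <- v
        stack <- c(stack, nxt[r, 1L])
      }
    }
  }
  internal <- order_v[!(order_v %in% seq_len(n_tip))]
  new_id <- integer(n_vert)
  new_id[seq_len(n_tip)] <- seq_len(n_tip)
  new_id[internal] <- n_tip + seq_along(internal)
  wmap <- new.env()
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    assign(paste(min(a, b), max(a, b)), edges[k, 3L], envir = wmap)
  }
  child <- order_v[order_v != root]
  edge <- cbind(new_id[parent[child]], new_id[child])
  elen <- vapply(child, function(v)
    get(paste(min(v, parent[v]), max(v, parent[v])), envir = wmap),
    numeric(1))
  phylo <- list(edge = edge, edge.length = elen,
                tip.label = labels, Nnode = length(internal))
  class(phylo) <- "phylo"
  attr(phylo, "order") <- NULL
  ape::reorder.phylo(phylo, "cladewise")
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest tip-to-tip path, the
#' standard rate-agnostic rooting for reference phylogenies.  When the
#' midpoint falls inside an edge a degree-2 root node is inserted, splitting
#' the edge and conserving all path lengths.  Ties in the longest path are
#' broken by lexicographic order of the (sorted) tip-label pair.  Edge
#' numbers are re-assigned post-order on the rooted tree.
#'
#' @param rt a `ref_tree` with at least 2 tips.
#' @return a rooted `ref_tree`; the two maximal root-to-tip distances are
#'   equal within 1e-9 and total branch length is conserved.
#' @export
midpoint_root <- function(rt) {
  phylo <- rt$phylo
  n_tip <- length(phylo$tip.label)
  if (n_tip < 2L) stop("midpoint rooting needs at least 2 tips")
  up <- if (ape::is.rooted(phylo) && n_tip > 2L) ape::unroot(phylo) else phylo
  if (sum(up$edge.length) <= 0) {
    warning("all branch lengths are zero; rooting at an arbitrary internal node")
    ed <- cbind(up$edge, up$edge.length)
    out <- orient_tree(ed, n_tip + 1L, n_tip, up$tip.label)
    return(new_ref_tree(out, postorder_edge_numbers(out), TRUE))
  }
  D <- ape::dist.nodes(up)
  dt <- D[seq_len(n_tip), seq_len(n_tip), drop = FALSE]
  maxd <- max(dt)
  idx <- which(dt >= maxd - 1e-12 & upper.tri(dt), arr.ind = TRUE)
  pair_lab <- apply(idx, 1L, function(r)
    paste(sort(up$tip.label[r]), collapse = "\r"))
  best <- idx[order(pair_lab)[1L], ]
  i <- best[[1L]]; j <- best[[2L]]
  path <- ape::nodepath(up, i, j)
  half <- D[i, j] / 2
  edmat <- up$edge
  keys <- paste(edmat[, 1L], edmat[, 2L])
  cum <- 0
  a <- b <- NA_integer_; x <- NA_real_; len <- NA_real_
  for (k in seq_len(length(path) - 1L)) {
    a <- path[k]; b <- path[k + 1L]
    row <- match(paste(a, b), keys)
    if (is.na(row)) row <- match(paste(b, a), keys)
    len <- up$edge.length[row]
    if (cum + len >= half - 1e-12) { x <- half - cum; break }
    cum <- cum + len
  }
  x <- min(max(x, 0), len)
  edges <- cbind(up$edge, up$edge.length)
  tol <- 1e-9
  if (x < tol && a > n_tip) {
    root <- a
  } else if (len - x < tol && b > n_tip) {
    root <- b
  } else {
    root <- max(n_tip + up$Nnode, max(up$edge)) + 1L
    drop <- (edges[, 1L] == a & edges[, 2L] == b) |
            (edges[, 1L] == b & edges[, 2L] == a)
    edges <- edges[!drop, , drop = FALSE]
    edges <- rbind(edges, c(root, a, x), c(root, b, len - x))
  }
  out <- orient_tree(edges, root, n_tip, up$tip.label)
  res <- new_ref_tree(out, postorder_edge_numbers(out), TRUE)
  depths <- root_to_tip_lengths(res)
  top2 <- sort(depths, decreasing = TRUE)[1:2]
  if (abs(top2[1L] - top2[2L]) > 1e-9)
    stop("internal error: midpoint balance check failed")
  res
}

#' Root-to-tip branch lengths
#'
#' @param rt a rooted `ref_tree`.
#' @return named numeric vector, sum of branch lengths on the root-to-tip
#'   path for every tip.
#' @export
root_to_tip_lengths <- function(rt) {
  ## rely on the ref_tree flag: ape::is.rooted() reports FALSE for a
  ## deliberately rooted basal polytomy (e.g. a star tree rooted at its hub)
  if (!rt$rooted)
    stop("tree is unrooted; call midpoint_root() first")
  d <- ape::node.depth.edgelength(rt$phylo)
  stats::setNames(d[seq_along(rt$phylo$tip.label)], rt$phylo$tip.label)
}

## root-to-node distance for every vertex (internal helper for placements)
node_depths <- function(rt) {
  if (!rt$rooted) stop("tree is unrooted; call midpoint_root() first")
  ape::node.depth.edgelength(rt$phylo)
}

#' Read a taxon-to-phylum taxonomy table
#'
#' @param path TSV with header columns `taxon_id` and `phylum`.
#' @return data.frame with those two character columns.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv(path)
  if (!all(c("taxon_id", "phylum") %in% colnames(df)))
    stop("taxonomy table must have columns 'taxon_id' and 'phylum'")
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon_id in taxonomy table")
  df[, c("taxon_id", "phylum")]
}

#' Per-phylum medians of reference root-to-tip lengths
#'
#' The rER baseline: for each phylum, the median root-to-tip branch length
#' of the reference taxa assigned to it (even counts: mean of the two
#' central values).
#'
#' @param rt rooted `ref_tree`.
#' @param taxonomy data.frame with `taxon_id`, `phylum` covering every tip.
#' @return named numeric vector, one median per phylum.
#' @export
phylum_reference_medians <- function(rt, taxonomy) {
  lens <- root_to_tip_lengths(rt)
  miss <- setdiff(names(lens), taxonomy$taxon_id)
  if (length(miss))
    stop("tips missing from taxonomy: ", paste(miss, collapse = ", "))
  phy <- taxonomy$phylum[match(names(lens), taxonomy$taxon_id)]
  empty <- setdiff(unique(taxonomy$phylum), phy)
  if (length(empty))
    warning("phyla with no tips excluded: ", paste(empty, collapse = ", "))
  med <- tapply(lens, phy, stats::median)
  med <- med[sort(names(med))]
  stats::setNames(as.numeric(med), names(med))
}
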