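## jplace placement ingest.  Producers disagree on what `distal_length`
## measures; the reader normalizes to an internal proximal-offset convention
## (distance from the root-facing node of the edge to the attachment point)
## under a configurable `offset_from` switch.  The default "distal" treats
## the file value as the length of the distal-side segment of the edge, i.e.
## proximal offset = edge length - distal_length; "proximal" takes the file
## value as the proximal offset directly.

jplace_required_fields <- c("edge_num", "distal_length", "pendant_length",
                            "like_weight_ratio")

#' Read a jplace placement file
#'
#' Supports jplace versions 1-3 (`n`, `nm` or `name` query naming).  Records
#' are normalized to the internal proximal-offset convention and, when a
#' reference tree is supplied, validated against its edge numbers and edge
#' lengths.
#'
#' @param x path to a jplace file or a JSON string.
#' @param tree optional `ref_tree` used for validation and offset
#'   normalization.
#' @param offset_from `"distal"` (default, see above) or `"proximal"`.
#' @param sample_id identifier stored on the returned set.
#' @return a `placement_set`: list with `sample_id`, `records` (data.frame
#'   with query_id, edge_num, distal_length, pendant_length,
#'   like_weight_ratio, offset), `tree_text`, `offset_from`.
#' @export
read_jplace <- function(x, tree = NULL, offset_from = c("distal", "proximal"),
                        sample_id = NA_character_) {
  offset_from <- match.arg(offset_from)
  txt <- if (length(x) == 1L && !grepl("[{]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else paste(x, collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) stop("malformed jplace JSON: ",
                                           conditionMessage(e)))
  fields <- unlist(doc$fields)
  if (!all(jplace_required_fields %in% fields))
    stop("jplace 'fields' must name ",
         paste(jplace_required_fields, collapse = ", "),
         "; found: ", paste(fields, collapse = ", "))
  fidx <- match(jplace_required_fields, fields)
  recs <- lapply(doc$placements, function(p) {
    qname <- if (!is.null(p$n)) unlist(p$n)[1L]
             else if (!is.null(p$nm)) unlist(p$nm[[1L]])[1L]
             else if (!is.null(p$name)) unlist(p$name)[1L]
             else stop("placement without 'n'/'nm'/'name'")
    do.call(rbind, lapply(p$p, function(row) {
      row <- unlist(row)
      data.frame(query_id = qname,
                 edge_num = as.integer(row[fidx[1L]]),
                 distal_length = as.numeric(row[fidx[2L]]),
                 pendant_length = as.numeric(row[fidx[3L]]),
                 like_weight_ratio = as.numeric(row[fidx[4L]]),
                 stringsAsFactors = FALSE)
    }))
  })
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(query_id = character(), edge_num = integer(),
                          distal_length = numeric(), pendant_length = numeric(),
                          like_weight_ratio = numeric())
  if (any(records$pendant_length < 0)) stop("negative pendant length")
  wsum <- tapply(records$like_weight_ratio, records$query_id, sum)
  if (length(wsum) && any(wsum > 1 + 1e-6))
    stop("like_weight_ratio sums exceed 1 for: ",
         paste(names(wsum)[wsum > 1 + 1e-6], collapse = ", "))
  ps <- structure(list(sample_id = sample_id, records = records,
                       tree_text = doc$tree %||% NA_character_,
                       offset_from = offset_from),
                  class = "placement_set")
  if (!is.null(tree)) ps <- normalize_placements(ps, tree)
  ps
}

#' Normalize placements against a reference tree
#'
#' Adds the internal `offset` column (distance from the proximal node) and
#' checks edge numbers and offsets against the tree.
#'
#' @param ps a `placement_set`.
#' @param tree a rooted `ref_tree`.
#' @return the `placement_set` with `offset` filled in.
#' @export
normalize_placements <- function(ps, tree) {
  rec <- ps$records
  row <- match(rec$edge_num, tree$edge_num)
  if (anyNA(row)) {
    bad <- rec$query_id[is.na(row)]
    stop("edge number absent from reference tree for query: ",
         paste(unique(bad), collapse = ", "))
  }
  elen <- tree$phylo$edge.length[row]
  off <- if (ps$offset_from == "distal") elen - rec$distal_length
         else rec$distal_length
  bad <- off < -1e-6 | off > elen + 1e-6
  if (any(bad))
    stop("attachment offset outside edge for query: ",
         paste(unique(rec$query_id[bad]), collapse = ", "))
  rec$offset <- pmin(pmax(off, 0), elen)
  ps$records <- rec
  ps
}

#' Select the best placement per query
#'
#' Keeps the record with the maximal like-weight ratio for each query;
#' exact ties go to the smaller edge number.
#'
#' @param ps a `placement_set` (or its records data.frame).
#' @return records data.frame with one row per query, ordered by query id.
#' @export
best_placement <- function(ps) {
  rec <- if (inherits(ps, "placement_set")) ps$records else ps
  if (nrow(rec) == 0L) stop("no placement records")
  ord <- order(rec$query_id, -rec$like_weight_ratio, rec$edge_num)
  rec <- rec[ord, , drop = FALSE]
  rec <- rec[!duplicated(rec$query_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Root-to-query-tip branch length of a placement
#'
#' Distance from the root to the attachment point (proximal node depth +
#' offset along the edge) plus the pendant branch length.
#'
#' @param tree rooted `ref_tree`.
#' @param rec one or more normalized placement records (rows with
#'   `edge_num`, `offset`, `pendant_length`).
#' @return numeric vector of root-to-query-tip lengths.
#' @export
query_tip_length <- function(tree, rec) {
  if (is.null(rec$offset) || anyNA(rec$offset))
    stop("records are not normalized; call normalize_placements()")
  depths <- node_depths(tree)
  row <- match(rec$edge_num, tree$edge_num)
  if (anyNA(row)) stop("edge number absent from reference tree")
  elen <- tree$phylo$edge.length[row]
  if (any(rec$offset > elen + 1e-6)) stop("corrupt placement: offset > edge length")
  prox <- tree$phylo$edge[row, 1L]
  depths[prox] + rec$offset + rec$pendant_length
}

#' Read a per-query sample manifest
#'
#' @param path TSV with header columns `query_id`, `marker_id`, `phylum`.
#' @return data.frame with those columns.
#' @export
read_query_manifest <- function(path) {
  df <- read_tsv(path)
  need <- c("query_id", "marker_id", "phylum")
  if (!all(need %in% colnames(df)))
    stop("query manifest must have columns ", paste(need, collapse = ", "))
  df[, need]
}

#' Write a placement set as jplace (version 3)
#'
#' Used by the synthetic-study generator; emits the same offset convention
#' the reader's default expects.
#'
#' @param tree rooted `ref_tree` (embedded with edge numbers).
#' @param records data.frame with `query_id`, `edge_num`, `offset`,
#'   `pendant_length`, `like_weight_ratio`.
#' @param file output path.
#' @param offset_from convention to encode `distal_length` under.
#' @return the path, invisibly.
#' @export
write_jplace <- function(tree, records, file,
                         offset_from = c("distal", "proximal")) {
  offset_from <- match.arg(offset_from)
  row <- match(records$edge_num, tree$edge_num)
  elen <- tree$phylo$edge.length[row]
  distal <- if (offset_from == "distal") elen - records$offset
            else records$offset
  placements <- lapply(seq_len(nrow(records)), function(i) {
    list(p = list(list(records$edge_num[i], distal[i],
                       records$pendant_length[i],
                       records$like_weight_ratio[i])),
         n = list(records$query_id[i]))
  })
  doc <- list(version = 3L,
              tree = write_newick(tree, edge_numbers = TRUE),
              fields = list("edge_num", "distal_length", "pendant_length",
                            "like_weight_ratio"),
              placements = placements,
              metadata = list(invocation = "rerate::write_jplace"))
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(file)
}
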