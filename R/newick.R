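#' Build an island dataset from time-calibrated trees
#'
#' Convenience constructor that extracts colonisation (stem) and branching
#' (crown and subsequent node) ages from ultrametric, time-calibrated Newick
#' trees.  Each tree must contain the island taxa of one colonisation
#' together with at least one mainland relative; the colonisation time is the
#' age of the divergence of the island clade from its closest mainland
#' relative, and the branching times are the node ages within the island
#' clade.
#'
#' @param newick_paths character vector of Newick file paths, one per
#'   colonisation.
#' @param island_taxa list (one character vector per tree) naming the island
#'   tips.
#' @param nonendemic_taxa list (parallel to `newick_paths`) of island tips
#'   that are conspecific with the mainland species (non-endemic).  A single
#'   non-endemic tip yields a status-3 record; a non-endemic tip co-occurring
#'   with endemic tips yields a status-5 record whose branching times come
#'   from the endemic part of the clade.
#' @param labels optional record labels (defaults to file base names).
#' @param lineage_classes class label per tree (default `"all"`).
#' @param island_age,M,class_fractions dataset-level fields, as in
#'   [island_dataset()].
#' @return a validated [island_dataset()].
#' @export
dataset_from_trees <- function(newick_paths, island_taxa,
                               nonendemic_taxa = vector("list",
                                                        length(newick_paths)),
                               labels = NULL, lineage_classes = "all",
                               island_age, M, class_fractions = c(all = 1)) {
  if (length(island_taxa) != length(newick_paths))
    stop("island_taxa must list one taxon set per tree", call. = FALSE)
  if (is.null(labels))
    labels <- sub("\\.[^.]*$", "", basename(newick_paths))
  lineage_classes <- rep_len(lineage_classes, length(newick_paths))
  colonists <- lapply(seq_along(newick_paths), function(i) {
    record_from_tree(newick_paths[[i]], island_taxa[[i]],
                     nonendemic_taxa[[i]], labels[[i]], lineage_classes[[i]])
  })
  island_dataset(island_age, M, colonists, class_fractions)
}

record_from_tree <- function(path, island, nonendemic, label, class) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not read Newick tree from ", path,
                        call. = FALSE)
  if (!ape::is.ultrametric(tr, tol = 1e-6))
    stop("tree in ", path, " is not ultrametric", call. = FALSE)
  tips <- tr$tip.label
  missing <- setdiff(island, tips)
  if (length(missing))
    stop("island taxa absent from tree ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(setdiff(tips, island)) == 0)
    stop("tree in ", path, " has no mainland relative", call. = FALSE)
  nonendemic <- intersect(nonendemic %||% character(), island)
  ages <- ape::branching.times(tr)
  ntip <- length(tips)

  clade_stem_age <- function(taxa) {
    # age of the divergence of `taxa` from their sister lineage
    node <- if (length(taxa) == 1L) match(taxa, tips)
            else ape::getMRCA(tr, taxa)
    if (length(taxa) > 1L) {
      desc <- tips[unlist(clade_tip_indices(tr, node))]
      extra <- setdiff(desc, taxa)
      if (length(extra))
        stop("island clade in ", path, " is not monophyletic; interleaved ",
             "taxa: ", paste(extra, collapse = ", "), call. = FALSE)
    }
    parent <- tr$edge[tr$edge[, 2] == node, 1]
    if (length(parent) == 0)
      stop("island clade in ", path, " spans the root; no mainland sister",
           call. = FALSE)
    unname(ages[as.character(parent)])
  }

  endemic <- setdiff(island, nonendemic)
  if (length(endemic) == 0L) {
    if (length(island) != 1L)
      stop("several non-endemic island tips in ", path,
           ": expected a single non-diverged population", call. = FALSE)
    return(colonist_record(label, 3L, clade_stem_age(island),
                           lineage_class = class))
  }
  status <- if (length(nonendemic)) 5L else 4L
  t_c <- clade_stem_age(island)
  bt <- numeric()
  if (length(endemic) > 1L) {
    mrca <- ape::getMRCA(tr, endemic)
    inner <- clade_internal_nodes(tr, mrca)
    bt <- sort(unname(ages[as.character(inner)]), decreasing = TRUE)
  }
  # status 5: the branching times describe the endemic clade; the divergence
  # of the re-immigrant from the mainland is recent and is not part of the
  # record's event times
  if (status == 5L && length(endemic) > 1L) {
    t_c_end <- clade_stem_age(endemic)
    bt <- bt[bt < t_c_end]
    t_c <- max(t_c, t_c_end)
  }
  colonist_record(label, status, t_c, bt, lineage_class = class)
}

# all internal nodes in the clade rooted at `node`, including `node`
clade_internal_nodes <- function(tr, node) {
  ntip <- length(tr$tip.label)
  out <- integer()
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd > ntip) {
      out <- c(out, nd)
      stack <- c(stack, tr$edge[tr$edge[, 1] == nd, 2])
    }
  }
  out
}

# tip indices descending from `node` (depends only on the edge table, so it
# is invariant to taxon ordering in the Newick string)
clade_tip_indices <- function(tr, node) {
  ntip <- length(tr$tip.label)
  tipset <- integer()
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd <= ntip) tipset <- c(tipset, nd)
    else stack <- c(stack, tr$edge[tr$edge[, 1] == nd, 2])
  }
  list(tipset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
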