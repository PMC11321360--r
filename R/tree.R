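#' Parse a Newick gene tree with leaf allele labels
#'
#' Reads a rooted binary Newick tree with branch lengths in generations and
#' attaches a derived/ancestral label to every leaf. Node and leaf ages are
#' inferred from path lengths, with the youngest leaf pinned at age 0; a
#' leaf whose tip sits above the youngest leaf is an ancient sample of the
#' corresponding age.
#'
#' @param newick a Newick string or path to a file containing one tree.
#' @param labels named vector (leaf name -> 0 ancestral / 1 derived), or a
#'   two-column data frame `name, label`.
#' @return object of class `"labeled_tree"`: list with the `phylo` tree,
#'   `ages` (per node, tips first), `labels` (0/1 per tip, in tip order),
#'   and `root` (root node number).
#' @export
parse_labeled_newick <- function(newick, labels) {
  phy <- if (file.exists(newick[1]) && !grepl("\\(", newick[1]))
    ape::read.tree(newick) else ape::read.tree(text = newick)
  if (is.null(phy)) stop("could not parse Newick input", call. = FALSE)
  if (is.null(phy$edge.length)) stop("tree must have branch lengths", call. = FALSE)
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop(sprintf("tree must be rooted and binary (node with > 2 children found)"),
         call. = FALSE)
  if (is.data.frame(labels)) labels <- stats::setNames(labels[[2]], labels[[1]])
  miss <- setdiff(phy$tip.label, names(labels))
  if (length(miss))
    stop(sprintf("missing allele label for leaf '%s'", miss[1]), call. = FALSE)
  lab <- as.integer(labels[phy$tip.label])
  if (any(is.na(lab) | !(lab %in% 0:1)))
    stop("labels must be 0 (ancestral) or 1 (derived)", call. = FALSE)
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth[seq_len(ntip)]) - depth
  # float noise tolerance scales with tree height (sampled trees carry
  # rounding error in their branch lengths)
  ages[abs(ages) < 1e-6 * max(ages, 1)] <- 0
  structure(list(phylo = phy, ages = ages, labels = lab, root = ntip + 1L),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat(sprintf("Labeled gene tree: %d leaves (%d derived), root age %.4g generations\n",
              length(x$labels), sum(x$labels), x$ages[x$root]))
  invisible(x)
}

# descendant tip numbers of every node, in a preorder (cladewise) node order
# starting at the root -- the order of first appearance in the Newick string.
.preorder_cladesets <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in rev(seq_len(nrow(phy$edge)))) {  # edges are cladewise: reverse = postorder
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  order <- c(ntip + 1L, phy$edge[, 2])
  list(order = order, desc = desc)
}

#' Minimum leaf flips to satisfy the infinite-sites assumption
#'
#' Under infinite sites the derived-labelled leaves must form exactly one
#' clade. When they do not (as happens for sampled marginal trees), this
#' finds the candidate clade (any node's leaf set, including single leaves;
#' never the empty set, since the derived allele must segregate) minimizing
#' the number of label disagreements, relabels the leaves to that clade,
#' and reports the flip count. Ties break to the first minimizing clade in
#' a preorder traversal of the Newick string.
#'
#' @param tree a [parse_labeled_newick()] tree.
#' @return list with `tree` (relabelled), `flips` (count), and `clade`
#'   (tip numbers of the chosen derived clade).
#' @export
repair_infinite_sites <- function(tree) {
  stopifnot(inherits(tree, "labeled_tree"))
  lab <- tree$labels
  if (sum(lab) == 0)
    stop("no derived leaves: the derived allele must segregate", call. = FALSE)
  cs <- .preorder_cladesets(tree$phylo)
  n_der <- sum(lab)
  best <- NULL; best_cost <- Inf
  for (nd in cs$order) {
    tips <- cs$desc[[nd]]
    cost <- sum(lab[tips] == 0) + (n_der - sum(lab[tips] == 1))
    if (cost < best_cost) { best_cost <- cost; best <- tips }
  }
  new_lab <- integer(length(lab))
  new_lab[best] <- 1L
  tree$labels <- new_lab
  list(tree = tree, flips = best_cost, clade = best)
}

#' Extract coalescent events from a labelled tree
#'
#' Classifies internal nodes by the rules of the structured coalescent on a
#' labelled tree: a node is a derived coalescence if and only if all its
#' descendant leaves are derived; the parent of the oldest derived
#' coalescence (or of the single derived leaf) is the mixed coalescence,
#' listed among the ancestral coalescences but with its age recorded
#' separately; all other internal nodes are ancestral coalescences. Leaves
#' with age > 0 are recorded as ancient derived/ancestral leaves. Horizon
#' truncation happens later, at [compile_emissions()].
#'
#' @param tree a [parse_labeled_newick()] tree whose derived leaves form a
#'   clade (run [repair_infinite_sites()] first otherwise).
#' @return a [tree_events()].
#' @export
extract_coalescent_events <- function(tree) {
  stopifnot(inherits(tree, "labeled_tree"))
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  lab <- tree$labels
  cs <- .preorder_cladesets(tree$phylo)
  der_tips <- which(lab == 1L)
  if (!length(der_tips))
    stop("no derived leaves: the derived allele must segregate", call. = FALSE)
  # the derived leaves must form one clade
  if (length(der_tips) > 1L) {
    mrca <- ape::getMRCA(phy, der_tips)
    if (!setequal(cs$desc[[mrca]], der_tips))
      stop("derived leaves do not form a clade; run repair_infinite_sites() first",
           call. = FALSE)
    top_der <- mrca
  } else {
    top_der <- der_tips
  }
  internal <- (ntip + 1L):(ntip + phy$Nnode)
  is_der_node <- vapply(internal, function(nd) all(lab[cs$desc[[nd]]] == 1L),
                        logical(1))
  der_nodes <- internal[is_der_node]
  mixed_node <- if (top_der == tree$root) NA_integer_ else
    phy$edge[phy$edge[, 2] == top_der, 1]
  anc_nodes <- setdiff(internal, der_nodes)
  ages <- tree$ages
  tree_events(der_coal = ages[der_nodes],
              anc_coal = ages[anc_nodes],
              mixed_age = if (is.na(mixed_node)) NA_real_ else ages[mixed_node],
              der_leaves = ages[der_tips[ages[der_tips] > 0]],
              anc_leaves = {
                at <- which(lab == 0L)
                ages[at[ages[at] > 0]]
              },
              n_der_modern = sum(lab == 1L & ages[seq_len(ntip)] == 0),
              n_anc_modern = sum(lab == 0L & ages[seq_len(ntip)] == 0))
}

#' Read / write importance-sample event files
#'
#' One block per sampled marginal gene tree, times in generations before
#' present:
#' \preformatted{
#' SAMPLE 1
#' Modern: nD nA
#' DerCoals: t1 t2 ...
#' AncCoals: t1 t2 ...
#' Mixed: t
#' DerLeaves: ...
#' AncLeaves: ...
#' }
#' `AncCoals` includes the mixed coalescence; `Mixed` repeats its age (or
#' `NA` when the mutation arose above the root). Unsorted times are sorted
#' with a warning. All samples must share the modern leaf counts.
#'
#' @param path file path.
#' @return list of [tree_events()], one per importance sample.
#' @export
read_importance_samples <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  starts <- grep("^SAMPLE\\b", lines)
  if (!length(starts)) stop("no SAMPLE blocks found", call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  num <- function(s, sort_times = TRUE) {
    v <- suppressWarnings(as.numeric(strsplit(s, "\\s+")[[1]]))
    v <- v[!is.na(v)]
    if (sort_times && length(v) > 1L && is.unsorted(v)) {
      warning("unsorted event times sorted", call. = FALSE)
      v <- sort(v)
    }
    v
  }
  samples <- lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    field <- function(key, sort_times = TRUE) {
      ln <- grep(paste0("^", key, ":"), blk, value = TRUE)
      if (!length(ln)) return(numeric(0))
      num(sub(paste0("^", key, ":"), "", ln[1]), sort_times)
    }
    modern <- field("Modern", sort_times = FALSE)
    if (length(modern) != 2)
      stop(sprintf("block %d: 'Modern: nD nA' line missing or malformed", i),
           call. = FALSE)
    mixed <- field("Mixed")
    tree_events(der_coal = field("DerCoals"), anc_coal = field("AncCoals"),
                mixed_age = if (length(mixed)) mixed[1] else NA_real_,
                der_leaves = field("DerLeaves"), anc_leaves = field("AncLeaves"),
                n_der_modern = modern[1], n_anc_modern = modern[2])
  })
  key <- vapply(samples, function(s)
    paste(s$n_der_modern, s$n_anc_modern), character(1))
  if (length(unique(key)) != 1L)
    stop("importance samples disagree on modern leaf counts", call. = FALSE)
  samples
}

#' @rdname read_importance_samples
#' @param samples list of [tree_events()].
#' @export
write_importance_samples <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) paste(format(v, digits = 12, trim = TRUE, scientific = FALSE),
                           collapse = " ")
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    writeLines(c(sprintf("SAMPLE %d", i),
                 sprintf("Modern: %d %d", s$n_der_modern, s$n_anc_modern),
                 paste("DerCoals:", fmt(s$der_coal)),
                 paste("AncCoals:", fmt(s$anc_coal)),
                 paste("Mixed:", if (is.na(s$mixed_age)) "NA" else fmt(s$mixed_age)),
                 paste("DerLeaves:", fmt(s$der_leaves)),
                 paste("AncLeaves:", fmt(s$anc_leaves))), con)
  }
  invisible(path)
}
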