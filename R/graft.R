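#' Dated phylogeny with tip taxonomy
#'
#' Pairs an `ape::phylo` tree (branch lengths in millions of years, Myr)
#' with a taxonomy table assigning each tip to a genus and family. The
#' taxonomy drives polytomy grafting of species missing from the tree;
#' genus and family come from metadata rather than being parsed out of
#' binomials, so "Genus sp." placeholders are handled.
#'
#' @param tree an `ape::phylo`, rooted, with branch lengths.
#' @param taxonomy data.frame `species,genus,family`; may cover more
#'   species than the current tips.
#' @param tol relative ultrametricity tolerance.
#' @param force_ultrametric extend tips to the maximum depth when the tree
#'   misses the tolerance (off by default).
#' @return object of class `tax_tree`.
#' @export
tax_tree <- function(tree, taxonomy, tol = 1e-6, force_ultrametric = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "genus", "family") %in% names(taxonomy)))
  if (anyDuplicated(tree$tip.label)) stop("duplicated tip labels", call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree needs nonnegative branch lengths", call. = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depths)
  if (h > 0 && max(abs(depths - h)) / h > tol) {
    if (!force_ultrametric) {
      stop("tree is not ultrametric (relative deviation ",
           signif(max(abs(depths - h)) / h, 3), " > ", tol, ")", call. = FALSE)
    }
    term <- match(seq_along(tree$tip.label), tree$edge[, 2])
    tree$edge.length[term] <- tree$edge.length[term] + (h - depths)
  }
  structure(list(tree = tree, taxonomy = taxonomy), class = "tax_tree")
}

#' @export
print.tax_tree <- function(x, ...) {
  cat("<tax_tree> ", length(x$tree$tip.label), " tips, height ",
      signif(tree_height(x), 4), " Myr\n", sep = "")
  invisible(x)
}

#' Height (root-to-tip depth, Myr) of an ultrametric `tax_tree`
#' @param tt a [tax_tree()].
#' @return numeric height.
#' @export
tree_height <- function(tt) {
  max(ape::node.depth.edgelength(tt$tree)[seq_along(tt$tree$tip.label)])
}

#' Test ultrametricity of a dated tree
#'
#' @param tt a [tax_tree()].
#' @param tol relative tolerance on root-to-tip depth spread.
#' @return logical.
#' @export
is_ultrametric_tree <- function(tt, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tt$tree)[seq_along(tt$tree$tip.label)]
  h <- max(depths)
  h == 0 || max(abs(depths - h)) / h <= tol
}

node_age <- function(tree, node) {
  d <- ape::node.depth.edgelength(tree)
  max(d[seq_along(tree$tip.label)]) - d[node]
}

#' Graft one species onto the tree as a polytomy
#'
#' Attaches a species missing from the reference phylogeny at the most
#' recent common ancestor of its congeneric tips; if the genus has no tip,
#' at the family MRCA. With a single congeneric (or confamilial) tip the
#' attachment point is that tip's parent node (its stem) - the standard
#' megaphylogeny convention. The new pendant branch length equals the age
#' of the attachment node, so the tree stays ultrametric: the tip extends
#' to the present.
#'
#' @param tt a [tax_tree()].
#' @param species species name to add (absent from the tree).
#' @param genus,family taxonomy of the species; defaults looked up in
#'   `tt$taxonomy`.
#' @return a list: `tree` (the updated `tax_tree`) and `report`, a one-row
#'   data.frame with `species`, `attachment_level` (`"genus"`, `"family"`
#'   or `"failed"`), `attachment_node_age` and `assigned_branch_length`.
#'   On failure the tree is returned unchanged.
#' @export
graft_species <- function(tt, species, genus = NULL, family = NULL) {
  tree <- tt$tree
  if (species %in% tree$tip.label) {
    stop("species already a tip: ", species, call. = FALSE)
  }
  row <- match(species, tt$taxonomy$species)
  if (is.null(genus)) genus <- if (!is.na(row)) tt$taxonomy$genus[row] else NA
  if (is.null(family)) family <- if (!is.na(row)) tt$taxonomy$family[row] else NA

  tip_tax <- tt$taxonomy[match(tree$tip.label, tt$taxonomy$species), ]
  pick_node <- function(members) {
    tips <- which(tree$tip.label %in% members)
    if (length(tips) == 0L) return(NULL)
    if (length(tips) >= 2L) return(ape::getMRCA(tree, tips))
    tree$edge[tree$edge[, 2] == tips, 1]  # stem: parent of the lone tip
  }
  level <- "failed"
  node <- NULL
  if (!is.na(genus)) {
    node <- pick_node(tree$tip.label[!is.na(tip_tax$genus) & tip_tax$genus == genus])
    if (!is.null(node)) level <- "genus"
  }
  if (is.null(node) && !is.na(family)) {
    node <- pick_node(tree$tip.label[!is.na(tip_tax$family) & tip_tax$family == family])
    if (!is.null(node)) level <- "family"
  }
  if (is.null(node)) {
    return(list(tree = tt, report = data.frame(
      species = species, attachment_level = "failed",
      attachment_node_age = NA_real_, assigned_branch_length = NA_real_,
      stringsAsFactors = FALSE)))
  }
  age <- node_age(tree, node)
  newtip <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = species,
                           edge.length = age, Nnode = 1L), class = "phylo")
  tree2 <- ape::bind.tree(tree, newtip, where = node, position = 0)
  tax2 <- tt$taxonomy
  if (is.na(row)) {
    tax2 <- rbind(tax2, data.frame(species = species, genus = as.character(genus),
                                   family = as.character(family),
                                   stringsAsFactors = FALSE))
  }
  list(tree = tax_tree(tree2, tax2),
       report = data.frame(species = species, attachment_level = level,
                           attachment_node_age = age,
                           assigned_branch_length = age,
                           stringsAsFactors = FALSE))
}

#' Graft every missing plant species of a dataset onto the tree
#'
#' @param tt a [tax_tree()].
#' @param dataset a list of [assemblage()] objects (or a single one).
#' @return list: `tree` (updated `tax_tree`) and `report` (one row per
#'   grafted or failed species; zero rows when nothing was missing).
#' @export
graft_all <- function(tt, dataset) {
  if (inherits(dataset, "assemblage")) dataset <- list(dataset)
  plants <- unique(do.call(rbind, lapply(dataset, function(a)
    a$table$plants[, c("species", "genus", "family")])))
  missing <- plants[!plants$species %in% tt$tree$tip.label, , drop = FALSE]
  reports <- list()
  for (i in seq_len(nrow(missing))) {
    res <- graft_species(tt, missing$species[i],
                         genus = missing$genus[i], family = missing$family[i])
    tt <- res$tree
    reports[[i]] <- res$report
    if (res$report$attachment_level == "failed") {
      warning("could not graft '", missing$species[i],
              "': no congeneric or confamilial tip", call. = FALSE)
    }
  }
  list(tree = tt,
       report = if (length(reports)) do.call(rbind, reports) else
         data.frame(species = character(), attachment_level = character(),
                    attachment_node_age = numeric(),
                    assigned_branch_length = numeric()))
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths along the path connecting two tips, in Myr.
#'
#' @param tt a [tax_tree()].
#' @param sp1,sp2 tip labels.
#' @return numeric distance.
#' @export
patristic_distance <- function(tt, sp1, sp2) {
  tips <- tt$tree$tip.label
  if (!sp1 %in% tips) stop("unknown tip: ", sp1, call. = FALSE)
  if (!sp2 %in% tips) stop("unknown tip: ", sp2, call. = FALSE)
  if (sp1 == sp2) return(0)
  dm <- patristic_matrix(tt)
  dm[sp1, sp2]
}

#' Full patristic distance matrix
#'
#' @param tt a [tax_tree()].
#' @return square numeric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(tt) {
  ape::cophenetic.phylo(tt$tree)
}

#' Phylogenetic isolation of a focal plant within an assemblage
#'
#' Mean patristic distance (Myr) from the focal plant to every native
#' plant co-occurring in the assemblage. For a native focal plant the
#' zero distance to itself is excluded by default (`exclude_self = TRUE`);
#' including it would mechanically deflate native isolation relative to
#' exotics.
#'
#' @param tt a [tax_tree()] containing all assemblage plants as tips.
#' @param a an [assemblage()].
#' @param focal focal plant species name.
#' @param exclude_self drop the focal plant from its own comparator set.
#' @param dist_matrix optional precomputed [patristic_matrix()] (an
#'   optimization when looping over plants).
#' @return one-row data.frame: `assemblage_id`, `focal_species`,
#'   `phylo_isolation`, `n_comparators`.
#' @export
phylo_isolation <- function(tt, a, focal, exclude_self = TRUE,
                            dist_matrix = NULL) {
  pl <- a$table$plants
  if (!focal %in% pl$species) stop("focal plant not in assemblage: ", focal,
                                   call. = FALSE)
  natives <- pl$species[pl$origin == "native"]
  if (exclude_self) natives <- setdiff(natives, focal)
  if (length(natives) == 0L) {
    stop("no native comparators for '", focal, "' in assemblage ",
         a$assemblage_id, call. = FALSE)
  }
  dm <- if (is.null(dist_matrix)) patristic_matrix(tt) else dist_matrix
  miss <- setdiff(c(focal, natives), rownames(dm))
  if (length(miss)) stop("plants missing from tree: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  data.frame(assemblage_id = a$assemblage_id, focal_species = focal,
             phylo_isolation = mean(dm[focal, natives]),
             n_comparators = length(natives), stringsAsFactors = FALSE)
}

#' Read a dated tree plus taxonomy from files
#'
#' @param newick_path Newick file with branch lengths.
#' @param taxonomy_path CSV `species,genus,family`.
#' @param ... passed to [tax_tree()].
#' @return a `tax_tree`.
#' @export
read_tax_tree <- function(newick_path, taxonomy_path, ...) {
  tax_tree(ape::read.tree(newick_path),
           read.csv(taxonomy_path, stringsAsFactors = FALSE), ...)
}

#' Write a `tax_tree` to Newick + taxonomy CSV
#'
#' @param tt a [tax_tree()].
#' @param newick_path,taxonomy_path output paths.
#' @return invisibly, the newick path.
#' @export
write_tax_tree <- function(tt, newick_path, taxonomy_path) {
  ape::write.tree(tt$tree, file = newick_path)
  write.csv(tt$taxonomy, taxonomy_path, row.names = FALSE, quote = FALSE)
  invisible(newick_path)
}
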