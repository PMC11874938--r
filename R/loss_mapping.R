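# Dollo-parsimony loss mapping: given presence/absence states at the tips
# of a rooted species tree and a single gain at (or above) the root, find
# the minimum number of independent loss events and their branch
# placements.

#' Parse a rooted newick tree
#'
#' Thin wrapper around [ape::read.tree()] with positional validation of
#' the bracket structure, so malformed strings fail with the offending
#' character position.
#'
#' @param text Newick string (must end in `;`) or a file path.
#' @return An `ape::phylo` tree.
#' @export
#' @examples
#' parse_newick("((A,B),(C,D));")
parse_newick <- function(text) {
  if (!grepl("[(;]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0) {
        stop("newick parse error at position ", i,
             ": unmatched closing parenthesis")
      }
    }
  }
  if (depth != 0) {
    stop("newick parse error at position ", length(chars),
         ": ", depth, " unclosed parenthesis(es)")
  }
  if (!grepl(";\\s*$", text)) {
    stop("newick parse error at position ", length(chars),
         ": missing terminal ';'")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL)
  if (is.null(tree)) stop("newick parse error: unreadable tree")
  if (any(duplicated(tree$tip.label))) {
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

# children of each node as a list indexed by node id
node_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  kids
}

# tips descending from each node (ids), as a list
node_tipsets <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  tips <- vector("list", n_nodes)
  for (i in seq_len(ntip)) tips[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    tips[[p]] <- c(tips[[p]], tips[[ch]])
  }
  tips
}

#' Minimum independent losses under Dollo parsimony
#'
#' The gene is gained once at (or above) the root (root state fixed
#' `present`); losses are placed on branches so that every
#' `absent`-constrained tip descends from a loss and no
#' `present`-constrained tip does.  `unknown` tips are unconstrained and
#' never force a loss.  Ties between equal-count placements are broken
#' deterministically in favour of losses closer to the tips (the loss
#' branch of each all-absent component is the edge above the most recent
#' common ancestor of its absent tips).  `pseudogene` states are mapped
#' via `pseudogene_as`: `"present"` (the DNA persists; the default for
#' gene-loss counting) or `"absent"` (functional loss).
#'
#' @param tree An `ape::phylo` rooted tree.
#' @param states Tip states: named character vector or a tibble with
#'   columns `species` and `state`; states in
#'   `present`/`absent`/`pseudogene`/`unknown`.  Tips without a state are
#'   `unknown`.
#' @param gene Label carried into the report.
#' @param pseudogene_as `"present"` or `"absent"`.
#' @return A list of class `"loss_report"`: `gene`, `min_losses`,
#'   `loss_branches` (tibble: `edge`, `parent`, `child`, `clade` - the
#'   tip labels below the loss), `unique_optimum`, `infeasible`,
#'   `pseudogene_as`.
#' @export
dollo_min_losses <- function(tree, states, gene = "gene",
                             pseudogene_as = c("present", "absent")) {
  pseudogene_as <- match.arg(pseudogene_as)
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(states)) {
    states <- stats::setNames(states$state, states$species)
  }
  bad <- setdiff(names(states), tree$tip.label)
  if (length(bad) > 0) {
    stop("states given for species not in the tree: ",
         paste(bad, collapse = ", "))
  }
  ok_states <- c("present", "absent", "pseudogene", "unknown")
  if (!all(states %in% ok_states)) {
    stop("states must be one of ", paste(ok_states, collapse = "/"))
  }
  st <- stats::setNames(rep("unknown", ape::Ntip(tree)), tree$tip.label)
  st[names(states)] <- states
  st[st == "pseudogene"] <- pseudogene_as

  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  # per-node flags, computed tips-first along the postordered edges
  has_present <- logical(n_nodes)
  has_absent <- logical(n_nodes)
  has_present[seq_len(ntip)] <- st == "present"
  has_absent[seq_len(ntip)] <- st == "absent"
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    has_present[p] <- has_present[p] || has_present[ch]
    has_absent[p] <- has_absent[p] || has_absent[ch]
  }
  # a node is "lossable" when its subtree holds >= 1 absent and 0 present;
  # the root itself is never lossable because its state is fixed present
  # (the Dollo gain happens at or above the root)
  lossable <- has_absent & !has_present
  lossable[root] <- FALSE
  parent_of <- integer(n_nodes)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]

  # maximal lossable nodes: lossable and (root or parent not lossable)
  is_max <- lossable
  for (node in seq_len(n_nodes)) {
    if (node != root && lossable[node]) {
      is_max[node] <- !lossable[parent_of[node]]
    }
  }
  maximal <- which(is_max)
  tipsets <- node_tipsets(tree)
  unique_opt <- TRUE
  branches <- list()
  for (node in maximal) {
    # push the loss down to the MRCA of the constrained-absent tips
    absent_tips <- intersect(tipsets[[node]], which(st == "absent"))
    mrca <- if (length(absent_tips) == 1) {
      absent_tips
    } else {
      ape::getMRCA(tree, absent_tips)
    }
    if (mrca != node) unique_opt <- FALSE
    edge_idx <- which(tree$edge[, 2] == mrca)
    branches[[length(branches) + 1L]] <- tibble::tibble(
      edge = edge_idx,
      parent = tree$edge[edge_idx, 1],
      child = mrca,
      clade = list(sort(tree$tip.label[intersect(tipsets[[mrca]],
                                                 seq_len(ntip))])))
  }
  loss_branches <- if (length(branches) > 0) {
    dplyr::bind_rows(branches)
  } else {
    tibble::tibble(edge = integer(), parent = integer(),
                   child = integer(), clade = list())
  }
  structure(list(gene = gene, min_losses = length(maximal),
                 loss_branches = loss_branches,
                 unique_optimum = unique_opt,
                 infeasible = FALSE,
                 pseudogene_as = pseudogene_as,
                 tree = tree, states = st),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss_report> %s: %d minimum loss event(s)%s\n", x$gene,
              x$min_losses,
              if (x$unique_optimum) " (placement unique)" else
                " (alternative equal placements exist)"))
  if (nrow(x$loss_branches) > 0) {
    for (i in seq_len(nrow(x$loss_branches))) {
      cat("  loss above:",
          paste(x$loss_branches$clade[[i]], collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @rdname dollo_min_losses
#' @param x A `loss_report`.
#' @param ... Unused.
#' @export
tidy.loss_report <- function(x, ...) {
  lb <- x$loss_branches
  tibble::tibble(gene = x$gene,
                 loss = seq_len(nrow(lb)),
                 parent = lb$parent, child = lb$child,
                 clade = vapply(lb$clade, paste, character(1),
                                collapse = ","))
}

#' @rdname dollo_min_losses
#' @export
glance.loss_report <- function(x, ...) {
  tibble::tibble(gene = x$gene, min_losses = x$min_losses,
                 unique_optimum = x$unique_optimum,
                 pseudogene_as = x$pseudogene_as)
}

#' Summarize loss events across genes
#'
#' Combines per-gene Dollo loss reports computed on the same tree into a
#' loss-count table, and flags tips where a ligand gene is retained but
#' its receptor has been lost (the pattern diagnostic of a decaying
#' signalling system).
#'
#' @param reports Named list of `loss_report` objects (same tree).
#' @param ligand,receptor Optional gene names (as used in `reports`) to
#'   compare; tips where the ligand is present (or pseudogenized DNA
#'   persists) but the receptor is absent are flagged.
#' @return A list of class `"loss_summary"`: `table` (tibble: gene,
#'   min_losses, unique_optimum), `ligand_retained_receptor_lost`
#'   (character vector of tips), `reports`.
#' @export
summarize_events <- function(reports, ligand = NULL, receptor = NULL) {
  stopifnot(length(reports) > 0)
  if (is.null(names(reports))) {
    names(reports) <- vapply(reports, function(r) r$gene, character(1))
  }
  tipsets <- lapply(reports, function(r) sort(r$tree$tip.label))
  if (length(unique(tipsets)) != 1) {
    ref <- tipsets[[1]]
    for (g in names(tipsets)) {
      missing <- setdiff(ref, tipsets[[g]])
      if (length(missing) > 0) {
        stop("tip sets differ across genes; missing from ", g, ": ",
             paste(missing, collapse = ", "))
      }
    }
    stop("tip sets differ across genes")
  }
  tab <- dplyr::bind_rows(lapply(reports, glance))
  flagged <- character()
  if (!is.null(ligand) && !is.null(receptor)) {
    lig <- reports[[ligand]]$states
    rec <- reports[[receptor]]$states
    flagged <- sort(names(lig)[lig == "present" & rec == "absent"])
  }
  structure(list(table = tab,
                 ligand_retained_receptor_lost = flagged,
                 reports = reports),
            class = "loss_summary")
}

#' @export
print.loss_summary <- function(x, ...) {
  cat("<loss_summary>\n")
  print(x$table)
  if (length(x$ligand_retained_receptor_lost) > 0) {
    cat("ligand retained but receptor lost:",
        paste(x$ligand_retained_receptor_lost, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a loss report as annotated newick
#'
#' Losses are recorded as `#loss` suffixes on the labels of the nodes
#' below the loss branches.
#'
#' @param report A `loss_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_loss_newick <- function(report, path) {
  tree <- report$tree
  ntip <- ape::Ntip(tree)
  if (is.null(tree$node.label)) {
    tree$node.label <- rep("", tree$Nnode)
  }
  for (child in report$loss_branches$child) {
    if (child <= ntip) {
      tree$tip.label[child] <- paste0(tree$tip.label[child], "#loss")
    } else {
      tree$node.label[child - ntip] <-
        paste0(tree$node.label[child - ntip], "#loss")
    }
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
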