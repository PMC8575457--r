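#' Read a rooted tree from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that validates what the parsimony
#' machinery needs: a parseable tree with unique tip labels. Branch lengths
#' are kept but unused by parsimony. Polytomies are allowed.
#'
#' @param path Path to a Newick file (first tree is used).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stop("cannot parse Newick in '", path, "'")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip name(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

#' Read tip phenotype states
#'
#' Two-column CSV (tip, state) mapping each tip of a tree to its discrete
#' tuning phenotype (e.g. `C2` or `C4`).
#'
#' @param path Path to a CSV file with a header row.
#' @return Named character vector of states.
#' @export
read_tip_states <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (ncol(df) < 2L) stop("tip-state file must have two columns (tip, state)")
  if (anyDuplicated(df[[1L]])) stop("duplicate tip(s) in state file")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Minimum-change ancestral phenotype reconstruction
#'
#' Small parsimony for a discrete phenotype on a rooted tree: counts the
#' minimum number of state changes needed to explain the tip states and
#' reports, per node, the set of states occurring in at least one
#' minimum-change labeling assignment, plus one concrete optimal labeling.
#' Changes are unweighted (all state-to-state costs equal) and branch
#' lengths are ignored. Multifurcating nodes are handled by the
#' majority-state generalization of the binary intersection rule, which
#' preserves the minimum-change guarantee; the change count is invariant to
#' re-rooting.
#'
#' The reported labeling is deterministic: the root takes the
#' alphabetically first optimal state, and each descendant keeps its
#' parent's state whenever that is optimal at the node.
#'
#' @param tree A rooted [ape::phylo] tree (see [read_newick()]).
#' @param tip_states Named character vector mapping every tip label to a
#'   state.
#' @return An object of class `parsimony_fit`: list with `min_changes`,
#'   `node_state_sets` (tips named by label, internal nodes `node_<i>` in
#'   ape numbering; tip sets are singletons), `labeling` (one optimal state
#'   per node, same names), and `changes` (data.frame of edges
#'   parent/child/from/to on which the labeling changes state).
#' @export
fitch <- function(tree, tip_states) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo tree")
  tips <- tree$tip.label
  if (length(tips) < 1L) stop("tree must have at least one tip")
  absent <- setdiff(tips, names(tip_states))
  if (length(absent)) {
    stop("missing state for tip(s): ", paste(absent, collapse = ", "))
  }
  ntip <- length(tips)
  nnode <- tree$Nnode
  nall <- ntip + nnode
  kids <- split(tree$edge[, 2L], factor(tree$edge[, 1L], levels = seq_len(nall)))
  V <- vector("list", nall)   # optimal ("majority") state sets
  VU <- vector("list", nall)  # runner-up sets (one fewer child vote)
  cost <- 0L
  bottom_up <- function(node) {
    ch <- kids[[node]]
    if (length(ch) == 0L) {
      V[[node]] <<- unname(tip_states[[tips[node]]])
      VU[[node]] <<- character(0)
      return(invisible(NULL))
    }
    for (k in ch) bottom_up(k)
    votes <- table(unlist(V[ch], use.names = FALSE))
    top <- max(votes)
    V[[node]] <<- sort(names(votes)[votes == top])
    VU[[node]] <<- sort(names(votes)[votes == top - 1L])
    cost <<- cost + (length(ch) - top)
    invisible(NULL)
  }
  root <- ntip + 1L
  bottom_up(root)
  # top-down: keep the parent's state when optimal (in V, or in VU where the
  # saved parent-child change offsets the lost child vote), else first of V
  labeling <- character(nall)
  top_down <- function(node, parent_state) {
    s <- if (!is.null(parent_state) &&
             (parent_state %in% V[[node]] || parent_state %in% VU[[node]])) {
      parent_state
    } else {
      V[[node]][1L]
    }
    labeling[node] <<- s
    for (k in kids[[node]]) top_down(k, s)
    invisible(NULL)
  }
  top_down(root, NULL)
  node_names <- c(tips, paste0("node_", (ntip + 1L):nall))[seq_len(nall)]
  e <- tree$edge
  changed <- labeling[e[, 1L]] != labeling[e[, 2L]]
  changes <- data.frame(parent = node_names[e[changed, 1L]],
                        child = node_names[e[changed, 2L]],
                        from = labeling[e[changed, 1L]],
                        to = labeling[e[changed, 2L]],
                        stringsAsFactors = FALSE)
  structure(list(min_changes = as.integer(cost),
                 node_state_sets = stats::setNames(V, node_names),
                 labeling = stats::setNames(labeling, node_names),
                 changes = changes, tree = tree),
            class = "parsimony_fit")
}

#' @export
print.parsimony_fit <- function(x, ...) {
  cat(sprintf("Parsimony reconstruction: %d tips, minimum %d state change(s)\n",
              length(x$tree$tip.label), x$min_changes))
  if (nrow(x$changes)) {
    for (i in seq_len(nrow(x$changes))) {
      cat(sprintf("  %s -> %s on the branch to %s\n",
                  x$changes$from[i], x$changes$to[i], x$changes$child[i]))
    }
  }
  invisible(x)
}

#' Write a parsimony reconstruction as JSON
#'
#' @param fit A [fitch()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_parsimony <- function(fit, path) {
  if (!inherits(fit, "parsimony_fit")) stop("'fit' must be a parsimony_fit")
  jsonlite::write_json(list(min_changes = fit$min_changes,
                            node_state_sets = fit$node_state_sets,
                            labeling = as.list(fit$labeling),
                            changes = fit$changes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
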