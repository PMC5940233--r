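#' Read a rooted phylogeny from Newick
#'
#' Thin wrapper around [ape::read.tree()] that validates tip labels.
#' Newick strings are read as written: the outermost clause is taken as
#' the root, and a basal trifurcation is accepted as a (soft) multifurcating
#' root. Trees are never re-rooted here, because loss/gain polarity
#' downstream depends on the root the user supplies.
#'
#' @param path Path to a Newick file (or use `text`).
#' @param text Newick string, as an alternative to `path`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tree)) abort("unparseable Newick input")
  # ape keeps the quote characters of quoted labels; strip them
  tree$tip.label <- gsub("^['\"]|['\"]$", "", tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate tip labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  tree
}

check_tip_states <- function(tree, tip_states) {
  if (is.logical(tip_states)) {
    tip_states <- setNames(ifelse(tip_states, "present", "absent"),
                           names(tip_states))
  }
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing)) {
    abort(paste0("tips without a state: ", paste(missing, collapse = ", ")))
  }
  st <- tip_states[tree$tip.label]
  if (!all(st %in% c("present", "absent"))) {
    abort("tip states must be 'present' or 'absent'")
  }
  st
}

#' Fitch small parsimony for a binary presence/absence character
#'
#' Computes the minimum number of state changes needed to explain the tip
#' states on the tree, together with one optimal internal labeling.
#' Implemented as unit-cost Sankoff dynamic programming, which handles
#' multifurcations exactly (the generalized Fitch rule). The labeling is
#' resolved on a top-down pass preferring the parent's state where the
#' dynamic program ties (delays changes toward the tips); at the root,
#' ties resolve toward `root_preference`.
#'
#' @param tree A rooted `phylo` object.
#' @param tip_states Named vector over all tips: `"present"`/`"absent"`
#'   (logical accepted, `TRUE` = present).
#' @param root_preference State used to break a tie at the root;
#'   `"present"` by default (plastid genes are ancestrally present).
#' @return A list: `min_changes`, `internal_states` (named by ape node
#'   number), `tip_states`, `node_states` (states for all nodes, tips
#'   first in ape order).
#' @export
fitch_parsimony <- function(tree, tip_states, root_preference = "present") {
  st <- check_tip_states(tree, tip_states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  # cost[s, v] = minimum changes in the subtree of v given state s at v
  cost <- matrix(0, nrow = 2, ncol = ntip + nnode,
                 dimnames = list(c("present", "absent"), NULL))
  cost[, seq_len(ntip)] <- Inf
  for (i in seq_len(ntip)) cost[st[[i]], i] <- 0
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    child <- tr$edge[k, 2]; parent <- tr$edge[k, 1]
    cost["present", parent] <- cost["present", parent] +
      min(cost["present", child], cost["absent", child] + 1)
    cost["absent", parent] <- cost["absent", parent] +
      min(cost["absent", child], cost["present", child] + 1)
  }
  min_changes <- min(cost[, root])

  states <- character(ntip + nnode)
  states[seq_len(ntip)] <- st
  if (cost["present", root] == cost["absent", root]) {
    states[root] <- root_preference
  } else {
    states[root] <- rownames(cost)[which.min(cost[, root])]
  }
  # preorder resolution: edges of the postorder ordering, reversed
  for (k in rev(seq_len(nrow(tr$edge)))) {
    child <- tr$edge[k, 2]; parent <- tr$edge[k, 1]
    if (child <= ntip) next
    ps <- states[parent]
    other <- setdiff(c("present", "absent"), ps)
    keep <- cost[ps, child]
    switch_cost <- cost[other, child] + 1
    states[child] <- if (keep <= switch_cost) ps else other
  }
  internal <- setNames(states[(ntip + 1):(ntip + nnode)],
                       (ntip + 1):(ntip + nnode))
  list(min_changes = as.integer(min_changes), internal_states = internal,
       tip_states = st, node_states = states)
}

#' Count loss and gain events under parsimony
#'
#' Classifies each parsimony state change along the tree as a loss
#' (present -> absent) or a gain (absent -> present), reading change
#' direction off the optimal labeling from [fitch_parsimony()]. With
#' `root_state_assumption = "present"` the ancestral state is taken as
#' present wherever the parsimony score allows it — the natural polarity
#' for plastid genes, which are ancestrally encoded and lost over time.
#' With `"infer"` root ties also resolve toward present, but no preference
#' is asserted beyond the tie-break. `n_losses + n_gains` always equals
#' the parsimony minimum.
#'
#' @inheritParams fitch_parsimony
#' @param root_state_assumption `"present"` or `"infer"`.
#' @return A list: `n_losses`, `n_gains`, `min_changes`, `root_state`,
#'   plus the `fitch_parsimony()` labeling under `fit`.
#' @export
count_losses_gains <- function(tree, tip_states,
                               root_state_assumption = c("present", "infer")) {
  root_state_assumption <- match.arg(root_state_assumption)
  fit <- fitch_parsimony(tree, tip_states, root_preference = "present")
  states <- fit$node_states
  losses <- 0L; gains <- 0L
  for (k in seq_len(nrow(tree$edge))) {
    ps <- states[tree$edge[k, 1]]; cs <- states[tree$edge[k, 2]]
    if (ps == "present" && cs == "absent") losses <- losses + 1L
    if (ps == "absent" && cs == "present") gains <- gains + 1L
  }
  root <- length(tree$tip.label) + 1L
  list(n_losses = losses, n_gains = gains, min_changes = fit$min_changes,
       root_state = states[root], fit = fit)
}

#' Map one gene's presence/absence onto the phylogeny
#'
#' Convenience constructor tying a presence-matrix column to the tree:
#' runs [fitch_parsimony()] and [count_losses_gains()] and packages the
#' result as a `character_map`.
#'
#' @param tree A rooted `phylo`.
#' @param matrix A `presence_matrix` whose species are tree tips.
#' @param gene Gene symbol.
#' @inheritParams count_losses_gains
#' @return A `character_map`: list with `gene`, `tip_states`,
#'   `internal_states`, `min_changes`, `n_losses`, `n_gains`,
#'   `root_state`.
#' @export
character_map <- function(tree, matrix, gene,
                          root_state_assumption = c("present", "infer")) {
  missing <- setdiff(matrix$species_id, tree$tip.label)
  if (length(missing)) {
    abort(paste0("matrix species missing from tree: ",
                 paste(missing, collapse = ", ")))
  }
  if (!gene %in% matrix_genes(matrix)) abort(paste0("gene not in matrix: ", gene))
  tips <- setNames(matrix[[gene]], matrix$species_id)
  res <- count_losses_gains(tree, tips, root_state_assumption)
  structure(
    list(gene = gene, tip_states = res$fit$tip_states,
         internal_states = res$fit$internal_states,
         min_changes = res$min_changes, n_losses = res$n_losses,
         n_gains = res$n_gains, root_state = res$root_state, tree = tree),
    class = "character_map"
  )
}

#' @export
print.character_map <- function(x, ...) {
  cat("<character_map> ", x$gene, ": ", x$min_changes, " changes (",
      x$n_losses, " losses, ", x$n_gains, " gains), root ",
      x$root_state, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.character_map <- function(x, ...) {
  tibble(
    gene = x$gene,
    min_changes = x$min_changes,
    n_losses = x$n_losses,
    n_gains = x$n_gains,
    root_state = x$root_state
  )
}

#' Parsimony loss/gain table for several genes
#'
#' @param tree A rooted `phylo`.
#' @param matrix A `presence_matrix`.
#' @param genes Gene symbols; defaults to every matrix gene.
#' @inheritParams count_losses_gains
#' @return A tibble: `gene`, `min_changes`, `n_losses`, `n_gains`,
#'   `root_state`, `n_absent_tips`.
#' @export
map_genes <- function(tree, matrix, genes = matrix_genes(matrix),
                      root_state_assumption = c("present", "infer")) {
  root_state_assumption <- match.arg(root_state_assumption)
  purrr::map(genes, function(g) {
    cm <- character_map(tree, matrix, g, root_state_assumption)
    mutate(tidy(cm), n_absent_tips = sum(cm$tip_states == "absent"))
  }) |> bind_rows()
}

#' Annotated Newick with reconstructed internal states
#'
#' Writes the tree with internal node labels of the form
#' `gene=present|absent` so the reconstruction can be inspected in any
#' tree viewer.
#'
#' @param map A `character_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_character_map <- function(map, path) {
  tree <- map$tree
  tree$node.label <- unname(map$internal_states)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Per-clade presence fractions and habitat composition
#'
#' For every internal node, the fraction of descendant tips carrying each
#' gene, plus the habitat make-up of the clade — the tabular analogue of
#' reading clade-wide losses off a painted tree.
#'
#' @param tree A rooted `phylo`.
#' @param matrix A `presence_matrix`; species must all be tree tips.
#' @param genes Gene symbols to summarise; defaults to all.
#' @return A tibble: `node`, `n_tips`, `n_marine`, `n_freshwater`,
#'   `n_brackish`, `gene`, `presence_fraction`.
#' @export
clade_presence_summary <- function(tree, matrix,
                                   genes = matrix_genes(matrix)) {
  missing <- setdiff(matrix$species_id, tree$tip.label)
  if (length(missing)) {
    abort(paste0("matrix species missing from tree: ",
                 paste(missing, collapse = ", ")))
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; c <- tr$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  row_of <- match(tree$tip.label, matrix$species_id)
  purrr::map((ntip + 1):(ntip + nnode), function(v) {
    tips <- desc[[v]]
    rows <- row_of[tips]
    rows <- rows[!is.na(rows)]
    hab <- matrix$habitat[rows]
    purrr::map(genes, function(g) {
      tibble(
        node = v, n_tips = length(rows),
        n_marine = sum(hab == "marine"),
        n_freshwater = sum(hab == "freshwater"),
        n_brackish = sum(hab == "brackish"),
        gene = g,
        presence_fraction = mean(matrix[[g]][rows])
      )
    }) |> bind_rows()
  }) |> bind_rows()
}
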