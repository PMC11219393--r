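#' Gene birth placement by parsimony under the conversion assumption
#'
#' Places gene duplications on the species tree so that the number of birth
#' and death events is minimal under the assumption that duplicated genes
#' homogenize frequently by gene conversion: sequence similarity between
#' paralogs within a species carries no placement information, so each
#' duplication is placed once, on the stem branch of the most recent common
#' ancestor of every species bearing it, rather than as repeated
#' lineage-specific births.
#'
#' Two sources of birth evidence are used. Capture-detected duplications
#' (locus categories 1, 2 and 3) give one birth per duplicated gene, placed
#' at the MRCA of the species showing the duplicated state; category-4 loci
#' (high SNP density without high depth) contribute no births. Ancient
#' paralog families described in `families` (distinct loci that descend
#' from a single ancestral gene) give one birth per non-ancestral member,
#' placed at the MRCA of the species in which that member is present in any
#' state.
#'
#' @param matrix Status matrix: data frame with columns `species`, `gene`,
#'   `status` (`intact`, `disrupted`, `segregating`, `intact_and_disrupted`,
#'   `absent`), `category` (NA or 1-4) and optionally `shared_group`.
#' @param tree A [species_tree()].
#' @param families Optional data frame (`family`, `gene`, `ancestral`
#'   logical) declaring ancient paralog families; exactly one ancestral
#'   member per family.
#' @return Event ledger data frame: `branch_id`, `type = "birth"`, `gene`,
#'   `provenance = "inferred"`.
#' @export
place_births <- function(matrix, tree, families = NULL) {
  check_matrix(matrix, tree)
  if (is.null(matrix$category)) matrix$category <- NA_integer_
  events <- new_ledger()
  if (!is.null(families)) {
    stopifnot(all(c("family", "gene", "ancestral") %in% names(families)))
    for (i in which(!families$ancestral)) {
      g <- families$gene[i]
      bearers <- matrix$species[matrix$gene == g & matrix$status != "absent"]
      if (length(bearers) == 0)
        stop("family member '", g, "' has no bearing species")
      node <- mrca_node(tree, unique(bearers))
      events <- rbind(events, data.frame(
        branch_id = branch_of_node(tree, node), type = "birth",
        gene = g, provenance = "inferred"))
    }
  }
  dup_genes <- unique(matrix$gene[!is.na(matrix$category) &
                                  matrix$category %in% 1:3])
  for (g in dup_genes) {
    sp <- matrix$species[matrix$gene == g & !is.na(matrix$category) &
                         matrix$category %in% 1:3]
    node <- mrca_node(tree, unique(sp))
    events <- rbind(events, data.frame(
      branch_id = branch_of_node(tree, node), type = "birth",
      gene = paste0(g, "-dup"), provenance = "inferred"))
  }
  events
}

new_ledger <- function() {
  data.frame(branch_id = integer(), type = character(), gene = character(),
             provenance = character(), stringsAsFactors = FALSE)
}

check_matrix <- function(matrix, tree) {
  need <- c("species", "gene", "status")
  if (!all(need %in% names(matrix)))
    stop("status matrix needs columns: ", paste(need, collapse = ", "))
  ok <- c("intact", "disrupted", "segregating", "intact_and_disrupted",
          "absent")
  if (!all(matrix$status %in% ok))
    stop("unknown status: ", paste(setdiff(matrix$status, ok), collapse = ", "))
  unknown <- setdiff(matrix$species, tree$phy$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Death placement: losses under Dollo parsimony, disruptions by shared
#' mutation
#'
#' Each gene originates exactly once (its birth branch from the ledger, or
#' the root stem for genes with no birth event). Absences are explained by
#' the minimal set of losses: one loss on the stem of every maximal subtree
#' whose tips all lack the gene. Disruptions shared across species -- same
#' `shared_group` annotation, meaning the disruptive mutation itself was
#' checked to be identical -- are placed once at the common ancestor of the
#' group; unannotated disruptions are placed independently on each terminal
#' branch. Segregating pseudogenes generate no death events.
#'
#' @inheritParams place_births
#' @param births Event ledger containing the gene births (inferred and/or
#'   prior, e.g. from [merge_prior()]).
#' @return Event ledger of `disruption` and `loss` events (provenance
#'   `"inferred"`).
#' @export
place_deaths <- function(matrix, tree, births) {
  check_matrix(matrix, tree)
  events <- new_ledger()
  tips <- tree$phy$tip.label
  for (g in unique(matrix$gene)) {
    rows <- matrix[matrix$gene == g, ]
    b <- births[births$type == "birth" & births$gene == g, ]
    origin_node <- if (nrow(b)) node_of_branch(tree, b$branch_id[1])
                   else length(tips) + 1L
    scope <- tips_below(tree, origin_node)
    absent <- rows$species[rows$status == "absent"]
    absent <- union(absent, setdiff(scope, rows$species))
    outside <- setdiff(rows$species[rows$status != "absent"], scope)
    if (length(outside))
      stop("gene '", g, "' present above its birth branch in: ",
           paste(outside, collapse = ", "))
    if (length(absent)) {
      for (node in maximal_absent_nodes(tree, origin_node, absent))
        events <- rbind(events, data.frame(
          branch_id = branch_of_node(tree, node), type = "loss",
          gene = g, provenance = "inferred"))
    }
    disr <- rows[rows$status %in% c("disrupted", "intact_and_disrupted"), ]
    if (nrow(disr)) {
      grp <- if ("shared_group" %in% names(disr)) disr$shared_group
             else rep(NA_character_, nrow(disr))
      shared <- !is.na(grp)
      for (gname in unique(grp[shared])) {
        sp <- disr$species[shared & grp == gname]
        node <- mrca_node(tree, sp)
        events <- rbind(events, data.frame(
          branch_id = branch_of_node(tree, node), type = "disruption",
          gene = g, provenance = "inferred"))
      }
      for (sp in disr$species[!shared]) {
        node <- match(sp, tips)
        events <- rbind(events, data.frame(
          branch_id = branch_of_node(tree, node), type = "disruption",
          gene = g, provenance = "inferred"))
      }
    }
  }
  events
}

# highest nodes (within the subtree of origin_node) whose tips are all absent
maximal_absent_nodes <- function(tree, origin_node, absent) {
  out <- integer(0)
  visit <- function(node) {
    below <- tips_below(tree, node)
    if (all(below %in% absent)) {
      out <<- c(out, node)
    } else {
      for (kid in node_children(tree, node)) visit(kid)
    }
  }
  visit(origin_node)
  out
}

#' Merge prior-knowledge events into an inferred ledger
#'
#' Prior events (externally asserted placements, e.g. from earlier
#' literature or from gene trees that include database genomes) are
#' appended with their provenance retained. Same-branch birth+loss pairs
#' are permitted: they are invisible to leaf-only inference but real. A
#' prior event that conflicts with an inferred event of the same gene and
#' type (different branch) is an error unless `override = TRUE`, in which
#' case the prior placement replaces the inferred one.
#'
#' @param inferred Event ledger (e.g. from [place_births()]).
#' @param prior Data frame with `branch_id`, `type`, `gene` and optionally
#'   `note`.
#' @param override Let conflicting prior placements win.
#' @return Combined event ledger.
#' @export
merge_prior <- function(inferred, prior, override = FALSE) {
  if (is.null(prior) || nrow(prior) == 0) return(inferred)
  stopifnot(all(c("branch_id", "type", "gene") %in% names(prior)))
  out <- inferred
  for (i in seq_len(nrow(prior))) {
    p <- prior[i, ]
    clash <- which(out$gene == p$gene & out$type == p$type &
                   out$branch_id != p$branch_id)
    if (length(clash)) {
      if (!override)
        stop("prior ", p$type, " of '", p$gene, "' on branch ", p$branch_id,
             " conflicts with inferred placement on branch ",
             paste(out$branch_id[clash], collapse = ","),
             " (set override = TRUE to prefer the prior)")
      out <- out[-clash, ]
    }
    dup <- any(out$gene == p$gene & out$type == p$type &
               out$branch_id == p$branch_id)
    if (!dup)
      out <- rbind(out, data.frame(branch_id = p$branch_id, type = p$type,
                                   gene = p$gene, provenance = "prior"))
  }
  rownames(out) <- NULL
  out
}

#' Per-branch birth and death totals with category weighting
#'
#' Births each count +1 (only category 1/2/3 duplications generate birth
#' events). Deaths are weighted by what the dying unit contained:
#' disruption or loss of a single-locus, category-2 or category-4 gene
#' counts -1; disruption of a category-1/3 congregated locus counts -2 when
#' every sequence of the locus was disrupted and -1 when intact and
#' disrupted sequences coexisted; category-4 mixed loci and segregating
#' pseudogenes count 0 (and generate no events). Events for genes absent
#' from the matrix are accepted only with prior provenance (single-locus
#' weight).
#'
#' @param ledger Combined event ledger.
#' @param matrix Status matrix (see [place_births()]).
#' @param tree Optional [species_tree()]; when given, the weight of an
#'   event on a terminal branch is judged from that species' statuses only.
#' @return Data frame `branch_id`, `births`, `deaths` (absolute weighted
#'   totals), one row per branch with activity.
#' @export
count_branch_events <- function(ledger, matrix, tree = NULL) {
  if (nrow(ledger) == 0)
    return(data.frame(branch_id = integer(), births = integer(),
                      deaths = integer()))
  if (is.null(matrix$category)) matrix$category <- NA_integer_
  w <- numeric(nrow(ledger))
  is_birth <- ledger$type == "birth"
  w[is_birth] <- 1
  for (i in which(!is_birth)) {
    g <- ledger$gene[i]
    rows <- matrix[matrix$gene == g, , drop = FALSE]
    if (!is.null(tree)) {
      node <- node_of_branch(tree, ledger$branch_id[i])
      if (node <= length(tree$phy$tip.label)) {
        sp_rows <- rows[rows$species == tree$phy$tip.label[node], ,
                        drop = FALSE]
        if (nrow(sp_rows)) rows <- sp_rows
      }
    }
    if (nrow(rows) == 0) {
      if (identical(ledger$provenance[i], "inferred"))
        stop("event for unknown gene '", g, "'")
      w[i] <- 1
      next
    }
    cat_ <- suppressWarnings(max(c(rows$category, -Inf), na.rm = TRUE))
    if (is.finite(cat_) && cat_ %in% c(1, 3)) {
      mixed <- any(rows$status == "intact_and_disrupted")
      w[i] <- if (ledger$type[i] == "disruption" && !mixed) 2 else 1
    } else if (is.finite(cat_) && cat_ == 4) {
      mixed <- any(rows$status == "intact_and_disrupted")
      w[i] <- if (mixed) 0 else 1
    } else {
      w[i] <- 1
    }
  }
  agg_b <- tapply(w[is_birth], ledger$branch_id[is_birth], sum)
  agg_d <- tapply(w[!is_birth], ledger$branch_id[!is_birth], sum)
  branches <- sort(unique(ledger$branch_id))
  data.frame(
    branch_id = branches,
    births = as.integer(ifelse(is.na(agg_b[as.character(branches)]), 0,
                               agg_b[as.character(branches)])),
    deaths = as.integer(ifelse(is.na(agg_d[as.character(branches)]), 0,
                               agg_d[as.character(branches)])))
}

#' Ancestral intact-gene totals along the species tree
#'
#' Propagates an intact-gene count from above the root stem to every node:
#' each node's total is its parent's total plus births minus (weighted)
#' deaths on the connecting branch. Leaf totals include segregating
#' pseudogenes, because segregating pseudogenizations are not counted as
#' deaths.
#'
#' @param root_intact Intact-gene count above the root stem (before any
#'   root-stem events).
#' @param counts Per-branch totals from [count_branch_events()].
#' @param tree A [species_tree()].
#' @return Data frame `node`, `branch_id`, `label` (tip label or ""),
#'   `intact` total at the node.
#' @export
ancestral_counts <- function(root_intact, counts, tree) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  total <- function(node, from) {
    b <- counts[counts$branch_id == branch_of_node(tree, node), ]
    net <- if (nrow(b)) b$births - b$deaths else 0
    val <- from + net
    if (val < 0)
      stop("negative intact count at node ", node,
           ": inconsistent ledger or root count")
    val
  }
  out <- data.frame(node = integer(), branch_id = integer(),
                    label = character(), intact = numeric())
  walk <- function(node, from) {
    val <- total(node, from)
    out <<- rbind(out, data.frame(
      node = node, branch_id = branch_of_node(tree, node),
      label = if (node <= ntip) phy$tip.label[node] else "",
      intact = val))
    for (kid in node_children(tree, node)) walk(kid, val)
  }
  walk(root, root_intact)
  out
}

#' Convert a simulated true history into a countable event ledger
#'
#' Keeps the births of intact (or segregating) copies, the disruptions of
#' intact copies that fixed (a segregating outcome is not a death), and the
#' losses of copies that were still intact or segregating when lost.
#' Conversion events never change copy number and are dropped. Provenance
#' is `"truth"`.
#'
#' @param sim A `sim_history` from [simulate_history()].
#' @return An event ledger data frame.
#' @export
history_ledger <- function(sim) {
  h <- sim$history
  keep <- (h$event == "birth" & h$intact_before) |
    (h$event == "disruption" & h$intact_before & !h$segregating) |
    (h$event == "loss" & h$intact_before)
  h <- h[keep, , drop = FALSE]
  data.frame(branch_id = h$branch_id,
             type = h$event,
             gene = h$gene_id,
             provenance = "truth", stringsAsFactors = FALSE)
}

#' Construct the ancestral gene set from design databases and capture
#'
#' The ancestral gene set is defined as the genes intact in at least one of
#' the whole-genome assemblies used to design the capture probes, plus any
#' gene disrupted in every design database but found intact in at least one
#' captured individual. Gene copies with `-1`/`-2` suffixes are collapsed
#' to their base gene name before matching. Genes present in neither source
#' are excluded and reported in the `"excluded"` attribute.
#'
#' @param inventory Data frame `gene`, `database`, `status` (`intact`,
#'   `disrupted`, `truncated`, `absent`) over the design databases.
#' @param capture Data frame `gene`, `species`, `status` of capture-derived
#'   statuses (any status vocabulary containing `"intact"`; segregating
#'   pseudogenes carry an intact allele and count as intact evidence).
#' @return Sorted character vector of ancestral gene names, with attribute
#'   `"excluded"`.
#' @export
build_ancestral_set <- function(inventory, capture) {
  stopifnot(all(c("gene", "database", "status") %in% names(inventory)))
  stopifnot(all(c("gene", "status") %in% names(capture)))
  base_name <- function(g) sub("-[0-9]+$", "", g)
  inv_intact <- tapply(inventory$status == "intact",
                       base_name(inventory$gene), any)
  cap_intact <- tapply(capture$status %in% c("intact", "segregating",
                                             "segregating_pseudogene"),
                       base_name(capture$gene), any)
  genes <- names(inv_intact)
  in_db <- genes[inv_intact]
  rescued <- genes[!inv_intact &
                   !is.na(cap_intact[genes]) & cap_intact[genes]]
  excluded <- setdiff(genes, c(in_db, rescued))
  out <- sort(unique(c(in_db, rescued)))
  attr(out, "excluded") <- excluded
  out
}
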