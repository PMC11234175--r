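#' @include network-schema.R
NULL

#' Read / write an expression table
#'
#' Tab-separated text with header `gene_id  time_h  value  replicate`:
#' replicated gene-by-time measurements of mRNA (or protein) abundance.
#'
#' @param path file path
#' @return data.frame with columns `gene_id`, `time_h`, `value`, `replicate`
#' @export
readExpressionTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_expression_table(tab)
  tab
}

#' @rdname readExpressionTable
#' @param expr the expression table to write
#' @export
writeExpressionTable <- function(expr, path) {
  .check_expression_table(expr)
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_expression_table <- function(expr) {
  need <- c("gene_id", "time_h", "value", "replicate")
  miss <- setdiff(need, names(expr))
  if (length(miss))
    stop("expression table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(expr) == 0) stop("expression table is empty", call. = FALSE)
  if (any(expr$value < 0)) stop("expression values must be >= 0", call. = FALSE)
  if (any(expr$time_h < 0)) stop("expression times must be >= 0", call. = FALSE)
  invisible(expr)
}

#' Genes expressed at baseline
#'
#' A gene counts as expressed when its replicate-mean value at the baseline
#' (earliest measured) time exceeds `threshold`. This is the gate used to
#' drop enzymes from the canonical network when individualizing it to a cell
#' type.
#'
#' @param expr expression table (`gene_id`, `time_h`, `value`, `replicate`)
#' @param threshold non-negative expression cutoff; the default 0 keeps any
#'   gene with positive baseline signal.
#' @return character vector of expressed gene ids (sorted)
#' @export
expressedGenes <- function(expr, threshold = 0) {
  .check_expression_table(expr)
  stopifnot(threshold >= 0)
  t0 <- min(expr$time_h)
  base <- expr[expr$time_h == t0, , drop = FALSE]
  means <- tapply(base$value, base$gene_id, mean)
  sort(names(means)[means > threshold])
}

#' Metabolites producible from the seed precursors
#'
#' Least fixpoint of substrate-flow reachability: starting from the seed
#' metabolites, a reaction fires when all of its metabolite substrates are
#' already producible, every protein it needs (enzyme or protein substrate)
#' is present in the network, and firing adds its metabolite products.
#' Proteins and mRNAs are not part of the returned set; their presence in the
#' network is what makes them available (they are made by translation, which
#' lies outside the metabolic closure).
#'
#' @param net a [ReactionNetwork-class]
#' @param seeds character vector of seed species keys; defaults to the
#'   network's seed set.
#' @return character vector (sorted) of producible metabolite species keys
#' @export
producibleMetabolites <- function(net, seeds = seedMetabolites(net)) {
  sp <- net@species
  keys <- speciesKey(sp$id, sp$compartment)
  unknown <- setdiff(seeds, keys)
  if (length(unknown))
    stop("unknown seed id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  is_metabolite <- stats::setNames(sp$role == "metabolite", keys)

  producible <- stats::setNames(logical(length(keys)), keys)
  producible[seeds] <- TRUE
  repeat {
    changed <- FALSE
    for (r in net@reactions) {
      if (!is.na(r@enzyme) && !(r@enzyme %in% keys)) next
      subs <- names(r@substrates)
      met_subs <- subs[is_metabolite[subs] %in% TRUE]
      prot_subs <- setdiff(subs, met_subs)
      if (!all(prot_subs %in% keys)) next
      if (!all(producible[met_subs])) next
      prods <- names(r@products)
      met_prods <- prods[is_metabolite[prods] %in% TRUE]
      new_ones <- met_prods[!producible[met_prods]]
      if (length(new_ones)) {
        producible[new_ones] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(names(producible)[producible])
}

#' Prune a canonical network to a cell type
#'
#' Individualizes the canonical network against a baseline expression table:
#' (1) every Michaelis-Menten reaction whose enzyme gene is not expressed is
#' removed, together with the unexpressed protein species and their
#' transport/translocation reactions; (2) reactions with a metabolite
#' substrate that is no longer producible from the seeds are removed,
#' iterating to a fixpoint; (3) species participating in no remaining
#' reaction and not in the seed set are dropped. Non-enzymatic reactions are
#' never removed for expression reasons, only for unproducible substrates.
#'
#' If pruning disconnects everything from the seeds a warning (not an error)
#' is raised and the empty model returned.
#'
#' @param net canonical [ReactionNetwork-class]; every Michaelis-Menten
#'   enzyme must carry a gene id.
#' @param expr baseline expression table (protein if available, else mRNA).
#' @param threshold expression cutoff passed to [expressedGenes()].
#' @return list with elements `network` (the pruned
#'   [ReactionNetwork-class]) and `report` (list with `removed_enzymes`,
#'   `removed_reactions` data.frame of id + reason, `removed_species`,
#'   `iterations`).
#' @export
pruneNetwork <- function(net, expr, threshold = 0) {
  .assert_valid(net, "network (before pruning)")
  expressed <- expressedGenes(expr, threshold)
  sp <- net@species
  keys <- speciesKey(sp$id, sp$compartment)

  ## genes observable in the table; genes absent from the table entirely are
  ## treated as unexpressed, like a zero measurement
  gene_of <- stats::setNames(sp$gene, keys)
  unexpressed_prot <- keys[sp$role == "protein" & !(sp$gene %in% expressed)]

  removed <- list()
  keep <- net@reactions
  ## step 1: expression gate
  gate <- vapply(keep, function(r) {
    if (r@rateLaw@form == "michaelis_menten" &&
        r@enzyme %in% unexpressed_prot) return(TRUE)
    ## transports/translocations of an unexpressed protein go with it
    any(c(names(r@substrates), names(r@products)) %in% unexpressed_prot)
  }, logical(1))
  for (r in keep[gate])
    removed[[r@id]] <- "enzyme_unexpressed"
  keep <- keep[!gate]

  net2 <- net
  net2@reactions <- keep
  net2@species <- sp[!(keys %in% unexpressed_prot), , drop = FALSE]

  ## step 2: reachability fixpoint
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    prod_ok <- tryCatch(producibleMetabolites(net2),
                        error = function(e) character(0))
    sp2 <- net2@species
    keys2 <- speciesKey(sp2$id, sp2$compartment)
    is_met <- stats::setNames(sp2$role == "metabolite", keys2)
    drop <- vapply(net2@reactions, function(r) {
      ms <- names(r@substrates)[is_met[names(r@substrates)] %in% TRUE]
      !all(ms %in% prod_ok)
    }, logical(1))
    if (!any(drop)) break
    for (r in net2@reactions[drop])
      removed[[r@id]] <- "substrate_unproducible"
    net2@reactions <- net2@reactions[!drop]
  }

  ## step 3: drop non-protein species with no remaining participation,
  ## outside the seeds. Expressed proteins are kept even when currently
  ## orphaned: translation/degradation reactions and translocation events
  ## attach to them downstream of pruning.
  sp2 <- net2@species
  keys2 <- speciesKey(sp2$id, sp2$compartment)
  used <- unique(unlist(lapply(net2@reactions, function(r)
    c(names(r@substrates), names(r@products),
      if (!is.na(r@enzyme)) r@enzyme))))
  orphan <- setdiff(keys2[sp2$role != "protein"], c(used, net@seeds))
  removed_species <- sort(c(intersect(unexpressed_prot, keys), orphan))
  net2@species <- sp2[!(keys2 %in% orphan), , drop = FALSE]
  net2@seeds <- intersect(net@seeds, speciesKey(net2@species$id, net2@species$compartment))

  if (length(net2@reactions) == 0)
    warning("pruning removed all reactions: the cell-type model is empty",
            call. = FALSE)

  rem_ids <- sort(names(removed))
  report <- list(
    removed_enzymes = sort(unique(stats::na.omit(gene_of[unexpressed_prot]))),
    removed_reactions = data.frame(
      id = rem_ids,
      reason = vapply(rem_ids, function(i) removed[[i]], character(1)),
      row.names = NULL, stringsAsFactors = FALSE),
    removed_species = removed_species,
    iterations = iterations
  )
  list(network = net2, report = report)
}

#' Serialize a prune report
#' @param report the `report` element returned by [pruneNetwork()]
#' @param path optional output path
#' @return JSON text, invisibly when written to `path`
#' @export
writePruneReport <- function(report, path = NULL) {
  txt <- .to_json(list(
    removed_enzymes = as.list(report$removed_enzymes),
    removed_reactions = lapply(seq_len(nrow(report$removed_reactions)),
      function(i) list(id = report$removed_reactions$id[i],
                       reason = report$removed_reactions$reason[i])),
    removed_species = as.list(report$removed_species),
    iterations = report$iterations))
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
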