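#' Annotate entities against the pathway map
#'
#' Partitions a set of entities (transcript hits keyed by reference
#' accession, or reference compounds) into annotated and unannotated against
#' the KEGG-style pathway map, and collects the pathways they touch.
#'
#' @param entity_ids Character vector of entity ids (may be empty).
#' @param kind \code{"transcript_hit"} or \code{"compound"}.
#' @param pathway_map Pathway map data frame
#'   (\code{\link{read_pathway_map}}).
#' @return Object of class \code{pathway_annotation}: list with
#'   \code{kind}, \code{annotated}, \code{unannotated}, \code{pathways}
#'   (sorted union), \code{pathway_entities} (named list) and
#'   \code{coverage} (fraction annotated; \code{NA} for empty input).
#' @export
annotate_entities <- function(entity_ids, kind = c("transcript_hit", "compound"),
                              pathway_map) {
  kind <- match.arg(kind)
  validate_pathway_map(pathway_map)
  ids <- unique(entity_ids)
  rows <- pathway_map[pathway_map$entity_kind == kind &
                        pathway_map$entity_id %in% ids, , drop = FALSE]
  annotated <- sort(unique(rows$entity_id))
  structure(list(
    kind = kind,
    annotated = annotated,
    unannotated = sort(setdiff(ids, annotated)),
    pathways = sort(unique(rows$pathway_id)),
    pathway_entities = lapply(split(rows$entity_id, rows$pathway_id),
                              function(e) sort(unique(e))),
    entity_pathways = lapply(split(rows$pathway_id, rows$entity_id),
                             function(p) sort(unique(p))),
    coverage = if (length(ids) == 0L) NA_real_
               else length(annotated) / length(ids)
  ), class = "pathway_annotation")
}

#' @export
print.pathway_annotation <- function(x, ...) {
  cat("Pathway annotation (", x$kind, "): ", length(x$annotated),
      " annotated / ", length(x$annotated) + length(x$unannotated),
      " entities", sep = "")
  if (!is.na(x$coverage)) cat(sprintf(" (%.1f%%)", 100 * x$coverage))
  cat("; ", length(x$pathways), " pathways\n", sep = "")
  invisible(x)
}

#' Shared-pathway core of the integrated dataset
#'
#' The core is the intersection of the pathway sets inferred from the
#' transcriptome annotations and from the HCS co-clustered reference
#' compounds; the union is reported alongside. Entities are restricted to
#' those touching at least one shared pathway.
#'
#' @param transcript_annot,compound_annot \code{pathway_annotation} objects
#'   for the two entity kinds.
#' @param pathway_map Optional pathway map used to resolve the target
#'   systems of the shared pathways.
#' @return Object of class \code{shared_core}: list with \code{shared},
#'   \code{union}, \code{transcripts}, \code{compounds}, \code{systems}.
#' @export
shared_core <- function(transcript_annot, compound_annot, pathway_map = NULL) {
  tp <- transcript_annot$pathways
  cp <- compound_annot$pathways
  shared <- sort(intersect(tp, cp))
  if (length(shared) == 0L)
    warning("no pathways shared between transcript and compound annotations")
  touch <- function(annot)
    sort(unique(as.character(unlist(annot$pathway_entities[shared],
                                    use.names = FALSE))))
  systems <- character(0)
  if (!is.null(pathway_map) && length(shared) > 0L) {
    rows <- pathway_map[pathway_map$pathway_id %in% shared, , drop = FALSE]
    systems <- sort(unique(rows$system))
  }
  structure(list(shared = shared,
                 union = sort(union(tp, cp)),
                 transcripts = touch(transcript_annot),
                 compounds = touch(compound_annot),
                 systems = systems),
            class = "shared_core")
}

#' @export
print.shared_core <- function(x, ...) {
  cat("Shared-pathway core: ", length(x$shared), " shared of ",
      length(x$union), " union pathways; ",
      length(x$transcripts), " transcripts, ",
      length(x$compounds), " compounds", sep = "")
  if (length(x$systems) > 0L)
    cat("; ", length(x$systems), " target systems", sep = "")
  cat("\n")
  invisible(x)
}

#' Build the tripartite integrated network
#'
#' Nodes are the core transcript hits and compounds, the shared pathways and
#' their target systems; edges link each entity to the shared pathways it
#' annotates to (\code{relation = "targets"}) and each pathway to its single
#' system (\code{relation = "part_of"}). Entities never connect to
#' non-shared pathways.
#'
#' @param core A \code{shared_core}.
#' @param pathway_map Pathway map providing the incidences and systems; a
#'   shared pathway missing a system entry is an error naming the pathway.
#' @return An \code{igraph} object with vertex attributes \code{kind},
#'   \code{label}, \code{system} and edge attribute \code{relation},
#'   vertices in canonical (kind, name) order.
#' @export
build_network <- function(core, pathway_map) {
  if (length(core$shared) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  rows <- pathway_map[pathway_map$pathway_id %in% core$shared, , drop = FALSE]
  sys_of <- tapply(rows$system, rows$pathway_id, function(s) unique(s)[1L])
  no_sys <- core$shared[!core$shared %in% names(sys_of) |
                          is.na(sys_of[core$shared])]
  if (length(no_sys) > 0L)
    stop("pathway(s) without a target system in the map: ",
         paste(no_sys, collapse = ", "))
  name_of <- tapply(rows$pathway_name, rows$pathway_id,
                    function(s) unique(s)[1L])

  ent_rows <- rows[(rows$entity_kind == "transcript_hit" &
                      rows$entity_id %in% core$transcripts) |
                   (rows$entity_kind == "compound" &
                      rows$entity_id %in% core$compounds), , drop = FALSE]

  vertices <- rbind(
    data.frame(name = core$transcripts, kind = "transcript_hit",
               label = core$transcripts, system = "",
               stringsAsFactors = FALSE),
    data.frame(name = core$compounds, kind = "compound",
               label = core$compounds, system = "",
               stringsAsFactors = FALSE),
    data.frame(name = core$shared, kind = "pathway",
               label = as.character(name_of[core$shared]),
               system = as.character(sys_of[core$shared]),
               stringsAsFactors = FALSE),
    data.frame(name = sort(unique(as.character(sys_of[core$shared]))),
               kind = "system",
               label = sort(unique(as.character(sys_of[core$shared]))),
               system = "", stringsAsFactors = FALSE)
  )
  vertices <- vertices[order(match(vertices$kind, kind_levels),
                             vertices$name), , drop = FALSE]

  e1 <- data.frame(from = ent_rows$entity_id, to = ent_rows$pathway_id,
                   relation = "targets", stringsAsFactors = FALSE)
  e1 <- e1[order(e1$from, e1$to), , drop = FALSE]
  e1 <- e1[!duplicated(e1[c("from", "to")]), , drop = FALSE]
  e2 <- data.frame(from = core$shared,
                   to = as.character(sys_of[core$shared]),
                   relation = "part_of", stringsAsFactors = FALSE)
  edges <- rbind(e1, e2)

  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Extract a symptom-specific subnetwork
#'
#' A symptom cluster is the subnetwork induced by a curated list of pathways
#' with putative roles in one envenomation outcome (such as pain): the
#' listed pathways, every entity adjacent to them and the systems they
#' belong to. Unknown pathway ids are reported and skipped.
#'
#' @param network Integrated network from \code{\link{build_network}}.
#' @param symptom_name Label for the cluster.
#' @param pathway_ids Character vector of pathway ids defining the symptom.
#' @return Object of class \code{symptom_cluster}: list with
#'   \code{symptom}, \code{pathways}, \code{transcripts}, \code{compounds},
#'   \code{systems}, \code{counts} and the induced \code{subnetwork}.
#' @export
extract_symptom_cluster <- function(network, symptom_name, pathway_ids) {
  if (igraph::vcount(network) == 0L) {
    known <- character(0)
  } else {
    pw_nodes <- igraph::V(network)$name[igraph::V(network)$kind == "pathway"]
    known <- intersect(pathway_ids, pw_nodes)
    unknown <- setdiff(pathway_ids, pw_nodes)
    if (length(unknown) > 0L)
      warning("unknown pathway id(s) skipped: ",
              paste(sort(unknown), collapse = ", "))
  }
  if (length(known) == 0L) {
    return(structure(list(symptom = symptom_name, pathways = character(0),
                          transcripts = character(0),
                          compounds = character(0), systems = character(0),
                          counts = c(pathways = 0L, transcripts = 0L,
                                     compounds = 0L, systems = 0L),
                          subnetwork = igraph::make_empty_graph(directed = FALSE)),
                     class = "symptom_cluster"))
  }
  vmatch <- match(known, igraph::V(network)$name)
  nb <- unique(unlist(igraph::adjacent_vertices(network, vmatch)))
  nb_names <- igraph::V(network)$name[nb]
  nb_kind <- igraph::V(network)$kind[nb]
  transcripts <- sort(nb_names[nb_kind == "transcript_hit"])
  compounds <- sort(nb_names[nb_kind == "compound"])
  systems <- sort(nb_names[nb_kind == "system"])
  keep <- c(sort(known), transcripts, compounds, systems)
  sub <- igraph::induced_subgraph(network,
                                  match(keep, igraph::V(network)$name))
  structure(list(symptom = symptom_name, pathways = sort(known),
                 transcripts = transcripts, compounds = compounds,
                 systems = systems,
                 counts = c(pathways = length(known),
                            transcripts = length(transcripts),
                            compounds = length(compounds),
                            systems = length(systems)),
                 subnetwork = sub),
            class = "symptom_cluster")
}

#' @export
print.symptom_cluster <- function(x, ...) {
  cat("Symptom cluster '", x$symptom, "': ", x$counts[["pathways"]],
      " pathways, ", x$counts[["transcripts"]], " transcripts, ",
      x$counts[["compounds"]], " compounds, ", x$counts[["systems"]],
      " systems\n", sep = "")
  invisible(x)
}
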