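#' Export a provenance graph to GraphML, DOT or JSON
#'
#' Nodes carry the panel id plus its document and figure back-pointers
#' (parsed from the id or taken from the graph's node metadata); edges carry
#' their content-sharing weight. The JSON form round-trips losslessly through
#' [importGraphJSON()].
#'
#' @param graph a \linkS4class{ProvenanceGraph}.
#' @param path output file.
#' @param format "json", "graphml" or "dot"; any other value is a usage
#'   error.
#' @return the path, invisibly.
#' @export
exportGraph <- function(graph, path, format = c("json", "graphml", "dot")) {
  if (!is.character(format) || !format[1] %in% c("json", "graphml", "dot"))
    stop("unknown export format: ", format[1],
         " (use \"json\", \"graphml\" or \"dot\")")
  format <- format[1]
  nodes <- sort(graph@nodes)
  nodeRecord <- function(id) {
    parts <- strsplit(id, "/", fixed = TRUE)[[1]]
    list(id = id,
         doc_id = parts[1],
         figure_id = if (length(parts) >= 2)
           paste(parts[1:2], collapse = "/") else parts[1])
  }
  edges <- graph@edges
  if (nrow(edges) > 0) {
    a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
    edges <- data.frame(from = a, to = b, weight = edges$weight,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  }
  switch(format,
    json = {
      obj <- list(level = graph@level, is_tree = graph@isTree,
                  nodes = lapply(nodes, nodeRecord),
                  edges = lapply(seq_len(nrow(edges)), function(i)
                    list(from = edges$from[i], to = edges$to[i],
                         weight = edges$weight[i])))
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE), path)
    },
    graphml = {
      esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
      lines <- c(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
        "  <key id=\"d0\" for=\"node\" attr.name=\"doc_id\" attr.type=\"string\"/>",
        "  <key id=\"d1\" for=\"node\" attr.name=\"figure_id\" attr.type=\"string\"/>",
        "  <key id=\"w\" for=\"edge\" attr.name=\"weight\" attr.type=\"double\"/>",
        sprintf("  <graph id=\"provenance\" edgedefault=\"undirected\">"))
      for (id in nodes) {
        rec <- nodeRecord(id)
        lines <- c(lines, sprintf(
          "    <node id=\"%s\"><data key=\"d0\">%s</data><data key=\"d1\">%s</data></node>",
          esc(id), esc(rec$doc_id), esc(rec$figure_id)))
      }
      for (i in seq_len(nrow(edges)))
        lines <- c(lines, sprintf(
          "    <edge source=\"%s\" target=\"%s\"><data key=\"w\">%s</data></edge>",
          esc(edges$from[i]), esc(edges$to[i]),
          format(edges$weight[i], digits = 15)))
      lines <- c(lines, "  </graph>", "</graphml>")
      writeLines(lines, path)
    },
    dot = {
      lines <- c("graph provenance {")
      for (id in nodes)
        lines <- c(lines, sprintf("  \"%s\";", id))
      for (i in seq_len(nrow(edges)))
        lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [weight=%s];",
                                  edges$from[i], edges$to[i],
                                  format(edges$weight[i], digits = 15)))
      lines <- c(lines, "}")
      writeLines(lines, path)
    })
  invisible(path)
}

#' @rdname exportGraph
#' @param path JSON file written by [exportGraph()].
#' @export
importGraphJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- sort(vapply(obj$nodes, function(n) n$id, character(1)))
  edges <- if (length(obj$edges) == 0)
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  else data.frame(
    from = vapply(obj$edges, function(e) e$from, character(1)),
    to = vapply(obj$edges, function(e) e$to, character(1)),
    weight = vapply(obj$edges, function(e) as.numeric(e$weight), numeric(1)),
    stringsAsFactors = FALSE)
  new("ProvenanceGraph", nodes = nodes, edges = edges,
      nodeMeta = data.frame(), isTree = isTRUE(obj$is_tree),
      level = obj$level %||% "image")
}
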