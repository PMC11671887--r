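#' Declare a multi-indicator composite construct
#'
#' A composite construct summarises a block of collinear indicators (the
#' intensity-spectrum bins) as a higher-order latent score built from `k`
#' supervised PLS components.
#'
#' @param indicators Character vector of indicator column names.
#' @param k Number of underlying PLS components (default 2).
#' @return An object of class `fitpath_construct`.
#' @export
composite <- function(indicators, k = 2) {
  stopifnot(is.character(indicators), length(indicators) >= 1, k >= 1)
  structure(list(indicators = indicators, k = as.integer(k), type = "composite"),
            class = "fitpath_construct")
}

as_construct <- function(x, name) {
  if (inherits(x, "fitpath_construct")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(structure(list(indicators = x, k = 1L, type = "single"),
                     class = "fitpath_construct"))
  }
  abort(sprintf(
    "Construct `%s` must be a single indicator name or a composite().", name
  ))
}

parse_edges <- function(txt, what) {
  m <- regmatches(txt, regexec("^\\s*(\\S+)\\s*->\\s*(\\S+)\\s*$", txt))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(sprintf("Cannot parse %s: %s", what, paste(txt[bad], collapse = "; ")))
  }
  tibble(from = vapply(m, `[`, "", 2), to = vapply(m, `[`, "", 3))
}

#' Specify a PLS path model
#'
#' A structural model over named constructs.  Constructs are either a single
#' indicator column (given as its name) or a [composite()] over an indicator
#' block.  Structural paths are written `"A -> B"`; interaction (moderation)
#' terms are written `"A:B -> C"` and enter as the re-standardised
#' element-wise product of the two construct scores (two-stage
#' product-of-scores approach).
#'
#' @param ... Named constructs, e.g. `PA = composite(bins), CRF = "crf"`.
#' @param paths Character vector of `"from -> to"` structural paths; the
#'   implied directed graph must be acyclic.
#' @param interactions Optional character vector of `"A:B -> C"` terms.
#' @return An object of class `pls_model_spec`.
#' @examples
#' m <- pls_model(
#'   PA = composite(c("b1", "b2", "b3")), CRF = "crf", CS = "cs",
#'   paths = c("PA -> CRF", "CRF -> CS", "PA -> CS")
#' )
#' @export
pls_model <- function(..., paths, interactions = NULL) {
  constructs <- list(...)
  if (is.null(names(constructs)) || any(!nzchar(names(constructs)))) {
    abort("Every construct must be named.")
  }
  constructs <- imap(constructs, as_construct)
  edges <- parse_edges(paths, "paths")
  inter <- NULL
  if (!is.null(interactions)) {
    ie <- parse_edges(interactions, "interactions")
    parts <- strsplit(ie$from, ":", fixed = TRUE)
    if (any(vapply(parts, length, integer(1)) != 2L)) {
      abort("Interactions must name exactly two constructs, as \"A:B -> C\".")
    }
    inter <- tibble(
      a = vapply(parts, `[`, "", 1), b = vapply(parts, `[`, "", 2),
      to = ie$to, name = gsub(":", "_x_", ie$from, fixed = TRUE)
    )
  }
  node_names <- c(names(constructs), inter$name)
  ref <- unique(c(edges$from, edges$to, inter$a, inter$b, inter$to))
  unknown <- setdiff(ref, node_names)
  if (length(unknown)) {
    abort(paste0("Paths reference unknown construct(s): ",
                 paste(unknown, collapse = ", ")))
  }
  all_edges <- bind_rows(edges,
                         if (!is.null(inter)) tibble(from = inter$name, to = inter$to))
  order <- topo_sort(node_names, all_edges)   # errors on cycles
  structure(
    list(constructs = constructs, paths = edges, interactions = inter,
         order = order),
    class = "pls_model_spec"
  )
}

topo_sort <- function(nodes, edges) {
  indeg <- setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  queue <- nodes[indeg == 0L]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    kids <- edges$to[edges$from == v]
    for (w in kids) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nodes)) abort("Structural graph must be acyclic.")
  out
}

#' @export
print.pls_model_spec <- function(x, ...) {
  cat("PLS path model\n")
  for (nm in names(x$constructs)) {
    con <- x$constructs[[nm]]
    if (con$type == "composite") {
      cat(sprintf("  %s: composite of %d indicators (k = %d)\n",
                  nm, length(con$indicators), con$k))
    } else {
      cat(sprintf("  %s: indicator `%s`\n", nm, con$indicators))
    }
  }
  cat("  paths:", paste(x$paths$from, "->", x$paths$to, collapse = "; "), "\n")
  if (!is.null(x$interactions)) {
    cat("  interactions:",
        paste0(x$interactions$a, ":", x$interactions$b, " -> ",
               x$interactions$to, collapse = "; "), "\n")
  }
  invisible(x)
}

# the ultimate outcome used as the stage-1 PLS target: the unique sink
# construct (no outgoing structural path) reachable from `from`.
model_sink <- function(model, from) {
  edges <- model$paths
  if (!is.null(model$interactions)) {
    edges <- bind_rows(edges, tibble(from = model$interactions$name,
                                     to = model$interactions$to))
  }
  reach <- from
  repeat {
    nxt <- unique(c(reach, edges$to[edges$from %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  sinks <- setdiff(reach, edges$from)
  sinks <- setdiff(sinks, from)
  if (length(sinks) != 1L) {
    abort(sprintf(
      "Cannot identify a unique outcome construct downstream of `%s`.", from
    ))
  }
  sinks
}

#' Serialise / restore a model specification
#'
#' @param model A [pls_model()] specification.
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `write_model` invisibly returns `path`; `read_model` returns the
#'   restored `pls_model_spec`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model_spec"))
  obj <- list(
    constructs = map(model$constructs, function(con) {
      list(indicators = as.list(con$indicators), k = con$k, type = con$type)
    }),
    paths = paste(model$paths$from, "->", model$paths$to),
    interactions = if (!is.null(model$interactions)) {
      paste0(model$interactions$a, ":", model$interactions$b, " -> ",
             model$interactions$to)
    }
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  constructs <- map(obj$constructs, function(con) {
    ind <- unlist(con$indicators)
    if (identical(con$type, "composite")) composite(ind, k = con$k) else ind
  })
  args <- c(constructs, list(paths = unlist(obj$paths)))
  if (!is.null(obj$interactions) && length(obj$interactions)) {
    args$interactions <- unlist(obj$interactions)
  }
  do.call(pls_model, args)
}
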