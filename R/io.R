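# Readers and writers for the formats the framework touches: OBO ontologies,
# GAF / two-column annotation tables, whitespace edge lists and complex
# membership tables. Gene and term identifiers are opaque case-sensitive
# strings; no identifier mapping is attempted.

#' Construct a GO DAG object
#'
#' A `go_dag` holds a set of GO term identifiers and the child-to-parent
#' links between them, each link tagged with its relation (`is_a` or
#' `part_of`). Only these two relation types participate in semantic
#' similarity, so only they are representable.
#'
#' @param terms Character vector of term identifiers.
#' @param edges Data frame with columns `child`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`). May have zero rows.
#' @param namespace Optional named character vector giving the namespace of
#'   each term (e.g. `"biological_process"`).
#' @return An object of class `go_dag` with elements `terms`, `edges`,
#'   `namespace`.
#' @examples
#' dag <- go_dag(c("GO:1", "GO:2"),
#'               data.frame(child = "GO:1", parent = "GO:2", relation = "is_a"))
#' @export
go_dag <- function(terms, edges = NULL, namespace = NULL) {
  terms <- unique(as.character(terms))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = as.character(edges$child),
                        parent = as.character(edges$parent),
                        relation = as.character(edges$relation),
                        stringsAsFactors = FALSE)
  }
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel))
    stop("unsupported relation(s): ", paste(bad_rel, collapse = ", "))
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(unknown))
    stop("edge endpoint(s) not in term set: ", paste(utils::head(unknown, 5), collapse = ", "))
  edges <- unique(edges)
  dag <- structure(list(terms = terms, edges = edges, namespace = namespace),
                   class = "go_dag")
  if (nrow(edges) > 0L && !is_acyclic(dag))
    stop("term relations contain a cycle; not a DAG")
  dag
}

is_acyclic <- function(dag) {
  g <- igraph::graph_from_data_frame(dag$edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = dag$terms))
  igraph::is_dag(g)
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG:", length(x$terms), "terms,", nrow(x$edges), "edges (",
      sum(x$edges$relation == "is_a"), "is_a /",
      sum(x$edges$relation == "part_of"), "part_of )\n")
  invisible(x)
}

#' Read an OBO ontology file
#'
#' Parses the OBO flat-file format, keeping `is_a` and `relationship: part_of`
#' links only; other relationship types (e.g. `regulates`) are ignored because
#' the semantic-similarity weights are defined for is-a and part-of edges
#' alone. Obsolete terms are excluded together with any edge touching them.
#'
#' @param path Path to an OBO file.
#' @return A [go_dag()] object.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character()
  ns <- character()
  child <- character(); parent <- character(); relation <- character()
  cur_id <- NA_character_
  cur_ns <- NA_character_
  cur_obsolete <- FALSE
  cur_parents <- list()
  in_term <- FALSE
  obsolete_ids <- character()

  flush_term <- function() {
    if (is.na(cur_id)) return()
    if (cur_obsolete) {
      obsolete_ids <<- c(obsolete_ids, cur_id)
    } else {
      terms <<- c(terms, cur_id)
      ns <<- c(ns, cur_ns)
      for (p in cur_parents) {
        child <<- c(child, cur_id)
        parent <<- c(parent, p[[1L]])
        relation <<- c(relation, p[[2L]])
      }
    }
  }

  for (i in seq_along(lines)) {
    line <- sub("!.*$", "", lines[[i]])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush_term()
      cur_id <- NA_character_; cur_ns <- NA_character_
      cur_obsolete <- FALSE; cur_parents <- list()
      in_term <- identical(line, "[Term]")
      next
    }
    if (!in_term) next
    if (!grepl(":", line, fixed = TRUE))
      stop("malformed OBO stanza at line ", i, ": ", lines[[i]])
    key <- sub(":.*$", "", line)
    val <- trimws(sub("^[^:]+:", "", line))
    if (key == "id") {
      cur_id <- val
    } else if (key == "namespace") {
      cur_ns <- val
    } else if (key == "is_obsolete") {
      cur_obsolete <- identical(val, "true")
    } else if (key == "is_a") {
      cur_parents <- c(cur_parents, list(list(sub("\\s.*$", "", val), "is_a")))
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] == "part_of")
        cur_parents <- c(cur_parents, list(list(parts[[2L]], "part_of")))
    }
  }
  flush_term()

  edges <- data.frame(child = child, parent = parent, relation = relation,
                      stringsAsFactors = FALSE)
  # drop edges to obsolete or undeclared parents
  keep <- edges$parent %in% terms
  if (any(!keep))
    message("read_obo: dropped ", sum(!keep), " edge(s) to obsolete/unknown terms")
  go_dag(terms, edges[keep, , drop = FALSE],
         namespace = stats::setNames(ns, terms))
}

#' Construct an annotation set
#'
#' Maps gene identifiers to sets of GO term identifiers. Two kinds are
#' distinguished: `"target"` (a gene's own annotations) and `"homolog"`
#' (annotations transferred from homologs, supplied precomputed).
#'
#' @param annotations Named list: gene id -> character vector of term ids.
#' @param kind `"target"` or `"homolog"`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(annotations, kind = c("target", "homolog")) {
  kind <- match.arg(kind)
  annotations <- lapply(annotations, function(x) sort(unique(as.character(x))))
  structure(list(annotations = annotations, kind = kind),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("AnnotationSet (", x$kind, "): ", length(x$annotations), " genes, ",
      length(unique(unlist(x$annotations))), " distinct terms\n", sep = "")
  invisible(x)
}

#' Annotations of a gene
#'
#' @param ann An [annotation_set()].
#' @param gene Gene identifier.
#' @return Character vector of term ids (empty if the gene is unannotated).
#' @export
gene_terms <- function(ann, gene) {
  x <- ann$annotations[[gene]]
  if (is.null(x)) character() else x
}

#' Read gene -> GO annotations
#'
#' Accepts either GAF 2.x (17 tab-separated columns, `!` comment lines;
#' gene = DB Object Symbol, column 3; rows whose qualifier contains `NOT`
#' are skipped) or a plain two-column `gene<TAB>term` table.
#'
#' @param path Path to the annotation file.
#' @param kind `"target"` or `"homolog"`.
#' @param dag Optional [go_dag()]; terms not present in it are dropped with a
#'   message giving the count.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, kind = c("target", "homolog"), dag = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty annotation file: ", path)
    return(annotation_set(list(), kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1L]])
  if (ncol1 >= 15L) {              # GAF
    keep <- vapply(fields, function(f) !grepl("NOT", f[[4L]]), logical(1))
    genes <- vapply(fields[keep], `[[`, character(1), 3L)
    terms <- vapply(fields[keep], `[[`, character(1), 5L)
  } else if (ncol1 == 2L) {        # gene<TAB>term
    genes <- vapply(fields, `[[`, character(1), 1L)
    terms <- vapply(fields, `[[`, character(1), 2L)
  } else {
    stop("unrecognized annotation format in ", path,
         " (expected GAF 2.x or gene<TAB>term)")
  }
  if (!is.null(dag)) {
    known <- terms %in% dag$terms
    if (any(!known))
      message("read_annotations: dropped ", sum(!known),
              " annotation(s) with terms absent from the DAG")
    genes <- genes[known]; terms <- terms[known]
  }
  annotation_set(split(terms, genes), kind)
}

#' Genes with no annotation in either set
#'
#' Genes whose target and homolog term sets are both empty produce all-zero
#' feature vectors and cannot be classified; they are flagged "less-studied".
#'
#' @param genes Character vector of gene ids to check.
#' @param target,homolog [annotation_set()] objects.
#' @return Character vector of less-studied gene ids.
#' @export
less_studied_genes <- function(genes, target, homolog) {
  genes[vapply(genes, function(g) {
    length(gene_terms(target, g)) == 0L && length(gene_terms(homolog, g)) == 0L
  }, logical(1))]
}

# ---- networks ----

#' Construct an undirected gene network
#'
#' Vertices are gene ids; edges are undirected with non-negative weight
#' (default 1). Self-loops are rejected; duplicate edges keep the maximum
#' weight so that merging multi-source interaction files is idempotent.
#'
#' @param edges Data frame with columns `from`, `to` and optionally `weight`.
#' @param vertices Optional character vector of vertex ids (vertices with no
#'   edges are allowed); edge endpoints are always included.
#' @return An object of class `gene_network` with elements `vertices` and
#'   `edges` (canonical order: `from < to`).
#' @export
gene_network <- function(edges = NULL, vertices = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, nrow(edges))
    if (anyNA(w) || any(w < 0)) stop("edge weights must be non-negative numbers")
    a <- as.character(edges$from); b <- as.character(edges$to)
    loop <- a == b
    if (any(loop)) {
      warning("dropped ", sum(loop), " self-loop(s)")
      a <- a[!loop]; b <- b[!loop]; w <- w[!loop]
    }
    from <- pmin(a, b); to <- pmax(a, b)
    key <- paste(from, to, sep = "\t")
    if (anyDuplicated(key)) {
      w <- vapply(split(w, key), max, numeric(1))
      from <- sub("\t.*$", "", names(w))
      to <- sub("^.*\t", "", names(w))
    }
    edges <- data.frame(from = from, to = to, weight = as.numeric(w),
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }
  vertices <- sort(unique(c(as.character(vertices), edges$from, edges$to)))
  structure(list(vertices = vertices, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene network:", length(x$vertices), "vertices,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a gene network to an igraph graph
#'
#' @param net A [gene_network()].
#' @return An undirected, weighted `igraph` graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$vertices))
  igraph::E(g)$weight <- net$edges$weight
  g
}

#' Edge-weight lookup f(u, v)
#'
#' @param net A [gene_network()].
#' @param u,v Gene ids.
#' @return The edge weight, or 0 if the edge is absent.
#' @export
edge_weight <- function(net, u, v) {
  from <- pmin(u, v); to <- pmax(u, v)
  idx <- match(paste(from, to, sep = "\t"),
               paste(net$edges$from, net$edges$to, sep = "\t"))
  w <- net$edges$weight[idx]
  w[is.na(w)] <- 0
  w
}

#' Read an undirected network from an edge list
#'
#' Rows are `geneA geneB [weight]`, whitespace- or tab-separated; `#` lines
#' are comments. Reversed duplicates collapse to one undirected edge.
#'
#' @param path Path to the edge-list file.
#' @return A [gene_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vert_lines <- lines[grepl("^#vertex\\s", lines)]
  isolated <- sub("^#vertex\\s+", "", vert_lines)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(gene_network(vertices = isolated))
  fields <- strsplit(trimws(lines), "\\s+")
  n <- lengths(fields)
  if (any(n < 2L)) stop("edge list rows need at least two columns")
  gene_network(data.frame(
    from = vapply(fields, `[[`, character(1), 1L),
    to = vapply(fields, `[[`, character(1), 2L),
    weight = vapply(fields, function(f)
      if (length(f) >= 3L) as.numeric(f[[3L]]) else 1, numeric(1)),
    stringsAsFactors = FALSE), vertices = isolated)
}

#' Write a network as a TSV edge list
#'
#' Edgeless vertices are preserved as `#vertex <id>` comment lines so that a
#' write/read round trip is the identity.
#'
#' @param net A [gene_network()].
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  isolated <- setdiff(net$vertices, c(net$edges$from, net$edges$to))
  if (length(isolated))
    writeLines(paste("#vertex", isolated), con)
  utils::write.table(net$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- complexes ----

#' Construct a complex set
#'
#' @param complexes Named list: complex id -> character vector of subunit gene
#'   ids. Subunit lists are deduplicated.
#' @param min_size Complexes with fewer subunits than this are dropped
#'   (default 3, the size below which substructure is undefined). Use
#'   `min_size = 1` to keep everything.
#' @return An object of class `complex_set`.
#' @export
complex_set <- function(complexes, min_size = 3L) {
  complexes <- lapply(complexes, function(x) unique(as.character(x)))
  complexes <- complexes[lengths(complexes) >= min_size]
  structure(complexes, class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  cat("ComplexSet:", length(x), "complexes; subunit counts ",
      if (length(x)) paste(range(lengths(x)), collapse = "-") else "NA", "\n")
  invisible(x)
}

#' Read a complex membership table
#'
#' Rows are `complexId<TAB>gene` (one subunit per row). Subunits are
#' deduplicated; with `min_size = 3` (the default) complexes with fewer than
#' three subunits are dropped, since no substructure can be defined for them.
#'
#' @param path Path to the table.
#' @param min_size Minimum subunit count to retain a complex.
#' @return A [complex_set()].
#' @export
read_complexes <- function(path, min_size = 3L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(complex_set(list(), min_size))
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 2L)) stop("complex table rows need two columns")
  cid <- vapply(fields, `[[`, character(1), 1L)
  gene <- vapply(fields, `[[`, character(1), 2L)
  complex_set(split(gene, cid), min_size)
}

#' Write a complex membership table
#'
#' @param complexes A [complex_set()].
#' @param path Output path.
#' @export
write_complexes <- function(complexes, path) {
  df <- data.frame(
    complex = rep(names(complexes), lengths(complexes)),
    gene = unlist(complexes, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict an annotation set to one GO namespace
#'
#' @param ann An [annotation_set()].
#' @param dag A [go_dag()] carrying per-term namespaces.
#' @param ns Namespace to keep, or `"all"` (no filtering).
#' @return A filtered [annotation_set()].
#' @export
filter_namespace <- function(ann, dag, ns = "all") {
  if (identical(ns, "all")) return(ann)
  if (is.null(dag$namespace)) stop("DAG carries no namespace information")
  keep <- names(dag$namespace)[dag$namespace == ns]
  annotation_set(lapply(ann$annotations, intersect, keep), ann$kind)
}
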